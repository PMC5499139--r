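# Pedigree gene-drop simulator: LD structure, recombination model,
# Mendelian consistency, penetrance, noise injection, determinism.

test_that("single-block limit makes all markers on a chromosome fully correlated", {
  cfg <- small_config(seed = 2, block_length_bp = 4e5)  # block = chromosome
  set.seed(cfg$seed)
  ginfo <- make_genome(cfg)
  ped <- default_pedigree(20, c(0, 0))
  sites <- recscan:::assemble_sites(cfg, ginfo)
  pool <- simulate_founder_haplotypes(cfg, sites, ped)
  for (ch in unique(sites$chrom)) {
    mk <- sites$kind == "marker" & sites$chrom == ch
    cols <- pool[, sites$site_id[mk], drop = FALSE]
    expect_true(all(cols == cols[, 1]))   # pairwise r^2 = 1
  }
})

test_that("block length 1 gives near-zero LD between adjacent markers", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length_bp = 1e6,
                    n_markers_per_chrom = 200, block_length_bp = 1,
                    genes_per_chrom = 1, causal_chrom_index = 1,
                    causal_gene_slot = 1, n_background_variants = 2)
  set.seed(cfg$seed)
  ginfo <- make_genome(cfg)
  ped <- default_pedigree(200, c(0, 0))
  sites <- recscan:::assemble_sites(cfg, ginfo)
  pool <- simulate_founder_haplotypes(cfg, sites, ped)
  mk <- which(sites$kind == "marker")
  r2 <- vapply(seq_len(length(mk) - 1), function(i) {
    suppressWarnings(cor(pool[, mk[i]], pool[, mk[i + 1]]))^2
  }, numeric(1))
  expect_lt(mean(r2, na.rm = TRUE), 0.1)
})

test_that("marker allele frequencies fall in the configured MAF range in expectation", {
  sim <- simulate_dataset(sim_config(seed = 9, n_extra_founders = 30))
  f_ids <- sim$pedigree$id[is.na(sim$pedigree$sire)]
  freqs <- allele_frequencies(
    genotype_matrix(sim$genotypes$dosage[f_ids, , drop = FALSE],
                    sim$genotypes$map, sim$genotypes$alleles))
  # backbone frequencies are drawn from [0.1, 0.5]; sample noise aside,
  # the bulk must sit inside a modestly widened band
  expect_gt(mean(freqs > 0.05 & freqs < 0.6), 0.9)
})

test_that("identical seed and config reproduce byte-identical artifacts", {
  cfg <- small_config(seed = 17)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  emit_dataset(simulate_dataset(cfg), d1)
  emit_dataset(simulate_dataset(cfg), d2)
  for (f in c("calls.vcf", "array.ped", "array.map", "genome.fa",
              "genes.gff3", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("zero recombination transmits intact parental haplotypes", {
  cfg <- small_config(seed = 4, recombination_rate = 0)
  set.seed(cfg$seed)
  ginfo <- make_genome(cfg)
  ped <- default_pedigree(2, c(2, 0))
  sites <- recscan:::assemble_sites(cfg, ginfo)
  pool <- simulate_founder_haplotypes(cfg, sites, ped)
  haps <- gene_drop(ped, pool, sites, cfg)
  # chromosomes assort independently: compare per chromosome
  for (kid in c("C101", "C102")) {
    for (ch in unique(sites$chrom)) {
      cols <- sites$site_id[sites$chrom == ch]
      from_sire <- haps[paste(kid, 1, sep = "."), cols]
      expect_true(identical(from_sire, haps["SIRE.1", cols]) ||
                    identical(from_sire, haps["SIRE.2", cols]))
    }
  }
})

test_that("gene drop is Mendelian-consistent at every site for every trio", {
  sim <- simulate_dataset(sim_config(seed = 8))
  ped <- sim$pedigree
  haps <- sim$haplotypes
  kids <- ped[!is.na(ped$sire), ]
  dos <- function(id) haps[paste(id, 1, sep = "."), ] +
    haps[paste(id, 2, sep = "."), ]
  for (i in seq_len(nrow(kids))) {
    gk <- dos(kids$id[i]); gs <- dos(kids$sire[i]); gd <- dos(kids$dam[i])
    lo <- (gs == 2) + (gd == 2)
    hi <- 2 - ((gs == 0) + (gd == 0))
    expect_true(all(gk >= lo & gk <= hi), label = kids$id[i])
  }
})

test_that("crossover counts are Poisson with mean rate x Mb / 100", {
  set.seed(99)
  n <- vapply(seq_len(10000), function(i) {
    length(recscan:::sample_crossovers(1, 1e8))   # 1 cM/Mb over 100 Mb
  }, numeric(1))
  expect_equal(mean(n), 1.0, tolerance = 0.05)
})

test_that("an individual with exactly one known parent is rejected", {
  expect_error(pedigree(id = c("a", "b"), sire = c(NA, "a"),
                        dam = c(NA, NA)),
               "exactly one known parent", class = "recscan_pedigree_error")
})

test_that("phenotype is a deterministic function of the causal genotype", {
  sim <- simulate_dataset(small_config(seed = 21))
  dos <- unlist(sim$truth$carrier_state)[sim$pedigree$id]
  expect_identical(sim$pedigree$phenotype == "affected", unname(dos == 2L))
  # every parent of an affected individual carries at least one alt allele
  aff <- sim$pedigree[sim$pedigree$phenotype == "affected", ]
  expect_true(all(dos[unique(c(aff$sire, aff$dam))] >= 1))
})

test_that("carrier x carrier with 4 offspring yields >=1 affected at the binomial rate", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 1e5,
                    n_markers_per_chrom = 5, block_length_bp = 2e4,
                    genes_per_chrom = 1, causal_chrom_index = 1,
                    causal_gene_slot = 1, n_background_variants = 2,
                    n_extra_founders = 0, offspring_per_litter = c(4, 0))
  set.seed(cfg$seed)
  ginfo <- make_genome(cfg)
  ped <- default_pedigree(0, c(4, 0))
  ped <- pedigree(id = setdiff(ped$id, "DAM2"),
                  sire = ped$sire[ped$id != "DAM2"],
                  dam = ped$dam[ped$id != "DAM2"],
                  sex = ped$sex[ped$id != "DAM2"])
  sites <- recscan:::assemble_sites(cfg, ginfo)
  hit <- vapply(seq_len(2000), function(s) {
    set.seed(s)
    pool <- simulate_founder_haplotypes(cfg, sites, ped)
    haps <- gene_drop(ped, pool, sites, cfg)
    out <- assign_phenotypes(haps, ped)
    any(out$phenotype == "affected" & !is.na(out$sire))
  }, logical(1))
  expect_lt(abs(mean(hit) - (1 - (3 / 4)^4)), 0.03)
})

test_that("the causal record is hom-alt in cases and het in their parents", {
  sim <- simulate_dataset(sim_config(seed = 12))
  ck <- which(sim$callset$variants$pos == sim$truth$causal$pos &
                sim$callset$variants$chrom == sim$truth$causal$chrom)
  g <- sim$callset$genotypes[ck, ]
  roles <- recscan:::roles_from_pedigree(sim$pedigree)
  cases <- intersect(names(g), roles$cases)
  parents <- intersect(names(g), roles$parents)
  expect_true(all(g[cases] == "hom_alt"))
  expect_true(all(g[parents] == "het"))
})

test_that("per-annotation filter failures occur at the configured binomial rate", {
  cfg <- sim_config(seed = 31, filter_fail_frac = 0.10,
                    n_background_variants = 200, indel_frac = 0,
                    mnp_frac = 0)
  sim <- simulate_dataset(cfg)
  n_bg <- n_qd_fail <- 0
  v <- sim$callset$variants
  causal <- v$pos == sim$truth$causal$pos & v$chrom == sim$truth$causal$chrom
  n_bg <- sum(!causal)
  n_qd_fail <- sum(v$qd[!causal] < 2.0)
  expect_equal(n_qd_fail, 0.10 * n_bg, tolerance = 8 / (0.1 * n_bg))
})

test_that("causal allele frequency among unrelated founders matches its configured value", {
  sim <- simulate_dataset(sim_config(seed = 6, n_extra_founders = 100,
                                     causal_founder_freq = 0.2))
  extras <- grep("^U", sim$pedigree$id, value = TRUE)
  dos <- unlist(sim$truth$carrier_state)[extras]
  f <- sum(dos) / (2 * length(extras))
  expect_lt(abs(f - 0.2), 0.09)   # binomial: sd ~ 0.028 at 200 alleles
})

test_that("emit_dataset writes a complete, re-readable artifact bundle", {
  sim <- simulate_dataset(small_config(seed = 13))
  out <- tempfile()
  paths <- emit_dataset(sim, out)
  expect_true(all(file.exists(paths)))
  expect_length(paths, 8)
  # refuses to clobber without overwrite
  expect_error(emit_dataset(sim, out), "exists", class = "recscan_io_error")
  back <- read_ped_map(paths[["ped"]], paths[["map"]])
  expect_identical(back$genotypes$dosage, sim$genotypes$dosage)
  truth <- jsonlite::read_json(paths[["truth"]])
  vs <- read_vcf(paths[["vcf"]])
  hit <- which(vs$variants$chrom == truth$causal$chrom &
                 vs$variants$pos == truth$causal$pos)
  expect_length(hit, 1)
  expect_equal(vs$variants$ref[hit], truth$causal$ref)
  expect_equal(vs$variants$alt[hit], truth$causal$alt)
  gen <- read_genome(paths[["fasta"]], paths[["gff"]])
  expect_setequal(names(gen$genes), names(sim$genes))
})
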