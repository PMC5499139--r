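# Recessive concordance scan, haplotype-block clustering, region ranking.

test_that("minor allele follows sample frequency with alt favoured on ties", {
  expect_equal(determine_minor_allele(c(0, 0, 1, 2)), "alt")   # alt freq 3/8
  expect_equal(determine_minor_allele(c(2, 2, 1, 2)), "ref")
  expect_true(is.na(determine_minor_allele(c(0, 0, 0))))       # monomorphic
  expect_equal(determine_minor_allele(c(0, 2, 1, 1)), "alt")   # tie at 0.5
  expect_error(determine_minor_allele(c(NA, NA)),
               class = "recscan_data_error")
})

test_that("the concordance rule requires hom-minor cases, het parents, non-hom-minor controls", {
  cfg <- scan_config(case_ids = c("a", "b"), parent_ids = c("c", "d", "e"),
                     control_ids = c("f", "g", "h", "i"))
  # alt allele count 8/18 < 0.5, so alt is the minor allele
  base <- c(a = 2L, b = 2L, c = 1L, d = 1L, e = 1L, f = 0L, g = 1L,
            h = 0L, i = 0L)
  expect_true(marker_concordant(base, cfg))
  expect_false(marker_concordant(replace(base, "a", 1L), cfg))  # case het
  expect_false(marker_concordant(replace(base, "f", 2L), cfg))  # control hom-minor
  expect_false(marker_concordant(replace(base, "c", 2L), cfg))  # parent hom
  expect_false(marker_concordant(replace(base, "b", NA), cfg))  # strict on missing
  expect_false(marker_concordant(replace(base, "g", NA), cfg))
  # when ref is the minor allele the rule flips: cases hom-ref
  flipped <- c(a = 0L, b = 0L, c = 1L, d = 1L, e = 1L, f = 2L, g = 2L,
               h = 2L, i = 2L)
  expect_true(marker_concordant(flipped, cfg))
  expect_error(marker_concordant(base[1:5], cfg),
               class = "recscan_config_error")
})

test_that("scan requires at least one case and disjoint role sets", {
  expect_error(scan_config(character(), "p1"), class = "recscan_config_error")
  expect_error(scan_config("a", c("a", "b")), class = "recscan_config_error")
})

test_that("scan_markers matches an independent brute-force oracle", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    got <- scan_markers(inst$gm, scan_config(inst$cases, inst$parents,
                                             inst$controls))
    want <- brute_force_scan(inst$gm, inst$cases, inst$parents,
                             inst$controls)
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("clustering joins markers within the window and splits beyond it", {
  map <- marker_map(c("m1", "m2", "m3"), "chr1", c(1e6, 3e6, 9.5e6))
  r <- cluster_regions(c("m1", "m2", "m3"), map, 5e6)
  expect_equal(nrow(r), 2)
  expect_equal(r$n_markers, c(2L, 1L))
  expect_equal(r$start_bp, c(1e6, 9.5e6))
  expect_equal(r$end_bp, c(3e6, 9.5e6))
  # gap exactly equal to the window merges (inclusive comparison)
  map2 <- marker_map(c("a", "b"), "chr1", c(1e6, 6e6))
  expect_equal(nrow(cluster_regions(c("a", "b"), map2, 5e6)), 1)
  expect_equal(nrow(cluster_regions(character(), map2, 5e6)), 0)
})

test_that("regions partition the concordant set with no mergeable pair left", {
  set.seed(42)
  for (i in 1:5) {
    n <- 40
    map <- marker_map(sprintf("m%02d", 1:n),
                      sample(c("chr1", "chr2"), n, replace = TRUE),
                      sample.int(5e7, n))
    picked <- sort(sample(map$marker_id, 15))
    r <- cluster_regions(picked, map, 2e6)
    members <- unlist(r$member_markers)
    expect_setequal(members, picked)
    expect_equal(anyDuplicated(members), 0L)
    expect_equal(sum(r$n_markers), length(picked))
    for (ch in unique(r$chrom)) {
      rc <- r[r$chrom == ch, ]
      rc <- rc[order(rc$start_bp), ]
      if (nrow(rc) > 1)
        expect_true(all(rc$start_bp[-1] - rc$end_bp[-nrow(rc)] > 2e6))
    }
  }
})

test_that("ranking orders by marker count, then density, then coordinate", {
  regions <- cluster_regions(character(0), marker_map("x", "chr1", 1), 1)
  fig <- data.frame(
    chrom = c("chr30", "chr4", "chr20"),
    start_bp = c(25254123L, 556510L, 9562689L),
    end_bp = c(39976525L, 10473708L, 20226838L),
    n_markers = c(103L, 61L, 60L), stringsAsFactors = FALSE)
  fig$density <- fig$n_markers / ((fig$end_bp - fig$start_bp + 1) / 1e6)
  fig$member_markers <- list(character(), character(), character())
  shuffled <- fig[c(2, 3, 1), ]
  ranked <- rank_regions(shuffled)
  expect_equal(ranked$n_markers, c(103L, 61L, 60L))
  expect_equal(ranked$chrom, c("chr30", "chr4", "chr20"))
  # tie on marker count: density decides
  tie <- data.frame(chrom = c("chr1", "chr2"), start_bp = c(1L, 1L),
                    end_bp = c(10000000L, 5000000L),
                    n_markers = c(10L, 10L), density = c(1.0, 2.0))
  tie$member_markers <- list(character(), character())
  expect_equal(rank_regions(tie)$chrom, c("chr2", "chr1"))
  expect_equal(nrow(rank_regions(tie[0, ])), 0)
})

test_that("candidate genes attach to regions by span intersection", {
  genes <- list(
    gA = gene_model("gA", "chr1", "+",
                    data.frame(start = 900, end = 1400),
                    data.frame(start = 1000, end = 1299)),
    gB = gene_model("gB", "chr2", "+",
                    data.frame(start = 100, end = 400),
                    data.frame(start = 150, end = 299)))
  regions <- data.frame(chrom = "chr1", start_bp = 1200L, end_bp = 5000L,
                        n_markers = 3L, density = 1, rank = 1L)
  hits <- select_candidate_genes(regions, genes, c("gA", "gB", "gZ"))
  expect_equal(hits$gene_id, "gA")      # partial overlap included
  expect_equal(attr(hits, "unmatched"), "gZ")
})

test_that("the seeded causal block is fully concordant and its gene is selected", {
  # no-crossover limit: within-block perfect LD with the causal allele is
  # exact (a crossover inside the block during a meiosis can split it)
  sim <- simulate_dataset(sim_config(seed = 14, recombination_rate = 0))
  d <- run_discovery(sim)
  reg <- sim$truth$expected_region
  block_markers <- sim$genotypes$map$marker_id[
    sim$genotypes$map$chrom == reg$chrom &
      sim$genotypes$map$pos_bp >= reg$start_bp &
      sim$genotypes$map$pos_bp <= reg$end_bp]
  expect_gt(length(block_markers), 3)
  expect_true(all(block_markers %in% d$concordant))
  hits <- select_candidate_genes(d$regions, sim$genes, sim$candidate_genes)
  expect_true(sim$truth$causal_gene_id %in% hits$gene_id)
})

test_that("permuting phenotypes destroys concordance", {
  sim <- simulate_dataset(sim_config(seed = 15))
  ids <- sim$pedigree$id
  counts <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    perm <- sample(ids)
    roles <- recscan:::roles_from_pedigree(sim$pedigree)
    cfg <- scan_config(case_ids = perm[seq_along(roles$cases)],
                       parent_ids = perm[length(roles$cases) +
                                           seq_along(roles$parents)])
    length(scan_markers(sim$genotypes, cfg))
  }, numeric(1))
  expect_equal(median(counts), 0)
})
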