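# Shared fixtures, built in code at test time.

# A small, fast simulation used where the full default scale is not needed.
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 2, chrom_length_bp = 4e5,
               n_markers_per_chrom = 40, block_length_bp = 5e4,
               genes_per_chrom = 2, causal_chrom_index = 1,
               causal_gene_slot = 1, n_background_variants = 60)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Gene with the two-exon geometry of interest: 45 bp of CDS in exon 1, so
# CDS position 58 falls 13 bp into exon 2, with codon 20 = AAA (Lys).
causal_geometry_gene <- function(n_codons = 521, strand = "+") {
  utr <- 20L; intron <- 200L; e1_cds <- 45L
  s <- 101L
  cds2_len <- 3L * n_codons - e1_cds
  e1 <- c(s, s + utr + e1_cds - 1L)
  cds1 <- c(s + utr, s + utr + e1_cds - 1L)
  e2s <- e1[2] + intron + 1L
  cds2 <- c(e2s, e2s + cds2_len - 1L)
  e2 <- c(e2s, cds2[2] + utr)
  codons <- c("ATG", rep("AAA", n_codons - 2L), "TAA")
  codons[7] <- "AGC"   # Ser at codon 7 for the synonymous p-name case
  cds_seq <- paste(codons, collapse = "")
  L <- e2[2] + 100L
  seqv <- rep("C", L)
  fwd <- if (strand == "+") cds_seq else recscan:::revcomp(cds_seq)
  seqv[cds1[1]:cds1[2]] <- strsplit(substring(fwd, 1, e1_cds), "")[[1]]
  seqv[cds2[1]:cds2[2]] <- strsplit(substring(fwd, e1_cds + 1), "")[[1]]
  genome <- Biostrings::DNAStringSet(setNames(paste(seqv, collapse = ""),
                                              "chrT"))
  gene <- gene_model("GT_1", "chrT", strand,
                     exons = data.frame(start = c(e1[1], e2[1]),
                                        end = c(e1[2], e2[2])),
                     cds = data.frame(start = c(cds1[1], cds2[1]),
                                      end = c(cds1[2], cds2[2])))
  list(gene = gene, genome = genome, cds_seq = cds_seq,
       # genomic position of CDS position 58 on the plus strand
       pos58 = cds2[1] + (58L - e1_cds) - 1L)
}

# Independent brute-force concordance scan: a literal per-marker,
# per-individual re-evaluation of the selection rule, kept free of any
# package scan code.
brute_force_scan <- function(gm, cases, parents, controls) {
  hits <- character(0)
  for (j in seq_len(ncol(gm$dosage))) {
    d <- gm$dosage[, j]
    dd <- d[!is.na(d)]
    if (length(dd) == 0) next
    fa <- sum(dd) / (2 * length(dd))
    if (fa == 0 || fa == 1) next
    minor_hom <- if (fa <= 0.5) 2L else 0L
    major_hom <- 2L - minor_hom
    ok <- TRUE
    for (id in cases) {
      g <- d[id]
      if (is.na(g) || g != minor_hom) { ok <- FALSE; break }
    }
    if (ok) for (id in parents) {
      g <- d[id]
      if (is.na(g) || g != 1L) { ok <- FALSE; break }
    }
    if (ok) for (id in controls) {
      g <- d[id]
      if (is.na(g) || !(g == 1L || g == major_hom)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, gm$map$marker_id[j])
  }
  hits
}

# Random small genotype instance with role assignment, for oracle tests.
random_instance <- function(seed, n_ind = 10, n_mark = 50) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n_ind))
  dosage <- matrix(sample(c(0:2, NA), n_ind * n_mark, replace = TRUE,
                          prob = c(.35, .3, .25, .1)),
                   n_ind, n_mark, dimnames = list(ids, NULL))
  map <- marker_map(sprintf("m%03d", seq_len(n_mark)), "chr1",
                    sort(sample.int(1e6, n_mark)))
  colnames(dosage) <- map$marker_id
  gm <- genotype_matrix(dosage, map,
                        data.frame(marker_id = map$marker_id, ref = "A",
                                   alt = "T"))
  list(gm = gm, cases = ids[1:2], parents = ids[3:5], controls = ids[6:10])
}

# run scan -> regions -> cascade on a simulated dataset, in memory
run_discovery <- function(sim) {
  roles <- recscan:::roles_from_pedigree(sim$pedigree)
  sc <- scan_config(roles$cases, roles$parents)
  conc <- scan_markers(sim$genotypes, sc)
  regions <- rank_regions(cluster_regions(conc, sim$genotypes$map,
                                          sc$merge_window_bp))
  hits <- select_candidate_genes(regions, sim$genes, sim$candidate_genes)
  cc <- cascade_config(intersect(roles$cases, sim$sequenced_ids),
                       intersect(roles$parents, sim$sequenced_ids))
  cascade <- run_cascade(sim$callset, sim$genes, sim$genome, cc,
                         candidate_intervals = sim$genes[unique(hits$gene_id)],
                         known_sites = sim$known_sites)
  list(concordant = conc, regions = regions, cascade = cascade,
       roles = roles)
}
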