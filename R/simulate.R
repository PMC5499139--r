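# Synthetic-data generator: a small multi-chromosome genome with gene
# models, a multi-generation pedigree segregating a fully penetrant
# autosomal-recessive trait, block-LD array genotypes produced by gene
# dropping with Poisson recombination, and a WGS-style callset carrying the
# seeded causal variant plus configurable background noise. Every pipeline
# stage can therefore be exercised end-to-end without external data.

#' @importFrom stats rnorm
NULL

#' Simulation configuration
#'
#' Defaults describe the study conditions the package targets: a breed-style
#' pedigree (one sire mated to two dams, giving full- and half-sib litters)
#' segregating a fully penetrant recessive trait, megabase-scale LD blocks
#' scaled down to a desk-size genome, a single causal stop-gained SNV at
#' CDS position 58 of a 521-codon gene (codon 20, so the truncated product
#' is 19 residues), and a WGS quartet of two cases plus two parents.
#'
#' @param seed integer RNG seed; all outputs are deterministic in it.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_markers_per_chrom array markers per chromosome (placed on a
#'   jittered grid so coverage is even).
#' @param block_length_bp perfect-LD block size: markers within a block are
#'   fully correlated on a per-block haplotype backbone.
#' @param maf_range range the per-block backbone allele frequency is drawn
#'   from, within (0, 0.5].
#' @param recombination_rate cM per Mb (crossovers per meiosis per
#'   chromosome are Poisson with mean rate x length(Mb)/100; Haldane, no
#'   interference).
#' @param genes_per_chrom gene models per chromosome; each has two exons
#'   with 45 bp of CDS in exon 1, so coding positions past c.45 fall in
#'   exon 2.
#' @param causal_chrom_index,causal_gene_slot which gene carries the causal
#'   variant.
#' @param causal_consequence "stop_gained", "missense" or "synonymous".
#' @param causal_founder_freq causal-allele frequency among the haplotypes
#'   of non-breeding founders (breeding founders are obligate carriers and
#'   start heterozygous).
#' @param n_background_variants,frac_exonic,indel_frac,mnp_frac background
#'   callset composition.
#' @param filter_fail_frac per-annotation failure rate: each hard-filter
#'   annotation applicable to a background record is independently sampled
#'   beyond its threshold at this fraction.
#' @param known_frac fraction of background records flagged as known
#'   population variants (and listed in the emitted known-site file).
#' @param low_score_frac fraction of coding background records given a
#'   deleteriousness score below 0.05 (the rest score >= 0.05; the causal
#'   variant always scores < 0.05; non-coding records are unscored).
#' @param pedigree optional [pedigree()] replacing the default structure.
#' @param n_extra_founders unrelated genotyped controls added to the family.
#' @param offspring_per_litter sizes of the sire x dam1 and sire x dam2
#'   litters.
#' @param sequenced_subset sample ids for the WGS callset; default two
#'   cases plus the first case's parents.
#' @param penetrance fixed at 1: affected iff homozygous-alternate.
#' @param max_retries bounded rejection sampling to guarantee at least two
#'   affected offspring (seed advances deterministically per attempt).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3, chrom_length_bp = 1e6,
                       n_markers_per_chrom = 120, block_length_bp = 1e5,
                       maf_range = c(0.1, 0.5), recombination_rate = 1,
                       genes_per_chrom = 4, causal_chrom_index = 2,
                       causal_gene_slot = 2,
                       causal_consequence = "stop_gained",
                       causal_founder_freq = 0.1,
                       n_background_variants = 240, frac_exonic = 0.2,
                       indel_frac = 0.12, mnp_frac = 0.03,
                       filter_fail_frac = 0.02, known_frac = 0.3,
                       low_score_frac = 0.05,
                       pedigree = NULL, n_extra_founders = 9,
                       offspring_per_litter = c(4, 3),
                       sequenced_subset = NULL,
                       penetrance = 1, max_retries = 1000) {
  if (penetrance != 1)
    stop_recscan("penetrance is fixed at 1 (full-penetrance model)",
                 class = "recscan_config_error")
  if (n_markers_per_chrom < 1 || n_chromosomes < 1 || chrom_length_bp < 1)
    stop_recscan("counts must be positive", class = "recscan_config_error")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_recscan("maf_range must lie within (0, 0.5]",
                 class = "recscan_config_error")
  if (!causal_consequence %in% c("stop_gained", "missense", "synonymous"))
    stop_recscan("unknown causal consequence '%s'", causal_consequence,
                 class = "recscan_config_error")
  structure(as.list(environment()), class = "sim_config")
}

#' Default simulated pedigree
#'
#' One sire mated to two dams (full-sib litter plus half-sib litter, as in
#' family-based recessive mapping designs) and a panel of unrelated
#' genotyped founders serving as population controls.
#'
#' @param n_extra_founders number of unrelated control founders.
#' @param offspring_per_litter integer vector of two litter sizes.
#' @return a [pedigree()].
#' @export
default_pedigree <- function(n_extra_founders = 9,
                             offspring_per_litter = c(4, 3)) {
  ids <- c("SIRE", "DAM1", "DAM2")
  sire <- dam <- rep(NA_character_, 3)
  sex <- c("M", "F", "F")
  for (litter in 1:2) {
    n <- offspring_per_litter[litter]
    if (n > 0) {
      kid <- sprintf("C%d%02d", litter, seq_len(n))
      ids <- c(ids, kid)
      sire <- c(sire, rep("SIRE", n))
      dam <- c(dam, rep(sprintf("DAM%d", litter), n))
      sex <- c(sex, rep(c("M", "F"), length.out = n))
    }
  }
  if (n_extra_founders > 0) {
    ids <- c(ids, sprintf("U%02d", seq_len(n_extra_founders)))
    sire <- c(sire, rep(NA_character_, n_extra_founders))
    dam <- c(dam, rep(NA_character_, n_extra_founders))
    sex <- c(sex, rep(c("F", "M"), length.out = n_extra_founders))
  }
  pedigree(id = ids, sire = sire, dam = dam, sex = sex)
}

NON_STOP_CODONS <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab)[tab != "*"]
})

random_cds <- function(n_codons, fixed = NULL) {
  body <- sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE)
  codons <- c("ATG", body, "TAA")
  if (!is.null(fixed)) codons[as.integer(names(fixed))] <- fixed
  paste(codons, collapse = "")
}

#' Build the synthetic genome and gene models
#'
#' Genes sit mid-block so that the causal variant and its gene share one LD
#' block with array markers on both sides. The causal gene has a 521-codon
#' CDS with codon 20 fixed to AAA (Lys); the causal SNV converts it to a
#' stop (A>T at CDS position 58), a missense (A>G at 58) or a synonymous
#' change (A>G at 60) depending on the configured consequence.
#'
#' @param config a [sim_config()]. Consumes RNG state.
#' @return list with `genome` (DNAStringSet), `genes` (named gene_model
#'   list), and `causal` (chrom, pos, ref, alt, gene_id, cds_pos,
#'   block_start, block_end).
#' @export
make_genome <- function(config) {
  utr <- 20L; intron <- 200L; exon1_cds <- 45L
  genome <- list(); genes <- list(); causal <- NULL
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    L <- as.integer(config$chrom_length_bp)
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (gi in seq_len(config$genes_per_chrom)) {
      gid <- sprintf("G%d_%d", ci, gi)
      is_causal <- ci == config$causal_chrom_index &&
        gi == config$causal_gene_slot
      n_codons <- if (is_causal) 521L else 100L
      center <- L * gi / (config$genes_per_chrom + 1)
      bl <- config$block_length_bp
      block_start <- floor((center - 1) / bl) * bl + 1
      s <- as.integer(block_start + round(0.3 * bl))
      cds2_len <- 3L * n_codons - exon1_cds
      e1 <- c(s, s + utr + exon1_cds - 1L)
      cds1 <- c(s + utr, s + utr + exon1_cds - 1L)
      e2s <- e1[2] + intron + 1L
      cds2 <- c(e2s, e2s + cds2_len - 1L)
      e2 <- c(e2s, cds2[2] + utr)
      strand <- if (is_causal || (ci + gi) %% 2 == 0) "+" else "-"
      fixed <- if (is_causal) c("20" = "AAA") else NULL
      cds_seq <- random_cds(n_codons, fixed)
      fwd <- if (strand == "+") cds_seq else revcomp(cds_seq)
      seqv[cds1[1]:cds1[2]] <- strsplit(substring(fwd, 1, exon1_cds), "")[[1]]
      seqv[cds2[1]:cds2[2]] <- strsplit(substring(fwd, exon1_cds + 1), "")[[1]]
      genes[[gid]] <- gene_model(gid, chrom, strand,
                                 exons = data.frame(start = c(e1[1], e2[1]),
                                                    end = c(e1[2], e2[2])),
                                 cds = data.frame(start = c(cds1[1], cds2[1]),
                                                  end = c(cds1[2], cds2[2])))
      if (is_causal) {
        cpos <- if (config$causal_consequence == "synonymous") 60L else 58L
        alt <- if (config$causal_consequence == "stop_gained") "T" else "G"
        gpos <- cds2[1] + (cpos - exon1_cds) - 1L   # causal gene is '+'
        vb <- floor((gpos - 1) / bl)
        causal <- list(chrom = chrom, pos = gpos,
                       ref = seqv[gpos], alt = alt, gene_id = gid,
                       cds_pos = cpos,
                       block_start = as.integer(vb * bl + 1),
                       block_end = as.integer(min((vb + 1) * bl, L)))
      }
    }
    genome[[chrom]] <- paste(seqv, collapse = "")
  }
  list(genome = Biostrings::DNAStringSet(unlist(genome)),
       genes = genes, causal = causal)
}

ALLELE_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("A", "T"),
                      c("C", "G"), c("C", "T"), c("G", "T"))

marker_sites <- function(config) {
  out <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    n <- config$n_markers_per_chrom
    L <- config$chrom_length_bp
    spacing <- L / n
    pos <- round(spacing * (seq_len(n) - 0.5) +
                   runif(n, -spacing / 3, spacing / 3))
    pos <- pmin(pmax(as.integer(pos), 1L), as.integer(L))
    pos <- sort(unique(pos))
    pair <- ALLELE_PAIRS[sample(nrow(ALLELE_PAIRS), length(pos),
                                replace = TRUE), , drop = FALSE]
    out[[ci]] <- data.frame(
      site_id = sprintf("M%d_%04d", ci, seq_along(pos)),
      chrom = paste0("chr", ci), pos = pos, kind = "marker",
      ref = pair[, 1], alt = pair[, 2], bg_freq = NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

background_sites <- function(config, ginfo) {
  n <- config$n_background_variants
  n_ex <- round(config$frac_exonic * n)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- ginfo$genome
  base_at <- function(chrom, at, len = 1L)
    as.character(Biostrings::subseq(seqs[[chrom]], at, at + len - 1L))
  pos <- integer(n); chrom <- character(n)
  coding_genes <- ginfo$genes
  for (i in seq_len(n)) {
    if (i <= n_ex) {
      g <- coding_genes[[sample(length(coding_genes), 1)]]
      iv <- g$cds[sample(nrow(g$cds), 1), ]
      chrom[i] <- g$chrom
      pos[i] <- sample(iv$start:iv$end, 1)
    } else {
      chrom[i] <- sample(chroms, 1)
      pos[i] <- sample.int(as.integer(config$chrom_length_bp), 1)
    }
  }
  cls <- sample(c("snv", "indel", "mnp"), n, replace = TRUE,
                prob = c(1 - config$indel_frac - config$mnp_frac,
                         config$indel_frac, config$mnp_frac))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    b <- base_at(chrom[i], pos[i])
    if (cls[i] == "snv") {
      ref[i] <- b
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    } else if (cls[i] == "mnp") {
      ref[i] <- base_at(chrom[i], pos[i], 2L)
      alt[i] <- paste0(sample(setdiff(c("A", "C", "G", "T"),
                                      substring(ref[i], 1, 1)), 1),
                       sample(setdiff(c("A", "C", "G", "T"),
                                      substring(ref[i], 2, 2)), 1))
    } else if (runif(1) < 0.5) {     # deletion
      len <- sample(1:3, 1)
      ref[i] <- base_at(chrom[i], pos[i], len + 1L)
      alt[i] <- b
    } else {                          # insertion
      ref[i] <- b
      alt[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                                       replace = TRUE), collapse = ""))
    }
  }
  df <- data.frame(site_id = sprintf("BG%04d", seq_len(n)), chrom = chrom,
                   pos = pos, kind = "background", ref = ref, alt = alt,
                   bg_freq = runif(n, 0.05, 0.4), stringsAsFactors = FALSE)
  # drop clashes with the causal site or duplicated positions
  key <- paste(df$chrom, df$pos)
  df <- df[!duplicated(key) &
             key != paste(ginfo$causal$chrom, ginfo$causal$pos), ,
           drop = FALSE]
  df
}

assemble_sites <- function(config, ginfo) {
  cz <- ginfo$causal
  causal_row <- data.frame(site_id = "CAUSAL", chrom = cz$chrom,
                           pos = cz$pos, kind = "causal", ref = cz$ref,
                           alt = cz$alt, bg_freq = NA_real_,
                           stringsAsFactors = FALSE)
  sites <- rbind(marker_sites(config), causal_row,
                 background_sites(config, ginfo))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

block_of <- function(pos, block_length_bp) (pos - 1) %/% block_length_bp

#' Simulate founder haplotypes with block LD
#'
#' Array markers (and the causal site) are perfectly correlated within
#' non-overlapping LD blocks: every site in a block copies the block's
#' haplotype backbone allele, whose frequency is drawn from `maf_range`.
#' The block containing the causal variant uses the causal-allele
#' assignment instead: breeding founders (those with offspring) start
#' heterozygous, other founders draw the allele at `causal_founder_freq`.
#' Background variant sites are unlinked, with per-site frequencies.
#'
#' @param config a [sim_config()].
#' @param sites site table from the generator.
#' @param ped a [pedigree()].
#' @return 0/1 matrix of (2 x founders) haplotypes x sites; rownames
#'   `id.1`, `id.2`.
#' @export
simulate_founder_haplotypes <- function(config, sites, ped) {
  f_ids <- founders(ped)
  breeding <- f_ids[f_ids %in% c(ped$sire, ped$dam)]
  nh <- 2L * length(f_ids)
  H <- matrix(0L, nrow = nh, ncol = nrow(sites),
              dimnames = list(paste(rep(f_ids, each = 2), 1:2, sep = "."),
                              sites$site_id))
  causal_chrom <- sites$chrom[sites$kind == "causal"]
  causal_block <- block_of(sites$pos[sites$kind == "causal"],
                           config$block_length_bp)
  for (ch in unique(sites$chrom)) {
    in_ch <- sites$chrom == ch & sites$kind %in% c("marker", "causal")
    blocks <- block_of(sites$pos, config$block_length_bp)
    for (b in sort(unique(blocks[in_ch]))) {
      cols <- which(in_ch & blocks == b)
      if (length(causal_chrom) && ch == causal_chrom && b == causal_block) {
        backbone <- integer(nh)
        for (k in seq_along(f_ids)) {
          rows <- c(2L * k - 1L, 2L * k)
          backbone[rows] <- if (f_ids[k] %in% breeding) sample(c(1L, 0L))
                            else rbinom(2, 1, config$causal_founder_freq)
        }
      } else {
        f <- runif(1, config$maf_range[1], config$maf_range[2])
        backbone <- rbinom(nh, 1, f)
      }
      H[, cols] <- backbone
    }
  }
  bg <- which(sites$kind == "background")
  for (j in bg) H[, j] <- rbinom(nh, 1, sites$bg_freq[j])
  H
}

sample_crossovers <- function(recombination_rate, chrom_length_bp) {
  lambda <- recombination_rate * (chrom_length_bp / 1e6) / 100
  k <- rpois(1, lambda)
  if (k == 0) numeric(0) else sort(runif(k, 0, chrom_length_bp))
}

make_gamete <- function(parent_haps, sites, config) {
  gamete <- integer(ncol(parent_haps))
  for (ch in unique(sites$chrom)) {
    cols <- which(sites$chrom == ch)
    bp <- sample_crossovers(config$recombination_rate, config$chrom_length_bp)
    start <- sample(1:2, 1)
    seg <- findInterval(sites$pos[cols], bp)
    use <- ifelse(seg %% 2 == 0, start, 3 - start)
    gamete[cols] <- ifelse(use == 1, parent_haps[1, cols],
                           parent_haps[2, cols])
  }
  gamete
}

#' Drop founder haplotypes through a pedigree
#'
#' Each non-founder receives one recombined haplotype per parent;
#' crossovers per meiosis per chromosome are Poisson with mean
#' `recombination_rate x length(Mb)/100`, placed uniformly (Haldane). The
#' result is Mendelian-consistent by construction.
#'
#' @param ped a [pedigree()].
#' @param pool founder haplotypes from [simulate_founder_haplotypes()].
#' @param sites site table.
#' @param config a [sim_config()].
#' @return 0/1 matrix of (2 x individuals) haplotypes x sites.
#' @export
gene_drop <- function(ped, pool, sites, config) {
  H <- matrix(0L, nrow = 2L * nrow(ped), ncol = nrow(sites),
              dimnames = list(paste(rep(ped$id, each = 2), 1:2, sep = "."),
                              sites$site_id))
  done <- setNames(rep(FALSE, nrow(ped)), ped$id)
  for (f in founders(ped)) {
    H[paste(f, 1:2, sep = "."), ] <- pool[paste(f, 1:2, sep = "."), ]
    done[f] <- TRUE
  }
  while (!all(done)) {
    progress <- FALSE
    for (i in which(!done)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (!done[s] || !done[d]) next
      H[paste(ped$id[i], 1, sep = "."), ] <-
        make_gamete(H[paste(s, 1:2, sep = "."), , drop = FALSE], sites, config)
      H[paste(ped$id[i], 2, sep = "."), ] <-
        make_gamete(H[paste(d, 1:2, sep = "."), , drop = FALSE], sites, config)
      done[ped$id[i]] <- TRUE
      progress <- TRUE
    }
    if (!progress)
      stop_recscan("pedigree cannot be ordered (missing parents?)",
                   class = "recscan_pedigree_error")
  }
  H
}

site_dosage <- function(haps, ped_ids, site_col) {
  h1 <- haps[paste(ped_ids, 1, sep = "."), site_col]
  h2 <- haps[paste(ped_ids, 2, sep = "."), site_col]
  setNames(as.integer(h1 + h2), ped_ids)
}

#' Assign phenotypes under full penetrance
#'
#' Affected iff homozygous for the causal alternate allele; everyone else
#' unaffected. Pure labelling: any resampling to reach a minimum number of
#' affected individuals happens in [simulate_dataset()].
#'
#' @param haps gene-dropped haplotypes.
#' @param ped a [pedigree()].
#' @param causal_site_id column name of the causal site.
#' @return the pedigree with `phenotype` and `role` filled in (cases,
#'   obligate-carrier parents of cases, controls).
#' @export
assign_phenotypes <- function(haps, ped, causal_site_id = "CAUSAL") {
  dos <- site_dosage(haps, ped$id, causal_site_id)
  ped$phenotype <- ifelse(dos == 2L, "affected", "unaffected")
  affected <- ped$id[ped$phenotype == "affected"]
  carrier_parents <- unique(c(ped$sire[ped$id %in% affected],
                              ped$dam[ped$id %in% affected]))
  carrier_parents <- carrier_parents[!is.na(carrier_parents)]
  ped$role <- ifelse(ped$id %in% affected, "case",
                     ifelse(ped$id %in% carrier_parents, "obligate_carrier",
                            "control"))
  ped
}

DOSAGE_TO_GT <- c("hom_ref", "het", "hom_alt")

#' Build the WGS-style callset from gene-dropped haplotypes
#'
#' Emits the causal record plus the background sites, with per-sample
#' genotypes read off the diplotypes of the sequenced subset. Passing
#' records draw call-quality annotations well inside the hard-filter
#' bounds; each applicable annotation of a background record is
#' independently pushed beyond its threshold at the configured failure
#' rate; a fraction are flagged as known
#' population variants; coding background records receive deleteriousness
#' scores (mostly tolerated), the causal record always scores deleterious,
#' and non-coding records are unscored.
#'
#' @param haps gene-dropped haplotypes.
#' @param sites site table.
#' @param ginfo [make_genome()] output.
#' @param config a [sim_config()].
#' @param sequenced_ids sample ids to genotype (must be pedigree members
#'   present in `haps`).
#' @return a [variant_set()].
#' @export
make_wgs_callset <- function(haps, sites, ginfo, config, sequenced_ids) {
  if (!all(paste(sequenced_ids, 1, sep = ".") %in% rownames(haps)))
    stop_recscan("sequenced subset not present in pedigree haplotypes",
                 class = "recscan_config_error")
  vrows <- which(sites$kind %in% c("causal", "background"))
  n <- length(vrows)
  gmat <- matrix("missing", n, length(sequenced_ids),
                 dimnames = list(NULL, sequenced_ids))
  for (r in seq_len(n)) {
    dos <- site_dosage(haps, sequenced_ids, sites$site_id[vrows[r]])
    gmat[r, ] <- DOSAGE_TO_GT[dos + 1L]
  }
  is_causal <- sites$kind[vrows] == "causal"
  cls <- variant_class(sites$ref[vrows], sites$alt[vrows])
  v <- data.frame(chrom = sites$chrom[vrows], pos = sites$pos[vrows],
                  ref = sites$ref[vrows], alt = sites$alt[vrows],
                  qd = runif(n, 10, 35), fs = runif(n, 0, 20),
                  mq = runif(n, 50, 60), haplotype_score = runif(n, 0, 5),
                  mq_ranksum = rnorm(n), readpos_ranksum = rnorm(n),
                  is_known = FALSE, score = NA_real_,
                  stringsAsFactors = FALSE)
  # each applicable annotation fails independently at filter_fail_frac
  pf <- config$filter_fail_frac
  fail_on <- function(applicable) !is_causal & applicable & runif(n) < pf
  snv <- cls == "snv"
  w <- fail_on(TRUE); v$qd[w] <- runif(sum(w), 0, 1.9)
  w <- fail_on(snv); v$fs[w] <- runif(sum(w), 60.5, 120)
  w <- fail_on(!snv); v$fs[w] <- runif(sum(w), 200.5, 400)
  w <- fail_on(snv); v$mq[w] <- runif(sum(w), 10, 39.5)
  w <- fail_on(snv); v$haplotype_score[w] <- runif(sum(w), 13.5, 25)
  w <- fail_on(snv); v$mq_ranksum[w] <- runif(sum(w), -20, -13)
  w <- fail_on(snv); v$readpos_ranksum[w] <- runif(sum(w), -15, -8.5)
  w <- fail_on(!snv); v$readpos_ranksum[w] <- runif(sum(w), -30, -20.5)
  v$is_known <- !is_causal & runif(n) < config$known_frac
  vs <- variant_set(v, gmat)
  ann <- annotate_variants(vs, ginfo$genes, ginfo$genome)
  coding <- ann$region_class == "coding"
  low <- runif(n) < config$low_score_frac
  vs$variants$score[coding & !is_causal] <-
    ifelse(low[coding & !is_causal], runif(sum(coding & !is_causal), 0, 0.049),
           runif(sum(coding & !is_causal), 0.05, 1))
  vs$variants$score[is_causal] <- runif(1, 0.001, 0.04)
  vs
}

#' Simulate a complete dataset
#'
#' Master routine: builds the genome and gene models, lays out array
#' markers and callset sites, simulates founder haplotypes, gene-drops them
#' through the pedigree, labels phenotypes, and assembles array genotypes,
#' the WGS callset and the truth set. Rejection-samples (bounded,
#' deterministic seed advance) until at least two non-founder individuals
#' are affected and no founder is.
#'
#' @param config a [sim_config()].
#' @return object of class `recscan_sim`: list with `config`, `genome`,
#'   `genes`, `pedigree`, `genotypes` (a [genotype_matrix()]), `callset`
#'   (a [variant_set()]), `known_sites`, `candidate_genes`, `truth`,
#'   `sequenced_ids`, `sites`, `haplotypes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  ginfo <- make_genome(config)
  ped0 <- if (is.null(config$pedigree))
    default_pedigree(config$n_extra_founders, config$offspring_per_litter)
  else config$pedigree
  sites <- assemble_sites(config, ginfo)
  f_ids <- founders(ped0)

  ped <- NULL
  for (attempt in seq_len(config$max_retries)) {
    set.seed(config$seed + attempt)
    pool <- simulate_founder_haplotypes(config, sites, ped0)
    haps <- gene_drop(ped0, pool, sites, config)
    cand <- assign_phenotypes(haps, ped0)
    affected <- cand$id[cand$phenotype == "affected"]
    if (length(affected) >= 2 && !any(affected %in% f_ids)) {
      ped <- cand
      break
    }
  }
  if (is.null(ped))
    stop_recscan(
      "no attempt of %d produced >= 2 affected offspring; widen the pedigree or raise causal_founder_freq",
      config$max_retries, class = "recscan_simulation_error")

  mk <- sites$kind == "marker"
  dosage <- t(vapply(ped$id, function(id) {
    as.integer(haps[paste(id, 1, sep = "."), mk] +
                 haps[paste(id, 2, sep = "."), mk])
  }, integer(sum(mk))))
  map <- marker_map(sites$site_id[mk], sites$chrom[mk], sites$pos[mk])
  gm <- genotype_matrix(
    matrix(dosage, nrow = nrow(ped), dimnames = list(ped$id, sites$site_id[mk])),
    map,
    data.frame(marker_id = sites$site_id[mk], ref = sites$ref[mk],
               alt = sites$alt[mk], stringsAsFactors = FALSE))

  cases <- ped$id[ped$role == "case"]
  sequenced <- config$sequenced_subset
  if (is.null(sequenced)) {
    first <- cases[1]
    sequenced <- unique(c(cases[seq_len(min(2, length(cases)))],
                          ped$sire[ped$id == first], ped$dam[ped$id == first]))
  }
  callset <- make_wgs_callset(haps, sites, ginfo, config, sequenced)

  known <- callset$variants[callset$variants$is_known,
                            c("chrom", "pos", "ref", "alt"), drop = FALSE]
  cz <- ginfo$causal
  truth <- list(
    causal = cz[c("chrom", "pos", "ref", "alt", "gene_id", "cds_pos")],
    causal_gene_id = cz$gene_id,
    expected_region = list(chrom = cz$chrom, start_bp = cz$block_start,
                           end_bp = cz$block_end),
    carrier_state = as.list(site_dosage(haps, ped$id, "CAUSAL")))

  structure(list(config = config, genome = ginfo$genome, genes = ginfo$genes,
                 pedigree = ped, genotypes = gm, callset = callset,
                 known_sites = known,
                 candidate_genes = names(ginfo$genes), truth = truth,
                 sequenced_ids = sequenced, sites = sites,
                 haplotypes = haps),
            class = "recscan_sim")
}

#' @export
print.recscan_sim <- function(x, ...) {
  cat(sprintf(
    "<recscan_sim> seed %d: %d individuals (%d affected), %d markers, %d callset records\n",
    x$config$seed, nrow(x$pedigree),
    sum(x$pedigree$phenotype == "affected"), ncol(x$genotypes$dosage),
    n_variants(x$callset)))
  cat(sprintf("causal: %s %s:%d %s>%s (c.%d)\n", x$truth$causal_gene_id,
              x$truth$causal$chrom, x$truth$causal$pos, x$truth$causal$ref,
              x$truth$causal$alt, x$truth$causal$cds_pos))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `array.ped`, `array.map`, `calls.vcf`,
#' `known_sites.tsv`, `candidate_genes.txt` and `truth.json`, all
#' re-readable by the package's readers.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @param overwrite allow clobbering existing files.
#' @return named vector of written paths.
#' @export
emit_dataset <- function(sim, outdir, overwrite = FALSE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_recscan("cannot create '%s'", outdir, class = "recscan_io_error")
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             gff = file.path(outdir, "genes.gff3"),
             ped = file.path(outdir, "array.ped"),
             map = file.path(outdir, "array.map"),
             vcf = file.path(outdir, "calls.vcf"),
             known = file.path(outdir, "known_sites.tsv"),
             genes = file.path(outdir, "candidate_genes.txt"),
             truth = file.path(outdir, "truth.json"))
  if (!overwrite && any(file.exists(paths)))
    stop_recscan("output file exists (use overwrite = TRUE): %s",
                 paths[file.exists(paths)][1], class = "recscan_io_error")
  Biostrings::writeXStringSet(sim$genome, paths[["fasta"]], width = 70)
  write_gff3(sim$genes, paths[["gff"]])
  write_ped_map(sim$pedigree, sim$genotypes, paths[["ped"]], paths[["map"]])
  write_vcf(sim$callset, paths[["vcf"]])
  write_known_sites(sim$known_sites, paths[["known"]])
  writeLines(sim$candidate_genes, paths[["genes"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
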