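# Staged variant-prioritization cascade: hard filters on call-quality
# annotations, known-variant exclusion, candidate-region restriction,
# protein-level consequence classification, inheritance concordance, and a
# deleteriousness gate. Stage order and thresholds follow standard GATK-era
# hard-filtering practice for a fully penetrant recessive quartet design.

#' Cascade configuration
#'
#' Hard-filter thresholds are strict inequalities: a record fails only when
#' an annotation is present and strictly beyond its bound, so records
#' exactly at a threshold pass and absent annotations never fail.
#'
#' @param case_ids affected, expected homozygous-alternate individuals.
#' @param carrier_ids obligate carriers, expected heterozygous.
#' @param control_ids optional unaffected non-carrier individuals, expected
#'   not homozygous-alternate (off by default: the classic quartet design
#'   sequences two cases and two parents only).
#' @param snp_thresholds,indel_thresholds named lists of hard-filter bounds.
#' @param deleteriousness_max keep variants with score strictly below this.
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(case_ids, carrier_ids, control_ids = character(),
                           snp_thresholds = list(
                             QD_min = 2.0, FS_max = 60.0, MQ_min = 40.0,
                             HaplotypeScore_max = 13.0, MQRankSum_min = -12.5,
                             ReadPosRankSum_min = -8.0),
                           indel_thresholds = list(
                             QD_min = 2.0, FS_max = 200.0,
                             ReadPosRankSum_min = -20.0),
                           deleteriousness_max = 0.05) {
  ids <- c(case_ids, carrier_ids, control_ids)
  if (anyDuplicated(ids))
    stop_recscan("case/carrier/control id sets must be disjoint",
                 class = "recscan_config_error")
  if (!all(is.finite(unlist(snp_thresholds))) ||
      !all(is.finite(unlist(indel_thresholds))))
    stop_recscan("thresholds must be finite", class = "recscan_config_error")
  structure(list(case_ids = case_ids, carrier_ids = carrier_ids,
                 control_ids = control_ids,
                 snp_thresholds = snp_thresholds,
                 indel_thresholds = indel_thresholds,
                 deleteriousness_max = deleteriousness_max),
            class = "cascade_config")
}

#' Apply hard filters to one variant record
#'
#' SNVs are tested against the SNP thresholds; insertions, deletions and
#' MNPs against the indel thresholds. Comparisons are strict: fail iff
#' QD < 2.0, FS > 60.0, MQ < 40.0, HaplotypeScore > 13.0,
#' MQRankSum < -12.5, ReadPosRankSum < -8.0 (SNV defaults); indels fail iff
#' QD < 2.0, FS > 200.0, ReadPosRankSum < -20.0. Absent annotations do not
#' fail.
#'
#' @param record one-row slice of a [variant_set()]'s `variants` table.
#' @param config a [cascade_config()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated thresholds).
#' @export
hard_filter <- function(record, config) {
  th <- if (record$variant_class == "snv") config$snp_thresholds
        else config$indel_thresholds
  reasons <- character()
  fails <- function(val, bound, low) {
    !is.na(val) && ((low && val < bound) || (!low && val > bound))
  }
  if (!is.null(th$QD_min) && fails(record$qd, th$QD_min, TRUE))
    reasons <- c(reasons, "QD")
  if (!is.null(th$FS_max) && fails(record$fs, th$FS_max, FALSE))
    reasons <- c(reasons, "FS")
  if (!is.null(th$MQ_min) && fails(record$mq, th$MQ_min, TRUE))
    reasons <- c(reasons, "MQ")
  if (!is.null(th$HaplotypeScore_max) &&
      fails(record$haplotype_score, th$HaplotypeScore_max, FALSE))
    reasons <- c(reasons, "HaplotypeScore")
  if (!is.null(th$MQRankSum_min) &&
      fails(record$mq_ranksum, th$MQRankSum_min, TRUE))
    reasons <- c(reasons, "MQRankSum")
  if (!is.null(th$ReadPosRankSum_min) &&
      fails(record$readpos_ranksum, th$ReadPosRankSum_min, TRUE))
    reasons <- c(reasons, "ReadPosRankSum")
  list(pass = length(reasons) == 0, reasons = reasons)
}

hard_filter_mask <- function(vs, config) {
  vapply(seq_len(n_variants(vs)), function(i) {
    hard_filter(vs$variants[i, ], config)$pass
  }, logical(1))
}

#' Exclude known population variants
#'
#' Matching is on the full `(chrom, pos, ref, alt)` key: a novel allele at a
#' known polymorphic position is retained.
#'
#' @param vs a [variant_set()].
#' @param known_sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (and/or records flagged `is_known` in the set itself).
#' @param use_flag also drop records whose `is_known` flag is set.
#' @return filtered [variant_set()].
#' @export
exclude_known <- function(vs, known_sites = NULL, use_flag = TRUE) {
  drop <- if (use_flag) vs$variants$is_known else rep(FALSE, n_variants(vs))
  if (!is.null(known_sites) && nrow(known_sites) > 0) {
    key <- variant_key(vs)
    known_key <- paste(known_sites$chrom, known_sites$pos, known_sites$ref,
                       known_sites$alt, sep = ":")
    drop <- drop | key %in% known_key
  }
  subset_variants(vs, !drop)
}

#' Restrict a variant set to candidate intervals
#'
#' Keeps records whose position lies within any interval (1-based,
#' inclusive at both ends).
#'
#' @param vs a [variant_set()].
#' @param intervals data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (a ranked region table works directly), or a named list of
#'   [gene_model()] whose spans are used.
#' @return filtered [variant_set()].
#' @export
restrict_to_candidates <- function(vs, intervals) {
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(g) {
      sp <- gene_span(g)
      data.frame(chrom = g$chrom, start_bp = sp[1], end_bp = sp[2],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(intervals) || nrow(intervals) == 0)
    return(subset_variants(vs, rep(FALSE, n_variants(vs))))
  keep <- vapply(seq_len(n_variants(vs)), function(i) {
    any(intervals$chrom == vs$variants$chrom[i] &
          intervals$start_bp <= vs$variants$pos[i] &
          intervals$end_bp >= vs$variants$pos[i])
  }, logical(1))
  subset_variants(vs, keep)
}

#' Test a record for recessive inheritance concordance
#'
#' True iff every case is homozygous-alternate, every carrier is
#' heterozygous, and every configured control is not homozygous-alternate.
#' A missing genotype among cases or carriers fails the record — the
#' mechanized reading of the manual "genotype quality and conformation"
#' check: all sequenced individuals must have called genotypes.
#'
#' @param genotypes named genotype vector for one record
#'   (hom_ref/het/hom_alt/missing).
#' @param config a [cascade_config()].
#' @return logical.
#' @export
inheritance_concordant <- function(genotypes, config) {
  need <- c(config$case_ids, config$carrier_ids, config$control_ids)
  absent <- setdiff(need, names(genotypes))
  if (length(absent) > 0)
    stop_recscan("sample '%s' not present in VCF genotypes", absent[1],
                 class = "recscan_config_error")
  g_case <- genotypes[config$case_ids]
  g_car <- genotypes[config$carrier_ids]
  g_ctl <- genotypes[config$control_ids]
  if (any(g_case == "missing") || any(g_car == "missing")) return(FALSE)
  all(g_case == "hom_alt") && all(g_car == "het") &&
    all(g_ctl != "hom_alt")
}

#' Deleteriousness gate
#'
#' Keeps records whose score is strictly below `deleteriousness_max`.
#' Truncating classes (stop-gained, frameshift) without a score pass —
#' prediction tools routinely leave truncating variants unscored; other
#' unscored records are dropped with a logged reason.
#'
#' @param vs a [variant_set()].
#' @param calls matching [annotate_variants()] rows (for coding class).
#' @param config a [cascade_config()].
#' @return filtered [variant_set()]; attribute `dropped_unscored` counts
#'   records dropped solely for a missing score.
#' @export
deleterious_gate <- function(vs, calls, config) {
  sc <- vs$variants$score
  truncating <- !is.na(calls$coding_class) &
    calls$coding_class %in% c("stop_gained", "frameshift")
  keep <- ifelse(is.na(sc), truncating, sc < config$deleteriousness_max)
  out <- subset_variants(vs, keep)
  attr(out, "dropped_unscored") <- sum(is.na(sc) & !truncating)
  out
}

PROTEIN_ALTERING <- c("missense", "stop_gained", "stop_lost", "start_lost",
                      "frameshift", "inframe_insertion", "inframe_deletion")

#' Run the full prioritization cascade
#'
#' Stages, in order: hard filters; known-variant exclusion; candidate-region
#' restriction; protein-altering consequence classification; inheritance
#' concordance; deleteriousness gate. Per-stage SNV and indel counts are
#' recorded; counts are non-increasing by construction.
#'
#' @param vs a [variant_set()].
#' @param genes named list of [gene_model()].
#' @param genome `DNAStringSet` reference.
#' @param config a [cascade_config()].
#' @param candidate_intervals interval data.frame or gene-model list for
#'   [restrict_to_candidates()]; defaults to the spans of `genes`.
#' @param known_sites optional known-site data.frame for [exclude_known()].
#' @return object of class `cascade_result`: list with `stages` (stage
#'   count table), `survivors` (final [variant_set()]), `calls` (their
#'   consequence annotations).
#' @export
run_cascade <- function(vs, genes, genome, config,
                        candidate_intervals = genes, known_sites = NULL) {
  stages <- data.frame(stage = character(), snv_in = integer(),
                       snv_out = integer(), indel_in = integer(),
                       indel_out = integer(), stringsAsFactors = FALSE)
  count2 <- function(v) {
    snv <- sum(v$variants$variant_class == "snv")
    c(snv = snv, indel = n_variants(v) - snv)
  }
  log_stage <- function(name, vin, vout) {
    ci <- count2(vin); co <- count2(vout)
    rbind(stages, data.frame(stage = name, snv_in = ci[["snv"]],
                             snv_out = co[["snv"]], indel_in = ci[["indel"]],
                             indel_out = co[["indel"]],
                             stringsAsFactors = FALSE))
  }

  s1 <- subset_variants(vs, hard_filter_mask(vs, config))
  stages <- log_stage("hard_filter", vs, s1)

  s2 <- exclude_known(s1, known_sites)
  stages <- log_stage("exclude_known", s1, s2)

  s3 <- restrict_to_candidates(s2, candidate_intervals)
  stages <- log_stage("candidate_regions", s2, s3)

  calls3 <- annotate_variants(s3, genes, genome)
  keep_coding <- !is.na(calls3$coding_class) &
    calls3$coding_class %in% PROTEIN_ALTERING & !calls3$unsupported
  s4 <- subset_variants(s3, keep_coding)
  calls4 <- calls3[keep_coding, , drop = FALSE]
  stages <- log_stage("protein_altering", s3, s4)

  keep_inh <- vapply(seq_len(n_variants(s4)), function(i) {
    inheritance_concordant(s4$genotypes[i, ], config)
  }, logical(1))
  s5 <- subset_variants(s4, keep_inh)
  calls5 <- calls4[keep_inh, , drop = FALSE]
  stages <- log_stage("inheritance", s4, s5)

  s6 <- deleterious_gate(s5, calls5, config)
  sc <- s5$variants$score
  trunc5 <- !is.na(calls5$coding_class) &
    calls5$coding_class %in% c("stop_gained", "frameshift")
  keep_del <- ifelse(is.na(sc), trunc5, sc < config$deleteriousness_max)
  calls6 <- calls5[keep_del, , drop = FALSE]
  stages <- log_stage("deleterious", s5, s6)

  rownames(calls6) <- NULL
  structure(list(stages = stages, survivors = s6, calls = calls6),
            class = "cascade_result")
}

cascade_survivor_table <- function(cascade) {
  v <- cascade$survivors$variants
  if (nrow(v) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene_id = character(),
                      coding_class = character(), hgvs_c = character(),
                      hgvs_p = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             gene_id = cascade$calls$gene_id,
             coding_class = cascade$calls$coding_class,
             hgvs_c = cascade$calls$hgvs_c, hgvs_p = cascade$calls$hgvs_p,
             score = v$score, stringsAsFactors = FALSE)
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final survivors: %d\n", n_variants(x$survivors)))
  invisible(x)
}
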