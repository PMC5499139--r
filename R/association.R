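# Validation statistics: Mendelian segregation checking under a fully
# penetrant autosomal-recessive model, the allelic (2x2, 1 df, no
# continuity correction) chi-square association test, and PLINK-style
# method-of-moments identity-by-descent estimation.

#' Check segregation of one site under an autosomal-recessive model
#'
#' Consistent iff every affected individual is homozygous-alternate, every
#' unaffected individual is not, every parent of an affected carries at
#' least one alternate allele, and every child's genotype is
#' Mendelian-consistent with its parents. Violations name the individual
#' and the broken rule; individuals with missing genotypes or unknown
#' phenotypes are skipped for the phenotype rules.
#'
#' @param genotypes named vector (hom_ref/het/hom_alt/missing) keyed by
#'   individual id.
#' @param ped a [pedigree()].
#' @return list with `consistent` (logical) and `violations` (data.frame
#'   `id`, `rule`).
#' @export
segregation_check <- function(genotypes, ped) {
  viol <- data.frame(id = character(), rule = character(),
                     stringsAsFactors = FALSE)
  add <- function(id, rule) rbind(viol, data.frame(id = id, rule = rule,
                                                   stringsAsFactors = FALSE))
  gt <- function(id) {
    if (!id %in% names(genotypes)) return("missing")
    genotypes[[id]]
  }
  alt_count <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]; g <- gt(id)
    if (g == "missing") next
    if (ped$phenotype[i] == "affected" && g != "hom_alt")
      viol <- add(id, "affected_not_hom_alt")
    if (ped$phenotype[i] == "unaffected" && g == "hom_alt")
      viol <- add(id, "unaffected_hom_alt")
    if (ped$phenotype[i] == "affected") {
      for (p in c(ped$sire[i], ped$dam[i])) {
        if (!is.na(p) && gt(p) == "hom_ref")
          viol <- add(p, "parent_of_affected_without_alt")
      }
    }
    # Mendelian consistency with both parents when all three are called
    if (!is.na(ped$sire[i]) && !is.na(ped$dam[i])) {
      gs <- alt_count[[gt(ped$sire[i])]]; gd <- alt_count[[gt(ped$dam[i])]]
      gc <- alt_count[[g]]
      if (!anyNA(c(gs, gd, gc))) {
        lo <- (gs == 2L) + (gd == 2L)
        hi <- 2L - ((gs == 0L) + (gd == 0L))
        if (gc < lo || gc > hi) viol <- add(id, "mendelian_error")
      }
    }
  }
  viol <- unique(viol)
  list(consistent = nrow(viol) == 0, violations = viol)
}

#' Allelic chi-square association test
#'
#' Builds the 2x2 allelic contingency table (alternate vs reference allele
#' counts in cases and controls; two alleles per genotype) and computes the
#' Pearson chi-square statistic with 1 degree of freedom and no continuity
#' correction. The p-value is the upper-tail chi-square probability,
#' evaluated in double precision (accurate far below 1e-34).
#'
#' @param case_counts,control_counts genotype counts, named or positional
#'   `c(hom_ref, het, hom_alt)`.
#' @return object of class `association_result`: allele counts,
#'   `chi_square`, `df` (1) and `p_value`.
#' @export
allelic_chisq <- function(case_counts, control_counts) {
  as3 <- function(x) {
    if (!is.null(names(x))) x <- x[c("hom_ref", "het", "hom_alt")]
    if (length(x) != 3 || anyNA(x) || any(x < 0))
      stop_recscan("genotype counts must be 3 non-negative values",
                   class = "recscan_data_error")
    as.numeric(x)
  }
  ca <- as3(case_counts); co <- as3(control_counts)
  case_alt <- 2 * ca[3] + ca[2]; case_ref <- 2 * ca[1] + ca[2]
  control_alt <- 2 * co[3] + co[2]; control_ref <- 2 * co[1] + co[2]
  if (case_alt + case_ref == 0 || control_alt + control_ref == 0)
    stop_recscan("need at least one case and one control allele",
                 class = "recscan_data_error")
  if (case_alt + control_alt == 0 || case_ref + control_ref == 0)
    stop_recscan("monomorphic site: allelic chi-square undefined",
                 class = "recscan_data_error")
  a <- case_alt; b <- case_ref; c <- control_alt; d <- control_ref
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  structure(list(case_alt = case_alt, case_ref = case_ref,
                 control_alt = control_alt, control_ref = control_ref,
                 chi_square = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> alleles alt/ref cases %d/%d controls %d/%d\n",
    x$case_alt, x$case_ref, x$control_alt, x$control_ref))
  cat(sprintf("chi-square = %.4g (df = 1), p = %.4g\n", x$chi_square,
              x$p_value))
  invisible(x)
}

#' Per-marker alternate allele frequencies
#'
#' Frequency = alternate dosage sum / (2 x non-missing individuals).
#' Markers with no non-missing call are excluded with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector of alternate-allele frequencies.
#' @export
allele_frequencies <- function(gm) {
  n_ok <- colSums(!is.na(gm$dosage))
  if (any(n_ok == 0))
    warning(sprintf("%d marker(s) with all genotypes missing excluded",
                    sum(n_ok == 0)))
  keep <- n_ok > 0
  freq <- colSums(gm$dosage[, keep, drop = FALSE], na.rm = TRUE) /
    (2 * n_ok[keep])
  freq
}

#' Method-of-moments IBD estimate for one pair
#'
#' PLINK-style estimator: per marker, the expected probabilities of sharing
#' 0/1/2 alleles identical-by-state given 0/1/2 alleles identical-by-descent
#' are computed from sample allele frequencies with the standard
#' finite-sample (falling-factorial) bias corrections, summed over markers,
#' and inverted against the observed IBS counts to give Z0, Z1, Z2.
#' Estimates are clamped to [0,1] and renormalized;
#' PI_HAT = Z1/2 + Z2.
#'
#' @param gm a [genotype_matrix()] containing both individuals.
#' @param pair character vector of two individual ids.
#' @param freqs alternate-allele frequencies per marker (e.g. from
#'   [allele_frequencies()] on a founder panel); markers with frequency
#'   outside (0,1) are dropped as uninformative.
#' @param n_freq_samples number of individuals behind `freqs` (drives the
#'   bias-correction counts); defaults to the matrix size.
#' @param min_markers minimum informative markers required.
#' @return object of class `ibd_estimate` with `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `n_markers`.
#' @export
ibd_mom <- function(gm, pair, freqs = NULL, n_freq_samples = NULL,
                    min_markers = 50) {
  if (length(pair) != 2 || !all(pair %in% rownames(gm$dosage)))
    stop_recscan("pair must name two genotyped individuals",
                 class = "recscan_config_error")
  if (is.null(freqs)) freqs <- allele_frequencies(gm)
  if (is.null(n_freq_samples)) n_freq_samples <- nrow(gm$dosage)
  freqs <- freqs[names(freqs) %in% colnames(gm$dosage)]
  d1 <- gm$dosage[pair[1], names(freqs)]
  d2 <- gm$dosage[pair[2], names(freqs)]
  ok <- !is.na(d1) & !is.na(d2) & freqs > 0 & freqs < 1
  if (sum(ok) < min_markers)
    stop_recscan("only %d informative markers (need >= %d)", sum(ok),
                 min_markers, class = "recscan_estimation_error")
  d1 <- d1[ok]; d2 <- d2[ok]; p <- freqs[ok]

  ibs <- 2L - abs(d1 - d2)
  # an aa x AA pair shares zero alleles IBS even though |dosage diff| = 2
  # is already 0; the other double-het case: dosage 1 vs 1 shares 2 by
  # state under biallelic coding
  obs <- c(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2))

  Tn <- 2 * n_freq_samples          # total alleles behind the frequencies
  x <- p * Tn                       # expected alt-allele count
  y <- (1 - p) * Tn
  ff <- function(v, k) {
    out <- rep(1, length(v))
    for (i in seq_len(k)) out <- out * (v - (i - 1))
    out
  }
  D4 <- ff(Tn, 4); D3 <- ff(Tn, 3); D2 <- ff(Tn, 2)
  e00 <- 2 * ff(x, 2) * ff(y, 2) / D4
  e10 <- 4 * (ff(x, 3) * y + x * ff(y, 3)) / D4
  e20 <- (ff(x, 4) + ff(y, 4) + 4 * ff(x, 2) * ff(y, 2)) / D4
  e11 <- 2 * (ff(x, 2) * y + x * ff(y, 2)) / D3
  e21 <- (ff(x, 3) + ff(y, 3) + ff(x, 2) * y + x * ff(y, 2)) / D3

  S00 <- sum(e00); S10 <- sum(e10); S20 <- sum(e20)
  S11 <- sum(e11); S21 <- sum(e21); S22 <- sum(ok)

  z0 <- obs[1] / S00
  z1 <- (obs[2] - z0 * S10) / S11
  z2 <- (obs[3] - z0 * S20 - z1 * S21) / S22
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  structure(list(pair = pair, Z0 = z[1], Z1 = z[2], Z2 = z[3],
                 PI_HAT = z[2] / 2 + z[3], n_markers = sum(ok)),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("<ibd_estimate> %s - %s: Z0=%.3f Z1=%.3f Z2=%.3f PI_HAT=%.3f (%d markers)\n",
              x$pair[1], x$pair[2], x$Z0, x$Z1, x$Z2, x$PI_HAT, x$n_markers))
  invisible(x)
}
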