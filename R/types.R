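#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rbinom rpois runif setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

GENO_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

stop_recscan <- function(fmt, ..., class = "recscan_error") {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(class, "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

#' Construct a marker map
#'
#' A marker map is the ordered list of array markers with their genomic
#' coordinates (1-based). Markers are sorted by chromosome then position and
#' must carry unique identifiers.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom character vector of chromosome names.
#' @param pos_bp integer vector of 1-based positions.
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chrom`, `pos_bp`, sorted by `(chrom, pos_bp)`.
#' @export
marker_map <- function(marker_id, chrom, pos_bp) {
  pos_bp <- as.integer(pos_bp)
  if (anyDuplicated(marker_id))
    stop_recscan("duplicate marker ids in map (e.g. '%s')",
                 marker_id[duplicated(marker_id)][1], class = "recscan_format_error")
  if (any(pos_bp < 1L))
    stop_recscan("marker positions must be >= 1", class = "recscan_format_error")
  df <- data.frame(marker_id = as.character(marker_id),
                   chrom = as.character(chrom),
                   pos_bp = pos_bp, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos_bp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Construct a genotype matrix
#'
#' Array genotypes coded as alternate-allele dosage: 0, 1, 2 or `NA`
#' (missing). Rows are individuals, columns markers; column order follows the
#' marker map.
#'
#' @param dosage integer matrix, individuals x markers, values in
#'   `{0, 1, 2, NA}`; dimnames give individual and marker ids.
#' @param map a [marker_map()].
#' @param alleles data.frame with columns `marker_id`, `ref`, `alt` giving the
#'   allele labels whose `alt` the dosage counts.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, alleles) {
  if (!inherits(map, "marker_map")) stop_recscan("map must be a marker_map")
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | (dosage >= 0L & dosage <= 2L)
  if (!all(ok))
    stop_recscan("dosage values must be 0, 1, 2 or NA", class = "recscan_format_error")
  if (ncol(dosage) != nrow(map))
    stop_recscan("dosage has %d columns but map has %d markers",
                 ncol(dosage), nrow(map), class = "recscan_format_error")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker_id
  if (!identical(colnames(dosage), map$marker_id))
    dosage <- dosage[, map$marker_id, drop = FALSE]
  alleles <- alleles[match(map$marker_id, alleles$marker_id), , drop = FALSE]
  rownames(alleles) <- NULL
  structure(list(dosage = dosage, map = map, alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Construct a pedigree
#'
#' Individuals with optional sire/dam links, sex, disease phenotype and an
#' analysis role. An individual must have either both parents recorded or
#' neither; parent ids must exist in the pedigree and no individual may be
#' its own ancestor.
#'
#' @param id character vector of individual ids.
#' @param sire,dam character vectors of parent ids, `NA` for founders.
#' @param sex character, "M"/"F"/NA.
#' @param phenotype character, one of "affected", "unaffected", "unknown".
#' @param role character, one of "case", "obligate_carrier", "control",
#'   "unassigned".
#' @return A `data.frame` of class `pedigree`.
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = NA,
                     phenotype = "unknown", role = "unassigned") {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   sire = as.character(rep_len(sire, n)),
                   dam = as.character(rep_len(dam, n)),
                   sex = as.character(rep_len(sex, n)),
                   phenotype = as.character(rep_len(phenotype, n)),
                   role = as.character(rep_len(role, n)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop_recscan("duplicate individual ids", class = "recscan_format_error")
  if (!all(df$phenotype %in% c("affected", "unaffected", "unknown")))
    stop_recscan("phenotype must be affected/unaffected/unknown")
  if (!all(df$role %in% c("case", "obligate_carrier", "control", "unassigned")))
    stop_recscan("unknown role label")
  one_parent <- xor(is.na(df$sire), is.na(df$dam))
  if (any(one_parent))
    stop_recscan("individual '%s' has exactly one known parent (need both or neither)",
                 df$id[one_parent][1], class = "recscan_pedigree_error")
  for (p in c("sire", "dam")) {
    known <- !is.na(df[[p]])
    if (!all(df[[p]][known] %in% df$id))
      stop_recscan("%s '%s' not present in pedigree", p,
                   setdiff(df[[p]][known], df$id)[1], class = "recscan_pedigree_error")
  }
  # cycle check: repeatedly peel individuals whose parents are all peeled
  remaining <- df$id
  repeat {
    peelable <- vapply(remaining, function(i) {
      r <- df[df$id == i, ]
      (is.na(r$sire) || !(r$sire %in% remaining)) &&
        (is.na(r$dam) || !(r$dam %in% remaining))
    }, logical(1))
    if (!any(peelable)) break
    remaining <- remaining[!peelable]
  }
  if (length(remaining) > 0)
    stop_recscan("pedigree contains an ancestry cycle involving '%s'",
                 remaining[1], class = "recscan_pedigree_error")
  class(df) <- c("pedigree", "data.frame")
  df
}

founders <- function(ped) ped$id[is.na(ped$sire) & is.na(ped$dam)]

#' Construct a set of variant records
#'
#' A compact container for biallelic variant calls: a variant table plus a
#' genotype matrix in categorical coding (`hom_ref`, `het`, `hom_alt`,
#' `missing`).
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `qd`, `fs`, `mq`, `haplotype_score`, `mq_ranksum`,
#'   `readpos_ranksum` (NA when the annotation is absent), `is_known`
#'   (logical), `score` (deleteriousness in `[0,1]`, NA when absent).
#' @param genotypes character matrix, variants x samples, values among
#'   `hom_ref`/`het`/`hom_alt`/`missing`; column names are sample ids.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, genotypes) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop_recscan("variants must have columns %s", paste(need, collapse = ", "))
  opt_num <- c("qd", "fs", "mq", "haplotype_score", "mq_ranksum",
               "readpos_ranksum", "score")
  for (nm in opt_num) if (is.null(variants[[nm]]))
    variants[[nm]] <- rep(NA_real_, nrow(variants))
  if (is.null(variants$is_known))
    variants$is_known <- rep(FALSE, nrow(variants))
  if (any(variants$ref == variants$alt))
    stop_recscan("ref and alt alleles must differ", class = "recscan_format_error")
  bad <- !is.na(variants$score) & (variants$score < 0 | variants$score > 1)
  if (any(bad))
    stop_recscan("deleteriousness score outside [0,1]", class = "recscan_format_error")
  variants$variant_class <- variant_class(variants$ref, variants$alt)
  if (nrow(variants) > 0) {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != nrow(variants))
      stop_recscan("genotype matrix rows (%d) != variant rows (%d)",
                   nrow(genotypes), nrow(variants))
    if (!all(genotypes %in% GENO_LEVELS))
      stop_recscan("genotype codes must be hom_ref/het/hom_alt/missing")
  }
  rownames(variants) <- NULL
  structure(list(variants = variants, genotypes = genotypes),
            class = "variant_set")
}

#' Classify variant alleles as snv/insertion/deletion/mnp
#' @param ref,alt character vectors of alleles.
#' @return character vector.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "snv",
         ifelse(lr < la, "insertion",
                ifelse(lr > la, "deletion", "mnp")))
}

n_variants <- function(vs) nrow(vs$variants)

variant_key <- function(vs) {
  with(vs$variants, paste(chrom, pos, ref, alt, sep = ":"))
}

subset_variants <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE],
              vs$genotypes[idx, , drop = FALSE])
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants x %d samples (%s)\n",
              n_variants(x), ncol(x$genotypes),
              paste(names(table(x$variants$variant_class)), collapse = "/")))
  invisible(x)
}

#' Construct a gene model
#'
#' A gene with strand, exons and CDS stored in genomic coordinates (1-based
#' inclusive, ascending); orientation is applied only when projecting to CDS
#' coordinates or translating.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons,cds data.frames with columns `start`, `end` (1-based,
#'   inclusive). CDS intervals must lie within exons and the total CDS length
#'   must be a multiple of 3.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds) {
  if (!strand %in% c("+", "-")) stop_recscan("strand must be '+' or '-'")
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- rownames(cds) <- NULL
  chk <- function(iv, what) {
    if (any(iv$end < iv$start))
      stop_recscan("gene %s: %s interval with end < start", gene_id, what,
                   class = "recscan_model_error")
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
      stop_recscan("gene %s: overlapping %s intervals", gene_id, what,
                   class = "recscan_model_error")
  }
  chk(exons, "exon"); chk(cds, "CDS")
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
  }, logical(1))
  if (!all(in_exon))
    stop_recscan("gene %s: CDS interval outside exons", gene_id,
                 class = "recscan_model_error")
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L)
    stop_recscan("gene %s: CDS length %d not divisible by 3", gene_id, cds_len,
                 class = "recscan_model_error")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, cds_length = cds_len),
            class = "gene_model")
}

gene_span <- function(g) c(min(g$exons$start), max(g$exons$end))

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, sp[1], sp[2], x$strand,
              nrow(x$exons), x$cds_length))
  invisible(x)
}
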