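# Concordance mapping on array genotypes: select markers whose genotype
# configuration matches fully penetrant autosomal-recessive inheritance
# (cases homozygous for the minor allele, obligate-carrier parents
# heterozygous, controls carrying at most one minor allele), cluster the
# concordant markers into haplotype-block regions, and rank regions by
# marker count and density.

#' Scan configuration for concordance mapping
#'
#' @param case_ids,parent_ids,control_ids disjoint individual-id sets.
#'   Cases are affected individuals, parents their obligate-carrier parents;
#'   controls default (at scan time) to all remaining genotyped individuals.
#' @param merge_window_bp markers within this distance join one
#'   haplotype-block region (default 5 Mb, the within-breed LD scale).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(case_ids, parent_ids, control_ids = NULL,
                        merge_window_bp = 5e6) {
  if (length(case_ids) < 1)
    stop_recscan("at least one case id is required", class = "recscan_config_error")
  all_ids <- c(case_ids, parent_ids, control_ids)
  if (anyDuplicated(all_ids))
    stop_recscan("case/parent/control id sets must be disjoint",
                 class = "recscan_config_error")
  if (merge_window_bp <= 0)
    stop_recscan("merge_window_bp must be positive", class = "recscan_config_error")
  structure(list(case_ids = case_ids, parent_ids = parent_ids,
                 control_ids = control_ids,
                 merge_window_bp = as.numeric(merge_window_bp)),
            class = "scan_config")
}

#' Determine the minor allele of a marker
#'
#' The minor allele is the one at sample frequency < 0.5 over all genotyped
#' individuals. Monomorphic markers have no minor allele. An exact 0.5 tie
#' is resolved to the alternate allele (deterministic; flagged downstream).
#'
#' @param dosages integer vector of alt-allele dosages (NA = missing).
#' @return "alt", "ref", or NA (monomorphic).
#' @export
determine_minor_allele <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0)
    stop_recscan("all genotypes missing for marker", class = "recscan_data_error")
  f_alt <- sum(d) / (2 * length(d))
  if (f_alt == 0 || f_alt == 1) return(NA_character_)
  if (f_alt <= 0.5) "alt" else "ref"
}

#' Test one marker for recessive concordance
#'
#' True iff every case is homozygous for the minor allele, every parent is
#' heterozygous, and every control is heterozygous or homozygous for the
#' major allele. A missing genotype in any required individual makes the
#' marker non-concordant (strict rule).
#'
#' @param dosages named integer dosage vector over all genotyped individuals.
#' @param config a [scan_config()].
#' @return logical.
#' @export
marker_concordant <- function(dosages, config) {
  ids <- c(config$case_ids, config$parent_ids, config$control_ids)
  missing_ids <- setdiff(ids, names(dosages))
  if (length(missing_ids) > 0)
    stop_recscan("unknown individual id '%s' in scan config", missing_ids[1],
                 class = "recscan_config_error")
  minor <- determine_minor_allele(dosages)
  if (is.na(minor)) return(FALSE)
  hom_minor <- if (minor == "alt") 2L else 0L
  hom_major <- if (minor == "alt") 0L else 2L
  g_case <- dosages[config$case_ids]
  g_par <- dosages[config$parent_ids]
  g_ctl <- dosages[config$control_ids]
  if (anyNA(g_case) || anyNA(g_par) || anyNA(g_ctl)) return(FALSE)
  all(g_case == hom_minor) && all(g_par == 1L) &&
    all(g_ctl == 1L | g_ctl == hom_major)
}

#' Scan all markers for recessive concordance
#'
#' @param gm a [genotype_matrix()].
#' @param config a [scan_config()]; a NULL `control_ids` is filled with all
#'   genotyped individuals that are neither cases nor parents.
#' @return character vector of concordant marker ids, in map order.
#' @export
scan_markers <- function(gm, config) {
  ids <- rownames(gm$dosage)
  if (is.null(config$control_ids)) {
    config$control_ids <- setdiff(ids, c(config$case_ids, config$parent_ids))
  }
  bad <- setdiff(c(config$case_ids, config$parent_ids, config$control_ids), ids)
  if (length(bad) > 0)
    stop_recscan("scan config references unknown individual '%s'", bad[1],
                 class = "recscan_config_error")
  keep <- vapply(seq_len(ncol(gm$dosage)), function(j) {
    d <- gm$dosage[, j]
    if (all(is.na(d))) return(FALSE)
    marker_concordant(d, config)
  }, logical(1))
  gm$map$marker_id[keep]
}

#' Cluster concordant markers into haplotype-block regions
#'
#' Single-linkage per chromosome: consecutive concordant markers whose gap
#' is at most `merge_window_bp` (inclusive) join one region. Region bounds
#' are the min/max member positions.
#'
#' @param marker_ids concordant marker ids.
#' @param map a [marker_map()].
#' @param merge_window_bp linkage window in bp.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `density` (markers per Mb), `member_markers` (list-column).
#' @export
cluster_regions <- function(marker_ids, map, merge_window_bp = 5e6) {
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer(),
                      density = numeric(), stringsAsFactors = FALSE)
  empty$member_markers <- list()
  if (length(marker_ids) == 0) return(empty)
  sub <- map[map$marker_id %in% marker_ids, , drop = FALSE]
  out <- empty
  for (ch in unique(sub$chrom)) {
    s <- sub[sub$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos_bp), , drop = FALSE]
    gap <- c(Inf, diff(s$pos_bp))
    grp <- cumsum(gap > merge_window_bp)
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      span <- max(m$pos_bp) - min(m$pos_bp) + 1L
      row <- data.frame(chrom = ch, start_bp = min(m$pos_bp),
                        end_bp = max(m$pos_bp), n_markers = nrow(m),
                        density = nrow(m) / (span / 1e6),
                        stringsAsFactors = FALSE)
      row$member_markers <- list(m$marker_id)
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Rank candidate regions
#'
#' Descending by marker count, ties by density descending, then by
#' `(chrom, start_bp)` ascending. The ordering is total and stable.
#'
#' @param regions output of [cluster_regions()].
#' @return the same data.frame, ordered, with a `rank` column prepended.
#' @export
rank_regions <- function(regions) {
  if (nrow(regions) == 0) {
    regions$rank <- integer()
    return(regions[, c("rank", setdiff(names(regions), "rank"))])
  }
  o <- order(-regions$n_markers, -regions$density, regions$chrom,
             regions$start_bp)
  regions <- regions[o, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  regions[, c("rank", setdiff(names(regions), "rank"))]
}

#' Select candidate genes intersecting ranked regions
#'
#' A candidate gene is attached to every region its genomic span intersects
#' (partial overlap counts). Candidate ids with no matching gene model are
#' reported in the `unmatched` attribute rather than raising.
#'
#' @param ranked_regions output of [rank_regions()].
#' @param genes named list of [gene_model()].
#' @param candidate_gene_ids character vector of gene ids to consider.
#' @return data.frame `region_rank`, `gene_id`, `chrom`, `start`, `end`;
#'   attribute `unmatched` lists ids absent from the gene models.
#' @export
select_candidate_genes <- function(ranked_regions, genes, candidate_gene_ids) {
  unmatched <- setdiff(candidate_gene_ids, names(genes))
  hit <- data.frame(region_rank = integer(), gene_id = character(),
                    chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (gid in intersect(candidate_gene_ids, names(genes))) {
    g <- genes[[gid]]
    sp <- gene_span(g)
    for (i in seq_len(nrow(ranked_regions))) {
      r <- ranked_regions[i, ]
      if (g$chrom == r$chrom && sp[1] <= r$end_bp && sp[2] >= r$start_bp) {
        hit <- rbind(hit, data.frame(region_rank = r$rank, gene_id = gid,
                                     chrom = g$chrom, start = sp[1],
                                     end = sp[2], stringsAsFactors = FALSE))
      }
    }
  }
  hit <- hit[order(hit$region_rank, hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  attr(hit, "unmatched") <- unmatched
  hit
}
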