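# End-to-end orchestration: simulate (optional) -> concordance scan ->
# candidate genes -> prioritization cascade -> consequence annotation ->
# segregation / association, with TSV reports and a machine-readable
# summary. Intermediate artifacts are always written to disk and re-read
# through the package's own readers, so a pipeline run also round-trips
# every format.

#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory for reports and (in simulation mode) the
#'   emitted dataset.
#' @param seed integer seed recorded in the summary and driving the
#'   simulation when present.
#' @param simulate NULL for file-based runs, or a (possibly empty) list of
#'   [sim_config()] overrides.
#' @param inputs for file-based runs: named list with `ped`, `map`, `vcf`,
#'   `fasta`, `gff`, and optionally `known`, `candidate_genes`.
#' @param scan optional overrides: `case_ids`, `parent_ids`, `control_ids`,
#'   `merge_window_bp`.
#' @param cascade optional overrides passed to [cascade_config()].
#' @param score_field INFO key of the deleteriousness score in the VCF.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = list(), inputs = NULL,
                       scan = list(), cascade = list(), score_field = "SIFT") {
  if (is.null(simulate) && is.null(inputs))
    stop_recscan("either a simulation block or input paths are required",
                 class = "recscan_config_error")
  if (is.null(simulate)) {
    need <- c("ped", "map", "vcf", "fasta", "gff")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0)
      stop_recscan("missing input path(s): %s",
                   paste(missing, collapse = ", "),
                   class = "recscan_config_error")
    gone <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(gone) > 0)
      stop_recscan("input file does not exist: %s", gone[1],
                   class = "recscan_config_error")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, scan = scan,
                 cascade = cascade, score_field = score_field),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments (`out_dir`, `seed`,
#' `simulate`, `inputs`, `scan`, `cascade`, `score_field`).
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

roles_from_pedigree <- function(ped) {
  cases <- ped$id[ped$phenotype == "affected"]
  parents <- unique(c(ped$sire[ped$id %in% cases],
                      ped$dam[ped$id %in% cases]))
  parents <- setdiff(parents[!is.na(parents)], cases)
  controls <- setdiff(ped$id, c(cases, parents))
  list(cases = cases, parents = parents, controls = controls)
}

#' Run the full discovery pipeline
#'
#' Stages: (optional) dataset simulation and emission; PED/MAP + VCF +
#' genome loading; recessive concordance scan with haplotype-block
#' clustering and ranking; candidate-gene selection; prioritization
#' cascade; segregation and allelic association on the survivors (using
#' the truth diplotypes as an in-silico validation genotyping assay in
#' simulation mode, or the VCF samples otherwise). Writes `regions.tsv`,
#' `cascade.tsv`, `survivors.tsv`, `assoc.tsv` and `summary.json` under
#' `out_dir`. Identical config + seed produces identical outputs.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(sim_config, c(config$simulate,
                                     list(seed = config$seed)))
    sim <- simulate_dataset(sim_cfg)
    data_dir <- file.path(out_dir, "data")
    paths <- emit_dataset(sim, data_dir, overwrite = TRUE)
    inputs <- list(ped = paths[["ped"]], map = paths[["map"]],
                   vcf = paths[["vcf"]], fasta = paths[["fasta"]],
                   gff = paths[["gff"]], known = paths[["known"]],
                   candidate_genes = paths[["genes"]])
  } else inputs <- config$inputs

  pm <- read_ped_map(inputs$ped, inputs$map)
  ped <- pm$pedigree; gm <- pm$genotypes
  gen <- read_genome(inputs$fasta, inputs$gff)
  vs <- read_vcf(inputs$vcf, score_field = config$score_field)
  known <- if (!is.null(inputs$known)) read_known_sites(inputs$known) else NULL
  candidates <- if (!is.null(inputs$candidate_genes))
    readLines(inputs$candidate_genes) else names(gen$genes)

  roles <- roles_from_pedigree(ped)
  sc <- scan_config(
    case_ids = config$scan$case_ids %||% roles$cases,
    parent_ids = config$scan$parent_ids %||% roles$parents,
    control_ids = config$scan$control_ids,
    merge_window_bp = config$scan$merge_window_bp %||% 5e6)
  concordant <- scan_markers(gm, sc)
  regions <- rank_regions(cluster_regions(concordant, gm$map,
                                          sc$merge_window_bp))
  gene_hits <- select_candidate_genes(regions, gen$genes, candidates)
  sel_genes <- gen$genes[unique(gene_hits$gene_id)]

  vcf_samples <- colnames(vs$genotypes)
  cc <- do.call(cascade_config, c(
    list(case_ids = config$cascade$case_ids %||%
           intersect(roles$cases, vcf_samples),
         carrier_ids = config$cascade$carrier_ids %||%
           intersect(roles$parents, vcf_samples)),
    config$cascade[setdiff(names(config$cascade),
                           c("case_ids", "carrier_ids"))]))
  cascade <- run_cascade(vs, gen$genes, gen$genome, cc,
                         candidate_intervals = sel_genes,
                         known_sites = known)

  surv <- cascade_survivor_table(cascade)
  assoc_rows <- NULL; seg_verdicts <- list()
  for (i in seq_len(nrow(surv))) {
    g <- validation_genotypes(surv$chrom[i], surv$pos[i], surv$ref[i],
                              surv$alt[i], sim, vs, ped)
    if (is.null(g)) next
    seg <- segregation_check(g, ped)
    seg_verdicts[[paste0(surv$chrom[i], ":", surv$pos[i])]] <- seg$consistent
    counts <- function(ids) {
      gg <- g[names(g) %in% ids & g != "missing"]
      c(hom_ref = sum(gg == "hom_ref"), het = sum(gg == "het"),
        hom_alt = sum(gg == "hom_alt"))
    }
    unaffected <- ped$id[ped$phenotype == "unaffected"]
    res <- tryCatch(allelic_chisq(counts(roles$cases), counts(unaffected)),
                    error = function(e) NULL)
    if (!is.null(res)) {
      assoc_rows <- rbind(assoc_rows, data.frame(
        site = sprintf("%s:%d:%s:%s", surv$chrom[i], surv$pos[i],
                       surv$ref[i], surv$alt[i]),
        case_alt = res$case_alt, case_ref = res$case_ref,
        control_alt = res$control_alt, control_ref = res$control_ref,
        chi_square = res$chi_square, df = res$df, p_value = res$p_value,
        stringsAsFactors = FALSE))
    }
  }

  report_regions <- regions[, c("rank", "chrom", "start_bp", "end_bp",
                                "n_markers", "density")]
  write_report(cascade = cascade, regions = report_regions,
               associations = assoc_rows %||%
                 data.frame(site = character(), case_alt = integer(),
                            case_ref = integer(), control_alt = integer(),
                            control_ref = integer(), chi_square = numeric(),
                            df = integer(), p_value = numeric()),
               out_dir = out_dir)

  summary <- list(
    seed = config$seed,
    n_concordant_markers = length(concordant),
    top_region = if (nrow(regions) > 0)
      as.list(report_regions[1, ]) else NULL,
    candidate_genes = unique(gene_hits$gene_id),
    survivors = surv,
    segregation_consistent = seg_verdicts,
    association = if (!is.null(assoc_rows)) assoc_rows else list())
  if (!is.null(sim)) summary$truth_causal <- sim$truth$causal
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotypes of every pedigree member at one site: from the simulation
# truth diplotypes when available (the in-silico analog of validation
# genotyping), else from the VCF samples that are pedigree members.
validation_genotypes <- function(chrom, pos, ref, alt, sim, vs, ped) {
  if (!is.null(sim)) {
    hit <- which(sim$sites$chrom == chrom & sim$sites$pos == pos &
                   sim$sites$ref == ref & sim$sites$alt == alt)
    if (length(hit) == 1) {
      dos <- site_dosage(sim$haplotypes, ped$id, sim$sites$site_id[hit])
      return(setNames(DOSAGE_TO_GT[dos + 1L], ped$id))
    }
  }
  key <- which(vs$variants$chrom == chrom & vs$variants$pos == pos &
                 vs$variants$ref == ref & vs$variants$alt == alt)
  if (length(key) != 1) return(NULL)
  g <- vs$genotypes[key, ]
  g <- g[names(g) %in% ped$id]
  if (length(g) == 0) NULL else g
}
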