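# Readers/writers for the standard formats the pipeline touches: plink-style
# PED/MAP, VCF (via vcfR), FASTA (Biostrings), GFF3 (rtracklayer), and the
# pipeline's own tab-separated reports. All coordinates are 1-based inclusive.

PED_PHENO <- c("1" = "unaffected", "2" = "affected", "0" = "unknown",
               "-9" = "unknown")

#' Read a PED/MAP pair into pedigree and genotype objects
#'
#' PED rows carry family id, individual id, sire, dam, sex, phenotype, then
#' two allele columns per marker ("0" = missing allele). Phenotype codes 1/2
#' map to unaffected/affected; 0 and -9 both map to unknown. Because PED
#' files carry no ref/alt polarity, the lexicographically smaller observed
#' allele is taken as the reference and dosage counts the other allele.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return list with elements `pedigree` and `genotypes`
#'   (a [genotype_matrix()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(map_raw) != 4)
    stop_recscan("MAP file must have 4 columns, found %d", ncol(map_raw),
                 class = "recscan_format_error")
  map <- marker_map(marker_id = map_raw[[2]], chrom = map_raw[[1]],
                    pos_bp = as.integer(map_raw[[4]]))
  n_mark <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  lens <- lengths(toks)
  if (any(lens != want))
    stop_recscan("PED line %d has %d fields, expected %d",
                 which(lens != want)[1], lens[lens != want][1], want,
                 class = "recscan_format_error")
  m <- do.call(rbind, toks)
  ids <- m[, 2]
  sire <- ifelse(m[, 3] == "0", NA_character_, m[, 3])
  dam <- ifelse(m[, 4] == "0", NA_character_, m[, 4])
  sex <- c("1" = "M", "2" = "F")[m[, 5]]
  pheno <- PED_PHENO[m[, 6]]
  if (anyNA(pheno))
    stop_recscan("unknown phenotype code '%s'", m[is.na(pheno), 6][1],
                 class = "recscan_format_error")
  ped <- pedigree(id = ids, sire = sire, dam = dam, sex = unname(sex),
                  phenotype = unname(pheno))

  a1 <- m[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE]
  a2 <- m[, 6L + 2L * seq_len(n_mark), drop = FALSE]
  valid <- c("0", "A", "C", "G", "T")
  bad <- !(a1 %in% valid) | !(a2 %in% valid)
  if (any(bad))
    stop_recscan("unknown allele symbol '%s' in PED",
                 c(a1[bad], a2[bad])[1], class = "recscan_format_error")

  # PED missing convention: a genotype is missing iff either allele is "0"
  dosage <- matrix(NA_integer_, nrow = length(ids), ncol = n_mark,
                   dimnames = list(ids, map$marker_id))
  ref <- alt <- rep(NA_character_, n_mark)
  # map columns are sorted; PED columns follow the original MAP row order
  ped_order <- match(map$marker_id, map_raw[[2]])
  for (j in seq_len(n_mark)) {
    x1 <- a1[, ped_order[j]]; x2 <- a2[, ped_order[j]]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2)
      stop_recscan("marker %s has >2 alleles in PED", map$marker_id[j],
                   class = "recscan_format_error")
    if (length(obs) == 0) next
    ref[j] <- obs[1]
    if (length(obs) == 2) alt[j] <- obs[2]
    d <- (x1 == alt[j]) + (x2 == alt[j])
    if (length(obs) == 1) d <- rep(0L, length(x1))
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  alleles <- data.frame(marker_id = map$marker_id, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  list(pedigree = ped,
       genotypes = genotype_matrix(dosage, map, alleles))
}

#' Write a pedigree and genotype matrix as a PED/MAP pair
#'
#' Inverse of [read_ped_map()]; the round trip reproduces dosage exactly when
#' each marker's ref allele sorts before its alt allele (as the simulator
#' guarantees).
#'
#' @param ped a [pedigree()]; @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param family_id family column written to every PED row.
#' @export
write_ped_map <- function(ped, gm, ped_path, map_path, family_id = "FAM1") {
  map <- gm$map
  writeLines(sprintf("%s\t%s\t0\t%d", map$chrom, map$marker_id, map$pos_bp),
             map_path)
  sex_code <- ifelse(is.na(ped$sex), "0", ifelse(ped$sex == "M", "1", "2"))
  ph_code <- c(unaffected = "1", affected = "2", unknown = "0")[ped$phenotype]
  rows <- vapply(seq_len(nrow(ped)), function(i) {
    id <- ped$id[i]
    d <- gm$dosage[id, ]
    ref <- gm$alleles$ref; alt <- gm$alleles$alt
    alt_w <- ifelse(is.na(alt), ref, alt)
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, alt_w, ref))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2L, alt_w, ref))
    paste(c(family_id, id,
            ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
            ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
            sex_code[i], ph_code[i], rbind(g1, g2)), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

INFO_NUM_KEYS <- c(qd = "QD", fs = "FS", mq = "MQ",
                   haplotype_score = "HaplotypeScore",
                   mq_ranksum = "MQRankSum", readpos_ranksum = "ReadPosRankSum")

#' Read a VCF into a variant set
#'
#' Parses a VCF v4.x (plain or bgzipped) with vcfR and validates it into
#' biallelic [variant_set()] records. Multi-allelic sites are split into one
#' record per ALT; genotypes that reference a different ALT are recoded as
#' missing for that record. Absent INFO annotations are recorded as `NA`
#' (absent), never imputed.
#'
#' @param vcf_path path to the VCF.
#' @param score_field INFO key holding the per-variant deleteriousness score
#'   (a probability-like value in `[0,1]`, e.g. a SIFT score).
#' @param known_flag INFO flag marking known population variants.
#' @return A [variant_set()].
#' @export
read_vcf <- function(vcf_path, score_field = "SIFT", known_flag = "KNOWN") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (nrow(fix) == 0)
    return(variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()),
                       matrix(character(), 0, 0)))
  if (is.null(gt) || ncol(gt) < 2)
    stop_recscan("VCF has no sample genotype columns",
                 class = "recscan_format_error")
  fmt_has_gt <- vapply(strsplit(gt[, "FORMAT"], ":"), function(f) "GT" %in% f,
                       logical(1))
  if (!all(fmt_has_gt))
    stop_recscan("VCF record without GT in FORMAT (line for %s:%s)",
                 fix[!fmt_has_gt, "CHROM"][1], fix[!fmt_has_gt, "POS"][1],
                 class = "recscan_format_error")
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop_recscan("malformed POS '%s'", fix[is.na(pos), "POS"][1],
                 class = "recscan_format_error")
  samples <- colnames(gt)[-1]
  gt_idx <- vapply(strsplit(gt[, "FORMAT"], ":"), function(f) match("GT", f),
                   integer(1))

  info_list <- strsplit(ifelse(is.na(fix[, "INFO"]), "", fix[, "INFO"]), ";")
  parse_info <- function(kv) {
    eq <- regmatches(kv, regexpr("=", kv), invert = TRUE)
    keys <- vapply(eq, `[`, character(1), 1)
    vals <- vapply(eq, function(x) if (length(x) > 1) x[2] else NA_character_,
                   character(1))
    setNames(vals, keys)
  }
  infos <- lapply(info_list, parse_info)

  out_var <- list(); out_gt <- list(); k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    info <- infos[[i]]
    num <- vapply(INFO_NUM_KEYS, function(key) {
      if (key %in% names(info)) as.numeric(info[[key]]) else NA_real_
    }, numeric(1))
    score <- if (score_field %in% names(info))
      as.numeric(info[[score_field]]) else NA_real_
    known <- known_flag %in% names(info)
    gt_raw <- vapply(seq_along(samples), function(s) {
      strsplit(gt[i, s + 1L], ":")[[1]][gt_idx[i]]
    }, character(1))
    allele_lists <- strsplit(gt_raw, "[/|]")
    for (a in seq_along(alts)) {
      codes <- vapply(allele_lists, function(al) {
        if (length(al) != 2 || any(al == ".")) return("missing")
        if (!all(al %in% c("0", as.character(a)))) return("missing")
        c("hom_ref", "het", "hom_alt")[sum(al == as.character(a)) + 1L]
      }, character(1))
      k <- k + 1L
      out_var[[k]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = pos[i],
        ref = fix[i, "REF"], alt = alts[a],
        qd = num[["qd"]], fs = num[["fs"]], mq = num[["mq"]],
        haplotype_score = num[["haplotype_score"]],
        mq_ranksum = num[["mq_ranksum"]],
        readpos_ranksum = num[["readpos_ranksum"]],
        is_known = known, score = score, stringsAsFactors = FALSE)
      out_gt[[k]] <- codes
    }
  }
  gmat <- do.call(rbind, out_gt)
  colnames(gmat) <- samples
  variant_set(do.call(rbind, out_var), gmat)
}

num_fmt <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, scientific = FALSE, trim = TRUE, digits = 10))
}

#' Write a variant set as a VCF v4.2 file
#'
#' Deterministic output: fixed header, fixed INFO key order, no timestamps —
#' the same variant set always produces identical bytes.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @param score_field,known_flag INFO keys used for the deleteriousness
#'   score and the known-population-variant flag.
#' @export
write_vcf <- function(vs, path, score_field = "SIFT", known_flag = "KNOWN") {
  v <- vs$variants
  samples <- colnames(vs$genotypes)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=recscan",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype score">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    sprintf('##INFO=<ID=%s,Number=0,Type=Flag,Description="Known population variant">',
            known_flag),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Deleteriousness score">',
            score_field),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    kv <- c(QD = num_fmt(v$qd[i]), FS = num_fmt(v$fs[i]), MQ = num_fmt(v$mq[i]),
            HaplotypeScore = num_fmt(v$haplotype_score[i]),
            MQRankSum = num_fmt(v$mq_ranksum[i]),
            ReadPosRankSum = num_fmt(v$readpos_ranksum[i]))
    info <- paste(sprintf("%s=%s", names(kv)[!is.na(kv)], kv[!is.na(kv)]),
                  collapse = ";")
    parts <- info
    if (v$is_known[i]) parts <- paste(c(parts[nzchar(parts)], known_flag),
                                      collapse = ";")
    if (!is.na(v$score[i]))
      parts <- paste(c(parts[nzchar(parts)],
                       sprintf("%s=%s", score_field, num_fmt(v$score[i]))),
                     collapse = ";")
    if (!nzchar(parts)) parts <- "."
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            parts, "GT", gt_code[vs$genotypes[i, ]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a reference genome and gene models
#'
#' Loads a FASTA (Biostrings) and a GFF3 (rtracklayer) and validates the
#' gene/mRNA/exon/CDS features into [gene_model()] objects. Minus-strand
#' genes keep genomic coordinates; orientation is applied at projection and
#' translation time.
#'
#' @param fasta_path,gff_path input paths.
#' @return list with `genome` (a `DNAStringSet`) and `genes` (named list of
#'   [gene_model()]).
#' @export
read_genome <- function(fasta_path, gff_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  ids <- as.character(df$ID)
  parents <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  gene_rows <- which(df$type == "gene")
  gene_of <- function(row) {
    # walk Parent links up to the enclosing gene feature
    p <- parents[row]
    while (!is.na(p)) {
      hit <- which(ids == p)
      if (!length(hit)) return(NA_character_)
      if (df$type[hit[1]] == "gene") return(ids[hit[1]])
      p <- parents[hit[1]]
    }
    NA_character_
  }
  genes <- list()
  for (gi in gene_rows) {
    gid <- ids[gi]
    sub_rows <- which(df$type %in% c("exon", "CDS"))
    owner <- vapply(sub_rows, gene_of, character(1))
    mine <- sub_rows[!is.na(owner) & owner == gid]
    ex <- df[mine[df$type[mine] == "exon"], c("start", "end"), drop = FALSE]
    cd <- df[mine[df$type[mine] == "CDS"], c("start", "end"), drop = FALSE]
    genes[[gid]] <- gene_model(gid, as.character(df$seqnames[gi]),
                               as.character(df$strand[gi]), ex, cd)
    if (!genes[[gid]]$chrom %in% names(genome))
      stop_recscan("gene %s on sequence '%s' absent from FASTA", gid,
                   genes[[gid]]$chrom, class = "recscan_model_error")
  }
  list(genome = genome, genes = genes)
}

#' Write gene models as GFF3
#'
#' Deterministic gene/mRNA/exon/CDS layout used by the dataset emitter.
#' @param genes named list of [gene_model()].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    sp <- gene_span(g)
    lines <- c(lines,
      sprintf("%s\trecscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, sp[1], sp[2], g$strand, g$gene_id),
      sprintf("%s\trecscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, sp[1], sp[2], g$strand, g$gene_id, g$gene_id),
      sprintf("%s\trecscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              g$chrom, g$exons$start, g$exons$end, g$strand, g$gene_id,
              seq_len(nrow(g$exons)), g$gene_id),
      sprintf("%s\trecscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.t1",
              g$chrom, g$cds$start, g$cds$end, g$strand, g$gene_id,
              seq_len(nrow(g$cds)), g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a known-population-variant site list
#'
#' Tab-separated `chrom pos ref alt`, '#' comments allowed.
#' @param path input path.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_known_sites <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "pos", "ref", "alt"),
                   colClasses = c("character", "integer", "character",
                                  "character"))
  df
}

#' @rdname read_known_sites
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
write_known_sites <- function(sites, path) {
  writeLines(c("#chrom\tpos\tref\talt",
               sprintf("%s\t%d\t%s\t%s", sites$chrom, sites$pos, sites$ref,
                       sites$alt)), path)
  invisible(path)
}

write_tsv_report <- function(df, path, header_cols) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(header_cols, collapse = "\t")), con)
  if (nrow(df) > 0) {
    df <- df[, header_cols, drop = FALSE]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = ".")
  }
  invisible(path)
}

#' Write the pipeline's tab-separated reports
#'
#' Emits `cascade.tsv` (one filter stage per row with SNV/indel survivor
#' counts), `regions.tsv` (ranked concordant regions), and `assoc.tsv`
#' (association results). Files are UTF-8, LF, tab-delimited with a
#' '#'-prefixed header, written in a deterministic column order.
#'
#' @param cascade a [run_cascade()] result, or NULL to skip.
#' @param regions a ranked region data.frame, or NULL.
#' @param associations an association data.frame, or NULL.
#' @param out_dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_report <- function(cascade = NULL, regions = NULL, associations = NULL,
                         out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_recscan("cannot create output directory '%s'", out_dir,
                 class = "recscan_io_error")
  paths <- c()
  if (!is.null(cascade)) {
    p <- file.path(out_dir, "cascade.tsv")
    write_tsv_report(cascade$stages, p,
                     c("stage", "snv_in", "snv_out", "indel_in", "indel_out"))
    sv <- cascade_survivor_table(cascade)
    ps <- file.path(out_dir, "survivors.tsv")
    write_tsv_report(sv, ps, c("chrom", "pos", "ref", "alt", "gene_id",
                               "coding_class", "hgvs_c", "hgvs_p", "score"))
    paths <- c(paths, cascade = p, survivors = ps)
  }
  if (!is.null(regions)) {
    p <- file.path(out_dir, "regions.tsv")
    write_tsv_report(regions, p, c("rank", "chrom", "start_bp", "end_bp",
                                   "n_markers", "density"))
    paths <- c(paths, regions = p)
  }
  if (!is.null(associations)) {
    p <- file.path(out_dir, "assoc.tsv")
    write_tsv_report(associations, p,
                     c("site", "case_alt", "case_ref", "control_alt",
                       "control_ref", "chi_square", "df", "p_value"))
    paths <- c(paths, assoc = p)
  }
  paths
}
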