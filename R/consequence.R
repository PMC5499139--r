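# Codon-level consequence annotation: projection of variants onto gene
# models, classification against the standard genetic code, and HGVS-style
# c./p. naming. This is the machinery that turns "A>T at chr30-like
# coordinates" into "c.58A>T, p.Lys20*".

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "*", X = "Xaa")

codon_table <- function() Biostrings::GENETIC_CODE

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Translate a CDS with the standard genetic code
#'
#' The trailing stop codon is dropped. An internal stop truncates the
#' product; its codon index is reported in the `internal_stop` attribute.
#' Codons containing a base outside ACGT translate to 'X'.
#'
#' @param cds_sequence character scalar, length divisible by 3.
#' @return protein string (one-letter codes), possibly with attribute
#'   `internal_stop` (codon index of the premature stop).
#' @export
translate_cds <- function(cds_sequence) {
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L)
    stop_recscan("CDS length %d not divisible by 3", n,
                 class = "recscan_model_error")
  if (n == 0L) return("")
  tab <- codon_table()
  codons <- substring(toupper(cds_sequence), seq(1, n, 3), seq(3, n, 3))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) return(paste(aa, collapse = ""))
  first <- stop_at[1]
  prot <- paste(aa[seq_len(first - 1L)], collapse = "")
  if (first < length(aa))  # premature: stop before the final codon
    attr(prot, "internal_stop") <- first
  prot
}

#' Length of the truncated product after a stop-gained substitution
#'
#' A premature stop at codon k leaves the k-1 residues preceding it.
#' @param stop_codon_index 1-based codon index of the new stop.
#' @return integer peptide length.
#' @export
truncated_peptide_length <- function(stop_codon_index) {
  if (any(stop_codon_index < 1))
    stop_recscan("stop codon index must be >= 1", class = "recscan_contract_error")
  as.integer(stop_codon_index) - 1L
}

#' Extract the spliced CDS sequence of a gene
#'
#' @param gene a [gene_model()].
#' @param genome a `DNAStringSet` keyed by chromosome.
#' @return CDS sequence in translation order (reverse-complemented for
#'   minus-strand genes).
#' @export
cds_sequence <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, gene$cds$start[i],
                                    gene$cds$end[i]))
  }, character(1))
  fwd <- paste(parts, collapse = "")
  if (gene$strand == "+") fwd else revcomp(fwd)
}

#' Project a genomic position onto a gene's spliced CDS
#'
#' Returns the region class of the position relative to the gene and, for
#' coding positions, the 1-based offset within the spliced CDS in
#' translation order. On minus-strand genes the offset counts from the CDS
#' 3'-most genomic base.
#'
#' @param chrom,pos variant coordinate (1-based).
#' @param gene a [gene_model()].
#' @param ref_len length of the reference allele (used to flag indels that
#'   straddle an exon/CDS boundary as unsupported).
#' @return list with `region_class` (`intergenic`, `intronic`, `exonic_utr`,
#'   `coding`), `cds_pos` (or NA), and `unsupported` (logical).
#' @export
project_to_cds <- function(chrom, pos, gene, ref_len = 1L) {
  out <- list(region_class = "intergenic", cds_pos = NA_integer_,
              unsupported = FALSE)
  if (chrom != gene$chrom) return(out)
  sp <- gene_span(gene)
  last <- pos + ref_len - 1L
  if (last < sp[1] || pos > sp[2]) return(out)
  in_cds <- gene$cds$start <= pos & gene$cds$end >= pos
  end_in_cds <- gene$cds$start <= last & gene$cds$end >= last
  if (ref_len > 1L) {
    # multi-base ref: require full containment in one CDS/exon interval
    contained_cds <- any(gene$cds$start <= pos & gene$cds$end >= last)
    touches_cds <- any(gene$cds$start <= last & gene$cds$end >= pos)
    if (touches_cds && !contained_cds) {
      out$unsupported <- TRUE
      out$region_class <- "coding"
      return(out)
    }
    in_cds <- rep(contained_cds, nrow(gene$cds))
  }
  if (any(in_cds)) {
    iv <- which(in_cds)[1]
    before <- if (iv > 1)
      sum(gene$cds$end[seq_len(iv - 1)] - gene$cds$start[seq_len(iv - 1)] + 1L)
    else 0L
    fwd_off <- before + (pos - gene$cds$start[iv]) + 1L
    out$region_class <- "coding"
    out$cds_pos <- if (gene$strand == "+") fwd_off
                   else gene$cds_length - (fwd_off + ref_len - 1L) + 1L
    return(out)
  }
  in_exon <- any(gene$exons$start <= pos & gene$exons$end >= pos)
  out$region_class <- if (in_exon) "exonic_utr" else "intronic"
  out
}

#' Classify a coding SNV by codon substitution
#'
#' Mutates the codon containing `cds_pos`, translates reference and mutant
#' codons with the standard genetic code, and classifies the change.
#'
#' @param cds_pos 1-based position in the spliced CDS.
#' @param ref_base,alt_base CDS-strand alleles.
#' @param cds_seq the spliced CDS sequence (translation order).
#' @return list with `coding_class`, `codon_index`, `ref_aa`, `alt_aa`
#'   (one-letter, '*' for stop).
#' @export
classify_snv <- function(cds_pos, ref_base, alt_base, cds_seq) {
  if (cds_pos < 1 || cds_pos > nchar(cds_seq))
    stop_recscan("cds_pos %d outside CDS of length %d", cds_pos,
                 nchar(cds_seq), class = "recscan_contract_error")
  have <- toupper(substring(cds_seq, cds_pos, cds_pos))
  if (have != toupper(ref_base))
    stop_recscan(
      "reference mismatch at CDS position %d: model has '%s', variant ref '%s'",
      cds_pos, have, ref_base, class = "recscan_reference_error")
  codon_index <- ((cds_pos - 1L) %/% 3L) + 1L
  cstart <- 3L * (codon_index - 1L) + 1L
  ref_codon <- toupper(substring(cds_seq, cstart, cstart + 2L))
  within <- cds_pos - cstart + 1L
  alt_codon <- ref_codon
  substring(alt_codon, within, within) <- toupper(alt_base)
  tab <- codon_table()
  ref_aa <- unname(tab[ref_codon]); alt_aa <- unname(tab[alt_codon])
  if (is.na(ref_aa)) ref_aa <- "X"
  if (is.na(alt_aa)) alt_aa <- "X"
  coding_class <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else if (codon_index == 1L && ref_codon == "ATG") "start_lost"
    else "missense"
  list(coding_class = coding_class, codon_index = codon_index,
       ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Classify a coding indel as in-frame or frameshift
#'
#' @param cds_pos 1-based CDS position of the indel.
#' @param indel_length number of inserted or deleted bases (> 0).
#' @param kind "insertion" or "deletion".
#' @return coding class string.
#' @export
classify_indel <- function(cds_pos, indel_length, kind) {
  if (indel_length < 1)
    stop_recscan("indel length must be positive", class = "recscan_contract_error")
  if (indel_length %% 3L == 0L) {
    if (kind == "insertion") "inframe_insertion" else "inframe_deletion"
  } else "frameshift"
}

#' HGVS-style c. and p. names for a coding SNV call
#'
#' @param cds_pos CDS position; @param ref_base,alt_base CDS-strand alleles.
#' @param call result of [classify_snv()].
#' @return list with `hgvs_c`, `hgvs_p`. Synonymous changes are named
#'   `p.Xxx{codon}=`; stops use '*'; start-loss uses the `p.Met1?` form.
#' @export
hgvs_names <- function(cds_pos, ref_base, alt_base, call) {
  if (is.null(call$coding_class) || is.na(call$codon_index))
    stop_recscan("hgvs_names requires a coding call with a codon index",
                 class = "recscan_contract_error")
  hgvs_c <- sprintf("c.%d%s>%s", cds_pos, toupper(ref_base), toupper(alt_base))
  ref3 <- unname(AA_THREE[call$ref_aa])
  alt3 <- unname(AA_THREE[call$alt_aa])
  hgvs_p <- switch(call$coding_class,
    synonymous = sprintf("p.%s%d=", ref3, call$codon_index),
    stop_gained = sprintf("p.%s%d*", ref3, call$codon_index),
    stop_lost = sprintf("p.*%d%sext", call$codon_index, alt3),
    start_lost = "p.Met1?",
    sprintf("p.%s%d%s", ref3, call$codon_index, alt3))
  list(hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

#' Annotate a variant set against gene models
#'
#' For every record, finds the containing gene (if any), projects the
#' position onto the spliced CDS, classifies the consequence and formats
#' HGVS names. SNVs get full codon-level resolution; indels are classified
#' in-frame/frameshift; MNPs are reported as class "mnp" without amino-acid
#' resolution. Indels straddling a CDS boundary are flagged unsupported and
#' left unclassified.
#'
#' @param vs a [variant_set()].
#' @param genes named list of [gene_model()].
#' @param genome `DNAStringSet` reference.
#' @return data.frame with one row per variant: `gene_id`, `region_class`,
#'   `coding_class`, `cds_pos`, `codon_index`, `ref_aa`, `alt_aa`, `hgvs_c`,
#'   `hgvs_p`, `unsupported`.
#' @export
annotate_variants <- function(vs, genes, genome) {
  v <- vs$variants
  n <- nrow(v)
  out <- data.frame(
    gene_id = rep(NA_character_, n), region_class = rep("intergenic", n),
    coding_class = rep(NA_character_, n), cds_pos = rep(NA_integer_, n),
    codon_index = rep(NA_integer_, n), ref_aa = rep(NA_character_, n),
    alt_aa = rep(NA_character_, n), hgvs_c = rep(NA_character_, n),
    hgvs_p = rep(NA_character_, n), unsupported = rep(FALSE, n),
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  cds_cache <- list()
  for (i in seq_len(n)) {
    hit <- NULL
    for (g in genes) {
      if (g$chrom != v$chrom[i]) next
      sp <- gene_span(g)
      if (v$pos[i] >= sp[1] && v$pos[i] <= sp[2]) { hit <- g; break }
    }
    if (is.null(hit)) next
    proj <- project_to_cds(v$chrom[i], v$pos[i], hit, nchar(v$ref[i]))
    out$gene_id[i] <- hit$gene_id
    out$region_class[i] <- proj$region_class
    out$unsupported[i] <- proj$unsupported
    if (proj$region_class != "coding" || proj$unsupported) next
    out$cds_pos[i] <- proj$cds_pos
    cls <- v$variant_class[i]
    if (cls == "snv") {
      if (is.null(cds_cache[[hit$gene_id]]))
        cds_cache[[hit$gene_id]] <- cds_sequence(hit, genome)
      seq <- cds_cache[[hit$gene_id]]
      ref_c <- if (hit$strand == "+") v$ref[i] else complement_base(v$ref[i])
      alt_c <- if (hit$strand == "+") v$alt[i] else complement_base(v$alt[i])
      call <- classify_snv(proj$cds_pos, ref_c, alt_c, seq)
      nm <- hgvs_names(proj$cds_pos, ref_c, alt_c, call)
      out$coding_class[i] <- call$coding_class
      out$codon_index[i] <- call$codon_index
      out$ref_aa[i] <- call$ref_aa
      out$alt_aa[i] <- call$alt_aa
      out$hgvs_c[i] <- nm$hgvs_c
      out$hgvs_p[i] <- nm$hgvs_p
    } else if (cls %in% c("insertion", "deletion")) {
      len <- abs(nchar(v$ref[i]) - nchar(v$alt[i]))
      out$coding_class[i] <- classify_indel(proj$cds_pos, len, cls)
    } else {
      out$coding_class[i] <- "mnp"
    }
  }
  out
}
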