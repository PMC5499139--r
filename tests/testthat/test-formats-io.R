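# PED/MAP, VCF, FASTA/GFF3 and report I/O.

write_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

test_that("PED/MAP decoding maps alleles, phenotypes and missingness", {
  map <- write_tmp("1\tsnp1\t0\t500", ".map")
  ped <- write_tmp(c("FAM d1 0 0 1 2 T T",
                     "FAM d2 0 0 2 1 A T",
                     "FAM d3 0 0 1 1 A A",
                     "FAM d4 0 0 2 0 0 0"), ".ped")
  r <- read_ped_map(ped, map)
  expect_equal(r$pedigree$phenotype, c("affected", "unaffected",
                                       "unaffected", "unknown"))
  expect_equal(r$pedigree$sex, c("M", "F", "M", "F"))
  # lexicographically smaller observed allele is REF: dosage counts T
  expect_equal(unname(r$genotypes$dosage[, "snp1"]), c(2L, 1L, 0L, NA))
  expect_equal(r$genotypes$alleles$ref, "A")
  expect_equal(r$genotypes$alleles$alt, "T")
})

test_that("phenotype code -9 also maps to unknown", {
  map <- write_tmp("1\tsnp1\t0\t500", ".map")
  ped <- write_tmp("FAM d1 0 0 1 -9 A A", ".ped")
  expect_equal(read_ped_map(ped, map)$pedigree$phenotype, "unknown")
})

test_that("malformed PED rows raise format errors naming the problem", {
  map <- write_tmp("1\tsnp1\t0\t500", ".map")
  short <- write_tmp("FAM d1 0 0 1 2 T", ".ped")
  expect_error(read_ped_map(short, map), "fields",
               class = "recscan_format_error")
  badallele <- write_tmp("FAM d1 0 0 1 2 T Z", ".ped")
  expect_error(read_ped_map(badallele, map), "allele",
               class = "recscan_format_error")
})

test_that("PED/MAP round trip reproduces dosage and phenotypes exactly", {
  sim <- simulate_dataset(small_config(seed = 11))
  pedf <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_ped_map(sim$pedigree, sim$genotypes, pedf, mapf)
  back <- read_ped_map(pedf, mapf)
  expect_identical(back$genotypes$dosage, sim$genotypes$dosage)
  expect_identical(back$pedigree$phenotype, sim$pedigree$phenotype)
  expect_identical(back$pedigree$sire, sim$pedigree$sire)
})

vcf_header <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
  '##INFO=<ID=FS,Number=1,Type=Float,Description="fs">',
  '##INFO=<ID=KNOWN,Number=0,Type=Flag,Description="known">',
  '##INFO=<ID=SIFT,Number=1,Type=Float,Description="score">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"))

test_that("VCF genotypes and INFO annotations decode into domain records", {
  vcf <- write_tmp(c(vcf_header, paste(
    c("chr1", "100", ".", "A", "T", ".", "PASS", "QD=1.5;FS=3.0", "GT",
      "1/1", "0/1", "0/1", "0/0"), collapse = "\t")), ".vcf")
  vs <- read_vcf(vcf)
  expect_equal(nrow(vs$variants), 1)
  expect_equal(unname(vs$genotypes[1, ]),
               c("hom_alt", "het", "het", "hom_ref"))
  expect_equal(vs$variants$qd, 1.5)
  expect_equal(vs$variants$fs, 3.0)
  expect_true(is.na(vs$variants$mq))           # absent, never imputed
  expect_true(is.na(vs$variants$score))
  expect_false(vs$variants$is_known)
})

test_that("VCF INFO parsing is key-order invariant", {
  row <- function(info) paste(c("chr1", "100", ".", "A", "T", ".", "PASS",
                                info, "GT", "0/1", "0/0", "0/0", "0/0"),
                              collapse = "\t")
  v1 <- read_vcf(write_tmp(c(vcf_header, row("QD=5;FS=2;SIFT=0.3;KNOWN")),
                           ".vcf"))
  v2 <- read_vcf(write_tmp(c(vcf_header, row("KNOWN;SIFT=0.3;FS=2;QD=5")),
                           ".vcf"))
  expect_identical(v1$variants, v2$variants)
})

test_that("multi-allelic sites split per ALT with cross-ALT genotypes missing", {
  vcf <- write_tmp(c(vcf_header, paste(
    c("chr1", "100", ".", "A", "T,G", ".", "PASS", "QD=5", "GT",
      "1/1", "0/2", "1/2", "0/0"), collapse = "\t")), ".vcf")
  vs <- read_vcf(vcf)
  expect_equal(nrow(vs$variants), 2)
  expect_equal(vs$variants$alt, c("T", "G"))
  # record for ALT=T: 0/2 and 1/2 reference the other ALT -> missing
  expect_equal(unname(vs$genotypes[1, ]),
               c("hom_alt", "missing", "missing", "hom_ref"))
  expect_equal(unname(vs$genotypes[2, ]),
               c("missing", "het", "missing", "hom_ref"))
})

test_that("VCF round trip preserves records and genotypes", {
  sim <- simulate_dataset(small_config(seed = 5))
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$callset, p)
  back <- read_vcf(p)
  expect_equal(back$variants$pos, sim$callset$variants$pos)
  expect_identical(unname(back$genotypes), unname(sim$callset$genotypes))
  expect_equal(back$variants$qd, sim$callset$variants$qd, tolerance = 1e-8)
  expect_equal(back$variants$score, sim$callset$variants$score,
               tolerance = 1e-8)
  expect_identical(back$variants$is_known, sim$callset$variants$is_known)
})

test_that("FASTA+GFF3 load into validated gene models", {
  fa <- write_tmp(c(">chrA", strrep("ACGT", 100)), ".fa")
  gff_ok <- write_tmp(c(
    "##gff-version 3",
    "chrA\tx\tgene\t90\t180\t.\t+\t.\tID=g1",
    "chrA\tx\tmRNA\t90\t180\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrA\tx\texon\t90\t180\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
    "chrA\tx\tCDS\t101\t160\t.\t+\t0\tID=g1.c1;Parent=g1.t1"), ".gff3")
  g <- read_genome(fa, gff_ok)
  expect_named(g$genes, "g1")
  expect_equal(g$genes$g1$cds_length, 60L)
})

test_that("a CDS length not divisible by 3 raises a model error naming the gene", {
  fa <- write_tmp(c(">chrA", strrep("ACGT", 100)), ".fa")
  gff_bad <- write_tmp(c(
    "##gff-version 3",
    "chrA\tx\tgene\t90\t180\t.\t+\t.\tID=g1",
    "chrA\tx\tmRNA\t90\t180\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrA\tx\texon\t90\t180\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
    "chrA\tx\tCDS\t101\t159\t.\t+\t0\tID=g1.c1;Parent=g1.t1"), ".gff3")
  expect_error(read_genome(fa, gff_bad), "g1", class = "recscan_model_error")
})

test_that("minus-strand multi-exon genes keep ascending genomic exon order", {
  fa <- write_tmp(c(">chrA", strrep("ACGT", 100)), ".fa")
  gff <- write_tmp(c(
    "##gff-version 3",
    "chrA\tx\tgene\t50\t200\t.\t-\t.\tID=g2",
    "chrA\tx\tmRNA\t50\t200\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chrA\tx\texon\t150\t200\t.\t-\t.\tID=g2.e1;Parent=g2.t1",
    "chrA\tx\texon\t50\t100\t.\t-\t.\tID=g2.e2;Parent=g2.t1",
    "chrA\tx\tCDS\t160\t189\t.\t-\t0\tID=g2.c1;Parent=g2.t1",
    "chrA\tx\tCDS\t61\t90\t.\t-\t0\tID=g2.c2;Parent=g2.t1"), ".gff3")
  g <- read_genome(fa, gff)
  expect_equal(g$genes$g2$strand, "-")
  expect_equal(g$genes$g2$exons$start, c(50, 150))
  expect_equal(g$genes$g2$cds$start, c(61, 160))
})

test_that("report writer emits deterministic headers and survivor names", {
  sim <- simulate_dataset(small_config(seed = 5))
  d <- run_discovery(sim)
  out <- tempfile()
  write_report(cascade = d$cascade,
               regions = d$regions[, c("rank", "chrom", "start_bp", "end_bp",
                                       "n_markers", "density")],
               out_dir = out)
  casc <- readLines(file.path(out, "cascade.tsv"))
  expect_equal(casc[1], "#stage\tsnv_in\tsnv_out\tindel_in\tindel_out")
  expect_length(casc, 1 + nrow(d$cascade$stages))
  # survivor rows round-trip the in-memory HGVS names
  sv <- read.table(file.path(out, "survivors.tsv"), sep = "\t",
                   comment.char = "#",
                   col.names = c("chrom", "pos", "ref", "alt", "gene_id",
                                 "coding_class", "hgvs_c", "hgvs_p", "score"))
  expect_equal(sv$hgvs_c, d$cascade$calls$hgvs_c)
  expect_equal(sv$hgvs_p, d$cascade$calls$hgvs_p)
})

test_that("an empty cascade yields header-only report files", {
  empty_vs <- variant_set(data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character()),
                          matrix(character(), 0, 0))
  sim <- simulate_dataset(small_config(seed = 5))
  cc <- cascade_config("C101", "SIRE")
  cas <- run_cascade(empty_vs, sim$genes, sim$genome, cc)
  out <- tempfile()
  write_report(cascade = cas, out_dir = out)
  expect_length(readLines(file.path(out, "survivors.tsv")), 1)
  expect_true(all(cas$stages$snv_out == 0))
})
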