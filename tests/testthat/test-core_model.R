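test_that("VCF records parse with the stated coordinate and split rules", {
  vcf <- tiny_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:RD:AD:FREQ\t0/1:15:5:25%",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT:RD:AD:FREQ\t0/1:10:4,6:.",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:RD:AD:FREQ\t0/1:10:5:33%"))
  v <- parse_variant_records(vcf, sample_id = "s1")
  expect_equal(nrow(v), 3L)
  expect_equal(v$pos0[1], 99L)           # POS - 1
  expect_equal(v$af[1], 0.25)
  # multi-allelic split: two rows at the same pos0
  expect_equal(v$pos0[2:3], c(199L, 199L))
  expect_equal(v$alt[2:3], c("G", "T"))
  expect_equal(v$alt_depth[2:3], c(4L, 6L))
  # indel skipped and counted
  expect_equal(attr(v, "skipped_nonsnv"), 1L)
})

test_that("VCF dialect fallback and error contracts work", {
  v <- parse_variant_records(tiny_vcf(
    "chr2\t50\t.\tT\tC\t.\tPASS\t.\tGT:DP:AD\t0/1:40:30,10"))
  expect_equal(v$total_depth, 40L)
  expect_equal(v$alt_depth, 10L)
  expect_error(parse_variant_records(c("not a vcf", "#CHROM")),
               "fileformat")
  expect_error(parse_variant_records(tiny_vcf("chr1\txx\t.\tA\tG\t.\t.\t.")),
               "line 3")
  nodepth <- tiny_vcf("chr1\t10\t.\tA\tG\t.\t.\t.\tGT\t0/1")
  expect_equal(attr(parse_variant_records(nodepth), "skipped_nodepth"), 1L)
  expect_error(parse_variant_records(nodepth,
    config = vcf_dialect_config(on_missing = "fail")), "depth")
})

test_that("VCF write then re-parse round-trips 1000 randomized records", {
  set.seed(11)
  n <- 1000
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  dp <- sample(10:500, n, replace = TRUE)
  ad <- vapply(dp, function(d) sample.int(d, 1), 0L)
  v <- variant_calls(sample(paste0("chr", 1:5), n, TRUE),
                     sample.int(1e6, n), ref, alt, dp, ad, "rt")
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(v, path)
  v2 <- parse_variant_records(path, sample_id = "rt")
  ord <- function(x) {
    x <- x[order(x$chrom, x$pos0, x$alt), c("chrom", "pos0", "ref", "alt",
                                            "total_depth", "alt_depth", "af")]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(as.data.frame(v2)), ord(as.data.frame(v)))
  # coordinate convention: printed POS is pos0 + 1
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_equal(sort(pos), sort(v$pos0 + 1L))
})

test_that("BED records parse with defaults, and empty intervals error", {
  b <- parse_interval_records(c("chr1\t10\t20\tseedA\t0\t+", "chr2\t5\t6"))
  expect_equal(b$name, c("seedA", "."))
  expect_equal(b$strand, c("+", "+"))
  expect_equal(b$end0 - b$start0, c(10L, 1L))
  expect_error(parse_interval_records("chr2\t9\t9"), "record 1")
})

test_that("catalog records convert coordinates, strand and region labels", {
  cat_txt <- c("chromosome\tposition\tgene\tstrand\tregion",
               "chr12\t69237005\tMDM2\t+\t3'UTR",
               "chr3\t500\tFOO\t-\tcoding",
               "chr4\t10\tBAR\t+\t3utr")
  s <- parse_catalog_records(cat_txt,
    col_map = list(chrom = "chromosome", position = "position",
                   gene = "gene", region = "region", strand = "strand"))
  expect_equal(s$pos0[1], 69237004L)
  expect_equal(s$region[c(1, 3)], c("3UTR", "3UTR"))
  # minus strand stored complemented on the + reference strand
  expect_equal(s$ref[2], "T")
  expect_equal(s$alt[2], "C")
  expect_equal(s$strand[2], "-")
  expect_warning(
    parse_catalog_records(c("chromosome\tposition\tgene\tstrand\tregion",
                            "chr1\t5\tX\t+\tweird")),
    "unknown region")
})

test_that("SAM alignment blocks follow the CIGAR contract", {
  ref_len <- 200L
  hdr <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:chr1\tLN:%d", ref_len))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr,
    paste("r1", 0, "chr1", 11, 60, "30M", "*", 0, 0,
          strrep("A", 30), "*", sep = "\t"),
    paste("r2", 0, "chr1", 1, 60, "10M50N10M", "*", 0, 0,
          strrep("C", 20), "*", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, strrep("G", 10), "*",
          sep = "\t"),                      # unmapped: excluded
    paste("r4", 1024, "chr1", 11, 60, "30M", "*", 0, 0,
          strrep("T", 30), "*", sep = "\t") # duplicate: excluded
  ), sam)
  aln <- parse_alignment_records(sam)
  expect_equal(vapply(aln, `[[`, "", "read_id"), c("r1", "r2"))
  expect_equal(aln[[1]]$blocks,
               matrix(c(10L, 40L, 0L, 30L), 1,
                      dimnames = list(NULL, c("ref0", "ref1", "q0", "q1"))))
  expect_equal(unname(aln[[2]]$blocks[, "ref0"]), c(0L, 60L))
  expect_equal(unname(aln[[2]]$blocks[, "ref1"]), c(10L, 70L))
  expect_equal(unname(aln[[2]]$blocks[, "q0"]), c(0L, 10L))
})

test_that("query spans of parsed blocks match the CIGAR-implied aligned bases", {
  # randomized CIGARs: property over M/I/D/N/S runs
  set.seed(21)
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000")
  recs <- character(0); expected <- integer(0)
  for (i in 1:50) {
    nops <- sample(1:5, 1)
    ops <- c("M", sample(c("M", "I", "D", "N"), nops, TRUE), "M")
    lens <- sample(1:30, length(ops), TRUE)
    qlen <- sum(lens[ops %in% c("M", "I")])
    cig <- paste0(lens, ops, collapse = "")
    recs <- c(recs, paste(paste0("p", i), 0, "chr1", 1000, 60, cig, "*",
                          0, 0, strrep("A", qlen), "*", sep = "\t"))
    expected <- c(expected, sum(lens[ops == "M"]))
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, recs), sam)
  aln <- parse_alignment_records(sam)
  got <- vapply(aln, function(a) sum(a$blocks[, "q1"] - a$blocks[, "q0"]), 0L)
  expect_equal(unname(got), expected)
  # reference and query spans agree block-wise (pure-match blocks)
  for (a in aln)
    expect_equal(a$blocks[, "ref1"] - a$blocks[, "ref0"],
                 a$blocks[, "q1"] - a$blocks[, "q0"])
})

test_that("editing matrix TSV round-trips including the missing mask", {
  sites <- editing_sites(c("chr1", "chr1", "chr2"), c(5L, 9L, 3L), "A", "G",
                         region = c("coding", "3UTR", "intron"),
                         gene = c("g1", "g1", NA))
  depth <- matrix(c(20, NA, 15, 30, 12, NA), 3, 2)
  level <- matrix(c(0.25, NA, 1 / 3, 0, 0.05, NA), 3, 2)
  m <- editing_matrix(sites, c("s1", "s2"), depth, level)
  path <- tempfile(fileext = ".tsv")
  write_editing_matrix(m, path)
  m2 <- read_editing_matrix(path)
  expect_equal(m2$depth, m$depth)
  expect_equal(m2$level, m$level, tolerance = 1e-12)
  expect_equal(m2$sites$key, m$sites$key)
  expect_equal(m2$sites$gene, m$sites$gene)
})

test_that("container validators reject contract violations", {
  expect_error(genome_reference(c(chr1 = "ACGX")), "non-ACGTN")
  expect_error(variant_calls("chr1", 1, "A", "A", 10, 2), "differ")
  expect_error(variant_calls("chr1", 1, "A", "G", 10, 12), "alt_depth")
  expect_error(exon_annotation("chr1", c(0, 10), c(10, 20), "tx1"),
               "overlap or touch")
  expect_error(editing_matrix(editing_sites("chr1", 1, "A", "G"), "s1",
                              matrix(NA_real_), matrix(0.5)), "missing mask")
})
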