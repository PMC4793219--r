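test_that("supporting-read extraction honours block coverage and alt base", {
  v <- one_variant(pos0 = 100L, alt = "G")
  seq20 <- paste0(strrep("A", 10), "G", strrep("A", 9))
  r_alt <- make_read("alt", "chr1", c(90, 110, 0, 20), seq20)
  r_ref <- make_read("ref", "chr1", c(90, 110, 0, 20), strrep("A", 20))
  r_off <- make_read("off", "chr1", c(200, 220, 0, 20), seq20)
  # covers pos0 only through an N gap (5M3N5M spanning 98..110)
  r_gap <- make_read("gap", "chr1", c(93, 98, 0, 5, 101, 106, 5, 10),
                     strrep("G", 10))
  expect_equal(length(extract_supporting_reads(v, list())), 0L)
  got <- extract_supporting_reads(v, list(r_alt, r_ref, r_off, r_gap))
  expect_equal(vapply(got, `[[`, "", "read_id"), "alt")
})

test_that("candidate loci recover unique and duplicated placements", {
  set.seed(5)
  base <- rand_dna(10000)
  seg <- substr(base, 2001, 2300)
  # plant the duplicate verbatim at 7001
  dup <- paste0(substr(base, 1, 7000), seg, substr(base, 7301, 10000))
  ref <- genome_reference(c(chr1 = dup))
  idx <- kmer_index(ref, 11)
  read_seq <- substr(dup, 2051, 2125)
  rd <- make_read("r", "chr1", c(2050, 2125, 0, 75), read_seq)
  w <- generate_candidate_loci(rd, ref, scoring_scheme(), idx)
  covers <- function(w, p) any(w$start0 <= p & p < w$end0)
  expect_true(covers(w, 2080))
  expect_true(covers(w, 7080))   # the duplicate copy is found
  # a unique read yields a single window
  uread <- make_read("u", "chr1", c(4000, 4075, 0, 75), substr(dup, 4001, 4075))
  wu <- generate_candidate_loci(uread, ref, scoring_scheme(), idx)
  expect_equal(nrow(wu), 1L)
  # shorter than min_seed: only the original-locus window
  sread <- make_read("s", "chr1", c(4000, 4008, 0, 8), substr(dup, 4001, 4008))
  ws <- generate_candidate_loci(sread, ref, scoring_scheme(), idx)
  expect_equal(nrow(ws), 1L)
  expect_true(covers(ws, 4004))
})

test_that("realignment scores match simple arithmetic cases", {
  set.seed(6)
  refseq <- rand_dna(200)
  ref <- genome_reference(c(chr1 = refseq))
  w <- data.frame(chrom = "chr1", start0 = 0L, end0 = 200L, strand = "+")
  q <- substr(refseq, 51, 70)
  h <- realign_read(make_read("a", "chr1", c(50, 70, 0, 20), q), w, ref)
  expect_equal(h[[1]]$score, 20)
  expect_equal(h[[1]]$identity, 1)
  substr(q, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, 10, 10))[1]
  h <- realign_read(make_read("b", "chr1", c(50, 70, 0, 20), q), w, ref)
  expect_equal(h[[1]]$score, 18)  # 19 matches - 1 mismatch
})

test_that("a read over a planted intron realigns spliced at intron cost", {
  set.seed(8)
  e1 <- rand_dna(40); intr <- rand_dna(100); e2 <- rand_dna(40)
  ref <- genome_reference(c(chr1 = paste0(e1, intr, e2)))
  q <- paste0(substr(e1, 11, 40), substr(e2, 1, 30))  # 60-base junction read
  w <- data.frame(chrom = "chr1", start0 = 0L, end0 = 180L, strand = "+")
  h <- realign_read(make_read("j", "chr1", c(10, 70, 0, 60), q), w, ref)
  expect_true(h[[1]]$spliced)
  expect_equal(h[[1]]$score, 60 - 3)
  expect_equal(nrow(h[[1]]$blocks), 2L)
  expect_equal(unname(h[[1]]$blocks[2, "ref0"]), 140L)
  # and it beats the oracle-computed ungapped score
  orc <- oracle_align(q, paste0(e1, intr, e2))
  expect_equal(h[[1]]$score, orc$best)
})

test_that("read verdicts follow the selection rules and boundaries", {
  v <- one_variant(pos0 = 100L, alt = "G")
  qG <- paste0(strrep("A", 10), "G", strrep("A", 9))
  locus_ok <- make_hit("chr1", c(90, 110, 0, 20), qG, 18)
  off <- make_hit("chr1", c(500, 520, 0, 20), qG, 20)
  off_weak <- make_hit("chr1", c(500, 520, 0, 20), qG, 10)
  # single confirming hit
  expect_equal(select_best_alignment(list(locus_ok), v)$status, "CONFIRM")
  expect_equal(select_best_alignment(list(locus_ok), v)$reason, "ok")
  # stronger hit elsewhere wins
  r <- select_best_alignment(list(off, locus_ok), v)
  expect_equal(r$reason, "best_elsewhere")
  # near-tie boundary: off-locus 19 vs locus 20 (0.95 * 20 = 19, inclusive)
  locus_20 <- make_hit("chr1", c(90, 110, 0, 20), qG, 20)
  off_19 <- make_hit("chr1", c(500, 520, 0, 20), qG, 19)
  expect_equal(select_best_alignment(list(locus_20, off_19), v)$reason,
               "near_tie")
  off_18.9 <- make_hit("chr1", c(500, 520, 0, 20), qG, 18.9)
  expect_equal(select_best_alignment(list(locus_20, off_18.9), v)$status,
               "CONFIRM")
  # spliced placement that skips the variant column
  spl <- make_hit("chr1", c(90, 100, 0, 10, 130, 140, 10, 20),
                  strrep("A", 20), 19, spliced = TRUE)
  expect_equal(select_best_alignment(list(spl, locus_ok), v)$reason,
               "spliced_better")
  # gapped placement restoring the reference base
  qA <- strrep("A", 20)
  gap <- make_hit("chr1", c(90, 110, 0, 20), qA, 19, gapped = TRUE)
  expect_equal(select_best_alignment(list(gap, locus_ok), v)$reason,
               "gapped_better")
  # top hit covers but base is no longer alt, ungapped
  lost <- make_hit("chr1", c(90, 110, 0, 20), qA, 20)
  expect_equal(select_best_alignment(list(lost, locus_ok), v)$reason,
               "alt_lost")
  expect_error(select_best_alignment(list(), v), "empty")
  # weak off-locus hit does not disturb a confirmation
  expect_equal(select_best_alignment(list(locus_20, off_weak), v)$status,
               "CONFIRM")
})

test_that("variant adjudication maps verdict mixtures to artifact classes", {
  v <- one_variant()
  mk <- function(status, reason) list(read_id = "x", status = status,
                                      reason = reason)
  conf <- mk("CONFIRM", "ok")
  adj <- adjudicate_variant(v, rep(list(conf), 10))
  expect_equal(adj$status, "PASS")
  expect_equal(adj$confirmed_fraction, 1)
  adj <- adjudicate_variant(v, c(rep(list(conf), 5),
                                 rep(list(mk("REFUTE", "best_elsewhere")), 5)))
  expect_equal(adj$status, "MULTI_ALIGNMENT")
  adj <- adjudicate_variant(v, rep(list(mk("REFUTE", "spliced_better")), 6))
  expect_equal(adj$status, "SPLICE_JUNCTION")
  adj <- adjudicate_variant(v, rep(list(mk("REFUTE", "gapped_better")), 6))
  expect_equal(adj$status, "INDEL_ARTIFACT")
  # modal tie breaks in the fixed order MULTI > SPLICE
  adj <- adjudicate_variant(v, c(rep(list(mk("REFUTE", "near_tie")), 3),
                                 rep(list(mk("REFUTE", "spliced_better")), 3)))
  expect_equal(adj$status, "MULTI_ALIGNMENT")
  # confirmed fraction fine but below the read floor
  adj <- adjudicate_variant(v, rep(list(conf), 3))
  expect_equal(adj$status, "LOW_SUPPORT")
  expect_equal(adjudicate_variant(v, list())$status, "LOW_SUPPORT")
  expect_equal(adjudicate_variant(v, list())$n_supporting, 0L)
})

test_that("junction proximity uses half-open boundary arithmetic", {
  ann <- exon_annotation("chr1", c(100, 300), c(200, 400), "tx1")
  expect_equal(junction_proximity(list(chrom = "chr1", pos0 = 199), ann), 1)
  expect_equal(junction_proximity(list(chrom = "chr1", pos0 = 150), ann), 50)
  expect_equal(junction_proximity(list(chrom = "chr9", pos0 = 1), ann), Inf)
  expect_equal(junction_proximity(list(chrom = "chr1", pos0 = 1), NULL), Inf)
})

test_that("realignment equals the independent oracle on random small cases", {
  # spot-check here; the full 200-case sweep runs in the acceptance suite
  set.seed(31)
  sch <- scoring_scheme()
  for (i in 1:40) {
    m <- sample(20:60, 1); n <- sample(5:min(30, m), 1)
    refseq <- rand_dna(m)
    q <- if (runif(1) < 0.5) {
      s <- sample(seq_len(m - n + 1), 1)
      x <- substr(refseq, s, s + n - 1)
      ch <- strsplit(x, "")[[1]]
      k <- sample(seq_len(n), sample(0:2, 1))
      if (length(k)) ch[k] <- vapply(ch[k], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(ch, collapse = "")
    } else rand_dna(n)
    modes <- editscan:::.cpp_align_modes(q, refseq, sch$match, sch$mismatch,
                                         sch$gap_open, sch$gap_extend,
                                         sch$intron_gap, sch$max_intron,
                                         sch$min_intron)
    orc <- oracle_align(q, refseq, min_intron = sch$min_intron)
    expect_equal(max(modes$ungapped$score, modes$gapped$score,
                     modes$spliced$score), orc$best,
                 info = paste("case", i))
    expect_equal(modes$gapped$score, orc$gapped, info = paste("case", i))
  }
})

test_that("gapped mode agrees with Biostrings local alignment scoring", {
  set.seed(32)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    refseq <- rand_dna(60); q <- rand_dna(25)
    modes <- editscan:::.cpp_align_modes(q, refseq, 1, -1, -2, -1, -3,
                                         50000, 20)
    pw <- Biostrings::pairwiseAlignment(q, refseq, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 1, gapExtension = 1)
    expect_equal(modes$gapped$score, Biostrings::score(pw))
  }
})

test_that("lowering near_tie_ratio never grows the confirmed set", {
  fx <- small_raar_fixture()
  v <- fx$reads$variants
  confirmed_ids <- function(ratio) {
    cfg <- raar_config(scheme = scoring_scheme(near_tie_ratio = ratio))
    res <- run_raar(v, fx$alignments, fx$genome$reference,
                    annotation = fx$genome$annotation, config = cfg)
    with(res$variants, paste(chrom, pos0, alt))[res$variants$filter == "PASS"]
  }
  c95 <- confirmed_ids(0.95)
  c80 <- confirmed_ids(0.80)
  expect_true(all(c80 %in% c95))
})

test_that("run_raar is deterministic and correct on the small fixture", {
  fx <- small_raar_fixture()
  res1 <- run_raar(fx$reads$variants, fx$alignments, fx$genome$reference,
                   annotation = fx$genome$annotation)
  res2 <- run_raar(fx$reads$variants, fx$alignments, fx$genome$reference,
                   annotation = fx$genome$annotation)
  expect_identical(res1$variants, res2$variants)
  truth <- fx$reads$truth
  m <- merge(data.frame(key = editscan:::site_key(res1$variants),
                        filter = res1$variants$filter), truth, by = "key")
  expect_true(all(m$filter[m$class == "true_editing"] == "PASS"))
  expect_true(all(m$filter[m$class == "MULTI_ALIGNMENT"] == "raar_multi"))
  # VCF output is byte-identical across runs
  f1 <- tempfile(); f2 <- tempfile()
  write_variant_vcf(res1$variants, f1)
  write_variant_vcf(res2$variants, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty input
  empty <- fx$reads$variants[0, ]
  res0 <- run_raar(empty, fx$alignments, fx$genome$reference)
  expect_equal(nrow(res0$variants), 0L)
  expect_equal(sum(res0$report$n_variants), 0L)
})

test_that("clean error-free data passes untouched", {
  spec <- fixture_spec(seed = 13,
                       genome = list(n_genes = 4L, chrom_length = 8000L),
                       editing = list(n_sites = 6L),
                       artifacts = list(n_paralog = 0L, n_junction = 0L,
                                        n_indel = 0L),
                       reads = list(depth = 20L, error_rate = 0))
  g <- simulate_genome_with_paralogs(spec)
  rx <- simulate_reads_with_artifacts(g, spec)
  sam <- tempfile(fileext = ".sam"); writeLines(rx$sam, sam)
  res <- run_raar(rx$variants, parse_alignment_records(sam), g$reference,
                  annotation = g$annotation)
  expect_true(all(res$variants$filter == "PASS"))
})

test_that("external PSL hits replace internal realignment", {
  v <- one_variant(pos0 = 100L, alt = "G", total = 6L, altd = 6L)
  set.seed(44)
  refseq <- rand_dna(1000)
  substr(refseq, 101, 101) <- "A"
  ref <- genome_reference(c(chr1 = refseq))
  qG <- substr(refseq, 71, 130); substr(qG, 31, 31) <- "G"
  reads <- lapply(1:6, function(i)
    make_read(paste0("p", i), "chr1", c(70, 130, 0, 60), qG))
  # PSL claims a perfect placement elsewhere for every read
  psl_lines <- vapply(1:6, function(i)
    paste(c(60, 0, 0, 0, 0, 0, 0, 0, "+", paste0("p", i), 60, 0, 60,
            "chr1", 1000, 700, 760, 1, "60,", "0,", "700,"),
          collapse = "\t"), "")
  psl <- parse_psl_records(psl_lines)
  res <- run_raar(v, reads, ref, psl = psl,
                  config = raar_config(min_alt_reads = 3L))
  expect_equal(res$variants$filter, "raar_multi")
})
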