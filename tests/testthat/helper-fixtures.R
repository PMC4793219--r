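# Shared in-code fixtures.

# A ReadAlignment record from explicit blocks.
make_read <- function(id, chrom, blocks, seq, strand = "+", mapq = 50L) {
  blocks <- matrix(as.integer(blocks), ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, c("ref0", "ref1", "q0", "q1")))
  list(read_id = id, chrom = chrom, start0 = min(blocks[, "ref0"]),
       strand = strand, mapq = mapq, seq = seq, blocks = blocks)
}

# A realignment hit in the shape produced by realign_read().
make_hit <- function(chrom, blocks, query, score, spliced = FALSE,
                     gapped = FALSE, strand = "+") {
  blocks <- matrix(as.integer(blocks), ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, c("ref0", "ref1", "q0", "q1")))
  list(chrom = chrom, start0 = min(blocks[, "ref0"]),
       end0 = max(blocks[, "ref1"]), strand = strand, blocks = blocks,
       score = score, identity = 1, spliced = spliced, gapped = gapped,
       query = query)
}

one_variant <- function(chrom = "chr1", pos0 = 100L, ref = "A", alt = "G",
                        total = 20L, altd = 10L, sample_id = "s1") {
  variant_calls(chrom, pos0, ref, alt, total, altd, sample_id)
}

# Tiny VarScan-dialect VCF text.
tiny_vcf <- function(rows) {
  c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE",
    rows)
}

# small deterministic RAAR fixture (shared by several test files)
small_raar_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 7,
                           genome = list(n_genes = 6L, chrom_length = 12000L),
                           editing = list(n_sites = 8L),
                           artifacts = list(n_paralog = 3L, n_junction = 3L,
                                            n_indel = 2L),
                           reads = list(depth = 20L))
      g <- simulate_genome_with_paralogs(spec)
      rx <- simulate_reads_with_artifacts(g, spec)
      sam <- tempfile(fileext = ".sam")
      writeLines(rx$sam, sam)
      cache <<- list(spec = spec, genome = g, reads = rx, sam = sam,
                     alignments = parse_alignment_records(sam))
    }
    cache
  }
})
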