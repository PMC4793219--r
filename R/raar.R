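# Realignment-based Alignment Artifact Removal (RAAR).
#
# A candidate variant from an RNA-Seq caller is re-examined by realigning
# each of its alt-carrying supporting reads against candidate loci found by
# exact k-mer seeding, under three local-alignment modes (ungapped, affine
# gapped, spliced with one intron).  A read CONFIRMs the variant only if its
# best placement still covers the variant position with the alt base intact
# and no near-tying placement exists elsewhere; the per-read verdicts are
# then aggregated into a per-variant pass/artifact adjudication.

REFUTE_REASONS <- c("best_elsewhere", "near_tie", "spliced_better",
                    "gapped_better", "alt_lost")
ARTIFACT_CLASSES <- c("PASS", "MULTI_ALIGNMENT", "SPLICE_JUNCTION",
                      "INDEL_ARTIFACT", "LOW_SUPPORT")
FILTER_TAGS <- c(PASS = "PASS", MULTI_ALIGNMENT = "raar_multi",
                 SPLICE_JUNCTION = "raar_splice",
                 INDEL_ARTIFACT = "raar_indel",
                 LOW_SUPPORT = "raar_lowsupport")

#' Scoring scheme for realignment
#'
#' Score units are arbitrary; only ratios and differences matter.  A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`.  An intron (a
#' reference-only gap of length 1..`max_intron`, allowed once per
#' alignment) costs the flat `intron_gap`.
#'
#' @param match,mismatch per-column scores (match > 0 > mismatch).
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @param intron_gap flat intron penalty (negative).
#' @param max_intron maximum intron length in bases.
#' @param min_intron minimum reference gap treated as an intron; shorter
#'   reference gaps are deletions and pay the affine penalty.  Keeps
#'   small indels out of the spliced mode.
#' @param near_tie_ratio a placement elsewhere within this fraction of the
#'   best score refutes a read (multi-alignment ambiguity).
#' @param min_seed exact-match seed length for candidate locus search.
#' @return list of class `ScoringScheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = -1, intron_gap = -3,
                           max_intron = 50000L, min_intron = 20L,
                           near_tie_ratio = 0.95, min_seed = 11L) {
  stopifnot(match > 0, mismatch < 0, near_tie_ratio > 0, near_tie_ratio <= 1,
            max_intron >= 1, min_intron >= 1, min_intron <= max_intron)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, intron_gap = intron_gap,
                 max_intron = as.integer(max_intron),
                 min_intron = as.integer(min_intron),
                 near_tie_ratio = near_tie_ratio,
                 min_seed = as.integer(min_seed)),
            class = "ScoringScheme")
}

#' RAAR configuration
#'
#' @param scheme a [scoring_scheme()].
#' @param min_confirm_frac minimum fraction of supporting reads that must
#'   CONFIRM for the variant to pass.
#' @param min_alt_reads minimum number of confirming reads.
#' @param junction_window variants within this distance (bases) of an
#'   annotated exon boundary are force-routed through spliced realignment.
#' @return list of class `raar_config`.
#' @export
raar_config <- function(scheme = scoring_scheme(), min_confirm_frac = 0.90,
                        min_alt_reads = 5L, junction_window = 4L) {
  structure(list(scheme = scheme, min_confirm_frac = min_confirm_frac,
                 min_alt_reads = as.integer(min_alt_reads),
                 junction_window = as.integer(junction_window)),
            class = "raar_config")
}

#' Extract the reads supporting a variant
#'
#' A read supports the variant iff one of its aligned blocks covers `pos0`
#' and the query base aligned at that column equals the alt base.  Reads
#' spanning the position inside a gap between blocks (e.g. an N skip) do
#' not cover it.
#'
#' @param variant one-row [variant_calls()] data.frame (or list with
#'   chrom/pos0/alt).
#' @param alignments list of ReadAlignment records
#'   (see [parse_alignment_records()]).
#' @return the supporting subset of `alignments` (possibly empty).
#' @export
extract_supporting_reads <- function(variant, alignments) {
  keep <- vapply(alignments, function(a) {
    if (a$chrom != variant$chrom) return(FALSE)
    b <- aligned_query_base(a$blocks, a$seq, variant$pos0)
    !is.na(b) && b == variant$alt
  }, TRUE)
  alignments[keep]
}

# Query base aligned at reference position pos0, or NA if not covered by a
# block.  blocks: matrix(ref0, ref1, q0, q1); seq: query string.
aligned_query_base <- function(blocks, seq, pos0) {
  hit <- which(blocks[, "ref0"] <= pos0 & pos0 < blocks[, "ref1"])
  if (length(hit) == 0) return(NA_character_)
  qpos <- blocks[hit[1], "q0"] + (pos0 - blocks[hit[1], "ref0"])
  substr(seq, qpos + 1, qpos + 1)
}

#' Build an exact k-mer index of a reference
#'
#' @param reference a [genome_reference()].
#' @param k seed length.
#' @return environment mapping k-mer to a data.frame(chrom, pos0); used by
#'   [generate_candidate_loci()].  Build once, reuse across reads.
#' @export
kmer_index <- function(reference, k = 11L) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (chrom in names(reference$sequences)) {
    s <- reference$sequences[[chrom]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    sp <- split(starts[ok] - 1L, kmers[ok])
    for (km in names(sp)) {
      prev <- if (exists(km, envir = env, inherits = FALSE))
        get(km, envir = env) else NULL
      assign(km, rbind(prev, data.frame(chrom = chrom, pos0 = sp[[km]])),
             envir = env)
    }
  }
  attr(env, "k") <- as.integer(k)
  env
}

#' Find candidate loci for realigning a read
#'
#' Seeds every `min_seed`-mer of the read (both orientations) in a
#' precomputed reference k-mer index, clusters hits by alignment diagonal,
#' and pads each cluster by the read length.  The read's original locus is
#' always included.
#'
#' @param read a ReadAlignment record.
#' @param reference a [genome_reference()].
#' @param scheme a [scoring_scheme()] (supplies `min_seed`).
#' @param index optional [kmer_index()] (built on the fly if NULL).
#' @param join_gap windows on the same chromosome and strand separated by
#'   at most this many bases are joined into one, so that a spliced
#'   alignment can bridge the two seed clusters of a junction-spanning
#'   read.  Capped at `scheme$max_intron`.
#' @return data.frame(chrom, start0, end0, strand) of candidate windows.
#' @export
generate_candidate_loci <- function(read, reference, scheme = scoring_scheme(),
                                    index = NULL, join_gap = 5000L) {
  join_gap <- min(join_gap, scheme$max_intron)
  k <- scheme$min_seed
  qlen <- nchar(read$seq)
  orig_lo <- max(0L, min(read$blocks[, "ref0"]) - qlen)
  orig_hi <- min(reference$lengths[[read$chrom]],
                 max(read$blocks[, "ref1"]) + qlen)
  windows <- data.frame(chrom = read$chrom, start0 = orig_lo, end0 = orig_hi,
                        strand = "+", stringsAsFactors = FALSE)
  if (qlen < k) return(windows)
  if (is.null(index)) index <- kmer_index(reference, k)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read$seq else revcomp(read$seq)
    starts <- seq_len(qlen - k + 1L)
    kmers <- unique(substring(q, starts, starts + k - 1L))
    hit_list <- lapply(kmers, function(km)
      if (exists(km, envir = index, inherits = FALSE)) {
        h <- get(km, envir = index)
        # diagonal = ref position of the would-be read start
        qoff <- starts[match(km, substring(q, starts, starts + k - 1L))]
        h$diag <- h$pos0 - (qoff - 1L)
        h
      } else NULL)
    hits <- do.call(rbind, hit_list)
    if (is.null(hits) || nrow(hits) == 0) next
    for (chrom in unique(hits$chrom)) {
      d <- sort(hits$diag[hits$chrom == chrom])
      # cluster diagonals closer than one read length
      grp <- cumsum(c(1L, diff(d) > qlen))
      for (g in unique(grp)) {
        dd <- d[grp == g]
        lo <- max(0L, min(dd) - qlen)
        hi <- min(reference$lengths[[chrom]], max(dd) + 2L * qlen)
        windows <- rbind(windows,
                         data.frame(chrom = chrom, start0 = lo, end0 = hi,
                                    strand = strand, stringsAsFactors = FALSE))
      }
    }
  }
  # merge windows closer than join_gap (per chrom x strand)
  windows <- unique(windows)
  merged <- do.call(rbind, lapply(split(windows,
                                        paste(windows$chrom, windows$strand)),
    function(w) {
      w <- w[order(w$start0), , drop = FALSE]
      out <- w[1, , drop = FALSE]
      for (i in seq_len(nrow(w))[-1]) {
        if (w$start0[i] <= out$end0[nrow(out)] + join_gap) {
          out$end0[nrow(out)] <- max(out$end0[nrow(out)], w$end0[i])
        } else out <- rbind(out, w[i, , drop = FALSE])
      }
      out
    }))
  rownames(merged) <- NULL
  merged[order(merged$chrom, merged$start0, merged$strand), , drop = FALSE]
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Realign a read against candidate windows
#'
#' For each window the best local alignment under three modes is computed:
#' ungapped, gapped (affine small indels) and spliced (one reference-only
#' intron gap of length <= `max_intron` at cost `intron_gap`).  Per window
#' the single highest-scoring mode is kept; on ties the simpler mode wins
#' (ungapped over gapped over spliced) unless `prefer_spliced = TRUE`, in
#' which case a spliced alignment tying the best non-spliced score is kept
#' (used when a variant sits within the junction window of an annotated
#' exon boundary).
#'
#' @param read a ReadAlignment record.
#' @param windows data.frame from [generate_candidate_loci()].
#' @param reference a [genome_reference()].
#' @param scheme a [scoring_scheme()].
#' @param prefer_spliced prefer a tying spliced alignment (see above).
#' @return list of realignment hits sorted by score descending, ties by
#'   (chrom, start0).  Each hit has chrom, start0, end0, strand, blocks
#'   (reference coordinates, genome frame), score, identity, spliced,
#'   gapped, and `query` (the oriented query whose coordinates the blocks'
#'   q0/q1 refer to).
#' @export
realign_read <- function(read, windows, reference, scheme = scoring_scheme(),
                         prefer_spliced = FALSE) {
  hits <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    refseq <- substr(reference$sequences[[w$chrom]], w$start0 + 1, w$end0)
    q <- if (w$strand == "+") read$seq else revcomp(read$seq)
    modes <- .cpp_align_modes(q, refseq, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend,
                              scheme$intron_gap, scheme$max_intron,
                              scheme$min_intron)
    scores <- c(ungapped = modes$ungapped$score, gapped = modes$gapped$score,
                spliced = modes$spliced$score)
    best <- max(scores)
    if (best <= 0) next
    pick <- if (prefer_spliced && scores["spliced"] >= best) "spliced"
      else names(scores)[which(scores >= best)][1] # order: ungapped, gapped, spliced
    mode <- modes[[pick]]
    blocks <- mode$blocks
    if (nrow(blocks) == 0) next
    blocks[, c("ref0", "ref1")] <- blocks[, c("ref0", "ref1")] + w$start0
    hits[[length(hits) + 1L]] <- list(
      chrom = w$chrom, start0 = min(blocks[, "ref0"]),
      end0 = max(blocks[, "ref1"]), strand = w$strand, blocks = blocks,
      score = mode$score, identity = mode$matches / max(mode$cols, 1),
      spliced = pick == "spliced",
      gapped = (pick == "gapped" && mode$gapped) ||
        (pick == "spliced" && mode$gapped),
      query = q)
  }
  if (length(hits) == 0) return(hits)
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, `[[`, "", "chrom"),
               vapply(hits, `[[`, 0, "start0"))
  hits[ord]
}

#' Adjudicate one supporting read from its realignment hits
#'
#' A read CONFIRMs its variant iff (a) the top-scoring hit covers the
#' variant position, (b) the aligned query base there is still the alt
#' base, (c) the placement does not erase the mismatch via a spliced or
#' gapped alignment, and (d) no placement not covering the position scores
#' within `near_tie_ratio` of the best.
#'
#' @param hits list from [realign_read()] (non-empty; the original locus is
#'   always a candidate window).
#' @param variant one-row variant (chrom, pos0, alt).
#' @param scheme a [scoring_scheme()].
#' @param read_id carried through to the verdict.
#' @return list(read_id, status = "CONFIRM"/"REFUTE", reason).
#' @export
select_best_alignment <- function(hits, variant, scheme = scoring_scheme(),
                                  read_id = NA_character_) {
  if (length(hits) == 0) stop("empty hit list: the original locus must always be realigned")
  top <- hits[[1]]
  best_score <- top$score
  covers <- function(h) h$chrom == variant$chrom &&
    !is.na(aligned_query_base(h$blocks, h$query, variant$pos0))
  base_at <- function(h) aligned_query_base(h$blocks, h$query, variant$pos0)
  at_locus <- function(h) h$chrom == variant$chrom &&
    h$start0 <= variant$pos0 && variant$pos0 < h$end0
  verdict <- function(status, reason) list(read_id = read_id, status = status,
                                           reason = reason)
  if (covers(top) && !is.na(base_at(top)) && base_at(top) == variant$alt) {
    # (d) near-tie test against hits not covering the position
    for (h in hits[-1]) {
      if (!covers(h) && h$score >= scheme$near_tie_ratio * best_score)
        return(verdict("REFUTE", "near_tie"))
    }
    return(verdict("CONFIRM", "ok"))
  }
  # top placement does not retain the alt at pos0
  if (at_locus(top) || covers(top)) {
    if (top$spliced) return(verdict("REFUTE", "spliced_better"))
    if (top$gapped) return(verdict("REFUTE", "gapped_better"))
    return(verdict("REFUTE", "alt_lost"))
  }
  verdict("REFUTE", "best_elsewhere")
}

#' Aggregate read verdicts into a per-variant artifact verdict
#'
#' @param variant one-row variant table.
#' @param verdicts list of read verdicts from [select_best_alignment()].
#' @param config a [raar_config()].
#' @return list with status (PASS or artifact class), n_supporting,
#'   n_confirmed, confirmed_fraction.
#' @export
adjudicate_variant <- function(variant, verdicts, config = raar_config()) {
  n_sup <- length(verdicts)
  if (n_sup == 0)
    return(list(status = "LOW_SUPPORT", n_supporting = 0L, n_confirmed = 0L,
                confirmed_fraction = NA_real_))
  status <- vapply(verdicts, `[[`, "", "status")
  reason <- vapply(verdicts, `[[`, "", "reason")
  n_conf <- sum(status == "CONFIRM")
  frac <- n_conf / n_sup
  if (frac >= config$min_confirm_frac && n_conf >= config$min_alt_reads)
    return(list(status = "PASS", n_supporting = n_sup, n_confirmed = n_conf,
                confirmed_fraction = frac))
  if (frac >= config$min_confirm_frac) {
    cls <- "LOW_SUPPORT" # confirmed but below the read floor
  } else {
    rr <- reason[status == "REFUTE"]
    mapped <- c(best_elsewhere = "MULTI_ALIGNMENT", near_tie = "MULTI_ALIGNMENT",
                spliced_better = "SPLICE_JUNCTION",
                gapped_better = "INDEL_ARTIFACT",
                alt_lost = "LOW_SUPPORT")[rr]
    tab <- table(factor(mapped, levels = c("MULTI_ALIGNMENT",
                                           "SPLICE_JUNCTION",
                                           "INDEL_ARTIFACT", "LOW_SUPPORT")))
    cls <- names(tab)[which.max(tab)] # ties break in the fixed order above
  }
  list(status = cls, n_supporting = n_sup, n_confirmed = n_conf,
       confirmed_fraction = frac)
}

#' Distance from a variant to the nearest annotated exon boundary
#'
#' @param variant one-row variant table (chrom, pos0).
#' @param annotation an [exon_annotation()] (or NULL).
#' @return minimum absolute distance in bases over all exon boundaries on
#'   the variant's chromosome; `Inf` if the chromosome is absent or the
#'   annotation is NULL.
#' @export
junction_proximity <- function(variant, annotation) {
  if (is.null(annotation)) return(Inf)
  e <- annotation[annotation$chrom == variant$chrom, , drop = FALSE]
  if (nrow(e) == 0) return(Inf)
  min(abs(variant$pos0 - e$start0), abs(e$end0 - variant$pos0))
}

#' Run the full RAAR filter
#'
#' Realigns the supporting reads of every candidate variant and annotates
#' the VCF FILTER column with the verdict: `PASS`, `raar_multi`,
#' `raar_splice`, `raar_indel` or `raar_lowsupport`.
#'
#' @param vcf_in path to the candidate VCF (or a parsed
#'   [variant_calls()] data.frame).
#' @param alignments path to SAM/BAM (or a parsed alignment list).
#' @param reference a [genome_reference()] or FASTA path.
#' @param annotation optional [exon_annotation()] or BED path; variants
#'   within `junction_window` of an exon boundary are force-routed through
#'   spliced realignment.
#' @param psl optional Blat PSL path (or parsed [parse_psl_records()]
#'   list); for reads present in it, the external hits replace internal
#'   realignment.
#' @param config a [raar_config()].
#' @param vcf_out optional path; if given, the annotated VCF is written.
#' @return list with `variants` (input variants + `filter`,
#'   `n_supporting`, `n_confirmed` columns) and `report` (data.frame of
#'   per-class counts).
#' @export
run_raar <- function(vcf_in, alignments, reference, annotation = NULL,
                     psl = NULL, config = raar_config(), vcf_out = NULL) {
  variants <- if (is.character(vcf_in)) parse_variant_records(vcf_in) else vcf_in
  if (is.character(alignments))
    alignments <- parse_alignment_records(alignments)
  if (is.character(reference)) reference <- read_genome_fasta(reference)
  if (is.character(annotation)) {
    b <- parse_interval_records(annotation)
    annotation <- exon_annotation(b$chrom, b$start0, b$end0, b$name, b$strand)
  }
  if (is.character(psl)) psl <- parse_psl_records(psl, config$scheme)
  bad <- setdiff(unique(vapply(alignments, `[[`, "", "chrom")),
                 names(reference$sequences))
  if (length(bad))
    stop("alignment chromosome(s) absent from reference: ",
         paste(bad, collapse = ", "))
  idx <- kmer_index(reference, config$scheme$min_seed)
  n <- nrow(variants)
  filt <- character(n); nsup <- integer(n); nconf <- integer(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    sup <- extract_supporting_reads(v, alignments)
    force_spliced <- junction_proximity(v, annotation) <= config$junction_window
    verdicts <- lapply(sup, function(read) {
      ext <- if (!is.null(psl)) psl[[read$read_id]] else NULL
      hits <- if (!is.null(ext)) {
        for (j in seq_along(ext)) ext[[j]]$query <- read$seq
        ord <- order(-vapply(ext, `[[`, 0, "score"),
                     vapply(ext, `[[`, "", "chrom"),
                     vapply(ext, `[[`, 0, "start0"))
        ext[ord]
      } else {
        w <- generate_candidate_loci(read, reference, config$scheme, idx)
        realign_read(read, w, reference, config$scheme,
                     prefer_spliced = force_spliced)
      }
      select_best_alignment(hits, v, config$scheme, read_id = read$read_id)
    })
    adj <- adjudicate_variant(v, verdicts, config)
    filt[i] <- FILTER_TAGS[[adj$status]]
    nsup[i] <- adj$n_supporting; nconf[i] <- adj$n_confirmed
  }
  variants$filter <- filt
  variants$n_supporting <- nsup
  variants$n_confirmed <- nconf
  report <- as.data.frame(table(factor(filt, levels = unname(FILTER_TAGS))),
                          stringsAsFactors = FALSE)
  names(report) <- c("filter", "n_variants")
  if (!is.null(vcf_out)) write_variant_vcf(variants, vcf_out, "editscan-raar")
  list(variants = variants, report = report)
}
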