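# Editing site / event / level quantification.
#
# Two-step detection: (i) stringent calling -- a substitution becomes a
# *site* if at least one sample shows >= 5 supporting reads and >= 5%
# allele frequency; (ii) relaxed retrieval -- at the confident sites, every
# event with total depth >= 10 is retrieved regardless of level (zero-level
# events included), which recovers the prevalent lowly-edited fraction that
# the stringent cutoff suppresses.

#' Thresholds for editing site calling and retrieval
#'
#' @param min_alt_reads minimum supporting (edited) reads in at least one
#'   sample for a substitution to qualify as a site (inclusive).
#' @param min_af minimum allele frequency in that sample (inclusive).
#' @param dna_af_cut a variant is discarded as a DNA polymorphism/mutation
#'   if its allele frequency in paired DNA-Seq is >= this value.
#' @param relaxed_min_depth events with total coverage strictly below this
#'   are discarded during relaxed retrieval.
#' @return list of class `CallThresholds`.
#' @export
call_thresholds <- function(min_alt_reads = 5L, min_af = 0.05,
                            dna_af_cut = 0.05, relaxed_min_depth = 10L) {
  stopifnot(min_alt_reads >= 0, min_af >= 0, min_af <= 1,
            dna_af_cut >= 0, dna_af_cut <= 1, relaxed_min_depth >= 0)
  structure(list(min_alt_reads = as.integer(min_alt_reads), min_af = min_af,
                 dna_af_cut = dna_af_cut,
                 relaxed_min_depth = as.integer(relaxed_min_depth)),
            class = "CallThresholds")
}

#' Remove RNA variants supported by paired DNA-Seq
#'
#' An RNA variant is removed iff a DNA variant at the same
#' (chrom, pos0, alt) has allele frequency >= `dna_af_cut` (inclusive).
#' RNA variants with no DNA record at the position are kept and flagged
#' `dna_uncovered` (the conservative choice: absence of DNA evidence is
#' not evidence of a germline/somatic DNA change).
#'
#' @param rna_variants,dna_variants [variant_calls()] data.frames.
#' @param thresholds a [call_thresholds()].
#' @return list(kept, removed); `kept` gains a logical `dna_uncovered`
#'   column.
#' @export
apply_dna_filter <- function(rna_variants, dna_variants,
                             thresholds = call_thresholds()) {
  key <- function(v) paste(v$chrom, v$pos0, v$alt, sep = ":")
  dna_af <- tapply(dna_variants$af, key(dna_variants), max)
  k <- key(rna_variants)
  af <- dna_af[k]
  remove <- !is.na(af) & af >= thresholds$dna_af_cut
  kept <- rna_variants[!remove, , drop = FALSE]
  kept$dna_uncovered <- as.vector(is.na(af[!remove]))
  list(kept = kept, removed = rna_variants[remove, , drop = FALSE])
}

#' Call editing sites from per-sample variants
#'
#' A substitution (chrom, pos0, ref, alt) is designated a site iff at
#' least one sample has `alt_depth >= min_alt_reads` **and**
#' `af >= min_af` (both inclusive).  Input is assumed already
#' artifact- and DNA-filtered.
#'
#' @param variants a [variant_calls()] data.frame pooling all samples.
#' @param thresholds a [call_thresholds()].
#' @param region,gene optional per-variant annotations carried to sites.
#' @return an [editing_sites()] data.frame, deduplicated and sorted by
#'   (chrom, pos0).
#' @export
call_editing_sites <- function(variants, thresholds = call_thresholds(),
                               region = "unknown", gene = NA_character_) {
  ok <- variants$alt_depth >= thresholds$min_alt_reads &
    variants$af >= thresholds$min_af
  v <- variants[ok, , drop = FALSE]
  if (length(region) == nrow(variants)) region <- region[ok]
  if (length(gene) == nrow(variants)) gene <- gene[ok]
  key <- paste(v$chrom, v$pos0, v$ref, v$alt)
  first <- !duplicated(key)
  s <- editing_sites(v$chrom[first], v$pos0[first], v$ref[first], v$alt[first],
                     region = if (length(region) > 1) region[first] else region,
                     gene = if (length(gene) > 1) gene[first] else gene)
  s <- s[order(s$chrom, s$pos0, s$alt), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Substitution spectrum of editing events
#'
#' Counts the 12 substitution types (as stored on the + reference strand)
#' and their frequencies; in A-to-I editing data A>G (and its antisense
#' image T>C) dominates.
#'
#' @param events a data.frame with `ref` and `alt` columns
#'   ([variant_calls()] or event tables).
#' @return data.frame of class `SpectrumTable` with columns type, count,
#'   frequency (frequencies sum to 1; all-NA when there are no events,
#'   with attribute `empty = TRUE`).
#' @export
substitution_spectrum <- function(events) {
  type <- factor(paste0(events$ref, ">", events$alt),
                 levels = SUBSTITUTION_TYPES)
  counts <- table(type)
  total <- sum(counts)
  out <- data.frame(type = SUBSTITUTION_TYPES, count = as.integer(counts),
                    frequency = if (total > 0) as.numeric(counts) / total
                    else NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("SpectrumTable", "data.frame")
  attr(out, "empty") <- total == 0
  out
}

#' Histogram of editing levels with moving-average smoothing
#'
#' Levels (fractions) are expressed in percent and binned into
#' `[0,5), [5,10), ..., [95,100]` (the last bin closed).  The smoothed
#' series is a centred moving average of the raw frequencies; at the
#' edges the mean is taken over the available neighbours (2-term means
#' for a window of 3).
#'
#' @param levels numeric vector of editing levels in `[0, 1]` (or a
#'   data.frame with a `level` column).
#' @param bin_width bin width in percentage points.
#' @param smooth_window centred moving-average window (odd).
#' @return data.frame of class `LevelHistogram` with columns bin_lo,
#'   bin_hi, count, frequency, smoothed.
#' @export
level_histogram <- function(levels, bin_width = 5, smooth_window = 3) {
  if (is.data.frame(levels)) levels <- levels$level
  stopifnot(all(levels >= 0 & levels <= 1), smooth_window %% 2 == 1)
  edges <- seq(0, 100, by = bin_width)
  pct <- 100 * levels
  idx <- pmin(findInterval(pct, edges, rightmost.closed = FALSE,
                           left.open = FALSE), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  freq <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_,
                                                             length(counts))
  half <- (smooth_window - 1) %/% 2
  smoothed <- vapply(seq_along(freq), function(i) {
    lo <- max(1, i - half); hi <- min(length(freq), i + half)
    mean(freq[lo:hi])
  }, 0)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = counts, frequency = freq, smoothed = smoothed)
  class(out) <- c("LevelHistogram", "data.frame")
  out
}

#' Relaxed retrieval of events at confident sites
#'
#' Builds an editing matrix over confident sites: a cell holds
#' `(depth, alt/depth)` whenever total depth >= `relaxed_min_depth`
#' (zero-level events retained; no allele-frequency floor), and is
#' missing otherwise or when the site is absent from the pileup.
#'
#' @param sites an [editing_sites()] data.frame.
#' @param pileup data.frame with columns chrom, pos0, sample_id, depth,
#'   alt_depth (one row per site x sample observed).
#' @param thresholds a [call_thresholds()].
#' @param samples optional fixed sample ordering.
#' @return an [editing_matrix()].
#' @export
relaxed_retrieval <- function(sites, pileup, thresholds = call_thresholds(),
                              samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(pileup$sample_id))
  ns <- nrow(sites); np <- length(samples)
  depth <- level <- matrix(NA_real_, ns, np)
  skey <- paste(sites$chrom, sites$pos0)
  pkey <- paste(pileup$chrom, pileup$pos0)
  si <- match(pkey, skey); ci <- match(pileup$sample_id, samples)
  ok <- !is.na(si) & !is.na(ci) & pileup$depth >= thresholds$relaxed_min_depth
  depth[cbind(si[ok], ci[ok])] <- pileup$depth[ok]
  level[cbind(si[ok], ci[ok])] <- pileup$alt_depth[ok] / pileup$depth[ok]
  editing_matrix(sites, samples, depth, level)
}

#' Minimal pileup over provided sites (fixture-scale)
#'
#' Counts, for each site and sample, the reads whose aligned blocks cover
#' the position and how many carry the alt base.  Intended for synthetic
#' fixtures, not for production-scale BAMs.
#'
#' @param sites an [editing_sites()] data.frame.
#' @param alignments_by_sample named list (sample_id ->
#'   list of ReadAlignment).
#' @return a pileup data.frame for [relaxed_retrieval()].
#' @export
pileup_sites <- function(sites, alignments_by_sample) {
  rows <- list()
  for (sample_id in names(alignments_by_sample)) {
    aln <- alignments_by_sample[[sample_id]]
    chroms <- vapply(aln, `[[`, "", "chrom")
    for (i in seq_len(nrow(sites))) {
      cand <- aln[chroms == sites$chrom[i]]
      bases <- vapply(cand, function(a)
        aligned_query_base(a$blocks, a$seq, sites$pos0[i]), "")
      covered <- !is.na(bases)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos0 = sites$pos0[i], sample_id = sample_id,
        depth = sum(covered), alt_depth = sum(bases[covered] == sites$alt[i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
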