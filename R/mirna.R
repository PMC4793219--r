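# 3'UTR microRNA seed-match disruption analysis.
#
# A-to-I editing inside a predicted seed match can destroy perfect
# Watson-Crick seed pairing (the edited A reads as G) or, symmetrically,
# create a perfect match that the unedited sequence lacks.  Combined with
# the gene's role (oncogene / tumour suppressor) and the direction of
# editing change in tumours, four regulatory subtypes describe how altered
# editing can promote tumour growth.

#' Construct a table of miRNA seed-match target sites
#'
#' @param family miRNA family name.
#' @param seed 7-mer seed (positions 2-8 of the mature miRNA, 5'->3',
#'   RNA alphabet; T accepted and converted to U).
#' @param chrom,start0,end0,strand genomic interval of the predicted
#'   seed match on the target (0-based half-open; length >= 7).
#' @return data.frame of class `MirnaTargetSites`.
#' @export
mirna_target_sites <- function(family, seed, chrom, start0, end0,
                               strand = "+") {
  seed <- chartr("tT", "uU", as.character(seed))
  seed <- toupper(seed)
  df <- data.frame(family = as.character(family), seed = seed,
                   chrom = as.character(chrom), start0 = as.integer(start0),
                   end0 = as.integer(end0), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(nchar(df$seed) != 7)) stop("seed must be a 7-mer")
  if (any(grepl("[^ACGU]", df$seed))) stop("seed must be RNA (A/C/G/U)")
  if (any(df$end0 - df$start0 < 7)) stop("seed-match interval shorter than 7")
  class(df) <- c("MirnaTargetSites", "data.frame")
  df
}

#' Intersect editing sites with miRNA seed-match intervals
#'
#' A single-base site at `pos0` overlaps a target interval iff
#' `start0 <= pos0 < end0`.  Strand-blind by default (the intersectBed
#' convention); set `stranded = TRUE` to require matching strands.
#'
#' @param sites an [editing_sites()] data.frame.
#' @param targets a [mirna_target_sites()] data.frame.
#' @param stranded require strand agreement.
#' @return data.frame pairing `site_key` with the overlapped target rows
#'   (columns site_key, site_idx, target_idx, family, seed, offset), where
#'   `offset` is the 0-based position of the site within the target
#'   interval.
#' @export
intersect_seed_regions <- function(sites, targets, stranded = FALSE) {
  s <- IRanges::IRanges(start = sites$pos0 + 1L, width = 1L)
  t <- IRanges::IRanges(start = targets$start0 + 1L,
                        width = targets$end0 - targets$start0)
  ov <- IRanges::findOverlaps(s, t)
  qi <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
  keep <- sites$chrom[qi] == targets$chrom[ti]
  if (stranded) keep <- keep & sites$strand[qi] == targets$strand[ti]
  qi <- qi[keep]; ti <- ti[keep]
  data.frame(site_key = site_key(sites)[qi], site_idx = qi, target_idx = ti,
             family = targets$family[ti], seed = targets$seed[ti],
             offset = sites$pos0[qi] - targets$start0[ti],
             stringsAsFactors = FALSE)
}

#' Effect of an A-to-I edit on seed complementarity
#'
#' The 7-base target subsequence (mRNA sense, 5'->3') pairs antiparallel
#' with the seed: seed position i pairs with target position 8 - i.
#' Canonical pairs are A:U and G:C; G:U wobble counts as pairing only when
#' `wobble_counts = TRUE`.  The edited sequence replaces the A at
#' `edited_offset` (0-based within the subsequence) by G.
#'
#' @param target_subseq 7-character target subsequence (DNA or RNA
#'   alphabet; T is read as U).
#' @param seed 7-mer seed (RNA).
#' @param edited_offset 0-based offset of the edited position in
#'   `target_subseq`; must be in `[0, 7)`.
#' @param wobble_counts count G:U wobble as a valid pair.
#' @return `"destroys"` (unedited matches perfectly, edited does not),
#'   `"creates"` (the reverse) or `"none"`.
#' @export
evaluate_seed_effect <- function(target_subseq, seed, edited_offset,
                                 wobble_counts = FALSE) {
  target <- toupper(chartr("tT", "uU", target_subseq))
  target <- chartr("T", "U", target)
  seed <- toupper(chartr("tT", "uU", seed))
  stopifnot(nchar(target) == 7, nchar(seed) == 7)
  if (edited_offset < 0 || edited_offset >= 7)
    stop("edited_offset must be in [0, 7)")
  tgt <- strsplit(target, "")[[1]]
  if (tgt[edited_offset + 1] != "A")
    return("none") # only an A can be edited; no state change otherwise
  edited <- tgt
  edited[edited_offset + 1] <- "G"
  perfect <- function(t) .seed_match(t, seed, wobble_counts)
  u <- perfect(tgt); e <- perfect(edited)
  if (u && !e) "destroys" else if (!u && e) "creates" else "none"
}

# Perfect seed match: seed position i (1..7, 5'->3') pairs with target
# position 8 - i (antiparallel).
.seed_match <- function(target_chars, seed, wobble_counts) {
  sd <- strsplit(seed, "")[[1]]
  for (i in 1:7) {
    s <- sd[i]; t <- target_chars[8 - i]
    ok <- (s == "A" && t == "U") || (s == "U" && t == "A") ||
      (s == "G" && t == "C") || (s == "C" && t == "G")
    if (wobble_counts)
      ok <- ok || (s == "G" && t == "U") || (s == "U" && t == "G")
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Correlation between editing and expression changes
#'
#' Pearson correlation between per-sample editing-level deltas and log2
#' expression deltas, after excluding listed samples (e.g. those with a
#' copy-number alteration at the locus).
#'
#' @param delta_editing,delta_expression named numeric vectors (names are
#'   sample ids) or unnamed equal-length vectors.
#' @param exclude sample ids to drop before computing.
#' @return list(r, n, flagged); `r` is NA and `flagged` TRUE when fewer
#'   than 3 samples remain or either vector has zero variance.
#' @export
delta_correlation <- function(delta_editing, delta_expression,
                              exclude = character()) {
  if (!is.null(names(delta_editing)) && !is.null(names(delta_expression))) {
    common <- intersect(names(delta_editing), names(delta_expression))
    common <- setdiff(common, exclude)
    x <- delta_editing[common]; y <- delta_expression[common]
  } else {
    stopifnot(length(delta_editing) == length(delta_expression))
    keep <- !(seq_along(delta_editing) %in% exclude)
    x <- delta_editing[keep]; y <- delta_expression[keep]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n = length(x), flagged = TRUE))
  list(r = cor(x, y), n = length(x), flagged = FALSE)
}

#' Compare two groups of correlation values
#'
#' Two-sample t-test on the r-values of a focal site group (e.g. the
#' seed-disrupting sites) versus a background group; Welch
#' (unequal-variance) by default.
#'
#' @param group_a,group_b numeric vectors of correlations (length >= 2).
#' @param pooled use the pooled-variance (classic Student) test.
#' @return list(t, p, df).
#' @export
compare_correlation_groups <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 values")
  ht <- t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Classify a site into the four-subtype regulatory model
#'
#' The model table maps (gene role, direction of editing change in tumour,
#' seed effect) onto subtypes:
#' \itemize{
#'   \item I: oncogene, editing up, edit destroys the seed match --
#'     miRNA repression of the oncogene is lost.
#'   \item II: tumour suppressor, editing up, edit creates a seed match --
#'     the suppressor acquires miRNA repression.
#'   \item III: tumour suppressor, editing down, edit destroys --
#'     the less-edited transcript regains the site and is repressed.
#'   \item IV: oncogene, editing down, edit creates -- the less-edited
#'     transcript loses the editing-created site and escapes repression.
#' }
#' Any other triple is `inconsistent` with the model.
#'
#' @param role "oncogene" or "tumor_suppressor".
#' @param direction "up" or "down".
#' @param seed_effect "destroys", "creates" or "none".
#' @return list(role, direction, seed_effect, subtype) where subtype is
#'   "I", "II", "III", "IV" or "inconsistent".
#' @export
classify_regulatory_subtype <- function(role = c("oncogene", "tumor_suppressor"),
                                        direction = c("up", "down"),
                                        seed_effect = c("destroys", "creates",
                                                        "none")) {
  role <- match.arg(role); direction <- match.arg(direction)
  seed_effect <- match.arg(seed_effect)
  subtype <- if (role == "oncogene" && direction == "up" &&
                 seed_effect == "destroys") "I"
  else if (role == "tumor_suppressor" && direction == "up" &&
           seed_effect == "creates") "II"
  else if (role == "tumor_suppressor" && direction == "down" &&
           seed_effect == "destroys") "III"
  else if (role == "oncogene" && direction == "down" &&
           seed_effect == "creates") "IV"
  else "inconsistent"
  list(role = role, direction = direction, seed_effect = seed_effect,
       subtype = subtype)
}
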