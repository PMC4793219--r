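# Cross-sample recurrence, cohort validation, paired differential editing
# with Benjamini-Hochberg FDR, and per-gene direction summaries.

#' Validation rule for cohort support of an editing site
#'
#' A sample *supports* a site when depth >= `min_depth`, edited reads >=
#' `min_alt` and allele frequency >= `min_af` (all inclusive).  Sites
#' supported by at least `real_min_samples` samples are called real.
#'
#' @param min_depth,min_alt,min_af,real_min_samples rule parameters.
#' @return list of class `ValidationRule`.
#' @export
validation_rule <- function(min_depth = 10L, min_alt = 1L, min_af = 0.01,
                            real_min_samples = 2L) {
  stopifnot(min_depth > 0, min_alt > 0, min_af > 0, real_min_samples > 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt = as.integer(min_alt), min_af = min_af,
                 real_min_samples = as.integer(real_min_samples)),
            class = "ValidationRule")
}

#' Recurrence of editing across samples
#'
#' Restricted to sites with depth >= `min_depth` in *every* sample, counts
#' per site the number of samples with non-zero editing level.
#'
#' @param matrix an [editing_matrix()].
#' @param min_depth per-sample coverage floor (inclusive).
#' @return data.frame(site, n_samples_present) over qualifying sites.
#' @export
recurrence_distribution <- function(matrix, min_depth = 20L) {
  stopifnot(length(matrix$samples) >= 1)
  ok <- apply(!is.na(matrix$depth) & matrix$depth >= min_depth, 1, all)
  present <- rowSums(matrix$level[ok, , drop = FALSE] > 0)
  data.frame(site = site_key(matrix$sites)[ok],
             n_samples_present = as.integer(present),
             stringsAsFactors = FALSE)
}

#' Validate one site against a cohort
#'
#' Categories: `real` (supported by >= `real_min_samples` samples),
#' `likely` (exactly one), `unsupported` (no support but at least one
#' sample had depth >= `min_depth`), `insufficient` (no sample reached the
#' coverage floor, or empty cohort).
#'
#' @param cells data.frame with columns depth, alt (edited reads) and af,
#'   one row per cohort sample.
#' @param rule a [validation_rule()].
#' @return one of "real", "likely", "unsupported", "insufficient".
#' @export
validate_against_cohort <- function(cells, rule = validation_rule()) {
  if (is.null(cells) || nrow(cells) == 0) return("insufficient")
  covered <- cells$depth >= rule$min_depth
  supporting <- covered & cells$alt >= rule$min_alt & cells$af >= rule$min_af
  n <- sum(supporting)
  if (n >= rule$real_min_samples) "real"
  else if (n == 1) "likely"
  else if (any(covered)) "unsupported"
  else "insufficient"
}

#' Paired t-test on editing levels
#'
#' Classic paired Student t on the per-pair differences with n - 1 degrees
#' of freedom.  Degenerate inputs follow a stated convention: identical
#' vectors give t = 0, p = 1; zero-variance differences with non-zero mean
#' give p = 0 and are flagged.
#'
#' @param tumor,normal equal-length numeric vectors, paired by index.
#' @return list(t, p, df, mean_diff, degenerate).
#' @export
paired_t_test <- function(tumor, normal) {
  stopifnot(length(tumor) == length(normal))
  n <- length(tumor)
  if (n < 2) stop("paired t-test requires at least 2 pairs")
  d <- tumor - normal
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0,
                            degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1, mean_diff = m,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j: p_j >= p_i} (m * p_j / rank_j)`, i.e. `p * m / rank`
#' followed by a cumulative minimum from the largest p down, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  ord <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * pvalues[ord]))
  q[order(ord)]
}

#' Paired tumour-normal differential editing
#'
#' For each site, editing levels are compared across tumour-normal pairs
#' with a paired t-test; pairs with a missing cell in either member are
#' dropped, and sites with fewer than `min_pairs` usable pairs are not
#' tested.  Benjamini-Hochberg q-values are computed across all tested
#' sites of the tumour type (optionally within region-class families).
#'
#' @param matrix an [editing_matrix()] containing both tumour and normal
#'   columns.
#' @param pairs data.frame with columns `tumor` and `normal` naming matrix
#'   columns.
#' @param tumor_type label carried into the results.
#' @param alpha significance cutoff on q.
#' @param min_pairs minimum usable pairs per site.
#' @param by_region if TRUE, BH families are (tumour type x region class)
#'   instead of pooling all tested sites of the tumour type.
#' @return data.frame of class `DifferentialResult`: site fields plus
#'   n_pairs, mean_tumor, mean_normal, delta, t, p, q, direction,
#'   significant.
#' @export
differential_editing <- function(matrix, pairs, tumor_type = "cohort",
                                 alpha = 0.05, min_pairs = 10L,
                                 by_region = FALSE) {
  ti <- match(pairs$tumor, matrix$samples)
  ni <- match(pairs$normal, matrix$samples)
  if (anyNA(ti) || anyNA(ni)) stop("pairs reference unknown matrix columns")
  rows <- list()
  for (i in seq_len(nrow(matrix$sites))) {
    tl <- matrix$level[i, ti]; nl <- matrix$level[i, ni]
    ok <- !is.na(tl) & !is.na(nl)
    if (sum(ok) < min_pairs) next
    tt <- paired_t_test(tl[ok], nl[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      matrix$sites[i, c("chrom", "pos0", "ref", "alt", "strand", "region",
                        "gene", "key")],
      tumor_type = tumor_type, n_pairs = sum(ok),
      mean_tumor = mean(tl[ok]), mean_normal = mean(nl[ok]),
      delta = mean(tl[ok]) - mean(nl[ok]), t = tt$t, p = tt$p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no testable sites (all below min_pairs)")
    return(data.frame())
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (by_region) {
    res$q <- NA_real_
    for (rg in unique(res$region))
      res$q[res$region == rg] <- bh_fdr(res$p[res$region == rg])
  } else {
    res$q <- bh_fdr(res$p)
  }
  res$direction <- ifelse(res$delta >= 0, "up", "down")
  res$significant <- res$q <= alpha
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Classify the editing direction of one site across tumour types
#'
#' A site is called `up` iff at least two tumour types show a significant
#' increase while no more than one shows a significant decrease; `down`
#' symmetrically; otherwise `not_called`.
#'
#' @param results data.frame with one row per tumour type for the site and
#'   columns `significant` (logical) and `direction` ("up"/"down").
#' @return "up", "down" or "not_called".
#' @export
classify_site_direction <- function(results) {
  n_up <- sum(results$significant & results$direction == "up")
  n_down <- sum(results$significant & results$direction == "down")
  if (n_up >= 2 && n_down <= 1) "up"
  else if (n_down >= 2 && n_up <= 1) "down"
  else "not_called"
}

#' Per-gene summary of site direction calls
#'
#' Counts, per gene, the sites called up and down; a gene is `consistent`
#' when all its called sites agree in direction (exactly one of the two
#' counts is zero and the other positive).
#'
#' @param site_calls data.frame with columns `gene` and `call`
#'   ("up"/"down"/"not_called").
#' @param gene_filter optional character vector restricting the genes
#'   (e.g. a cancer gene census list).
#' @param min_sites minimum number of called (up or down) sites for a gene
#'   to be reported.
#' @return data.frame of class `GeneDirectionSummary` with columns gene,
#'   n_sites_up, n_sites_down, consistent.
#' @export
summarize_gene_directions <- function(site_calls, gene_filter = NULL,
                                      min_sites = 2L) {
  sc <- site_calls[site_calls$call %in% c("up", "down"), , drop = FALSE]
  if (!is.null(gene_filter)) sc <- sc[sc$gene %in% gene_filter, , drop = FALSE]
  genes <- sort(unique(sc$gene))
  out <- data.frame(
    gene = genes,
    n_sites_up = vapply(genes, function(g)
      sum(sc$gene == g & sc$call == "up"), 0L),
    n_sites_down = vapply(genes, function(g)
      sum(sc$gene == g & sc$call == "down"), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$n_sites_up + out$n_sites_down >= min_sites, , drop = FALSE]
  out$consistent <- pmin(out$n_sites_up, out$n_sites_down) == 0 &
    pmax(out$n_sites_up, out$n_sites_down) > 0
  rownames(out) <- NULL
  class(out) <- c("GeneDirectionSummary", "data.frame")
  out
}
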