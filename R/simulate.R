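# Seeded synthetic-data generators with truth tables.
#
# The generators emulate the input shapes of an RNA-editing study without
# any external data: a small genome with paralogous duplications and
# two-exon gene models; reads with planted editing and deliberately
# mis-recorded artifact alignments (the target of the RAAR filter is the
# adjudication, not the aligner, so artifact reads are emitted
# pre-misaligned); paired tumour/normal editing matrices with planted
# differential effects (beta-binomial counts for realistic
# overdispersion); and expression deltas coupled to editing deltas at a
# stated population correlation.  All outputs are byte-identical for a
# fixed seed.

#' Fixture specification for the synthetic generators
#'
#' Defaults describe the package's stated test world: a two-chromosome
#' 40 kb genome, 75-base error-free reads at 50x over planted sites,
#' editing levels 0.2-0.6, artifact counts matching the acceptance
#' fixture, and a 40-pair cohort of 1000 sites with 50 planted
#' differential sites at delta = 0.15 and beta-binomial overdispersion
#' 0.01.
#'
#' @param seed integer seed; the same seed and spec give byte-identical
#'   outputs.
#' @param genome,editing,artifacts,reads,cohort,coupling plan lists;
#'   any omitted entry keeps its default.
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, genome = list(), editing = list(),
                         artifacts = list(), reads = list(),
                         cohort = list(), coupling = list()) {
  merge <- function(def, usr) { def[names(usr)] <- usr; def }
  spec <- structure(list(
    seed = as.integer(seed),
    genome = merge(list(n_chrom = 2L, chrom_length = 20000L,
                        paralog_length = 300L, paralog_divergence = 0,
                        n_genes = 12L, exon_length = 300L,
                        intron_length = 150L), genome),
    editing = merge(list(n_sites = 30L, level_range = c(0.2, 0.6),
                         substitution_mix = c("A>G" = 1)), editing),
    artifacts = merge(list(n_paralog = 10L, n_junction = 10L, n_indel = 5L,
                           indel_size = 3L), artifacts),
    reads = merge(list(depth = 50L, read_length = 75L, error_rate = 0,
                       artifact_depth = 12L), reads),
    cohort = merge(list(n_pairs = 40L, n_sites = 1000L, n_differential = 50L,
                        delta = 0.15, base_level = c(0.1, 0.4),
                        overdispersion = 0.01, mean_depth = 50L), cohort),
    coupling = merge(list(target_r = 0.1, n_coupled = 3L,
                          base_delta_expr_sd = 0.5), coupling)),
    class = "FixtureSpec")
  stopifnot(spec$cohort$overdispersion >= 0, spec$cohort$overdispersion < 1,
            all(spec$editing$level_range >= 0 & spec$editing$level_range <= 1))
  spec
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
}

#' Simulate a genome with paralogous duplications and gene models
#'
#' Chromosome 1 carries the gene models (two exons each, so every gene has
#' one splice junction) and the true-editing loci; paralog source segments
#' live on chromosome 1 and their (near-)verbatim copies on chromosome 2.
#' Each copy pair is identical except one forced divergent base at the
#' segment centre (the multi-alignment artifact position) plus optional
#' random divergence.  The first intron base of every gene is forced to
#' differ from the first base of the downstream exon so that ungapped
#' read-through at the junction always produces a mismatch.
#'
#' @param spec a [fixture_spec()].
#' @return list(reference, annotation, paralog_map, gene_table).
#' @export
simulate_genome_with_paralogs <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  g <- spec$genome
  chroms <- paste0("chr", seq_len(g$n_chrom))
  seqs <- setNames(vapply(chroms, function(z) .rand_dna(g$chrom_length), ""),
                   chroms)
  # gene models on chr1: [exon1][intron][exon2], laid out left to right
  gene_span <- 2L * g$exon_length + g$intron_length
  slot <- gene_span + 200L
  genes <- data.frame(
    gene = paste0("gene", seq_len(g$n_genes)),
    chrom = "chr1",
    e1_start = 500L + (seq_len(g$n_genes) - 1L) * slot, stringsAsFactors = FALSE)
  genes$e1_end <- genes$e1_start + g$exon_length
  genes$e2_start <- genes$e1_end + g$intron_length
  genes$e2_end <- genes$e2_start + g$exon_length
  if (max(genes$e2_end) > g$chrom_length - 100L)
    stop("chromosome too short for the requested gene models")
  # force intron[0] != exon2[0] at every junction
  s1 <- strsplit(seqs["chr1"], "")[[1]]
  for (i in seq_len(nrow(genes))) {
    i0 <- genes$e1_end[i] + 1L       # 1-based index of first intron base
    e0 <- genes$e2_start[i] + 1L
    if (s1[i0] == s1[e0])
      s1[i0] <- sample(setdiff(c("A", "C", "G", "T"), s1[e0]), 1)
  }
  seqs["chr1"] <- paste(s1, collapse = "")
  # paralogs: sources interleaved after the genes on chr1, copies on chr2
  n_par <- spec$artifacts$n_paralog
  if (n_par > 0 && g$n_chrom < 2)
    stop("paralog copies need a second chromosome")
  src_base <- max(genes$e2_end) + 500L
  if (src_base + n_par * (g$paralog_length + 100L) > g$chrom_length)
    stop("chromosome too short for the requested paralogs")
  pmap <- data.frame(
    id = if (n_par > 0) paste0("par", seq_len(n_par)) else character(0),
    src_chrom = rep("chr1", n_par),
    src_start0 = src_base + (seq_len(n_par) - 1L) * (g$paralog_length + 100L),
    dst_chrom = rep(chroms[min(2L, g$n_chrom)], n_par),
    dst_start0 = 500L + (seq_len(n_par) - 1L) * (g$paralog_length + 100L),
    length = rep(g$paralog_length, n_par), stringsAsFactors = FALSE)
  for (i in seq_len(n_par)) {
    seg <- substr(seqs[pmap$src_chrom[i]], pmap$src_start0[i] + 1L,
                  pmap$src_start0[i] + pmap$length[i])
    segc <- strsplit(seg, "")[[1]]
    if (g$paralog_divergence > 0) {
      mut <- which(runif(length(segc)) < g$paralog_divergence)
      segc[mut] <- .other_base(segc[mut])
    }
    # forced divergent base at the segment centre
    mid <- pmap$length[i] %/% 2L
    segc[mid + 1L] <- sample(setdiff(c("A", "C", "G", "T"), segc[mid + 1L]), 1)
    dst <- seqs[pmap$dst_chrom[i]]
    seqs[pmap$dst_chrom[i]] <- paste0(
      substr(dst, 1L, pmap$dst_start0[i]),
      paste(segc, collapse = ""),
      substr(dst, pmap$dst_start0[i] + pmap$length[i] + 1L, nchar(dst)))
  }
  ann <- exon_annotation(
    chrom = rep(genes$chrom, each = 2L),
    start0 = as.vector(rbind(genes$e1_start, genes$e2_start)),
    end0 = as.vector(rbind(genes$e1_end, genes$e2_end)),
    transcript_id = rep(genes$gene, each = 2L), strand = "+")
  list(reference = genome_reference(seqs), annotation = ann,
       paralog_map = pmap, gene_table = genes)
}

# one SAM line for an ungapped/custom alignment
.sam_line <- function(id, chrom, pos1, cigar, seq, flag = 0L, mapq = 50L) {
  paste(id, flag, chrom, pos1, mapq, cigar, "*", 0, 0, seq, "*", sep = "\t")
}

#' Simulate reads with planted editing and planted artifacts
#'
#' Emits a SAM fixture, the implied candidate-variant table (VCF-shaped)
#' and a truth table labelling every variant:
#' \describe{
#'   \item{true_editing}{mid-exon A>G sites; edited reads drawn
#'     binomially at the planted level.}
#'   \item{SPLICE_JUNCTION}{junction-spanning reads recorded as ungapped
#'     alignments over-hanging into the intron; the first intron base
#'     becomes a false variant.  Correctly spliced (N-CIGAR) reads are
#'     also emitted and must not support the variant.}
#'   \item{MULTI_ALIGNMENT}{reads from the paralog copy recorded at the
#'     source locus; the copy's divergent base becomes a false variant.}
#'   \item{INDEL_ARTIFACT}{reads from a small-deletion haplotype recorded
#'     ungapped; the first downstream mismatch becomes a false variant.}
#' }
#'
#' @param genome output of [simulate_genome_with_paralogs()].
#' @param spec the same [fixture_spec()].
#' @return list(sam (character lines), variants ([variant_calls()]),
#'   truth (data.frame key/class/level), sites (true [editing_sites()])).
#' @export
simulate_reads_with_artifacts <- function(genome, spec = fixture_spec()) {
  set.seed(spec$seed + 1L)
  ref <- genome$reference; genes <- genome$gene_table
  rl <- spec$reads$read_length
  depth <- spec$reads$depth
  adepth <- spec$reads$artifact_depth
  if (depth <= 0) stop("read depth at planted sites must be positive")
  sam <- character(0); variants <- list(); truth <- list()
  rid <- 0L
  nid <- function(tag) { rid <<- rid + 1L; sprintf("%s_%06d", tag, rid) }
  emit <- function(lines) sam <<- c(sam, lines)
  base_at <- function(chrom, pos0)
    substr(ref$sequences[[chrom]], pos0 + 1L, pos0 + 1L)
  maybe_err <- function(s) {
    if (spec$reads$error_rate <= 0) return(s)
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < spec$reads$error_rate)
    if (length(hit)) ch[hit] <- .other_base(ch[hit])
    paste(ch, collapse = "")
  }

  # ---- true editing sites: mid-exon positions with ref base A ----------
  n_sites <- spec$editing$n_sites
  margin <- rl + 10L
  cand <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    e1 <- (genes$e1_start[i] + margin):(genes$e1_end[i] - margin)
    data.frame(gene = genes$gene[i], pos0 = e1, stringsAsFactors = FALSE)
  }))
  cand$base <- vapply(cand$pos0, function(p) base_at("chr1", p), "")
  cand <- cand[cand$base == "A", , drop = FALSE]
  if (nrow(cand) < n_sites)
    stop("not enough mid-exon A positions for the requested sites")
  picked <- cand[sort(sample(nrow(cand), n_sites)), , drop = FALSE]
  levels <- runif(n_sites, spec$editing$level_range[1],
                  spec$editing$level_range[2])
  for (i in seq_len(n_sites)) {
    p <- picked$pos0[i]
    # candidate variants model a caller's output: events below the 5-read
    # stringent floor would never appear in the VCF, so the draw is
    # conditioned on detectability (bounded redraw, deterministic per seed)
    n_alt <- rbinom(1, depth, levels[i])
    tries <- 0L
    while (n_alt < 5L && tries < 1000L) {
      n_alt <- rbinom(1, depth, levels[i]); tries <- tries + 1L
    }
    n_alt <- max(n_alt, min(5L, depth))
    starts <- p - sample.int(rl - 10L, depth, replace = TRUE) - 4L
    is_alt <- c(rep(TRUE, n_alt), rep(FALSE, depth - n_alt))
    for (j in seq_len(depth)) {
      s0 <- starts[j]
      sq <- substr(ref$sequences[["chr1"]], s0 + 1L, s0 + rl)
      if (is_alt[j]) substr(sq, p - s0 + 1L, p - s0 + 1L) <- "G"
      emit(.sam_line(nid("edit"), "chr1", s0 + 1L, paste0(rl, "M"),
                     maybe_err(sq)))
    }
    if (n_alt > 0) {
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = "chr1", pos0 = p, ref = "A", alt = "G",
        total_depth = depth, alt_depth = n_alt, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        key = paste0("chr1:", p, ":A>G"), class = "true_editing",
        level = levels[i], gene = picked$gene[i], stringsAsFactors = FALSE)
    }
  }
  true_sites <- do.call(rbind, truth)

  # ---- junction artifacts ---------------------------------------------
  n_j <- spec$artifacts$n_junction
  if (n_j > nrow(genes)) stop("more junction artifacts than gene junctions")
  for (i in seq_len(n_j)) {
    j_end <- genes$e1_end[i]          # exon1 end0 = first intron base pos0
    e2 <- genes$e2_start[i]
    pos0 <- j_end
    refb <- base_at("chr1", pos0)
    altb <- base_at("chr1", e2)       # exon2 first base, forced != refb
    for (j in seq_len(adepth)) {
      len1 <- sample(25:(rl - 25L), 1)
      len2 <- rl - len1
      sq <- paste0(substr(ref$sequences[["chr1"]], j_end - len1 + 1L, j_end),
                   substr(ref$sequences[["chr1"]], e2 + 1L, e2 + len2))
      # recorded ungapped, over-hanging into the intron
      emit(.sam_line(nid("junc"), "chr1", j_end - len1 + 1L,
                     paste0(rl, "M"), maybe_err(sq)))
    }
    # correctly spliced reads over the same junction (N CIGAR)
    for (j in seq_len(8L)) {
      len1 <- sample(25:(rl - 25L), 1)
      len2 <- rl - len1
      sq <- paste0(substr(ref$sequences[["chr1"]], j_end - len1 + 1L, j_end),
                   substr(ref$sequences[["chr1"]], e2 + 1L, e2 + len2))
      cig <- sprintf("%dM%dN%dM", len1, e2 - j_end, len2)
      emit(.sam_line(nid("spl"), "chr1", j_end - len1 + 1L, cig,
                     maybe_err(sq)))
    }
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = "chr1", pos0 = pos0, ref = refb, alt = altb,
      total_depth = adepth, alt_depth = adepth, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      key = paste0("chr1:", pos0, ":", refb, ">", altb),
      class = "SPLICE_JUNCTION", level = NA_real_, gene = genes$gene[i],
      stringsAsFactors = FALSE)
  }

  # ---- multi-alignment (paralog) artifacts ----------------------------
  pmap <- genome$paralog_map
  for (i in seq_len(spec$artifacts$n_paralog)) {
    mid <- pmap$length[i] %/% 2L
    srcp <- pmap$src_start0[i] + mid     # variant position on the source
    dstp <- pmap$dst_start0[i] + mid
    refb <- base_at(pmap$src_chrom[i], srcp)
    altb <- base_at(pmap$dst_chrom[i], dstp)   # forced divergent base
    # reads genuinely from the copy, recorded at the source locus
    for (j in seq_len(adepth)) {
      off <- sample.int(rl - 10L, 1) + 4L
      sq <- substr(ref$sequences[[pmap$dst_chrom[i]]],
                   dstp - off + 2L, dstp - off + rl + 1L)
      emit(.sam_line(nid("para"), pmap$src_chrom[i], srcp - off + 2L,
                     paste0(rl, "M"), maybe_err(sq)))
    }
    # honest reference reads at the source locus for depth
    for (j in seq_len(adepth)) {
      off <- sample.int(rl - 10L, 1) + 4L
      sq <- substr(ref$sequences[[pmap$src_chrom[i]]],
                   srcp - off + 2L, srcp - off + rl + 1L)
      emit(.sam_line(nid("srcref"), pmap$src_chrom[i], srcp - off + 2L,
                     paste0(rl, "M"), maybe_err(sq)))
    }
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = pmap$src_chrom[i], pos0 = srcp, ref = refb, alt = altb,
      total_depth = 2L * adepth, alt_depth = adepth, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      key = paste0(pmap$src_chrom[i], ":", srcp, ":", refb, ">", altb),
      class = "MULTI_ALIGNMENT", level = NA_real_, gene = NA_character_,
      stringsAsFactors = FALSE)
  }

  # ---- indel-adjacent artifacts ---------------------------------------
  # deletion haplotypes in the second exon of the first n_indel genes
  del <- spec$artifacts$indel_size
  for (i in seq_len(spec$artifacts$n_indel)) {
    g <- genes[i, ]
    dstart <- g$e2_start + 60L              # deletion of ref [dstart, dstart+del)
    hap <- paste0(substr(ref$sequences[["chr1"]], dstart - 60L + 1L, dstart),
                  substr(ref$sequences[["chr1"]], dstart + del + 1L,
                         dstart + del + 120L))
    # first downstream position where the ungapped read-through mismatches
    post <- substr(ref$sequences[["chr1"]], dstart + 1L, dstart + 60L)
    shifted <- substr(ref$sequences[["chr1"]], dstart + del + 1L,
                      dstart + del + 60L)
    mm <- which(strsplit(post, "")[[1]] != strsplit(shifted, "")[[1]])[1]
    pos0 <- dstart + mm - 1L
    refb <- base_at("chr1", pos0)
    altb <- substr(shifted, mm, mm)
    for (j in seq_len(adepth)) {
      off <- sample(20:40, 1)              # bases of haplotype before dstart
      hs <- 60L - off + 1L
      sq <- substr(hap, hs, hs + rl - 1L)
      # recorded ungapped at the position implied by the read prefix
      emit(.sam_line(nid("indel"), "chr1", dstart - off + 1L,
                     paste0(rl, "M"), maybe_err(sq)))
    }
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = "chr1", pos0 = pos0, ref = refb, alt = altb,
      total_depth = adepth, alt_depth = adepth, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      key = paste0("chr1:", pos0, ":", refb, ">", altb),
      class = "INDEL_ARTIFACT", level = NA_real_, gene = g$gene,
      stringsAsFactors = FALSE)
  }

  vdf <- do.call(rbind, variants)
  vdf$sample_id <- "fixture"
  vdf$af <- vdf$alt_depth / vdf$total_depth
  vdf <- validate_variant_calls(
    vdf[, c("chrom", "pos0", "ref", "alt", "total_depth", "alt_depth",
            "sample_id", "af")])
  tdf <- do.call(rbind, truth)
  if (anyDuplicated(tdf$key)) stop("internal: duplicate truth keys")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$lengths), ref$lengths))
  tkeys <- tdf$key[tdf$class == "true_editing"]
  sites <- editing_sites(vdf$chrom, vdf$pos0, vdf$ref, vdf$alt)
  list(sam = c(header, sam), variants = vdf, truth = tdf,
       sites = sites[sites$key %in% tkeys, , drop = FALSE])
}

# beta-binomial draw: n trials, mean p, overdispersion rho
.rbetabinom <- function(k, n, p, rho) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (rho <= 0) return(rbinom(k, n, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  rbinom(k, n, rbeta(k, a, b))
}

#' Simulate a paired tumour/normal editing cohort
#'
#' Per site, a base editing level is drawn from the spec's range; per
#' sample, depth is Poisson and edited reads are beta-binomial around the
#' (tumour-shifted, for the planted differential sites) base level.
#' Cells under the relaxed depth floor are missing.
#'
#' @param spec a [fixture_spec()].
#' @param thresholds a [call_thresholds()] supplying the relaxed depth
#'   floor for the missing mask.
#' @return list(matrix ([editing_matrix()] with tumour+normal columns),
#'   pairs (data.frame tumor/normal), truth (per-site differential flag,
#'   delta, base_level)).
#' @export
simulate_editing_cohort <- function(spec = fixture_spec(),
                                    thresholds = call_thresholds()) {
  set.seed(spec$seed + 2L)
  co <- spec$cohort
  stopifnot(co$n_pairs >= 2)
  ns <- co$n_sites; np <- co$n_pairs
  tumor <- paste0("T", sprintf("%03d", seq_len(np)))
  normal <- paste0("N", sprintf("%03d", seq_len(np)))
  base <- runif(ns, co$base_level[1], co$base_level[2])
  diff_idx <- if (co$n_differential > 0) sort(sample.int(ns, co$n_differential))
              else integer(0)
  delta <- numeric(ns); delta[diff_idx] <- co$delta
  sites <- editing_sites("chrE", seq_len(ns) * 100L, "A", "G",
                         region = rep(c("coding", "3UTR"), length.out = ns),
                         gene = paste0("gene", ceiling(seq_len(ns) / 5)))
  draw <- function(mean_level) {
    depth <- matrix(rpois(ns * np, co$mean_depth), ns, np)
    edited <- matrix(0L, ns, np)
    for (i in seq_len(ns))
      edited[i, ] <- .rbetabinom(np, depth[i, ], mean_level[i],
                                 co$overdispersion)
    level <- ifelse(depth > 0, edited / depth, NA)
    miss <- depth < thresholds$relaxed_min_depth
    depth[miss] <- NA; level[miss] <- NA
    list(depth = depth, level = level)
  }
  tum <- draw(pmin(base + delta, 0.99))
  nor <- draw(base)
  mat <- editing_matrix(sites, c(tumor, normal),
                        cbind(tum$depth, nor$depth),
                        cbind(tum$level, nor$level))
  truth <- data.frame(key = site_key(sites), differential = delta > 0,
                      delta = delta, base_level = base,
                      stringsAsFactors = FALSE)
  list(matrix = mat, pairs = data.frame(tumor = tumor, normal = normal,
                                        stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate expression deltas coupled to editing deltas
#'
#' For each coupled site, the per-pair expression delta is
#' `beta * delta_editing + noise`, with the noise standard deviation
#' chosen so the population Pearson correlation equals `target_r`
#' (`r = beta * sd_edit / sqrt(beta^2 sd_edit^2 + sd_noise^2)`).
#' Uncoupled sites get pure noise (r = 0).
#'
#' @param cohort output of [simulate_editing_cohort()].
#' @param spec the same [fixture_spec()]; `spec$coupling$target_r` and
#'   `n_coupled` control the coupling.
#' @param seed optional override of the derived noise seed.
#' @return list(delta_editing (site x pair matrix), delta_expression
#'   (same shape), truth (per-site target r)).
#' @export
simulate_coupled_expression <- function(cohort, spec = fixture_spec(),
                                        seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed + 3L else seed)
  cp <- spec$coupling
  if (abs(cp$target_r) > 1) stop("infeasible target correlation")
  m <- cohort$matrix
  ti <- match(cohort$pairs$tumor, m$samples)
  ni <- match(cohort$pairs$normal, m$samples)
  d_edit <- m$level[, ti, drop = FALSE] - m$level[, ni, drop = FALSE]
  ns <- nrow(d_edit); np <- ncol(d_edit)
  coupled <- seq_len(min(cp$n_coupled, ns))
  d_expr <- matrix(rnorm(ns * np, 0, cp$base_delta_expr_sd), ns, np)
  target <- numeric(ns)
  if (abs(cp$target_r) > 0) {
    for (i in coupled) {
      x <- d_edit[i, ]
      sd_edit <- sd(x, na.rm = TRUE)
      beta <- sign(cp$target_r)
      sd_noise <- if (abs(cp$target_r) == 1) 0 else
        sd_edit * sqrt(1 / cp$target_r^2 - 1)
      d_expr[i, ] <- beta * x + rnorm(np, 0, sd_noise)
      target[i] <- cp$target_r
    }
  }
  dimnames(d_edit) <- dimnames(d_expr) <-
    list(site_key(m$sites), cohort$pairs$tumor)
  list(delta_editing = d_edit, delta_expression = d_expr,
       truth = data.frame(key = site_key(m$sites), target_r = target,
                          stringsAsFactors = FALSE))
}

#' Write a read-level fixture to disk
#'
#' @param genome output of [simulate_genome_with_paralogs()].
#' @param reads output of [simulate_reads_with_artifacts()].
#' @param outdir directory (created if needed).
#' @return named character vector of the emitted paths.
#' @export
write_fixture <- function(genome, reads, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             bed = file.path(outdir, "exons.bed"),
             sam = file.path(outdir, "reads.sam"),
             vcf = file.path(outdir, "candidates.vcf"),
             truth = file.path(outdir, "truth.tsv"))
  write_genome_fasta(genome$reference, paths["fasta"])
  a <- genome$annotation
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", a$chrom, a$start0, a$end0,
                     a$transcript_id, a$strand), paths["bed"])
  writeLines(reads$sam, paths["sam"])
  write_variant_vcf(reads$variants, paths["vcf"], "editscan-simulate")
  write.table(reads$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
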