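# Readers and writers for the interchange formats the toolkit touches.
#
# The VCF reader is deliberately small and dialect-driven: editing pipelines
# consume caller-specific FORMAT fields (VarScan's RD/AD/FREQ vs the
# DP + comma-separated AD convention), record-level skip/fail policy and
# line-numbered errors are part of the contract, so a thin targeted parser
# is used rather than a general-purpose VCF stack.

#' VCF dialect configuration
#'
#' Maps caller-specific FORMAT fields onto total and alt-supporting read
#' counts.  Two dialects ship with the package:
#' \describe{
#'   \item{varscan}{`RD` (ref reads), `AD` (alt reads), `FREQ` ("12.5\%").
#'     Depth = RD + AD.}
#'   \item{dp_ad}{`DP` plus comma-separated `AD` (ref,alt1,alt2,...).}
#' }
#' The reader tries the dialects in the order given and uses the first one
#' whose fields are present.
#'
#' @param dialects character vector, subset of `c("varscan", "dp_ad")`.
#' @param on_missing what to do when neither dialect's depth fields are
#'   present in a record: `"skip"` (count and drop) or `"fail"`.
#' @return a list of class `vcf_dialect_config`.
#' @export
vcf_dialect_config <- function(dialects = c("varscan", "dp_ad"),
                               on_missing = c("skip", "fail")) {
  dialects <- match.arg(dialects, c("varscan", "dp_ad"), several.ok = TRUE)
  structure(list(dialects = dialects, on_missing = match.arg(on_missing)),
            class = "vcf_dialect_config")
}

#' Parse candidate variant records from a VCF
#'
#' Reads SNV records from a VCF 4.x file or character vector of lines.
#' 1-based POS is converted to 0-based `pos0`; multi-allelic records are
#' split into one row per alternate allele; non-SNV records (indels,
#' symbolic alleles) are skipped and counted.
#'
#' @param x path to a VCF file, or a character vector of VCF lines.
#' @param sample_id label recorded in the `sample_id` column.
#' @param config a [vcf_dialect_config()].
#' @return a [variant_calls()] data.frame with attributes
#'   `skipped_nonsnv` (count) and `skipped_nodepth` (count), plus a
#'   `filter` column carrying the VCF FILTER field.
#' @export
parse_variant_records <- function(x, sample_id = "sample1",
                                  config = vcf_dialect_config()) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF header at line 1: missing ##fileformat")
  body_idx <- which(!startsWith(lines, "#"))
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1)
    stop("malformed VCF header: expected exactly one #CHROM line")
  out <- vector("list", length(body_idx))
  skipped_nonsnv <- 0L; skipped_nodepth <- 0L
  for (ii in seq_along(body_idx)) {
    ln <- body_idx[ii]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF line ", ln, ": fewer than 8 fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF line ", ln, ": non-integer POS")
    ref <- toupper(f[4]); alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    snv <- nchar(ref) == 1 && ref %in% c("A", "C", "G", "T") &
      nchar(alts) == 1 & alts %in% c("A", "C", "G", "T")
    if (!any(snv)) { skipped_nonsnv <- skipped_nonsnv + 1L; next }
    alts <- alts[snv]
    counts <- .vcf_depths(f, alts, config)
    if (is.null(counts)) {
      if (config$on_missing == "fail")
        stop("VCF line ", ln, ": no depth fields under the configured dialects")
      skipped_nodepth <- skipped_nodepth + 1L; next
    }
    out[[ii]] <- data.frame(chrom = f[1], pos0 = pos - 1L, ref = ref,
                            alt = alts, total_depth = counts$dp,
                            alt_depth = counts$ad, sample_id = sample_id,
                            filter = f[7], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df))
    df <- data.frame(chrom = character(), pos0 = integer(), ref = character(),
                     alt = character(), total_depth = integer(),
                     alt_depth = integer(), sample_id = character(),
                     filter = character(), stringsAsFactors = FALSE)
  df$af <- ifelse(df$total_depth > 0, df$alt_depth / df$total_depth, NA_real_)
  df <- df[, c("chrom", "pos0", "ref", "alt", "total_depth", "alt_depth",
               "sample_id", "af", "filter")]
  df <- validate_variant_calls(df)
  attr(df, "skipped_nonsnv") <- skipped_nonsnv
  attr(df, "skipped_nodepth") <- skipped_nodepth
  df
}

# Extract (dp, ad) per alt allele from a split VCF record, or NULL.
.vcf_depths <- function(f, alts, config) {
  if (length(f) < 10) return(NULL)
  keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
  vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
  fmt <- setNames(as.list(vals), keys[seq_along(vals)])
  for (d in config$dialects) {
    if (d == "varscan" && all(c("RD", "AD") %in% names(fmt))) {
      rd <- as.integer(fmt$RD)
      ad <- as.integer(strsplit(fmt$AD, ",", fixed = TRUE)[[1]])
      if (length(ad) == 1) ad <- rep(ad, length(alts))
      return(list(dp = rep(rd + sum(ad), length(alts)), ad = ad))
    }
    if (d == "dp_ad" && all(c("DP", "AD") %in% names(fmt))) {
      dp <- as.integer(fmt$DP)
      ad <- as.integer(strsplit(fmt$AD, ",", fixed = TRUE)[[1]])
      if (length(ad) >= length(alts) + 1) ad <- ad[-1] # drop ref count
      return(list(dp = rep(dp, length(alts)), ad = ad[seq_along(alts)]))
    }
  }
  NULL
}

#' Write variant calls as VCF
#'
#' Emits a minimal VCF 4.2 with VarScan-style `RD`/`AD`/`FREQ` FORMAT
#' fields; the `filter` column (if present) populates FILTER.
#'
#' @param variants a [variant_calls()] data.frame, optionally with a
#'   `filter` column.
#' @param path output path.
#' @param source_tag value for the `##source` header line.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, source_tag = "editscan") {
  filt <- if ("filter" %in% names(variants)) variants$filter else
    rep(".", nrow(variants))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_tag),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reference read depth\">",
           "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant read depth\">",
           "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  ord <- order(variants$chrom, variants$pos0, variants$alt)
  v <- variants[ord, , drop = FALSE]; filt <- filt[ord]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:RD:AD:FREQ\t0/1:%d:%d:%s",
                  v$chrom, v$pos0 + 1L, v$ref, v$alt, filt,
                  v$total_depth - v$alt_depth, v$alt_depth,
                  sprintf("%.4g%%", 100 * v$af))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse read alignments from SAM/BAM
#'
#' Loads aligned reads into the package's normal form: per read, a set of
#' aligned blocks `(ref_start0, ref_end0, q_start0, q_end0)` derived from
#' CIGAR M/=/X runs; I/D/N/S/H operations consume only the proper
#' coordinate.  Unmapped and duplicate-flagged reads are excluded.
#'
#' @param path a SAM (text) or BAM file.  SAM input is converted with
#'   [Rsamtools::asBam()] on the fly.
#' @param region optional `list(chrom=, start0=, end0=)`; only reads whose
#'   reference span overlaps the region are returned.
#' @return a list of `ReadAlignment` records: `read_id`, `chrom`, `start0`,
#'   `strand`, `mapq`, `seq` (query as aligned, forward reference strand),
#'   and `blocks` (integer matrix with columns ref0, ref1, q0, q1).
#' @export
parse_alignment_records <- function(path, region = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("qname", "seq", "mapq", "flag"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(ga) == 0) return(list())
  meta <- S4Vectors::mcols(ga)
  gdf <- as.data.frame(ga)   # seqnames, strand, cigar, start, end, ...
  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(gdf$cigar, ops = ops,
                                                          pos = gdf$start)
  qq <- GenomicAlignments::cigarRangesAlongQuerySpace(gdf$cigar, ops = ops)
  seqs <- as.character(meta$seq)
  out <- vector("list", length(ga))
  for (i in seq_along(ga)) {
    r <- rr[[i]]; q <- qq[[i]]
    blocks <- cbind(ref0 = IRanges::start(r) - 1L, ref1 = IRanges::end(r),
                    q0 = IRanges::start(q) - 1L, q1 = IRanges::end(q))
    out[[i]] <- list(read_id = meta$qname[i],
                     chrom = as.character(gdf$seqnames[i]),
                     start0 = gdf$start[i] - 1L,
                     strand = as.character(gdf$strand[i]), mapq = meta$mapq[i],
                     seq = seqs[i], blocks = blocks)
  }
  if (!is.null(region)) {
    keep <- vapply(out, function(a) {
      a$chrom == region$chrom &&
        min(a$blocks[, "ref0"]) < region$end0 &&
        max(a$blocks[, "ref1"]) > region$start0
    }, TRUE)
    out <- out[keep]
  }
  out
}

#' Parse BED3-6 interval records
#'
#' @param x path or character vector of tab-separated BED lines.
#' @return data.frame with columns chrom, start0, end0, name, score,
#'   strand; missing name/strand default to "." and "+".  Intervals are
#'   0-based half-open; `start0 >= end0` is an error naming the record.
#' @export
parse_interval_records <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                 nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), name = character(),
                      score = numeric(), strand = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3)) stop("BED record ", which(nf < 3)[1], ": fewer than 3 columns")
  get <- function(i, default) vapply(f, function(v)
    if (length(v) >= i && nzchar(v[i])) v[i] else default, "")
  df <- data.frame(chrom = get(1, ""), start0 = as.integer(get(2, NA)),
                   end0 = as.integer(get(3, NA)), name = get(4, "."),
                   score = suppressWarnings(as.numeric(get(5, "0"))),
                   strand = get(6, "+"), stringsAsFactors = FALSE)
  bad <- which(df$start0 >= df$end0)
  if (length(bad))
    stop("BED record ", bad[1], ": empty or inverted interval (start >= end)")
  df
}

#' Parse a known-editing-site catalog (RADAR-style TSV)
#'
#' Expects a tab-separated table with header.  Positions are 1-based in the
#' file and converted to `pos0`.  Sites on the minus strand (editing of the
#' antisense A) are stored as T>C on the plus reference strand with the
#' strand recorded.  Unknown region labels map to "unknown" with a warning.
#'
#' @param x path or character vector of lines.
#' @param col_map named list mapping the logical fields `chrom`,
#'   `position`, `gene`, `region`, `strand` to column names in the file.
#' @return an [editing_sites()] data.frame.
#' @export
parse_catalog_records <- function(x,
    col_map = list(chrom = "chromosome", position = "position",
                   gene = "gene", region = "region", strand = "strand")) {
  # quote = "": labels like 3'UTR must not open a quoted field
  df <- if (length(x) == 1 && file.exists(x))
    read.table(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE, quote = "", comment.char = "")
  else read.table(text = paste0(paste(x, collapse = "\n"), "\n"),
                  sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, quote = "", comment.char = "")
  need <- unlist(col_map)
  if (!all(need %in% names(df)))
    stop("catalog is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  region <- .normalize_region(df[[col_map$region]])
  strand <- df[[col_map$strand]]
  ref <- ifelse(strand == "-", "T", "A")
  alt <- ifelse(strand == "-", "C", "G")
  editing_sites(df[[col_map$chrom]],
                as.integer(df[[col_map$position]]) - 1L,
                ref, alt, strand = strand, region = region,
                gene = df[[col_map$gene]])
}

.normalize_region <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  map <- c(coding = "coding", cds = "coding", exonic = "coding",
           "3utr" = "3UTR", utr3 = "3UTR", "5utr" = "5UTR", utr5 = "5UTR",
           intron = "intron", intronic = "intron",
           intergenic = "intergenic", unknown = "unknown")
  out <- unname(map[key])
  if (anyNA(out)) {
    warning("unknown region label(s) mapped to 'unknown': ",
            paste(unique(x[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "unknown"
  }
  out
}

#' Parse Blat PSL realignment output
#'
#' Reads the 21-column PSL standard (header lines tolerated).  Each line
#' becomes a realignment hit in the same normal form produced by
#' [realign_read()], with the score recomputed under the supplied scoring
#' scheme from the match/mismatch/gap counts.
#'
#' @param x path or character vector of PSL lines.
#' @param scheme a [scoring_scheme()] used to score each hit.
#' @return named list (by query/read name) of lists of realignment hits.
#' @export
parse_psl_records <- function(x, scheme = scoring_scheme()) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  keep <- grepl("^[0-9]+\t", lines)
  lines <- lines[keep]
  hits <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 21) stop("PSL record with fewer than 21 columns")
    matches <- as.integer(f[1]); mism <- as.integer(f[2])
    rep_m <- as.integer(f[3])
    qgap_n <- as.integer(f[5]); qgap_b <- as.integer(f[6])
    tgap_n <- as.integer(f[7]); tgap_b <- as.integer(f[8])
    strand <- f[9]; qname <- f[10]; tname <- f[14]
    tstart <- as.integer(f[16]); tend <- as.integer(f[17])
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    qstarts <- as.integer(strsplit(f[20], ",")[[1]])
    tstarts <- as.integer(strsplit(f[21], ",")[[1]])
    gap_pen <- function(n, b) if (n == 0) 0 else
      n * scheme$gap_open + (b - n) * scheme$gap_extend
    score <- (matches + rep_m) * scheme$match + mism * scheme$mismatch +
      gap_pen(qgap_n, qgap_b) + gap_pen(tgap_n, tgap_b)
    blocks <- cbind(ref0 = tstarts, ref1 = tstarts + sizes,
                    q0 = qstarts, q1 = qstarts + sizes)
    cols <- sum(sizes) + qgap_b + tgap_b
    hit <- list(chrom = tname, start0 = tstart, end0 = tend, strand = strand,
                blocks = blocks, score = score,
                identity = (matches + rep_m) / max(cols, 1),
                # reference gaps of >= 20 bases are treated as introns
                spliced = tgap_n > 0 && length(sizes) > 1 &&
                  any(diff(tstarts) - sizes[-length(sizes)] >= 20),
                gapped = qgap_n > 0 || tgap_n > 0,
                query = NA_character_)
    hits[[qname]] <- c(hits[[qname]], list(hit))
  }
  hits
}
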