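# Domain containers.  Tabular objects are plain data.frames with documented
# column contracts (the limma/data.table idiom); the few structured objects
# get light S3 classes with validators.

REGION_LEVELS <- c("coding", "3UTR", "5UTR", "intron", "intergenic", "unknown")
SUBSTITUTION_TYPES <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      function(a, b) paste0(a, ">", b)))
SUBSTITUTION_TYPES <- SUBSTITUTION_TYPES[substr(SUBSTITUTION_TYPES, 1, 1) !=
                                         substr(SUBSTITUTION_TYPES, 3, 3)]

#' Construct a genome reference
#'
#' A genome reference is a named set of uppercase DNA sequences.  Internally
#' all coordinates in the package are 0-based half-open; 1-based conventions
#' (VCF POS, catalog positions) are converted at the I/O boundary.
#'
#' @param sequences named character vector (or list) of DNA strings
#'   (A/C/G/T/N).  Lowercase input is uppercased.
#' @return An object of class `GenomeReference` with elements `sequences`
#'   (named character) and `lengths` (named integer).
#' @examples
#' ref <- genome_reference(c(chr1 = "ACGTACGT"))
#' ref$lengths
#' @export
genome_reference <- function(sequences) {
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences))))
    stop("sequences must have unique, non-empty chromosome names")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN character in chromosome(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(sequences = sequences, lengths = nchar(sequences)),
            class = "GenomeReference")
}

#' @export
print.GenomeReference <- function(x, ...) {
  cat("GenomeReference with", length(x$sequences), "sequence(s)\n")
  print(x$lengths)
  invisible(x)
}

#' Read a genome reference from FASTA
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return A [genome_reference()] object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_reference(setNames(as.character(ss), nm))
}

#' Write a genome reference to FASTA
#' @param reference a [genome_reference()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct an exon annotation
#'
#' @param chrom,start0,end0 exon intervals, 0-based half-open.
#' @param transcript_id transcript each exon belongs to.
#' @param strand "+" or "-".
#' @return data.frame of class `ExonAnnotation` sorted by
#'   (transcript, start).  Within a transcript, exons must be
#'   non-overlapping and separated by at least one intronic base.
#' @export
exon_annotation <- function(chrom, start0, end0, transcript_id, strand = "+") {
  df <- data.frame(chrom = as.character(chrom), start0 = as.integer(start0),
                   end0 = as.integer(end0),
                   transcript_id = as.character(transcript_id),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$end0 <= df$start0)) stop("exon end0 must exceed start0")
  df <- df[order(df$transcript_id, df$start0), , drop = FALSE]
  for (tx in unique(df$transcript_id)) {
    e <- df[df$transcript_id == tx, ]
    if (nrow(e) > 1 && any(e$start0[-1] - e$end0[-nrow(e)] < 1))
      stop("exons of transcript ", tx, " overlap or touch (intron length < 1)")
  }
  class(df) <- c("ExonAnnotation", "data.frame")
  df
}

#' Construct a variant call table
#'
#' One row per candidate substitution in one sample.  `pos0` is 0-based.
#'
#' @param chrom,pos0,ref,alt,total_depth,alt_depth,sample_id vectors,
#'   recycled to common length.
#' @return data.frame with the additional column `af = alt_depth /
#'   total_depth`, validated against the call contract.
#' @export
variant_calls <- function(chrom, pos0, ref, alt, total_depth, alt_depth,
                          sample_id = "sample1") {
  df <- data.frame(chrom = as.character(chrom), pos0 = as.integer(pos0),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   total_depth = as.integer(total_depth),
                   alt_depth = as.integer(alt_depth),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  df$af <- df$alt_depth / df$total_depth
  validate_variant_calls(df)
}

#' Validate a variant call table
#' @param df data.frame with the [variant_calls()] columns.
#' @return `df`, invisibly valid.
#' @export
validate_variant_calls <- function(df) {
  stopifnot(all(c("chrom", "pos0", "ref", "alt", "total_depth", "alt_depth",
                  "af", "sample_id") %in% names(df)))
  if (nrow(df) == 0) return(df)
  if (any(df$total_depth <= 0)) stop("total_depth must be positive")
  if (any(df$alt_depth < 0 | df$alt_depth > df$total_depth))
    stop("alt_depth must lie in [0, total_depth]")
  if (any(abs(df$af - df$alt_depth / df$total_depth) > 1e-9))
    stop("af inconsistent with alt_depth / total_depth")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  if (any(!df$ref %in% c("A", "C", "G", "T")) ||
      any(!df$alt %in% c("A", "C", "G", "T")))
    stop("ref/alt must be a single base in {A,C,G,T}")
  df
}

#' Construct an editing site table
#'
#' @param chrom,pos0,ref,alt site coordinates (0-based) and substitution,
#'   designated on the + strand of the reference.
#' @param strand strand the editing occurs on ("+" or "-").
#' @param region region label, one of coding, 3UTR, 5UTR, intron,
#'   intergenic, unknown.
#' @param gene optional gene symbol (NA allowed).
#' @return data.frame of class `EditingSites` with a `key` column
#'   `"chrom:pos0:ref>alt"`.
#' @export
editing_sites <- function(chrom, pos0, ref, alt, strand = "+",
                          region = "unknown", gene = NA_character_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), pos0 = as.integer(pos0),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   strand = rep_len(as.character(strand), n),
                   region = rep_len(as.character(region), n),
                   gene = rep_len(as.character(gene), n),
                   stringsAsFactors = FALSE)
  if (any(!df$region %in% REGION_LEVELS))
    stop("region must be one of: ", paste(REGION_LEVELS, collapse = ", "))
  df$key <- site_key(df)
  class(df) <- c("EditingSites", "data.frame")
  df
}

site_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste0(df$chrom, ":", df$pos0, ":", df$ref, ">", df$alt)
}

#' Construct an editing matrix
#'
#' Sites x samples container of read depth and editing level with an
#' explicit missing mask: a cell is missing (NA in both matrices) iff the
#' site had insufficient coverage or was unobserved in that sample.
#'
#' @param sites an [editing_sites()] data.frame (rows).
#' @param samples character vector of sample ids (columns).
#' @param depth,level numeric matrices `length(sites) x length(samples)`;
#'   NA marks missing cells (must agree between the two).
#' @return object of class `EditingMatrix`.
#' @export
editing_matrix <- function(sites, samples, depth, level) {
  depth <- as.matrix(depth); level <- as.matrix(level)
  stopifnot(nrow(depth) == nrow(sites), ncol(depth) == length(samples),
            all(dim(depth) == dim(level)))
  if (!identical(is.na(depth), is.na(level)))
    stop("depth and level must share the same missing mask")
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth")
  if (any(level < 0 | level > 1, na.rm = TRUE)) stop("level outside [0, 1]")
  dimnames(depth) <- dimnames(level) <- list(site_key(sites), samples)
  structure(list(sites = sites, samples = as.character(samples),
                 depth = depth, level = level),
            class = "EditingMatrix")
}

#' @export
print.EditingMatrix <- function(x, ...) {
  cat("EditingMatrix:", nrow(x$sites), "site(s) x", length(x$samples),
      "sample(s);", sum(is.na(x$depth)), "missing cell(s)\n")
  invisible(x)
}

#' @export
dim.EditingMatrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Write an editing matrix as TSV
#'
#' Rows are keyed `"chrom:pos0:ref>alt"`, columns are samples, cells are
#' `"depth,level"` or `"NA"` for missing.
#'
#' @param x an [editing_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_editing_matrix <- function(x, path) {
  cells <- matrix("NA", nrow(x$depth), ncol(x$depth))
  ok <- !is.na(x$depth)
  cells[ok] <- paste0(x$depth[ok], ",", format(x$level[ok], digits = 15,
                                               trim = TRUE, scientific = FALSE))
  out <- data.frame(site = site_key(x$sites), strand = x$sites$strand,
                    region = x$sites$region, gene = x$sites$gene,
                    cells, stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("site", "strand", "region", "gene", x$samples)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an editing matrix from TSV
#' @param path a file written by [write_editing_matrix()].
#' @return an [editing_matrix()].
#' @export
read_editing_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = character(0))
  keys <- df$site
  parts <- regmatches(keys, regexec("^(.*):(\\d+):([ACGT])>([ACGT])$", keys))
  if (any(lengths(parts) != 5)) stop("malformed site key in matrix file")
  parts <- do.call(rbind, parts)
  sites <- editing_sites(parts[, 2], as.integer(parts[, 3]), parts[, 4],
                         parts[, 5], strand = df$strand, region = df$region,
                         gene = ifelse(df$gene == "NA", NA, df$gene))
  samples <- setdiff(names(df), c("site", "strand", "region", "gene"))
  cells <- as.matrix(df[, samples, drop = FALSE])
  depth <- level <- matrix(NA_real_, nrow(cells), ncol(cells))
  ok <- cells != "NA"
  if (any(ok)) {
    sp <- strsplit(cells[ok], ",", fixed = TRUE)
    depth[ok] <- as.numeric(vapply(sp, `[`, "", 1))
    level[ok] <- as.numeric(vapply(sp, `[`, "", 2))
  }
  editing_matrix(sites, samples, depth, level)
}
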