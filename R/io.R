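# Readers and writers for the pipeline's plain-text interchange formats.
# Coordinates are 0-based half-open on disk (BED convention) and in memory.

#' Read mapped cDNAs from the pipeline TSV dialect
#'
#' The TSV dialect has columns `chrom`, `start`, `end`, `barcode`, `strand`,
#' `deletions` (comma-separated 0-based genomic positions, `.` if none;
#' barcode `.` means barcode-free). Coordinates are 0-based half-open.
#'
#' @param path path to a TSV file with a header line.
#' @return a validated mapped-cDNA data.frame (see [validate_cdnas()]).
#' @export
read_cdnas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  df$barcode[df$barcode == "."] <- NA_character_
  df$deletions[df$deletions == "."] <- ""
  validate_cdnas(df[, c("chrom", "start", "end", "strand", "barcode",
                        "deletions")])
}

#' Write mapped cDNAs to the pipeline TSV dialect
#'
#' @param records mapped-cDNA data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cdnas <- function(records, path) {
  records <- validate_cdnas(records)
  out <- data.frame(chrom = records$chrom, start = records$start,
                    end = records$end, barcode = records$barcode,
                    strand = records$strand, deletions = records$deletions,
                    stringsAsFactors = FALSE)
  out$barcode[is.na(out$barcode)] <- "."
  out$deletions[out$deletions == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cross-link sites from BED6
#'
#' Sites are stored one nucleotide per record: `start` is the 0-based site
#' position, `end = start + 1`, the name column carries the source
#' (`truncation`/`deletion`) and the score column the cDNA count.
#'
#' @param path BED6 path.
#' @return a cross-link site data.frame (see [validate_sites()]).
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  validate_sites(data.frame(chrom = as.character(df$chrom),
                            strand = as.character(df$strand),
                            position = as.integer(df$start),
                            count = as.integer(df$score),
                            source = as.character(df$name),
                            stringsAsFactors = FALSE))
}

#' Write cross-link sites as BED6
#'
#' @param sites cross-link site data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  sites <- validate_sites(sites)
  out <- data.frame(chrom = sites$chrom, start = sites$position,
                    end = sites$position + 1L, name = sites$source,
                    score = sites$count, strand = sites$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genomic segment annotation
#'
#' Segments are typed genomic intervals (BED-like TSV: `chrom`, `start`,
#' `end`, `type`, `score`, `strand`) used to re-position sites when building
#' the randomized background. Strand `.` means the segment covers both
#' strands. Within each chromosome segments are expected to be
#' non-overlapping.
#'
#' @param path BED-like TSV path (no header).
#' @return data.frame with columns chrom, start, end, type, strand.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "type",
                                        "score", "strand"))
  data.frame(chrom = as.character(df$chrom), start = as.integer(df$start),
             end = as.integer(df$end), type = as.character(df$type),
             strand = as.character(df$strand), stringsAsFactors = FALSE)
}

#' Write a genomic segment annotation
#'
#' @param segments segment data.frame (chrom, start, end, type, strand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end, type = segments$type,
                    score = 0L, strand = segments$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-position score track as bedGraph
#'
#' Runs of equal score are merged into single intervals.
#'
#' @param track a `score_track` (see [ycay_score()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$score)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- data.frame(chrom = track$chrom, start = starts, end = ends,
                    score = r$values)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read mapped cDNAs from a SAM file
#'
#' Single-nucleotide (and longer) deletions are taken from `D` operations in
#' the CIGAR string; each deleted reference base becomes one deletion
#' position. The random barcode is read either from an optional SAM tag or
#' from the last `:`-separated field of the read name.
#'
#' @param path SAM file path.
#' @param barcode_from `"tag"` or `"name_suffix"`; use `"none"` for
#'   barcode-free libraries.
#' @param tag SAM tag holding the barcode when `barcode_from = "tag"`.
#' @return a mapped-cDNA data.frame with 0-based half-open coordinates.
#' @export
read_cdna_sam <- function(path, barcode_from = c("tag", "name_suffix", "none"),
                          tag = "BC") {
  barcode_from <- match.arg(barcode_from)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    tag = if (barcode_from == "tag") tag else character(0))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(ga)
  barcode <- switch(barcode_from,
    tag = as.character(md[[tag]]),
    name_suffix = vapply(strsplit(md$qname, ":", fixed = TRUE),
                         function(x) x[[length(x)]], character(1)),
    none = rep(NA_character_, length(ga)))
  delr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), ops = "D",
    pos = GenomicAlignments::start(ga))
  dels <- vapply(delr, function(r) {
    if (!length(r)) return("")
    paste(unlist(lapply(seq_along(r), function(i)
      seq(IRanges::start(r)[i], IRanges::end(r)[i]))) - 1L, collapse = ",")
  }, character(1))
  validate_cdnas(data.frame(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    barcode = barcode,
    deletions = dels,
    stringsAsFactors = FALSE))
}
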