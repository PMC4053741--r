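# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  invisible(strand)
}

#' Validate a mapped-cDNA data frame
#'
#' A mapped-cDNA table has one row per aligned cDNA with columns `chrom`,
#' `start`, `end` (0-based half-open genomic coordinates), `strand` (`+`/`-`),
#' `barcode` (random barcode string, `NA` for barcode-free libraries) and
#' `deletions` (comma-separated 0-based genomic positions deleted in the read,
#' `""` if none). All coordinates in this package are 0-based half-open.
#'
#' @param records data.frame of mapped cDNAs.
#' @return the validated data.frame, invisibly coerced to canonical types.
#' @export
validate_cdnas <- function(records) {
  need <- c("chrom", "start", "end", "strand", "barcode", "deletions")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing cDNA columns: ", paste(miss, collapse = ", "), call. = FALSE)
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$strand <- as.character(records$strand)
  records$barcode <- as.character(records$barcode)
  records$deletions <- as.character(records$deletions)
  records$deletions[is.na(records$deletions)] <- ""
  .check_strand(records$strand)
  if (any(records$start >= records$end))
    stop("cDNA records must satisfy start < end", call. = FALSE)
  dl <- parse_deletions(records$deletions)
  bad <- mapply(function(d, s, e) length(d) && (min(d) < s || max(d) >= e),
                dl, records$start, records$end)
  if (any(bad))
    stop("deletion positions must lie within [start, end)", call. = FALSE)
  records
}

#' @keywords internal
parse_deletions <- function(deletions) {
  out <- strsplit(deletions, ",", fixed = TRUE)
  lapply(out, function(x) as.integer(x[nzchar(x)]))
}

#' @keywords internal
format_deletions <- function(dlist) {
  vapply(dlist, function(x) paste(x, collapse = ","), character(1))
}

# 5' end of the read in genomic coordinates (read orientation)
.pos5 <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

# chromosome lengths of a DNAStringSet genome, named
.chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a FASTA path", call. = FALSE)
  if (is.null(names(genome)))
    stop("genome sequences must be named", call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# reverse-complement of a character vector of sequences
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Validate a cross-link site data frame
#'
#' Cross-link sites are single nucleotides with columns `chrom`, `strand`,
#' `position` (0-based), `count` (number of unique cDNAs supporting the site)
#' and `source` (`"truncation"` or `"deletion"`).
#'
#' @param sites data.frame of cross-link sites.
#' @return the validated data.frame.
#' @export
validate_sites <- function(sites) {
  need <- c("chrom", "strand", "position", "count", "source")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("missing site columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$strand <- as.character(sites$strand)
  sites$position <- as.integer(sites$position)
  sites$count <- as.integer(sites$count)
  .check_strand(sites$strand)
  if (any(sites$count < 1L)) stop("site counts must be >= 1", call. = FALSE)
  sites
}
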