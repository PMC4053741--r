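# Re-definition of deletion sites falling in TTT homopolymer context.
#
# Gapped aligners cannot position a deletion within a homonucleotide run and
# report it at the run's genomically rightmost base regardless of strand; in
# transcript orientation that is the 3' end of the uridine tract for
# plus-strand cDNAs and its 5' end for minus-strand cDNAs, shifting the two
# strands' motif profiles against each other. The correction tests the three
# bases at transcript offsets -2..0 (plus strand) / 0..+2 (minus strand) of
# each deletion site -- the same genomic window [d-2, d] on both strands --
# and, when the transcript-sense sequence is TTT, moves the site to the motif
# center d-1.

#' Re-define deletion sites within TTT motifs to the motif center
#'
#' For a plus-strand deletion site `d` the genomic bases `d-2..d` are tested
#' for `TTT`; for a minus-strand site the same genomic window is tested in
#' transcript sense (genomic `AAA`). On a match the site moves to `d-1`, the
#' middle of the TTT motif. Sites whose window extends past the chromosome
#' boundary are left unchanged and tallied. A single pass is applied, as in
#' the original one-shot correction.
#'
#' @param sites cross-link site data.frame with `source == "deletion"`.
#' @param genome DNAStringSet or FASTA path.
#' @return the sites with additional columns `original_position` and
#'   `redefined`; attributes `n_boundary` (windows off the chromosome) and
#'   `n_in_longer_run` (triggered windows embedded in runs longer than 3).
#' @export
redefine_deletions <- function(sites, genome) {
  sites <- validate_sites(sites)
  if (!all(sites$source == "deletion"))
    stop("redefine_deletions applies to deletion-derived sites only",
         call. = FALSE)
  genome <- .as_genome(genome)
  chrlen <- .chrom_lengths(genome)
  seqs <- lapply(as.character(genome), identity)

  n <- nrow(sites)
  newpos <- sites$position
  redefined <- logical(n)
  in_bounds <- sites$position >= 2L & sites$position < chrlen[sites$chrom]
  n_boundary <- sum(!in_bounds)
  n_longer <- 0L

  for (ch in unique(sites$chrom)) {
    s <- seqs[[ch]]
    i <- which(sites$chrom == ch & in_bounds)
    if (!length(i)) next
    d <- sites$position[i]
    win <- substring(s, d - 1L, d + 1L)  # genomic [d-2, d], 1-based substring
    target <- ifelse(sites$strand[i] == "+", "TTT", "AAA")
    hit <- win == target
    newpos[i[hit]] <- d[hit] - 1L
    redefined[i[hit]] <- TRUE
    # flag windows sitting inside a longer homonucleotide run
    if (any(hit)) {
      dd <- d[hit]
      base <- substring(target[hit], 1L, 1L)
      left <- ifelse(dd >= 3L, substring(s, dd - 2L, dd - 2L), "")
      right <- ifelse(dd + 1L < chrlen[ch], substring(s, dd + 2L, dd + 2L), "")
      n_longer <- n_longer + sum(left == base | right == base)
    }
  }
  out <- sites
  out$original_position <- sites$position
  out$position <- as.integer(newpos)
  out$redefined <- redefined
  stopifnot(all(abs(out$position - out$original_position) <= 2L))
  attr(out, "n_boundary") <- n_boundary
  attr(out, "n_in_longer_run") <- n_longer
  out
}

#' Merge re-defined deletion sites that collide
#'
#' After re-definition, sites sharing (chrom, strand, position) are merged
#' and their deletion counts summed; the total deletion count is conserved.
#'
#' @param sites output of [redefine_deletions()] (or any site data.frame).
#' @return cross-link site data.frame with one row per distinct position.
#' @export
merge_redefined <- function(sites) {
  sites <- validate_sites(sites)
  key <- paste(sites$chrom, sites$strand, sites$position, sep = "\r")
  counts <- tapply(sites$count, key, sum)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    position = as.integer(vapply(parts, `[`, "", 3L)),
                    count = as.integer(counts),
                    source = "deletion", stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position, out$strand), ]
  rownames(out) <- NULL
  validate_sites(out)
}
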