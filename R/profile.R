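# Motif occurrence, closest-motif, enrichment, nucleotide-composition and
# motif-variant profiles around cross-link sites, with a segment-randomized
# background. All offsets are in transcript orientation with the cross-link
# site at offset 0; minus-strand sites are scanned on the reverse complement
# with offsets mirrored.

#' @keywords internal
offset_profile <- function(offset, value, n_sites, kind, motif = NULL,
                           n_excluded = 0L) {
  out <- data.frame(offset = offset, value = value)
  attr(out, "n_sites") <- n_sites
  attr(out, "n_excluded") <- n_excluded
  attr(out, "kind") <- kind
  attr(out, "motif") <- motif
  class(out) <- c("offset_profile", "data.frame")
  out
}

#' @export
print.offset_profile <- function(x, ...) {
  cat(sprintf("offset profile (%s%s): offsets %d..%d, n_sites = %d\n",
              attr(x, "kind"),
              if (!is.null(attr(x, "motif")))
                paste0(", motif ", attr(x, "motif")) else "",
              min(x$offset), max(x$offset), attr(x, "n_sites")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# transcript-oriented sequence windows covering transcript offsets
# [-up, +down] around each site; sites whose window leaves the chromosome are
# dropped (kept flag returned)
.site_windows <- function(sites, genome, up, down) {
  genome <- .as_genome(genome)
  chrlen <- .chrom_lengths(genome)
  plus <- sites$strand == "+"
  gstart <- ifelse(plus, sites$position - up, sites$position - down)
  gend <- ifelse(plus, sites$position + down, sites$position + up)
  keep <- gstart >= 0L & gend < chrlen[sites$chrom]
  seqs <- character(sum(keep))
  idx <- which(keep)
  chrs <- as.character(genome)
  for (ch in unique(sites$chrom[idx])) {
    s <- chrs[[ch]]
    i <- idx[sites$chrom[idx] == ch]
    seqs[match(i, idx)] <- substring(s, gstart[i] + 1L, gend[i] + 1L)
  }
  minus <- !plus[idx]
  if (any(minus)) seqs[minus] <- .revcomp(seqs[minus])
  list(seqs = seqs, keep = keep)
}

# per-window transcript-sense motif start offsets (list, one vector per site)
.motif_offsets <- function(sites, motif, genome, window) {
  window <- as.integer(window)
  L <- nchar(motif)
  w <- .site_windows(sites, genome, up = window, down = window + L - 1L)
  if (!length(w$seqs))
    return(list(offsets = list(), keep = w$keep))
  m <- Biostrings::vmatchPattern(motif, Biostrings::DNAStringSet(w$seqs),
                                 fixed = FALSE)
  offs <- lapply(Biostrings::startIndex(m), function(st) {
    if (is.null(st)) return(integer(0))
    o <- st - 1L - window
    o[o >= -window & o <= window]
  })
  list(offsets = offs, keep = w$keep)
}

#' Motif occurrence around cross-link sites
#'
#' Counts, for each transcript-sense offset in `-window..window`, the number
#' of sites at which an instance of the (IUPAC) motif starts at that offset.
#' Overlapping instances are all counted. Sites whose window extends beyond
#' the chromosome are excluded and tallied in the `n_excluded` attribute.
#'
#' @param sites cross-link site data.frame.
#' @param motif IUPAC motif string (e.g. `"YCAY"`).
#' @param genome DNAStringSet or FASTA path.
#' @param window half-width of the offset window in nt.
#' @return an `offset_profile` of per-offset counts.
#' @export
motif_occurrence <- function(sites, motif, genome, window = 30L) {
  sites <- validate_sites(sites)
  mo <- .motif_offsets(sites, motif, genome, window)
  counts <- tabulate(unlist(mo$offsets) + window + 1L, nbins = 2L * window + 1L)
  offset_profile(seq(-window, window), counts, n_sites = sum(mo$keep),
                 kind = "occurrence", motif = motif,
                 n_excluded = sum(!mo$keep))
}

#' Closest-motif profile around cross-link sites
#'
#' Records, per site, at most one motif start: the instance whose start offset
#' has the smallest absolute distance to the site; exact distance ties are
#' resolved in favor of the upstream (negative-offset) instance. Sites with no
#' instance in the window contribute nothing, so the profile total is at most
#' the number of sites.
#'
#' @inheritParams motif_occurrence
#' @return an `offset_profile` of per-offset closest-motif counts.
#' @export
closest_motif <- function(sites, motif, genome, window = 30L) {
  sites <- validate_sites(sites)
  mo <- .motif_offsets(sites, motif, genome, window)
  chosen <- vapply(mo$offsets, function(o) {
    if (!length(o)) return(NA_integer_)
    o[order(abs(o), o)][1L]
  }, integer(1))
  chosen <- chosen[!is.na(chosen)]
  counts <- tabulate(chosen + window + 1L, nbins = 2L * window + 1L)
  offset_profile(seq(-window, window), counts, n_sites = sum(mo$keep),
                 kind = "closest", motif = motif, n_excluded = sum(!mo$keep))
}

# index of the segment containing each site (same chrom; strand must match
# unless the segment is unstranded '.'), NA if none
.segment_of <- function(sites, segments) {
  out <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    seg <- which(segments$chrom == ch)
    if (!length(seg)) next
    seg <- seg[order(segments$start[seg])]
    i <- which(sites$chrom == ch)
    j <- findInterval(sites$position[i], segments$start[seg])
    ok <- j >= 1L
    ok[ok] <- sites$position[i][ok] < segments$end[seg[j[ok]]]
    strand_ok <- ok
    strand_ok[ok] <- segments$strand[seg[j[ok]]] %in% c(".", "*") |
      segments$strand[seg[j[ok]]] == sites$strand[i][ok]
    out[i[strand_ok]] <- seg[j[strand_ok]]
  }
  out
}

#' Segment-randomized background motif occurrence
#'
#' Re-positions every site uniformly within its containing annotated genomic
#' segment (keeping its strand), computes the motif occurrence profile of the
#' re-positioned set, and averages over `n` randomizations. The original
#' position may be redrawn. Sites falling outside all segments are excluded
#' with a warning tally.
#'
#' @inheritParams motif_occurrence
#' @param segments segment annotation data.frame (see [read_segments()]).
#' @param n number of randomizations (default 100).
#' @param window half-width in nt (default 50, the background window).
#' @param seed optional integer seed for reproducible re-positioning.
#' @return an `offset_profile` of per-offset mean background counts, with
#'   attribute `n_randomizations`.
#' @export
randomized_background <- function(sites, segments, motif, genome, n = 100L,
                                  window = 50L, seed = NULL) {
  sites <- validate_sites(sites)
  if (!is.null(seed)) set.seed(seed)
  segi <- .segment_of(sites, segments)
  if (anyNA(segi))
    warning(sum(is.na(segi)), " site(s) outside all segments excluded from ",
            "background", call. = FALSE)
  sites <- sites[!is.na(segi), ]
  segi <- segi[!is.na(segi)]
  acc <- numeric(2L * window + 1L)
  kept <- 0
  for (r in seq_len(n)) {
    width <- segments$end[segi] - segments$start[segi]
    newpos <- segments$start[segi] +
      as.integer(floor(stats::runif(nrow(sites)) * width))
    rs <- sites
    rs$position <- newpos
    prof <- motif_occurrence(rs, motif, genome, window)
    acc <- acc + prof$value
    kept <- kept + attr(prof, "n_sites")
  }
  offset_profile(seq(-window, window), acc / n,
                 n_sites = kept / n, kind = "background", motif = motif)
}

#' Motif enrichment over a randomized background
#'
#' Per-offset ratio of observed to background motif occurrence (both
#' normalized per contributing site), plus a smoothed track in which each
#' offset carries the mean enrichment over the offsets -2..+2 around it. The
#' maximal contiguous run of offsets whose smoothed enrichment is at or above
#' `threshold` is reported in the `enriched_region` attribute (`NULL` if
#' none). Offsets with zero background are reported as missing.
#'
#' @param observed `offset_profile` from [motif_occurrence()].
#' @param background `offset_profile` from [randomized_background()].
#' @param smooth half-width of the smoothing window (default 2).
#' @param threshold enrichment threshold for the reported region (default 2,
#'   two-fold).
#' @return data.frame of class `enrichment_profile` with columns `offset`,
#'   `observed`, `background`, `enrichment`, `smoothed`.
#' @export
motif_enrichment <- function(observed, background, smooth = 2L,
                             threshold = 2) {
  off <- intersect(observed$offset, background$offset)
  if (!length(off)) stop("profiles share no offsets", call. = FALSE)
  obs <- observed$value[match(off, observed$offset)] /
    attr(observed, "n_sites")
  bg <- background$value[match(off, background$offset)] /
    attr(background, "n_sites")
  ratio <- ifelse(bg > 0, obs / bg, NA_real_)
  k <- 2L * smooth + 1L
  smoothed <- as.numeric(stats::filter(ratio, rep(1 / k, k), sides = 2))
  out <- data.frame(offset = off, observed = obs, background = bg,
                    enrichment = ratio, smoothed = smoothed)
  above <- !is.na(smoothed) & smoothed >= threshold
  region <- NULL
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    region <- c(from = off[starts[best]], to = off[ends[best]])
  }
  attr(out, "enriched_region") <- region
  attr(out, "threshold") <- threshold
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Nucleotide composition around cross-link sites
#'
#' Per-offset base frequencies (transcript orientation) across sites. Columns
#' sum to 1 at every offset.
#'
#' @inheritParams motif_occurrence
#' @return matrix with rows A, C, G, T and one column per offset
#'   `-window..window`; attribute `n_sites`.
#' @export
nucleotide_composition <- function(sites, genome, window = 30L) {
  sites <- validate_sites(sites)
  w <- .site_windows(sites, genome, up = window, down = window)
  if (!length(w$seqs)) stop("no usable sites", call. = FALSE)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(w$seqs))
  cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  freq <- sweep(cm, 2L, colSums(cm), "/")
  colnames(freq) <- seq(-window, window)
  attr(freq, "n_sites") <- sum(w$keep)
  attr(freq, "n_excluded") <- sum(!w$keep)
  freq
}

#' Proportions of motif variants near versus around cross-link sites
#'
#' For each offset range, the proportion of each variant among all variant
#' instances starting in that range, pooled over sites. The default variants
#' are the four YCAY instantiations; the default ranges compare motifs
#' starting at offsets 0..+2 (at the site) with -20..+20 (the wider
#' vicinity).
#'
#' @inheritParams motif_occurrence
#' @param variants character vector of concrete (non-degenerate) motifs.
#' @param near_range,wide_range length-2 integer vectors `c(from, to)`.
#' @return data.frame with columns `variant`, `near`, `wide` (proportions
#'   summing to 1 per range) plus count columns `near_n`, `wide_n`.
#' @export
motif_variant_proportions <- function(sites, genome,
                                      variants = c("TCAT", "TCAC",
                                                   "CCAT", "CCAC"),
                                      near_range = c(0L, 2L),
                                      wide_range = c(-20L, 20L)) {
  sites <- validate_sites(sites)
  for (r in list(near_range, wide_range))
    if (length(r) != 2L || r[1] > r[2])
      stop("ranges must be c(from, to) with from <= to", call. = FALSE)
  window <- max(abs(c(near_range, wide_range)))
  counts <- matrix(0L, nrow = length(variants), ncol = 2L,
                   dimnames = list(variants, c("near", "wide")))
  for (v in variants) {
    mo <- .motif_offsets(sites, v, genome, window)
    o <- unlist(mo$offsets)
    counts[v, "near"] <- sum(o >= near_range[1] & o <= near_range[2])
    counts[v, "wide"] <- sum(o >= wide_range[1] & o <= wide_range[2])
  }
  props <- sweep(counts, 2L, colSums(counts), "/")
  data.frame(variant = variants, near = props[, "near"],
             wide = props[, "wide"], near_n = counts[, "near"],
             wide_n = counts[, "wide"], row.names = NULL,
             stringsAsFactors = FALSE)
}
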