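# YCAY cluster scoring: 41-nt sliding-window motif density, segmentation of
# the score track into clusters, and correlation of cluster scores with cDNA
# counts at cross-link sites.

#' YCAY score track over a genomic region
#'
#' The score of a position is the number of motif instances completely
#' contained in the window of `flank` nucleotides upstream and downstream of
#' it (41 nt for the default `flank = 20`): an instance starting at genomic
#' `s` with length `L` counts toward position `p` iff
#' `s >= p - flank` and `s + L - 1 <= p + flank`. Overlapping instances are
#' counted independently. Positions within `flank` of a chromosome end use
#' the truncated window.
#'
#' @param genome DNAStringSet or FASTA path.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region to score.
#' @param strand strand whose transcript sense the motif is matched on
#'   (instances are located by their genomic span, so the score track itself
#'   is in genomic coordinates).
#' @param motif IUPAC motif (default `"YCAY"`).
#' @param flank half-window in nt (default 20).
#' @return a `score_track` list: `chrom`, `start`, `end`, `strand`, and the
#'   integer `score` vector (one value per position in `[start, end)`).
#' @export
ycay_score <- function(genome, chrom, start, end, strand = "+",
                       motif = "YCAY", flank = 20L) {
  genome <- .as_genome(genome)
  .check_strand(strand)
  chrlen <- .chrom_lengths(genome)[chrom]
  if (start < 0L || end > chrlen || start >= end)
    stop("region must lie within the chromosome", call. = FALSE)
  L <- nchar(motif)
  ctx_start <- max(0L, start - flank)
  ctx_end <- min(chrlen, end + flank)
  seq <- Biostrings::subseq(genome[[chrom]], ctx_start + 1L, ctx_end)
  pat <- if (strand == "+") motif else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  m <- Biostrings::matchPattern(pat, seq, fixed = FALSE)
  # genomic (0-based) start positions of the motif instances
  gstarts <- Biostrings::start(m) - 1L + ctx_start
  pos <- seq.int(start, end - 1L)
  # instances with gstart in [p - flank, p + flank - L + 1] count for p
  ind <- integer(ctx_end - ctx_start)
  if (length(gstarts)) {
    tab <- tabulate(gstarts - ctx_start + 1L, nbins = length(ind))
    ind <- tab
  }
  cs <- c(0L, cumsum(ind))
  lo <- pmax(pos - flank, ctx_start)
  hi <- pmin(pos + flank - L + 1L, ctx_end - 1L)
  score <- ifelse(hi >= lo,
                  cs[hi - ctx_start + 2L] - cs[lo - ctx_start + 1L], 0L)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 score = as.integer(score)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score track %s:%d-%d (%s), max score %d\n",
              x$chrom, x$start, x$end, x$strand, max(x$score)))
  invisible(x)
}

# cluster segmentation of one score vector; returns matrix [from, to]
# (1-based indices into v)
.segment_scores <- function(v) {
  out <- NULL
  r <- rle(v > 0L)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1L
  for (isl in which(r$values)) {
    a <- istart[isl]; b <- iend[isl]
    x <- v[a:b]
    # plateau-aware local maxima: runs of equal value flanked by strictly
    # smaller values (island edges count as smaller), anchored at midpoints
    rx <- rle(x)
    re <- cumsum(rx$lengths)
    rs <- re - rx$lengths + 1L
    k <- length(rx$values)
    left <- c(-Inf, rx$values[-k])
    right <- c(rx$values[-1L], -Inf)
    ismax <- rx$values > left & rx$values > right
    anchors <- floor((rs[ismax] + re[ismax]) / 2)
    vals <- rx$values[ismax]
    nmax <- length(anchors)
    cur_start <- 1L
    cur_peak <- vals[1L]
    if (nmax > 1L) {
      for (i in seq_len(nmax - 1L)) {
        valley <- (anchors[i] + 1L):(anchors[i + 1L] - 1L)
        vmin <- min(x[valley])
        if (vmin < 0.9 * min(cur_peak, vals[i + 1L])) {
          minpos <- valley[x[valley] == vmin]
          mid <- floor((min(minpos) + max(minpos)) / 2)
          out <- rbind(out, c(a + cur_start - 1L, a + mid - 1L))
          cur_start <- mid + 1L
          cur_peak <- vals[i + 1L]
        } else {
          cur_peak <- max(cur_peak, vals[i + 1L])
        }
      }
    }
    out <- rbind(out, c(a + cur_start - 1L, b))
  }
  out
}

#' Segment a score track into motif clusters
#'
#' Implements the five-step segmentation: (1) local maxima of the score track
#' are found (a plateau of equal values flanked by strictly smaller values is
#' one maximum, anchored at its midpoint); (2) where the score between two
#' maxima reaches 0, clusters end at the zero positions; (3) otherwise the
#' valley minimum is compared with 0.9 times the smaller of the two adjacent
#' maxima; (4) if the minimum is smaller the cluster is split at the middle
#' of the run of minimum-value positions; (5) if not, the peaks are joined
#' and the merged peak is compared with the next maximum. Maxima are
#' processed left to right. A valley exactly at 0.9 times the smaller
#' maximum is not smaller, so the peaks merge.
#'
#' @param track a `score_track` from [ycay_score()].
#' @return data.frame of clusters: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `cluster_score` (maximum score inside). Clusters
#'   are disjoint and cover exactly the positions with positive score.
#' @export
find_clusters <- function(track) {
  stopifnot(inherits(track, "score_track"))
  seg <- .segment_scores(track$score)
  if (is.null(seg))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      cluster_score = integer(0)))
  data.frame(chrom = track$chrom,
             start = track$start + seg[, 1L] - 1L,
             end = track$start + seg[, 2L],
             strand = track$strand,
             cluster_score = apply(seg, 1L, function(fr)
               max(track$score[fr[1L]:fr[2L]])),
             stringsAsFactors = FALSE)
}

#' Correlate cluster scores with cDNA counts
#'
#' For every cluster containing at least one cross-link site, the cluster
#' score is paired with the highest site cDNA count inside the cluster, and
#' Spearman's rank correlation (average ranks for ties) is computed with a
#' two-sided p-value from the asymptotic t approximation.
#'
#' @param clusters data.frame from [find_clusters()].
#' @param sites cross-link site data.frame.
#' @param match_strand require site strand to equal cluster strand
#'   (default FALSE: sites are matched by position only).
#' @return list with `rho`, `p_value`, `n_clusters`, and the qualifying
#'   clusters augmented with `max_cdna_count` and `n_sites`.
#' @export
correlate_clusters <- function(clusters, sites, match_strand = FALSE) {
  sites <- validate_sites(sites)
  n <- nrow(clusters)
  max_count <- integer(n)
  n_sites <- integer(n)
  for (i in seq_len(n)) {
    sel <- sites$chrom == clusters$chrom[i] &
      sites$position >= clusters$start[i] &
      sites$position < clusters$end[i]
    if (match_strand) sel <- sel & sites$strand == clusters$strand[i]
    n_sites[i] <- sum(sel)
    max_count[i] <- if (n_sites[i]) max(sites$count[sel]) else 0L
  }
  qual <- n_sites >= 1L
  if (sum(qual) < 3L)
    stop("fewer than 3 clusters contain a cross-link site; ",
         "correlation not computed", call. = FALSE)
  x <- clusters$cluster_score[qual]
  y <- max_count[qual]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in cluster scores or counts; ",
            "correlation undefined", call. = FALSE)
    rho <- NA_real_; pval <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, alternative = "two.sided",
                      method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    pval <- ct$p.value
  }
  out <- clusters[qual, , drop = FALSE]
  out$max_cdna_count <- y
  out$n_sites <- n_sites[qual]
  list(rho = rho, p_value = pval, n_clusters = sum(qual), clusters = out)
}
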