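# Two-component mixture of read-through and truncated cDNAs, estimated from
# deletion proportions. The library's deletion proportion p_iCLIP is modeled
# as f * p_RT + (1 - f) * p_BG, where p_RT is the deletion proportion of a
# pure read-through (CLIP) library, p_BG the background (mRNA-Seq) proportion,
# and f the read-through fraction of the library.

.check_prop <- function(...) {
  p <- c(...)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Estimate the read-through fraction f of a library
#'
#' Solves the two-component mixture `p_iclip = f * p_rt + (1 - f) * p_bg`
#' for `f = (p_iclip - p_bg) / (p_rt - p_bg)`.
#'
#' @param p_iclip deletion proportion of the library of interest.
#' @param p_rt deletion proportion of a pure read-through (CLIP) library.
#' @param p_bg background deletion proportion (mRNA-Seq).
#' @return the read-through fraction `f` in `[0, 1]` (clipped with a warning
#'   if the inputs violate the ordering `p_bg <= p_iclip <= p_rt`).
#' @export
estimate_f <- function(p_iclip, p_rt, p_bg) {
  .check_prop(p_iclip, p_rt, p_bg)
  if (p_rt == p_bg)
    stop("p_rt equals p_bg: mixture is unidentifiable", call. = FALSE)
  if (p_rt < p_bg)
    stop("p_bg must be smaller than p_rt", call. = FALSE)
  f <- (p_iclip - p_bg) / (p_rt - p_bg)
  if (f < 0 || f > 1) {
    warning("estimated f outside [0, 1]; inputs violate the mixture ",
            "ordering, clipping", call. = FALSE)
    f <- min(max(f, 0), 1)
  }
  f
}

#' Estimate the read-through share k among deletion-bearing cDNAs
#'
#' The posterior fraction of deletion-bearing cDNAs that are read-through:
#' `k = f * p_rt / (f * p_rt + (1 - f) * p_bg)`.
#'
#' @param f read-through fraction of the library (see [estimate_f()]).
#' @inheritParams estimate_f
#' @return `k` in `[0, 1]`.
#' @export
estimate_k <- function(f, p_rt, p_bg) {
  .check_prop(f, p_rt, p_bg)
  den <- f * p_rt + (1 - f) * p_bg
  if (den == 0)
    stop("no deletions expected under these rates: k undefined",
         call. = FALSE)
  f * p_rt / den
}

#' Read-through and truncated shares among deletion-free cDNAs
#'
#' Removes the deletion-bearing cDNAs (of which a fraction `k` are
#' read-through) from the library total to obtain the read-through share of
#' the deletion-free remainder:
#' `(total * f - n_del * k) / (total - n_del)`.
#'
#' @param total total unique cDNAs in the library.
#' @param n_del unique cDNAs with a deletion anywhere in the read.
#' @param f read-through fraction of the whole library.
#' @param k read-through share among the deletion-bearing cDNAs.
#' @return named vector with `readthrough` and `truncated` shares among the
#'   deletion-free cDNAs (clipped to `[0, 1]` with a warning on inconsistent
#'   inputs).
#' @export
truncated_fraction_among_no_del <- function(total, n_del, f, k) {
  .check_prop(f, k)
  if (n_del >= total) stop("n_del must be smaller than total", call. = FALSE)
  rt <- (total * f - n_del * k) / (total - n_del)
  if (rt < 0 || rt > 1) {
    warning("inconsistent inputs: share clipped to [0, 1]", call. = FALSE)
    rt <- min(max(rt, 0), 1)
  }
  c(readthrough = rt, truncated = 1 - rt)
}

#' Full mixture estimate from three library deletion statistics
#'
#' Computes the windowed deletion proportions of the target, pure
#' read-through reference, and background libraries, then `f`, `k` (both from
#' the windowed proportions) and the read-through/truncated split among
#' deletion-free cDNAs (using the unwindowed deletion-bearing count).
#' Count pairs are carried exactly and divided only where each proportion
#' enters a formula.
#'
#' @param stats_target,stats_rt,stats_bg [deletion_stats()] of the library of
#'   interest, the read-through reference (CLIP) and the background
#'   (mRNA-Seq).
#' @return a `mixture_estimate` list: the three proportions, `f`, `k`,
#'   `readthrough_no_del`, `truncated_no_del`.
#' @export
estimate_mixture <- function(stats_target, stats_rt, stats_bg) {
  stopifnot(inherits(stats_target, "deletion_stats"),
            inherits(stats_rt, "deletion_stats"),
            inherits(stats_bg, "deletion_stats"))
  p_target <- stats_target$cdnas_with_deletion_in_window /
    stats_target$total_unique_cdnas
  p_rt <- stats_rt$cdnas_with_deletion_in_window /
    stats_rt$total_unique_cdnas
  p_bg <- stats_bg$cdnas_with_deletion_in_window /
    stats_bg$total_unique_cdnas
  f <- estimate_f(p_target, p_rt, p_bg)
  k <- estimate_k(f, p_rt, p_bg)
  nodel <- truncated_fraction_among_no_del(
    stats_target$total_unique_cdnas,
    stats_target$cdnas_with_any_deletion, f, k)
  out <- list(p_target = p_target, p_rt = p_rt, p_bg = p_bg, f = f, k = k,
              readthrough_no_del = unname(nodel["readthrough"]),
              truncated_no_del = unname(nodel["truncated"]),
              window_nt = stats_target$window_nt)
  class(out) <- "mixture_estimate"
  out
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("read-through/truncated mixture (window %d nt):\n",
           "  deletion proportions: target %.4f, read-through ref %.4f, ",
           "background %.4f\n",
           "  f (read-through fraction of library)        = %.3f\n",
           "  k (read-through share of deletion-bearing)  = %.3f\n",
           "  read-through share among deletion-free      = %.3f\n",
           "  truncated share among deletion-free         = %.3f\n"),
    x$window_nt, x$p_target, x$p_rt, x$p_bg, x$f, x$k,
    x$readthrough_no_del, x$truncated_no_del))
  invisible(x)
}
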