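# cDNA ingest: barcode/position collapsing and derivation of truncation- and
# deletion-site events from mapped cDNA records.

#' Select the deletion closest to the beginning of each read
#'
#' When a cDNA carries more than one deletion, only the one nearest the read's
#' 5' end is retained for all downstream deletion analyses: the smallest
#' genomic coordinate on the plus strand, the largest on the minus strand.
#'
#' @param records mapped-cDNA data.frame.
#' @return integer vector of selected deletion positions (`NA` where the read
#'   has no deletion).
#' @export
select_deletion <- function(records) {
  records <- validate_cdnas(records)
  dl <- parse_deletions(records$deletions)
  out <- rep(NA_integer_, nrow(records))
  nonempty <- lengths(dl) > 0L
  mins <- vapply(dl[nonempty], min, integer(1))
  maxs <- vapply(dl[nonempty], max, integer(1))
  out[nonempty] <- ifelse(records$strand[nonempty] == "+", mins, maxs)
  out
}

# shared collapse engine; `records` must already carry a barcode key
.collapse <- function(records) {
  sel <- select_deletion(records)
  dt <- data.table::as.data.table(records)
  dt[, `:=`(sel = sel, pos5 = .pos5(start, end, strand))]
  dt[, has_del := !is.na(sel)]
  grp <- c("barcode", "chrom", "strand", "pos5")

  agg <- dt[, list(n = .N, ndel = sum(has_del),
                   start_min = min(start), end_max = max(end)), by = grp]
  # mixed groups resolve by majority; ties favor deletion-free
  agg[, keep_del := ndel > n - ndel]

  deld <- dt[has_del == TRUE,
             list(cnt = .N), by = c(grp, "sel")]
  # most frequent deletion wins; frequency ties -> closest to the read 5' end
  deld[, tiekey := ifelse(strand == "+", sel, -sel)]
  data.table::setorderv(deld, c(grp, "cnt", "tiekey"),
                        order = c(rep(1L, length(grp)), -1L, 1L))
  win <- deld[, list(windel = sel[1L]), by = grp]

  out <- merge(agg, win, by = grp, all.x = TRUE)
  out[, deletions := data.table::fifelse(keep_del & !is.na(windel),
                                         as.character(windel), "")]
  out[, start := data.table::fifelse(strand == "+", pos5, start_min)]
  out[, end := data.table::fifelse(strand == "+", end_max, pos5 + 1L)]
  res <- as.data.frame(out[, c("chrom", "start", "end", "strand",
                               "barcode", "deletions"), with = FALSE])
  res <- res[order(res$chrom, res$start, res$end, res$strand, res$barcode), ]
  rownames(res) <- NULL
  validate_cdnas(res)
}

#' Collapse PCR duplicates by random barcode
#'
#' Reads sharing a random barcode and the same starting position (the 5' end
#' of the read in read orientation: `start` on the plus strand, `end - 1` on
#' the minus strand) are collapsed to one unique cDNA. Within a group, the
#' retained deletion is the most frequent one; frequency ties are broken in
#' favor of the deletion closest to the beginning of the read. Groups mixing
#' deletion-free and deletion-bearing duplicates resolve by majority, with
#' ties favoring the deletion-free state.
#'
#' @param records mapped-cDNA data.frame with barcodes.
#' @return one mapped-cDNA row per unique (barcode, chrom, strand, start)
#'   group, carrying at most one deletion.
#' @export
collapse_barcoded <- function(records) {
  records <- validate_cdnas(records)
  if (anyNA(records$barcode))
    stop("collapse_barcoded requires barcodes; use join_no_barcode for ",
         "barcode-free libraries", call. = FALSE)
  .collapse(records)
}

#' Join barcode-free reads starting at the same position
#'
#' For libraries without random barcodes (CLIP, mRNA-Seq) all reads starting
#' at the same genomic position are joined into a single unique cDNA, as if
#' the same random barcode had been allocated to every read; deletion merging
#' follows the same rules as [collapse_barcoded()].
#'
#' @param records mapped-cDNA data.frame (barcodes ignored).
#' @return one mapped-cDNA row per unique (chrom, strand, start) group.
#' @export
join_no_barcode <- function(records) {
  records <- validate_cdnas(records)
  records$barcode <- "joined"
  out <- .collapse(records)
  out$barcode <- NA_character_
  out
}

#' Derive truncation-site positions from cDNA 5' ends
#'
#' The cross-link site identified by a truncated cDNA is the nucleotide
#' preceding the sequence read in transcript orientation: `start - 1` on the
#' plus strand, `end` on the minus strand (0-based). Records whose site would
#' fall off the chromosome are skipped and tallied in the `n_skipped`
#' attribute.
#'
#' @param records mapped-cDNA data.frame.
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   skip minus-strand reads ending at the chromosome edge.
#' @return data.frame with one row per kept record: chrom, strand, position,
#'   source = "truncation"; attribute `n_skipped`.
#' @export
derive_truncation_sites <- function(records, chrom_lengths = NULL) {
  records <- validate_cdnas(records)
  pos <- ifelse(records$strand == "+", records$start - 1L, records$end)
  keep <- pos >= 0L
  if (!is.null(chrom_lengths))
    keep <- keep & pos < chrom_lengths[records$chrom]
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) skipped: truncation site off chromosome",
            call. = FALSE)
  out <- data.frame(chrom = records$chrom[keep],
                    strand = records$strand[keep],
                    position = as.integer(pos[keep]),
                    source = rep("truncation", sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

# aggregate per-record site events into counted cross-link sites
.count_sites <- function(events) {
  if (!nrow(events))
    return(validate_sites(data.frame(chrom = character(0),
                                     strand = character(0),
                                     position = integer(0),
                                     count = integer(0),
                                     source = character(0))[0, ]))
  key <- paste(events$chrom, events$strand, events$position, events$source,
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    position = as.integer(vapply(parts, `[`, "", 3L)),
                    count = as.integer(tab),
                    source = vapply(parts, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position, out$strand), ]
  rownames(out) <- NULL
  validate_sites(out)
}

#' Cross-link sites identified by cDNA truncations
#'
#' Aggregates the truncation sites of deletion-free unique cDNAs into counted
#' cross-link sites. Deletion-bearing cDNAs are excluded by default because
#' they are predominantly read-through and not informative about truncation
#' positions.
#'
#' @param records collapsed mapped-cDNA data.frame.
#' @param deletion_free_only drop deletion-bearing cDNAs first (default TRUE).
#' @param chrom_lengths see [derive_truncation_sites()].
#' @return cross-link site data.frame (source = "truncation").
#' @export
truncation_sites <- function(records, deletion_free_only = TRUE,
                             chrom_lengths = NULL) {
  records <- validate_cdnas(records)
  if (deletion_free_only) records <- records[records$deletions == "", ]
  .count_sites(derive_truncation_sites(records, chrom_lengths))
}

#' Cross-link sites identified by cDNA deletions
#'
#' One event per deletion-bearing unique cDNA, at the selected deletion (the
#' one closest to the beginning of the read).
#'
#' @param records collapsed mapped-cDNA data.frame.
#' @return cross-link site data.frame (source = "deletion").
#' @export
deletion_sites <- function(records) {
  records <- validate_cdnas(records)
  sel <- select_deletion(records)
  keep <- !is.na(sel)
  .count_sites(data.frame(chrom = records$chrom[keep],
                          strand = records$strand[keep],
                          position = sel[keep], source = "deletion",
                          stringsAsFactors = FALSE))
}

#' Per-library deletion accounting
#'
#' Counts unique cDNAs, cDNAs with any deletion, and cDNAs whose selected
#' deletion lies within the first `window_nt` nucleotides of the read
#' (read-relative 5' to 3' offsets `[0, window_nt)`), the windowing used to
#' make libraries with different read lengths comparable.
#'
#' @param records collapsed (unique) mapped-cDNA data.frame.
#' @param window_nt read-relative window in nt (default 25).
#' @param min_library minimum unique-cDNA count; smaller libraries are
#'   refused (set to 0 to override, e.g. for toy data).
#' @return a `deletion_stats` list: `total_unique_cdnas`,
#'   `cdnas_with_any_deletion`, `cdnas_with_deletion_in_window`, `window_nt`.
#' @export
deletion_stats <- function(records, window_nt = 25L, min_library = 10000L) {
  if (window_nt <= 0L) stop("window_nt must be positive", call. = FALSE)
  records <- validate_cdnas(records)
  if (nrow(records) < min_library)
    stop("library has fewer than ", min_library, " unique cDNAs; ",
         "set min_library = 0 to analyze it anyway", call. = FALSE)
  sel <- select_deletion(records)
  offs <- ifelse(records$strand == "+", sel - records$start,
                 (records$end - 1L) - sel)
  out <- list(total_unique_cdnas = nrow(records),
              cdnas_with_any_deletion = sum(!is.na(sel)),
              cdnas_with_deletion_in_window =
                sum(!is.na(offs) & offs >= 0L & offs < window_nt),
              window_nt = as.integer(window_nt))
  class(out) <- "deletion_stats"
  out
}

#' Proportion of unique cDNAs with a deletion inside the read window
#'
#' The deletion proportion of a library: the fraction of unique cDNAs whose
#' selected deletion falls in the first `window_nt` nucleotides of the read.
#' Accepts a mapped-cDNA data.frame, a [deletion_stats()] object, or a raw
#' count pair.
#'
#' @param x records data.frame, `deletion_stats`, or a count of
#'   deletion-bearing cDNAs.
#' @param total total unique cDNAs (only when `x` is a count).
#' @param window_nt read-relative window in nt.
#' @param ... passed to [deletion_stats()].
#' @return the deletion proportion in `[0, 1]`.
#' @export
deletion_proportion <- function(x, total = NULL, window_nt = 25L, ...) {
  if (inherits(x, "deletion_stats"))
    return(x$cdnas_with_deletion_in_window / x$total_unique_cdnas)
  if (is.data.frame(x)) {
    s <- deletion_stats(x, window_nt = window_nt, ...)
    return(s$cdnas_with_deletion_in_window / s$total_unique_cdnas)
  }
  if (is.numeric(x) && !is.null(total)) {
    if (any(x > total)) stop("count exceeds total", call. = FALSE)
    return(x / total)
  }
  stop("x must be records, deletion_stats, or a count with total",
       call. = FALSE)
}
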