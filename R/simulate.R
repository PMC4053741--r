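# Synthetic-data generator: a toy genome with planted YCAY clusters and TTT
# homopolymer runs, plus simulated mapped cDNAs following the two-population
# (read-through vs truncated) model that the downstream estimation assumes.

YCAY_VARIANTS <- c("TCAT", "TCAC", "CCAT", "CCAC")

#' Build a simulation configuration
#'
#' The defaults describe the study conditions the pipeline is designed for:
#' a read-through fraction of 0.18 with per-read deletion probabilities of
#' 0.11 (read-through) and 0.004 (truncated/background) inside the first
#' 25 nt of the read, 50 nt average cDNA length, and deletions strongly
#' biased toward homonucleotide runs.
#'
#' @param genome_length chromosome length in nt.
#' @param n_chromosomes number of chromosomes. Planted features are placed on
#'   the first chromosome; later chromosomes are background sequence drawn
#'   from independent derived RNG streams, so adding chromosomes does not
#'   perturb earlier ones.
#' @param ycay_cluster_spec data.frame with one row per planted YCAY cluster:
#'   `n_motifs` (number of YCAY tetramers) and `spacing` (nt between
#'   consecutive motifs).
#' @param ttt_run_spec data.frame with columns `length` (run length in T's)
#'   and `count` (number of runs of that length to plant).
#' @param readthrough_fraction true mixture weight f of read-through cDNAs.
#' @param del_rate_readthrough per-read deletion probability for read-through
#'   cDNAs (must be >= `del_rate_background`).
#' @param del_rate_background per-read deletion probability for truncated
#'   cDNAs.
#' @param homopolymer_del_bias multiplicative weight for placing a deletion at
#'   a read position lying inside a homonucleotide run of length >= 3.
#' @param n_cdnas number of cDNA molecules before PCR duplication.
#' @param barcode_length random-barcode length in nt.
#' @param pcr_duplication_rate geometric rate of extra PCR copies per
#'   molecule (0 = no duplicates).
#' @param read_length mean cDNA length in nt.
#' @param read_length_jitter half-width of the uniform cDNA length
#'   distribution around `read_length`.
#' @param ttt_before_motif_frac fraction of planted motifs immediately
#'   preceded (in transcript orientation) by a TTT run, emulating
#'   TTTCAY-type contexts.
#' @param minus_strand_frac fraction of planted clusters on the minus strand.
#' @param segment_size size of the alternating genic/intergenic annotation
#'   blocks in nt.
#' @param aligner_shift if TRUE, a simulated deletion falling inside a
#'   homonucleotide run is reported at the genomically rightmost base of the
#'   run, emulating the ambiguity convention of gapped aligners that causes
#'   the strand-dependent offset the re-definition step corrects.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(genome_length = 100000L,
                              n_chromosomes = 1L,
                              ycay_cluster_spec = data.frame(
                                n_motifs = rep(3:8, length.out = 20),
                                spacing = 2L),
                              ttt_run_spec = data.frame(
                                length = c(3L, 5L), count = c(40L, 10L)),
                              readthrough_fraction = 0.18,
                              del_rate_readthrough = 0.11,
                              del_rate_background = 0.004,
                              homopolymer_del_bias = 10,
                              n_cdnas = 50000L,
                              barcode_length = 9L,
                              pcr_duplication_rate = 0.25,
                              read_length = 50L,
                              read_length_jitter = 15L,
                              ttt_before_motif_frac = 0.2,
                              minus_strand_frac = 0.5,
                              segment_size = 1000L,
                              aligner_shift = TRUE,
                              seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              ycay_cluster_spec = ycay_cluster_spec,
              ttt_run_spec = ttt_run_spec,
              readthrough_fraction = readthrough_fraction,
              del_rate_readthrough = del_rate_readthrough,
              del_rate_background = del_rate_background,
              homopolymer_del_bias = homopolymer_del_bias,
              n_cdnas = as.integer(n_cdnas),
              barcode_length = as.integer(barcode_length),
              pcr_duplication_rate = pcr_duplication_rate,
              read_length = as.integer(read_length),
              read_length_jitter = as.integer(read_length_jitter),
              ttt_before_motif_frac = ttt_before_motif_frac,
              minus_strand_frac = minus_strand_frac,
              segment_size = as.integer(segment_size),
              aligner_shift = aligner_shift,
              seed = as.integer(seed))
  probs <- c(readthrough_fraction = readthrough_fraction,
             del_rate_readthrough = del_rate_readthrough,
             del_rate_background = del_rate_background,
             pcr_duplication_rate = pcr_duplication_rate,
             ttt_before_motif_frac = ttt_before_motif_frac,
             minus_strand_frac = minus_strand_frac)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  if (cfg$del_rate_background > cfg$del_rate_readthrough)
    stop("del_rate_background must be <= del_rate_readthrough", call. = FALSE)
  if (cfg$homopolymer_del_bias < 1)
    stop("homopolymer_del_bias must be >= 1", call. = FALSE)
  if (cfg$genome_length < 1000L)
    stop("genome_length must be >= 1000 nt", call. = FALSE)
  if (cfg$read_length - cfg$read_length_jitter < 5L)
    stop("read_length_jitter too large for read_length", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# footprint (nt) of one planted cluster block in transcript orientation
.cluster_block <- function(n_motifs, spacing, ttt_frac) {
  parts <- character(0)
  motif_off <- integer(n_motifs)
  ttt_pref <- logical(n_motifs)
  pos <- 0L
  for (i in seq_len(n_motifs)) {
    if (stats::runif(1) < ttt_frac) {
      parts <- c(parts, "TTT")
      pos <- pos + 3L
      ttt_pref[i] <- TRUE
    }
    variant <- sample(YCAY_VARIANTS, 1L)
    parts <- c(parts, variant)
    motif_off[i] <- pos
    pos <- pos + 4L
    if (i < n_motifs) {
      spacer <- paste(sample(c("A", "G"), spacing, replace = TRUE),
                      collapse = "")
      parts <- c(parts, spacer)
      pos <- pos + spacing
    }
  }
  list(seq = paste(parts, collapse = ""), motif_off = motif_off,
       ttt_pref = ttt_pref)
}

# non-overlapping placement of blocks of given widths within [margin, len - margin)
.place_blocks <- function(widths, len, margin = 150L, gap = 30L) {
  starts <- integer(0)
  ends <- integer(0)
  out <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in 1:2000) {
      s <- margin + floor(stats::runif(1) * (len - 2L * margin - w))
      if (!length(starts) || all(s + w + gap <= starts | s >= ends + gap)) {
        starts <- c(starts, s)
        ends <- c(ends, s + w)
        out[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("requested planted features exceed genome length; ",
           "increase genome_length or reduce the feature specs",
           call. = FALSE)
  }
  out
}

#' Generate a toy genome with planted YCAY clusters and TTT runs
#'
#' Background sequence is drawn uniformly over ACGT from a seeded RNG (one
#' derived stream per chromosome). YCAY clusters (each a series of motif
#' tetramers, optionally TTT-prefixed, with fixed spacing) and isolated TTT
#' runs (flanked by non-T bases so they are not embedded in longer runs) are
#' written into the first chromosome at recorded positions. One cross-link
#' site is recorded per planted motif, at the transcript position immediately
#' preceding the motif start, with occupancy weight equal to the motif count
#' of its cluster. The segment annotation alternates genic/intergenic blocks.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulation` with elements `genome`
#'   (named DNAStringSet), `segments` (data.frame), and `truth` (list with
#'   `sites`, `motifs`, `runs` data.frames and the true simulation
#'   parameters).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- vector("list", config$n_chromosomes)

  # chromosome 1 carries the planted features
  set.seed(config$seed + 10007L)
  base <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)

  cs <- config$ycay_cluster_spec
  blocks <- lapply(seq_len(nrow(cs)), function(i)
    .cluster_block(cs$n_motifs[i], cs$spacing[i], config$ttt_before_motif_frac))
  cluster_strand <- ifelse(stats::runif(nrow(cs)) < config$minus_strand_frac,
                           "-", "+")
  rs <- config$ttt_run_spec
  run_len <- rep(rs$length, rs$count)
  widths <- c(vapply(blocks, function(b) nchar(b$seq), integer(1)),
              run_len + 2L)  # runs carry one non-T flank on each side
  pos <- .place_blocks(widths, config$genome_length)
  nb <- length(blocks)

  motifs <- NULL
  for (i in seq_len(nb)) {
    b <- blocks[[i]]
    g <- pos[i]
    w <- nchar(b$seq)
    s <- cluster_strand[i]
    ins <- if (s == "+") b$seq else .revcomp(b$seq)
    base[(g + 1):(g + w)] <- strsplit(ins, "")[[1]]
    # genomic coordinate of the motif's transcript start
    tstart <- if (s == "+") g + b$motif_off else g + w - 1L - b$motif_off
    motifs <- rbind(motifs, data.frame(
      chrom = chroms[1], strand = s, tstart = tstart,
      cluster = i, n_motifs = cs$n_motifs[i], ttt_prefix = b$ttt_pref,
      stringsAsFactors = FALSE))
  }
  runs <- NULL
  if (length(run_len)) {
    for (j in seq_along(run_len)) {
      g <- pos[nb + j]
      l <- run_len[j]
      flanks <- sample(c("A", "C", "G"), 2L, replace = TRUE)
      base[(g + 1):(g + l + 2L)] <- c(flanks[1], rep("T", l), flanks[2])
      runs <- rbind(runs, data.frame(chrom = chroms[1], start = g + 1L,
                                     length = l, stringsAsFactors = FALSE))
    }
  }
  seqs[[1]] <- paste(base, collapse = "")

  for (k in seq_len(config$n_chromosomes - 1L)) {
    set.seed(config$seed + 10007L * (k + 1L))
    seqs[[k + 1L]] <- paste(sample(c("A", "C", "G", "T"),
                                   config$genome_length, replace = TRUE),
                            collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  # cross-link site 1 nt transcript-upstream of each planted motif start;
  # occupancy weight = motif instances (planted or not) fully contained in
  # the 41-nt window centered on the site, in the site's transcript sense:
  # affinity grows with the local density of proximal motifs
  site_pos <- ifelse(motifs$strand == "+", motifs$tstart - 1L,
                     motifs$tstart + 1L)
  find_starts <- function(re) {
    m <- gregexpr(re, seqs[[1]], perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  plus_lo <- find_starts("(?=[CT]CA[CT])")          # spans [s, s+3]
  minus_lo <- find_starts("(?=[AG]TG[AG])")         # reverse complement
  weight <- vapply(seq_len(nrow(motifs)), function(i) {
    s <- if (motifs$strand[i] == "+") plus_lo else minus_lo
    sum(s >= site_pos[i] - 20L & s + 3L <= site_pos[i] + 20L)
  }, integer(1))
  sites <- data.frame(chrom = motifs$chrom, strand = motifs$strand,
                      position = as.integer(site_pos),
                      weight = weight, stringsAsFactors = FALSE)
  stopifnot(all(sites$position >= 0L),
            all(sites$position < config$genome_length))

  segments <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0L, config$genome_length - 1L, by = config$segment_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + config$segment_size, config$genome_length),
               type = rep_len(c("genic", "intergenic"), length(starts)),
               strand = ".", stringsAsFactors = FALSE)
  }))

  truth <- list(sites = sites, motifs = motifs, runs = runs,
                f = config$readthrough_fraction,
                del_rate_readthrough = config$del_rate_readthrough,
                del_rate_background = config$del_rate_background)
  structure(list(genome = genome, segments = segments, truth = truth),
            class = "simulation")
}

# per-position map: genomic 0-based position -> rightmost position of the
# maximal run of `letter` (length >= minlen) containing it, NA elsewhere
.run_right_map <- function(seq_chr, letter, minlen = 3L) {
  x <- strsplit(seq_chr, "")[[1]] == letter
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minlen
  map <- rep(NA_integer_, nchar(seq_chr))
  for (i in which(keep)) map[starts[i]:ends[i]] <- ends[i] - 1L
  map
}

#' Simulate mapped cDNAs from planted cross-link sites
#'
#' Each cDNA is assigned to a planted site (occupancy-weighted) and is
#' read-through with probability `readthrough_fraction`, otherwise truncated.
#' A truncated cDNA starts exactly one nucleotide 3' of its cross-link site in
#' transcript orientation, so the site is the nucleotide preceding the read.
#' A read-through cDNA's 5' end extends 2-20 nt past the site. Deletions are
#' single-nucleotide, placed with the class-specific per-read rate at a
#' transcript offset within the first 25 nt of the read, with positions inside
#' homonucleotide runs up-weighted by `homopolymer_del_bias`; when
#' `aligner_shift` is set, a deletion inside a run is reported at the run's
#' genomically rightmost base. Random barcodes are attached and PCR duplicates
#' appended.
#'
#' @param sim a `simulation` from [generate_genome()] (or its `genome`).
#' @param truth planted truth (defaults to `sim$truth`).
#' @param config the [simulation_config()] used to generate the genome.
#' @return a mapped-cDNA data.frame; attribute `class_readthrough` records
#'   the true class of each pre-duplication molecule.
#' @export
simulate_cdnas <- function(sim, truth = NULL, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(sim, "simulation")) {
    genome <- sim$genome
    truth <- truth %||% sim$truth
  } else {
    genome <- .as_genome(sim)
  }
  if (is.null(truth)) stop("planted truth is required", call. = FALSE)
  sites <- truth$sites
  set.seed(config$seed + 777L)

  n <- config$n_cdnas
  idx <- sample.int(nrow(sites), n, replace = TRUE, prob = sites$weight)
  chrom <- sites$chrom[idx]
  strand <- sites$strand[idx]
  spos <- sites$position[idx]
  rt <- stats::runif(n) < config$readthrough_fraction
  len <- sample(seq(config$read_length - config$read_length_jitter,
                    config$read_length + config$read_length_jitter),
                n, replace = TRUE)
  ext <- sample(2:20, n, replace = TRUE)

  # genomic extent; transcript 5' end is site+1 (truncated) or site+1-ext-...
  start <- integer(n); end <- integer(n)
  plus <- strand == "+"
  start[plus] <- ifelse(rt[plus], spos[plus] - ext[plus], spos[plus] + 1L)
  end[plus] <- start[plus] + len[plus]
  end[!plus] <- ifelse(rt[!plus], spos[!plus] + ext[!plus] + 1L,
                       spos[!plus])
  start[!plus] <- end[!plus] - len[!plus]
  chrlen <- .chrom_lengths(genome)
  start <- pmax(start, 0L)
  end <- pmin(end, chrlen[chrom])

  # deletion placement
  p <- ifelse(rt, config$del_rate_readthrough, config$del_rate_background)
  has_del <- stats::runif(n) < p
  dels <- character(n)
  dels[] <- ""
  if (any(has_del)) {
    run_t <- lapply(as.character(genome), .run_right_map, letter = "T")
    run_a <- lapply(as.character(genome), .run_right_map, letter = "A")
    for (i in which(has_del)) {
      w_nt <- min(25L, end[i] - start[i])
      offs <- seq_len(w_nt) - 1L
      g <- if (plus[i]) start[i] + offs else (end[i] - 1L) - offs
      rmap <- if (plus[i]) run_t[[chrom[i]]] else run_a[[chrom[i]]]
      in_run <- !is.na(rmap[g + 1L])
      wts <- 1 + (config$homopolymer_del_bias - 1) * in_run
      j <- sample.int(w_nt, 1L, prob = wts)
      d <- g[j]
      if (config$aligner_shift && !is.na(rmap[d + 1L]))
        d <- min(rmap[d + 1L], end[i] - 1L)
      d <- min(max(d, start[i]), end[i] - 1L)
      dels[i] <- as.character(d)
    }
  }

  bl <- config$barcode_length
  bc <- matrix(sample(c("A", "C", "G", "T"), n * bl, replace = TRUE),
               nrow = n)
  barcode <- do.call(paste0, as.data.frame(bc, stringsAsFactors = FALSE))

  records <- data.frame(chrom = chrom, start = start, end = end,
                        strand = strand, barcode = barcode,
                        deletions = dels, stringsAsFactors = FALSE)
  ndup <- if (config$pcr_duplication_rate > 0)
    stats::rgeom(n, prob = 1 - config$pcr_duplication_rate) else integer(n)
  if (sum(ndup) > 0)
    records <- rbind(records, records[rep(seq_len(n), ndup), ])
  rownames(records) <- NULL
  attr(records, "class_readthrough") <- rt
  validate_cdnas(records)
}

#' Write a simulation to disk
#'
#' Writes the genome as FASTA, segments as BED-like TSV, planted truth as TSV
#' and (optionally) the simulated cDNAs in the pipeline TSV dialect.
#'
#' @param sim a `simulation` from [generate_genome()].
#' @param dir output directory (created if needed).
#' @param records optional mapped-cDNA data.frame from [simulate_cdnas()].
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, records = NULL) {
  stopifnot(inherits(sim, "simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             segments = file.path(dir, "segments.bed"),
             truth = file.path(dir, "truth_sites.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_segments(sim$segments, paths["segments"])
  utils::write.table(sim$truth$sites, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(records)) {
    paths <- c(paths, cdnas = file.path(dir, "cdnas.tsv"))
    write_cdnas(records, paths["cdnas"])
  }
  invisible(paths)
}
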