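# fixtures built in code: toy genomes, record constructors, and the
# independent oracles used against the implementation

toy_genome <- function(seq, name = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# G-padded genome with arbitrary planted substrings: plant is a data.frame
# with columns pos (0-based) and seq
padded_genome <- function(len, plant = NULL, fill = "G") {
  base <- rep(fill, len)
  if (!is.null(plant)) {
    for (i in seq_len(nrow(plant))) {
      s <- strsplit(plant$seq[i], "")[[1]]
      base[(plant$pos[i] + 1):(plant$pos[i] + length(s))] <- s
    }
  }
  toy_genome(paste(base, collapse = ""))
}

cdna <- function(chrom = "chr1", start, end, strand = "+", barcode = NA,
                 deletions = "") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             barcode = as.character(barcode), deletions = deletions,
             stringsAsFactors = FALSE)
}

site_df <- function(position, strand = "+", count = 1L, chrom = "chr1",
                    source = "truncation") {
  data.frame(chrom = chrom, strand = strand, position = as.integer(position),
             count = as.integer(count), source = source,
             stringsAsFactors = FALSE)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# ---- independent oracles -------------------------------------------------

# all (overlapping) start positions (0-based) of an IUPAC motif in a string
oracle_motif_starts <- function(seq, motif = "YCAY") {
  map <- c(A = "A", C = "C", G = "G", T = "T", Y = "[CT]", R = "[AG]",
           N = "[ACGT]")
  re <- paste0("(?=", paste(map[strsplit(motif, "")[[1]]], collapse = ""),
               ")")
  m <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# brute-force sliding-window motif count at 0-based position p
oracle_window_score <- function(seq, p, flank = 20L, motif = "YCAY") {
  starts <- oracle_motif_starts(seq, motif)
  L <- nchar(motif)
  lo <- max(p - flank, 0L)
  hi <- min(p + flank, nchar(seq) - 1L)
  sum(starts >= lo & starts + L - 1L <= hi)
}

# Spearman rho and asymptotic two-sided p from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

# delta-method 3-SE band for the mixture estimate f-hat
f_tolerance <- function(p_i, n_i, p_r, n_r, p_b, n_b) {
  d <- p_r - p_b
  f <- (p_i - p_b) / d
  v <- (p_i * (1 - p_i) / n_i) / d^2 +
    (f / d)^2 * p_r * (1 - p_r) / n_r +
    ((1 - f) / d)^2 * p_b * (1 - p_b) / n_b
  3 * sqrt(v)
}

# simulate one library and return its windowed deletion stats
sim_library_stats <- function(sim, f, n, seed, window_nt = 25L) {
  cfg <- simulation_config(n_cdnas = n, readthrough_fraction = f, seed = seed)
  rec <- simulate_cdnas(sim, sim$truth, cfg)
  deletion_stats(collapse_barcoded(rec), window_nt = window_nt,
                 min_library = 0L)
}
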