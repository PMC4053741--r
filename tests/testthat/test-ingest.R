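test_that("truncation sites are the nucleotide preceding the read", {
  expect_equal(derive_truncation_sites(cdna(start = 100, end = 150))$position,
               99L)
  expect_equal(derive_truncation_sites(
    cdna(start = 100, end = 150, strand = "-"))$position, 150L)
  # site would fall off the chromosome: skipped with a warning
  expect_warning(out <- derive_truncation_sites(cdna(start = 0, end = 50)),
                 "skipped")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_warning(
    out2 <- derive_truncation_sites(
      cdna(start = 60, end = 100, strand = "-"), c(chr1 = 100L)),
    "skipped")
  expect_equal(nrow(out2), 0L)
})

test_that("the deletion closest to the read 5' end is selected", {
  expect_equal(select_deletion(cdna(start = 100, end = 150,
                                    deletions = "120,140")), 120L)
  expect_equal(select_deletion(cdna(start = 100, end = 150, strand = "-",
                                    deletions = "120,140")), 140L)
  expect_equal(select_deletion(cdna(start = 100, end = 150,
                                    deletions = "130")), 130L)
  expect_true(is.na(select_deletion(cdna(start = 100, end = 150))))
})

test_that("barcode collapsing follows the frequency and tie rules", {
  # same barcode, same start, same deletion: one record keeps it
  r <- rbind(cdna(start = 100, end = 140, barcode = "X", deletions = "105"),
             cdna(start = 100, end = 150, barcode = "X", deletions = "105"))
  out <- collapse_barcoded(r)
  expect_equal(nrow(out), 1L)
  expect_equal(out$deletions, "105")

  # 1 vs 1 frequency tie resolves to the deletion closest to the read start
  r <- rbind(cdna(start = 100, end = 150, barcode = "X", deletions = "105"),
             cdna(start = 100, end = 150, barcode = "X", deletions = "110"))
  expect_equal(collapse_barcoded(r)$deletions, "105")
  # on the minus strand the closest deletion is the largest coordinate
  r <- rbind(cdna(start = 100, end = 150, strand = "-", barcode = "X",
                  deletions = "105"),
             cdna(start = 100, end = 150, strand = "-", barcode = "X",
                  deletions = "110"))
  expect_equal(collapse_barcoded(r)$deletions, "110")

  # distinct barcodes are never collapsed
  r <- rbind(cdna(start = 100, end = 150, barcode = "X"),
             cdna(start = 100, end = 150, barcode = "Y"))
  expect_equal(nrow(collapse_barcoded(r)), 2L)

  # mixed deletion/no-deletion groups resolve by majority, ties -> no deletion
  r <- rbind(cdna(start = 100, end = 150, barcode = "X", deletions = "105"),
             cdna(start = 100, end = 150, barcode = "X"))
  expect_equal(collapse_barcoded(r)$deletions, "")
  r <- rbind(r, cdna(start = 100, end = 150, barcode = "X",
                     deletions = "105"))
  expect_equal(collapse_barcoded(r)$deletions, "105")
})

test_that("barcode-free joining keys on (chrom, strand, start) only", {
  r <- do.call(rbind, replicate(10, cdna(start = 500, end = 540),
                                simplify = FALSE))
  expect_equal(nrow(join_no_barcode(r)), 1L)
  r2 <- rbind(cdna(start = 500, end = 540), cdna(start = 501, end = 541))
  expect_equal(nrow(join_no_barcode(r2)), 2L)
  # majority deletion merging
  r3 <- rbind(cdna(start = 500, end = 540, deletions = "505"),
              cdna(start = 500, end = 540, deletions = "505"),
              cdna(start = 500, end = 540, deletions = "507"))
  out <- join_no_barcode(r3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$deletions, "505")
})

test_that("collapsing is idempotent and matches a set oracle", {
  set.seed(21)
  n <- 400L
  r <- cdna(start = sample(100:120, n, TRUE), end = 0,
            strand = sample(c("+", "-"), n, TRUE),
            barcode = sample(c("AA", "CC", "GG"), n, TRUE))
  r$end <- r$start + sample(30:50, n, TRUE)
  has <- runif(n) < 0.3
  r$deletions[has] <- as.character(r$start[has] + sample(0:10, sum(has), TRUE))
  once <- collapse_barcoded(r)
  expect_identical(collapse_barcoded(once), once)
  # unique count equals the brute-force distinct key count
  key <- unique(paste(r$barcode, r$chrom, r$strand,
                      ifelse(r$strand == "+", r$start, r$end - 1L)))
  expect_equal(nrow(once), length(key))
  # no-barcode version against its own oracle
  joined <- join_no_barcode(r)
  key2 <- unique(paste(r$chrom, r$strand,
                       ifelse(r$strand == "+", r$start, r$end - 1L)))
  expect_equal(nrow(joined), length(key2))
  expect_identical(join_no_barcode(joined), joined)
})

test_that("a pure truncated library reproduces the planted sites exactly", {
  cfg <- simulation_config(genome_length = 20000L,
                           ycay_cluster_spec = data.frame(n_motifs = 3:5,
                                                          spacing = 3L),
                           ttt_run_spec = data.frame(length = 3L, count = 5L),
                           readthrough_fraction = 0,
                           del_rate_background = 0,
                           del_rate_readthrough = 0,
                           n_cdnas = 3000L, seed = 22L)
  sim <- generate_genome(cfg)
  rec <- simulate_cdnas(sim, config = cfg)
  ts <- truncation_sites(collapse_barcoded(rec))
  planted <- paste(sim$truth$sites$chrom, sim$truth$sites$strand,
                   sim$truth$sites$position)
  got <- paste(ts$chrom, ts$strand, ts$position)
  expect_true(all(got %in% planted))
  expect_true(all(planted %in% got))  # 3000 draws cover all 12 sites
})

test_that("deletion accounting windows read-relative offsets", {
  r <- rbind(
    cdna(start = 100, end = 140, deletions = "105"),   # offset 5: in window
    cdna(start = 100, end = 140, deletions = "132"),   # offset 32: out
    cdna(start = 100, end = 145, strand = "-", deletions = "141"), # offset 3
    cdna(start = 100, end = 145, strand = "-", deletions = "110"), # offset 34
    cdna(start = 200, end = 240))
  s <- deletion_stats(r, window_nt = 25L, min_library = 0L)
  expect_equal(s$total_unique_cdnas, 5L)
  expect_equal(s$cdnas_with_any_deletion, 4L)
  expect_equal(s$cdnas_with_deletion_in_window, 2L)
  expect_equal(deletion_proportion(s), 2 / 5)
  # a window wider than any read reproduces the unwindowed count
  s2 <- deletion_stats(r, window_nt = 100L, min_library = 0L)
  expect_equal(s2$cdnas_with_deletion_in_window, s2$cdnas_with_any_deletion)
  expect_error(deletion_stats(r, window_nt = 0L), "positive")
  # libraries below the minimum size are refused unless overridden
  expect_error(deletion_stats(r), "10000")
  # raw count arithmetic
  expect_equal(deletion_proportion(10, total = 200), 0.05)
})

test_that("SAM input yields 0-based records with CIGAR deletions", {
  sam <- file.path(withr::local_tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 255, "10M1D15M", "*", 0, 0,
          strrep("A", 25), "*", "BC:Z:ACGT", sep = "\t"),
    paste("r2", 16, "chr1", 201, 255, "25M", "*", 0, 0,
          strrep("A", 25), "*", "BC:Z:TTGG", sep = "\t")),
    sam)
  rec <- read_cdna_sam(sam, barcode_from = "tag")
  expect_equal(rec$start, c(100L, 200L))
  expect_equal(rec$end, c(126L, 225L))  # 10M 1D 15M spans 26 reference nt
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$deletions, c("110", ""))
  expect_equal(rec$barcode, c("ACGT", "TTGG"))
})
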