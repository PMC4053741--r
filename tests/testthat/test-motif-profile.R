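test_that("single planted motif produces a single occurrence at +1", {
  g <- padded_genome(101, data.frame(pos = 51, seq = "TCAT"))
  s <- site_df(50)
  p <- motif_occurrence(s, "YCAY", g, window = 10)
  expect_equal(p$value[p$offset == 1], 1L)
  expect_equal(sum(p$value), 1L)
  expect_equal(attr(p, "n_sites"), 1L)
})

test_that("overlapping instances are counted (CCACCAC -> starts 0 and 3)", {
  g <- padded_genome(101, data.frame(pos = 50, seq = "CCACCAC"))
  p <- motif_occurrence(site_df(50), "YCAY", g, window = 10)
  expect_equal(p$value[p$offset %in% c(0, 3)], c(1L, 1L))
  expect_equal(sum(p$value), 2L)
})

test_that("occurrence matches the overlap-aware regex oracle on random data", {
  set.seed(51)
  for (rep in 1:5) {
    s <- random_seq(400)
    g <- toy_genome(s)
    sites <- site_df(sample(60:340, 15))
    w <- 20L
    p <- motif_occurrence(sites, "YCAY", g, window = w)
    starts <- oracle_motif_starts(s, "YCAY")
    expected <- integer(2L * w + 1L)
    for (pos in sites$position) {
      offs <- starts - pos
      offs <- offs[offs >= -w & offs <= w]
      expected[offs + w + 1L] <- expected[offs + w + 1L] + 1L
    }
    expect_equal(p$value, expected)
  }
})

test_that("profiles are invariant under genome reverse complement", {
  set.seed(52)
  s <- random_seq(300)
  g <- toy_genome(s)
  sites <- site_df(sample(50:250, 10),
                   strand = sample(c("+", "-"), 10, TRUE))
  g_rc <- toy_genome(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  sites_rc <- sites
  sites_rc$position <- nchar(s) - 1L - sites$position
  sites_rc$strand <- ifelse(sites$strand == "+", "-", "+")
  for (fn in list(motif_occurrence, closest_motif)) {
    a <- fn(sites, "YCAY", g, window = 15)
    b <- fn(sites_rc, "YCAY", g_rc, window = 15)
    expect_identical(a$value, b$value)
  }
  ca <- nucleotide_composition(sites, g, window = 15)
  cb <- nucleotide_composition(sites_rc, g_rc, window = 15)
  expect_equal(ca, cb, ignore_attr = TRUE)
})

test_that("closest-motif ties resolve upstream and totals stay <= n_sites", {
  # instances at -5 and +5: upstream wins
  g <- padded_genome(121, data.frame(pos = c(55, 65), seq = "TCAT"))
  p <- closest_motif(site_df(60), "YCAY", g, window = 10)
  expect_equal(p$value[p$offset == -5], 1L)
  expect_equal(sum(p$value), 1L)
  # instances at -3 and +2: |+2| < |-3|
  g2 <- padded_genome(121, data.frame(pos = c(57, 62), seq = "TCAT"))
  p2 <- closest_motif(site_df(60), "YCAY", g2, window = 10)
  expect_equal(p2$value[p2$offset == 2], 1L)
  # single instance at +1
  g3 <- padded_genome(121, data.frame(pos = 61, seq = "TCAT"))
  p3 <- closest_motif(site_df(60), "YCAY", g3, window = 10)
  expect_equal(p3$value[p3$offset == 1], 1L)
  # sites with no instance contribute nothing
  set.seed(53)
  s <- random_seq(500)
  sites <- site_df(sample(60:440, 25))
  pc <- closest_motif(sites, "YCAY", toy_genome(s), window = 12)
  expect_lte(sum(pc$value), nrow(sites))
})

test_that("background on uniform sequence approaches the closed-form rate", {
  set.seed(54)
  s <- random_seq(30000)
  g <- toy_genome(s)
  segments <- data.frame(chrom = "chr1", start = 0L, end = 30000L,
                         type = "genic", strand = ".")
  sites <- site_df(sample(200:29800, 40))
  bg <- randomized_background(sites, segments, "YCAY", g, n = 60L,
                              window = 50L, seed = 55L)
  rate <- mean(bg$value) / attr(bg, "n_sites")
  # P(YCAY at a fixed offset) = (1/2)(1/4)(1/4)(1/2) = 1/64 on uniform ACGT
  expect_equal(rate, 1 / 64, tolerance = 0.08)
})

test_that("background re-positioning is seeded and respects segments", {
  set.seed(56)
  s <- random_seq(2000)
  g <- toy_genome(s)
  segments <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                         end = c(1000L, 2000L),
                         type = c("genic", "intergenic"), strand = ".")
  sites <- site_df(sample(100:1900, 12))
  b1 <- randomized_background(sites, segments, "YCAY", g, n = 5L,
                              window = 20L, seed = 99L)
  b2 <- randomized_background(sites, segments, "YCAY", g, n = 5L,
                              window = 20L, seed = 99L)
  expect_identical(b1$value, b2$value)
  # degenerate 1-nt segment pins the site to its original position
  seg1 <- data.frame(chrom = "chr1", start = 500L, end = 501L,
                     type = "genic", strand = ".")
  site1 <- site_df(500)
  b3 <- randomized_background(site1, seg1, "YCAY", g, n = 3L, window = 20L,
                              seed = 1L)
  obs <- motif_occurrence(site1, "YCAY", g, window = 20L)
  expect_equal(b3$value, as.numeric(obs$value))
  # sites outside all segments are excluded with a warning
  expect_warning(
    randomized_background(site_df(1500), seg1, "YCAY", g, n = 2L,
                          window = 20L, seed = 1L),
    "outside")
})

test_that("enrichment ratios, smoothing and the threshold region behave", {
  mk <- function(v, kind) crosslinkr:::offset_profile(
    seq(-5, 5), v, n_sites = 1L, kind = kind)
  flat <- rep(2, 11)
  e <- motif_enrichment(mk(flat, "occurrence"), mk(flat, "background"))
  expect_true(all(e$enrichment == 1))
  # a 29-fold offset is reported as such
  obs <- flat; obs[7] <- 2 * 29
  e2 <- motif_enrichment(mk(obs, "occurrence"), mk(flat, "background"))
  expect_equal(e2$enrichment[e2$offset == 1], 29)
  # isolated spike of 5 smooths to height 1 across five offsets
  spike <- c(0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0)
  e3 <- motif_enrichment(mk(spike, "occurrence"), mk(rep(1, 11), "background"))
  expect_equal(e3$smoothed[e3$offset %in% -2:2], rep(1, 5))
  # zero background reported as missing
  bg0 <- flat; bg0[1] <- 0
  e4 <- motif_enrichment(mk(flat, "occurrence"), mk(bg0, "background"))
  expect_true(is.na(e4$enrichment[1]))
  # contiguous two-fold region
  obs5 <- c(1, 1, 4, 4, 4, 4, 4, 1, 1, 1, 1)
  e5 <- motif_enrichment(mk(obs5, "occurrence"), mk(rep(1, 11), "background"),
                         threshold = 2)
  reg <- attr(e5, "enriched_region")
  expect_false(is.null(reg))
  expect_true(reg["from"] <= reg["to"])
})

test_that("nucleotide composition is normalized and flat on uniform data", {
  g <- padded_genome(101, data.frame(pos = 50, seq = "T"), fill = "G")
  comp <- nucleotide_composition(site_df(50), g, window = 5)
  expect_equal(comp["T", "0"], 1)
  expect_equal(unname(colSums(comp)), rep(1, 11))
  set.seed(57)
  s <- random_seq(20000)
  sites <- site_df(sample(100:19900, 300))
  comp2 <- nucleotide_composition(sites, toy_genome(s), window = 10)
  expect_true(all(abs(comp2 - 0.25) < 0.12))
  expect_equal(unname(colSums(comp2)), rep(1, 21))
})

test_that("variant proportions recover a planted near/wide contrast", {
  # 100 sites; each carries one motif at offset +1 (26 CCAT / 74 TCAC) and
  # one at offset -15 (46 CCAT / 54 TCAC): wide-range CCAT = 72/200 = 36%,
  # near-range CCAT = 26/100 = 26%
  n <- 100L
  pos <- 100L + 80L * (0:(n - 1L))
  near_v <- rep(c("CCAT", "TCAC"), c(26, 74))
  far_v <- rep(c("CCAT", "TCAC"), c(46, 54))
  g <- padded_genome(100L + 80L * n, rbind(
    data.frame(pos = pos + 1L, seq = near_v),
    data.frame(pos = pos - 15L, seq = far_v)))
  props <- motif_variant_proportions(site_df(pos), g)
  expect_equal(props$near[props$variant == "CCAT"], 0.26)
  expect_equal(props$wide[props$variant == "CCAT"], 0.36)
  expect_equal(sum(props$near), 1)
  expect_equal(sum(props$wide), 1)
  # all-TCAC near range
  g2 <- padded_genome(1000, data.frame(pos = c(101, 201), seq = "TCAC"))
  p2 <- motif_variant_proportions(site_df(c(100, 200)), g2)
  expect_equal(p2$near[p2$variant == "TCAC"], 1)
  expect_error(motif_variant_proportions(site_df(100), g2,
                                         near_range = c(2, 0)), "from <= to")
})

test_that("sites too close to the chromosome edge are excluded and tallied", {
  g <- padded_genome(60, data.frame(pos = 30, seq = "TCAT"))
  p <- motif_occurrence(rbind(site_df(2), site_df(29)), "YCAY", g,
                        window = 10)
  expect_equal(attr(p, "n_excluded"), 1L)
  expect_equal(attr(p, "n_sites"), 1L)
})
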