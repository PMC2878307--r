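test_that("Welch window matches its closed form and symmetry", {
  expect_equal(welch_window(3), c(0, 1, 0))
  expect_equal(welch_window(5), c(0, 0.75, 1, 0.75, 0))
  W <- welch_window(64)
  expect_equal(W, rev(W))
  expect_equal(max(welch_window(65)), 1)
  expect_error(welch_window(2), ">= 3")
})

test_that("FFT power spectrum agrees with the brute-force DFT oracle", {
  set.seed(101)
  for (N in c(8L, 12L, 16L, 24L, 32L, 48L, 64L)) {
    for (rep in 1:3) {
      bits <- stats::rbinom(N, 1L, 0.3)
      F_fft <- power_spectrum(bits)
      F_dft <- dft_power_oracle(bits)
      denom <- pmax(abs(F_dft), max(F_dft))
      expect_lt(max(abs(F_fft - F_dft) / denom), 1e-9)
    }
  }
})

test_that("power spectrum handles degenerate and constructed inputs", {
  expect_equal(power_spectrum(rep(0L, 16)), rep(0, 8))
  expect_error(power_spectrum(numeric(0)), "empty")
  # period-4 indicator of length 8 with no window or centering:
  # energy only at n = 0 and n = 2
  F <- power_spectrum(c(1, 0, 0, 0, 1, 0, 0, 0), window = NULL, center = FALSE)
  expect_equal(F[c(1, 3)], c(4, 4))
  expect_equal(F[c(2, 4)], c(0, 0))
})

test_that("S/N ratio normalises to unit mean and excludes the DC bin", {
  F <- c(999, rep(2, 10))
  expect_equal(sn_ratio(F), rep(1, 10))
  R <- sn_ratio(c(0, 2, 4))
  expect_equal(R, c(2 / 3, 4 / 3))
  set.seed(5)
  F2 <- c(10, stats::runif(63))
  expect_equal(mean(sn_ratio(F2)), 1)
  expect_error(sn_ratio(c(5, 0, 0)), "all-zero")
})

test_that("fragment sampling avoids gaps, honours the seed and fails on all-N", {
  g <- Biostrings::DNAStringSet(c(
    c1 = paste0(random_chrom(3000, 2), strrep("N", 200), random_chrom(1000, 3))
  ))
  fr <- sample_fragments(g, 30, frag_len = 500L, seed = 9)
  expect_true(all(nchar(fr$seq) == 500L))
  expect_false(any(grepl("N", fr$seq)))
  # every start must come from the two N-free blocks
  expect_true(all(fr$start + 500L <= 3000L | fr$start >= 3200L))
  fr2 <- sample_fragments(g, 30, frag_len = 500L, seed = 9)
  expect_identical(fr, fr2)

  gN <- Biostrings::DNAStringSet(c(c1 = strrep("N", 1000)))
  expect_error(sample_fragments(gN, 5, frag_len = 500L), "500")
})

test_that("random control fragments follow the requested composition", {
  fr <- random_control(c(A = 1, C = 0, G = 0, T = 0), 3, frag_len = 50L, seed = 1)
  expect_true(all(fr$seq == strrep("A", 50)))
  comp <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  fr2 <- random_control(comp, 20, frag_len = 1000L, seed = 2)
  counts <- table(strsplit(paste(fr2$seq, collapse = ""), "")[[1]])
  n <- 20 * 1000
  for (b in names(comp)) {
    sd_b <- sqrt(n * comp[[b]] * (1 - comp[[b]]))
    expect_lt(abs(counts[[b]] - n * comp[[b]]), 3 * sd_b)
  }
  expect_identical(random_control(comp, 5, 100L, seed = 3),
                   random_control(comp, 5, 100L, seed = 3))
  expect_error(random_control(c(A = -0.1, C = 0.5, G = 0.3, T = 0.3), 1, 10L))
})

test_that("averaged spectra reduce to single-fragment S/N and are order-invariant", {
  set.seed(21)
  frags <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 512, replace = TRUE), collapse = "")
  }, "")
  sp1 <- average_spectrum(frags[1], "AA/TT")
  bits <- encode_step(frags[1], "AA/TT")
  expect_equal(sp1$mean_sn, sn_ratio(power_spectrum(bits)))
  expect_equal(average_spectrum(frags, "AA/TT")$mean_sn,
               average_spectrum(rev(frags), "AA/TT")$mean_sn)
  expect_error(average_spectrum(c("ACGTACGT", "ACGT"), "AA/TT"), "same length")
  # period axis is N/n and strictly decreasing
  expect_equal(sp1$period_bp, 511 / sp1$n)
  expect_true(all(diff(sp1$period_bp) < 0))
})

test_that("a planted periodic step is recovered at the right spectral bin", {
  frags <- planted_period_fragments(16L, 50L, frag_len = 1025L, seed = 4)
  sp <- average_spectrum(frags, "AA/TT")
  N <- 1024
  expect_lte(abs(sp$n[which.max(sp$mean_sn)] - N / 16), 1)
})

test_that("peak finding ranks planted peaks and returns nothing on flat spectra", {
  sp <- tibble::tibble(n = 1:200, period_bp = 1024 / (1:200), mean_sn = 1)
  expect_equal(nrow(find_spectrum_peaks(sp, band_bp = c(10, 500))), 0L)

  bump <- function(n0, h, w = 4) h * exp(-(sp$n - n0)^2 / (2 * w^2))
  sp2 <- sp
  sp2$mean_sn <- 1 + bump(64, 3) + bump(150, 1.5)
  pk <- find_spectrum_peaks(sp2, band_bp = c(4, 500), top_k = 2)
  expect_equal(pk$n[1], 64L)
  expect_equal(pk$n[2], 150L)
  expect_error(find_spectrum_peaks(sp2, band_bp = c(0.1, 0.2)), "empty")
})
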