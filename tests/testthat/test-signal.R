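test_that("the smoothed signal conserves p.p.b. mass exactly", {
  lens <- c(c1 = 1000L)
  s <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = 500L), lens, 21L)
  v <- s[["c1"]]
  expect_equal(sum(v), 1e9)
  expect_equal(sum(v > 0), 21L)
  expect_equal(unique(v[v > 0]), 1e9 / 21)

  s2 <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = c(200L, 800L)),
                          lens, 21L)
  expect_equal(sum(s2[["c1"]][1:500]), 5e8)
  expect_equal(sum(s2[["c1"]][501:1000]), 5e8)

  # w = 1 is the pure scaled histogram
  s3 <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = c(10L, 10L, 20L)),
                          lens, 1L)
  expect_equal(s3[["c1"]][11], 2e9 / 3)
  expect_equal(s3[["c1"]][21], 1e9 / 3)

  expect_error(nucleosome_signal(tibble::tibble(chrom = "c1", pos = 5L), lens, 20L),
               "odd")
  expect_error(nucleosome_signal(tibble::tibble(chrom = "x", pos = 5L), lens),
               "no midpoints")
})

test_that("p.p.b. mass is conserved at every pipeline stage (property)", {
  tags <- small_tags()
  mids <- tibble::tibble(chrom = tags$chrom, pos = tag_midpoint(tags))
  g <- small_sim()$genome
  for (w in c(1L, 21L, 51L)) {
    s <- nucleosome_signal(mids, g, w)
    expect_equal(sum(vapply(s, sum, 0)), 1e9, tolerance = 1e-9)
  }
})

test_that("the random background signal is flat and reproducible", {
  lens <- c(c1 = 20000L)
  b <- background_signal(lens, 200000L, seed = 3, window_w = 21L)
  expect_equal(sum(b[["c1"]]), 1e9)
  # away from edges the per-position mean is 1e9 / L; Poisson check on
  # 500-bp block sums
  interior <- b[["c1"]][1001:19000]
  blocks <- colSums(matrix(interior, nrow = 500))
  expected <- 500 * 1e9 / 20000
  # each block holds ~ 200000 * 500/20000 = 5000 fragments worth of mass
  sd_block <- expected / sqrt(200000 * 500 / 20000)
  expect_true(all(abs(blocks - expected) < 4 * sd_block))
  b2 <- background_signal(lens, 200000L, seed = 3, window_w = 21L)
  expect_identical(b, b2)
})

test_that("profile alignment anchors, averages linearly and flips strands", {
  lens <- c(c1 = 5000L)
  sig <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = 2000L), lens, 1L)
  one <- tibble::tibble(chrom = "c1", start = 1900L, end = 2100L, strand = "+",
                        center = 2000L)
  pr <- align_profile(sig, one, "center", flank = 300L)
  expect_equal(pr$mean_signal[pr$offset == 0], 1e9)
  expect_equal(sum(pr$mean_signal != 0), 1L)

  # averaging k identical elements equals the single-element profile
  three <- one[rep(1, 3), ]
  pr3 <- align_profile(sig, three, "center", flank = 300L)
  expect_equal(pr3$mean_signal, pr$mean_signal)

  # minus-strand element with a spike at centre + 10 maps to offset -10
  sig2 <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = 2010L), lens, 1L)
  minus <- one
  minus$strand <- "-"
  prm <- align_profile(sig2, minus, "center", flank = 300L)
  expect_equal(prm$offset[prm$mean_signal > 0], -10L)
  pru <- align_profile(sig2, minus, "center", flank = 300L, strand_aware = FALSE)
  expect_equal(pru$offset[pru$mean_signal > 0], 10L)

  # an element whose flank leaves the chromosome is excluded and counted
  edge <- tibble::tibble(chrom = "c1", start = 0L, end = 200L, strand = "+",
                         center = 100L)
  pr2 <- align_profile(sig, dplyr::bind_rows(one, edge), "center", flank = 300L)
  expect_equal(attr(pr2, "n_excluded"), 1L)
  expect_equal(attr(pr2, "n_elements"), 1L)
  expect_error(align_profile(sig, edge, "center", flank = 300L), "no element")
})

test_that("end anchors follow element orientation", {
  lens <- c(c1 = 5000L)
  sig <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = 1900L), lens, 1L)
  el <- tibble::tibble(chrom = "c1", start = 1900L, end = 2100L, strand = "+")
  pr5 <- align_profile(sig, el, "end5", flank = 100L)
  expect_equal(pr5$offset[pr5$mean_signal > 0], 0L)
  elm <- el
  elm$strand <- "-"
  pr5m <- align_profile(sig, elm, "end5", flank = 300L)
  # 5' end of a minus element is at end - 1 = 2099; spike at 1900 is 199
  # downstream in element orientation
  expect_equal(pr5m$offset[pr5m$mean_signal > 0], 199L)
})

test_that("bedGraph export writes run-length blocks that tile the signal", {
  lens <- c(c1 = 100L)
  s <- nucleosome_signal(tibble::tibble(chrom = "c1", pos = 50L), lens, 5L)
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(s, p)
  bg <- utils::read.table(p, sep = "\t")
  expect_equal(nrow(bg), 1L)
  expect_equal(bg$V2, 48L)
  expect_equal(bg$V3, 53L)
  expect_equal(bg$V4, signif(2e8, 8))
})
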