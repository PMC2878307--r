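test_that("probe-edge association uses the documented sign convention", {
  el <- tibble::tibble(chrom = "c1", start = 1000L, end = 1300L, strand = "+")
  pr <- function(center) tibble::tibble(chrom = "c1", center = center,
                                        value = 0, cell_type = "x")
  # at the 5' edge: distance 0
  a <- select_probes_near(pr(1000L), el)
  expect_equal(a$distance[a$edge == "5p"], 0L)
  # 100 bp outside the 5' edge: distance -100
  a2 <- select_probes_near(pr(900L), el)
  expect_equal(a2$distance[a2$edge == "5p"], -100L)
  # first base outside the 3' edge: distance 0
  a3 <- select_probes_near(pr(1300L), el)
  expect_equal(a3$distance[a3$edge == "3p"], 0L)
  expect_false("5p" %in% a3$edge)  # beyond the far edge: no 5p claim
  # 601 bp from both edges: excluded
  a4 <- select_probes_near(pr(399L), el, max_dist = 600L)
  expect_equal(nrow(a4), 0L)
  # an inside probe of a short element associates with both edges
  a5 <- select_probes_near(pr(1100L), el)
  expect_setequal(a5$edge, c("5p", "3p"))
  expect_equal(a5$distance[a5$edge == "5p"], 100L)
  expect_equal(a5$distance[a5$edge == "3p"], -200L)
})

test_that("minus-strand elements flip the edge frame", {
  el <- tibble::tibble(chrom = "c1", start = 1000L, end = 1300L, strand = "-")
  pr <- tibble::tibble(chrom = "c1", center = 1400L, value = 0, cell_type = "x")
  a <- select_probes_near(pr, el)
  # probe 100 bp upstream of the 5' end (which sits at end - 1)
  expect_equal(a$distance[a$edge == "5p"], -101L)
})

test_that("distance averaging is exact, filterable and order-invariant", {
  assoc <- tibble::tibble(
    chrom = "c1", center = 1:4, value = c(1, 3, 10, 20),
    cell_type = c("a", "a", "b", "a"), probe_id = 1:4,
    element_id = 1L, edge = "5p", distance = c(-5L, -5L, -5L, 0L)
  )
  p <- average_by_distance(assoc)
  expect_equal(p$mean_value[p$distance == -5], mean(c(1, 3, 10)))
  expect_equal(p$n_probes[p$distance == -5], 3L)
  # the full grid is reported, empty bins as NA
  expect_equal(p$n_probes[p$distance == -3], 0L)
  expect_true(is.na(p$mean_value[p$distance == -3]))
  pa <- average_by_distance(assoc, cell_filter = "a")
  expect_equal(pa$mean_value[pa$distance == -5], 2)
  expect_equal(average_by_distance(assoc[sample(4), ]), p)
})

test_that("the shuffled background preserves values and degenerates correctly", {
  assoc <- tibble::tibble(
    chrom = "c1", center = 1:6, value = 7, cell_type = "x", probe_id = 1:6,
    element_id = 1L, edge = "5p", distance = c(-2L, -2L, -1L, 0L, 1L, 1L)
  )
  bg <- shuffled_background(assoc, n_shuffles = 5, seed = 1)
  expect_true(all(bg$bg_mean == 7))
  expect_true(all(bg$bg_sd == 0))
  expect_error(shuffled_background(assoc[1, ], seed = 1), "at least 2")
  expect_identical(shuffled_background(assoc, seed = 9),
                   shuffled_background(assoc, seed = 9))
})

test_that("shuffling permutes but never alters the multiset of probe values", {
  probes <- simulate_probes(small_sim())
  els <- alu_elements(small_sim()$elements)
  assoc <- select_probes_near(probes, els)
  ids <- sort(unique(assoc$probe_id))
  value_of <- vapply(ids, function(i) assoc$value[assoc$probe_id == i][1], 0)
  set.seed(4)
  perm <- sample(value_of)
  expect_equal(sort(perm), sort(value_of))
})

test_that("planted edge enrichment is recovered exactly in the planted band", {
  sim <- small_sim()
  els <- alu_elements(sim$elements)
  probes <- simulate_probes(sim)
  tp <- tiling_profile(probes, els, bin_width = 50L, seed = 5)
  z <- (tp$mean_value - tp$bg_mean) / tp$bg_sd
  hot <- !is.na(z) & z > 2
  enriched <- tp[hot, c("edge", "distance")]
  want <- dplyr::bind_rows(
    tibble::tibble(edge = "5p", distance = c(-150, -100, -50)),
    tibble::tibble(edge = "3p", distance = c(0, 50, 100))
  )
  expect_equal(dplyr::arrange(enriched, edge, distance),
               dplyr::arrange(want, edge, distance),
               ignore_attr = TRUE)
  # strong depletion (more than half the planted effect below the null)
  # occurs only inside elements; interior bins of short classes sit within
  # 100 bp of both edges, so it can reach any interior bin, never a flank
  delta <- sim$truth$config$probe_delta
  cold <- !is.na(z) & z < -2 & tp$mean_value < tp$bg_mean - delta / 2
  depleted <- tp[cold, c("edge", "distance")]
  expect_gt(nrow(depleted), 0L)
  expect_true(all(
    (depleted$edge == "5p" & depleted$distance >= 0) |
    (depleted$edge == "3p" & depleted$distance < 0)
  ))
})
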