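test_that("pairs-TSV loading enforces the mononucleosome insert window", {
  p <- write_tmp(c(
    "c1\t100\t246\t1\t.",                       # insert 147: keep
    "c1\t100\t220\t1\t.",                       # insert 121: drop
    "c1\t100\t272\t1\t.",                       # insert 173: drop
    "c1\t500\t630\t3\tc1:500;c1:9000;c1:12000"  # insert 131: keep, multi
  ), ".tsv")
  tags <- load_tag_pairs(p)
  expect_equal(nrow(tags), 2L)
  expect_equal(attr(tags, "n_dropped"), 2L)
  expect_equal(tags$n_hits, c(1L, 3L))
  expect_equal(tags$hits[[2]]$fwd5, c(500L, 9000L, 12000L))
})

test_that("tag pairs round-trip through the pairs-TSV writer", {
  tags <- small_tags()[1:500, ]
  p <- tempfile(fileext = ".tsv")
  write_tag_pairs(tags, p)
  back <- load_tag_pairs(p)
  expect_equal(back$fwd5, tags$fwd5)
  expect_equal(back$rev5, tags$rev5)
  expect_equal(back$n_hits, tags$n_hits)
  i <- which(tags$n_hits > 1L)[1]
  if (!is.na(i)) expect_equal(back$hits[[i]], tags$hits[[i]])
})

test_that("SAM proper pairs load identically to the equivalent pairs TSV", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:10000",
    # fwd5 = 100 (0-based), insert 147 -> rev5 = 246
    paste("r1", 99, "c1", 101, 42, "36M", "=", 212, 147,
          strrep("A", 36), strrep("I", 36), sep = "\t"),
    paste("r1", 147, "c1", 212, 42, "36M", "=", 101, -147,
          strrep("A", 36), strrep("I", 36), sep = "\t")
  )
  psam <- write_tmp(sam, ".sam")
  from_sam <- load_tag_pairs(psam, format = "sam")
  ptsv <- write_tmp("c1\t100\t246\t1\t.", ".tsv")
  from_tsv <- load_tag_pairs(ptsv)
  expect_equal(from_sam[c("chrom", "fwd5", "rev5", "n_hits")],
               from_tsv[c("chrom", "fwd5", "rev5", "n_hits")])
})

test_that("midpoints use floor of the mean of the two 5' ends", {
  expect_equal(tag_midpoint(100L, 246L), 173L)
  expect_equal(tag_midpoint(0L, 146L), 73L)
  expect_equal(tag_midpoint(100L, 247L), 173L)
  tags <- tibble::tibble(fwd5 = c(10L, 20L), rev5 = c(156L, 166L))
  expect_equal(tag_midpoint(tags), c(83L, 93L))
})

test_that("tag categorisation splits unique and multi-hit tags by Alu overlap", {
  els <- tibble::tibble(chrom = "c1", start = c(1000L, 5000L),
                        end = c(1300L, 5300L), strand = "+",
                        center = c(1150L, 5150L))
  mk <- function(fwd5, n_hits = 1L, hit_fwd5 = integer(0)) {
    h <- tibble::tibble(chrom = rep("c1", length(hit_fwd5)), fwd5 = hit_fwd5)
    tibble::tibble(chrom = "c1", fwd5 = fwd5, rev5 = fwd5 + 146L,
                   n_hits = n_hits, hits = list(h))
  }
  tags <- dplyr::bind_rows(
    mk(1050L),                                    # midpoint 1123 in Alu
    mk(2000L),                                    # outside
    mk(1050L, 3L, c(1050L, 5050L, 1100L)),        # all hits in Alu
    mk(1050L, 2L, c(1050L, 9000L)),               # partial
    mk(8000L, 2L, c(8000L, 9000L))                # none
  )
  ct <- categorize_tags(tags, els)
  expect_equal(ct$unique_alu, 1L)
  expect_equal(ct$unique_other, 1L)
  expect_equal(ct$multi_complete, 1L)
  expect_equal(ct$multi_partial, 1L)
  expect_equal(ct$multi_none, 1L)
  expect_equal(ct$total, 5L)
})

test_that("category counts always sum to the total (property)", {
  els <- alu_elements(small_sim()$elements)
  for (s in 1:3) {
    set.seed(s)
    idx <- sample.int(nrow(small_tags()), 3000L)
    ct <- categorize_tags(small_tags()[idx, ], els)
    expect_equal(ct$unique_alu + ct$unique_other + ct$multi_complete +
                   ct$multi_partial + ct$multi_none, ct$total)
  }
})

test_that("multi-hit resolution computes per-tag dispersion and honours policy", {
  els <- tibble::tibble(chrom = "c1", start = c(1000L, 5000L, 9000L),
                        end = c(1300L, 5300L, 9300L), strand = "+",
                        center = c(1150L, 5150L, 9150L))
  mk <- function(hit_centers, n = length(hit_centers)) {
    all_fwd5 <- as.integer(hit_centers - 73L)
    h <- tibble::tibble(chrom = rep("c1", n), fwd5 = all_fwd5)
    tibble::tibble(chrom = "c1", fwd5 = all_fwd5[1], rev5 = all_fwd5[1] + 146L,
                   n_hits = n, hits = list(h))
  }
  # all hits at identical offset from their element centre -> SD 0
  t1 <- mk(c(1150L, 5150L, 9150L) + 40L)
  r1 <- multihit_augment(t1, els, "complete_only", seed = 1)
  expect_equal(r1$per_tag_sd, 0)
  expect_equal(nrow(r1$midpoints), 1L)
  expect_true(r1$midpoints$pos %in% (c(1150L, 5150L, 9150L) + 40L))

  # hits at distances {10, 12, 14} from the nearest centre -> SD 2.0
  t2 <- mk(c(1150L + 10L, 5150L + 12L, 9150L + 14L))
  r2 <- multihit_augment(t2, els, "complete_only", seed = 1)
  expect_equal(r2$per_tag_sd, 2.0)

  # 4 of 5 hits (80%) in Alu is excluded under the >85% policy
  t3 <- mk(c(1150L, 5150L, 9150L, 1160L, 50000L))
  expect_equal(nrow(multihit_augment(t3, els, "ge85", seed = 1)$midpoints), 0L)
  # but 5 of 5 qualifies
  t4 <- mk(c(1150L, 5150L, 9150L, 1160L, 5160L))
  expect_equal(nrow(multihit_augment(t4, els, "ge85", seed = 1)$midpoints), 1L)
  # determinism
  expect_identical(multihit_augment(t4, els, "ge85", seed = 7),
                   multihit_augment(t4, els, "ge85", seed = 7))
})
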