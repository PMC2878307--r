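test_that("planted elements hit the target coverage and class length windows", {
  sim <- small_sim()
  cfg <- sim$truth$config
  L <- sum(Biostrings::width(sim$genome))
  planted_bp <- sum(sim$elements$end - sim$elements$start)
  expect_lt(abs(planted_bp / L - cfg$alu_coverage), 0.1 * cfg$alu_coverage)
  len <- sim$elements$end - sim$elements$start
  expect_true(all(len[sim$elements$alu_class == "dimer"] >= 280 &
                  len[sim$elements$alu_class == "dimer"] <= 320))
  expect_true(all(len[sim$elements$alu_class == "FLAM"] >= 110 &
                  len[sim$elements$alu_class == "FLAM"] <= 150))
  expect_true(all(len[sim$elements$alu_class == "FRAM"] >= 150 &
                  len[sim$elements$alu_class == "FRAM"] <= 190))
  # planted names classify back through the annotation module
  els <- alu_elements(sim$elements[setdiff(names(sim$elements),
                                           c("alu_class", "center"))])
  expect_equal(els$alu_class, sim$elements$alu_class)
  # non-overlap
  ir <- IRanges::IRanges(sim$elements$start + 1L, sim$elements$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))), planted_bp)
})

test_that("zero coverage yields a plain random genome", {
  sim0 <- simulate_genome(sim_config(genome_len = 5e4, alu_coverage = 0,
                                     seed = 2))
  expect_equal(nrow(sim0$elements), 0L)
  expect_equal(sum(Biostrings::width(sim0$genome)), 5e4)
})

test_that("generators are byte-deterministic given the seed", {
  cfg <- sim_config(genome_len = 5e4, n_tags = 2000L, seed = 31L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$elements, s2$elements)
  expect_identical(simulate_nucleosome_tags(s1), simulate_nucleosome_tags(s2))
  expect_identical(simulate_probes(s1), simulate_probes(s2))
  g1 <- simulate_genes(s1)
  expect_identical(g1, simulate_genes(s2))
  expect_identical(simulate_tss_tags(s1, g1), simulate_tss_tags(s2, g1))
})

test_that("emitted files round-trip through the package readers", {
  sim <- small_sim()
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(sim$genome, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(as.character(g2), as.character(sim$genome))

  bed <- tempfile(fileext = ".bed")
  write_bed6(sim$elements, bed)
  back <- read_repeat_table(bed, "bed6")
  expect_equal(back$start, sim$elements$start)
  expect_equal(back$end, sim$elements$end)
  expect_equal(back$rep_name, sim$elements$rep_name)
  expect_equal(back$strand, sim$elements$strand)
})

test_that("simulated tag pairs respect the insert window and multi-hit design", {
  tags <- small_tags()
  insert <- tags$rev5 - tags$fwd5 + 1L
  expect_true(all(insert >= 122L & insert <= 172L))
  multi <- tags[tags$n_hits > 1L, ]
  expect_gt(nrow(multi), 0L)
  expect_true(all(vapply(multi$hits, nrow, 0L) == multi$n_hits))
  # multi-hit tags arise in elements and their hits stay in elements
  els <- alu_elements(small_sim()$elements)
  frac <- alunuc:::multihit_alu_fraction(multi[1:50, ], els)
  expect_true(all(frac == 1))
})

test_that("switching off right-slot weight removes the right-arm peak", {
  cfg <- sim_config(genome_len = 3e5, n_tags = 60000L,
                    slot_weights = c(left = 1, right = 0), seed = 8L)
  sim <- simulate_genome(cfg)
  tags <- simulate_nucleosome_tags(sim)
  mids <- tibble::tibble(chrom = tags$chrom, pos = tag_midpoint(tags))
  sig <- nucleosome_signal(mids[tags$n_hits <= 1L, ], sim$genome)
  els <- alu_elements(sim$elements)
  prof <- align_profile(sig, els[els$alu_class == "dimer", ], "center",
                        flank = 400L)
  sm <- function(off) {
    mean(prof$mean_signal[abs(prof$offset - off) <= 15])
  }
  # left slot (offset -92) towers over the silenced right slot (offset +72)
  expect_gt(sm(-92), 4 * sm(72))
})

test_that("probe simulation degenerates to constants without noise or bands", {
  cfg <- sim_config(genome_len = 5e4, probe_noise_sd = 0, probe_delta = 0,
                    probe_baseline = 2.5, seed = 5L)
  sim <- simulate_genome(cfg)
  pr <- simulate_probes(sim)
  expect_true(all(pr$value == 2.5))
  expect_setequal(unique(pr$cell_type), c("cellA", "cellB"))
  expect_equal(unique(diff(unique(pr$center))), 50L)
})

test_that("5' tag counts follow the planted Poisson intensities", {
  cfg <- sim_config(genome_len = 2e5, lambda_alu = 0, n_genes = 25L, seed = 12L)
  sim <- simulate_genome(cfg)
  genes <- simulate_genes(sim)
  tt <- simulate_tss_tags(sim, genes)
  # no tags at all inside elements when lambda_alu = 0
  expect_equal(count_tags(tt, sim$elements), 0L)
  # TSS windows: Poisson mean lambda_tss * 301 per gene
  tssr <- tibble::tibble(chrom = genes$chrom, start = genes$tss - 150L,
                         end = genes$tss + 151L)
  n_tss <- count_tags(tt, tssr)
  mu <- cfg$lambda_tss * 301 * nrow(genes)
  expect_lt(abs(n_tss - mu), 4 * sqrt(mu))
})
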