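# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# A reduced simulation: same structure as the default study conditions but
# on a 300-kb genome with fewer tags, enough for closed-loop unit tests.
small_sim_config <- function(seed = 42L) {
  sim_config(genome_len = 3e5, n_tags = 60000L, n_genes = 40L, seed = seed)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_genome(small_sim_config())
  }
  .fixture_env$sim
}

small_tags <- function() {
  if (is.null(.fixture_env$tags)) {
    .fixture_env$tags <- simulate_nucleosome_tags(small_sim())
  }
  .fixture_env$tags
}

# random genome string with no N, fixed seed
random_chrom <- function(len, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force O(N^2) DFT power spectrum, the independent oracle for the
# FFT path; mirrors the windowing/centering contract of power_spectrum()
dft_power_oracle <- function(bits, window = welch_window(length(bits)),
                             center = TRUE) {
  N <- length(bits)
  b <- as.numeric(bits)
  if (center) b <- b - mean(b)
  bw <- b * window
  k <- 0:(N - 1)
  vapply(0:(N %/% 2 - 1), function(n) {
    re <- sum(bw * cos(-2 * pi * n * k / N))
    im <- sum(bw * sin(-2 * pi * n * k / N))
    re^2 + im^2
  }, 0)
}

# fragments carrying an exact period-p step pattern: A-runs of length
# floor(p/2) repeated every p bp on an A/T-free background (C/G only), so
# the AA/TT indicator is an exact square wave of period p whose
# fundamental dominates its harmonics
planted_period_fragments <- function(p, n_frag, frag_len = 8193L, seed = 1L) {
  set.seed(seed)
  a_run <- (seq_len(frag_len) - 1L) %% p < p %/% 2L
  vapply(seq_len(n_frag), function(i) {
    chars <- sample(c("C", "G"), frag_len, replace = TRUE)
    chars[a_run] <- "A"
    paste(chars, collapse = "")
  }, "")
}
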