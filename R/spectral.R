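#' Welch window
#'
#' Parabolic taper used before the discrete Fourier transform to reduce
#' spectral leakage at high frequency:
#' `W(k) = 1 - ((k - (N-1)/2) / ((N-1)/2))^2` for `k = 0, ..., N-1`.
#' The endpoints are 0 and the centre is 1.
#'
#' @param N Window length (>= 3).
#' @return Numeric vector of length `N`.
#' @export
welch_window <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 3) {
    stop("`N` must be a single integer >= 3", call. = FALSE)
  }
  k <- seq_len(N) - 1
  half <- (N - 1) / 2
  1 - ((k - half) / half)^2
}

#' Windowed power spectrum of a binary step indicator
#'
#' Computes `F(n) = |sum_k B(k) W(k) exp(-2 pi i n k / N)|^2` for
#' `n = 0, ..., N/2 - 1`, where `B` is the 0/1 indicator and `W` a window
#' (Welch by default).  By default the indicator is mean-centred before
#' windowing: a step indicator has a large nonzero mean, and the window
#' shape leaks that mean into the lowest few frequency bins, which would
#' otherwise show spurious S/N peaks even on random sequence.
#'
#' @param bits 0/1 vector (even length expected; 8192 in the standard
#'   pipeline, from 8193-bp fragments).
#' @param window Window weights of the same length, or `NULL` for no
#'   windowing (all ones).  Defaults to [welch_window()].
#' @param center Subtract the indicator mean before windowing (default
#'   `TRUE`).
#' @return Numeric vector `F(n)`, `n = 0 .. floor(N/2) - 1`.
#' @export
power_spectrum <- function(bits, window = welch_window(length(bits)),
                           center = TRUE) {
  N <- length(bits)
  if (N == 0L) stop("empty input", call. = FALSE)
  if (is.null(window)) window <- rep(1, N)
  if (length(window) != N) stop("window length must match input", call. = FALSE)
  b <- as.numeric(bits)
  if (center) b <- b - mean(b)
  ft <- stats::fft(b * window)
  Mod(ft[seq_len(N %/% 2)])^2
}

#' Signal-to-noise ratio of a power spectrum
#'
#' Divides each spectral value by the background noise, defined as the
#' average power over all reported frequencies.  The DC bin (`n = 0`) is
#' excluded both from the background mean and from the output, since the
#' step indicator has a large nonzero mean that would otherwise dominate.
#'
#' @param F Power spectrum from [power_spectrum()] (`n = 0` first).
#' @return Numeric vector `R(n)` for `n = 1 .. length(F) - 1`; its mean
#'   is 1 by construction.
#' @export
sn_ratio <- function(F) {
  if (length(F) < 2L) stop("power spectrum too short", call. = FALSE)
  Fn <- F[-1L]
  bg <- mean(Fn)
  if (bg == 0) stop("all-zero power spectrum: S/N undefined", call. = FALSE)
  Fn / bg
}

# 0-based start positions (per chrom) whose [s, s + frag_len) window is N-free
eligible_starts <- function(genome, frag_len) {
  genome <- as_genome(genome)
  lapply(stats::setNames(names(genome), names(genome)), function(chr) {
    L <- length(genome[[chr]])
    if (L < frag_len) return(integer(0))
    isN <- as.integer(strsplit(as.character(genome[[chr]]), "")[[1]] == "N")
    cs <- c(0L, cumsum(isN))
    s <- 0:(L - frag_len)
    s[cs[s + frag_len + 1L] - cs[s + 1L] == 0L]
  })
}

#' Sample gap-free fragments from a genome
#'
#' Draws fragments of fixed length uniformly over all start positions whose
#' window contains no `N`, independently (overlaps between fragments are
#' allowed).  The standard fragment length is 8193 bp (2^13 + 1), giving
#' 8192-bit step indicators.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param n_frag Number of fragments.
#' @param frag_len Fragment length in bp (default 8193).
#' @param seed Integer seed for reproducible sampling, or `NULL`.
#' @return A tibble with columns `chrom`, `start` (0-based) and `seq`.
#' @export
sample_fragments <- function(genome, n_frag, frag_len = 8193L, seed = NULL) {
  genome <- as_genome(genome)
  starts <- eligible_starts(genome, frag_len)
  n_per <- vapply(starts, length, 0L)
  if (sum(n_per) == 0L) {
    stop("no N-free window of length ", frag_len, " in the genome", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  chroms <- sample(names(starts), n_frag, replace = TRUE, prob = n_per / sum(n_per))
  out <- tibble::tibble(
    chrom = chroms,
    start = vapply(chroms, function(chr) sample(starts[[chr]], 1L), 0L)
  )
  out$seq <- vapply(seq_len(n_frag), function(i) {
    as.character(Biostrings::subseq(genome[[out$chrom[i]]],
                                    start = out$start[i] + 1L,
                                    width = frag_len))
  }, "")
  out
}

#' Generate random control fragments
#'
#' Emits i.i.d. random DNA fragments at a given base composition, matching
#' the control used against genomic fragments: random sequence with the
#' same nucleotide frequencies carries no periodic structure.
#'
#' @param base_composition Named frequencies of A, C, G, T (must be
#'   nonnegative and sum to 1).
#' @param n_frag Number of fragments.
#' @param frag_len Fragment length in bp.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with a `seq` column.
#' @export
random_control <- function(base_composition, n_frag, frag_len = 8193L, seed = NULL) {
  comp <- base_composition[c("A", "C", "G", "T")]
  if (any(is.na(comp)) || any(comp < 0)) {
    stop("`base_composition` needs nonnegative A, C, G, T frequencies", call. = FALSE)
  }
  if (abs(sum(comp) - 1) > 1e-6) stop("base composition must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_frag), function(i) {
    paste(sample(c("A", "C", "G", "T"), frag_len, replace = TRUE, prob = comp),
          collapse = "")
  }, "")
  tibble::tibble(seq = seqs)
}

#' Average S/N periodicity spectrum over fragments
#'
#' Encodes each fragment as a 0/1 indicator of the target step, computes
#' the Welch-windowed power spectrum and its S/N ratio per fragment, and
#' averages the ratios bin-wise.  The period axis `p = N/n` (bp) is
#' attached, where `N` is the indicator length.
#'
#' @param fragments Character vector of equal-length sequences, or a data
#'   frame with a `seq` column (as from [sample_fragments()]).
#' @param step Step-class label (e.g. `"AA/TT"`) or a row from
#'   [step_class()].
#' @param n_action Passed to [encode_step()]; use `"zero"` for fragments
#'   from a repeat-masked genome.
#' @return An `alu_spectrum`: a tibble with columns `n`, `period_bp`,
#'   `mean_sn`, and attributes `step`, `n_fragments`, `N`.
#' @export
average_spectrum <- function(fragments, step, n_action = c("error", "zero")) {
  n_action <- match.arg(n_action)
  if (is.data.frame(fragments)) fragments <- fragments$seq
  if (length(fragments) < 1L) stop("need at least one fragment", call. = FALSE)
  lens <- nchar(fragments)
  if (length(unique(lens)) != 1L) {
    stop("fragments must all have the same length", call. = FALSE)
  }
  if (is.character(step)) step <- step_class(step)
  N <- lens[1] - 1L
  W <- welch_window(N)
  half <- N %/% 2
  acc <- numeric(half - 1L)
  for (fr in fragments) {
    bits <- encode_step(fr, step, n_action = n_action)
    acc <- acc + sn_ratio(power_spectrum(bits, W))
  }
  sn <- acc / length(fragments)
  n <- seq_len(half - 1L)
  out <- tibble::tibble(n = n, period_bp = N / n, mean_sn = sn)
  structure(out,
            class = c("alu_spectrum", class(out)),
            step = step$label,
            n_fragments = length(fragments),
            N = N)
}

#' Locate spectral peaks in a period band
#'
#' Smooths the S/N profile with a moving average (long-period bins are
#' sparse, so raw bin maxima are noisy), finds local maxima whose period
#' lies inside the band, and returns the `top_k` highest.  Ties rank the
#' longer period (smaller `n`) first.  The reported period is `N/n` at the
#' maximal bin.
#'
#' @param spectrum An `alu_spectrum` from [average_spectrum()] (or any
#'   tibble with `n`, `period_bp`, `mean_sn`).
#' @param band_bp Length-2 numeric: period band (bp) to search, e.g.
#'   `c(50, 250)`.
#' @param top_k Maximum number of peaks to return.
#' @param smooth Moving-average width in bins (odd; default 5).
#' @return A tibble with columns `n`, `period_bp`, `sn` (raw S/N at the
#'   peak bin) and `sn_smooth`, ordered by decreasing smoothed height.
#' @export
find_spectrum_peaks <- function(spectrum, band_bp = c(50, 250), top_k = 2L,
                                smooth = 5L) {
  stopifnot(length(band_bp) == 2L)
  band_bp <- sort(band_bp)
  sm <- as.numeric(stats::filter(spectrum$mean_sn, rep(1 / smooth, smooth),
                                 sides = 2))
  in_band <- which(spectrum$period_bp >= band_bp[1] &
                   spectrum$period_bp <= band_bp[2] & !is.na(sm))
  if (length(in_band) == 0L) stop("empty period band", call. = FALSE)
  interior <- in_band[in_band > 1L & in_band < nrow(spectrum)]
  is_peak <- vapply(interior, function(i) {
    sm[i] >= sm[i - 1L] && sm[i] >= sm[i + 1L] &&
      (sm[i] > sm[i - 1L] || sm[i] > sm[i + 1L])
  }, NA)
  idx <- interior[which(is_peak)]
  if (length(idx) == 0L) {
    return(tibble::tibble(n = integer(0), period_bp = numeric(0),
                          sn = numeric(0), sn_smooth = numeric(0)))
  }
  ord <- order(-sm[idx], spectrum$n[idx])
  idx <- idx[ord][seq_len(min(top_k, length(idx)))]
  tibble::tibble(
    n = spectrum$n[idx],
    period_bp = spectrum$period_bp[idx],
    sn = spectrum$mean_sn[idx],
    sn_smooth = sm[idx]
  )
}

#' One-call genome periodicity spectrum
#'
#' Convenience wrapper tying fragment acquisition to spectrum averaging in
#' the three standard modes: `raw` samples gap-free fragments from the
#' genome; `masked` first replaces the intervals in `mask` with `N` and
#' then samples gap-free fragments from the masked genome, so fragments
#' come entirely from mask-free windows; `random` generates i.i.d.
#' fragments at the genome's base composition.
#'
#' @param genome A `DNAStringSet`.
#' @param step Step-class label.
#' @param mode `"raw"`, `"masked"` or `"random"`.
#' @param mask Feature table to mask (required for `mode = "masked"`).
#' @param n_frag,frag_len,seed Passed to the samplers.
#' @return An `alu_spectrum` (see [average_spectrum()]); attribute `mode`
#'   records the mode.
#' @export
genome_spectrum <- function(genome, step, mode = c("raw", "masked", "random"),
                            mask = NULL, n_frag = 1000L, frag_len = 8193L,
                            seed = NULL) {
  mode <- match.arg(mode)
  genome <- as_genome(genome)
  if (mode == "random") {
    frags <- random_control(base_composition(genome), n_frag, frag_len, seed)
    out <- average_spectrum(frags, step)
  } else if (mode == "raw") {
    frags <- sample_fragments(genome, n_frag, frag_len, seed)
    out <- average_spectrum(frags, step)
  } else {
    if (is.null(mask)) stop("`mask` is required for mode = 'masked'", call. = FALSE)
    masked <- mask_regions(genome, mask)
    frags <- sample_fragments(masked, n_frag, frag_len, seed)
    out <- average_spectrum(frags, step)
  }
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}
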