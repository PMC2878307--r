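#' Smoothed nucleosome-centre signal
#'
#' Builds the per-position nucleosome signal S(i) from tag-pair midpoints:
#' the midpoint histogram is coarse-grain smoothed by convolution with a
#' uniform kernel (MNase digestion is imprecise, so a centre is evidence
#' for a small neighbourhood, not a single base), then normalised so the
#' genome-wide sum is 10^9 — parts-per-billion (p.p.b.) units, making
#' libraries of different depth comparable.
#'
#' @param midpoints A data frame with columns `chrom` and `pos`
#'   (0-based midpoint positions), or an integer vector for a single
#'   chromosome.
#' @param genome_lengths Named integer vector of chromosome lengths, or a
#'   `DNAStringSet`.
#' @param window_w Odd uniform-kernel width in bp (default 21).
#' @return A `nucleosome_signal`: a named list of per-chromosome numeric
#'   vectors (index `i + 1` holds position `i`), with attributes
#'   `window_w` and `total_tags`.  The values sum to 1e9 over the genome.
#' @export
nucleosome_signal <- function(midpoints, genome_lengths, window_w = 21L) {
  if (window_w %% 2L != 1L || window_w < 1L) {
    stop("`window_w` must be odd and positive", call. = FALSE)
  }
  if (methods::is(genome_lengths, "DNAStringSet")) {
    genome_lengths <- stats::setNames(Biostrings::width(genome_lengths),
                                      names(genome_lengths))
  }
  if (!is.data.frame(midpoints)) {
    if (length(genome_lengths) != 1L) {
      stop("vector midpoints need a single named chromosome length", call. = FALSE)
    }
    midpoints <- tibble::tibble(chrom = names(genome_lengths), pos = midpoints)
  }
  midpoints <- midpoints[midpoints$chrom %in% names(genome_lengths), , drop = FALSE]
  in_bounds <- midpoints$pos >= 0L &
    midpoints$pos < genome_lengths[midpoints$chrom]
  midpoints <- midpoints[in_bounds, , drop = FALSE]
  total <- nrow(midpoints)
  if (total == 0L) stop("no midpoints on known chromosomes", call. = FALSE)
  sig <- lapply(stats::setNames(names(genome_lengths), names(genome_lengths)),
                function(chr) {
    L <- genome_lengths[[chr]]
    pos <- midpoints$pos[midpoints$chrom == chr]
    h <- numeric(L)
    if (length(pos) > 0L) {
      t <- table(pos)
      h[as.integer(names(t)) + 1L] <- as.numeric(t)
    }
    moving_sum(h, window_w)
  })
  s <- sum(vapply(sig, sum, 0))
  sig <- lapply(sig, function(v) v * (1e9 / s))
  structure(sig, class = "nucleosome_signal",
            window_w = window_w, total_tags = total)
}

# centred moving sum with zero padding at the edges
moving_sum <- function(x, w) {
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(c(rep(0, half), x, rep(0, half))))
  cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]
}

#' @export
print.nucleosome_signal <- function(x, ...) {
  cat("<nucleosome_signal> ", length(x), " chromosome(s), ",
      attr(x, "total_tags"), " tags, window ", attr(x, "window_w"),
      " bp, p.p.b.-normalised\n", sep = "")
  invisible(x)
}

#' Random-fragment background signal
#'
#' Builds the matched background S_back(i): paired-end fragments of fixed
#' insert (147 bp, a complete nucleosome core) are dropped uniformly on
#' the genome and pushed through the same midpoint/smoothing/p.p.b.
#' pipeline, capturing every positional bias of the pipeline itself.
#'
#' @param genome_lengths Named chromosome lengths or a `DNAStringSet`.
#' @param n_fragments Number of random fragments.
#' @param seed Integer seed, or `NULL`.
#' @param window_w Smoothing width, as in [nucleosome_signal()].
#' @param insert Fragment insert size (default 147).
#' @return A `nucleosome_signal`.
#' @export
background_signal <- function(genome_lengths, n_fragments, seed = NULL,
                              window_w = 21L, insert = 147L) {
  if (methods::is(genome_lengths, "DNAStringSet")) {
    genome_lengths <- stats::setNames(Biostrings::width(genome_lengths),
                                      names(genome_lengths))
  }
  if (!is.null(seed)) set.seed(seed)
  eligible <- pmax(genome_lengths - insert + 1L, 0L)
  chroms <- sample(names(genome_lengths), n_fragments, replace = TRUE,
                   prob = eligible / sum(eligible))
  fwd5 <- vapply(chroms, function(chr) {
    sample.int(eligible[[chr]], 1L) - 1L
  }, 0L)
  rev5 <- fwd5 + insert - 1L
  mids <- tibble::tibble(chrom = chroms, pos = (fwd5 + rev5) %/% 2L)
  nucleosome_signal(mids, genome_lengths, window_w)
}

#' Average a signal around anchored elements
#'
#' Aligns a per-position signal to an anchor point of each element
#' (centre, 5' end or 3' end) and averages over elements at each offset in
#' a symmetric flank, optionally with a matched background signal.
#' Minus-strand elements are coordinate-flipped when `strand_aware`, so
#' "left" always means the element's 5' side.  Elements whose window would
#' run off a chromosome are excluded and counted.
#'
#' @param signal A `nucleosome_signal` (or named list of numeric vectors).
#' @param elements Element table with `chrom`, `start`, `end`, `strand`
#'   and, for `anchor = "center"`, `center`.
#' @param anchor `"center"`, `"end5"` or `"end3"`.
#' @param flank Half-width of the window in bp (default 1000).
#' @param strand_aware Flip minus-strand elements (default `TRUE`).
#' @param background Optional second signal treated identically and
#'   reported as `mean_background`.
#' @return An `alu_metaprofile`: tibble with `offset`, `mean_signal` and
#'   (if `background` given) `mean_background`; attributes `anchor`,
#'   `flank`, `n_elements`, `n_excluded`.
#' @export
align_profile <- function(signal, elements, anchor = c("center", "end5", "end3"),
                          flank = 1000L, strand_aware = TRUE,
                          background = NULL) {
  anchor <- match.arg(anchor)
  apos <- anchor_positions(elements, anchor)
  lens <- vapply(signal, length, 0L)
  known <- elements$chrom %in% names(signal)
  ok <- known & apos - flank >= 0L & apos + flank < lens[elements$chrom]
  n_excluded <- sum(!ok)
  if (!any(ok)) stop("no element fits inside its chromosome with this flank",
                     call. = FALSE)
  el <- elements[ok, , drop = FALSE]
  apos <- apos[ok]
  acc <- extract_mean(signal, el, apos, flank, strand_aware)
  out <- tibble::tibble(offset = seq(-flank, flank), mean_signal = acc)
  if (!is.null(background)) {
    out$mean_background <- extract_mean(background, el, apos, flank, strand_aware)
  }
  structure(out, class = c("alu_metaprofile", class(out)),
            anchor = anchor, flank = flank,
            n_elements = nrow(el), n_excluded = n_excluded)
}

anchor_positions <- function(elements, anchor) {
  switch(anchor,
    center = if ("center" %in% names(elements)) elements$center
             else (elements$start + elements$end) %/% 2L,
    end5 = ifelse(elements$strand == "-", elements$end - 1L, elements$start),
    end3 = ifelse(elements$strand == "-", elements$start, elements$end - 1L)
  )
}

extract_mean <- function(signal, elements, apos, flank, strand_aware) {
  acc <- numeric(2L * flank + 1L)
  for (i in seq_len(nrow(elements))) {
    v <- signal[[elements$chrom[i]]][(apos[i] - flank + 1L):(apos[i] + flank + 1L)]
    if (strand_aware && elements$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  acc / nrow(elements)
}

#' Local maxima of a metaprofile
#'
#' Finds local maxima of the (optionally smoothed) mean signal within an
#' offset window — used to read nucleosome slot positions and phased
#' flanking peaks off an element-anchored profile.
#'
#' @param profile An `alu_metaprofile`.
#' @param within Length-2 numeric offset window (default the whole
#'   profile).
#' @param smooth Moving-average width in positions (odd; default 31) used
#'   to suppress sampling noise before peak calling.
#' @param min_height Discard maxima whose smoothed height is below this
#'   value (default 0).
#' @return A tibble with `offset`, `height` (smoothed) and `raw`
#'   (unsmoothed mean signal), ordered by offset.
#' @export
profile_local_maxima <- function(profile, within = NULL, smooth = 31L,
                                 min_height = 0) {
  sm <- as.numeric(stats::filter(profile$mean_signal,
                                 rep(1 / smooth, smooth), sides = 2))
  idx <- which(!is.na(sm))
  idx <- idx[idx > 1L & idx < nrow(profile)]
  if (!is.null(within)) {
    idx <- idx[profile$offset[idx] >= within[1] & profile$offset[idx] <= within[2]]
  }
  is_max <- vapply(idx, function(i) {
    !is.na(sm[i - 1L]) && !is.na(sm[i + 1L]) &&
      sm[i] >= sm[i - 1L] && sm[i] >= sm[i + 1L] &&
      (sm[i] > sm[i - 1L] || sm[i] > sm[i + 1L])
  }, NA)
  idx <- idx[is_max & sm[idx] >= min_height]
  tibble::tibble(offset = profile$offset[idx], height = sm[idx],
                 raw = profile$mean_signal[idx])
}

#' Export a signal as bedGraph
#'
#' @param signal A `nucleosome_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(signal)) {
    v <- signal[[chr]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(chr, start[keep], end[keep], signif(r$values[keep], 8))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
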