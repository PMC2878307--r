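#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.alu_spectrum <- function(x, ...) {
  tibble::tibble(n = x$n, period_bp = x$period_bp, mean_sn = x$mean_sn)
}

#' @export
glance.alu_spectrum <- function(x, ...) {
  i <- which.max(x$mean_sn)
  tibble::tibble(
    step = attr(x, "step"),
    mode = attr(x, "mode") %||% NA_character_,
    n_fragments = attr(x, "n_fragments"),
    N = attr(x, "N"),
    max_sn = x$mean_sn[i],
    period_at_max = x$period_bp[i]
  )
}

#' Tidy a nucleosome signal into a long table
#'
#' @param x A `nucleosome_signal`.
#' @param chrom Optional chromosome to restrict to.
#' @param from,to Optional 0-based position window.
#' @param ... Unused.
#' @return A tibble with `chrom`, `pos` (0-based), `signal`.
#' @export
tidy.nucleosome_signal <- function(x, chrom = NULL, from = NULL, to = NULL, ...) {
  chroms <- chrom %||% names(x)
  dplyr::bind_rows(lapply(chroms, function(chr) {
    v <- x[[chr]]
    a <- (from %||% 0L) + 1L
    b <- min((to %||% (length(v) - 1L)) + 1L, length(v))
    tibble::tibble(chrom = chr, pos = seq(a, b) - 1L, signal = v[a:b])
  }))
}

#' @export
glance.nucleosome_signal <- function(x, ...) {
  tibble::tibble(
    n_chrom = length(x),
    genome_len = sum(vapply(x, length, 0L)),
    total_tags = attr(x, "total_tags"),
    window_w = attr(x, "window_w"),
    total_signal = sum(vapply(x, sum, 0))
  )
}

#' @export
tidy.alu_metaprofile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[intersect(
    c("offset", "mean_signal", "mean_background"), names(x))])
}

#' @export
glance.alu_metaprofile <- function(x, ...) {
  i <- which.max(x$mean_signal)
  tibble::tibble(
    anchor = attr(x, "anchor"),
    flank = attr(x, "flank"),
    n_elements = attr(x, "n_elements"),
    n_excluded = attr(x, "n_excluded"),
    max_signal = x$mean_signal[i],
    offset_at_max = x$offset[i]
  )
}

#' @export
tidy.alu_expression <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("category", "n_regions", "tag_count",
                                 "rate_ppm", "rate_sd")])
}

#' @export
glance.alu_expression <- function(x, ...) {
  tibble::tibble(
    total_tags = attr(x, "total_tags"),
    n_replicates = attr(x, "n_replicates"),
    n_categories = nrow(x),
    rate_tss = x$rate_ppm[x$category == "tss"][1],
    rate_alu = x$rate_ppm[x$category == "alu"][1],
    rate_random = x$rate_ppm[x$category == "random"][1]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
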