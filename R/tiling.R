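#' Associate probes with nearby element edges
#'
#' For every (probe, element-edge) pair within `max_dist`, records the
#' signed distance of the probe centre from the element's 5' or 3' edge,
#' oriented by element strand.  Sign convention: for the 5' edge, distance
#' 0 is the first base inside the element and negative distances are
#' outside (upstream); for the 3' edge, distance 0 is the first base
#' outside the element (downstream) and negative distances are inside.  A
#' probe can associate with both edges of a (short) element, or with
#' several elements; however an edge only claims probes on its own side —
#' a probe lying beyond the element's other edge is not given an
#' inside-direction distance larger than the element itself.
#'
#' @param probes A data frame with columns `chrom`, `center`, `value` and
#'   optionally `cell_type`.
#' @param elements Element table with `chrom`, `start`, `end`, `strand`.
#' @param max_dist Maximum absolute distance in bp (default 600).
#' @return A tibble with the probe columns plus `probe_id` (row in
#'   `probes`), `element_id`, `edge` (`"5p"`/`"3p"`) and `distance`.
#' @export
select_probes_near <- function(probes, elements, max_dist = 600L) {
  probes <- tibble::as_tibble(probes)
  probes$probe_id <- seq_len(nrow(probes))
  res <- vector("list", 2L)
  for (edge in c("5p", "3p")) {
    pieces <- lapply(intersect(unique(elements$chrom), unique(probes$chrom)),
                     function(chr) {
      el <- elements[elements$chrom == chr, , drop = FALSE]
      pr <- probes[probes$chrom == chr, , drop = FALSE]
      if (nrow(el) == 0L || nrow(pr) == 0L) return(NULL)
      epos <- edge_positions(el, edge)
      q <- IRanges::IRanges(start = pr$center + 1L, width = 1L)
      s <- IRanges::IRanges(start = epos - max_dist + 1L, width = 2L * max_dist + 1L)
      ov <- IRanges::findOverlaps(q, s)
      pi <- S4Vectors::queryHits(ov)
      ei <- S4Vectors::subjectHits(ov)
      d <- edge_distance(pr$center[pi], el[ei, , drop = FALSE], edge)
      len <- el$end[ei] - el$start[ei]
      valid <- if (edge == "5p") d <= len - 1L else d >= -len
      pi <- pi[valid]; ei <- ei[valid]; d <- d[valid]
      out <- pr[pi, , drop = FALSE]
      out$element_id <- which(elements$chrom == chr)[ei]
      out$edge <- edge
      out$distance <- d
      out
    })
    res[[if (edge == "5p") 1L else 2L]] <- dplyr::bind_rows(pieces)
  }
  out <- dplyr::bind_rows(res)
  out <- out[abs(out$distance) <= max_dist, , drop = FALSE]
  out
}

edge_positions <- function(elements, edge) {
  minus <- elements$strand == "-"
  if (edge == "5p") {
    ifelse(minus, elements$end, elements$start + 1L)  # 1-based base position
  } else {
    ifelse(minus, elements$start, elements$end)       # 1-based first base outside
  }
}

edge_distance <- function(center, elements, edge) {
  minus <- elements$strand == "-"
  if (edge == "5p") {
    # 0 = first base inside, negative = outside
    ifelse(minus, (elements$end - 1L) - center, center - elements$start)
  } else {
    # 0 = first base outside, negative = inside
    ifelse(minus, (elements$start - 1L) - center, center - elements$end)
  }
}

#' Average hybridisation values by edge distance
#'
#' Bins probe-edge associations by distance and averages the hybridisation
#' values per bin, per edge.  The full bin grid across the association
#' range is reported; empty bins carry `n_probes = 0` and `NA` means.
#'
#' @param assoc Association table from [select_probes_near()].
#' @param bin_width Bin width in bp (default 1, i.e. per-distance).
#' @param cell_filter Optional cell-type label(s) to restrict to.
#' @return A tibble with `edge`, `distance` (bin lower bound), `mean_value`
#'   and `n_probes`.
#' @export
average_by_distance <- function(assoc, bin_width = 1L, cell_filter = NULL) {
  if (!is.null(cell_filter)) {
    assoc <- assoc[assoc$cell_type %in% cell_filter, , drop = FALSE]
  }
  if (nrow(assoc) == 0L) stop("no probe associations to average", call. = FALSE)
  assoc$bin <- floor(assoc$distance / bin_width) * bin_width
  grid <- tidyr::expand_grid(
    edge = sort(unique(assoc$edge)),
    distance = seq(min(assoc$bin), max(assoc$bin), by = bin_width)
  )
  means <- assoc |>
    dplyr::group_by(.data$edge, distance = .data$bin) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_probes = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(grid, means, by = c("edge", "distance"))
  out$n_probes[is.na(out$n_probes)] <- 0L
  out
}

#' Shuffled-probe background for a distance profile
#'
#' Permutes the hybridisation values across all probes (positions fixed),
#' recomputes the distance profile, and repeats; the per-bin mean and
#' standard deviation across the shuffles form the null band against which
#' real enrichment or depletion is judged.
#'
#' @param assoc Association table from [select_probes_near()] (must carry
#'   `probe_id`).
#' @param n_shuffles Number of permutations (default 10).
#' @param seed Integer seed, or `NULL`.
#' @inheritParams average_by_distance
#' @return A tibble with `edge`, `distance`, `bg_mean`, `bg_sd`.
#' @export
shuffled_background <- function(assoc, n_shuffles = 10L, seed = NULL,
                                bin_width = 1L, cell_filter = NULL) {
  ids <- sort(unique(assoc$probe_id))
  if (length(ids) < 2L) stop("need at least 2 probes to shuffle", call. = FALSE)
  value_of <- vapply(ids, function(i) assoc$value[assoc$probe_id == i][1], 0)
  if (!is.null(seed)) set.seed(seed)
  profs <- lapply(seq_len(n_shuffles), function(s) {
    perm <- stats::setNames(sample(value_of), ids)
    sh <- assoc
    sh$value <- perm[as.character(sh$probe_id)]
    p <- average_by_distance(sh, bin_width, cell_filter)
    p$shuffle <- s
    p
  })
  dplyr::bind_rows(profs) |>
    dplyr::group_by(.data$edge, .data$distance) |>
    dplyr::summarise(
      bg_mean = mean(.data$mean_value, na.rm = TRUE),
      bg_sd = stats::sd(.data$mean_value, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Tiling-array distance profile with shuffled null
#'
#' One-call wrapper: associates probes with element edges, averages values
#' by binned distance, and attaches the shuffled background band.
#'
#' @inheritParams select_probes_near
#' @inheritParams average_by_distance
#' @inheritParams shuffled_background
#' @return An `alu_tiling_profile`: tibble with `edge`, `distance`,
#'   `mean_value`, `n_probes`, `bg_mean`, `bg_sd`; attributes `max_dist`,
#'   `bin_width`, `n_shuffles`.
#' @export
tiling_profile <- function(probes, elements, max_dist = 600L, bin_width = 1L,
                           n_shuffles = 10L, seed = NULL, cell_filter = NULL) {
  assoc <- select_probes_near(probes, elements, max_dist)
  prof <- average_by_distance(assoc, bin_width, cell_filter)
  bg <- shuffled_background(assoc, n_shuffles, seed, bin_width, cell_filter)
  out <- dplyr::left_join(prof, bg, by = c("edge", "distance"))
  structure(out, class = c("alu_tiling_profile", class(out)),
            max_dist = max_dist, bin_width = bin_width,
            n_shuffles = n_shuffles)
}
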