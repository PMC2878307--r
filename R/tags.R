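#' Load paired-end nucleosome tag pairs
#'
#' Reads mapper output into a tag-pair table.  Two formats are supported:
#' a plain pairs TSV with columns `chrom`, `fwd5`, `rev5`, `n_hits` and an
#' optional `hits` column (semicolon-separated `chrom:fwd5` alternative
#' locations, `.` if none), or SAM (properly paired records; requires the
#' Rsamtools package).  Pairs whose insert size `rev5 - fwd5 + 1` falls
#' outside `insert_range` are dropped; the count of dropped pairs is
#' attached as attribute `n_dropped`.
#'
#' @param path Input file.
#' @param format `"pairs"` or `"sam"`.
#' @param insert_range Inclusive insert-size bounds (default `c(122, 172)`,
#'   the mononucleosome window around the 147-bp core).
#' @return A tibble with columns `chrom`, `fwd5`, `rev5` (0-based 5' end
#'   positions of the plus- and minus-strand mates), `n_hits`, and `hits`
#'   (list column of tibbles with `chrom`, `fwd5` for every hit of
#'   multi-hit tags; empty for unique tags).
#' @export
load_tag_pairs <- function(path, format = c("pairs", "sam"),
                           insert_range = c(122L, 172L)) {
  format <- match.arg(format)
  if (format == "pairs") {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 3L) stop("pairs TSV needs >= 3 columns", call. = FALSE)
    tags <- tibble::tibble(
      chrom = raw[[1]],
      fwd5 = as.integer(raw[[2]]),
      rev5 = as.integer(raw[[3]]),
      n_hits = if (ncol(raw) >= 4L) as.integer(raw[[4]]) else 1L
    )
    hits_str <- if (ncol(raw) >= 5L) raw[[5]] else rep(".", nrow(raw))
    tags$hits <- parse_hits(hits_str)
  } else {
    tags <- read_sam_pairs(path)
  }
  insert <- tags$rev5 - tags$fwd5 + 1L
  keep <- !is.na(insert) & insert >= insert_range[1] & insert <= insert_range[2]
  out <- tags[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

parse_hits <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "." || s == "") {
      return(tibble::tibble(chrom = character(0), fwd5 = integer(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      chrom = vapply(parts, `[`, "", 1L),
      fwd5 = as.integer(vapply(parts, `[`, "", 2L))
    )
  })
}

format_hits <- function(hits) {
  vapply(hits, function(h) {
    if (is.null(h) || nrow(h) == 0L) return(".")
    paste(paste0(h$chrom, ":", h$fwd5), collapse = ";")
  }, "")
}

read_sam_pairs <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isMinusStrand = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "isize"),
    tag = "NH"
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$isize) & rec$isize > 0L
  nh <- rec$tag$NH
  if (is.null(nh)) nh <- rep(1L, length(rec$pos))
  nh[is.na(nh)] <- 1L
  n <- sum(keep)
  tibble::tibble(
    chrom = as.character(rec$rname)[keep],
    fwd5 = rec$pos[keep] - 1L,
    rev5 = rec$pos[keep] - 1L + rec$isize[keep] - 1L,
    n_hits = as.integer(nh[keep]),
    hits = rep(list(tibble::tibble(chrom = character(0), fwd5 = integer(0))), n)
  )
}

#' Write tag pairs to the pairs-TSV format
#'
#' @param tags Tag-pair tibble as from [load_tag_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_pairs <- function(tags, path) {
  hits <- if ("hits" %in% names(tags)) format_hits(tags$hits)
          else rep(".", nrow(tags))
  n_hits <- if ("n_hits" %in% names(tags)) tags$n_hits else 1L
  out <- data.frame(tags$chrom, tags$fwd5, tags$rev5, n_hits, hits)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Midpoint of a tag pair
#'
#' The midpoint of the two sequenced 5' ends is taken as the nucleosome
#' core centre; odd spans round down.
#'
#' @param fwd5,rev5 0-based 5' end positions of the plus- and minus-strand
#'   mates (vectors), or a data frame with those columns as `fwd5`.
#' @return Integer vector of midpoints.
#' @export
tag_midpoint <- function(fwd5, rev5 = NULL) {
  if (is.data.frame(fwd5)) {
    rev5 <- fwd5$rev5
    fwd5 <- fwd5$fwd5
  }
  (fwd5 + rev5) %/% 2L
}

# which points (chrom, pos) fall inside any feature interval (0-based half-open)
points_in_features <- function(chrom, pos, features) {
  out <- logical(length(chrom))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    f <- features[features$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0L) next
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    s <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Categorize tags by uniqueness and Alu overlap
#'
#' Reproduces the mapping summary: uniquely mapped tags are split by
#' whether their midpoint falls inside an Alu element; multi-hit tags are
#' split by the fraction of their hits overlapping Alu elements (complete
#' = all hits, partial = some, none = none).  A multi-hit tag's hit
#' positions are taken from its `hits` column (falling back to the primary
#' location when empty), judged by hit midpoint assuming the pair's insert
#' size.
#'
#' @param tags Tag-pair tibble.
#' @param elements Alu element table (from [alu_elements()] or any
#'   feature table with `chrom`, `start`, `end`).
#' @return A one-row tibble with columns `unique_alu`, `unique_other`,
#'   `multi_complete`, `multi_partial`, `multi_none`, `total`.
#' @export
categorize_tags <- function(tags, elements) {
  n_hits <- if ("n_hits" %in% names(tags)) tags$n_hits else rep(1L, nrow(tags))
  uniq <- n_hits <= 1L
  mids <- tag_midpoint(tags)
  in_alu <- points_in_features(tags$chrom, mids, elements)
  unique_alu <- sum(uniq & in_alu)
  unique_other <- sum(uniq & !in_alu)

  multi_idx <- which(!uniq)
  frac <- multihit_alu_fraction(tags[multi_idx, , drop = FALSE], elements)
  tibble::tibble(
    unique_alu = unique_alu,
    unique_other = unique_other,
    multi_complete = sum(frac == 1),
    multi_partial = sum(frac > 0 & frac < 1),
    multi_none = sum(frac == 0),
    total = nrow(tags)
  )
}

# per multi-hit tag: fraction of its hit midpoints inside Alu elements
multihit_alu_fraction <- function(tags, elements) {
  if (nrow(tags) == 0L) return(numeric(0))
  insert <- tags$rev5 - tags$fwd5 + 1L
  vapply(seq_len(nrow(tags)), function(i) {
    h <- tags$hits[[i]]
    if (is.null(h) || nrow(h) == 0L) {
      h <- tibble::tibble(chrom = tags$chrom[i], fwd5 = tags$fwd5[i])
    }
    mids <- (h$fwd5 + (h$fwd5 + insert[i] - 1L)) %/% 2L
    mean(points_in_features(h$chrom, mids, elements))
  }, 0)
}

#' Resolve multi-hit tags to single midpoints
#'
#' For each multi-hit tag whose hits are sufficiently Alu-associated, one
#' hit is chosen uniformly at random and converted to a midpoint, so that
#' multi-hit tags can be folded back into the nucleosome signal.  Also
#' reports, per tag, the standard deviation of the distances
#' (absolute, so that a hit in a reverse-oriented element copy matches)
#' between each hit's midpoint and the centre of its nearest Alu
#' element — small values mean the alternative hits all sit at the same
#' position relative to an Alu copy, i.e. resolving them cannot distort
#' the element-anchored profile.
#'
#' @param tags Tag-pair tibble (multi-hit rows carry `hits`).
#' @param elements Alu element table with `center` (see [alu_elements()]).
#' @param policy `"complete_only"`: use tags with all hits in Alu;
#'   `"ge85"`: tags with more than 85% of hits in Alu.
#' @param seed Integer seed for the random choice, or `NULL`.
#' @return A list with `midpoints` (tibble `chrom`, `pos`), `per_tag_sd`
#'   (numeric), and `mean_sd` (mean of `per_tag_sd`).
#' @export
multihit_augment <- function(tags, elements,
                             policy = c("complete_only", "ge85"),
                             seed = NULL) {
  policy <- match.arg(policy)
  n_hits <- if ("n_hits" %in% names(tags)) tags$n_hits else rep(1L, nrow(tags))
  multi <- tags[n_hits > 1L, , drop = FALSE]
  have_hits <- vapply(multi$hits, function(h) !is.null(h) && nrow(h) > 0L, NA)
  multi <- multi[have_hits, , drop = FALSE]
  frac <- multihit_alu_fraction(multi, elements)
  eligible <- if (policy == "complete_only") frac == 1 else frac > 0.85
  multi <- multi[eligible, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  if (nrow(multi) == 0L) {
    return(list(midpoints = tibble::tibble(chrom = character(0), pos = integer(0)),
                per_tag_sd = numeric(0), mean_sd = NA_real_))
  }
  insert <- multi$rev5 - multi$fwd5 + 1L
  centers_by_chrom <- split(elements$center, elements$chrom)
  centers_by_chrom <- lapply(centers_by_chrom, sort)

  pick <- vapply(multi$hits, function(h) sample.int(nrow(h), 1L), 0L)
  midpoints <- tibble::tibble(
    chrom = vapply(seq_along(pick), function(i) multi$hits[[i]]$chrom[pick[i]], ""),
    pos = vapply(seq_along(pick), function(i) {
      f <- multi$hits[[i]]$fwd5[pick[i]]
      (f + (f + insert[i] - 1L)) %/% 2L
    }, 0L)
  )
  per_tag_sd <- vapply(seq_len(nrow(multi)), function(i) {
    h <- multi$hits[[i]]
    mids <- (h$fwd5 + (h$fwd5 + insert[i] - 1L)) %/% 2L
    d <- vapply(seq_len(nrow(h)), function(j) {
      cs <- centers_by_chrom[[h$chrom[j]]]
      if (is.null(cs) || length(cs) == 0L) return(NA_real_)
      min(abs(cs - mids[j]))
    }, 0)
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(NA_real_)
    stats::sd(d)
  }, 0)
  list(midpoints = midpoints,
       per_tag_sd = per_tag_sd,
       mean_sd = mean(per_tag_sd, na.rm = TRUE))
}
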