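#' Length windows of the three Alu classes
#'
#' Dimeric Alu elements are retained at 280-320 bp, free left Alu monomers
#' (FLAM) at 110-150 bp, and free right Alu monomers (FRAM) at 150-190 bp;
#' annotated copies falling outside their class window are discarded as
#' incomplete.
#'
#' @return A tibble with columns `alu_class`, `min_len`, `max_len`
#'   (inclusive bounds in bp).
#' @export
alu_length_windows <- function() {
  tibble::tibble(
    alu_class = c("dimer", "FLAM", "FRAM"),
    min_len = c(280L, 110L, 150L),
    max_len = c(320L, 150L, 190L)
  )
}

#' Default repeat-name to Alu-class map
#'
#' Maps RepeatMasker `repName` values onto the three Alu classes by
#' pattern: names containing `FLAM` (or the historical `FAM`) are free left
#' monomers, names containing `FRAM` free right monomers, and any other
#' name starting with `Alu` is a dimeric Alu candidate.  Patterns are
#' regular expressions tried in order; the first match wins.
#'
#' @return A tibble with columns `pattern` and `alu_class`.
#' @seealso [read_name_map()] to load a custom map.
#' @export
default_name_map <- function() {
  tibble::tibble(
    pattern = c("FLAM", "^FAM$", "FRAM", "^Alu"),
    alu_class = c("FLAM", "FLAM", "FRAM", "dimer")
  )
}

#' Read a repeat-name map from a two-column TSV
#'
#' @param path Path to a tab-separated file with columns
#'   `pattern<TAB>class` (no header); `class` must be one of `dimer`,
#'   `FLAM`, `FRAM`.
#' @return A tibble with columns `pattern` and `alu_class`.
#' @export
read_name_map <- function(path) {
  map <- readr::read_tsv(path, col_names = c("pattern", "alu_class"),
                         col_types = "cc", progress = FALSE)
  bad <- setdiff(unique(map$alu_class), c("dimer", "FLAM", "FRAM"))
  if (length(bad) > 0L) {
    stop("unknown Alu class in name map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map
}

#' Read a repeat annotation table
#'
#' Reads either a UCSC RepeatMasker `rmsk` dump (tab-separated, with the
#' leading `bin` column; `genoStart` is already 0-based) or a plain BED6
#' file.  Coordinates are returned 0-based half-open in both cases.  Rows
#' with `start >= end` are rejected; their count is reported as a warning.
#'
#' @param path Path to the table.
#' @param dialect `"rmsk"` or `"bed6"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`.
#' @export
read_repeat_table <- function(path, dialect = c("rmsk", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "rmsk") {
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 11L) stop("rmsk table needs >= 11 columns", call. = FALSE)
    out <- tibble::tibble(
      chrom = raw[[6]],
      start = as.integer(raw[[7]]),
      end = as.integer(raw[[8]]),
      strand = raw[[10]],
      rep_name = raw[[11]]
    )
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 6L) stop("BED6 needs 6 columns", call. = FALSE)
    out <- tibble::tibble(
      chrom = raw[[1]],
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      strand = raw[[6]],
      rep_name = raw[[4]]
    )
  }
  # rmsk encodes unknown strand as "C" for complement; normalize
  out$strand <- ifelse(out$strand == "C", "-", out$strand)
  bad_strand <- !out$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sum(bad_strand), " row(s) with unknown strand set to '+'", call. = FALSE)
    out$strand[bad_strand] <- "+"
  }
  bad <- is.na(out$start) | is.na(out$end) | out$start >= out$end
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (start >= end or unparsable)", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Classify repeat features into Alu classes
#'
#' Adds an `alu_class` column (`dimer`, `FLAM`, `FRAM`, or `NA`) to a
#' repeat feature table.  A feature is assigned a class only when its
#' `rep_name` matches a pattern in `name_map` *and* its length lies inside
#' that class's length window (see [alu_length_windows()]); everything
#' else, including matching names of incomplete length, gets `NA`.
#'
#' @param features A data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `rep_name` (0-based half-open).
#' @param name_map Pattern-to-class map; see [default_name_map()].
#' @return The input as a tibble with an added `alu_class` column.
#' @export
classify_alu <- function(features, name_map = default_name_map()) {
  features <- tibble::as_tibble(features)
  cls <- rep(NA_character_, nrow(features))
  for (i in seq_len(nrow(name_map))) {
    hit <- is.na(cls) & grepl(name_map$pattern[i], features$rep_name)
    cls[hit] <- name_map$alu_class[i]
  }
  win <- alu_length_windows()
  len <- features$end - features$start
  for (i in seq_len(nrow(win))) {
    this <- !is.na(cls) & cls == win$alu_class[i]
    off <- this & (len < win$min_len[i] | len > win$max_len[i])
    cls[off] <- NA_character_
  }
  features$alu_class <- cls
  features
}

#' Filtered Alu element table
#'
#' Classifies repeat features and keeps only complete Alu elements,
#' attaching each element's centre position (`floor((start + end) / 2)`).
#'
#' @inheritParams classify_alu
#' @param classes Which classes to keep (default all three).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `alu_class`, `center`.
#' @export
alu_elements <- function(features, name_map = default_name_map(),
                         classes = c("dimer", "FLAM", "FRAM")) {
  out <- classify_alu(features, name_map)
  out <- out[!is.na(out$alu_class) & out$alu_class %in% classes, , drop = FALSE]
  out$center <- (out$start + out$end) %/% 2L
  out
}

#' Write intervals to BED6
#'
#' @param features A data frame with `chrom`, `start`, `end`, `strand` and
#'   either `rep_name` or `name` for the name field (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(features, path) {
  nm <- if ("rep_name" %in% names(features)) features$rep_name
        else if ("name" %in% names(features)) features$name
        else rep(".", nrow(features))
  bed <- tibble::tibble(
    chrom = features$chrom,
    start = features$start,
    end = features$end,
    name = nm,
    score = 0L,
    strand = features$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
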