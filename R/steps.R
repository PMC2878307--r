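#' Strand-symmetric nucleotide step classes
#'
#' A nucleotide *step* is a strand-symmetric mono- or dinucleotide category.
#' Because the two strands of double-stranded DNA are read in opposite
#' directions, a word and its reverse complement describe the same physical
#' step, so the 4 mononucleotides collapse into 2 classes (`A/T`, `G/C`) and
#' the 16 dinucleotides into 10 classes (6 complementary pairs such as
#' `AA/TT`, plus the 4 palindromic words `AT`, `CG`, `GC`, `TA`), 12 classes
#' in all.
#'
#' @param kind Which classes to return: `"all"` (default), `"mono"` or `"di"`.
#' @return A tibble with one row per step class and columns `label`,
#'   `kind` (`"mono"` or `"di"`) and `members` (list column of the 1 or 2
#'   words in the class).
#' @examples
#' step_classes()
#' step_classes("mono")
#' @export
step_classes <- function(kind = c("all", "mono", "di")) {
  kind <- match.arg(kind)
  mono <- list(c("A", "T"), c("G", "C"))
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  seen <- character(0)
  di <- list()
  for (w in dinucs) {
    rc <- revcomp_word(w)
    if (w %in% seen || rc %in% seen) next
    seen <- c(seen, w)
    di[[length(di) + 1L]] <- unique(c(w, rc))
  }
  out <- tibble::tibble(
    label = c(
      vapply(mono, paste, "", collapse = "/"),
      vapply(di, paste, "", collapse = "/")
    ),
    kind = rep(c("mono", "di"), c(length(mono), length(di))),
    members = c(mono, di)
  )
  if (kind != "all") out <- out[out$kind == kind, ]
  out
}

revcomp_word <- function(w) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
}

#' Look up a single step class by label
#'
#' Accepts either the full class label (`"AA/TT"`) or any member word
#' (`"TT"`, `"A"`).
#'
#' @param label Step-class label or member word.
#' @return A one-row tibble as returned by [step_classes()].
#' @export
step_class <- function(label) {
  sc <- step_classes()
  hit <- sc$label == label |
    vapply(sc$members, function(m) label %in% m, NA)
  if (!any(hit)) {
    stop("unknown step class: ", label, call. = FALSE)
  }
  sc[which(hit)[1L], ]
}

#' Encode a DNA sequence as a 0/1 step indicator
#'
#' Converts a fragment into the binary sequence used by the spectral
#' analysis: position `k` is 1 when the word starting at `k` belongs to the
#' target step class, 0 otherwise.  For a dinucleotide step of a fragment of
#' length `L` the indicator has length `L - 1` (one bit per overlapping
#' dinucleotide); mononucleotide indicators are truncated to the same
#' `L - 1` length so both kinds share a common transform length.
#'
#' @param sequence A single DNA string over `ACGT` (and `N` if
#'   `n_action = "zero"`).
#' @param step A step-class label, member word, or a one-row tibble from
#'   [step_class()].
#' @param n_action What to do with `N` positions: `"error"` (default;
#'   fragments are expected to be pre-filtered) or `"zero"`, which scores any
#'   word touching an `N` as 0 — used when sampling from a repeat-masked
#'   genome where masked stretches carry no step information.
#' @return Integer vector of 0/1 bits of length `nchar(sequence) - 1`.
#' @examples
#' encode_step("CTTGAAT", "AA/TT")  # 0 1 0 0 1 0
#' @export
encode_step <- function(sequence, step, n_action = c("error", "zero")) {
  n_action <- match.arg(n_action)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  if (is.character(step)) step <- step_class(step)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2L) stop("sequence too short to encode", call. = FALSE)
  if (any(chars == "N")) {
    if (n_action == "error") {
      stop("sequence contains N; fragments must be N-free", call. = FALSE)
    }
  }
  members <- step$members[[1]]
  if (step$kind == "di") {
    words <- paste0(chars[-L], chars[-1L])
    bits <- as.integer(words %in% members)
  } else {
    bits <- as.integer(chars %in% members)
    bits <- bits[-L]
  }
  bits
}
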