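#' Read a genome FASTA file
#'
#' Loads a multi-record FASTA into a `DNAStringSet`, uppercasing all
#' residues and mapping any character outside `ACGTN` (IUPAC ambiguity
#' codes, gaps) to `N`.  Record order follows the file.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record identifier (first
#'   whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA: ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  names(set) <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(set)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) stop("genome character vector must be named", call. = FALSE)
    return(Biostrings::DNAStringSet(x))
  }
  stop("cannot interpret object of class ", class(x)[1], " as a genome", call. = FALSE)
}

#' Mask genomic intervals with N
#'
#' Replaces every base covered by `features` with `N`, leaving all other
#' positions untouched.  Overlapping features are unioned first, so masking
#' is idempotent and independent of feature order.  Features extending past
#' a chromosome end are clipped with a warning; features on unknown
#' chromosomes are an error.
#'
#' @param genome A `DNAStringSet`.
#' @param features A data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @return A masked `DNAStringSet` with the same names and lengths.
#' @export
mask_regions <- function(genome, features) {
  genome <- as_genome(genome)
  stopifnot(all(c("chrom", "start", "end") %in% names(features)))
  if (nrow(features) == 0L) return(genome)
  unknown <- setdiff(unique(features$chrom), names(genome))
  if (length(unknown) > 0L) {
    stop("features on unknown chromosomes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_clipped <- 0L
  out <- genome
  for (chr in intersect(names(genome), unique(features$chrom))) {
    f <- features[features$chrom == chr, ]
    len <- length(genome[[chr]])
    over <- f$end > len | f$start < 0L
    if (any(over)) {
      n_clipped <- n_clipped + sum(over)
      f$start <- pmax(f$start, 0L)
      f$end <- pmin(f$end, len)
    }
    f <- f[f$start < f$end, , drop = FALSE]
    if (nrow(f) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(start = f$start + 1L, end = f$end))
    repl <- Biostrings::DNAStringSet(strrep("N", IRanges::width(ir)))
    out[[chr]] <- Biostrings::replaceAt(out[[chr]], ir, repl)
  }
  if (n_clipped > 0L) {
    warning(n_clipped, " feature(s) clipped to chromosome bounds", call. = FALSE)
  }
  out
}

#' Base composition of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named numeric vector of A, C, G, T frequencies among non-N
#'   bases (sums to 1).
#' @export
base_composition <- function(genome) {
  genome <- as_genome(genome)
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"), drop = FALSE])
  counts / sum(counts)
}
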