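#' Read a gene annotation table
#'
#' Reads either a UCSC `refGene.txt`-style dump (tab-separated with the
#' leading `bin` column; transcription start is `txStart` on plus-strand
#' genes and `txEnd - 1` on minus-strand genes, reported 0-based) or a
#' plain TSV with columns `chrom`, `tss`, `strand`.
#'
#' @param path Path to the table.
#' @param dialect `"refgene"` or `"tsv"`.
#' @return A tibble with columns `chrom`, `tss` (0-based), `strand`.
#' @export
read_gene_table <- function(path, dialect = c("refgene", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (dialect == "refgene") {
    if (ncol(raw) < 6L) stop("refGene table needs >= 6 columns", call. = FALSE)
    strand <- raw[[4]]
    tss <- ifelse(strand == "-", as.integer(raw[[6]]) - 1L, as.integer(raw[[5]]))
    out <- tibble::tibble(chrom = raw[[3]], tss = tss, strand = strand)
  } else {
    out <- tibble::tibble(chrom = raw[[1]], tss = as.integer(raw[[2]]),
                          strand = raw[[3]])
  }
  out
}

flank_windows <- function() {
  tibble::tibble(
    label = c("flank[-900,-601]", "flank[-600,-301]", "flank[-300,-1]",
              "flank[+1,+300]", "flank[+301,+600]", "flank[+601,+900]"),
    rel_from = c(-900L, -600L, -300L, 1L, 301L, 601L),
    rel_to = c(-601L, -301L, -1L, 300L, 600L, 900L)
  )
}

#' Build region categories for expression-rate analysis
#'
#' Constructs the interval sets whose 5'-tag rates are compared: Alu
#' element bodies; six 300-bp flank windows on both sides of each element
#' (coordinates relative to the element, -1 being the last base upstream
#' of the 5' end and +1 the first base downstream of the 3' end, oriented
#' by element strand); 301-bp windows (+/-150 bp inclusive) around gene
#' TSSs; and matched +/-150-bp windows around randomly selected N-free
#' sites, drawn independently `n_replicates` times so that a mean and
#' standard deviation can be reported for the random control.
#'
#' Regions extending past chromosome ends are clipped.
#'
#' @param elements Alu element table (`chrom`, `start`, `end`, `strand`).
#' @param genes Gene table (`chrom`, `tss`, `strand`).
#' @param genome A `DNAStringSet` (used for chromosome bounds and for
#'   N-free random-site selection), or a named length vector.
#' @param n_random Random sites per replicate (default: number of genes).
#' @param n_replicates Number of independent random-site sets (default 10).
#' @param seed Integer seed, or `NULL`.
#' @return A tibble of regions: `category`, `replicate` (`NA` except for
#'   random sites), `chrom`, `start`, `end` (0-based half-open).
#' @export
build_categories <- function(elements, genes, genome, n_random = nrow(genes),
                             n_replicates = 10L, seed = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    lens <- genome
    genome <- NULL
  }
  clip <- function(df) {
    df$start <- unname(pmax(df$start, 0L))
    df$end <- unname(pmin(df$end, unname(lens[df$chrom])))
    df[df$start < df$end, , drop = FALSE]
  }
  regions <- list()
  regions[["alu"]] <- tibble::tibble(
    category = "alu", replicate = NA_integer_,
    chrom = elements$chrom, start = elements$start, end = elements$end
  )
  fw <- flank_windows()
  minus <- elements$strand == "-"
  for (i in seq_len(nrow(fw))) {
    rf <- fw$rel_from[i]; rt <- fw$rel_to[i]
    if (rf < 0L) {
      # upstream of the 5' end: [-k, -1] maps to [start + rf, start + rt + 1)
      start <- ifelse(minus, elements$end - rt - 1L, elements$start + rf)
      end <- ifelse(minus, elements$end - rf, elements$start + rt + 1L)
    } else {
      # downstream of the 3' end: [+1, +k] maps to [end + rf - 1, end + rt)
      start <- ifelse(minus, elements$start - rt, elements$end + rf - 1L)
      end <- ifelse(minus, elements$start - rf + 1L, elements$end + rt)
    }
    regions[[fw$label[i]]] <- tibble::tibble(
      category = fw$label[i], replicate = NA_integer_,
      chrom = elements$chrom, start = start, end = end
    )
  }
  regions[["tss"]] <- tibble::tibble(
    category = "tss", replicate = NA_integer_,
    chrom = genes$chrom, start = genes$tss - 150L, end = genes$tss + 151L
  )
  if (n_random > 0L && n_replicates > 0L) {
    if (!is.null(seed)) set.seed(seed)
    if (!is.null(genome)) {
      starts <- eligible_starts(genome, 301L)
    } else {
      starts <- lapply(stats::setNames(names(lens), names(lens)),
                       function(chr) 0:(lens[[chr]] - 301L))
    }
    n_per <- vapply(starts, length, 0L)
    for (r in seq_len(n_replicates)) {
      chroms <- sample(names(starts), n_random, replace = TRUE,
                       prob = n_per / sum(n_per))
      st <- vapply(chroms, function(chr) sample(starts[[chr]], 1L), 0L)
      regions[[paste0("random_", r)]] <- tibble::tibble(
        category = "random", replicate = r,
        chrom = chroms, start = st, end = st + 301L
      )
    }
  }
  dplyr::bind_rows(lapply(regions, clip))
}

#' Count 5'-end tags falling in a region set
#'
#' A tag is counted once if its 5' position lies in any region of the set
#' (half-open intervals; overlapping regions do not double count).
#'
#' @param tags A data frame with columns `chrom`, `pos` (0-based 5' end)
#'   and optionally `strand`.
#' @param regions A data frame of intervals (`chrom`, `start`, `end`).
#' @return Integer tag count.
#' @export
count_tags <- function(tags, regions) {
  if (nrow(regions) == 0L || nrow(tags) == 0L) return(0L)
  sum(points_in_features(tags$chrom, tags$pos, regions))
}

#' Per-region expression rate in p.p.m.
#'
#' `rate = (tag_count / total_tags) * 1e6 / n_regions`: tags per million
#' mapped, averaged per region of the category.
#'
#' @param tag_count Tags counted in the category.
#' @param n_regions Number of regions in the category.
#' @param total_tags Total mapped tags in the library.
#' @return Rate in p.p.m. per region.
#' @export
ppm_rate <- function(tag_count, n_regions, total_tags) {
  if (n_regions <= 0L) stop("`n_regions` must be positive", call. = FALSE)
  if (total_tags <= 0L) stop("`total_tags` must be positive", call. = FALSE)
  (tag_count / total_tags) * 1e6 / n_regions
}

#' Average 5'-tag expression rates by region category
#'
#' Computes the p.p.m. expression rate for Alu bodies, the six Alu flank
#' windows, TSS windows, and random-site controls.  The random category is
#' summarised over its replicates (mean rate, with the across-replicate
#' standard deviation in `rate_sd`).
#'
#' @param tags 5'-tag table (`chrom`, `pos`, optionally `strand`).
#' @param elements Alu element table.
#' @param genes Gene table (`chrom`, `tss`, `strand`).
#' @param genome `DNAStringSet` or named chromosome lengths.
#' @param n_replicates Random-site replicates (default 10).
#' @param seed Integer seed, or `NULL`.
#' @param stranded If `TRUE`, only tags on the gene's strand are counted
#'   in TSS windows (default `FALSE`: all tags count everywhere).
#' @return An `alu_expression`: tibble with `category`, `n_regions`,
#'   `tag_count`, `rate_ppm`, `rate_sd` (`NA` except for random).
#' @export
expression_rates <- function(tags, elements, genes, genome,
                             n_replicates = 10L, seed = NULL,
                             stranded = FALSE) {
  total <- nrow(tags)
  regions <- build_categories(elements, genes, genome,
                              n_replicates = n_replicates, seed = seed)
  fixed <- regions[regions$category != "random", , drop = FALSE]
  rows <- lapply(split(fixed, fixed$category), function(rg) {
    tg <- tags
    if (stranded && rg$category[1] == "tss") {
      # match tag strand to the TSS strand via per-strand region sets
      plus <- rg[genes$strand == "+", , drop = FALSE]
      minus <- rg[genes$strand == "-", , drop = FALSE]
      cnt <- count_tags(tags[tags$strand == "+", , drop = FALSE], plus) +
        count_tags(tags[tags$strand == "-", , drop = FALSE], minus)
    } else {
      cnt <- count_tags(tg, rg)
    }
    tibble::tibble(category = rg$category[1], n_regions = nrow(rg),
                   tag_count = cnt,
                   rate_ppm = ppm_rate(cnt, nrow(rg), total),
                   rate_sd = NA_real_)
  })
  rnd <- regions[regions$category == "random", , drop = FALSE]
  if (nrow(rnd) > 0L) {
    rates <- vapply(split(rnd, rnd$replicate), function(rg) {
      ppm_rate(count_tags(tags, rg), nrow(rg), total)
    }, 0)
    counts <- vapply(split(rnd, rnd$replicate), function(rg) {
      count_tags(tags, rg)
    }, 0L)
    rows[["random"]] <- tibble::tibble(
      category = "random", n_regions = nrow(rnd) / length(rates),
      tag_count = as.integer(round(mean(counts))),
      rate_ppm = mean(rates), rate_sd = stats::sd(rates)
    )
  }
  order_lv <- c("alu", flank_windows()$label, "tss", "random")
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$category, order_lv)), , drop = FALSE]
  structure(out, class = c("alu_expression", class(out)),
            total_tags = total, n_replicates = n_replicates)
}

#' Read a 5'-tag table
#'
#' BED6 (`pos` = `start` for plus-strand tags, `end - 1` for minus) or a
#' plain TSV with columns `chrom`, `pos`, `strand`.
#'
#' @param path Input path.
#' @param format `"bed6"` or `"tsv"`.
#' @return A tibble with `chrom`, `pos` (0-based 5' end), `strand`.
#' @export
read_tss_tags <- function(path, format = c("bed6", "tsv")) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (format == "bed6") {
    strand <- raw[[6]]
    pos <- ifelse(strand == "-", as.integer(raw[[3]]) - 1L, as.integer(raw[[2]]))
    tibble::tibble(chrom = raw[[1]], pos = pos, strand = strand)
  } else {
    tibble::tibble(chrom = raw[[1]], pos = as.integer(raw[[2]]), strand = raw[[3]])
  }
}
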