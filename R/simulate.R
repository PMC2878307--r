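#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults emulate the
#' structure of a primate genome segment: an i.i.d. background at
#' human-like base composition, seeded with Alu-like elements — dimers of
#' two GC-rich monomers flanking an A-rich linker and ending in a poly(A)
#' tract, plus free left (FLAM-like) and free right (FRAM-like) monomers —
#' at about 7% sequence coverage; nucleosome centres with one strong slot
#' per monomer (the right arm of a dimer disfavoured), depletion over the
#' A-rich linker and tail, and phased flanking nucleosomes at the
#' nucleosome repeat length; paired-end 36-bp-read tag pairs with inserts
#' in 122-172 bp; a regular tiling-probe grid with enrichment just outside
#' and depletion just inside element edges; and Poisson 5' tags
#' concentrated at TSSs, depressed in Alu bodies and flanks.
#'
#' @param genome_len Genome length in bp (default 1e6, one chromosome).
#' @param chrom Chromosome name.
#' @param base_composition Background A, C, G, T frequencies.
#' @param alu_coverage Target fraction of the genome inside planted
#'   elements (default 0.07).
#' @param class_weights Sampling weights of the dimer/FLAM/FRAM classes.
#' @param dimer_template Lengths (bp) of the dimer parts:
#'   `left_monomer`, `a_linker`, `right_monomer`, `polyA`.
#' @param monomer_homology Fraction of the left-monomer sequence shared by
#'   the right monomer (default 0.8).
#' @param monomer_gc GC fraction of monomer sequence (default 0.6).
#' @param linker_a A frequency inside the A-rich linker (default 0.85).
#' @param mutation_rate Per-base substitution rate applied independently
#'   to each planted copy (default 0.05).
#' @param slot_offsets Nucleosome slot centres within a dimer, bp from the
#'   element 5' end (defaults 66 and 230: the monomer centres).
#' @param slot_weights Relative occupancy of the left and right dimer
#'   slots (defaults 1 and 0.4).
#' @param slot_sd Gaussian spread of in-slot centres (bp).
#' @param phasing_period Spacing of phased flanking nucleosomes (bp,
#'   default 185, inside the 170-200 nucleosome-repeat range).
#' @param phasing_decay Per-nucleosome attenuation of the phased flanking
#'   weights (default 0.7).
#' @param n_phased Phased nucleosomes simulated on each side (default 4).
#' @param phase_weight Weight of the first flanking nucleosome relative to
#'   a full slot (default 0.8).
#' @param flank_sd Gaussian spread of phased flanking centres (bp).
#' @param bg_tag_fraction Fraction of nucleosome tags placed uniformly.
#' @param n_tags Number of simulated tag pairs.
#' @param tag_insert_range Inclusive insert-size range of emitted pairs.
#' @param multihit_fraction Fraction of element-slot tags flagged
#'   multi-hit (default 0.1).
#' @param multihit_copies Extra homologous hits per multi-hit tag.
#' @param probe_spacing Tiling-probe grid spacing (bp, default 50).
#' @param probe_baseline,probe_noise_sd Probe value baseline and Gaussian
#'   noise SD.
#' @param probe_delta Planted hybridisation effect: `+probe_delta` within
#'   `enrich_band` bp outside element edges, `-probe_delta` within
#'   `deplete_band` bp inside.
#' @param enrich_band,deplete_band Band widths in bp (defaults 150 / 100).
#' @param cell_types Probe cell-type labels.
#' @param n_genes Number of simulated genes.
#' @param lambda_tss,lambda_bg,lambda_flank,lambda_alu Per-bp Poisson 5'
#'   tag intensities at TSS windows, background, Alu flanks (within 900
#'   bp) and Alu bodies.  Defaults keep the ordering
#'   `lambda_tss >> lambda_bg > lambda_flank > lambda_alu`.
#' @param seed Integer seed driving all generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_len = 1e6,
                       chrom = "chrS1",
                       base_composition = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295),
                       alu_coverage = 0.07,
                       class_weights = c(dimer = 0.92, FLAM = 0.06, FRAM = 0.02),
                       dimer_template = c(left_monomer = 132L, a_linker = 20L,
                                          right_monomer = 150L, polyA = 15L),
                       monomer_homology = 0.8,
                       monomer_gc = 0.6,
                       linker_a = 0.85,
                       mutation_rate = 0.05,
                       slot_offsets = c(left = 66L, right = 230L),
                       slot_weights = c(left = 1, right = 0.4),
                       slot_sd = 10,
                       phasing_period = 185L,
                       phasing_decay = 0.7,
                       n_phased = 4L,
                       phase_weight = 0.8,
                       flank_sd = 15,
                       bg_tag_fraction = 0.10,
                       n_tags = 200000L,
                       tag_insert_range = c(122L, 172L),
                       multihit_fraction = 0.1,
                       multihit_copies = 4L,
                       probe_spacing = 50L,
                       probe_baseline = 0,
                       probe_noise_sd = 0.05,
                       probe_delta = 0.5,
                       enrich_band = 150L,
                       deplete_band = 100L,
                       cell_types = c("cellA", "cellB"),
                       n_genes = 80L,
                       lambda_tss = 0.05,
                       lambda_bg = 0.002,
                       lambda_flank = 5e-4,
                       lambda_alu = 1e-4,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$alu_coverage < 0.5,
            all(cfg$slot_weights >= 0),
            cfg$phasing_period >= 140, cfg$phasing_period <= 260,
            abs(sum(cfg$base_composition) - 1) < 1e-6)
  structure(cfg, class = "sim_config")
}

rand_bases <- function(n, comp) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = comp)
}

mutate_seq <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
  }
  chars
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

# fixed per-run template sequences for the three element classes
make_templates <- function(config) {
  tl <- config$dimer_template
  gc <- config$monomer_gc
  mono_comp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  left <- rand_bases(tl[["left_monomer"]], mono_comp)
  right <- rand_bases(tl[["right_monomer"]], mono_comp)
  n_shared <- round(config$monomer_homology * min(length(left), length(right)))
  if (n_shared > 0L) right[seq_len(n_shared)] <- left[seq_len(n_shared)]
  la <- config$linker_a
  linker <- rand_bases(tl[["a_linker"]],
                       c(A = la, C = (1 - la) / 3, G = (1 - la) / 3, T = (1 - la) / 3))
  polyA <- rep("A", tl[["polyA"]])
  dimer <- c(left, linker, right, polyA)
  list(
    dimer = dimer,
    FLAM = c(left, polyA),
    FRAM = c(right, polyA),
    # part boundaries of the dimer (0-based offsets, half-open)
    dimer_parts = tibble::tibble(
      part = c("left_monomer", "a_linker", "right_monomer", "polyA"),
      start = cumsum(c(0L, tl[["left_monomer"]], tl[["a_linker"]],
                       tl[["right_monomer"]])),
      end = cumsum(unname(tl))
    )
  )
}

#' Simulate a genome with planted Alu-like elements
#'
#' Generates an i.i.d. background genome and inserts mutated copies of
#' fixed per-run dimer/FLAM/FRAM template sequences at non-overlapping
#' uniform positions (random strand; minus-strand copies are
#' reverse-complemented) until the target coverage is reached.  Element
#' names are `AluSim`, `FLAMSim`, `FRAMSim`, so the default
#' [default_name_map()] classifies them.
#'
#' @param config A [sim_config()].
#' @return An `alu_sim` list with `genome` (`DNAStringSet`), `elements`
#'   (feature tibble with `rep_name`), and `truth` (config, templates,
#'   per-instance table).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- as.integer(config$genome_len)
  bg <- rand_bases(L, config$base_composition)
  templates <- make_templates(config)
  class_len <- vapply(templates[c("dimer", "FLAM", "FRAM")], length, 0L)
  rep_names <- c(dimer = "AluSim", FLAM = "FLAMSim", FRAM = "FRAMSim")

  target_bp <- config$alu_coverage * L
  placed <- tibble::tibble(start = integer(0), end = integer(0),
                           alu_class = character(0), strand = character(0))
  occupied <- IRanges::IRanges()
  total_bp <- 0
  attempts <- 0L
  max_attempts <- 50L * ceiling(target_bp / min(class_len))
  while (total_bp < target_bp && attempts < max_attempts) {
    attempts <- attempts + 1L
    cls <- sample(names(config$class_weights), 1L, prob = config$class_weights)
    len <- class_len[[cls]]
    s <- sample.int(L - len + 1L, 1L) - 1L
    cand <- IRanges::IRanges(start = s + 1L, width = len)
    if (length(IRanges::findOverlaps(cand, occupied)) > 0L) next
    occupied <- c(occupied, cand)
    placed <- dplyr::bind_rows(placed, tibble::tibble(
      start = s, end = s + len, alu_class = cls,
      strand = sample(c("+", "-"), 1L)
    ))
    total_bp <- total_bp + len
  }
  if (total_bp < 0.9 * target_bp) {
    stop("could not reach target Alu coverage; genome too crowded", call. = FALSE)
  }
  placed <- placed[order(placed$start), , drop = FALSE]
  for (i in seq_len(nrow(placed))) {
    inst <- mutate_seq(templates[[placed$alu_class[i]]], config$mutation_rate)
    if (placed$strand[i] == "-") inst <- revcomp_chars(inst)
    bg[(placed$start[i] + 1L):placed$end[i]] <- inst
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(paste(bg, collapse = ""),
                                                     config$chrom))
  elements <- tibble::tibble(
    chrom = config$chrom,
    start = placed$start, end = placed$end,
    strand = placed$strand,
    rep_name = unname(rep_names[placed$alu_class]),
    alu_class = placed$alu_class,
    center = (placed$start + placed$end) %/% 2L
  )
  structure(list(
    genome = genome,
    elements = elements,
    truth = list(config = config, templates = templates,
                 coverage = total_bp / L)
  ), class = "alu_sim")
}

#' @export
print.alu_sim <- function(x, ...) {
  cat("<alu_sim> genome of ", sum(Biostrings::width(x$genome)), " bp, ",
      nrow(x$elements), " planted elements (",
      sprintf("%.2f%%", 100 * x$truth$coverage), " coverage)\n", sep = "")
  invisible(x)
}

# strand-aware genomic position of an offset within an element
element_offset_pos <- function(elements, offset) {
  ifelse(elements$strand == "-",
         elements$end - 1L - offset,
         elements$start + offset)
}

# per-element nucleosome-centre mixture components
center_components <- function(sim) {
  cfg <- sim$truth$config
  el <- sim$elements
  comp <- list()
  slot_tbl <- tibble::tibble(
    alu_class = c("dimer", "dimer", "FLAM", "FRAM"),
    slot = c("left", "right", "left", "right"),
    offset = c(cfg$slot_offsets[["left"]], cfg$slot_offsets[["right"]],
               cfg$dimer_template[["left_monomer"]] %/% 2L,
               cfg$dimer_template[["right_monomer"]] %/% 2L),
    weight = c(cfg$slot_weights[["left"]], cfg$slot_weights[["right"]], 1, 1)
  )
  for (i in seq_len(nrow(slot_tbl))) {
    sel <- el$alu_class == slot_tbl$alu_class[i]
    if (!any(sel)) next
    comp[[length(comp) + 1L]] <- tibble::tibble(
      chrom = el$chrom[sel],
      element_id = which(sel),
      mean = element_offset_pos(el[sel, ], slot_tbl$offset[i]),
      sd = cfg$slot_sd,
      weight = slot_tbl$weight[i],
      kind = "slot"
    )
  }
  for (k in seq_len(cfg$n_phased)) {
    w <- cfg$phase_weight * cfg$phasing_decay^k
    d <- round((k - 0.5) * cfg$phasing_period)
    comp[[length(comp) + 1L]] <- tibble::tibble(
      chrom = el$chrom, element_id = seq_len(nrow(el)),
      mean = el$start - d, sd = cfg$flank_sd, weight = w, kind = "phased"
    )
    comp[[length(comp) + 1L]] <- tibble::tibble(
      chrom = el$chrom, element_id = seq_len(nrow(el)),
      mean = el$end - 1L + d, sd = cfg$flank_sd, weight = w, kind = "phased"
    )
  }
  dplyr::bind_rows(comp)
}

# A-rich intervals (linker + polyA) of all planted elements, genomic coords
a_rich_intervals <- function(sim) {
  cfg <- sim$truth$config
  el <- sim$elements
  parts <- sim$truth$templates$dimer_parts
  out <- list()
  grab <- function(el_sel, off_start, off_end) {
    if (!any(el_sel)) return(NULL)
    e <- el[el_sel, , drop = FALSE]
    a <- element_offset_pos(e, off_start)
    b <- element_offset_pos(e, off_end - 1L)
    tibble::tibble(chrom = e$chrom, start = pmin(a, b), end = pmax(a, b) + 1L)
  }
  linker <- parts[parts$part == "a_linker", ]
  polyA_d <- parts[parts$part == "polyA", ]
  out$dimer_linker <- grab(el$alu_class == "dimer", linker$start, linker$end)
  out$dimer_polyA <- grab(el$alu_class == "dimer", polyA_d$start, polyA_d$end)
  flam_len <- cfg$dimer_template[["left_monomer"]]
  fram_len <- cfg$dimer_template[["right_monomer"]]
  pa <- cfg$dimer_template[["polyA"]]
  out$flam_polyA <- grab(el$alu_class == "FLAM", flam_len, flam_len + pa)
  out$fram_polyA <- grab(el$alu_class == "FRAM", fram_len, fram_len + pa)
  dplyr::bind_rows(out)
}

#' Simulate paired-end nucleosome tag pairs
#'
#' Draws nucleosome centres from the planted mixture — in-element slots
#' (Gaussian around each monomer slot, weighted by slot occupancy), phased
#' flanking nucleosomes at multiples of the repeat length on both sides of
#' every element with geometric decay, and a uniform background — with
#' zero density over the A-rich linker and poly(A) tract (centres landing
#' there are redrawn).  Each centre emits one pair with insert size
#' uniform in `tag_insert_range`, midpoint at the centre.  A fraction of
#' in-slot tags is flagged multi-hit, with alternative hits placed at the
#' homologous (strand-aware) offset of other copies of the same class.
#'
#' @param sim An `alu_sim` from [simulate_genome()].
#' @param n_tags Number of pairs (default from the config).
#' @param seed Seed (default `config$seed + 1`).
#' @return A tag-pair tibble (`chrom`, `fwd5`, `rev5`, `n_hits`, `hits`),
#'   as accepted by the profiling functions.
#' @export
simulate_nucleosome_tags <- function(sim, n_tags = NULL, seed = NULL) {
  cfg <- sim$truth$config
  if (is.null(n_tags)) n_tags <- cfg$n_tags
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  L <- sum(Biostrings::width(sim$genome))
  chrom <- names(sim$genome)[1]
  comp <- center_components(sim)
  avoid <- a_rich_intervals(sim)
  avoid_ir <- IRanges::IRanges(start = avoid$start + 1L, end = avoid$end)

  n_bg <- stats::rbinom(1L, n_tags, cfg$bg_tag_fraction)
  n_mix <- n_tags - n_bg
  pick <- sample.int(nrow(comp), n_mix, replace = TRUE, prob = comp$weight)
  centers <- round(stats::rnorm(n_mix, comp$mean[pick], comp$sd[pick]))
  # redraw centres that fall into A-rich intervals (nucleosome-free)
  for (it in 1:10) {
    bad <- IRanges::overlapsAny(IRanges::IRanges(start = centers + 1L, width = 1L),
                                avoid_ir)
    if (!any(bad)) break
    centers[bad] <- round(stats::rnorm(sum(bad), comp$mean[pick[bad]],
                                       comp$sd[pick[bad]]))
  }
  kind <- comp$kind[pick]
  elem <- comp$element_id[pick]
  bg_centers <- sample.int(L - 200L, n_bg) + 99L
  centers <- c(centers, bg_centers)
  kind <- c(kind, rep("bg", n_bg))
  elem <- c(elem, rep(NA_integer_, n_bg))
  ok <- centers >= 100L & centers < L - 100L
  centers <- centers[ok]; kind <- kind[ok]; elem <- elem[ok]

  insert <- sample(seq(cfg$tag_insert_range[1], cfg$tag_insert_range[2]),
                   length(centers), replace = TRUE)
  fwd5 <- centers - (insert - 1L) %/% 2L
  rev5 <- fwd5 + insert - 1L

  n <- length(centers)
  n_hits <- rep(1L, n)
  hits <- rep(list(tibble::tibble(chrom = character(0), fwd5 = integer(0))), n)
  el <- sim$elements
  slot_idx <- which(kind == "slot" & stats::runif(n) < cfg$multihit_fraction)
  for (i in slot_idx) {
    e <- elem[i]
    offset <- if (el$strand[e] == "-") el$end[e] - 1L - centers[i]
              else centers[i] - el$start[e]
    same <- setdiff(which(el$alu_class == el$alu_class[e]), e)
    if (length(same) == 0L) next
    others <- same[sample.int(length(same),
                              min(cfg$multihit_copies, length(same)))]
    h_centers <- element_offset_pos(el[others, , drop = FALSE], offset)
    h_fwd5 <- c(fwd5[i], h_centers - (insert[i] - 1L) %/% 2L)
    hits[[i]] <- tibble::tibble(chrom = chrom, fwd5 = as.integer(h_fwd5))
    n_hits[i] <- length(h_fwd5)
  }
  tibble::tibble(chrom = chrom, fwd5 = as.integer(fwd5),
                 rev5 = as.integer(rev5), n_hits = n_hits, hits = hits)
}

#' Simulate tiling-array probes
#'
#' Places probes on a regular grid and assigns each a hybridisation value
#' `baseline + planted band effects + Gaussian noise`, with
#' `+probe_delta` for probes within `enrich_band` bp outside an element
#' edge and `-probe_delta` within `deplete_band` bp inside (the same
#' edge-distance convention as [select_probes_near()]), for each
#' configured cell type.
#'
#' @param sim An `alu_sim`.
#' @param seed Seed (default `config$seed + 2`).
#' @return A probe tibble (`chrom`, `center`, `value`, `cell_type`).
#' @export
simulate_probes <- function(sim, seed = NULL) {
  cfg <- sim$truth$config
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  L <- sum(Biostrings::width(sim$genome))
  chrom <- names(sim$genome)[1]
  centers <- seq(cfg$probe_spacing %/% 2L, L - 1L, by = cfg$probe_spacing)
  el <- sim$elements
  effect <- numeric(length(centers))
  for (i in seq_len(nrow(el))) {
    d5 <- if (el$strand[i] == "-") (el$end[i] - 1L) - centers
          else centers - el$start[i]
    d3 <- if (el$strand[i] == "-") (el$start[i] - 1L) - centers
          else centers - el$end[i]
    enrich <- (d5 >= -cfg$enrich_band & d5 <= -1L) |
      (d3 >= 0L & d3 <= cfg$enrich_band - 1L)
    deplete <- (d5 >= 0L & d5 <= cfg$deplete_band - 1L) |
      (d3 >= -cfg$deplete_band & d3 <= -1L)
    effect[enrich] <- effect[enrich] + cfg$probe_delta
    effect[deplete] <- effect[deplete] - cfg$probe_delta
  }
  out <- lapply(cfg$cell_types, function(ct) {
    tibble::tibble(
      chrom = chrom, center = centers,
      value = cfg$probe_baseline + effect +
        stats::rnorm(length(centers), 0, cfg$probe_noise_sd),
      cell_type = ct
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate gene TSS annotations
#'
#' Picks TSS positions uniformly outside planted elements and their 1-kb
#' surroundings (so promoter tags do not bleed into Alu flank windows),
#' with random strand.
#'
#' @param sim An `alu_sim`.
#' @param n_genes Number of genes (default from the config).
#' @param seed Seed (default `config$seed + 3`).
#' @return A gene tibble (`chrom`, `tss`, `strand`).
#' @export
simulate_genes <- function(sim, n_genes = NULL, seed = NULL) {
  cfg <- sim$truth$config
  if (is.null(n_genes)) n_genes <- cfg$n_genes
  if (is.null(seed)) seed <- cfg$seed + 3L
  set.seed(seed)
  L <- sum(Biostrings::width(sim$genome))
  chrom <- names(sim$genome)[1]
  el <- sim$elements
  forbidden <- IRanges::reduce(IRanges::IRanges(
    start = pmax(el$start - 1000L, 0L) + 1L,
    end = pmin(el$end + 1000L, L)
  ))
  tss <- integer(0)
  while (length(tss) < n_genes) {
    cand <- sample.int(L - 400L, 2L * n_genes) + 199L
    ok <- !IRanges::overlapsAny(IRanges::IRanges(start = cand + 1L, width = 1L),
                                forbidden)
    tss <- c(tss, cand[ok])
  }
  tss <- tss[seq_len(n_genes)]
  tibble::tibble(chrom = chrom, tss = tss,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE))
}

#' Simulate 5'-end cDNA tags
#'
#' Emits Poisson tag counts per genomic position at planted intensities:
#' `lambda_tss` within TSS +/-150 windows, `lambda_alu` in element bodies,
#' `lambda_flank` within 900 bp of element edges, `lambda_bg` elsewhere.
#'
#' @param sim An `alu_sim`.
#' @param genes Gene tibble from [simulate_genes()].
#' @param seed Seed (default `config$seed + 4`).
#' @return A tag tibble (`chrom`, `pos`, `strand`).
#' @export
simulate_tss_tags <- function(sim, genes, seed = NULL) {
  cfg <- sim$truth$config
  if (is.null(seed)) seed <- cfg$seed + 4L
  set.seed(seed)
  L <- sum(Biostrings::width(sim$genome))
  chrom <- names(sim$genome)[1]
  rate <- rep(cfg$lambda_bg, L)
  el <- sim$elements
  set_rate <- function(rate, start, end, value) {
    for (i in seq_along(start)) {
      a <- max(start[i], 0L) + 1L
      b <- min(end[i], L)
      if (a <= b) rate[a:b] <- value
    }
    rate
  }
  rate <- set_rate(rate, el$start - 900L, el$end + 900L, cfg$lambda_flank)
  rate <- set_rate(rate, el$start, el$end, cfg$lambda_alu)
  rate <- set_rate(rate, genes$tss - 150L, genes$tss + 151L, cfg$lambda_tss)
  counts <- stats::rpois(L, rate)
  pos <- rep.int(seq_len(L) - 1L, counts)
  if (length(pos) == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          strand = character(0)))
  }
  tibble::tibble(chrom = chrom, pos = pos,
                 strand = sample(c("+", "-"), length(pos), replace = TRUE))
}
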