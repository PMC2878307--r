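#' Default pipeline configuration
#'
#' Parameters for [run_alu_pipeline()]: a `sim` block passed to
#' [sim_config()], plus per-stage analysis blocks.  Unknown fields are an
#' error, so typos in YAML configs are caught at validation.
#'
#' @param seed Global seed; each stage derives its own seed as
#'   `seed + 100 * stage_index` (stages in the order simulate, spectrum,
#'   profile, tiling, expression), so any stage can be reproduced alone.
#' @return A nested list of defaults.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    sim = list(),
    spectrum = list(step = "AA/TT", n_frag = 200L, frag_len = 8193L,
                    modes = c("raw", "masked", "random")),
    profile = list(flank = 1000L, window_w = 21L, classes = c("dimer", "FLAM", "FRAM"),
                   background_fragments = NULL, multihit = "none"),
    tiling = list(max_dist = 600L, bin_width = 50L, n_shuffles = 10L),
    expression = list(n_replicates = 10L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (!nm %in% names(base)) stop("unknown config field: ", nm, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) {
        if (nm != "sim" && !k %in% names(base[[nm]])) {
          stop("unknown config field: ", nm, "$", k, call. = FALSE)
        }
        base[[nm]][[k]] <- user[[nm]][[k]]
      }
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate a genome with planted
#' elements, tags, probes and 5' tags; compute the periodicity spectrum in
#' raw / masked / random modes; build the nucleosome signal and
#' element-anchored metaprofiles per Alu class with a matched background;
#' compute the tiling distance profile with shuffled null; and compute
#' expression rates.  Every stage's result is written as TSV (plus FASTA /
#' BED for the simulated inputs) into `outdir`, together with a
#' `manifest.json` recording the full parameter set, its hash, derived
#' per-stage seeds and output checksums — enough to reproduce the run
#' byte-for-byte.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file of overrides.
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_alu_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- function(i) as.integer(cfg$seed + 100L * i)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    paths[[name]] <<- p
    p
  }

  # stage 1: simulate
  sim_args <- cfg$sim
  sim_args$seed <- stage_seed(1L)
  sim <- simulate_genome(do.call(sim_config, sim_args))
  write_genome_fasta(sim$genome, emit("genome.fa"))
  write_bed6(sim$elements, emit("elements.bed"))
  tags <- simulate_nucleosome_tags(sim)
  write_tag_pairs(tags, emit("tags.tsv"))
  probes <- simulate_probes(sim)
  readr::write_tsv(probes, emit("probes.tsv"), progress = FALSE)
  genes <- simulate_genes(sim)
  readr::write_tsv(genes, emit("genes.tsv"), progress = FALSE)
  tss_tags <- simulate_tss_tags(sim, genes)
  readr::write_tsv(tss_tags, emit("tss_tags.tsv"), progress = FALSE)

  # stage 2: spectra
  for (mode in cfg$spectrum$modes) {
    sp <- genome_spectrum(sim$genome, cfg$spectrum$step, mode = mode,
                          mask = if (mode == "masked") sim$elements,
                          n_frag = cfg$spectrum$n_frag,
                          frag_len = cfg$spectrum$frag_len,
                          seed = stage_seed(2L))
    readr::write_tsv(tidy(sp), emit(paste0("spectrum_", mode, ".tsv")),
                     progress = FALSE)
  }

  # stage 3: nucleosome profiles
  els <- alu_elements(sim$elements)
  mids <- tibble::tibble(chrom = tags$chrom, pos = tag_midpoint(tags))
  uniq <- tags$n_hits <= 1L
  sig <- nucleosome_signal(mids[uniq, ], sim$genome, cfg$profile$window_w)
  n_bg <- cfg$profile$background_fragments %||% sum(uniq)
  bg <- background_signal(sim$genome, n_bg, seed = stage_seed(3L),
                          window_w = cfg$profile$window_w)
  for (cls in cfg$profile$classes) {
    sel <- els[els$alu_class == cls, , drop = FALSE]
    if (nrow(sel) == 0L) next
    prof <- align_profile(sig, sel, anchor = "center",
                          flank = cfg$profile$flank, background = bg)
    readr::write_tsv(tidy(prof), emit(paste0("profile_", cls, ".tsv")),
                     progress = FALSE)
  }

  # stage 4: tiling profile
  tp <- tiling_profile(probes, els, max_dist = cfg$tiling$max_dist,
                       bin_width = cfg$tiling$bin_width,
                       n_shuffles = cfg$tiling$n_shuffles,
                       seed = stage_seed(4L))
  readr::write_tsv(tibble::as_tibble(tp), emit("tiling.tsv"), progress = FALSE)

  # stage 5: expression rates
  ex <- expression_rates(tss_tags, els, genes, sim$genome,
                         n_replicates = cfg$expression$n_replicates,
                         seed = stage_seed(5L))
  readr::write_tsv(tidy(ex), emit("expression.tsv"), progress = FALSE)

  manifest <- list(
    package = "alunuc",
    version = as.character(utils::packageVersion("alunuc")),
    config = cfg,
    config_hash = rlang::hash(cfg),
    stage_seeds = stats::setNames(
      vapply(1:5, stage_seed, 0L),
      c("simulate", "spectrum", "profile", "tiling", "expression")
    ),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), hash = rlang::hash(readBin(p, "raw", file.size(p))))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
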