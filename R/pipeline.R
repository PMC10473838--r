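# Run configuration (validated YAML) and the umbrella pipeline: synthetic
# system -> metadynamics -> FES / convergence / error -> state split ->
# per-state energy networks -> per-state pocket maps -> overlaps, with a
# manifest that makes every run reproducible from config + seed.

config_schema <- list(
  seed = NULL, output_dir = NULL, temperature = NULL, log = NULL,
  potential = list(template = NULL, barrier = NULL),
  metad = list(hill_height = NULL, hill_widths = NULL, pace = NULL,
               bias_factor = NULL, n_walkers = NULL, steps_per_walker = NULL,
               timestep = NULL, diffusion = NULL, sample_stride = NULL),
  states = list(regions = NA, stride = NULL),
  receptor = list(n_residues = NULL, path_edges = NULL, two_chains = NULL,
                  spacing = NULL, path_charge = NULL, cavity_radius = NULL),
  ensembles = list(n_frames = NULL, noise_sd = NULL, cavity_fraction = NA),
  pen = list(cutoff = NULL, threshold = NULL, chain_scope = NULL,
             exclude_adjacent = NULL),
  pockets = list(spacing = NULL, probe = NULL, burial_radius = NULL,
                 burial_min = NULL, iso = NULL, min_voxels = NULL,
                 contact = NULL))

check_keys <- function(cfg, schema, prefix = "") {
  for (k in names(cfg)) {
    full <- paste0(prefix, k)
    if (!k %in% names(schema)) stop2("unknown config key: '", full, "'")
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]])) &&
        is.list(cfg[[k]])) {
      check_keys(cfg[[k]], schema[[k]], paste0(full, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' YAML configuration for [run_pipeline()]. Keys are validated against the
#' package schema — unknown keys are rejected with their full path, and
#' `seed` and `potential.template` are required. All physical quantities use
#' the package units (kcal/mol, Angstrom, degrees, Kelvin).
#'
#' @param path YAML file path.
#' @return Validated configuration list with attribute `md5`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
validate_config <- function(config) {
  check_keys(config, config_schema)
  if (is.null(config$seed)) stop2("missing required config key: 'seed'")
  if (is.null(config$potential$template)) {
    stop2("missing required config key: 'potential.template'")
  }
  invisible(config)
}

default_demo_config <- function() {
  list(
    seed = 1, temperature = 303.15,
    potential = list(template = "triple_well_2d"),
    metad = list(steps_per_walker = 8000L),
    states = list(stride = 2L),
    receptor = list(n_residues = 48L, two_chains = FALSE),
    ensembles = list(n_frames = 30L, noise_sd = 0.1,
                     cavity_fraction = list(basin1 = 0, basin2 = 0.4,
                                            basin3 = 1.0)),
    pen = list(cutoff = 11, threshold = 0.1),
    pockets = list(spacing = 1.0, probe = 1.4, burial_radius = 10,
                   burial_min = 6, iso = 0.2, min_voxels = 5))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the paper-shaped workflow on a validated configuration:
#' build the toy potential, run well-tempered multiple-walker metadynamics,
#' reconstruct the free-energy surface with convergence and block-error
#' analysis, split the CV samples into states over the declared basin
#' regions, then generate a planted-pathway bead receptor and, per state, a
#' conformational ensemble, its mean interaction-energy network with
#' shortest-path map, its pocket frequency map, and the pocket-network
#' overlap. Every artifact is written under `output_dir` together with a
#' `manifest.json` (config hash, resolved seed, package and R versions).
#'
#' @param config Path to a YAML config, or a config list.
#' @param output_dir Output directory (created); default
#'   `tempfile("allosteer_run")`.
#' @param seed Optional override of the config seed (recorded in the
#'   manifest).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results (`fes`,
#'   `convergence`, `partition`, per-state `spm` and `pockets`, `manifest`).
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  t0 <- Sys.time()
  config_md5 <- NA_character_
  if (is.character(config)) {
    cfg <- read_run_config(config)
    config_md5 <- attr(cfg, "md5")
  } else {
    cfg <- validate_config(config)
  }
  seed_overridden <- !is.null(seed)
  if (seed_overridden) cfg$seed <- seed
  base_seed <- as.integer(cfg$seed)
  tempr <- cfg$temperature %||% 303.15
  outdir <- output_dir %||% tempfile("allosteer_run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  keep <- function(p) {
    outputs <<- c(outputs, p)
    p
  }

  # --- stage 1: toy landscape and metadynamics -------------------------
  pot_args <- cfg$potential
  pot <- make_potential(pot_args$template,
                        barrier = pot_args$barrier %||% 3)
  mp <- do.call(metad_params, c(cfg$metad %||% list(),
                                list(temperature = tempr,
                                     seed = base_seed)))
  say("running WT-MetaD (", mp$n_walkers, " walkers x ",
      mp$steps_per_walker, " steps)")
  run <- run_wtmetad(pot, mp)
  write_hills(run$hills, keep(file.path(outdir, "hills.txt")))
  samp_series <- cv_series(run$samples$time,
                           cbind(run$samples$cv1, run$samples$cv2),
                           periodic = pot$periodic)
  write_colvar(samp_series, keep(file.path(outdir, "colvar.txt")))

  fes <- reconstruct_fes(run$bias, bias_factor = mp$bias_factor,
                         temperature = tempr)
  write_fes(fes, keep(file.path(outdir, "fes.txt")))
  conv <- delta_g_timeseries(run$bias, pot$basins,
                             bias_factor = mp$bias_factor,
                             temperature = tempr)
  utils::write.table(conv, keep(file.path(outdir, "convergence.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  w <- constant_bias_weights(run$samples, run$bias, tempr)
  rw <- reweight_constant_bias(run$samples, run$bias,
                               edges1 = fes$edges1, temperature = tempr)
  err <- block_error(run$samples$cv1, w, fes$edges1, n_blocks = 10,
                     temperature = tempr)
  rw$error <- err$error
  write_fes(rw, keep(file.path(outdir, "fes_cv1_reweighted.txt")))

  # --- stage 2: state split -------------------------------------------
  regions <- cfg$states$regions
  regions <- if (is.null(regions) || all(is.na(regions))) {
    state_regions(pot$basins[, c("name", "cv1_lo", "cv1_hi", "cv2_lo",
                                 "cv2_hi")] |>
                    stats::setNames(c("state", "cv1_lo", "cv1_hi",
                                      "cv2_lo", "cv2_hi")))
  } else {
    state_regions(lapply(regions, as.numeric))
  }
  part <- assign_states(samp_series, regions)
  say("state split: ", paste(names(part$counts), part$counts,
                             collapse = ", "))
  idx <- subsample_states(part, stride = cfg$states$stride %||% 2)
  utils::write.table(
    data.frame(frame = seq_along(part$labels), state = part$labels),
    keep(file.path(outdir, "states.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # --- stage 3: receptor, per-state networks and pockets ---------------
  rc <- cfg$receptor %||% list()
  rec <- make_bead_receptor(
    n_residues = rc$n_residues %||% 48,
    path_edges = rc$path_edges,
    two_chains = isTRUE(rc$two_chains),
    spacing = rc$spacing %||% 5,
    path_charge = rc$path_charge %||% 0.275,
    seed = base_seed)
  if (!is.null(rc$cavity_radius)) rec$cavity$radius <- rc$cavity_radius
  write_param_table(rec$params, keep(file.path(outdir, "params.tsv")))
  write_ground_truth(keep(file.path(outdir, "ground_truth.yaml")),
                     receptor = rec, potential = pot, temperature = tempr)

  en <- cfg$ensembles %||% list()
  pn <- cfg$pen %||% list()
  pk <- cfg$pockets %||% list()
  cav_frac <- en$cavity_fraction %||% 0
  states <- names(idx)
  results <- list()
  for (si in seq_along(states)) {
    st <- states[si]
    if (!length(idx[[st]])) next
    say("state '", st, "': ensemble + network + pockets")
    frac <- if (is.list(cav_frac)) (cav_frac[[st]] %||% 0) else cav_frac
    ens <- generate_ensemble(rec, n_frames = en$n_frames %||% 30,
                             noise_sd = en$noise_sd %||% 0.1,
                             cavity_fraction = frac,
                             seed = base_seed + 100L + si)
    sdir <- file.path(outdir, st)
    dir.create(sdir, showWarnings = FALSE)
    write_xyz(ens$coords, keep(file.path(sdir, "ensemble.xyz")))
    iem <- mean_iem(ens, cutoff = pn$cutoff %||% 11,
                    chain_scope = pn$chain_scope %||% "intra+inter",
                    exclude_adjacent = isTRUE(pn$exclude_adjacent))
    iem <- process_iem(iem)
    write_iem(iem, keep(file.path(sdir, "iem.txt")))
    spm <- build_spm(iem, threshold = pn$threshold %||% 0.1)
    write_spm_tables(spm, keep(file.path(sdir, "spm_nodes.tsv")),
                     keep(file.path(sdir, "spm_edges.tsv")))
    ov <- overlap_with_reference(spm, rec$reference_allosteric_set,
                                 all_residues = rec$residues$residue)
    fmap <- frequency_map(ens, probe = pk$probe %||% 1.4,
                          burial_radius = pk$burial_radius %||% 10,
                          burial_min = pk$burial_min %||% 6,
                          spacing = pk$spacing %||% 1.0)
    write_frequency_map(fmap, keep(file.path(sdir, "freq_map.txt")))
    pockets <- extract_pockets(fmap, iso = pk$iso %||% 0.2,
                               min_voxels = pk$min_voxels %||% 5)
    ptab <- pocket_pen_overlap(pockets, spm, rec$coords,
                               rec$atom_residue,
                               contact = pk$contact %||% 3.4)
    utils::write.table(ptab, keep(file.path(sdir, "pockets.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results[[st]] <- list(spm = spm, overlap = ov, pockets = pockets,
                          pocket_table = ptab, n_frames = dim(ens$coords)[3])
  }

  manifest <- list(
    package = "allosteer",
    version = as.character(utils::packageVersion("allosteer")),
    r_version = R.version.string,
    config_md5 = config_md5,
    seed = base_seed,
    seed_overridden = seed_overridden,
    config = cfg,
    outputs = basename(outputs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say(sprintf("pipeline done in %.1f s -> %s", manifest$elapsed_sec, outdir))
  invisible(list(potential = pot, run = run, fes = fes, convergence = conv,
                 reweighted = rw, partition = part, states = results,
                 receptor = rec, manifest = manifest,
                 output_dir = outdir))
}
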