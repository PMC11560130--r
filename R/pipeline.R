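# End-to-end orchestration: a YAML/JSON config selects stages and
# parameters; every artifact written is listed, with checksums, in a run
# manifest. Deterministic given the seed.

pipeline_stages <- c("simulate", "kymo", "contract", "helix", "pixstats",
                     "dynamics")

pipeline_known_keys <- list(
  top = c("stages", "seed", "out_dir", "params"),
  params = c("geometry", "profiles", "localizations", "pairs", "traces",
             "nb", "contract", "helix", "pixstats", "dynamics"))

#' Validate a pipeline configuration
#'
#' Unknown keys (at the top level or under `params`) are rejected before
#' any stage runs; stage names must come from the known set.
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]).
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_known_keys$top)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config$stages <- config$stages %||% pipeline_stages
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% tempfile("midpiece_run_")
  config$params <- config$params %||% list()
  unknown_p <- setdiff(names(config$params), pipeline_known_keys$params)
  if (length(unknown_p))
    stopf("unknown params key(s): %s", paste(unknown_p, collapse = ", "))
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: `simulate` (synthetic cross-section profiles, localizations,
#' regression pairs, traces, fluctuation stack, with ground-truth
#' sidecars), `kymo` (normalized-diameter kymograph), `contract`
#' (contraction report and fluorescence-diameter fit), `helix` (helix
#' geometry), `pixstats` (Manders + number & brightness), `dynamics`
#' (event ordering and pattern classification). Later stages consume the
#' outputs of `simulate`; the whole run is deterministic given
#' `config$seed`.
#'
#' @param config Path to a YAML file, or a named list. Keys: `stages`
#'   (subset of the stage names), `seed`, `out_dir`, `params` (per-stage
#'   parameter maps; see the demo config in
#'   `system.file("extdata/demo_config.yaml", package = "midpiece")`).
#' @return The run manifest (invisibly written to
#'   `<out_dir>/manifest.json`): parameters used, artifact paths with MD5
#'   checksums, and headline numbers per stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  p <- config$params
  artifacts <- character(0)
  summary <- list()
  state <- new.env(parent = emptyenv())

  emit <- function(path) artifacts <<- c(artifacts, path)

  if ("simulate" %in% config$stages) {
    geom <- make_geometry(p$geometry %||%
                            list(contraction_amplitude = 0.2))
    pr <- p$profiles %||% list()
    state$csk <- render_cross_profiles(
      geom,
      positions_um = pr$positions_um %||% seq(0, 20, by = 2.5),
      times_s = pr$times_s %||% seq(0, 240, by = 2),
      noise_sd = pr$noise_sd %||% 0.02,
      channels = c("membrane", "actin"),
      seed = seed)
    lp <- p$localizations %||% list()
    state$locs <- simulate_localizations(
      geom, n_points = lp$n_points %||% 2e4,
      precision_nm = lp$precision_nm %||% 15, seed = seed + 1L)
    state$pairs <- simulate_regression_pairs(
      n = (p$pairs %||% list())$n %||% 2000L, seed = seed + 2L)
    state$traces <- simulate_traces(
      ae_trace_spec(), noise_sd = 0.02, seed = seed + 3L,
      baseline_window = c(1L, 30L))
    nbp <- p$nb %||% list()
    state$nb_stack <- simulate_nb_stack(
      matrix(nbp$n_molecules %||% 50, 8, 8),
      brightness_counts = nbp$brightness %||% 4,
      n_frames = nbp$n_frames %||% 300L, seed = seed + 4L)
    emit(write_localizations(state$locs,
                             file.path(config$out_dir, "localizations.csv")))
    emit(write_traces(state$traces,
                      file.path(config$out_dir, "traces.csv")))
    utils::write.csv(state$pairs,
                     file.path(config$out_dir, "regression_pairs.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "regression_pairs.csv"))
    emit(write_result_json(
      list(geometry = unclass(geom),
           true_onset_s = state$csk$truth$onset_s),
      file.path(config$out_dir, "ground_truth.json")))
    summary$simulate <- list(n_localizations = nrow(state$locs),
                             n_positions = length(state$csk$positions_um))
  }

  if ("kymo" %in% config$stages && !is.null(state$csk)) {
    ds <- normalized_diameter_kymograph(state$csk, c(1L, 25L))
    k <- kymograph(t(ds$normalized),
                   arclength_step_um = diff(state$csk$positions_um[1:2]),
                   frame_interval_s = diff(state$csk$times_s[1:2]),
                   channel = "normalized_diameter",
                   baseline_window = c(1L, 25L))
    emit(write_kymograph(k, file.path(config$out_dir,
                                      "normalized_diameter_kymograph.csv")))
    summary$kymo <- list(
      baseline_diameter_um = mean(ds$diameter_um[, 1:25], na.rm = TRUE))
  }

  if ("contract" %in% config$stages && !is.null(state$csk)) {
    cp <- p$contract %||% list()
    rep <- analyze_contraction(state$csk, cp$baseline_window %||% c(1L, 25L))
    fit <- fit_fluorescence_diameter(state$pairs)
    emit(write_result_json(
      list(focus_count = rep$focus_count, foci = rep$foci,
           region_counts = rep$region_counts,
           model = unclass(fit)),
      file.path(config$out_dir, "contraction_report.json")))
    summary$contract <- list(focus_count = rep$focus_count,
                             slope = fit$slope, intercept = fit$intercept)
  }

  if ("helix" %in% config$stages && !is.null(state$locs)) {
    hp <- analyze_helix(state$locs)
    emit(write_result_json(hp, file.path(config$out_dir,
                                         "helix_params.json")))
    summary$helix <- list(pitch_nm = hp$pitch_nm, R_nm = hp$R_nm,
                          gyres = hp$gyres)
  }

  if ("pixstats" %in% config$stages && !is.null(state$csk)) {
    frame1 <- 1L
    m <- manders(pmax(state$csk$channels$membrane[, frame1, ], 0),
                 pmax(state$csk$channels$actin[, frame1, ], 0))
    nb <- nb_maps(state$nb_stack,
                  segment_frames = min(100L, dim(state$nb_stack$data)[1]))
    emit(write_result_json(
      list(manders = unclass(m),
           median_N = stats::median(nb$number, na.rm = TRUE),
           median_B = stats::median(nb$brightness, na.rm = TRUE)),
      file.path(config$out_dir, "pixel_statistics.json")))
    summary$pixstats <- list(M1 = m$M1, M2 = m$M2)
  }

  if ("dynamics" %in% config$stages && !is.null(state$traces)) {
    ev <- order_events(state$traces)
    emit(write_result_json(
      list(onsets = ev$onsets,
           calcium_precedes_membrane = ev$calcium_precedes_membrane),
      file.path(config$out_dir, "event_report.json")))
    summary$dynamics <- list(
      calcium_precedes_membrane = ev$calcium_precedes_membrane)
  }

  manifest <- list(seed = seed, stages = config$stages,
                   params = config$params,
                   artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                                      function(f) list(
                                        path = f,
                                        md5 = unname(tools::md5sum(f)))),
                   summary = summary)
  write_result_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
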