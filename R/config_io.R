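#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills missing fields from [wm_defaults()],
#' rejects unknown sections or keys, and checks all cross-field invariants
#' by constructing the typed parameter objects.
#'
#' @param path YAML file path.
#' @param quiet suppress the provenance echo of filled-in defaults.
#' @return a validated configuration bundle ([wm_defaults()] shape).
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- wm_defaults()
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- base
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  cfg$network$delay_range <- as.numeric(unlist(cfg$network$delay_range))
  # type-check through the constructors (they own the invariants)
  .cfg_network(cfg); .cfg_neuron_E(cfg); .cfg_neuron_I(cfg); .cfg_stp(cfg)
  if (cfg$sim$dt <= 0 || abs(1 / cfg$sim$dt - round(1 / cfg$sim$dt)) > 1e-9)
    stop("sim.dt must divide the 1 ms noise interval evenly", call. = FALSE)
  for (f in c("sigma_bg_E", "sigma_bg_I"))
    if (cfg$background[[f]] < 0)
      stop("background.", f, " must be non-negative", call. = FALSE)
  if (!quiet) {
    filled <- unlist(lapply(names(base), function(sec) {
      miss <- setdiff(names(base[[sec]]), names(raw[[sec]]))
      if (length(miss)) paste0(sec, ".", miss) else character(0)
    }))
    if (length(filled))
      message("defaults filled: ", paste(filled, collapse = ", "))
  }
  cfg
}

#' Write a configuration bundle to a YAML file
#'
#' Round-trips with [load_config()]: writing and re-reading a bundle gives
#' back an identical bundle.
#'
#' @param cfg a configuration bundle.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg$provenance <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run an experiment preset end to end
#'
#' Builds the network, compiles the preset's protocol, simulates, analyses
#' (population rates, population-spike trains of the loaded populations,
#' firing-rate differences, held-item count) and optionally writes the
#' raster, the STP traces and a JSON-like summary to an output directory.
#'
#' @param name preset name (see [wm_preset()]).
#' @param seed integer seed (network build and simulation noise).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param cfg configuration bundle.
#' @param sanity_range admissible spontaneous-rate range (Hz); a mean
#'   excitatory rate outside it aborts with a diagnostic.
#' @return list with `result` (the `"wm_sim"`), `network`, `preset` and
#'   `summary` (spontaneous rate, PS times and median intervals per loaded
#'   population, mean firing-rate difference, held-item count, `T_max`,
#'   `N_c`).
#' @export
run_preset <- function(name, seed = 1, out_dir = NULL, cfg = wm_defaults(),
                       sanity_range = c(0.05, 5)) {
  preset <- wm_preset(name, cfg)
  cfg <- preset$cfg
  net <- build_network(.cfg_network(cfg), seed = seed)
  sim <- sim_params(dt = cfg$sim$dt, T_total = preset$T_total, seed = seed,
                    trace_dt = cfg$sim$trace_dt,
                    traced_pops = preset$traced_pops,
                    trace_max_connections = cfg$sim$trace_max_connections)
  res <- run_simulation(net, preset$protocol, .cfg_neuron_E(cfg),
                        .cfg_neuron_I(cfg), .cfg_stp(cfg), sim)
  summ <- summarize_run(res, net, preset)
  if (summ$spontaneous_rate < sanity_range[1] ||
      summ$spontaneous_rate > sanity_range[2])
    stop(sprintf(
      "regime sanity check failed: spontaneous rate %.3f Hz outside [%g, %g]",
      summ$spontaneous_rate, sanity_range[1], sanity_range[2]), call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res$spikes,
                       file.path(out_dir, "raster.txt"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (p in names(res$traces))
      utils::write.table(res$traces[[p]],
                         file.path(out_dir, paste0("stp_trace_pop", p, ".txt")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summ$as_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(result = res, network = net, preset = preset, summary = summ)
}

#' Summarize a preset run
#'
#' @param res a `"wm_sim"`.
#' @param net the `"wm_network"` it ran on.
#' @param preset the [wm_preset()] bundle.
#' @return list with the quantitative readouts (see [run_preset()]).
#' @export
summarize_run <- function(res, net, preset) {
  cfg <- preset$cfg
  an <- cfg$analysis
  popmap <- net$popmap
  sw <- preset$windows$spontaneous
  dw <- preset$windows$delay
  E_ids <- seq_len(net$cfg$N_E)
  spont <- sum(res$spikes$time >= sw[1] & res$spikes$time < sw[2] &
                 res$spikes$id <= net$cfg$N_E) /
    net$cfg$N_E / (diff(sw) / 1000)
  stp <- .cfg_stp(cfg)
  T_max <- tmax_estimate(stp)
  ps_trains <- lapply(preset$loaded_pops, function(p) {
    r <- population_rate(res$spikes, popmap$members[[p]], bin_ms = an$ps_bin,
                         t_max = preset$T_total)
    detect_population_spikes(r, baseline_window = sw,
                             threshold_factor = an$ps_threshold_factor,
                             min_separation_ms = an$ps_min_separation,
                             abs_floor_hz = an$ps_abs_floor,
                             spikes = res$spikes,
                             population = popmap$members[[p]],
                             min_participation = an$min_participation)
  })
  names(ps_trains) <- as.character(preset$loaded_pops)
  held <- count_held_items(ps_trains, window = dw, T_max = T_max,
                           gap_factor = an$gap_factor)
  t_s <- ps_spacing(ps_trains, window = dw)
  dr <- lapply(preset$loaded_pops, function(p)
    firing_rate_difference(res$spikes, popmap$members[[p]], sw, dw))
  mean_dr <- vapply(dr, function(d) mean(d$dr), numeric(1))
  as_list <- list(
    preset = preset$name,
    spontaneous_rate_hz = spont,
    ps_times_ms = lapply(ps_trains, function(tr) tr$time),
    median_ps_interval_ms =
      lapply(ps_trains, function(tr)
        if (nrow(tr) > 1) stats::median(diff(tr$time)) else NA_real_),
    pooled_ps_spacing_ms = t_s,
    mean_rate_difference_hz = as.list(stats::setNames(
      mean_dr, paste0("pop", preset$loaded_pops))),
    held_items = as.integer(held),
    T_max_ms = T_max,
    N_c = if (is.na(t_s)) NA_real_ else capacity_estimate(T_max, t_s))
  list(spontaneous_rate = spont, ps_trains = ps_trains, held = held,
       t_s = t_s, mean_dr = mean_dr, T_max = T_max, as_list = as_list)
}
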