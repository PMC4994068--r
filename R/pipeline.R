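#' Scenario configuration for end-to-end runs
#'
#' Bundles everything a physiology or behavior scenario needs: the gas-phase
#' dilution series (label to PID peak), the genotype emulations (which
#' presynaptic inhibition kernels are active), the pulse shape and model
#' parameters, and a master seed. Genotypes map to kernel flags: `control`
#' keeps both kernels, `gA_off`/`gB_off` disable one, `both_off` disables
#' both — emulating receptor blockade or RNAi knockdown.
#'
#' @param scenario `"physiology"` or `"behavior"`.
#' @param dilutions Named numeric vector, dilution label to PID peak.
#' @param genotypes Character subset of `c("control", "gA_off", "gB_off",
#'   "both_off")`.
#' @param pulse An [odor_pulse_spec()] template (its `peak` is replaced per
#'   dilution).
#' @param osn An [osn_params()].
#' @param inhibition An [inhibition_params()] template.
#' @param bleach A [bleach_model()] for fluorescence rendering.
#' @param behavior A [behavior_params()] (behavior scenario).
#' @param arena An [arena_config()] (behavior scenario).
#' @param n_flies Flies per behavior run.
#' @param noise_sd Fluorescence noise SD (physiology scenario).
#' @param drive_ref Drive normalization for rendering, Hz.
#' @param seed Master integer seed; per-condition seeds are derived from it.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("physiology", "behavior"),
                            dilutions = c("1:25" = 0.3, "1:5" = 1.0),
                            genotypes = c("control", "both_off"),
                            pulse = odor_pulse_spec(onset_s = 2, duration_s = 1),
                            osn = osn_params(),
                            inhibition = inhibition_params(),
                            bleach = bleach_model(30, 15, 4, 60, 100),
                            behavior = behavior_params(),
                            arena = arena_config(),
                            n_flies = 20, noise_sd = 0, drive_ref = 100,
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (length(dilutions) < 1) stop("need at least one dilution", call. = FALSE)
  bad <- setdiff(genotypes, c("control", "gA_off", "gB_off", "both_off"))
  if (length(bad)) {
    stop("unknown genotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      scenario = scenario, dilutions = dilutions, genotypes = genotypes,
      pulse = pulse, osn = osn, inhibition = inhibition, bleach = bleach,
      behavior = behavior, arena = arena, n_flies = n_flies,
      noise_sd = noise_sd, drive_ref = drive_ref, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' Scalar fields (`scenario`, `dilutions`, `genotypes`, `n_flies`,
#' `noise_sd`, `drive_ref`, `seed`) and the nested parameter blocks
#' (`pulse`, `osn`, `inhibition`, `bleach`) are passed to the corresponding
#' constructors; omitted fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in c("scenario", "genotypes", "n_flies", "noise_sd", "drive_ref", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$dilutions)) args$dilutions <- unlist(raw$dilutions)
  if (!is.null(raw$pulse)) args$pulse <- do.call(odor_pulse_spec, raw$pulse)
  if (!is.null(raw$osn)) args$osn <- do.call(osn_params, raw$osn)
  if (!is.null(raw$inhibition)) args$inhibition <- do.call(inhibition_params, raw$inhibition)
  if (!is.null(raw$bleach)) args$bleach <- do.call(bleach_model, raw$bleach)
  do.call(scenario_config, args)
}

genotype_inhibition <- function(q, genotype) {
  inhibition_params(
    gA_weight = q$gA_weight, gA_tau_s = q$gA_tau_s,
    gB_weight = q$gB_weight, gB_tau_s = q$gB_tau_s,
    gA_enabled = q$gA_enabled && !genotype %in% c("gA_off", "both_off"),
    gB_enabled = q$gB_enabled && !genotype %in% c("gB_off", "both_off")
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "behavior")])
}

#' Run the physiology scenario
#'
#' For every dilution x genotype: synthesize the odor pulse, drive the OSN
#' rate model, apply the genotype's presynaptic inhibition, render a
#' voltage-indicator fluorescence trace on a bleaching baseline, run the full
#' preprocessing chain (bleach fit, divide detrend, box-car, percent dF/F,
#' inverted so responses are positive), and compute the contrast statistics.
#'
#' @param config A `scenario_config`.
#'
#' @return A tibble with one row per dilution x genotype: `dilution`,
#'   `genotype`, `peak_dff`, `sharpness_max`, `sharpness_offset`, `seed`,
#'   `config_hash`. The per-condition processed traces are attached as the
#'   `traces` attribute (named list), the sharpness timecourses as
#'   `timecourses`.
#' @export
run_physiology <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  offset_s <- config$pulse$onset_s + config$pulse$duration_s
  total_s <- offset_s + 5
  grid <- tidyr::expand_grid(
    dilution = names(config$dilutions),
    genotype = config$genotypes
  )
  traces <- list()
  timecourses <- list()
  chash <- config_hash(config)
  rows <- purrr::pmap_dfr(grid, function(dilution, genotype) {
    run_seed <- config$seed +
      match(dilution, names(config$dilutions)) * 1000L +
      match(genotype, config$genotypes)
    spec <- odor_pulse_spec(
      onset_s = config$pulse$onset_s, duration_s = config$pulse$duration_s,
      peak = unname(config$dilutions[dilution]),
      rise_tau_s = config$pulse$rise_tau_s,
      decay_tau_s = config$pulse$decay_tau_s,
      dilution_label = dilution
    )
    pid <- make_odor_pulse(spec, total_s, sample_rate = 125)
    rate <- osn_rate(pid, config$osn)
    term <- apply_presynaptic_inhibition(
      rate, genotype_inhibition(config$inhibition, genotype)
    )
    fluor <- render_arclight(term, config$bleach,
      scale = -0.05, noise_sd = config$noise_sd,
      drive_ref = config$drive_ref, seed = run_seed
    )
    proc <- process_trace(fluor,
      baseline_window = c(0, spec$onset_s - 0.3),
      exclude_window = c(spec$onset_s - 0.2, offset_s + 4),
      invert = TRUE
    )
    key <- paste(dilution, genotype, sep = "/")
    traces[[key]] <<- proc
    timecourses[[key]] <<- sharpness_timecourse(
      proc, offset_s, delays = seq(0.2, 3, by = 0.2)
    )
    in_pulse <- proc$time_s >= spec$onset_s & proc$time_s <= offset_s
    tibble::tibble(
      dilution = dilution, genotype = genotype,
      peak_dff = max(proc$value[in_pulse]),
      sharpness_max = sharpness_max(proc, offset_s,
                                    onset_time = spec$onset_s)$coefficient,
      sharpness_offset = sharpness_offset(proc, offset_s)$coefficient,
      seed = run_seed, config_hash = chash
    )
  })
  attr(rows, "traces") <- traces
  attr(rows, "timecourses") <- timecourses
  rows
}

#' Run the behavior scenario
#'
#' For every dilution x genotype: simulate the arena, then compute the
#' postpulse kinetics table (one row per fly per window) and the net
#' displacement at pulse end. Genotype emulation scales the drift
#' persistence — knocking down the inhibition that truncates sustained OSN
#' activity prolongs odor-driven drift past the pulse (factors 1, 1.5, 2.5, 4
#' for control, gA_off, gB_off, both_off).
#'
#' @param config A `scenario_config`.
#'
#' @return A list: `kinetics` (tibble, one row per dilution x genotype x fly
#'   x window), `net` (tibble, one row per dilution x genotype), each
#'   carrying `seed` and `config_hash` columns.
#' @export
run_behavior <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  persist_factor <- c(control = 1, gA_off = 1.5, gB_off = 2.5, both_off = 4)
  total_s <- config$pulse$onset_s + config$pulse$duration_s + 4.6
  grid <- tidyr::expand_grid(
    dilution = names(config$dilutions),
    genotype = config$genotypes
  )
  chash <- config_hash(config)
  res <- purrr::pmap(grid, function(dilution, genotype) {
    run_seed <- config$seed +
      match(dilution, names(config$dilutions)) * 1000L +
      match(genotype, config$genotypes)
    spec <- odor_pulse_spec(
      onset_s = config$pulse$onset_s, duration_s = config$pulse$duration_s,
      peak = unname(config$dilutions[dilution]),
      rise_tau_s = config$pulse$rise_tau_s,
      decay_tau_s = config$pulse$decay_tau_s,
      dilution_label = dilution
    )
    bp <- config$behavior
    bp$persistence_s <- bp$persistence_s * persist_factor[[genotype]]
    sim <- simulate_flies(config$n_flies, config$arena, bp, spec,
                          total_s = total_s, seed = run_seed)
    kin <- postpulse_kinetics(sim$trajectories, config$arena, spec,
                              frame_rate = config$arena$frame_rate)
    nd <- net_displacement(sim$trajectories, config$arena, spec,
                           frame_rate = config$arena$frame_rate)
    kin$dilution <- dilution
    kin$genotype <- genotype
    kin$seed <- run_seed
    kin$config_hash <- chash
    net_row <- tibble::tibble(
      dilution = dilution, genotype = genotype,
      mean_delta_d_cm = nd$group$mean_cm, sem_cm = nd$group$sem_cm,
      n = nd$group$n, seed = run_seed, config_hash = chash
    )
    list(kin = kin, net = net_row)
  })
  list(
    kinetics = purrr::map_dfr(res, "kin"),
    net = purrr::map_dfr(res, "net")
  )
}
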