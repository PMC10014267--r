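# End-to-end orchestration: simulate -> preprocess -> epoch -> forward ->
# invert -> maps -> connectivity -> stats, from a single validated config,
# with a provenance manifest.

pipeline_schema <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(n_epochs = 500L, stride_s = 1.1,
                    stride_jitter_frac = 0.05, lhs_frac = 0.5,
                    lhs_jitter_frac = 0.02, rate = 512, snr = 0.5,
                    noise_sd = NULL, line_hz = 50, line_amp_uv = 20,
                    blink_rate_hz = 0, blink_amp_uv = 120, start_s = 2,
                    sources = list()),
    inputs = list(eeg = NULL, events = NULL, montage = NULL, clinical = NULL),
    preprocess = list(filter = list(lo_hz = 1, hi_hz = 200, order = 7500),
                      notch = list(hz = 50, order = 3302, bw_hz = 2),
                      ica = list(enabled = FALSE, n_components = NULL),
                      reject = list(amplitude_uv = 200, flatline_uv = 0.5)),
    epoch = list(G = 200L, stride_bounds_s = c(0.5, 2.5)),
    forward = list(n_cortex = 500L, n_cerebellum = 100L),
    inverse = list(method = "eLORETA", reg_lambda = 0.05, depth_gamma = 1,
                   convention = "sem", summary = "abs"),
    connectivity = list(enabled = TRUE, targets = c("O1", "O2"),
                        epoch_len_s = 2, n_cycles = 7),
    clinical = list(enabled = FALSE, n_per_group = 25L, effects = list())
  )
}

validate_config <- function(config, schema = pipeline_schema(), path = "") {
  if (!is.list(config)) stopf("config%s must be a list", path)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s", path, paste(unknown, collapse = ", "))
  merged <- schema
  for (key in names(config)) {
    here <- paste0(path, "$", key)
    if (is.list(schema[[key]]) && !is.null(names(schema[[key]])) &&
        key != "sources" && key != "effects" && key != "inputs") {
      merged[[key]] <- validate_config(config[[key]], schema[[key]], here)
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  merged
}

#' Load and validate a pipeline configuration
#'
#' @param config path to a YAML file, or a named list. Keys are validated
#'   against the pipeline schema; unknown keys are rejected. Missing keys
#'   take their defaults.
#' @return the merged, validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
}

write_artifact <- function(obj, dir, name, manifest, params = list(),
                           inputs = character(0)) {
  path <- file.path(dir, paste0(name, ".rds"))
  saveRDS(obj, path, version = 2)
  manifest$stages[[name]] <- list(
    artifact = basename(path),
    md5 = unname(tools::md5sum(path)),
    params = params,
    inputs = as.list(inputs),
    seed = manifest$stage_seeds[[name]] %||% NULL)
  manifest
}

#' Run the full gait-EEG analysis pipeline
#'
#' Executes simulate (or load) -> band-pass -> notch -> common average ->
#' (optional ICA cleaning) -> stride epoching + rejection -> time-warping
#' -> forward model -> inverse -> z-score maps -> ROI time courses ->
#' (optional) scalp connectivity -> (optional) clinical battery. Every
#' stage writes its artifact into `out_dir` and a manifest entry (artifact
#' hash, parameters, derived seed), so a rerun with the same config
#' reproduces identical artifacts.
#'
#' @param config a config list or YAML path, see [pipeline_config()].
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param resume if `TRUE`, existing artifacts listed in the manifest are
#'   checked against their recorded hashes and the run halts on a
#'   mismatch (corrupt intermediate) instead of silently recomputing.
#' @return the manifest list, invisibly; artifacts and `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, resume = FALSE) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stopf("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("forward", "simulate", "preprocess", "epoch", "invert",
              "maps", "connectivity", "clinical")
  manifest <- list(config = cfg, stages = list(),
                   stage_seeds = stats::setNames(
                     lapply(stages, function(s) derive_seed(cfg$seed, s)),
                     stages))
  mpath <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(mpath)) {
    old <- jsonlite::read_json(mpath)
    for (st in names(old$stages)) {
      f <- file.path(out_dir, old$stages[[st]]$artifact)
      if (file.exists(f) &&
          !identical(unname(tools::md5sum(f)), old$stages[[st]]$md5[[1]]))
        stopf("integrity error: artifact for stage '%s' does not match its manifest hash", st)
    }
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stopf("pipeline halted at stage '%s': %s", name, conditionMessage(e)))
  }

  # forward model first: simulation projects through it
  space <- run_stage("forward", function()
    build_source_space(cfg$forward$n_cortex, cfg$forward$n_cerebellum,
                       seed = manifest$stage_seeds$forward))
  fwd <- run_stage("forward", function()
    leadfield_sphere(space, montage_1020()))
  manifest <- write_artifact(fwd, out_dir, "forward", manifest,
                             params = cfg$forward)

  if (!is.null(cfg$inputs$eeg)) {
    rec <- run_stage("simulate", function()
      read_eeg(cfg$inputs$eeg, cfg$inputs$montage))
    events <- run_stage("simulate", function() read_events(cfg$inputs$events))
  } else {
    sc <- cfg$simulate
    sources <- lapply(sc$sources, function(s) do.call(planted_source, s))
    scenario <- sim_scenario(
      n_epochs = sc$n_epochs, stride_s = sc$stride_s,
      stride_jitter_frac = sc$stride_jitter_frac, lhs_frac = sc$lhs_frac,
      lhs_jitter_frac = sc$lhs_jitter_frac, rate = sc$rate,
      sources = sources, snr = sc$snr, noise_sd = sc$noise_sd,
      line_hz = sc$line_hz, line_amp_uv = sc$line_amp_uv,
      blink_rate_hz = sc$blink_rate_hz, blink_amp_uv = sc$blink_amp_uv,
      start_s = sc$start_s, seed = manifest$stage_seeds$simulate)
    events <- run_stage("simulate", function() simulate_gait_events(scenario))
    rec <- run_stage("simulate", function()
      simulate_eeg(scenario, fwd, events))
  }
  manifest <- write_artifact(list(rec = rec, events = events), out_dir,
                             "simulate", manifest, params = cfg$simulate)

  pp <- cfg$preprocess
  rec <- run_stage("preprocess", function() {
    r <- bandpass_fir(rec, pp$filter$lo_hz, pp$filter$hi_hz, pp$filter$order)
    r <- notch_fir(r, pp$notch$hz, pp$notch$order, pp$notch$bw_hz)
    r <- common_average(r)
    if (isTRUE(pp$ica$enabled)) {
      ica <- infomax_ica(r, pp$ica$n_components,
                         seed = manifest$stage_seeds$preprocess)
      r <- reject_components(ica, r)
    }
    r
  })
  manifest <- write_artifact(rec, out_dir, "preprocess", manifest, params = pp)

  ep <- run_stage("epoch", function() {
    e <- extract_strides(rec, events, cfg$epoch$stride_bounds_s)
    e <- reject_epochs(e, pp$reject$amplitude_uv, pp$reject$flatline_uv)
    time_warp(e, cfg$epoch$G)
  })
  baseline <- run_stage("epoch", function() {
    e <- extract_strides(rec, events, cfg$epoch$stride_bounds_s)
    e <- reject_epochs(e, pp$reject$amplitude_uv, pp$reject$flatline_uv)
    e$baseline
  })
  manifest <- write_artifact(ep, out_dir, "epoch", manifest,
                             params = cfg$epoch)

  inv <- run_stage("invert", function()
    make_inverse(fwd, cfg$inverse$method, cfg$inverse$reg_lambda,
                 cfg$inverse$depth_gamma))
  src <- run_stage("invert", function() apply_inverse(inv, ep))
  bsrc <- run_stage("invert", function()
    baseline_source_means(inv, baseline, summary = cfg$inverse$summary))
  manifest <- write_artifact(inv, out_dir, "invert", manifest,
                             params = cfg$inverse)

  maps <- run_stage("maps", function()
    zscore_maps(src, bsrc, phase = ep$phase,
                convention = cfg$inverse$convention,
                summary = cfg$inverse$summary, space = space))
  roi <- run_stage("maps", function()
    roi_timecourse(apply(abs(src), c(1, 2), mean), space))
  manifest <- write_artifact(list(maps = maps, roi = roi), out_dir, "maps",
                             manifest, params = cfg$inverse)

  if (isTRUE(cfg$connectivity$enabled)) {
    conn <- run_stage("connectivity", function() {
      dp <- plv_difference(rec, cfg$connectivity$targets,
                           epoch_len_s = cfg$connectivity$epoch_len_s,
                           n_cycles = cfg$connectivity$n_cycles)
      ic <- imcoh(tfd(rec, epoch_len_s = cfg$connectivity$epoch_len_s,
                      n_cycles = cfg$connectivity$n_cycles),
                  cfg$connectivity$targets)
      list(dplv = dp, imcoh = ic)
    })
    manifest <- write_artifact(conn, out_dir, "connectivity", manifest,
                               params = cfg$connectivity)
  }

  if (isTRUE(cfg$clinical$enabled) || !is.null(cfg$inputs$clinical)) {
    clin <- run_stage("clinical", function() {
      tab <- if (!is.null(cfg$inputs$clinical)) read_clinical(cfg$inputs$clinical)
             else simulate_clinical(cfg$clinical$n_per_group,
                                    cfg$clinical$effects,
                                    seed = manifest$stage_seeds$clinical)
      list(table = tab, report = clinical_battery(tab))
    })
    manifest <- write_artifact(clin, out_dir, "clinical", manifest,
                               params = cfg$clinical)
  }

  out <- manifest[c("config", "stages", "stage_seeds")]
  jsonlite::write_json(out, mpath, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(out)
}
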