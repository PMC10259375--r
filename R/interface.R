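#' Write a simulation trace as tidy CSV
#'
#' Long format with columns `time_ms`, `variable`, `value`; variables are
#' `Vm`, `Vf<i>`, `I_CaL`, `I_gap<i>` (pA), `I_gap_total` and `stim`.
#'
#' @param trace A simulation trace from [integrate_coupled()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "simulation_trace"))
  nf <- ncol(trace$Vf)
  blocks <- list(data.frame(time_ms = trace$time, variable = "Vm",
                            value = trace$Vm),
                 data.frame(time_ms = trace$time, variable = "I_CaL",
                            value = trace$I_CaL),
                 data.frame(time_ms = trace$time, variable = "stim",
                            value = trace$stim),
                 data.frame(time_ms = trace$time, variable = "I_gap_total",
                            value = trace$I_gap_total))
  for (i in seq_len(nf)) {
    blocks <- c(blocks, list(
      data.frame(time_ms = trace$time, variable = paste0("Vf", i),
                 value = trace$Vf[, i]),
      data.frame(time_ms = trace$time, variable = paste0("I_gap", i),
                 value = trace$I_gap[, i])))
  }
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Write/read a scalar map as CSV
#'
#' @param map Matrix with a `units` attribute.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(row = as.vector(row(map)), col = as.vector(col(map)),
                   value = as.vector(map))
  attr_units <- attr(map, "units")
  df$units <- if (is.null(attr_units)) NA else attr_units
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  df <- read.csv(path)
  m <- matrix(NA_real_, max(df$row), max(df$col))
  m[cbind(df$row, df$col)] <- df$value
  if (!all(is.na(df$units))) attr(m, "units") <- df$units[1]
  m
}

#' Write/read a voltage movie as multipage TIFF
#'
#' Frames are stored as 32-bit float TIFF pages; frame interval and pitch
#' travel in a sidecar YAML file (`<path>.meta.yaml`).
#'
#' @param movie A [voltage_map_movie()].
#' @param path TIFF file path.
#' @return `path` (write) or a `voltage_map_movie` (read).
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF movie I/O")
  stopifnot(inherits(movie, "voltage_map_movie"))
  frames <- lapply(seq_len(dim(movie$data)[1]),
                   function(i) movie$data[i, , ])
  rng <- range(movie$data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(frames, function(f) (f - rng[1]) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  yaml::write_yaml(list(frame_ms = movie$frame_ms,
                        pitch_um = movie$pitch_um,
                        offset = rng[1], scale = scale),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF movie I/O")
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  data <- array(0, dim = c(length(frames), nrow(frames[[1]]),
                           ncol(frames[[1]])))
  for (i in seq_along(frames))
    data[i, , ] <- frames[[i]] * meta$scale + meta$offset
  voltage_map_movie(data, frame_ms = meta$frame_ms,
                    pitch_um = meta$pitch_um)
}

#' Materialize a run configuration
#'
#' A fully-defaulted, serializable description of a coupled simulation:
#' myocyte parameters, fibroblast specs, gap conductances, step controller
#' and pacing. Written/read as YAML so that every run is auditable.
#'
#' @param config A [coupled_config()].
#' @param pacing A [pacing_spec()].
#' @param controller A [step_controller()].
#' @param seed Integer seed recorded with the run (the simulator itself is
#'   deterministic).
#' @param path File to write (YAML).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, pacing = pacing_spec(),
                             controller = step_controller(), seed = 1,
                             path) {
  obj <- list(
    package = "cardiofib",
    version = as.character(utils::packageVersion("cardiofib")),
    seed = seed,
    myocyte = unclass(config$myocyte),
    g_gap = config$g_gap,
    fibroblasts = lapply(config$fibroblasts, function(f)
      list(phenotype = f$phenotype, g_scale = f$g_scale, E_rev = f$E_rev,
           Cm_CF = f$Cm_CF,
           iv = unclass(f$iv))),
    pacing = unclass(pacing),
    controller = unclass(controller))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  myo <- do.call(myocyte_params, obj$myocyte[c(
    "gNa_scale", "gK1_scale", "gNa_nominal", "gK1_nominal", "Cm_myo")])
  fibs <- lapply(obj$fibroblasts, function(f)
    fibroblast_spec(f$phenotype,
                    iv = boltzmann_iv(f$iv$A, f$iv$V_half, f$iv$k, f$iv$C),
                    g_scale = f$g_scale, E_rev = f$E_rev, Cm_CF = f$Cm_CF))
  list(config = coupled_config(myo, fibs, unlist(obj$g_gap)),
       pacing = do.call(pacing_spec, obj$pacing[c("CL", "beats", "amp",
                                                  "stim_dur")]),
       controller = step_controller(obj$controller$dt_min * 1e3,
                                    obj$controller$dt_max * 1e3,
                                    obj$controller$theta),
       seed = obj$seed)
}

#' Run the full modeling pipeline end to end
#'
#' Drives every stage in study order on synthetic inputs: clamp-trace
#' generation and Boltzmann fitting, volumetric capacitance extrapolation
#' (plus the reported-constant branch 18 pF x 1.95), young/aged coupled
#' trace simulations, a reduced APD90 sweep, reduced S1S2 failure-onset
#' runs (gK1 at 73%), and an optical-map analysis demonstration. Writes
#' stage outputs and a manifest to `outdir` and returns a comparison
#' report of the package's values against the reported reference values
#' and trend claims.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for all synthetic stages.
#' @param apd_grid,s1s2_grid Grid sizes (cells per axis) of the reduced
#'   sweeps.
#' @param movie_px Edge length of the demo movie grid.
#' @param quick If TRUE (default), use reduced problem sizes suitable for
#'   a desktop run of a few minutes.
#' @return List with `report` (data frame), `manifest` (list, also
#'   written to `manifest.yaml`).
#' @export
reproduce_paper <- function(outdir, seed = 1, apd_grid = 3, s1s2_grid = 2,
                            movie_px = 40, quick = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  report <- list()
  note <- function(quantity, value, reference, ok) {
    report[[length(report) + 1]] <<- data.frame(
      quantity = quantity, value = value, reference = reference, ok = ok)
  }

  # -- stage 1: clamp generation and Boltzmann fitting --------------------
  rec <- gen_clamp_traces(clamp_generator_spec(noise_sd_pA = 5),
                          seed = seed)
  pts <- extract_iv(rec)
  fit <- fit_boltzmann(pts, normalize = TRUE)
  iv_path <- file.path(outdir, "iv_fit.csv")
  write.csv(cbind(pts, fitted = eval_iv(fit$iv, pts$V_mV) *
                    fit$normalization), iv_path, row.names = FALSE)
  paths <- c(paths, iv_path)
  truth <- attr(rec, "ground_truth")$iv
  note("fitted V_half (mV)", fit$iv$V_half, truth$V_half,
       abs(fit$iv$V_half - truth$V_half) < 2)

  # -- stage 2: capacitance extrapolation ---------------------------------
  vols <- gen_volume_samples(n = 200, seed = seed)
  extr <- extrapolate_tissue_capacitance(vols$summary)
  rep_caps <- capacitance_report(18, 1.95)
  caps_path <- file.path(outdir, "capacitance.csv")
  write.csv(data.frame(
    quantity = c("Cm_tissue_pro_generator", "Cm_tissue_sen_generator",
                 "Cm_tissue_pro_reported", "Cm_tissue_sen_reported"),
    pF = c(extr, rep_caps)), caps_path, row.names = FALSE)
  paths <- c(paths, caps_path)
  note("senescent tissue capacitance (pF)", rep_caps[["senescent"]], 35,
       rep_caps[["senescent"]] == 35)

  # -- stage 3: young/aged trace simulations ------------------------------
  young <- run_condition_traces("young")
  aged <- run_condition_traces("aged")
  for (nm in c("young", "aged")) {
    r <- get(nm)
    write_trace_csv(r$trace, file.path(outdir, paste0(nm, "_trace.csv")))
    paths <- c(paths, file.path(outdir, paste0(nm, "_trace.csv")))
  }
  note("APD90 aged > young", aged$apd90 - young$apd90, "> 0",
       isTRUE(aged$apd90 > young$apd90))
  note("peak I_CaL aged (pA/pF)", aged$peak_ICaL, -7.4,
       abs(aged$peak_ICaL - (-7.4)) <= 0.1 * 7.4)
  note("peak I_CaL young (pA/pF)", young$peak_ICaL, -7.2,
       abs(young$peak_ICaL - (-7.2)) <= 0.1 * 7.2)
  note("peak I_gap aged (pA/pF)", aged$peak_Igap_conn, 8.1,
       abs(aged$peak_Igap_conn - 8.1) <= 0.81)
  note("peak I_gap young (pA/pF)", young$peak_Igap_conn, 7.4,
       abs(young$peak_Igap_conn - 7.4) <= 0.74)
  note("|I_CaL| aged > young", abs(aged$peak_ICaL) - abs(young$peak_ICaL),
       "> 0", isTRUE(abs(aged$peak_ICaL) > abs(young$peak_ICaL)))
  note("I_gap aged > young", aged$peak_Igap_conn - young$peak_Igap_conn,
       "> 0", isTRUE(aged$peak_Igap_conn > young$peak_Igap_conn))

  # -- stage 4: reduced APD90 sweep ---------------------------------------
  base <- coupled_config(myocyte_params(gNa_scale = 0.5),
                         list(fibroblast_spec("proliferating")), g_gap = 20)
  gv <- exp(seq(log(0.25), log(4), length.out = apd_grid))
  cmv <- seq(5, 50, length.out = apd_grid)
  sw <- sweep_apd_map(base, gv, cmv, pacing_spec(beats = 15))
  sw_path <- file.path(outdir, "apd_sweep.csv")
  write.csv(as.data.frame(as.table(sw$values)), sw_path, row.names = FALSE)
  paths <- c(paths, sw_path)
  mono_cm <- all(apply(sw$values, 1, function(r) all(diff(r) >= -0.5)))
  mono_g <- all(apply(sw$values, 2, function(c) all(diff(c) <= 0.5)))
  note("APD90 non-decreasing in Cm_CF", mono_cm, TRUE, mono_cm)
  note("APD90 non-increasing in g", mono_g, TRUE, mono_g)

  # -- stage 5: S1S2 failure onset (gK1 at 73%) ---------------------------
  spec <- s1s2_spec(n_s1 = if (quick) 6 else 8)
  onset_y <- s1s2_failure_cl(make_condition("young", gK1_scale = 0.73),
                             spec)
  onset_a <- s1s2_failure_cl(make_condition("aged", gK1_scale = 0.73),
                             spec)
  note("S1S2 onset CL aged > young (ms)",
       onset_a$onset_cl - onset_y$onset_cl, "> 0",
       isTRUE(onset_a$onset_cl > onset_y$onset_cl))

  # -- stage 6: optical-map demonstration ---------------------------------
  mv <- gen_wave_movie(rows = movie_px, cols = movie_px, apd_ms = 180,
                       cv_mps = 0.5, noise_sd = 0.02, seed = seed)
  gt <- attr(mv, "ground_truth")
  am <- apd_map(mv, gt$stim_times_ms)
  act <- activation_map(mv, t1_ms = 340)
  cv <- conduction_velocity_map(act, pitch_um = mv$pitch_um)
  write_map_csv(am, file.path(outdir, "apd_map.csv"))
  write_map_csv(cv, file.path(outdir, "cv_map.csv"))
  paths <- c(paths, file.path(outdir, c("apd_map.csv", "cv_map.csv")))
  apd_err <- abs(mean(am, na.rm = TRUE) - 180)
  cv_err <- abs(median(cv, na.rm = TRUE) - 0.5) / 0.5
  note("APD map mean error (ms)", apd_err, "< 2", apd_err < 2)
  note("CV map median error (frac)", cv_err, "< 0.05", cv_err < 0.05)

  report <- do.call(rbind, report)
  write.csv(report, file.path(outdir, "comparison_report.csv"),
            row.names = FALSE)
  paths <- c(paths, file.path(outdir, "comparison_report.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cardiofib")),
    seed = seed,
    settings = list(apd_grid = apd_grid, s1s2_grid = s1s2_grid,
                    movie_px = movie_px, quick = quick),
    outputs = as.list(tools::md5sum(paths)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  list(report = report, manifest = manifest)
}
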