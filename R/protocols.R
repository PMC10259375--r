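#' Pacing specification
#'
#' @param CL Cycle length, ms (default 350, mirroring the ex vivo
#'   optical-mapping stimulation rate).
#' @param beats Maximum number of beats (default 25).
#' @param amp Stimulus amplitude in pA/pF, or `"auto"` (default) for 1.5x
#'   the diastolic threshold found by bisection at this cycle length.
#' @param stim_dur Stimulus duration, ms (default 1).
#' @return Object of class `pacing_spec`.
#' @export
pacing_spec <- function(CL = 350, beats = 25, amp = "auto", stim_dur = 1) {
  stopifnot(CL > stim_dur, beats >= 1)
  structure(list(CL = CL, beats = beats, amp = amp, stim_dur = stim_dur),
            class = "pacing_spec")
}

#' S1S2 premature-stimulus specification
#'
#' @param s1_cl Conditioning (S1) cycle length, ms.
#' @param n_s1 Number of conditioning beats (default 8).
#' @param scan_start,scan_stop,scan_step S2 coupling-interval scan (ms);
#'   the scan runs downward from `scan_start` to `scan_stop`.
#' @param refine_ms Bisection refinement tolerance (default 1 ms).
#' @return Object of class `s1s2_spec`.
#' @export
s1s2_spec <- function(s1_cl = 350, n_s1 = 8, scan_start = 340,
                      scan_stop = 100, scan_step = 20, refine_ms = 1) {
  stopifnot(scan_start > scan_stop, scan_step > 0, n_s1 >= 1, refine_ms > 0)
  structure(list(s1_cl = s1_cl, n_s1 = n_s1, scan_start = scan_start,
                 scan_stop = scan_stop, scan_step = scan_step,
                 refine_ms = refine_ms),
            class = "s1s2_spec")
}

#' Measure action potential duration from a trace
#'
#' APD is measured from the time of maximum slope during the rising phase
#' to 50% or 90% repolarization, with the repolarization level referenced
#' to the peak-minus-diastolic amplitude and linear interpolation between
#' samples.
#'
#' @param trace A simulation trace from [integrate_coupled()] (or a list with `time`, `Vm`,
#'   `stim` entries on a uniform grid).
#' @param level Repolarization level: 50 or 90.
#' @param beat Which stimulated beat to analyze: an index or `"last"`.
#' @param upstroke_threshold Minimum max-slope (mV/ms) to count as an AP
#'   (default 10, i.e. 10 V/s).
#' @return Object of class `apd_measurement`: list with `apd` (ms, `NA` if
#'   not measurable), `status` (`"ok"`, `"no_ap"` or `"censored"`),
#'   `t_upstroke`, `t_peak`, `peak`, `diastolic` and `level`.
#' @export
measure_apd <- function(trace, level = 90, beat = "last",
                        upstroke_threshold = 10) {
  stopifnot(level %in% c(50, 90))
  t <- trace$time
  vm <- trace$Vm
  dt <- t[2] - t[1]
  onsets <- which(diff(c(0, trace$stim != 0)) == 1)
  if (length(onsets) == 0) onsets <- 1L
  if (identical(beat, "last")) beat <- length(onsets)
  if (beat < 1 || beat > length(onsets)) stop("no such stimulated beat")
  i0 <- onsets[beat]
  i1 <- if (beat < length(onsets)) onsets[beat + 1] - 1 else length(t)
  out <- list(apd = NA_real_, status = "no_ap", t_upstroke = NA_real_,
              t_peak = NA_real_, peak = NA_real_, diastolic = NA_real_,
              level = level)
  class(out) <- "apd_measurement"

  seg <- i0:i1
  dv <- diff(vm[seg]) / dt
  if (length(dv) < 2 || max(dv) < upstroke_threshold) return(out)
  iu <- which.max(dv)
  out$t_upstroke <- t[seg[1]] + (iu - 0.5) * dt
  dia_win <- max(1, i0 - round(5 / dt)):max(1, i0 - 1)
  out$diastolic <- mean(vm[dia_win])
  # peak after the upstroke
  post <- seg[seg >= seg[iu]]
  ipk <- post[which.max(vm[post])]
  out$t_peak <- t[ipk]
  out$peak <- vm[ipk]
  vlev <- out$peak - (level / 100) * (out$peak - out$diastolic)
  after <- which(vm < vlev & seq_along(vm) > ipk & seq_along(vm) <= i1)
  if (length(after) == 0) {
    out$status <- "censored"
    return(out)
  }
  ic <- after[1]
  # linear interpolation of the crossing
  frac <- (vm[ic - 1] - vlev) / (vm[ic - 1] - vm[ic])
  t_cross <- t[ic - 1] + frac * dt
  out$apd <- t_cross - out$t_upstroke
  out$status <- "ok"
  out
}

# phase-1 notch: local Vm minimum between the AP peak and the plateau dome
.notch_depth <- function(trace, apd) {
  if (apd$status != "ok") return(NA_real_)
  t <- trace$time
  vm <- trace$Vm
  dt <- t[2] - t[1]
  ipk <- which.min(abs(t - apd$t_peak))
  iend <- min(length(vm), ipk + round(60 / dt))
  seg <- vm[ipk:iend]
  # first local minimum followed by a rise (the dome); NA when monotone
  dmin <- which(diff(sign(diff(seg))) > 0) + 1
  if (length(dmin) == 0) return(NA_real_)
  seg[dmin[1]]
}

.threshold_cache <- new.env(parent = emptyenv())

.config_key <- function(config, CL) {
  paste(c(format(unlist(config$myocyte), digits = 15),
          format(config$g_gap, digits = 15),
          vapply(config$fibroblasts, function(f)
            paste(format(c(f$g_scale, f$E_rev, f$Cm_CF, unlist(f$iv[1:6])),
                         digits = 15), collapse = "|"), character(1)),
          format(CL, digits = 15)), collapse = ";")
}

#' Diastolic stimulus threshold by bisection
#'
#' Finds the minimum 1 ms rectangular stimulus amplitude that elicits an
#' action potential from the paced diastolic state at a given cycle length
#' (two conditioning beats, then bisection on a test pulse).
#'
#' @param config A [coupled_config()].
#' @param CL Cycle length, ms.
#' @param precision Bisection tolerance, pA/pF (default 0.5).
#' @param stim_dur Stimulus duration, ms.
#' @return Threshold amplitude, pA/pF.
#' @export
stim_threshold <- function(config, CL = 350, precision = 0.5, stim_dur = 1) {
  key <- .config_key(config, CL)
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  cond <- integrate_coupled(config, stim_times = c(0, CL), t_end = 2 * CL,
                            stim_amp = 60, stim_dur = stim_dur,
                            record_dt = 1)
  fires <- function(amp) {
    tr <- integrate_coupled(config, stim_times = 0, t_end = 60,
                            stim_amp = amp, stim_dur = stim_dur,
                            state0 = cond$state_final, vf0 = cond$vf_final,
                            record_dt = 0.1)
    dv <- diff(tr$Vm) / tr$record_dt
    max(tr$Vm) > 0 && max(dv) > 10
  }
  lo <- 1; hi <- 100
  if (!fires(hi)) stop("no AP elicited even at 100 pA/pF")
  while (fires(lo)) { hi <- lo; lo <- lo / 2; if (lo < 0.1) break }
  while (hi - lo > precision) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .threshold_cache[[key]] <- hi
  hi
}

.resolve_amp <- function(config, pacing) {
  if (identical(pacing$amp, "auto"))
    1.5 * stim_threshold(config, pacing$CL, stim_dur = pacing$stim_dur)
  else pacing$amp
}

#' Build the young or aged border-zone condition
#'
#' Young tissue: one myocyte coupled to four proliferating (18 pF)
#' myofibroblasts. Aged tissue: one myocyte coupled to one senescent
#' (35 pF) plus four proliferating myofibroblasts (the senescent fibroblast
#' is the first connection). Both use sodium conductance reduced to 50% of
#' normal (border-zone remodeling) and 20 nS per connection.
#'
#' @param name `"young"` or `"aged"`.
#' @param g_gap Gap conductance per connection, nS.
#' @param gNa_scale,gK1_scale Myocyte conductance scalings (gK1_scale
#'   defaults to 1 for trace simulations; use 0.73 for S1S2 runs).
#' @param Cm_pro,Cm_sen Fibroblast capacitances, pF.
#' @param gPro,gSen Fibroblast conductance scales, nS (defaults from
#'   [fibroblast_defaults()]).
#' @param Cm_myo Myocyte capacitance, pF (default per [myocyte_params()]).
#' @return A [coupled_config()].
#' @export
#' @examples
#' cfg <- make_condition("aged")
#' length(cfg$fibroblasts) # 5
make_condition <- function(name = c("young", "aged"), g_gap = 20,
                           gNa_scale = 0.5, gK1_scale = 1,
                           Cm_pro = 18, Cm_sen = 35,
                           gPro = NULL, gSen = NULL, Cm_myo = NULL) {
  name <- match.arg(name)
  myo <- if (is.null(Cm_myo)) {
    myocyte_params(gNa_scale = gNa_scale, gK1_scale = gK1_scale)
  } else {
    myocyte_params(gNa_scale = gNa_scale, gK1_scale = gK1_scale,
                   Cm_myo = Cm_myo)
  }
  pro <- function() fibroblast_spec("proliferating", g_scale = gPro,
                                    Cm_CF = Cm_pro)
  sen <- function() fibroblast_spec("senescent", g_scale = gSen,
                                    Cm_CF = Cm_sen)
  fibs <- switch(name,
    young = replicate(4, pro(), simplify = FALSE),
    aged = c(list(sen()), replicate(4, pro(), simplify = FALSE)))
  coupled_config(myocyte = myo, fibroblasts = fibs, g_gap = g_gap)
}

#' Pace a configuration to beat-to-beat APD convergence
#'
#' Paces beat by beat until APD90 changes by less than `tol` between
#' consecutive beats (or the beat budget is exhausted), then returns the
#' final beat.
#'
#' @param config A [coupled_config()].
#' @param pacing A [pacing_spec()].
#' @param tol Convergence tolerance on APD90, ms (default 0.5).
#' @param controller A [step_controller()].
#' @return List: `trace` (final beat), `apd_per_beat`, `converged`,
#'   `alternans` (TRUE when APD oscillates beat-to-beat but is stable at
#'   period 2), `amp` (stimulus amplitude used), `last_two` (traces of the
#'   last two beats when alternans is flagged).
#' @export
run_paced <- function(config, pacing = pacing_spec(), tol = 0.5,
                      controller = step_controller()) {
  amp <- .resolve_amp(config, pacing)
  state <- default_initial_state()
  vf <- NULL
  apds <- numeric(0)
  trace <- NULL
  prev_trace <- NULL
  converged <- FALSE
  for (b in seq_len(pacing$beats)) {
    prev_trace <- trace
    trace <- integrate_coupled(config, stim_times = 0, t_end = pacing$CL,
                               stim_amp = amp, stim_dur = pacing$stim_dur,
                               controller = controller,
                               state0 = state, vf0 = vf)
    state <- trace$state_final
    vf <- trace$vf_final
    m <- measure_apd(trace, 90)
    apds <- c(apds, if (m$status == "ok") m$apd else NA_real_)
    if (b >= 3 && !any(is.na(apds[(b - 1):b])) &&
        abs(apds[b] - apds[b - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  n <- length(apds)
  alternans <- FALSE
  if (!converged && n >= 4 && !any(is.na(apds[(n - 3):n]))) {
    alternans <- abs(apds[n] - apds[n - 2]) < tol &&
      abs(apds[n] - apds[n - 1]) >= tol
  }
  list(trace = trace, apd_per_beat = apds, converged = converged,
       alternans = alternans, amp = amp,
       last_two = if (alternans) list(prev_trace, trace) else NULL)
}

#' Simulate a named condition and summarize the steady-state beat
#'
#' Runs the young or aged configuration to beat-to-beat APD90 convergence
#' and reports the final beat: APD90, peak |I_CaL| density, peak
#' gap-current densities (per highlighted connection and total, both
#' normalized to the myocyte capacitance) and the phase-1 notch minimum.
#' The highlighted connection is the senescent fibroblast when present,
#' otherwise the first connection.
#'
#' @param name `"young"` or `"aged"`, or a ready [coupled_config()].
#' @param pacing A [pacing_spec()].
#' @param ... Passed to [make_condition()] when `name` is a string.
#' @return Object of class `condition_result`: list with `trace`, `apd90`,
#'   `peak_ICaL` (pA/pF, signed extremum), `peak_Igap_conn`,
#'   `peak_Igap_total` (pA/pF), `notch_mV`, `alternans`, `converged`.
#' @export
run_condition_traces <- function(name, pacing = pacing_spec(), ...) {
  config <- if (inherits(name, "coupled_config")) name
            else make_condition(name, ...)
  run <- run_paced(config, pacing)
  trace <- run$trace
  m <- measure_apd(trace, 90)
  nf <- length(config$fibroblasts)
  highlight <- 1L
  if (nf > 0) {
    phen <- vapply(config$fibroblasts, function(f) f$phenotype, character(1))
    if (any(phen == "senescent")) highlight <- which(phen == "senescent")[1]
  }
  peak_conn <- if (nf > 0) max(trace$I_gap_density[, highlight]) else NA_real_
  structure(list(
    trace = trace,
    apd90 = m$apd,
    apd_status = m$status,
    peak_ICaL = trace$I_CaL[which.max(abs(trace$I_CaL))],
    peak_Igap_conn = peak_conn,
    peak_Igap_total = if (nf > 0) max(trace$I_gap_density_total) else NA_real_,
    highlight = highlight,
    notch_mV = .notch_depth(trace, m),
    alternans = run$alternans,
    converged = run$converged,
    apd_per_beat = run$apd_per_beat),
    class = "condition_result")
}

.set_single_fib <- function(config, g_scale = NULL, Cm_CF = NULL) {
  stopifnot(length(config$fibroblasts) == 1)
  f <- config$fibroblasts[[1]]
  fibroblast_spec(f$phenotype, iv = boltzmann_iv(f$iv$A, f$iv$V_half,
                                                 f$iv$k, f$iv$C),
                  g_scale = if (is.null(g_scale)) f$g_scale else g_scale,
                  E_rev = f$E_rev,
                  Cm_CF = if (is.null(Cm_CF)) f$Cm_CF else Cm_CF)
}

#' APD90 map over fibroblast conductance and capacitance
#'
#' Paces a single-fibroblast configuration at every combination of
#' conductance scale and capacitance and records the steady-state APD90.
#'
#' @param base A [coupled_config()] with exactly one fibroblast.
#' @param g_values Conductance scales (nS).
#' @param Cm_values Capacitances (pF).
#' @param pacing A [pacing_spec()].
#' @return Object of class `sweep_result`: `axes` (named list), `values`
#'   (matrix, rows = `g_values`, cols = `Cm_values`), `status` (character
#'   matrix, `"ok"` or a failure reason).
#' @export
sweep_apd_map <- function(base, g_values, Cm_values,
                          pacing = pacing_spec()) {
  stopifnot(length(g_values) > 0, length(Cm_values) > 0)
  vals <- matrix(NA_real_, length(g_values), length(Cm_values),
                 dimnames = list(g = format(g_values), Cm = format(Cm_values)))
  status <- matrix("ok", nrow(vals), ncol(vals))
  for (i in seq_along(g_values)) {
    for (j in seq_along(Cm_values)) {
      res <- tryCatch({
        cfg <- base
        cfg$fibroblasts[[1]] <- .set_single_fib(base, g_values[i],
                                                Cm_values[j])
        r <- run_paced(cfg, pacing)
        m <- measure_apd(r$trace, 90)
        if (m$status != "ok") stop("no measurable AP (", m$status, ")")
        m$apd
      }, error = function(e) {
        status[i, j] <<- conditionMessage(e)
        NA_real_
      })
      vals[i, j] <- res
    }
  }
  structure(list(axes = list(g_scale = g_values, Cm_CF = Cm_values),
                 values = vals, status = status),
            class = "sweep_result")
}

# S2 response test: a regenerative AP within 50 ms of the S2 stimulus
.s2_success <- function(config, cond_state, cond_vf, ci, amp, s1_cl,
                        stim_dur = 1) {
  tr <- integrate_coupled(config, stim_times = c(0, ci),
                          t_end = ci + 260, stim_amp = amp,
                          stim_dur = stim_dur,
                          state0 = cond_state, vf0 = cond_vf)
  dt <- tr$record_dt
  dv <- diff(tr$Vm) / dt
  tmid <- tr$time[-1] - dt / 2
  win <- tmid >= ci & tmid <= (ci + 50)
  vwin <- tr$time >= ci & tr$time <= (ci + 50)
  any(win) && max(dv[win]) > 10 && max(tr$Vm[vwin]) > 0
}

#' S1S2 conduction-failure onset
#'
#' Applies conditioning S1 pacing followed by a single premature S2
#' stimulus, scanning the S2 coupling interval downward and refining by
#' bisection, and returns the largest coupling interval at which the S2
#' stimulus fails to elicit an action potential.
#'
#' @param config A [coupled_config()].
#' @param spec An [s1s2_spec()].
#' @return List: `onset_cl` (ms; `NA` when not bracketed), `status`
#'   (`"ok"`, `"no_failure_in_range"`, `"failure_at_start"`), `bracket`
#'   (the confirmed failing/succeeding pair), `amp`.
#' @export
s1s2_failure_cl <- function(config, spec = s1s2_spec()) {
  amp <- 1.5 * stim_threshold(config, spec$s1_cl)
  # conditioning: n_s1 - 1 full beats; S2 run starts at the last S1
  state <- default_initial_state()
  vf <- NULL
  if (spec$n_s1 > 1) {
    cond <- integrate_coupled(
      config, stim_times = seq(0, by = spec$s1_cl,
                               length.out = spec$n_s1 - 1),
      t_end = (spec$n_s1 - 1) * spec$s1_cl, stim_amp = amp,
      record_dt = 1)
    state <- cond$state_final
    vf <- cond$vf_final
  }
  test <- function(ci) .s2_success(config, state, vf, ci, amp, spec$s1_cl)

  cis <- seq(spec$scan_start, spec$scan_stop, by = -spec$scan_step)
  hi <- NA_real_  # smallest succeeding CI seen
  lo <- NA_real_  # largest failing CI seen
  for (ci in cis) {
    if (test(ci)) hi <- ci else { lo <- ci; break }
  }
  if (is.na(lo))
    return(list(onset_cl = NA_real_, status = "no_failure_in_range",
                bracket = NULL, amp = amp))
  if (is.na(hi))
    return(list(onset_cl = lo, status = "failure_at_start",
                bracket = NULL, amp = amp))
  while (hi - lo > spec$refine_ms) {
    mid <- (hi + lo) / 2
    if (test(mid)) hi <- mid else lo <- mid
  }
  list(onset_cl = lo, status = "ok", bracket = c(fail = lo, success = hi),
       amp = amp)
}

#' Conduction-failure onset map
#'
#' S1S2 failure-onset cycle length over a grid of one myocyte conductance
#' scaling (`gNa_scale` or `gK1_scale`) and fibroblast capacitance, for a
#' single-fibroblast configuration.
#'
#' @param base A [coupled_config()] with exactly one fibroblast.
#' @param axis `"gNa_scale"` or `"gK1_scale"`.
#' @param axis_values Values of the scaling factor.
#' @param Cm_values Fibroblast capacitances, pF.
#' @param spec An [s1s2_spec()].
#' @return A `sweep_result` with onset CL (ms) per cell; cells without a
#'   bracketed failure carry the status instead of a value.
#' @export
sweep_failure_map <- function(base, axis = c("gNa_scale", "gK1_scale"),
                              axis_values, Cm_values, spec = s1s2_spec()) {
  axis <- match.arg(axis)
  stopifnot(length(axis_values) > 0, length(Cm_values) > 0)
  vals <- matrix(NA_real_, length(axis_values), length(Cm_values),
                 dimnames = list(format(axis_values), format(Cm_values)))
  status <- matrix("ok", nrow(vals), ncol(vals))
  for (i in seq_along(axis_values)) {
    for (j in seq_along(Cm_values)) {
      res <- tryCatch({
        cfg <- base
        m <- cfg$myocyte
        m[[axis]] <- axis_values[i]
        cfg$myocyte <- do.call(myocyte_params, m[c(
          "gNa_scale", "gK1_scale", "gNa_nominal", "gK1_nominal", "Cm_myo")])
        cfg$fibroblasts[[1]] <- .set_single_fib(base, Cm_CF = Cm_values[j])
        r <- s1s2_failure_cl(cfg, spec)
        if (r$status != "ok" && r$status != "failure_at_start")
          stop(r$status)
        r$onset_cl
      }, error = function(e) {
        status[i, j] <<- conditionMessage(e)
        NA_real_
      })
      vals[i, j] <- res
    }
  }
  structure(list(axes = setNames(list(axis_values, Cm_values),
                                 c(axis, "Cm_CF")),
                 values = vals, status = status),
            class = "sweep_result")
}
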