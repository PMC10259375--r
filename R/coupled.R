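#' Gap-junctional current
#'
#' Ohmic coupling current between a myocyte and a fibroblast.
#'
#' @param Vm Myocyte membrane potential, mV.
#' @param Vf Fibroblast membrane potential, mV.
#' @param g_gap Gap-junctional conductance, nS (default 20).
#' @return Current in pA; positive = current leaving the myocyte into the
#'   fibroblast.
#' @export
#' @examples
#' gap_current(0, -100, 20) # 2000 pA
gap_current <- function(Vm, Vf, g_gap = 20) {
  stopifnot(is.finite(Vm), is.finite(Vf), is.finite(g_gap))
  g_gap * (Vm - Vf)
}

#' Coupled myocyte + fibroblast configuration
#'
#' One Mahajan myocyte electrically coupled to N passive fibroblasts in a
#' star topology (each fibroblast connected only to the myocyte).
#'
#' @param myocyte A [myocyte_params()] object.
#' @param fibroblasts List of [fibroblast_spec()] objects (may be empty for
#'   an uncoupled myocyte).
#' @param g_gap Gap conductance per connection, nS; scalar (recycled) or
#'   one value per fibroblast. Default 20 nS.
#' @return Object of class `coupled_config`.
#' @export
coupled_config <- function(myocyte = myocyte_params(), fibroblasts = list(),
                           g_gap = 20) {
  stopifnot(inherits(myocyte, "myocyte_params"))
  for (f in fibroblasts) stopifnot(inherits(f, "fibroblast_spec"))
  nf <- length(fibroblasts)
  if (nf > 0) g_gap <- rep_len(g_gap, nf) else g_gap <- numeric(0)
  if (any(g_gap < 0)) stop("g_gap must be non-negative")
  structure(list(myocyte = myocyte, fibroblasts = fibroblasts,
                 g_gap = g_gap),
            class = "coupled_config")
}

#' Adaptive time-step controller
#'
#' Forward-Euler step control: the step is
#' `dt = clamp(theta / max|dV/dt|, dt_min, dt_max)` over all cells.
#'
#' @param dt_min_us,dt_max_us Step bounds in microseconds (defaults 0.05
#'   and 5).
#' @param theta_mV Maximum voltage change allowed per step (default 0.1 mV).
#' @return Object of class `step_controller`.
#' @export
step_controller <- function(dt_min_us = 0.05, dt_max_us = 5, theta_mV = 0.1) {
  stopifnot(dt_min_us > 0, dt_max_us >= dt_min_us, theta_mV > 0)
  structure(list(dt_min = dt_min_us * 1e-3, dt_max = dt_max_us * 1e-3,
                 theta = theta_mV),
            class = "step_controller")
}

# resolve a fibroblast_spec into the flat description the C++ core takes
.fib_to_cpp <- function(spec) {
  iv <- spec$iv
  vh <- iv$V_half
  C <- iv$C
  if (iv$shift_mode == "horizontal") vh <- vh + iv$shift
  if (iv$shift_mode == "vertical") C <- C + iv$shift
  list(amp = spec$g_scale * .FIB_SPAN_MV, A = iv$A, vh = vh, k = iv$k,
       C = C, cm = spec$Cm_CF)
}

#' Right-hand side of the coupled system
#'
#' Derivatives of the full coupled state at one instant: the myocyte obeys
#' `dVm/dt = -I_ion - sum(I_gap)/Cm_myo + I_stim` and each fibroblast
#' `Cm_CF dVf/dt = -I_f(Vf) + I_gap`. With `g_gap = 0` the myocyte equations
#' reduce exactly to the uncoupled model.
#'
#' @param state Myocyte state vector (see [default_initial_state()]).
#' @param vf Numeric vector of fibroblast potentials, mV (one per
#'   fibroblast in `config`).
#' @param config A [coupled_config()].
#' @param I_stim Stimulus current density, pA/pF.
#' @return List with `myocyte` (state derivative), `vf` (dVf/dt, mV/ms),
#'   `I_gap` (per-connection, pA) and `currents` (myocyte breakdown).
#' @export
coupled_rhs <- function(state, vf, config, I_stim = 0) {
  stopifnot(inherits(config, "coupled_config"),
            length(vf) == length(config$fibroblasts))
  igap <- mapply(function(v, g) gap_current(state[["Vm"]], v, g),
                 vf, config$g_gap)
  igap <- as.numeric(igap)
  iext <- I_stim - sum(igap) / config$myocyte$Cm_myo
  rhs <- myocyte_rhs(state, config$myocyte, iext)
  dvf <- numeric(length(vf))
  for (i in seq_along(vf)) {
    f <- config$fibroblasts[[i]]
    dvf[i] <- (-fibroblast_current(vf[i], f) + igap[i]) / f$Cm_CF
  }
  list(myocyte = rhs$deriv, vf = dvf, I_gap = igap, currents = rhs$currents)
}

#' Integrate the coupled system
#'
#' Forward-Euler integration with the adaptive step of
#' [step_controller()], recording a uniform resampled view of the state.
#'
#' @param config A [coupled_config()].
#' @param stim_times Onset times of rectangular stimuli, ms.
#' @param t_end Duration of the run, ms.
#' @param stim_amp Stimulus amplitude, pA/pF.
#' @param stim_dur Stimulus duration, ms (default 1).
#' @param controller A [step_controller()].
#' @param state0 Initial myocyte state (default
#'   [default_initial_state()]).
#' @param vf0 Initial fibroblast potentials (default: each fibroblast's
#'   `E_rev`, the unstimulated fixed point of the passive membrane).
#' @param record_dt Sampling interval of the stored trace, ms (default
#'   0.1).
#' @return Object of class `simulation_trace`: `time` (ms), `Vm` (mV),
#'   `Vf` (matrix, one column per fibroblast), `I_CaL` (pA/pF), `I_gap`
#'   (pA, per connection), `I_gap_total` (pA), `stim` (pA/pF),
#'   `state_final`, `vf_final`, and the `config`/`controller` used.
#'   Gap-current densities normalized to the myocyte capacitance are in
#'   `I_gap_density` (per connection) and `I_gap_density_total` (pA/pF).
#' @export
integrate_coupled <- function(config, stim_times, t_end,
                              stim_amp, stim_dur = 1,
                              controller = step_controller(),
                              state0 = default_initial_state(),
                              vf0 = NULL, record_dt = 0.1) {
  stopifnot(inherits(config, "coupled_config"),
            inherits(controller, "step_controller"),
            is.finite(t_end), t_end > 0)
  nf <- length(config$fibroblasts)
  if (is.null(vf0))
    vf0 <- vapply(config$fibroblasts, function(f) f$E_rev, numeric(1))
  stopifnot(length(vf0) == nf)
  fibs <- lapply(config$fibroblasts, .fib_to_cpp)
  out <- .integrate_coupled_cpp(
    as.numeric(state0), as.numeric(vf0), config$myocyte,
    config$myocyte$Cm_myo, config$g_gap, fibs,
    as.numeric(stim_times), stim_dur, stim_amp, t_end,
    controller$dt_min, controller$dt_max, controller$theta, record_dt)
  cm <- config$myocyte$Cm_myo
  trace <- list(
    time = out$time, Vm = out$Vm, Vf = out$Vf,
    I_CaL = out$I_CaL, I_gap = out$I_gap,
    I_gap_total = if (nf > 0) rowSums(out$I_gap) else rep(0, length(out$time)),
    I_gap_density = out$I_gap / cm,
    stim = out$stim,
    state_final = out$state_final, vf_final = out$vf_final,
    config = config, controller = controller, record_dt = record_dt)
  trace$I_gap_density_total <- trace$I_gap_total / cm
  class(trace) <- "simulation_trace"
  trace
}

#' @export
print.simulation_trace <- function(x, ...) {
  nf <- ncol(x$Vf)
  cat("simulation_trace:", round(max(x$time), 1), "ms,", nf,
      "fibroblast(s), Vm range [", round(min(x$Vm), 1), ",",
      round(max(x$Vm), 1), "] mV\n")
  invisible(x)
}
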