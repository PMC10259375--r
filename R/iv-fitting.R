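#' Voltage-clamp step protocol description
#'
#' The whole-cell protocol used for fibroblast I-V characterization: a
#' holding potential followed by a family of long depolarizing/
#' hyperpolarizing steps.
#'
#' @param holding_mV Holding potential (default -60 mV).
#' @param steps_mV Step potentials (default -100 to +40 mV in 10 mV
#'   increments; at least 3 distinct values).
#' @param duration_ms Step duration (default 3000 ms).
#' @param sampling_ms Sampling interval (default 1 ms).
#' @return Object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(holding_mV = -60, steps_mV = seq(-100, 40, by = 10),
                           duration_ms = 3000, sampling_ms = 1) {
  if (length(unique(steps_mV)) < 3)
    stop("clamp protocol needs at least 3 distinct step potentials")
  if (duration_ms <= 0) stop("step duration must be positive")
  if (sampling_ms <= 0) stop("sampling interval must be positive")
  structure(list(holding_mV = holding_mV, steps_mV = steps_mV,
                 duration_ms = duration_ms, sampling_ms = sampling_ms),
            class = "clamp_protocol")
}

#' Extract tail-referenced current amplitudes from step records
#'
#' For each step potential, the amplitude is the mean current over a late
#' window during the step minus the mean tail current just after the step
#' ends. Referencing to the tail minimizes the contribution of
#' holding-level leak current.
#'
#' @param records Data frame with columns `step_mV`, `time_ms` (0 = step
#'   onset), `current_pA`; one sweep per step potential (as produced by
#'   [gen_clamp_traces()]).
#' @param protocol A [clamp_protocol()].
#' @param step_window_ms Width of the measurement window ending at the end
#'   of the step (default 100 ms).
#' @param tail_skip_ms Dead time after step end excluded from the tail
#'   window, avoiding the capacitive transient (default 5 ms).
#' @param tail_window_ms Width of the tail window (default 45 ms, i.e.
#'   5-50 ms after step end).
#' @return Data frame of class `iv_points` with columns `V_mV`,
#'   `amplitude_pA`.
#' @export
extract_iv <- function(records, protocol = clamp_protocol(),
                       step_window_ms = 100, tail_skip_ms = 5,
                       tail_window_ms = 45) {
  stopifnot(is.data.frame(records),
            all(c("step_mV", "time_ms", "current_pA") %in% names(records)))
  if (protocol$sampling_ms > 10)
    stop("sampling interval must be <= 10 ms for window averaging")
  dur <- protocol$duration_ms
  need <- dur + tail_skip_ms + tail_window_ms
  out <- lapply(protocol$steps_mV, function(v) {
    tr <- records[abs(records$step_mV - v) < 1e-9, ]
    if (nrow(tr) == 0)
      stop("protocol mismatch: no record for step potential ", v, " mV")
    if (max(tr$time_ms) < need - 1e-9)
      stop("truncated record at ", v, " mV: trace must cover the step plus ",
           tail_skip_ms + tail_window_ms, " ms of tail")
    in_step <- tr$time_ms >= (dur - step_window_ms) & tr$time_ms < dur
    in_tail <- tr$time_ms >= (dur + tail_skip_ms) &
      tr$time_ms < (dur + tail_skip_ms + tail_window_ms)
    if (!any(in_step) || !any(in_tail))
      stop("truncated record at ", v, " mV: empty measurement window")
    data.frame(V_mV = v,
               amplitude_pA = mean(tr$current_pA[in_step]) -
                 mean(tr$current_pA[in_tail]))
  })
  res <- do.call(rbind, out)
  if (any(!is.finite(res$amplitude_pA)))
    stop("non-finite amplitude extracted")
  class(res) <- c("iv_points", "data.frame")
  res
}

#' Fit a Boltzmann equation to I-V points
#'
#' Bounded nonlinear least squares of
#' `I(V) = A/(1 + exp((V_half - V)/k)) + C` with multiple starting values
#' for the slope factor (both rectification signs), since sigmoid fits are
#' multimodal in the sign of `k`. Ties are broken by lowest residual sum of
#' squares, then smallest `|k|`.
#'
#' @param points An `iv_points` data frame (columns `V_mV`,
#'   `amplitude_pA`), or any data frame with those columns.
#' @param normalize If `TRUE` (default), amplitudes are first divided by
#'   the maximum absolute amplitude, so the fitted `A`, `C` are
#'   dimensionless.
#' @param k_start Starting slope factors for the multi-start (mV).
#' @param k_bound Upper bound on `|k|` (mV); a fit with `|k|` at this bound
#'   is flagged as poorly identified.
#' @return Object of class `boltzmann_fit`: the [boltzmann_iv()] in `$iv`,
#'   plus `$rss`, `$converged`, `$poorly_identified`, `$normalization`
#'   (the divisor applied, 1 if `normalize = FALSE`) and `$n`.
#' @export
#' @examples
#' v <- seq(-100, 40, 10)
#' pts <- data.frame(V_mV = v,
#'                   amplitude_pA = 1 / (1 + exp((-15 - v) / 12)) - 0.2)
#' fit_boltzmann(pts)$iv
fit_boltzmann <- function(points, normalize = TRUE,
                          k_start = c(5, 15, 30, -5, -15, -30),
                          k_bound = 200) {
  stopifnot(all(c("V_mV", "amplitude_pA") %in% names(points)))
  v <- points$V_mV
  y <- points$amplitude_pA
  if (length(v) < 4) stop("need at least 4 I-V points")
  if (diff(range(v)) < 60) stop("I-V points must span at least 60 mV")
  if (diff(range(y)) == 0) stop("degenerate data: all amplitudes equal")
  norm <- 1
  if (normalize) {
    norm <- max(abs(y))
    y <- y / norm
  }
  span <- diff(range(y))
  best <- NULL
  for (k0 in k_start) {
    a0 <- if (k0 > 0) span else -span
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A / (1 + exp((vh - v) / k)) + C,
        start = list(A = a0, vh = median(v), k = k0, C = 0),
        lower = c(-Inf, min(v) - 200, if (k0 > 0) 0.1 else -k_bound, -Inf),
        upper = c(Inf, max(v) + 200, if (k0 > 0) k_bound else -0.1, Inf),
        data = data.frame(v = v, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    cand <- list(fit = fit, rss = rss, k = coef(fit)[["k"]])
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && abs(cand$k) < abs(best$k)))
      best <- cand
  }
  if (is.null(best))
    stop("fit failure: Boltzmann fit did not converge from any start")
  cf <- coef(best$fit)
  # canonical parameterization: the sigmoid is invariant under
  # (A, k, C) -> (-A, -k, C + A); report the k > 0 branch
  if (cf[["k"]] < 0) {
    cf[["C"]] <- cf[["C"]] + cf[["A"]]
    cf[["A"]] <- -cf[["A"]]
    cf[["k"]] <- -cf[["k"]]
  }
  poorly <- abs(cf[["k"]]) >= 0.95 * k_bound
  structure(list(
    iv = boltzmann_iv(cf[["A"]], cf[["vh"]], cf[["k"]], cf[["C"]]),
    rss = best$rss,
    converged = TRUE,
    poorly_identified = poorly,
    normalization = norm,
    n = length(v)),
    class = "boltzmann_fit")
}
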