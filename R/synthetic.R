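#' Generator specification for synthetic fibroblast clamp traces
#'
#' Ground-truth membrane description used by [gen_clamp_traces()]: a
#' Boltzmann I-V in pA, an access resistance and capacitance generating
#' the capacitive transients, an optional linear leak, and the noise level.
#'
#' @param iv True [boltzmann_iv()] in pA (default A = 1200 pA,
#'   V_half = -20 mV, k = 12 mV, C = -240 pA, an outwardly rectifying
#'   myofibroblast-like curve).
#' @param Cm_pF Cell capacitance (default 130 pF, in-vitro scale).
#' @param Rs_MOhm Access resistance (default 10 MOhm).
#' @param g_leak_nS Linear leak conductance (default 0; the tail-referenced
#'   extraction is designed to null holding-level leak).
#' @param E_leak_mV Leak reversal (default -20 mV).
#' @param noise_sd_pA Gaussian noise SD per sample (default 0).
#' @return List of class `clamp_generator_spec`.
#' @export
clamp_generator_spec <- function(iv = boltzmann_iv(1200, -20, 12, -240),
                                 Cm_pF = 130, Rs_MOhm = 10,
                                 g_leak_nS = 0, E_leak_mV = -20,
                                 noise_sd_pA = 0) {
  stopifnot(inherits(iv, "boltzmann_iv"), Cm_pF > 0, Rs_MOhm > 0,
            g_leak_nS >= 0, noise_sd_pA >= 0)
  structure(list(iv = iv, Cm_pF = Cm_pF, Rs_MOhm = Rs_MOhm,
                 g_leak_nS = g_leak_nS, E_leak_mV = E_leak_mV,
                 noise_sd_pA = noise_sd_pA),
            class = "clamp_generator_spec")
}

#' Generate synthetic voltage-clamp step records
#'
#' Emulates the fibroblast clamp experiment (holding at -60 mV, 3 s steps
#' from -100 to +40 mV): each sweep is the sum of a capacitive transient
#' (RC decay with the spec's access resistance and capacitance at each
#' voltage jump), the steady Boltzmann membrane current, a linear leak and
#' seeded Gaussian noise. The attached ground truth contains both the true
#' curve and the amplitudes the tail-referenced extraction should recover.
#'
#' @param spec A [clamp_generator_spec()].
#' @param protocol A [clamp_protocol()].
#' @param seed Integer seed fixing all randomness.
#' @param post_ms Recorded tail length after the step (default 100 ms).
#' @return Data frame (`step_mV`, `time_ms`, `command_mV`, `current_pA`)
#'   with attribute `ground_truth`: list with `iv` (true curve), and
#'   `expected_amplitude` (data frame `V_mV`, `amplitude_pA` of the
#'   noiseless tail-referenced amplitudes).
#' @export
gen_clamp_traces <- function(spec = clamp_generator_spec(),
                             protocol = clamp_protocol(), seed = 1,
                             post_ms = 100) {
  stopifnot(inherits(spec, "clamp_generator_spec"),
            inherits(protocol, "clamp_protocol"))
  set.seed(seed)
  hold <- protocol$holding_mV
  dur <- protocol$duration_ms
  dt <- protocol$sampling_ms
  tau_ms <- spec$Rs_MOhm * spec$Cm_pF * 1e-3
  steady <- function(v) {
    eval_iv(spec$iv, v) + spec$g_leak_nS * (v - spec$E_leak_mV)
  }
  times <- seq(0, dur + post_ms, by = dt)
  out <- lapply(protocol$steps_mV, function(v) {
    cmd <- ifelse(times < dur, v, hold)
    i <- ifelse(times < dur, steady(v), steady(hold))
    # capacitive transients at the two voltage jumps
    i <- i + (v - hold) / spec$Rs_MOhm * 1000 * exp(-times / tau_ms)
    post <- times >= dur
    i[post] <- i[post] + (hold - v) / spec$Rs_MOhm * 1000 *
      exp(-(times[post] - dur) / tau_ms)
    if (spec$noise_sd_pA > 0)
      i <- i + rnorm(length(i), 0, spec$noise_sd_pA)
    data.frame(step_mV = v, time_ms = times, command_mV = cmd,
               current_pA = i)
  })
  records <- do.call(rbind, out)
  truth <- list(
    iv = spec$iv,
    expected_amplitude = data.frame(
      V_mV = protocol$steps_mV,
      amplitude_pA = steady(protocol$steps_mV) - steady(hold)))
  attr(records, "ground_truth") <- truth
  records
}

#' Generate seeded cell-volume samples
#'
#' Lognormal volume samples for the four measurement groups (proliferating
#' and senescent, in tissue and in culture), emulating the confocal
#' volumetry that feeds the capacitance extrapolation. Defaults are chosen
#' so that the group means reproduce the reference conditions: a tissue
#' senescent/proliferating surface-area ratio of 1.95 and a
#' tissue-extrapolated proliferating capacitance of 18 pF from the
#' measured in-vitro 128.7 pF.
#'
#' @param n Samples per group (>= 2).
#' @param seed Integer seed.
#' @param median_tissue_pro Median proliferating in-tissue volume, um^3.
#' @param area_ratio Target tissue senescent/proliferating surface-area
#'   ratio (volume ratio is `area_ratio^(3/2)`), default 1.95.
#' @param median_culture_pro,median_culture_sen Median culture volumes,
#'   um^3.
#' @param gsd Geometric SD of all groups (default 1.6).
#' @param Cm_invitro_pro,Cm_invitro_sen Measured in-vitro capacitances, pF.
#' @return List: `summary` (a [volumetric_summary()] built from group
#'   means), `samples` (long data frame `group`, `volume_um3`),
#'   `area_ratio_target`.
#' @export
gen_volume_samples <- function(n = 50, seed = 1,
                               median_tissue_pro = 1200,
                               area_ratio = 1.95,
                               median_culture_pro = 22900,
                               median_culture_sen = 24700,
                               gsd = 1.6,
                               Cm_invitro_pro = 128.7,
                               Cm_invitro_sen = 138.4) {
  stopifnot(n >= 2, median_tissue_pro > 0, area_ratio > 0, gsd >= 1)
  set.seed(seed)
  medians <- c(tissue_pro = median_tissue_pro,
               tissue_sen = median_tissue_pro * area_ratio^(3 / 2),
               culture_pro = median_culture_pro,
               culture_sen = median_culture_sen)
  sdlog <- log(gsd)
  samples <- do.call(rbind, lapply(names(medians), function(g) {
    data.frame(group = g,
               volume_um3 = rlnorm(n, meanlog = log(medians[[g]]),
                                   sdlog = sdlog))
  }))
  means <- tapply(samples$volume_um3, samples$group, mean)
  summary <- volumetric_summary(
    vol_tissue_pro = means[["tissue_pro"]],
    vol_tissue_sen = means[["tissue_sen"]],
    vol_culture_pro = means[["culture_pro"]],
    vol_culture_sen = means[["culture_sen"]],
    Cm_invitro_pro = Cm_invitro_pro,
    Cm_invitro_sen = Cm_invitro_sen)
  list(summary = summary, samples = samples, area_ratio_target = area_ratio)
}

# Stylized AP waveform: sigmoid upstroke with maximum slope at t = 0, a
# plateau, then a linear phase-3 ramp reaching baseline exactly at t = apd.
# The slope corner at baseline arrival is the maximum of the second
# temporal derivative, and because a corner's curvature spreads
# symmetrically under any symmetric smoothing kernel, the detected
# location is unbiased under the analysis pipeline's filters. Ground
# truth is therefore analytic: activation 0, repolarization apd.
.stylized_ap <- function(t, apd, rise_ms = 1, ramp_ms = NULL) {
  if (is.null(ramp_ms)) ramp_ms <- min(45, 0.3 * apd)
  up <- 1 / (1 + exp(-4 * t / rise_ms))
  shape <- ifelse(t < apd - ramp_ms, 1, pmax(0, (apd - t) / ramp_ms))
  up * shape
}

#' Generate a synthetic planar-wave voltage movie
#'
#' A planar wavefront of stylized action potentials (sigmoid upstroke,
#' plateau, linear phase-3 ramp with a slope corner at baseline arrival)
#' translating across the
#' grid at a set conduction velocity and angle, with a per-pixel APD field
#' and seeded additive Gaussian noise; or, in VF mode, per-pixel periodic
#' activity at a prescribed dominant-frequency field. Ground-truth maps
#' are attached for every quantity the analysis pipeline estimates.
#'
#' @param rows,cols Grid size (>= 32 each).
#' @param n_beats Number of paced beats (>= 3; ignored in VF mode).
#' @param cl_ms Pacing cycle length, ms.
#' @param apd_ms APD ground truth: scalar or rows x cols matrix (ms).
#' @param cv_mps Conduction velocity, m/s (> 0).
#' @param angle_deg Wave propagation angle, degrees (0 = along columns).
#' @param frame_ms Frame interval, ms (default 1, the standard 1 kHz
#'   optical-mapping acquisition rate).
#' @param pitch_um Pixel pitch, um (default 200).
#' @param noise_sd Additive Gaussian noise SD (AP amplitude is 1).
#' @param seed Integer seed.
#' @param mode `"paced"` (default) or `"vf"`.
#' @param freq_hz For VF mode: dominant frequency, scalar or rows x cols
#'   matrix (Hz).
#' @param vf_waveform `"ap"` (periodic stylized APs) or `"sine"`.
#' @param duration_ms Movie length (default `n_beats * cl_ms` for paced
#'   mode, 4000 ms for VF mode).
#' @return A [voltage_map_movie()] with attribute `ground_truth`: list
#'   with `activation_ms` (first-beat activation map), `apd_ms`, `cv_mps`,
#'   `freq_hz` (VF mode), `stim_times_ms`.
#' @export
gen_wave_movie <- function(rows = 40, cols = 40, n_beats = 3, cl_ms = 350,
                           apd_ms = 180, cv_mps = 0.5, angle_deg = 0,
                           frame_ms = 1, pitch_um = 200, noise_sd = 0,
                           seed = 1, mode = c("paced", "vf"),
                           freq_hz = 14, vf_waveform = c("ap", "sine"),
                           duration_ms = NULL) {
  mode <- match.arg(mode)
  vf_waveform <- match.arg(vf_waveform)
  if (rows < 32 || cols < 32) stop("grid must be at least 32 x 32")
  set.seed(seed)
  apd <- if (is.matrix(apd_ms)) apd_ms else matrix(apd_ms, rows, cols)
  stopifnot(all(dim(apd) == c(rows, cols)))

  if (mode == "paced") {
    if (n_beats < 3) stop("need at least 3 beats")
    if (cv_mps <= 0) stop("conduction velocity must be positive")
    if (is.null(duration_ms)) duration_ms <- n_beats * cl_ms
    # activation delay across the grid, ms
    ang <- angle_deg * pi / 180
    proj <- outer(seq_len(rows) - 1, seq_len(cols) - 1,
                  function(r, c) c * cos(ang) + r * sin(ang))
    proj <- proj - min(proj)
    delay <- proj * pitch_um / (cv_mps * 1000) # um / (um/ms)
    if (max(delay) < frame_ms)
      stop("temporal-resolution error: wave crosses the grid in less ",
           "than one frame; reduce cv_mps or enlarge the grid")
    nfr <- floor(duration_ms / frame_ms)
    tvec <- (seq_len(nfr) - 1) * frame_ms
    stim_times <- seq(0, by = cl_ms, length.out = n_beats)
    lead_ms <- 10 # activation occurs this long after each beat onset
    data <- array(0, dim = c(nfr, rows, cols))
    for (b in stim_times) {
      for (r in seq_len(rows)) {
        dr <- delay[r, ]
        for (c in seq_len(cols)) {
          tt <- tvec - (b + lead_ms + dr[c])
          data[, r, c] <- data[, r, c] + .stylized_ap(tt, apd[r, c])
        }
      }
    }
    truth <- list(activation_ms = delay + lead_ms, apd_ms = apd,
                  cv_mps = cv_mps, stim_times_ms = stim_times)
  } else {
    freq <- if (is.matrix(freq_hz)) freq_hz else matrix(freq_hz, rows, cols)
    stopifnot(all(dim(freq) == c(rows, cols)), all(freq > 0))
    if (is.null(duration_ms)) duration_ms <- 4000
    nfr <- floor(duration_ms / frame_ms)
    tvec <- (seq_len(nfr) - 1) * frame_ms
    data <- array(0, dim = c(nfr, rows, cols))
    for (r in seq_len(rows)) {
      for (c in seq_len(cols)) {
        f <- freq[r, c]
        if (vf_waveform == "sine") {
          data[, r, c] <- 0.5 + 0.5 * sin(2 * pi * f * tvec / 1000)
        } else {
          period <- 1000 / f
          phase <- tvec %% period
          data[, r, c] <- .stylized_ap(phase - 2, 0.4 * period)
        }
      }
    }
    truth <- list(freq_hz = freq, apd_ms = NULL, cv_mps = NULL,
                  stim_times_ms = NULL)
  }
  if (noise_sd > 0)
    data <- data + array(rnorm(length(data), 0, noise_sd), dim = dim(data))
  movie <- voltage_map_movie(data, frame_ms = frame_ms, pitch_um = pitch_um)
  attr(movie, "ground_truth") <- truth
  movie
}
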