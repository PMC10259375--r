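#' Fluorescence voltage-mapping movie
#'
#' Container for an optical-mapping recording: a frames x rows x cols
#' array of fluorescence values, the frame interval and the pixel pitch.
#'
#' @param data Numeric 3-D array, frames x rows x cols.
#' @param frame_ms Frame interval, ms.
#' @param pitch_um Pixel pitch, um (default 200).
#' @param mask Optional logical rows x cols matrix, `TRUE` = valid pixel.
#' @return Object of class `voltage_map_movie`.
#' @export
voltage_map_movie <- function(data, frame_ms, pitch_um = 200, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, dim(data)[1] >= 2,
            frame_ms > 0, pitch_um > 0)
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[2], dim(data)[3])
  stopifnot(identical(dim(mask), dim(data)[2:3]))
  structure(list(data = data, frame_ms = frame_ms, pitch_um = pitch_um,
                 mask = mask),
            class = "voltage_map_movie")
}

#' Temporal polynomial filter
#'
#' Moving local least-squares cubic fit over a 13-sample window
#' (Savitzky-Golay smoothing with the stated order and length); exactly
#' reproduces polynomials up to the filter order, including at the series
#' edges.
#'
#' @param x Numeric series (length >= `window`).
#' @param order Polynomial order (default 3).
#' @param window Window length in samples (odd, default 13).
#' @return Filtered series, same length as `x`.
#' @export
temporal_polyfilter <- function(x, order = 3, window = 13) {
  if (length(x) < window)
    stop("series too short for the polynomial filter: need >= ", window,
         " samples, got ", length(x))
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

# quadratic sub-sample refinement of a discrete argmax
.parabolic_refine <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < 1e-300) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

#' Activation time from a fluorescence upstroke
#'
#' Time of the maximum first temporal derivative (central differences with
#' parabolic sub-sample refinement).
#'
#' @param series Filtered fluorescence series.
#' @param frame_ms Frame interval, ms.
#' @param noise_floor Minimum derivative (per ms) to accept as an
#'   activation; default `4 * mad(diff(series))/frame_ms`.
#' @return Activation time in ms from the first sample, or `NA` with
#'   attribute `status = "no_activation"`. A constant-derivative tie is
#'   broken to the earliest sample and flagged with
#'   `status = "degenerate"`.
#' @export
activation_time <- function(series, frame_ms, noise_floor = NULL) {
  n <- length(series)
  if (n < 3) return(structure(NA_real_, status = "no_activation"))
  d <- c(series[2] - series[1],
         (series[3:n] - series[1:(n - 2)]) / 2,
         series[n] - series[n - 1]) / frame_ms
  if (is.null(noise_floor))
    noise_floor <- max(4 * stats::mad(diff(series)) / frame_ms, 1e-12)
  dmax <- max(d)
  if (!is.finite(dmax) || dmax < noise_floor)
    return(structure(NA_real_, status = "no_activation"))
  ties <- which(d > dmax - 1e-12 * max(1, abs(dmax)))
  i <- ties[1]
  status <- if (length(ties) > 1) "degenerate" else "ok"
  structure((.parabolic_refine(d, i) - 1) * frame_ms, status = status)
}

#' Repolarization time from the second derivative
#'
#' Time of the maximum second temporal derivative within the post-peak
#' search window. The second derivative is estimated with a local cubic
#' polynomial (Savitzky-Golay derivative kernel spanning ~25 ms), and the
#' search is restricted to the repolarization limb: from the 50%-amplitude
#' crossing down to shortly after the signal first returns near baseline.
#' This keeps the detector on the terminal repolarization bend and away
#' from upstroke curvature and baseline noise.
#'
#' @param series Filtered fluorescence series.
#' @param frame_ms Frame interval, ms.
#' @param search_end_ms End of the search window, ms from the first sample
#'   (default: end of the series).
#' @return Repolarization time in ms, or `NA` with attribute
#'   `status = "no_repolarization"`.
#' @export
repolarization_time <- function(series, frame_ms, search_end_ms = NULL) {
  n <- length(series)
  if (n < 5) return(structure(NA_real_, status = "no_repolarization"))
  ipk <- which.max(series)
  iend <- if (is.null(search_end_ms)) n
          else min(n, floor(search_end_ms / frame_ms) + 1)
  if (iend - ipk < 3)
    return(structure(NA_real_, status = "no_repolarization"))
  # second derivative via a local cubic fit over ~25 ms
  nk <- floor(25 / frame_ms)
  if (nk %% 2 == 0) nk <- nk + 1
  nk <- max(5, min(nk, if (n %% 2 == 1) n else n - 1))
  d2 <- as.numeric(signal::sgolayfilt(series, p = 3, n = nk, m = 2,
                                      ts = frame_ms))
  base <- min(series[ipk:iend])
  amp <- series[ipk] - base
  if (amp <= 0) return(structure(NA_real_, status = "no_repolarization"))
  i50 <- which(seq_len(n) > ipk & series < base + 0.5 * amp)
  istart <- if (length(i50) > 0) i50[1] else ipk + 1
  ibase <- which(seq_len(n) > istart & series < base + 0.03 * amp)
  ilast <- if (length(ibase) > 0)
    min(iend, ibase[1] + ceiling(15 / frame_ms)) else iend
  idx <- seq.int(istart, max(istart, ilast))
  idx <- idx[idx <= iend & idx >= 2 & idx <= n - 1]
  if (length(idx) == 0)
    return(structure(NA_real_, status = "no_repolarization"))
  j <- idx[which.max(d2[idx])]
  if (!is.finite(d2[j]))
    return(structure(NA_real_, status = "no_repolarization"))
  structure((.parabolic_refine(d2, j) - 1) * frame_ms, status = "ok")
}

.new_map <- function(movie, units) {
  m <- matrix(NA_real_, dim(movie$data)[2], dim(movie$data)[3])
  attr(m, "units") <- units
  m
}

#' Per-pixel APD map
#'
#' APD per pixel as the difference between repolarization and activation
#' time, averaged over beats; per-pixel failures become `NA` without
#' aborting the map.
#'
#' @param movie A [voltage_map_movie()].
#' @param stim_times_ms Stimulus (beat onset) times, ms.
#' @param cl_ms Cycle length, ms (default inferred from `stim_times_ms`).
#' @param filter Apply [temporal_polyfilter()] first (default TRUE).
#' @return rows x cols matrix of APD in ms (attribute `units = "ms"`).
#' @export
apd_map <- function(movie, stim_times_ms, cl_ms = NULL, filter = TRUE) {
  stopifnot(inherits(movie, "voltage_map_movie"))
  if (is.null(cl_ms)) {
    cl_ms <- if (length(stim_times_ms) > 1) diff(stim_times_ms)[1]
             else dim(movie$data)[1] * movie$frame_ms
  }
  dt <- movie$frame_ms
  nfr <- dim(movie$data)[1]
  out <- .new_map(movie, "ms")
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      if (!movie$mask[r, c]) next
      series <- movie$data[, r, c]
      if (filter && length(series) >= 13)
        series <- temporal_polyfilter(series)
      apds <- c()
      for (t0 in stim_times_ms) {
        i0 <- floor(t0 / dt) + 1
        i1 <- min(nfr, floor((t0 + cl_ms) / dt))
        if (i1 - i0 < 10) next
        seg <- series[i0:i1]
        act <- activation_time(seg, dt)
        if (is.na(act)) next
        rep_t <- repolarization_time(seg, dt, search_end_ms = 0.9 * cl_ms)
        if (is.na(rep_t) || rep_t <= act) next
        apds <- c(apds, rep_t - act)
      }
      if (length(apds) > 0) out[r, c] <- mean(apds)
    }
  }
  out
}

#' Per-pixel activation-time map for one beat
#'
#' @inheritParams apd_map
#' @param t0_ms,t1_ms Analysis window, ms.
#' @return rows x cols matrix of activation times (ms).
#' @export
activation_map <- function(movie, t0_ms = 0, t1_ms = NULL, filter = TRUE) {
  stopifnot(inherits(movie, "voltage_map_movie"))
  dt <- movie$frame_ms
  nfr <- dim(movie$data)[1]
  if (is.null(t1_ms)) t1_ms <- nfr * dt
  i0 <- max(1, floor(t0_ms / dt) + 1)
  i1 <- min(nfr, floor(t1_ms / dt))
  out <- .new_map(movie, "ms")
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      if (!movie$mask[r, c]) next
      series <- movie$data[i0:i1, r, c]
      if (filter && length(series) >= 13)
        series <- temporal_polyfilter(series)
      a <- activation_time(series, dt)
      if (!is.na(a)) out[r, c] <- a + (i0 - 1) * dt
    }
  }
  out
}

#' Conduction-velocity map from activation-time gradients
#'
#' Least-squares plane fit of activation time over a centered window
#' (default 11 x 11 pixels); speed is the inverse gradient magnitude
#' converted with the pixel pitch, in m/s. Pixels whose window has fewer
#' than `min_valid_frac` valid neighbors, or an (effectively) zero
#' gradient, become `NA`.
#'
#' @param act_map Activation-time matrix (ms), as from [activation_map()].
#' @param pitch_um Pixel pitch, um (default 200).
#' @param window Window size in pixels (odd, default 11).
#' @param min_valid_frac Minimum fraction of valid neighbors (default 0.6).
#' @return rows x cols matrix of speeds (m/s, attribute `units`).
#' @export
conduction_velocity_map <- function(act_map, pitch_um = 200, window = 11,
                                    min_valid_frac = 0.6) {
  stopifnot(window %% 2 == 1, pitch_um > 0)
  h <- (window - 1) / 2
  nr <- nrow(act_map); nc <- ncol(act_map)
  out <- matrix(NA_real_, nr, nc)
  attr(out, "units") <- "m/s"
  offs <- seq(-h, h)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(act_map[r, c])) next
      rr <- r + offs; cc <- c + offs
      rok <- rr >= 1 & rr <= nr; cok <- cc >= 1 & cc <= nc
      sub <- matrix(NA_real_, window, window)
      sub[rok, cok] <- act_map[rr[rok], cc[cok], drop = FALSE]
      valid <- !is.na(sub)
      if (sum(valid) < min_valid_frac * window^2) next
      ys <- matrix(offs, window, window)        # row offset
      xs <- matrix(offs, window, window, byrow = TRUE) # col offset
      tv <- sub[valid]; xv <- xs[valid]; yv <- ys[valid]
      # centered least-squares plane: t = a + gx*x + gy*y
      xc <- xv - mean(xv); yc <- yv - mean(yv); tc <- tv - mean(tv)
      sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
      det <- sxx * syy - sxy^2
      if (det < 1e-9) next
      gx <- (syy * sum(xc * tc) - sxy * sum(yc * tc)) / det
      gy <- (sxx * sum(yc * tc) - sxy * sum(xc * tc)) / det
      gmag <- sqrt(gx^2 + gy^2) # ms per pixel
      if (gmag < 1e-6) next     # simultaneous activation: speed undefined
      out[r, c] <- pitch_um / gmag * 1e-3 # um/ms -> m/s
    }
  }
  out
}

# Welch-style averaged periodogram (mean-removed, Hann window, 50% overlap)
.welch_psd <- function(x, fs, n_segments = 8) {
  n <- length(x)
  seg_len <- max(16, 2^floor(log2(2 * n / (n_segments + 1))))
  if (seg_len > n) seg_len <- 2^floor(log2(n))
  step <- seg_len / 2
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(seg_len %/% 2 + 1)]
  }
  p <- acc / length(starts)
  f <- (seq_len(seg_len %/% 2 + 1) - 1) * fs / seg_len
  list(freq = f, power = p, resolution = fs / seg_len)
}

#' Dominant-frequency map
#'
#' Per-pixel dominant frequency from a segment-averaged, Hann-windowed
#' periodogram of the mean-removed signal: the spectral peak within the
#' configured band. Pixels whose band peak does not stand above the
#' spectral noise floor are flagged low-confidence (`NA`).
#'
#' @param movie A [voltage_map_movie()] covering at least 2 s.
#' @param band Frequency band searched, Hz (default 5-40).
#' @param min_peak_ratio Peak power must exceed this multiple of the
#'   median band power to be accepted (default 5).
#' @return rows x cols matrix of frequencies (Hz, attribute `units`), with
#'   attribute `resolution_hz` (frequency bin width).
#' @export
dominant_frequency_map <- function(movie, band = c(5, 40),
                                   min_peak_ratio = 5) {
  stopifnot(inherits(movie, "voltage_map_movie"))
  fs <- 1000 / movie$frame_ms
  nfr <- dim(movie$data)[1]
  if (nfr * movie$frame_ms < 2000)
    stop("dominant-frequency analysis needs at least 2 s of signal")
  out <- .new_map(movie, "Hz")
  res <- NA_real_
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      if (!movie$mask[r, c]) next
      psd <- .welch_psd(movie$data[, r, c], fs)
      res <- psd$resolution
      inband <- psd$freq >= band[1] & psd$freq <= band[2]
      if (!any(inband)) next
      p <- psd$power[inband]
      f <- psd$freq[inband]
      if (max(p) <= 0 || max(p) < min_peak_ratio * stats::median(p)) next
      out[r, c] <- f[which.max(p)]
    }
  }
  attr(out, "resolution_hz") <- res
  out
}
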