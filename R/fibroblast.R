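#' Boltzmann current-voltage relation
#'
#' Sigmoid summary of a whole-cell I-V curve,
#' `I(V) = A / (1 + exp((V_half - V)/k)) + C`, optionally shifted so that the
#' curve crosses zero at a prescribed reversal potential (see
#' [shift_to_reversal()]).
#'
#' @param A Amplitude (normalized units or pA).
#' @param V_half Half-activation potential (mV).
#' @param k Slope factor (mV, nonzero; positive = outwardly rectifying).
#' @param C Offset, same units as `A`.
#' @param shift Reversal-enforcing shift already applied: a horizontal
#'   translation (mV) or a vertical offset (units of `A`), per `shift_mode`.
#' @param shift_mode One of `"none"`, `"horizontal"`, `"vertical"`.
#' @return Object of class `boltzmann_iv`.
#' @export
#' @examples
#' iv <- boltzmann_iv(A = 1, V_half = -20, k = 10, C = -0.3)
#' eval_iv(iv, c(-80, 0, 40))
boltzmann_iv <- function(A, V_half, k, C = 0, shift = 0,
                         shift_mode = c("none", "horizontal", "vertical")) {
  shift_mode <- match.arg(shift_mode)
  if (k == 0) stop("Boltzmann slope k must be nonzero")
  structure(list(A = A, V_half = V_half, k = k, C = C,
                 shift = shift, shift_mode = shift_mode),
            class = "boltzmann_iv")
}

#' Evaluate a Boltzmann I-V curve
#'
#' @param iv A [boltzmann_iv()] object.
#' @param V Membrane potential(s), mV.
#' @return Current in the units of `iv$A`.
#' @export
eval_iv <- function(iv, V) {
  stopifnot(inherits(iv, "boltzmann_iv"))
  vh <- iv$V_half
  off <- iv$C
  if (iv$shift_mode == "horizontal") vh <- vh + iv$shift
  if (iv$shift_mode == "vertical") off <- off + iv$shift
  iv$A / (1 + exp((vh - V) / iv$k)) + off
}

#' Shift a Boltzmann curve to enforce a reversal potential
#'
#' Translates the curve so that `I(E_rev) = 0`, emulating the referencing of
#' the fitted myofibroblast I-V to the resting potential measured with sharp
#' electrodes. A horizontal translation is used when the unshifted sigmoid
#' attains zero (i.e. `-C/A` lies strictly inside (0, 1)); otherwise the
#' curve is offset vertically. The mode actually used is recorded in the
#' returned object.
#'
#' @param iv A [boltzmann_iv()] object (any prior shift is discarded).
#' @param E_rev Target reversal potential, mV.
#' @return A `boltzmann_iv` with `shift`/`shift_mode` set so that
#'   `eval_iv(., E_rev)` is zero to machine precision.
#' @export
shift_to_reversal <- function(iv, E_rev) {
  stopifnot(inherits(iv, "boltzmann_iv"))
  iv$shift <- 0
  iv$shift_mode <- "none"
  frac <- -iv$C / iv$A
  if (is.finite(frac) && frac > 0 && frac < 1) {
    # solve A/(1+exp((V_half + shift - E_rev)/k)) + C = 0 for the shift
    iv$shift <- iv$k * log(1 / frac - 1) - (iv$V_half - E_rev)
    iv$shift_mode <- "horizontal"
  } else {
    iv$shift <- -(iv$A / (1 + exp((iv$V_half - E_rev) / iv$k)) + iv$C)
    iv$shift_mode <- "vertical"
  }
  resid <- eval_iv(iv, E_rev)
  if (abs(resid) > 1e-9)
    stop("reversal shift failed: |I(E_rev)| = ", abs(resid))
  iv
}

.fib_defaults_cache <- new.env(parent = emptyenv())

#' Default fibroblast membrane parameters
#'
#' Reads the versioned default configuration shipped with the package
#' (`inst/extdata/fibroblast_defaults.yaml`): normalized Boltzmann I-V
#' parameters obtained by fitting the synthetic clamp generator's default
#' current shape through the package's own extraction/fitting pipeline, the
#' conductance scales gPro/gSen, the reversal potential and the
#' tissue-extrapolated capacitances.
#'
#' @return Named list with elements `proliferating` and `senescent`.
#' @export
fibroblast_defaults <- function() {
  if (is.null(.fib_defaults_cache$defaults)) {
    path <- system.file("extdata", "fibroblast_defaults.yaml",
                        package = "cardiofib")
    .fib_defaults_cache$defaults <- yaml::read_yaml(path)
  }
  .fib_defaults_cache$defaults
}

#' Passive fibroblast membrane specification
#'
#' A cardiac myofibroblast modeled as a passive, memoryless membrane: a
#' (shifted) Boltzmann I-V curve scaled by a conductance constant, a
#' reversal/resting potential and a whole-cell capacitance. The two
#' phenotypes differ by default only in capacitance (18 pF proliferating vs
#' 35 pF senescent, the tissue-extrapolated values).
#'
#' @param phenotype `"proliferating"` or `"senescent"`.
#' @param iv A [boltzmann_iv()]; default read from [fibroblast_defaults()].
#'   It is re-shifted to `E_rev` on construction.
#' @param g_scale Conductance scale gPro or gSen (nS for the normalized
#'   default I-V).
#' @param E_rev Reversal (resting) potential, mV.
#' @param Cm_CF Whole-cell capacitance, pF.
#' @return Object of class `fibroblast_spec`.
#' @export
#' @examples
#' f <- fibroblast_spec("senescent")
#' fibroblast_current(seq(-100, 40, 20), f)
fibroblast_spec <- function(phenotype = c("proliferating", "senescent"),
                            iv = NULL, g_scale = NULL, E_rev = NULL,
                            Cm_CF = NULL) {
  phenotype <- match.arg(phenotype)
  d <- fibroblast_defaults()[[phenotype]]
  if (is.null(iv))
    iv <- boltzmann_iv(d$iv$A, d$iv$V_half, d$iv$k, d$iv$C)
  if (is.null(g_scale)) g_scale <- d$g_scale
  if (is.null(E_rev)) E_rev <- d$E_rev
  if (is.null(Cm_CF)) Cm_CF <- d$Cm_CF
  stopifnot(Cm_CF > 0, g_scale >= 0)
  iv <- shift_to_reversal(iv, E_rev)
  structure(list(phenotype = phenotype, iv = iv, g_scale = g_scale,
                 E_rev = E_rev, Cm_CF = Cm_CF),
            class = "fibroblast_spec")
}

# Voltage span of the reference clamp protocol; a normalized I-V scaled by
# g_scale (nS) carries g_scale * span pA at unit normalized amplitude.
.FIB_SPAN_MV <- 140

#' Fibroblast membrane current
#'
#' Instantaneous (state-free) membrane current of a passive myofibroblast:
#' `I = g_scale * 140 mV * B(V)` where `B` is the normalized, reversal-shifted
#' Boltzmann curve. With a normalized curve, `g_scale` in nS is the
#' conductance of the linear resistor that would carry the same current over
#' the 140 mV span of the clamp protocol at unit amplitude.
#'
#' @param Vf Fibroblast membrane potential(s), mV.
#' @param spec A [fibroblast_spec()].
#' @return Current in pA (positive = outward).
#' @export
fibroblast_current <- function(Vf, spec) {
  stopifnot(inherits(spec, "fibroblast_spec"))
  spec$g_scale * .FIB_SPAN_MV * eval_iv(spec$iv, Vf)
}

#' Surface area of a sphere of given volume
#'
#' `A = (36 pi)^(1/3) V^(2/3)`, used to convert mean cell volumes to
#' relative membrane areas under the spherical-cell assumption.
#'
#' @param V Volume(s), um^3 (must be positive).
#' @return Area(s), um^2.
#' @export
#' @examples
#' sphere_area_from_volume(4 * pi / 3) # unit sphere: 4*pi
sphere_area_from_volume <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0))
    stop("volume must be positive and finite")
  (36 * pi)^(1 / 3) * V^(2 / 3)
}

#' Volumetric summary for capacitance extrapolation
#'
#' Mean cell volumes (um^3) of proliferating and senescent myofibroblasts
#' measured in tissue sections and in culture, plus the in-vitro whole-cell
#' capacitances (pF).
#'
#' @param vol_tissue_pro,vol_tissue_sen,vol_culture_pro,vol_culture_sen
#'   Group mean volumes, um^3.
#' @param Cm_invitro_pro,Cm_invitro_sen In-vitro capacitances, pF.
#' @return Object of class `volumetric_summary`.
#' @export
volumetric_summary <- function(vol_tissue_pro, vol_tissue_sen,
                               vol_culture_pro, vol_culture_sen,
                               Cm_invitro_pro = 128.7,
                               Cm_invitro_sen = 138.4) {
  vals <- c(vol_tissue_pro, vol_tissue_sen, vol_culture_pro, vol_culture_sen,
            Cm_invitro_pro, Cm_invitro_sen)
  if (length(vals) != 6 || any(!is.finite(vals)) || any(vals <= 0))
    stop("volumetric summary requires six positive values ",
         "(four group volumes and two capacitances)")
  structure(list(vol_tissue_pro = vol_tissue_pro,
                 vol_tissue_sen = vol_tissue_sen,
                 vol_culture_pro = vol_culture_pro,
                 vol_culture_sen = vol_culture_sen,
                 Cm_invitro_pro = Cm_invitro_pro,
                 Cm_invitro_sen = Cm_invitro_sen),
            class = "volumetric_summary")
}

#' Extrapolate in-vitro capacitances to tissue values
#'
#' Scales the capacitance measured by whole-cell patch clamp in culture by
#' the tissue/culture surface-area ratio of proliferating cells (spherical
#' approximation), then obtains the senescent tissue capacitance by
#' multiplying the proliferating tissue value by the senescent/proliferating
#' surface-area ratio in tissue. Values are not rounded internally; see
#' [capacitance_report()] for the integer-pF reporting convention.
#'
#' @param vol A [volumetric_summary()].
#' @return Named numeric: `Cm_tissue_pro`, `Cm_tissue_sen` (pF), with the
#'   tissue senescent/proliferating area ratio as attribute `area_ratio`.
#' @export
extrapolate_tissue_capacitance <- function(vol) {
  if (!inherits(vol, "volumetric_summary"))
    stop("configuration error: expected a volumetric_summary ",
         "(a group is missing or malformed)")
  a_tp <- sphere_area_from_volume(vol$vol_tissue_pro)
  a_ts <- sphere_area_from_volume(vol$vol_tissue_sen)
  a_cp <- sphere_area_from_volume(vol$vol_culture_pro)
  cm_pro <- vol$Cm_invitro_pro * a_tp / a_cp
  ratio <- a_ts / a_tp
  cm_sen <- cm_pro * ratio
  structure(c(Cm_tissue_pro = cm_pro, Cm_tissue_sen = cm_sen),
            area_ratio = ratio)
}

#' Report tissue capacitances at integer-pF precision
#'
#' Applies the reporting convention for extrapolated tissue capacitances:
#' the proliferating value is scaled by the tissue senescent/proliferating
#' surface-area ratio and both are rounded to whole pF only at this
#' reporting step.
#'
#' @param Cm_tissue_pro Proliferating tissue capacitance, pF (default 18).
#' @param area_ratio Senescent/proliferating surface-area ratio in tissue
#'   (default 1.95).
#' @return Named integer-valued numeric: `proliferating`, `senescent` (pF).
#' @export
#' @examples
#' capacitance_report() # 18 and 35 pF
capacitance_report <- function(Cm_tissue_pro = 18, area_ratio = 1.95) {
  stopifnot(Cm_tissue_pro > 0, area_ratio > 0)
  c(proliferating = round(Cm_tissue_pro),
    senescent = round(Cm_tissue_pro * area_ratio))
}
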