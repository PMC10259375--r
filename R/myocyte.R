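#' Parameter set for the Mahajan rabbit ventricular myocyte model
#'
#' Returns the maximal conductances and scaling factors of the Mahajan 2008
#' rabbit ventricular action potential model. Only the sodium and
#' inward-rectifier conductances are expected to be rescaled (border-zone
#' remodeling); all other constants are the published values.
#'
#' @param gNa_scale,gK1_scale Dimensionless multipliers in (0, 2] applied to
#'   the nominal maximal conductances (e.g. `gNa_scale = 0.5` models the
#'   ~50% sodium-channel downregulation of the infarct border zone).
#' @param gNa_nominal Nominal maximal sodium conductance, mS/uF (default 12).
#' @param gK1_nominal Nominal maximal inward-rectifier conductance, mS/uF
#'   (default 0.30).
#' @param Cm_myo Whole-cell myocyte capacitance in pF, used only to convert
#'   gap-junctional currents (pA) to current densities (pA/pF). Default
#'   180 pF, in the measured range for adult rabbit ventricular myocytes
#'   and consistent with reported border-zone gap-current densities.
#' @return An object of class `myocyte_params`: a named list of conductances
#'   (mS/uF), the L-type channel permeability `pCa` (cm/s), the Ca flux
#'   strength `gCaFlux` (mmol/(cm C)) and `Cm_myo` (pF).
#' @export
#' @examples
#' p <- myocyte_params(gNa_scale = 0.5)
#' p$gNa_nominal * p$gNa_scale # effective gNa, mS/uF
myocyte_params <- function(gNa_scale = 1, gK1_scale = 1,
                           gNa_nominal = 12, gK1_nominal = 0.30,
                           Cm_myo = 180) {
  stopifnot(gNa_nominal > 0, gK1_nominal > 0, Cm_myo > 0)
  if (gNa_scale <= 0 || gNa_scale > 2) stop("gNa_scale must be in (0, 2]")
  if (gK1_scale <= 0 || gK1_scale > 2) stop("gK1_scale must be in (0, 2]")
  structure(list(
    gNa_nominal = gNa_nominal, gNa_scale = gNa_scale,
    gK1_nominal = gK1_nominal, gK1_scale = gK1_scale,
    gKr = 0.0125, gKs = 0.1386, gtos = 0.04, gtof = 0.11,
    gNaK = 1.5, gNaCa = 0.84,
    pCa = 0.00054, gCaFlux = 182,
    Cm_myo = Cm_myo
  ), class = "myocyte_params")
}

#' Published resting initial conditions of the myocyte model
#'
#' State vector of the Mahajan model near its paced steady state: membrane
#' potential (mV), Hodgkin-Huxley gates, the seven-state Markov occupancies
#' of the L-type channel, Ca compartments (uM: dyadic `cp`, submembrane `cs`,
#' cytosolic `ci`; SR pools `cj`, `cjp` are cytosol-referenced uM),
#' bound troponin (uM) and intracellular sodium (mM).
#'
#' @return Named numeric vector of length 26 (class `myocyte_state`).
#' @export
#' @examples
#' s <- default_initial_state()
#' s[["Vm"]]
default_initial_state <- function() {
  structure(c(
    Vm = -87.169816169406, xm = 0.001075453357, xh = 0.990691306716,
    xj = 0.993888937283, xr = 0.007074239331, xs1 = 0.048267587131,
    xs2 = 0.105468807033, xtos = 0.00364776906, ytos = 0.174403618112,
    xtof = 0.003643592594, ytof = 0.993331326442,
    c1 = 1.8211252e-05, c2 = 0.979322592773, xi1ca = 0.001208153482,
    xi1ba = 3.3616596e-05, xi2ca = 0.004173008466, xi2ba = 0.015242594688,
    cp = 1.682601371882, cs = 0.226941113355, ci = 0.256752008084,
    cj = 104.450004990523, cjp = 97.505463697266, xir = 0.006679257264,
    tropi = 22.171689894953, trops = 19.864701949854, nai = 11.441712311614
  ), class = "myocyte_state")
}

#' Evaluate the myocyte model right-hand side
#'
#' Computes the time derivative of the full state and the breakdown of the
#' ionic membrane currents at a given state.
#'
#' @param state Named numeric state vector as from [default_initial_state()].
#' @param params A [myocyte_params()] object.
#' @param I_ext External current density in pA/pF; positive depolarizes
#'   (stimulus plus any gap-junctional contribution).
#' @return List with `deriv` (named derivative of the state, per ms) and
#'   `currents` (named vector, pA/pF: I_Na, I_CaL, I_Kr, I_Ks, I_to_f,
#'   I_to_s, I_K1, I_NaCa, I_NaK, and their sum I_ion).
#' @export
#' @examples
#' rhs <- myocyte_rhs(default_initial_state(), myocyte_params())
#' rhs$currents[["I_ion"]]
myocyte_rhs <- function(state, params = myocyte_params(), I_ext = 0) {
  stopifnot(inherits(params, "myocyte_params"))
  .mahajan_rhs_cpp(as.numeric(state), params, I_ext)
}

#' Nernst potassium reversal potential of the model's fixed concentrations
#' @return E_K in mV.
#' @export
nernst_ek <- function() {
  frt <- 96485 / (8314.472 * 308)
  (1 / frt) * log(5.4 / 140)
}
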