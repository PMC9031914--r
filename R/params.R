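#' Biochemical parameter set for the FvCB photosynthesis model
#'
#' Bundles the parameters of the Farquhar--von Caemmerer--Berry (FvCB) model
#' of C3 photosynthesis together with the light dependence of electron
#' transport. The same object drives the forward simulator and is the ground
#' truth that the fitting routines are validated against.
#'
#' Kinetic constants default to the standard tobacco-derived values at 25
#' degC: \code{Kc} = 404.9 umol mol-1, \code{Ko} = 278.4 mmol mol-1 and
#' \code{GammaStar} = 42.75 umol mol-1 at ambient oxygen (O = 210 mmol
#' mol-1). No temperature response is applied: all computations are at the
#' single cuvette temperature of the measurement protocol.
#'
#' @param Vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param Jmax Maximum electron transport rate, the asymptote of the
#'   non-rectangular hyperbola of J versus PAR (umol m-2 s-1).
#' @param GammaStar Photorespiratory CO2 compensation point Gamma* (umol
#'   mol-1) at the oxygen level \code{O}.
#' @param Rday Mitochondrial respiration in the light (umol m-2 s-1,
#'   positive).
#' @param gm Mesophyll conductance to CO2 (mol m-2 s-1); \code{Inf} means a
#'   Ci-basis model with Cc = Ci.
#' @param Kc Michaelis constant of Rubisco for CO2 (umol mol-1).
#' @param Ko Michaelis constant of Rubisco for O2 (mmol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1); 210 is ambient air.
#' @param alphaJ Initial slope of J versus PAR (mol e- mol photons-1); leaf
#'   absorptance and the PSII partitioning fraction are folded in.
#' @param thetaJ Curvature of the J versus PAR hyperbola, in (0, 1].
#'
#' @return An object of class \code{fvcb_params} (a named list).
#' @seealso [with_oxygen()], [fvcb_assimilation()], [j_of_par()]
#' @examples
#' p <- fvcb_params(Vcmax = 60, Jmax = 120)
#' p$GammaStar
#' @export
fvcb_params <- function(Vcmax = 60, Jmax = 120, GammaStar = 42.75, Rday = 1,
                        gm = Inf, Kc = 404.9, Ko = 278.4, O = 210,
                        alphaJ = 0.3, thetaJ = 0.7) {
  stopifnot(
    is.numeric(Vcmax), Vcmax >= 0,
    is.numeric(Jmax), Jmax >= 0,
    is.numeric(GammaStar), GammaStar >= 0,
    is.numeric(Rday), Rday >= 0,
    is.numeric(gm), gm > 0,
    Kc > 0, Ko > 0, O >= 0,
    alphaJ >= 0, thetaJ > 0, thetaJ <= 1
  )
  structure(
    list(Vcmax = Vcmax, Jmax = Jmax, GammaStar = GammaStar, Rday = Rday,
         gm = gm, Kc = Kc, Ko = Ko, O = O, alphaJ = alphaJ, thetaJ = thetaJ),
    class = "fvcb_params"
  )
}

#' Rescale an FvCB parameter set to a different oxygen level
#'
#' Gamma* arises from the Rubisco oxygenation/carboxylation specificity and
#' scales linearly with the oxygen mole fraction; the effective Michaelis
#' constant Km = Kc (1 + O/Ko) is recomputed from \code{O} inside the model,
#' so only Gamma* and O need to change here.
#'
#' @param p An [fvcb_params()] object.
#' @param O New oxygen mole fraction (mmol mol-1).
#' @return A new \code{fvcb_params} object at oxygen \code{O}.
#' @examples
#' low <- with_oxygen(fvcb_params(), 10)
#' low$GammaStar  # 42.75 * 10/210
#' @export
with_oxygen <- function(p, O) {
  stopifnot(inherits(p, "fvcb_params"), is.numeric(O), O >= 0)
  p2 <- p
  p2$GammaStar <- p$GammaStar * O / p$O
  p2$O <- O
  p2
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("FvCB parameters:\n")
  cat(sprintf("  Vcmax = %g, Jmax = %g umol m-2 s-1\n", x$Vcmax, x$Jmax))
  cat(sprintf("  GammaStar = %g umol mol-1 (O = %g mmol mol-1), Rday = %g\n",
              x$GammaStar, x$O, x$Rday))
  cat(sprintf("  gm = %g mol m-2 s-1, Kc = %g, Ko = %g\n", x$gm, x$Kc, x$Ko))
  cat(sprintf("  J(PAR): alphaJ = %g, thetaJ = %g\n", x$alphaJ, x$thetaJ))
  invisible(x)
}

#' Parameters of the fluorescence emission model
#'
#' Describes PSII chlorophyll-fluorescence emission used by the simulator:
#' dark-adapted yields, a Stern--Volmer NPQ light response, and a simple
#' photoinhibition term that raises post-illumination minimal fluorescence
#' above the calculated Fo' once PAR exceeds \code{Icrit} (this is what the
#' dark-assessed qPd protocol detects).
#'
#' @param FvFm Dark-adapted maximum PSII quantum yield, in (0, 1).
#' @param Fo Dark minimal fluorescence (arbitrary units).
#' @param NPQmax Amplitude of Stern--Volmer NPQ (dimensionless).
#' @param K50_NPQ PAR at half-maximal NPQ (umol photons m-2 s-1).
#' @param Icrit PAR above which the photoinhibitory Fo rise begins
#'   (umol photons m-2 s-1).
#' @param kinh Fractional Fo rise per unit PAR above \code{Icrit}
#'   (per umol photons m-2 s-1).
#' @param absorptance Leaf absorptance, in (0, 1].
#' @param fPSII Fraction of absorbed light reaching PSII, in (0, 1].
#' @return An object of class \code{fluor_params}.
#' @export
fluor_params <- function(FvFm = 0.8, Fo = 500, NPQmax = 3, K50_NPQ = 500,
                         Icrit = 600, kinh = 1e-3, absorptance = 0.84,
                         fPSII = 0.5) {
  stopifnot(
    FvFm > 0, FvFm < 1, Fo > 0, NPQmax >= 0, K50_NPQ > 0,
    Icrit >= 0, kinh >= 0,
    absorptance > 0, absorptance <= 1, fPSII > 0, fPSII <= 1
  )
  structure(
    list(FvFm = FvFm, Fo = Fo, Fm = Fo / (1 - FvFm), NPQmax = NPQmax,
         K50_NPQ = K50_NPQ, Icrit = Icrit, kinh = kinh,
         absorptance = absorptance, fPSII = fPSII),
    class = "fluor_params"
  )
}

#' Simulation protocol specification
#'
#' Protocol constants and noise levels for the forward simulator. Defaults
#' reproduce the measurement protocols of the study the package emulates: an
#' "up" CO2 ramp from 20 to 1520 ppm at 100 ppm min-1 recorded every 2 s,
#' light-response steps 1500, 1200, 900, 600, 300, 150, 50 umol photons m-2
#' s-1, and a chamber at 400 umol mol-1 CO2.
#'
#' @param noise_sd_A Gaussian standard deviation added to assimilation
#'   (umol m-2 s-1).
#' @param noise_sd_F Relative Gaussian standard deviation applied
#'   multiplicatively to fluorescence signals.
#' @param seed Integer random seed governing the whole trace.
#' @param par_steps PAR step sequence for light-response protocols
#'   (umol photons m-2 s-1).
#' @param ramp CO2 ramp: list with \code{start} and \code{end} (ppm),
#'   \code{rate} (ppm min-1) and \code{interval} (s between recordings).
#' @param Ca Chamber CO2 set-point for light-response protocols (umol mol-1).
#' @param gsw Stomatal conductance to water vapour used to derive Ci from
#'   chamber CO2 (mol m-2 s-1); study-realistic default.
#' @param par_sat Saturating PAR used for A-Ci protocols (umol photons m-2 s-1).
#' @return An object of class \code{sim_spec}.
#' @export
sim_spec <- function(noise_sd_A = 0.5, noise_sd_F = 0.01, seed = 1L,
                     par_steps = c(1500, 1200, 900, 600, 300, 150, 50),
                     ramp = list(start = 20, end = 1520, rate = 100, interval = 2),
                     Ca = 400, gsw = 0.1, par_sat = 1500) {
  stopifnot(
    noise_sd_A >= 0, noise_sd_F >= 0, length(par_steps) > 0,
    all(par_steps >= 0), is.list(ramp),
    all(c("start", "end", "rate", "interval") %in% names(ramp)),
    ramp$end > ramp$start, ramp$rate > 0, ramp$interval > 0,
    Ca > 0, gsw > 0, par_sat >= 0
  )
  structure(
    list(noise_sd_A = noise_sd_A, noise_sd_F = noise_sd_F,
         seed = as.integer(seed), par_steps = par_steps, ramp = ramp,
         Ca = Ca, gsw = gsw, par_sat = par_sat),
    class = "sim_spec"
  )
}

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
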