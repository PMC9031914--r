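#' Simulate a steady-state A-Ci curve
#'
#' Evaluates the forward FvCB model on a Ci grid at saturating PAR and adds
#' seeded Gaussian measurement noise. The generating parameters are embedded
#' in the curve's metadata so that downstream fits can be validated against
#' ground truth.
#'
#' @param p An [fvcb_params()] object.
#' @param spec A [sim_spec()]; the Ci grid spans the spec's CO2 ramp range
#'   and \code{spec$par_sat} is the measurement PAR.
#' @param n Number of grid points.
#' @param ci Optional explicit Ci grid (umol mol-1, positive, increasing);
#'   overrides \code{n}.
#' @return An \code{aci_curve}: a data.frame with columns \code{Ci},
#'   \code{A}, \code{par}, and attributes \code{meta} (list with
#'   \code{truth}, the noiseless model output, and provenance).
#' @examples
#' curve <- simulate_aci(fvcb_params(), sim_spec(noise_sd_A = 0))
#' head(curve)
#' @export
simulate_aci <- function(p, spec = sim_spec(), n = 40, ci = NULL) {
  stopifnot(inherits(p, "fvcb_params"), inherits(spec, "sim_spec"))
  if (is.null(ci)) {
    ci <- seq(spec$ramp$start, spec$ramp$end, length.out = n)
  }
  stopifnot(all(ci > 0), !is.unsorted(ci, strictly = TRUE))
  truth <- fvcb_assimilation(ci, spec$par_sat, p)
  A <- with_seed(spec$seed,
                 truth$A + stats::rnorm(length(ci), 0, spec$noise_sd_A))
  new_aci_curve(
    data.frame(Ci = ci, A = A, par = spec$par_sat),
    meta = list(source = "simulated", params = p, spec = spec,
                truth = cbind(Ci = ci, truth))
  )
}

new_aci_curve <- function(df, meta = list()) {
  stopifnot(all(c("Ci", "A") %in% names(df)))
  df <- df[order(df$Ci), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, meta = meta, class = c("aci_curve", "data.frame"))
}

# evaluate polynomial with coefficients c0 + c1 x + c2 x^2 + ...
polyval <- function(coefs, x) {
  out <- numeric(length(x))
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

new_racir_trace <- function(df, meta = list()) {
  need <- c("elapsed", "CO2_r", "CO2_s", "A", "Ci", "gsw", "direction")
  stopifnot(all(need %in% names(df)))
  if (is.unsorted(df$elapsed, strictly = TRUE)) {
    stop("RACiR trace times must be strictly increasing", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, meta = meta, class = c("racir_trace", "data.frame"))
}

#' Simulate a matched leaf/empty-chamber RACiR pair
#'
#' Generates a rapid A-Ci response "up" ramp: reference CO2 rises linearly
#' from \code{spec$ramp$start} to \code{spec$ramp$end} at
#' \code{spec$ramp$rate} ppm min-1, recorded every \code{spec$ramp$interval}
#' s. The empty-chamber trace records only the instrument artifact (a
#' polynomial in reference CO2) plus noise; the leaf trace records the true
#' steady-state assimilation at each chamber CO2 plus the same artifact plus
#' noise. Both traces share timestamps, so the empty trace can be used to
#' correct the leaf trace exactly as in the measurement protocol.
#'
#' @param p An [fvcb_params()] object.
#' @param spec A [sim_spec()].
#' @param artifact Numeric vector of polynomial coefficients (intercept
#'   first) describing the apparent assimilation of the empty chamber as a
#'   function of reference CO2.
#' @return A list with elements \code{leaf} and \code{empty}, both
#'   \code{racir_trace} data.frames with columns \code{elapsed},
#'   \code{CO2_r}, \code{CO2_s}, \code{A}, \code{Ci}, \code{gsw},
#'   \code{direction}; ground truth is in \code{attr(leaf, "meta")$truth}.
#' @examples
#' pair <- simulate_racir_pair(fvcb_params(), sim_spec(noise_sd_A = 0),
#'                             artifact = c(0.3, -1e-4))
#' nrow(pair$leaf)
#' @export
simulate_racir_pair <- function(p, spec = sim_spec(),
                                artifact = c(0.3, -2e-4)) {
  stopifnot(inherits(p, "fvcb_params"), inherits(spec, "sim_spec"),
            is.numeric(artifact), length(artifact) >= 1)
  r <- spec$ramp
  duration <- (r$end - r$start) / r$rate * 60
  elapsed <- seq(0, duration, by = r$interval)
  CO2_r <- r$start + r$rate / 60 * elapsed
  art <- polyval(artifact, CO2_r)
  truth <- fvcb_at_ca(CO2_r, spec$par_sat, p, spec$gsw)
  gtc <- spec$gsw / 1.6
  with_seed(spec$seed, {
    noise_leaf <- stats::rnorm(length(elapsed), 0, spec$noise_sd_A)
    noise_empty <- stats::rnorm(length(elapsed), 0, spec$noise_sd_A)
  })
  A_leaf <- truth$A + art + noise_leaf
  A_empty <- art + noise_empty
  meta <- list(source = "simulated", params = p, spec = spec,
               artifact = artifact, par = spec$par_sat,
               truth = cbind(elapsed = elapsed, CO2_r = CO2_r, truth))
  leaf <- new_racir_trace(
    data.frame(elapsed = elapsed, CO2_r = CO2_r, CO2_s = CO2_r,
               A = A_leaf, Ci = CO2_r - A_leaf / gtc, gsw = spec$gsw,
               direction = "up"),
    meta = meta
  )
  empty <- new_racir_trace(
    data.frame(elapsed = elapsed, CO2_r = CO2_r, CO2_s = CO2_r,
               A = A_empty, Ci = NA_real_, gsw = spec$gsw,
               direction = "up"),
    meta = list(source = "simulated", artifact = artifact, spec = spec)
  )
  list(leaf = leaf, empty = empty)
}

new_light_curve <- function(df, condition, meta = list()) {
  stopifnot(all(c("par", "A") %in% names(df)),
            condition %in% c("photorespiratory", "low_O2"))
  if (anyDuplicated(df$par)) stop("PAR steps must be unique", call. = FALSE)
  rownames(df) <- NULL
  structure(df, condition = condition, meta = meta,
            class = c("light_curve", "data.frame"))
}

# Stern-Volmer NPQ light response of the fluorescence model
npq_of_par <- function(par, f) f$NPQmax * par / (par + f$K50_NPQ)

#' Simulate paired photorespiratory / low-oxygen light-response curves
#'
#' Runs the forward model over the PAR steps of the light-response protocol
#' twice: once in normal air (oxygen \code{p$O}, the "photorespiratory"
#' condition) and once under a nitrogen mix (\code{O_low} mmol mol-1, Gamma*
#' rescaled proportionally), at a chamber CO2 of \code{spec$Ca}. Each step
#' also emits steady-state and maximal fluorescence (Fs, Fm') consistent with
#' the realised electron transport rate: PhiPSII = J / (par * absorptance *
#' fPSII), Fm' = Fm / (1 + NPQ(par)) and Fs = Fm' (1 - PhiPSII), so that
#' fluorescence-derived ETR inverts exactly to the model's J.
#'
#' Metadata embeds, per step and condition, the noiseless assimilation, Cc,
#' the limitation state, the electron transport rate, the photorespiratory
#' CO2 release 0.5 Vo of the normal-air leaf, and the noiseless AG - AN
#' difference.
#'
#' @param p An [fvcb_params()] object (normal-air oxygen).
#' @param f A [fluor_params()] object.
#' @param spec A [sim_spec()]; \code{spec$par_steps} are used verbatim.
#' @param O_low Oxygen mole fraction of the nitrogen mix (mmol mol-1).
#' @return List with elements \code{photorespiratory} and \code{low_O2},
#'   both \code{light_curve} data.frames with columns \code{par}, \code{A},
#'   \code{Ci}, \code{Fs}, \code{Fmp}.
#' @export
simulate_light_response_pair <- function(p, f = fluor_params(),
                                         spec = sim_spec(), O_low = 10) {
  stopifnot(inherits(p, "fvcb_params"), inherits(f, "fluor_params"),
            inherits(spec, "sim_spec"), length(spec$par_steps) > 0)
  p_low <- with_oxygen(p, O_low)
  steps <- spec$par_steps
  sim_one <- function(pp, noise) {
    g <- fvcb_at_ca(rep(spec$Ca, length(steps)), steps, pp, spec$gsw)
    J <- j_of_par(steps, pp)
    phi <- ifelse(steps > 0, J / (steps * f$absorptance * f$fPSII), 0)
    Fmp <- f$Fm / (1 + npq_of_par(steps, f))
    Fs <- Fmp * (1 - phi)
    truth <- data.frame(par = steps, A = g$A, Ci = g$Ci, Cc = g$Cc,
                        limitation = g$limitation, J = J, phiPSII = phi,
                        stringsAsFactors = FALSE)
    df <- data.frame(
      par = steps,
      A = g$A + noise$A,
      Ci = g$Ci,
      Fs = Fs * (1 + noise$F1),
      Fmp = Fmp * (1 + noise$F2)
    )
    list(df = df, truth = truth)
  }
  noise <- with_seed(spec$seed, {
    k <- length(steps)
    list(
      n = list(A = stats::rnorm(k, 0, spec$noise_sd_A),
               F1 = stats::rnorm(k, 0, spec$noise_sd_F),
               F2 = stats::rnorm(k, 0, spec$noise_sd_F)),
      g = list(A = stats::rnorm(k, 0, spec$noise_sd_A),
               F1 = stats::rnorm(k, 0, spec$noise_sd_F),
               F2 = stats::rnorm(k, 0, spec$noise_sd_F))
    )
  })
  net <- sim_one(p, noise$n)
  gross <- sim_one(p_low, noise$g)
  hv <- half_vo(net$truth$Cc, net$truth$limitation, steps, p)
  truth <- net$truth
  truth$half_vo <- hv
  truth$A_gross <- gross$truth$A
  truth$phresp_true <- gross$truth$A - net$truth$A
  meta <- list(source = "simulated", params = p, params_low = p_low,
               fluor = f, spec = spec, truth = truth,
               truth_low = gross$truth)
  list(
    photorespiratory = new_light_curve(net$df, "photorespiratory", meta),
    low_O2 = new_light_curve(gross$df, "low_O2", meta)
  )
}

new_fluor_trace <- function(df, Fo, Fm, meta = list()) {
  need <- c("step", "par", "Fs", "Fmp", "Fo_dark", "Fmp_dark")
  stopifnot(all(need %in% names(df)), Fm > Fo, Fo > 0)
  if (is.unsorted(df$par, strictly = TRUE)) {
    stop("qPd protocol PAR script must be strictly increasing", call. = FALSE)
  }
  structure(df, Fo = Fo, Fm = Fm, meta = meta,
            class = c("fluor_trace", "data.frame"))
}

#' Simulate the dark-assessed qP (qPd) fluorescence protocol
#'
#' Emulates the monitoring protocol: after dark adaptation (recording Fo and
#' Fm), the leaf is driven through a script of increasing light intensities;
#' at each step the steady-state and maximal fluorescence in the light (Fs,
#' Fm') are recorded, the light is switched off, and after brief far-red
#' illumination the dark minimal fluorescence and a dark saturating-pulse
#' maximum are recorded. Photoinhibition is modelled as a fractional rise of
#' the post-illumination minimal fluorescence above the calculated Fo':
#' \code{Fo_dark = Fo'_calc * (1 + kinh * max(0, par - Icrit))}. The dark
#' saturating-pulse maximum equals the step's Fm' (NPQ has not yet relaxed).
#'
#' @param f A [fluor_params()] object.
#' @param par_script Strictly increasing PAR step sequence (umol photons m-2
#'   s-1); the default is the eight-step script of the study protocol.
#' @param noise_sd_F Relative Gaussian noise on all fluorescence channels.
#' @param seed Random seed (used only when \code{noise_sd_F > 0}).
#' @return A \code{fluor_trace} data.frame with columns \code{step},
#'   \code{par}, \code{Fs}, \code{Fmp}, \code{Fo_dark}, \code{Fmp_dark} and
#'   attributes \code{Fo}, \code{Fm}.
#' @examples
#' tr <- simulate_qpd_protocol(fluor_params(kinh = 0))
#' tr$par
#' @export
simulate_qpd_protocol <- function(f = fluor_params(),
                                  par_script = c(60, 100, 250, 400, 600,
                                                 850, 1150, 1500),
                                  noise_sd_F = 0, seed = 1L) {
  stopifnot(inherits(f, "fluor_params"), all(par_script > 0))
  if (is.unsorted(par_script, strictly = TRUE)) {
    stop("`par_script` must be strictly increasing", call. = FALSE)
  }
  Fm <- f$Fm
  Fo <- f$Fo
  Fmp <- Fm / (1 + npq_of_par(par_script, f))
  # calculated Fo' (Oxborough-Baker): Fo / (Fv/Fm + Fo/Fm')
  Fop <- Fo / (f$FvFm + Fo / Fmp)
  qP_true <- 1 / (1 + par_script / f$K50_NPQ)
  Fs <- Fop + (1 - qP_true) * (Fmp - Fop)
  Fo_dark <- Fop * (1 + f$kinh * pmax(0, par_script - f$Icrit))
  df <- data.frame(step = seq_along(par_script), par = par_script,
                   Fs = Fs, Fmp = Fmp, Fo_dark = Fo_dark, Fmp_dark = Fmp)
  if (noise_sd_F > 0) {
    df[c("Fs", "Fmp", "Fo_dark", "Fmp_dark")] <- with_seed(seed, {
      lapply(df[c("Fs", "Fmp", "Fo_dark", "Fmp_dark")], function(x)
        x * (1 + stats::rnorm(length(x), 0, noise_sd_F)))
    })
  }
  new_fluor_trace(df, Fo = Fo, Fm = Fm,
                  meta = list(source = "simulated", fluor = f,
                              truth = data.frame(par = par_script,
                                                 Fo_prime_calc = Fop,
                                                 qP = qP_true)))
}

new_laisk_segments <- function(df, meta = list()) {
  stopifnot(all(c("Ci", "A", "par") %in% names(df)))
  pars <- unique(df$par)
  if (length(pars) != 3) {
    stop("Laisk protocol needs exactly three PAR levels", call. = FALSE)
  }
  structure(df, meta = meta, class = c("laisk_segments", "data.frame"))
}

#' Simulate low-light, low-CO2 segments for the Laisk protocol
#'
#' Generates the three A-Ci point sets measured under low light and low CO2
#' from which the apparent CO2 compensation point Ci* and day respiration
#' Rday are estimated.
#'
#' Two generating models are available. The default, \code{"tangent"},
#' produces data under the Laisk construction's own assumption of local
#' linearity: each segment lies on the line through the common point
#' (Ci*, -Rday) with the slope the FvCB model has there,
#' \eqn{s = \sigma/(1 + \sigma/g_m)} with \eqn{\sigma = J(PAR)/(12\Gamma^*)}
#' and \eqn{C_i^* = \Gamma^* - R_{day}/g_m}. \code{"fvcb"} instead evaluates
#' the full (curvilinear) forward model; applying the linear Laisk
#' construction to such segments exhibits the method's known curvature bias
#' (see the methods vignette).
#'
#' @param p An [fvcb_params()] object.
#' @param pars Three distinct PAR levels (umol photons m-2 s-1); the study
#'   used 421, 210 and 42 or 63 depending on variety.
#' @param ci Ci grid of each segment (umol mol-1), spanning the low-CO2
#'   window of the protocol.
#' @param model Generating model, \code{"tangent"} (default) or
#'   \code{"fvcb"}.
#' @param noise_sd Gaussian noise s.d. on A (umol m-2 s-1).
#' @param seed Random seed.
#' @return A \code{laisk_segments} data.frame with columns \code{Ci},
#'   \code{A}, \code{par}; truth (Ci*, Rday, slopes) in its metadata.
#' @export
simulate_laisk_segments <- function(p, pars = c(421, 210, 63),
                                    ci = seq(50, 150, by = 20),
                                    model = c("tangent", "fvcb"),
                                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(p, "fvcb_params"), length(pars) == 3,
            !anyDuplicated(pars), all(ci > 0))
  model <- match.arg(model)
  ci_star <- if (is.finite(p$gm)) p$GammaStar - p$Rday / p$gm else p$GammaStar
  J <- j_of_par(pars, p)
  sigma <- J / (12 * p$GammaStar)
  slope <- if (is.finite(p$gm)) sigma / (1 + sigma / p$gm) else sigma
  rows <- lapply(seq_along(pars), function(k) {
    A <- if (model == "tangent") {
      slope[k] * (ci - ci_star) - p$Rday
    } else {
      fvcb_assimilation(ci, pars[k], p)$A
    }
    data.frame(Ci = ci, A = A, par = pars[k])
  })
  df <- do.call(rbind, rows)
  if (noise_sd > 0) {
    df$A <- with_seed(seed, df$A + stats::rnorm(nrow(df), 0, noise_sd))
  }
  new_laisk_segments(
    df,
    meta = list(source = "simulated", params = p, model = model,
                truth = list(ci_star = ci_star, GammaStar = p$GammaStar,
                             Rday = p$Rday, slopes = slope, pars = pars))
  )
}
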