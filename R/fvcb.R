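#' Electron transport rate as a function of PAR
#'
#' Non-rectangular hyperbola of potential electron transport J against
#' incident PAR: the smaller root of
#' \deqn{\theta J^2 - (\alpha I + J_{max}) J + \alpha I J_{max} = 0.}
#' Computed in the numerically stable form
#' \eqn{2 \alpha I J_{max} / (s + \sqrt{s^2 - 4\theta \alpha I J_{max}})}
#' with \eqn{s = \alpha I + J_{max}}, which has no cancellation for small
#' \eqn{\theta} and reduces exactly to the Blackman limit
#' \code{min(alphaJ * par, Jmax)} at \code{thetaJ = 1}.
#'
#' @param par Incident PAR (umol photons m-2 s-1), vectorised.
#' @param p An [fvcb_params()] object.
#' @return Electron transport rate J (umol m-2 s-1), same length as
#'   \code{par}; always in \code{[0, Jmax]} and non-decreasing in PAR.
#' @examples
#' j_of_par(300, fvcb_params(Jmax = 120, alphaJ = 0.3, thetaJ = 0.7))
#' @export
j_of_par <- function(par, p) {
  stopifnot(inherits(p, "fvcb_params"), is.numeric(par))
  if (any(par < 0)) stop("`par` must be non-negative", call. = FALSE)
  aI <- p$alphaJ * par
  s <- aI + p$Jmax
  disc <- pmax(s^2 - 4 * p$thetaJ * aI * p$Jmax, 0)
  out <- 2 * aI * p$Jmax / (s + sqrt(disc))
  out[s == 0] <- 0 # Jmax = 0 and dark
  out
}

#' Invert the J-PAR hyperbola for the Jmax asymptote
#'
#' Given an electron transport rate \code{J} observed at PAR \code{par},
#' returns the \code{Jmax} asymptote of the non-rectangular hyperbola with
#' the stated initial slope and curvature. Closed form:
#' \eqn{J_{max} = J(\alpha I - \theta J) / (\alpha I - J)}.
#'
#' @param J Electron transport rate (umol m-2 s-1).
#' @param par PAR at which \code{J} was observed (umol photons m-2 s-1).
#' @param alphaJ Initial slope of J versus PAR.
#' @param thetaJ Curvature of J versus PAR.
#' @return Jmax (umol m-2 s-1).
#' @export
jmax_from_j <- function(J, par, alphaJ = 0.3, thetaJ = 0.7) {
  stopifnot(J >= 0, par > 0)
  aI <- alphaJ * par
  if (any(aI - J <= 0)) {
    stop("J at the light-limited slope: Jmax not identifiable (alphaJ * par <= J)",
         call. = FALSE)
  }
  J * (aI - thetaJ * J) / (aI - J)
}

# Net assimilation for one limitation branch of the FvCB model with the
# generic hyperbola A = V (Cc - GammaStar) / (Cc + K) - Rd.
# With finite mesophyll conductance, Cc = Ci - A/gm and A solves
#   A^2 - A (gm (Ci + K) + V - Rd) + gm (V (Ci - GammaStar) - Rd (Ci + K)) = 0;
# the smaller admissible root (Cc > 0) is taken.
limited_rate <- function(Ci, V, K, GammaStar, Rd, gm) {
  if (!is.finite(gm)) {
    return(V * (Ci - GammaStar) / (Ci + K) - Rd)
  }
  b <- -(gm * (Ci + K) + V - Rd)
  cc <- gm * (V * (Ci - GammaStar) - Rd * (Ci + K))
  disc <- b^2 - 4 * cc
  if (any(disc < 0)) {
    stop("no admissible root: demanded flux incompatible with gm",
         call. = FALSE)
  }
  a1 <- (-b - sqrt(disc)) / 2
  a2 <- (-b + sqrt(disc)) / 2
  # smaller root first; fall back to the larger only if it leaves Cc <= 0
  ok1 <- Ci - a1 / gm > 0
  out <- ifelse(ok1, a1, a2)
  if (any(Ci - out / gm <= 0)) {
    stop("no admissible root: chloroplast CO2 would be non-positive",
         call. = FALSE)
  }
  out
}

# gross-rate comparison: TRUE where Rubisco carboxylation Wc is the binding
# (smaller) gross rate at chloroplast CO2 Cc; ties go to Rubisco. Comparing
# gross rates (not net) keeps the limitation flag meaningful below GammaStar,
# where the net-rate min() would invert.
rubisco_binds <- function(Cc, J, p) {
  Km <- p$Kc * (1 + p$O / p$Ko)
  p$Vcmax * (4 * Cc + 8 * p$GammaStar) <= J * (Cc + Km)
}

#' Net assimilation from the FvCB model
#'
#' Forward FvCB model: gross carboxylation is the minimum of the
#' Rubisco-limited rate \eqn{W_c = V_{cmax} C_c/(C_c + K_c(1 + O/K_o))} and
#' the RuBP-regeneration-limited rate \eqn{W_j = J C_c/(4 C_c + 8 \Gamma^*)},
#' and net assimilation is \eqn{A = (1 - \Gamma^*/C_c)\,\min(W_c, W_j) -
#' R_{day}} at the chloroplast CO2 mole fraction \eqn{C_c = C_i - A/g_m},
#' solved self-consistently (analytic quadratic per limitation branch,
#' smaller admissible root). Ties between the branches are reported as
#' Rubisco-limited.
#'
#' @param Ci Intercellular CO2 mole fraction (umol mol-1), vectorised.
#' @param par Incident PAR (umol photons m-2 s-1), scalar or same length.
#' @param p An [fvcb_params()] object.
#' @return A data.frame with columns \code{A} (net assimilation, umol m-2
#'   s-1), \code{Cc} (umol mol-1) and \code{limitation} ("rubisco" or
#'   "rubp").
#' @examples
#' fvcb_assimilation(300, 1500, fvcb_params(Vcmax = 60, Jmax = 120))
#' @export
fvcb_assimilation <- function(Ci, par, p) {
  stopifnot(inherits(p, "fvcb_params"), is.numeric(Ci), is.numeric(par))
  if (any(Ci <= 0)) stop("`Ci` must be positive", call. = FALSE)
  if (any(par < 0)) stop("`par` must be non-negative", call. = FALSE)
  Km <- p$Kc * (1 + p$O / p$Ko)
  J <- j_of_par(par, p)
  Ac <- limited_rate(Ci, p$Vcmax, Km, p$GammaStar, p$Rday, p$gm)
  Aj <- limited_rate(Ci, J / 4, 2 * p$GammaStar, p$GammaStar, p$Rday, p$gm)
  Cc_c <- if (is.finite(p$gm)) Ci - Ac / p$gm else Ci
  rubisco <- rubisco_binds(Cc_c, J, p)
  A <- ifelse(rubisco, Ac, Aj)
  Cc <- if (is.finite(p$gm)) Ci - A / p$gm else Ci
  data.frame(
    A = A, Cc = Cc,
    limitation = ifelse(rubisco, "rubisco", "rubp"),
    stringsAsFactors = FALSE
  )
}

# Photorespiratory CO2 release 0.5*Vo implied by the active limitation at Cc:
# Rubisco-limited 0.5 Vo = Vcmax GammaStar / (Cc + Km); RuBP-limited
# 0.5 Vo = J GammaStar / (4 Cc + 8 GammaStar).
half_vo <- function(Cc, limitation, par, p) {
  Km <- p$Kc * (1 + p$O / p$Ko)
  J <- j_of_par(par, p)
  ifelse(limitation == "rubisco",
         p$Vcmax * p$GammaStar / (Cc + Km),
         J * p$GammaStar / (4 * Cc + 8 * p$GammaStar))
}

# Steady-state assimilation at chamber CO2 Ca: Ci = Ca - A/gtc with
# gtc = gsw/1.6 (CO2-basis stomatal conductance), so the quadratic solver is
# reused with the series conductance between chamber air and chloroplast.
fvcb_at_ca <- function(Ca, par, p, gsw) {
  stopifnot(all(Ca > 0), gsw > 0)
  gtc <- gsw / 1.6
  gtot <- if (is.finite(p$gm)) 1 / (1 / gtc + 1 / p$gm) else gtc
  Km <- p$Kc * (1 + p$O / p$Ko)
  J <- j_of_par(par, p)
  Ac <- limited_rate(Ca, p$Vcmax, Km, p$GammaStar, p$Rday, gtot)
  Aj <- limited_rate(Ca, J / 4, 2 * p$GammaStar, p$GammaStar, p$Rday, gtot)
  rubisco <- rubisco_binds(Ca - Ac / gtot, J, p)
  A <- ifelse(rubisco, Ac, Aj)
  Ci <- Ca - A / gtc
  Cc <- if (is.finite(p$gm)) Ci - A / p$gm else Ci
  data.frame(
    A = A, Ci = Ci, Cc = Cc,
    limitation = ifelse(rubisco, "rubisco", "rubp"),
    stringsAsFactors = FALSE
  )
}
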