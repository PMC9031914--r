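#' Non-rectangular hyperbola light-response value
#'
#' Four-parameter non-rectangular hyperbola of net assimilation against PAR:
#' \deqn{A_n = \frac{\Phi I + A_{max} - \sqrt{(\Phi I + A_{max})^2 -
#' 4 \Theta \Phi I A_{max}}}{2\Theta} - R_d,}
#' computed in the cancellation-free equivalent form
#' \eqn{2 \Phi I A_{max} / (s + \sqrt{s^2 - 4\Theta\Phi I A_{max}}) - R_d}
#' with \eqn{s = \Phi I + A_{max}}, which evaluates the rectangular-
#' hyperbola limit \eqn{\Phi I A_{max}/(\Phi I + A_{max}) - R_d} exactly at
#' \code{Theta = 0} without a special case.
#'
#' @param par PAR (umol photons m-2 s-1), vectorised.
#' @param Phi Apparent quantum yield (mol CO2 mol photons-1). May also be an
#'   \code{nrh_fit} object, in which case the remaining parameters are taken
#'   from it.
#' @param Amax Maximum gross photosynthetic rate (umol m-2 s-1).
#' @param Theta Curvature, in \code{[0, 1]}.
#' @param Rd Dark respiration (umol m-2 s-1, positive).
#' @return Net assimilation (umol m-2 s-1).
#' @examples
#' nrh_value(300, Phi = 0.06, Amax = 20, Theta = 0.7, Rd = 1)
#' @export
nrh_value <- function(par, Phi, Amax, Theta, Rd) {
  if (inherits(Phi, "nrh_fit")) {
    fit <- Phi
    Amax <- fit$Amax; Theta <- fit$Theta; Rd <- fit$Rd; Phi <- fit$Phi
  }
  stopifnot(is.numeric(par), Theta >= 0, Theta <= 1)
  if (any(par < 0)) stop("`par` must be non-negative", call. = FALSE)
  p <- Phi * par * Amax
  s <- Phi * par + Amax
  disc <- pmax(s^2 - 4 * Theta * p, 0)
  gross <- ifelse(s > 0, 2 * p / (s + sqrt(disc)), 0)
  gross - Rd
}

# tolerant evaluator for the optimiser: clamps Theta into [0, 1] because the
# Levenberg-Marquardt trial steps can overshoot the box by rounding error
.nrh_safe <- function(par, Phi, Amax, Theta, Rd) {
  nrh_value(par, Phi, Amax, min(max(Theta, 0), 1), Rd)
}

#' Fit the four-parameter non-rectangular hyperbola to a light curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of [nrh_value()]
#' to net assimilation versus PAR, multi-started over curvature values
#' Theta in \{0.3, 0.5, 0.7, 0.9\}; the start with the lowest SSE wins.
#'
#' @param curve A \code{light_curve} or data.frame with columns \code{par}
#'   and \code{A}; at least 5 steps including one at or below 150 umol
#'   photons m-2 s-1.
#' @param theta_starts Curvature multi-start grid.
#' @return An object of class \code{nrh_fit}: list with \code{Amax},
#'   \code{Rd}, \code{Phi}, \code{Theta}, \code{sse}, \code{converged},
#'   \code{boundary} (TRUE when a parameter is pinned at a bound).
#' @examples
#' d <- data.frame(par = c(50, 150, 300, 600, 900, 1200, 1500))
#' d$A <- nrh_value(d$par, Phi = 0.06, Amax = 20, Theta = 0.7, Rd = 1)
#' fit_nrh(d)
#' @export
fit_nrh <- function(curve, theta_starts = c(0.3, 0.5, 0.7, 0.9)) {
  stopifnot(is.data.frame(curve), all(c("par", "A") %in% names(curve)))
  d <- data.frame(par = curve$par, A = curve$A)
  d <- d[order(d$par), ]
  if (nrow(d) < 5) stop("need at least 5 light steps", call. = FALSE)
  if (min(d$par) > 150) {
    stop("need at least one step at or below 150 umol photons m-2 s-1 to anchor Phi",
         call. = FALSE)
  }
  if (stats::sd(d$A) == 0) {
    # flat curve: Amax unidentifiable
    return(structure(
      list(Amax = NA_real_, Rd = NA_real_, Phi = NA_real_, Theta = NA_real_,
           sse = 0, converged = FALSE, boundary = TRUE),
      class = "nrh_fit"
    ))
  }
  # starts: Rd from extrapolating the lowest steps, Phi from their slope
  lo <- d[seq_len(min(3, nrow(d))), ]
  sl <- stats::coef(stats::lm(A ~ par, data = lo))
  rd0 <- max(-sl[1], 0.01)
  phi0 <- min(max(sl[2], 1e-3), 0.2)
  amax0 <- max(max(d$A) + rd0, 0.5)
  lower <- c(Phi = 1e-4, Amax = 1e-2, Theta = 1e-6, Rd = 0)
  upper <- c(Phi = 1, Amax = Inf, Theta = 1, Rd = Inf)
  resid_fn <- function(q) {
    .nrh_safe(d$par, q[1], q[2], q[3], q[4]) - d$A
  }
  best <- NULL
  for (th0 in theta_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(Phi = phi0, Amax = amax0, Theta = th0, Rd = rd0),
        fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(cf = fit$par, sse = sse, converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    stop("non-rectangular hyperbola fit failed from all starts", call. = FALSE)
  }
  cf <- best$cf
  boundary <- cf["Theta"] <= lower["Theta"] * (1 + 1e-8) ||
    cf["Theta"] >= 1 - 1e-10 || cf["Phi"] <= lower["Phi"] * (1 + 1e-8) ||
    cf["Amax"] <= lower["Amax"] * (1 + 1e-8)
  structure(
    list(Amax = unname(cf["Amax"]), Rd = unname(cf["Rd"]),
         Phi = unname(cf["Phi"]), Theta = unname(cf["Theta"]),
         sse = best$sse, converged = isTRUE(best$converged),
         boundary = isTRUE(unname(boundary))),
    class = "nrh_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nrh_fit <- function(x, ...) {
  cat("Non-rectangular hyperbola light-response fit\n")
  cat(sprintf("  Amax  = %8.3f umol m-2 s-1\n", x$Amax))
  cat(sprintf("  Phi   = %8.4f mol CO2 mol photons-1\n", x$Phi))
  cat(sprintf("  Theta = %8.4f\n", x$Theta))
  cat(sprintf("  Rd    = %8.3f umol m-2 s-1\n", x$Rd))
  cat(sprintf("  SSE %.4g; converged: %s%s\n", x$sse, x$converged,
              if (isTRUE(x$boundary)) "; parameter at bound" else ""))
  invisible(x)
}

#' Photorespiration from paired light curves
#'
#' The operational photorespiration estimate of the low-oxygen difference
#' method: \code{Phresp = AG - AN} per PAR step, where AG is net assimilation
#' under non-photorespiratory (low O2) air and AN under normal air. Curves
#' are aligned on the intersection of their PAR grids (steps present in only
#' one curve are dropped with a warning). Negative values, which arise from
#' measurement noise, are retained and flagged rather than clipped.
#'
#' @param gross \code{light_curve} measured under low O2 (condition
#'   \code{"low_O2"}).
#' @param net \code{light_curve} measured under normal air (condition
#'   \code{"photorespiratory"}).
#' @return A \code{photoresp_series} data.frame: \code{par}, \code{AG},
#'   \code{AN}, \code{Phresp}, \code{flagged}.
#' @export
photorespiration_series <- function(gross, net) {
  cond_g <- attr(gross, "condition")
  cond_n <- attr(net, "condition")
  if (!is.null(cond_g) && !is.null(cond_n) && cond_g == cond_n) {
    stop("both curves carry the same gas condition label", call. = FALSE)
  }
  if (identical(cond_g, "photorespiratory") || identical(cond_n, "low_O2")) {
    stop("curves appear swapped: `gross` must be the low-O2 curve", call. = FALSE)
  }
  common <- intersect(gross$par, net$par)
  if (length(common) == 0) {
    stop("PAR grids of the two curves are disjoint", call. = FALSE)
  }
  dropped <- setdiff(union(gross$par, net$par), common)
  if (length(dropped) > 0) {
    warning(sprintf("dropping PAR steps present in only one curve: %s",
                    paste(sort(dropped), collapse = ", ")), call. = FALSE)
  }
  common <- sort(common)
  ag <- gross$A[match(common, gross$par)]
  an <- net$A[match(common, net$par)]
  ph <- ag - an
  structure(
    data.frame(par = common, AG = ag, AN = an, Phresp = ph,
               flagged = ph < 0),
    class = c("photoresp_series", "data.frame")
  )
}

#' PAR at which a light-response series saturates
#'
#' Formalises the visual "saturates at ..." statement: the plateau is the
#' mean of the two largest values, and the saturation PAR is the smallest
#' measured PAR whose value reaches \code{fraction} of the plateau.
#' Optionally interpolates linearly between the bracketing steps.
#'
#' @param values Response values (e.g. A or qN), one per PAR step.
#' @param par PAR steps, ascending.
#' @param fraction Fraction of the plateau defining saturation.
#' @param interpolate If \code{TRUE}, return the linear interpolation
#'   between the last step below and the first step at/above the criterion.
#' @return List with \code{par_sat}, \code{plateau}, \code{criterion} and
#'   \code{warning} (\code{TRUE} when the series peaks at the lowest PAR or
#'   only the last step reaches the criterion).
#' @examples
#' saturation_par(c(2, 8, 15, 19, 20, 20), c(50, 150, 300, 600, 900, 1250))
#' @export
saturation_par <- function(values, par, fraction = 0.95, interpolate = FALSE) {
  stopifnot(length(values) == length(par), length(par) > 0,
            fraction > 0, fraction <= 1)
  if (is.unsorted(par, strictly = TRUE)) {
    stop("`par` must be strictly ascending", call. = FALSE)
  }
  plateau <- mean(sort(values, decreasing = TRUE)[seq_len(min(2, length(values)))])
  crit <- fraction * plateau
  warn <- which.max(values) == 1
  idx <- which(values >= crit)
  if (length(idx) == 0) {
    idx <- length(values)
    warn <- TRUE
  }
  i <- idx[1]
  if (i == length(values)) warn <- TRUE # saturation only at the final step
  par_sat <- par[i]
  if (interpolate && i > 1 && values[i] > values[i - 1]) {
    par_sat <- par[i - 1] + (crit - values[i - 1]) *
      (par[i] - par[i - 1]) / (values[i] - values[i - 1])
    par_sat <- min(par_sat, par[i])
  }
  list(par_sat = par_sat, plateau = plateau, criterion = crit,
       warning = warn)
}
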