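#' Fit an A-Ci curve by the bilinear two-limitation method
#'
#' Estimates Vcmax and J by the "bilinear" FvCB fitting strategy: on a Ci
#' basis (mesophyll conductance treated as infinite at this stage, as in the
#' protocol, where gm is estimated separately by the variable-J method), both
#' limitation branches are linear in their parameter,
#' \deqn{A + R_{day} = V_{cmax} \frac{C_i - \Gamma^*}{C_i + K_c(1+O/K_o)}
#' \quad\text{or}\quad A + R_{day} = \frac{J}{4}\,
#' \frac{C_i - \Gamma^*}{C_i + 2\Gamma^*},}
#' so for every candidate transition Ci (grid = the observed Ci values) the
#' two segments are fitted by least squares and the transition minimising the
#' pooled SSE is chosen (SSE ties broken toward the lower transition).
#'
#' J is estimated at the curve's measurement PAR; the Jmax asymptote is
#' recovered by inverting the J-PAR hyperbola ([jmax_from_j()]) and J at the
#' reporting convention PAR = 1261 umol m-2 s-1 is evaluated from it, so all
#' three are returned.
#'
#' @param curve An \code{aci_curve} (columns \code{Ci}, \code{A}, optionally
#'   \code{par}).
#' @param constants An [fvcb_params()] carrying the fixed constants
#'   (GammaStar, Kc, Ko, O, alphaJ, thetaJ); Vcmax/Jmax in it are ignored.
#' @param Rday Known day respiration (umol m-2 s-1), e.g. the Laisk
#'   estimate. If \code{NULL}, Rday is co-fitted (shared by both segments,
#'   bounded below by 0).
#' @param par_ref Reference PAR for the J report (umol photons m-2 s-1).
#' @return An object of class \code{aci_fit}: list with \code{Vcmax},
#'   \code{J_at_par} (at the measurement PAR), \code{Jmax_asymptote},
#'   \code{J_at_ref}, \code{Rday_used}, \code{transition_Ci}, \code{sse},
#'   \code{n_rubisco}, \code{n_rubp}, \code{par}, \code{par_ref}.
#' @examples
#' curve <- simulate_aci(fvcb_params(Vcmax = 60, Jmax = 120),
#'                       sim_spec(noise_sd_A = 0))
#' fit_aci_bilinear(curve, fvcb_params(), Rday = 1)
#' @export
fit_aci_bilinear <- function(curve, constants = fvcb_params(), Rday = NULL,
                             par_ref = 1261) {
  stopifnot(is.data.frame(curve), all(c("Ci", "A") %in% names(curve)),
            inherits(constants, "fvcb_params"))
  Ci <- curve$Ci
  A <- curve$A
  ord <- order(Ci)
  Ci <- Ci[ord]; A <- A[ord]
  n <- length(Ci)
  if (n < 6) stop("need at least 6 points to fit both regimes", call. = FALSE)
  if (max(Ci) / min(Ci) <= 5) {
    stop("Ci range too narrow to span both limitation regimes (max/min <= 5)",
         call. = FALSE)
  }
  Gs <- constants$GammaStar
  Km <- constants$Kc * (1 + constants$O / constants$Ko)
  xc <- (Ci - Gs) / (Ci + Km)
  xj <- (Ci - Gs) / (4 * Ci + 8 * Gs)

  fit_at <- function(t) {
    below <- seq_len(t)
    above <- (t + 1):n
    if (is.null(Rday)) {
      X <- cbind(c(xc[below], rep(0, n - t)),
                 c(rep(0, t), xj[above]),
                 -1)
      cf <- stats::lsfit(X, A, intercept = FALSE)$coefficients
      if (cf[3] < 0) { # Rday bounded below at 0: refit without it
        cf12 <- c(sum(A[below] * xc[below]) / sum(xc[below]^2),
                  sum(A[above] * xj[above]) / sum(xj[above]^2))
        cf <- c(cf12, 0)
      }
      vc <- cf[1]; jj <- cf[2]; rd <- cf[3]
    } else {
      rd <- Rday
      y <- A + rd
      vc <- sum(y[below] * xc[below]) / sum(xc[below]^2)
      jj <- sum(y[above] * xj[above]) / sum(xj[above]^2)
    }
    pred <- c(vc * xc[below], jj * xj[above]) - rd
    list(vc = vc, j = jj, rd = rd, t = t, sse = sum((A - pred)^2))
  }
  cand <- lapply(3:(n - 3), fit_at)
  sse <- vapply(cand, `[[`, numeric(1), "sse")
  best <- cand[[which.min(sse)]] # which.min takes the first (lowest Ci) tie
  if (best$vc <= 0 || best$j <= 0) {
    stop("fit did not converge to positive rates; check the input curve",
         call. = FALSE)
  }
  # identifiability: when one limitation alone explains the curve as well as
  # the bilinear model does, the other regime was never observed
  single_sse <- function(x) {
    if (is.null(Rday)) {
      cf <- stats::lsfit(cbind(x, -1), A, intercept = FALSE)$coefficients
      sum((A - (x * cf[1] - cf[2]))^2)
    } else {
      y <- A + Rday
      sum((y - x * sum(y * x) / sum(x^2))^2)
    }
  }
  slack <- 2 * best$sse + 1e-8 * n
  if (single_sse(xc) <= slack) {
    stop("RuBP-regeneration regime not observed: Jmax unidentifiable",
         call. = FALSE)
  }
  if (single_sse(xj) <= slack) {
    stop("Rubisco regime not observed: Vcmax unidentifiable", call. = FALSE)
  }
  par_meas <- if ("par" %in% names(curve)) curve$par[1] else par_ref
  jmax <- tryCatch(
    jmax_from_j(best$j, par_meas, constants$alphaJ, constants$thetaJ),
    error = function(e) NA_real_
  )
  j_ref <- if (is.na(jmax)) NA_real_ else
    j_of_par(par_ref, fvcb_params(Jmax = jmax, alphaJ = constants$alphaJ,
                                  thetaJ = constants$thetaJ))
  structure(
    list(Vcmax = unname(best$vc), J_at_par = unname(best$j),
         Jmax_asymptote = unname(jmax), J_at_ref = unname(j_ref),
         Rday_used = unname(best$rd), transition_Ci = Ci[best$t],
         sse = best$sse, n_rubisco = best$t, n_rubp = n - best$t,
         par = par_meas, par_ref = par_ref),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("Bilinear FvCB A-Ci fit (Ci basis)\n")
  cat(sprintf("  Vcmax          = %8.3f umol m-2 s-1\n", x$Vcmax))
  cat(sprintf("  J at PAR %4.0f  = %8.3f umol m-2 s-1\n", x$par, x$J_at_par))
  cat(sprintf("  Jmax asymptote = %8.3f umol m-2 s-1\n", x$Jmax_asymptote))
  cat(sprintf("  J at PAR %4.0f  = %8.3f umol m-2 s-1\n", x$par_ref, x$J_at_ref))
  cat(sprintf("  Rday used      = %8.3f umol m-2 s-1\n", x$Rday_used))
  cat(sprintf("  transition Ci  = %8.1f umol mol-1 (%d + %d points), SSE %.4g\n",
              x$transition_Ci, x$n_rubisco, x$n_rubp, x$sse))
  invisible(x)
}
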