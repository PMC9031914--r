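#' Photochemical quenching coefficient qP
#'
#' \eqn{qP = (F_m' - F_s)/(F_m' - F_o')}: the fraction of PSII reaction
#' centres in the open state under the puddle model.
#'
#' @param fm_prime Light-adapted maximal fluorescence Fm'.
#' @param fs Steady-state fluorescence in the light.
#' @param fo_prime Light-adapted minimal fluorescence Fo' (measured or
#'   calculated).
#' @return qP, vectorised.
#' @examples
#' compute_qp(1200, 600, 400) # 0.75
#' @export
compute_qp <- function(fm_prime, fs, fo_prime) {
  if (any(fm_prime <= fo_prime)) {
    stop("degenerate fluorescence: Fm' must exceed Fo'", call. = FALSE)
  }
  (fm_prime - fs) / (fm_prime - fo_prime)
}

#' Non-photochemical quenching coefficient qN
#'
#' \eqn{qN = (F_m - F_m')/(F_m - F_o')}, exactly as printed in the study
#' protocol. Note the denominator uses the light-adapted Fo'; the classical
#' definition divides by the dark-adapted variable fluorescence
#' \eqn{F_m - F_o} instead, and is available via \code{variant = "classic"}
#' (which then expects the dark Fo in the third argument).
#'
#' @param fm Dark-adapted maximal fluorescence Fm.
#' @param fm_prime Light-adapted maximal fluorescence Fm'.
#' @param fo_prime Light-adapted minimal fluorescence Fo' (dark Fo for the
#'   classic variant).
#' @param variant \code{"printed"} (default) or \code{"classic"}.
#' @return qN, vectorised.
#' @examples
#' compute_qn(2000, 1200, 400) # 0.5
#' @export
compute_qn <- function(fm, fm_prime, fo_prime, variant = c("printed", "classic")) {
  variant <- match.arg(variant)
  if (any(fm <= fo_prime)) {
    stop("degenerate fluorescence: Fm must exceed Fo'", call. = FALSE)
  }
  (fm - fm_prime) / (fm - fo_prime)
}

#' Calculated light-adapted minimal fluorescence Fo'
#'
#' Oxborough-Baker estimate used when Fo' is not measured directly:
#' \deqn{F_o'^{calc} = \frac{F_o}{F_v/F_m + F_o/F_m'}.}
#' Equal to Fo in the dark-adapted state (Fm' = Fm) and decreasing with
#' Fm' as NPQ develops.
#'
#' @param fo Dark minimal fluorescence.
#' @param fm Dark maximal fluorescence.
#' @param fm_prime Light-adapted maximal fluorescence.
#' @return Fo'_calc, vectorised.
#' @examples
#' fo_prime_calc(500, 2500, 1250) # 416.67
#' @export
fo_prime_calc <- function(fo, fm, fm_prime) {
  if (any(fm <= fo)) stop("degenerate fluorescence: Fm must exceed Fo", call. = FALSE)
  if (any(fm_prime <= 0)) stop("Fm' must be positive", call. = FALSE)
  denom <- (fm - fo) / fm + fo / fm_prime
  if (any(denom <= 0)) {
    stop("degenerate fluorescence: non-positive Fo' denominator", call. = FALSE)
  }
  fo / denom
}

#' Quenching analysis of a qPd protocol trace
#'
#' Computes, per light step: the photochemical quenching qP (using measured
#' Fo' when a \code{Fo_light} column is present, else the calculated Fo'),
#' the non-photochemical quenching qN (printed convention), Stern-Volmer
#' \eqn{NPQ = (F_m - F_m')/F_m'}, the calculated Fo', and the dark-assessed
#' photochemical quenching
#' \deqn{qPd = \frac{F_{m,dark}' - F_{o,actual}}{F_{m,dark}' - F_o'^{calc}},}
#' which equals 1 while the post-illumination minimal fluorescence matches
#' the calculated Fo' and falls below 1 once photoinhibitory Fo rises set in.
#' qPd always uses the calculated Fo', per the protocol it follows.
#'
#' @param trace A \code{fluor_trace}: per-step columns \code{par}, \code{Fs},
#'   \code{Fmp}, \code{Fo_dark}, \code{Fmp_dark} (and optionally
#'   \code{Fo_light}), with dark-adapted \code{Fo}, \code{Fm} attributes.
#' @return A \code{quench_series} data.frame: \code{par}, \code{qP},
#'   \code{qN}, \code{NPQ}, \code{Fo_prime_calc}, \code{Fo_prime_used},
#'   \code{qPd}, \code{flagged} (coefficient outside [0, 1 + 0.05]).
#' @examples
#' tr <- simulate_qpd_protocol(fluor_params(kinh = 0))
#' compute_qpd_series(tr)$qPd
#' @export
compute_qpd_series <- function(trace) {
  need <- c("par", "Fs", "Fmp", "Fo_dark", "Fmp_dark")
  stopifnot(is.data.frame(trace), all(need %in% names(trace)))
  miss <- !stats::complete.cases(trace[c("Fo_dark", "Fmp_dark")])
  if (any(miss)) {
    stop(sprintf("missing dark-interval records at step(s): %s",
                 paste(which(miss), collapse = ", ")), call. = FALSE)
  }
  fo <- attr(trace, "Fo")
  fm <- attr(trace, "Fm")
  if (is.null(fo) || is.null(fm)) {
    stop("trace lacks dark-adapted Fo/Fm attributes", call. = FALSE)
  }
  fop_calc <- fo_prime_calc(fo, fm, trace$Fmp)
  fop_used <- if ("Fo_light" %in% names(trace) && !anyNA(trace$Fo_light)) {
    trace$Fo_light
  } else {
    fop_calc
  }
  qp <- compute_qp(trace$Fmp, trace$Fs, fop_used)
  qn <- compute_qn(fm, trace$Fmp, fop_used)
  npq <- (fm - trace$Fmp) / trace$Fmp
  qpd <- (trace$Fmp_dark - trace$Fo_dark) / (trace$Fmp_dark - fop_calc)
  eps <- 0.05
  flagged <- qp < -eps | qp > 1 + eps | qn < -eps | qn > 1 + eps |
    qpd > 1 + eps
  structure(
    data.frame(par = trace$par, qP = qp, qN = qn, NPQ = npq,
               Fo_prime_calc = fop_calc, Fo_prime_used = fop_used,
               qPd = qpd, flagged = flagged),
    class = c("quench_series", "data.frame")
  )
}

#' Photoprotection light threshold from a qPd series
#'
#' The PAR above which NPQ is no longer fully protective: the smallest
#' scripted PAR whose dark-assessed qPd falls below \code{criterion}.
#' Returns \code{NA} when qPd never crosses the criterion.
#'
#' @param series A \code{quench_series} (or data.frame with \code{par} and
#'   \code{qPd}), sorted by PAR.
#' @param criterion qPd floor defining "deviates from the maximum". The
#'   value 0.98 is a configurable convention, not a protocol constant.
#' @return List with \code{threshold} (PAR, or \code{NA}), and
#'   \code{bracket}: the last PAR with qPd at or above the criterion and the
#'   threshold step.
#' @examples
#' s <- data.frame(par = c(60, 100, 250, 400, 600),
#'                 qPd = c(1, 1, 0.99, 0.97, 0.92))
#' photoprotection_threshold(s)$threshold # 400
#' @export
photoprotection_threshold <- function(series, criterion = 0.98) {
  stopifnot(is.data.frame(series), all(c("par", "qPd") %in% names(series)))
  if (is.unsorted(series$par, strictly = TRUE)) {
    stop("`series` must be sorted by increasing PAR", call. = FALSE)
  }
  below <- which(series$qPd < criterion)
  if (length(below) == 0) {
    return(list(threshold = NA_real_, bracket = c(NA_real_, NA_real_)))
  }
  i <- below[1]
  list(
    threshold = series$par[i],
    bracket = c(if (i > 1) series$par[i - 1] else NA_real_, series$par[i])
  )
}
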