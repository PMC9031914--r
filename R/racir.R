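#' Delta-filter a RACiR trace to its quasi-linear portion
#'
#' Implements the instrument-style cleaning step for rapid A-Ci ramps: a
#' record is kept only if its assimilation differs from the last KEPT record
#' by at most \code{threshold}; the first record is always kept. Anchoring
#' on the last kept record makes the filter a single deterministic pass and
#' idempotent. Records failing the criterion (chamber mixing transients,
#' outliers) are dropped; order is preserved.
#'
#' @param trace A \code{racir_trace} (or any data.frame with an \code{A}
#'   column).
#' @param threshold Maximum allowed |A_i - A_last_kept| (umol m-2 s-1).
#' @return The filtered trace, same class and attributes.
#' @examples
#' tr <- simulate_racir_pair(fvcb_params(), sim_spec(noise_sd_A = 0))$leaf
#' nrow(delta_filter(tr, 0.05))
#' @export
delta_filter <- function(trace, threshold = 0.05) {
  stopifnot(is.data.frame(trace), "A" %in% names(trace), threshold >= 0)
  if (nrow(trace) < 2) {
    stop("delta_filter needs at least 2 records", call. = FALSE)
  }
  A <- trace$A
  keep <- logical(length(A))
  keep[1] <- TRUE
  last <- A[1]
  for (i in 2:length(A)) {
    if (abs(A[i] - last) <= threshold) {
      keep[i] <- TRUE
      last <- A[i]
    }
  }
  out <- trace[keep, , drop = FALSE]
  attributes(out)$meta <- attr(trace, "meta")
  rownames(out) <- NULL
  out
}

# second-order-corrected AIC for a least-squares fit with k estimated
# coefficients (+1 for sigma)
aicc_ls <- function(rss, n, k) {
  k <- k + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Correct a leaf RACiR trace with an empty-chamber trace
#'
#' The empty-chamber ramp records the instrument artifact (IRGA lag, match
#' offset, residual time delays) as an apparent assimilation. The artifact
#' is modelled as a polynomial in reference CO2 with the degree (1-5)
#' selected by small-sample corrected AIC, subtracted from the leaf trace,
#' and Ci is recomputed from the corrected assimilation and the stomatal
#' conductance (\code{Ci = CO2_s - 1.6 A / gsw}). The output is restricted
#' to the CO2 range where both ramps overlap.
#'
#' Only "up"-ramp records enter the correction; records flagged as "down"
#' are excluded. Both traces should already be [delta_filter()]ed.
#'
#' @param leaf Leaf \code{racir_trace}.
#' @param empty Empty-chamber \code{racir_trace} from the same day.
#' @param degree Optional fixed polynomial degree (1-5); default selects by
#'   corrected AIC.
#' @param align_lag If \code{TRUE}, estimate a constant time shift between
#'   the traces by maximising the cross-correlation of their first
#'   differences, and shift the empty trace accordingly before fitting.
#'   The residual-delay correction of the protocol is not parameterised in
#'   the source instrument documentation; this is an explicit assumption.
#' @return An \code{aci_curve} with correction metadata (degree,
#'   coefficients, residual s.d., possible \code{degraded_fit} flag)
#'   attached in \code{attr(, "meta")$correction}.
#' @export
correct_racir <- function(leaf, empty, degree = NULL, align_lag = FALSE) {
  stopifnot(inherits(leaf, "racir_trace"), inherits(empty, "racir_trace"))
  leaf <- leaf[leaf$direction == "up", , drop = FALSE]
  empty <- empty[empty$direction == "up", , drop = FALSE]
  if (nrow(leaf) < 6 || nrow(empty) < 6) {
    stop("need at least 6 up-ramp records in each trace", call. = FALSE)
  }
  if (align_lag) {
    lag <- best_lag(leaf$A, empty$A)
    # a lag of k records corresponds to a CO2 shift of k ramp increments
    empty$CO2_r <- empty$CO2_r + lag * mean(diff(empty$CO2_r))
  }
  lo <- max(min(leaf$CO2_r), min(empty$CO2_r))
  hi <- min(max(leaf$CO2_r), max(empty$CO2_r))
  leaf_span <- diff(range(leaf$CO2_r))
  if ((hi - lo) / leaf_span < 0.8) {
    stop(sprintf(
      "empty-chamber ramp overlaps only %.0f%% of the leaf ramp (>= 80%% required)",
      100 * (hi - lo) / leaf_span), call. = FALSE)
  }
  emp <- empty[empty$CO2_r >= lo & empty$CO2_r <= hi, , drop = FALSE]
  degraded <- FALSE
  if (is.null(degree)) {
    fits <- lapply(1:5, function(d)
      stats::lm(A ~ stats::poly(CO2_r, d, raw = TRUE), data = emp))
    rss <- vapply(fits, stats::deviance, numeric(1))
    ic <- mapply(aicc_ls, rss, nrow(emp), 2:6)
    # parsimony: smallest degree within 2 AICc units of the minimum
    degree <- which(ic <= min(ic) + 2)[1]
    fit <- fits[[degree]]
  } else {
    stopifnot(degree >= 1, degree <= 5)
    fit <- stats::lm(A ~ stats::poly(CO2_r, degree, raw = TRUE), data = emp)
  }
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    degraded <- TRUE
    coefs[is.na(coefs)] <- 0
  }
  out <- leaf[leaf$CO2_r >= lo & leaf$CO2_r <= hi, , drop = FALSE]
  A_corr <- out$A - polyval(unname(coefs), out$CO2_r)
  Ci_corr <- out$CO2_s - 1.6 * A_corr / out$gsw
  meta <- attr(leaf, "meta")
  meta$correction <- list(
    degree = degree, coefficients = unname(coefs),
    resid_sd = stats::sd(stats::residuals(fit)),
    degraded_fit = degraded,
    co2_window = c(lo, hi)
  )
  meta$source <- paste0(if (is.null(meta$source)) "" else meta$source,
                        "+racir_corrected")
  par_meas <- if (!is.null(meta$par)) meta$par else NA_real_
  new_aci_curve(
    data.frame(Ci = Ci_corr, A = A_corr, par = par_meas),
    meta = meta
  )
}

# integer lag (in records) maximising cross-correlation of first differences
best_lag <- function(x, y, max_lag = 25) {
  dx <- diff(x); dy <- diff(y)
  n <- min(length(dx), length(dy))
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- dx[(1 + l):n]; b <- dy[1:(n - l)]
    } else {
      a <- dx[1:(n + l)]; b <- dy[(1 - l):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  lags[which.max(score)]
}
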