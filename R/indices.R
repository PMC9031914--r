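#' Xanthophyll-cycle de-epoxidation state
#'
#' \eqn{DES = (Z + A)/(V + A + Z)}: the fraction of the xanthophyll-cycle
#' pool converted to the photoprotective de-epoxidised forms (zeaxanthin +
#' antheraxanthin). Unit-free and invariant to rescaling of the pool.
#'
#' @param V,A,Z Violaxanthin, antheraxanthin and zeaxanthin concentrations
#'   (any consistent unit), vectorised.
#' @return DES in \code{[0, 1]}.
#' @examples
#' deepoxidation_index(V = 3.2, A = 0.8, Z = 0.4) # 0.2727
#' @export
deepoxidation_index <- function(V, A, Z) {
  stopifnot(all(V >= 0), all(A >= 0), all(Z >= 0))
  pool <- V + A + Z
  if (any(pool <= 0)) {
    stop("undefined de-epoxidation state: empty xanthophyll pool", call. = FALSE)
  }
  (Z + A) / pool
}

#' Pigment ratios on a chlorophyll basis
#'
#' The three pigment indices of the analysis: the chlorophyll a/b ratio, the
#' xanthophyll-cycle pool (V + A + Z) per unit chlorophyll, and lutein per
#' unit chlorophyll. "Chlorophyll" defaults to chl a + chl b; a chl-a-only
#' basis is available since the source protocol does not specify the
#' denominator.
#'
#' @param chl_a,chl_b Chlorophyll a and b concentrations.
#' @param V,A,Z Xanthophyll-cycle pigment concentrations.
#' @param lutein Lutein concentration.
#' @param chl_basis Denominator: \code{"total"} (chl a + chl b) or
#'   \code{"chl_a"}.
#' @return A data.frame with columns \code{chl_ab}, \code{vaz_chl},
#'   \code{lutein_chl}; undefined ratios are \code{NA}.
#' @examples
#' pigment_ratios(chl_a = 3, chl_b = 1, V = 0.3, A = 0.05, Z = 0.05,
#'                lutein = 0.4)
#' @export
pigment_ratios <- function(chl_a, chl_b, V, A, Z, lutein,
                           chl_basis = c("total", "chl_a")) {
  chl_basis <- match.arg(chl_basis)
  stopifnot(all(chl_a >= 0), all(chl_b >= 0), all(V >= 0), all(A >= 0),
            all(Z >= 0), all(lutein >= 0))
  chl <- if (chl_basis == "total") chl_a + chl_b else chl_a
  ab <- ifelse(chl_b > 0, chl_a / chl_b, NA_real_)
  vaz <- ifelse(chl > 0, (V + A + Z) / chl, NA_real_)
  lut <- ifelse(chl > 0, lutein / chl, NA_real_)
  data.frame(chl_ab = ab, vaz_chl = vaz, lutein_chl = lut)
}

#' Leaf light-interception fraction
#'
#' Incident PAR on the lamina (sensor held at the leaf angle) as a
#' percentage of above-canopy PAR.
#'
#' @param leaf_par Incident PAR on the leaf (umol photons m-2 s-1).
#' @param canopy_par Above-canopy PAR (umol photons m-2 s-1).
#' @return Percentage (0-100, possibly above with a warning), vectorised.
#' @examples
#' interception_fraction(700, 2350) # ~29.8
#' @export
interception_fraction <- function(leaf_par, canopy_par) {
  stopifnot(all(leaf_par >= 0))
  if (any(canopy_par <= 0)) {
    stop("undefined interception: above-canopy PAR must be positive",
         call. = FALSE)
  }
  if (any(leaf_par > canopy_par)) {
    warning("leaf PAR exceeds above-canopy PAR at some points", call. = FALSE)
  }
  100 * leaf_par / canopy_par
}
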