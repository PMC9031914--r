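#' Estimate Ci* and Rday by the Laisk slope-intersection method
#'
#' Fits an ordinary least-squares line to each of three low-light, low-CO2
#' A-Ci segments. In theory the three lines meet at a single point whose
#' x coordinate is the apparent CO2 compensation point Ci* and whose
#' y coordinate is -Rday; in practice the three pairwise intersections form
#' a triangle, and the estimate is taken as the barycentre (centroid) of
#' that triangle.
#'
#' The x estimate is the Ci-basis apparent compensation point Ci*, which
#' equals Gamma* only for infinite mesophyll conductance (in general
#' Ci* = Gamma* - Rday/gm); it is stored as \code{GammaStar_app} to keep the
#' distinction explicit.
#'
#' @param segments A \code{laisk_segments} data.frame (columns \code{Ci},
#'   \code{A}, \code{par}) with exactly three distinct PAR levels and at
#'   least 3 points each.
#' @return An object of class \code{laisk_result}: list with
#'   \code{GammaStar_app}, \code{Rday}, \code{lines} (data.frame par,
#'   intercept, slope), \code{triangle} (3 x 2 matrix of intersection
#'   vertices), \code{barycentre}, \code{triangle_area} and
#'   \code{rday_out_of_range} flag (TRUE when the barycentre implies a
#'   negative Rday).
#' @examples
#' seg <- simulate_laisk_segments(fvcb_params())
#' fit_laisk(seg)
#' @export
fit_laisk <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("Ci", "A", "par") %in% names(segments)))
  pars <- sort(unique(segments$par), decreasing = TRUE)
  if (length(pars) != 3) {
    stop("the Laisk construction needs exactly three PAR levels", call. = FALSE)
  }
  lines <- t(vapply(pars, function(pp) {
    seg <- segments[segments$par == pp, ]
    if (nrow(seg) < 3) {
      stop(sprintf("segment at PAR %g has fewer than 3 points", pp),
           call. = FALSE)
    }
    stats::coef(stats::lm(A ~ Ci, data = seg))
  }, numeric(2)))
  colnames(lines) <- c("intercept", "slope")
  combs <- list(c(1, 2), c(1, 3), c(2, 3))
  verts <- t(vapply(combs, function(ij) {
    i <- ij[1]; j <- ij[2]
    ds <- lines[i, "slope"] - lines[j, "slope"]
    if (abs(ds) < 1e-10) {
      stop(sprintf("segments at PAR %g and %g are parallel (slopes equal within 1e-10)",
                   pars[i], pars[j]), call. = FALSE)
    }
    x <- (lines[j, "intercept"] - lines[i, "intercept"]) / ds
    c(x = x, y = lines[i, "intercept"] + lines[i, "slope"] * x)
  }, numeric(2)))
  colnames(verts) <- c("x", "y")
  bary <- colMeans(verts)
  area <- unname(abs((verts[2, 1] - verts[1, 1]) * (verts[3, 2] - verts[1, 2]) -
                     (verts[3, 1] - verts[1, 1]) * (verts[2, 2] - verts[1, 2])) / 2)
  rday <- -bary[["y"]]
  structure(
    list(
      GammaStar_app = bary[["x"]],
      Rday = rday,
      lines = data.frame(par = pars, intercept = lines[, "intercept"],
                         slope = lines[, "slope"], row.names = NULL),
      triangle = verts,
      barycentre = c(x = bary[["x"]], y = bary[["y"]]),
      triangle_area = area,
      rday_out_of_range = rday < 0
    ),
    class = "laisk_result"
  )
}

#' @export
print.laisk_result <- function(x, ...) {
  cat("Laisk slope-intersection estimate\n")
  cat(sprintf("  Ci* (apparent GammaStar) = %.3f umol mol-1\n", x$GammaStar_app))
  cat(sprintf("  Rday                     = %.4f umol m-2 s-1%s\n", x$Rday,
              if (x$rday_out_of_range) "  [out of range]" else ""))
  cat(sprintf("  intersection triangle area = %.4g\n", x$triangle_area))
  print(x$lines)
  invisible(x)
}

#' Electron transport rate from PSII operating efficiency
#'
#' \eqn{ETR = \Phi_{PSII} \cdot PAR \cdot \alpha \cdot f_{PSII}}, the
#' community-standard conversion with leaf absorptance 0.84 and an equal
#' excitation split between photosystems (0.5). The study protocol does not
#' state the factors, so both are exposed as arguments.
#'
#' @param phiPSII PSII operating efficiency (Fm' - Fs)/Fm', in \code{[0, 1]}.
#' @param par Incident PAR (umol photons m-2 s-1).
#' @param absorptance Leaf absorptance.
#' @param fPSII Fraction of absorbed quanta reaching PSII.
#' @return ETR (umol e- m-2 s-1), vectorised.
#' @examples
#' compute_etr(0.5, 1000) # 210
#' @export
compute_etr <- function(phiPSII, par, absorptance = 0.84, fPSII = 0.5) {
  stopifnot(is.numeric(phiPSII), is.numeric(par))
  if (any(phiPSII < 0 | phiPSII > 1)) {
    stop("`phiPSII` must lie in [0, 1]", call. = FALSE)
  }
  if (any(par < 0)) stop("`par` must be non-negative", call. = FALSE)
  phiPSII * par * absorptance * fPSII
}

#' Mesophyll conductance by the variable-J method
#'
#' Combines gas exchange and fluorescence-derived electron transport:
#' \deqn{g_m = \frac{A_N}{C_i - \Gamma^* \dfrac{ETR + 8(A_N + R_{day})}
#' {ETR - 4(A_N + R_{day})}}.}
#' The Gamma* term is the chloroplast CO2 mole fraction Cc implied by the
#' RuBP-regeneration-limited model, so the estimate is only meaningful at
#' measurement points where electron transport limits assimilation.
#'
#' Vectorised; entries yielding non-physical results (gm <= 0, Cc >= Ci or
#' Cc <= 0) are returned with \code{flagged = TRUE} rather than dropped.
#'
#' @param AN Net assimilation (umol m-2 s-1).
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param ETR Electron transport rate (umol e- m-2 s-1).
#' @param GammaStar Photorespiratory compensation point (umol mol-1).
#' @param Rday Day respiration (umol m-2 s-1, positive).
#' @return A \code{gm_series} data.frame: \code{gm} (mol m-2 s-1), \code{Cc},
#'   \code{flagged}, plus the echoed inputs.
#' @examples
#' variable_j_gm(AN = 10, Ci = 250, ETR = 100, GammaStar = 40, Rday = 1)
#' @export
variable_j_gm <- function(AN, Ci, ETR, GammaStar, Rday) {
  k <- max(length(AN), length(Ci), length(ETR))
  AN <- rep_len(AN, k); Ci <- rep_len(Ci, k); ETR <- rep_len(ETR, k)
  GammaStar <- rep_len(GammaStar, k); Rday <- rep_len(Rday, k)
  denom <- ETR - 4 * (AN + Rday)
  if (any(abs(denom) < 1e-12)) {
    stop("singularity: ETR equals 4 (AN + Rday) at some point", call. = FALSE)
  }
  Cc <- GammaStar * (ETR + 8 * (AN + Rday)) / denom
  gap <- Ci - Cc
  if (any(abs(gap) < 1e-12)) {
    stop("singularity: Ci equals the GammaStar term at some point", call. = FALSE)
  }
  gm <- AN / gap
  flagged <- gm <= 0 | Cc >= Ci | Cc <= 0
  structure(
    data.frame(gm = gm, Cc = Cc, flagged = flagged, AN = AN, Ci = Ci,
               ETR = ETR, GammaStar = GammaStar, Rday = Rday),
    class = c("gm_series", "data.frame")
  )
}

#' Variable-J mesophyll conductance from a measured light curve
#'
#' Convenience wrapper: derives PhiPSII = (Fm' - Fs)/Fm' from the per-step
#' fluorescence of a light curve, converts it to ETR with [compute_etr()],
#' and applies [variable_j_gm()] with the supplied (e.g. Laisk-derived)
#' Gamma* and Rday.
#'
#' @param curve A \code{light_curve} with columns \code{par}, \code{A},
#'   \code{Ci}, \code{Fs}, \code{Fmp}.
#' @param GammaStar,Rday Constants for [variable_j_gm()].
#' @param absorptance,fPSII Passed to [compute_etr()].
#' @return A \code{gm_series} data.frame with an added \code{par} column.
#' @export
gm_from_light_curve <- function(curve, GammaStar, Rday,
                                absorptance = 0.84, fPSII = 0.5) {
  stopifnot(is.data.frame(curve),
            all(c("par", "A", "Ci", "Fs", "Fmp") %in% names(curve)))
  phi <- (curve$Fmp - curve$Fs) / curve$Fmp
  etr <- compute_etr(phi, curve$par, absorptance, fPSII)
  out <- variable_j_gm(curve$A, curve$Ci, etr, GammaStar, Rday)
  out$par <- curve$par
  out
}
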