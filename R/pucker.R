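# Sugar pucker pseudorotation (Altona-Sundaralingam).

#' Pseudorotation phase and amplitude from five ring torsions
#'
#' Implements the Altona-Sundaralingam parameterisation of furanose ring
#' pucker.  With the convention `nu_j = tau_m * cos(P + 144 * (j - 2))`
#' (so `nu2 = tau_m * cos(P)`), the phase satisfies
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 * nu2 * (sin 36 + sin 72))`.
#' The quadrant is resolved with the two-argument arctangent and the
#' amplitude is recovered as the Euclidean norm of the
#' `(tau_m cos P, tau_m sin P)` pair, which is stable near P = 90 or 270
#' where `nu2` vanishes.
#'
#' @param nu0,nu1,nu2,nu3,nu4 the five endocyclic torsions in degrees,
#'   ordered along the ring `O4'-C1'-C2'-C3'-C4'` (nu0 about `O4'-C1'`,
#'   nu2 about `C2'-C3'`, ...).  Vectorised.
#' @return a matrix (or named vector for scalar input) with columns
#'   `phase` (degrees in `[0, 360)`, `NA` for an essentially planar ring
#'   of amplitude below 1 degree) and `amplitude` (degrees, >= 0).
#' @examples
#' nu <- 38 * cos((162 + 144 * ((0:4) - 2)) * pi / 180)
#' pucker(nu[1], nu[2], nu[3], nu[4], nu[5])   # phase 162, amplitude 38
#' @export
pucker <- function(nu0, nu1, nu2, nu3, nu4) {
  k <- 2 * (sin(36 * pi / 180) + sin(72 * pi / 180))
  s <- ((nu4 + nu1) - (nu3 + nu0)) / k      # tau_m * sin(P)
  amp <- sqrt(nu2^2 + s^2)
  phase <- wrap_angle(atan2(s, nu2) * 180 / pi, lower = 0)
  phase[amp < 1] <- NA_real_
  out <- cbind(phase = phase, amplitude = amp)
  if (nrow(out) == 1L) out[1L, ] else out
}

.PUCKER_STATES <- c("C3'-endo", "C4'-exo", "O1'-endo", "C1'-exo",
                    "C2'-endo", "C3'-exo", "C4'-endo", "O1'-exo",
                    "C1'-endo", "C2'-exo")

#' Name the sugar-pucker state of a pseudorotation phase
#'
#' The pseudorotation wheel is divided into twenty half-open 18-degree
#' sectors; adjacent sector pairs are grouped into the ten conventional
#' 36-degree states (`C3'-endo` = `[0, 36)`, ..., `C2'-endo` = `[144, 180)`,
#' ...).  The ring oxygen is labelled `O1'` as in the older nucleic-acid
#' nomenclature; `O4'` is the modern synonym.
#'
#' @param P pseudorotation phase in degrees (any range; wrapped to
#'   `[0, 360)`), possibly `NA` for planar rings.
#' @param oxygen label to use for the ring oxygen in state names, either
#'   `"O1'"` (default, as in classic pseudorotation tables) or `"O4'"`.
#' @return character vector of state names; `"planar"` where `P` is `NA`.
#' @examples
#' classify_pucker(160)  # "C2'-endo"
#' classify_pucker(90)   # "O1'-endo"
#' @export
classify_pucker <- function(P, oxygen = c("O1'", "O4'")) {
  oxygen <- match.arg(oxygen)
  states <- .PUCKER_STATES
  if (oxygen == "O4'") states <- sub("O1'", "O4'", states, fixed = TRUE)
  P <- wrap_angle(P, lower = 0)
  out <- states[pmin(floor(P / 36) + 1, 10L)]
  out[is.na(P)] <- "planar"
  out
}
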