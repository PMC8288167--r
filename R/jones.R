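# Jones-calculus primitives: rotations, polarizers, waveplates and the
# geometric-phase conversion-efficiency law.

#' Rotation matrix
#'
#' @param theta angle in radians.
#' @return 2x2 complex matrix `[[cos, -sin], [sin, cos]]`.
#' @export
rotation <- function(theta) {
  check_finite_scalar(theta, "theta")
  matrix(as.complex(c(cos(theta), sin(theta), -sin(theta), cos(theta))), 2, 2)
}

#' Linear polarizer
#'
#' Projector onto linear polarization at angle `theta` from the x axis:
#' `R(theta) diag(1, 0) R(-theta)`. Hermitian and idempotent.
#'
#' @inheritParams rotation
#' @return 2x2 complex Jones matrix.
#' @export
polarizer <- function(theta) {
  R <- rotation(theta)
  R %*% diag(c(1 + 0i, 0i)) %*% rotation(-theta)
}

#' Linear waveplate (retarder)
#'
#' A uniform birefringent element with slow/fast axis at angle `phi` and
#' retardance `gamma` between the two axes:
#' `R(phi) diag(exp(-i gamma/2), exp(+i gamma/2)) R(-phi)`. Unitary for all
#' arguments; `gamma = pi` is a half-wave plate.
#'
#' @param phi axis angle, radians.
#' @param gamma retardance, radians.
#' @return 2x2 complex Jones matrix.
#' @export
waveplate <- function(phi, gamma) {
  check_finite_scalar(phi, "phi")
  check_finite_scalar(gamma, "gamma")
  R <- rotation(phi)
  R %*% diag(exp(c(-1i, 1i) * gamma / 2)) %*% rotation(-phi)
}

#' Circular-to-circular conversion efficiency of a retarder
#'
#' Fraction of circularly polarized input power converted to the opposite
#' handedness by a waveplate of retardance `gamma`, independent of the axis
#' angle: `sin(gamma/2)^2`. A half-wave plate (`gamma = pi`) converts all of
#' it, which is the design point of the geometric-phase element ("conversion
#' efficiency close to unity").
#'
#' @param gamma retardance in radians (vectorized).
#' @return conversion efficiency in \[0, 1\].
#' @export
conversion_efficiency <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    stop_metaedge("`gamma` must be finite numeric", "metaedge_invalid_argument")
  }
  sin(gamma / 2)^2
}

#' Apply a uniform Jones matrix to a field
#'
#' @param field a [polarized_field()].
#' @param J 2x2 complex Jones matrix.
#' @return the transformed [polarized_field()].
#' @export
apply_jones <- function(field, J) {
  stopifnot(inherits(field, "polarized_field"))
  if (!is.matrix(J) || !all(dim(J) == c(2L, 2L))) {
    stop_metaedge("`J` must be a 2x2 matrix", "metaedge_invalid_argument")
  }
  J <- matrix(as.complex(J), 2, 2)
  polarized_field(J[1, 1] * field$ex + J[1, 2] * field$ey,
                  J[2, 1] * field$ex + J[2, 2] * field$ey,
                  field$grid, field$wavelength)
}
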