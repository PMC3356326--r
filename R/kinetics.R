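#' Micro-parameters of a tissue compartment model
#'
#' Rate constants of the reversible two-tissue compartment model: `K1`
#' (ml/g/min) is plasma-to-tissue transport, `k2` (1/min) clearance back
#' to plasma, `k3` (1/min) the specific binding rate, `k4` (1/min) the
#' dissociation rate, and `vB` the fractional blood volume of the region.
#' A one-tissue (reference) region is the special case `k3 = k4 = 0`.
#'
#' @param K1 Influx rate, ml/g/min, `>= 0`.
#' @param k2 Efflux rate, 1/min; must be `> 0` whenever `K1 > 0`.
#' @param k3 Binding rate, 1/min, `>= 0`.
#' @param k4 Dissociation rate, 1/min; must be `> 0` whenever `k3 > 0`
#'   (the model is reversible).
#' @param vB Fractional blood volume in `[0, 1)`.
#'
#' @return An object of class `tissue_kinetics`.
#' @export
#' @examples
#' tumor <- tissue_kinetics(K1 = 0.25, k2 = 0.45, k3 = 0.15, k4 = 0.04)
#' vt_true(tumor)   # K1/k2 * (1 + k3/k4)
#' bp_true(tumor)   # k3/k4
tissue_kinetics <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (K1 < 0 || k3 < 0 || k4 < 0) stop("rate constants must be >= 0")
  if (K1 > 0 && k2 <= 0) stop("k2 must be > 0 when K1 > 0")
  if (k3 > 0 && k4 <= 0) stop("k4 must be > 0 when k3 > 0 (reversible model)")
  if (vB < 0 || vB >= 1) stop("vB must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "tissue_kinetics")
}

#' @rdname tissue_kinetics
#' @param kin A `tissue_kinetics` object.
#' @export
vt_true <- function(kin) {
  if (kin$K1 == 0) return(0)
  kin$K1 / kin$k2 * (1 + bp_true(kin))
}

#' @rdname tissue_kinetics
#' @export
bp_true <- function(kin) if (kin$k3 == 0) 0 else kin$k3 / kin$k4

#' @rdname tissue_kinetics
#' @export
vnd_true <- function(kin) if (kin$K1 == 0) 0 else kin$K1 / kin$k2

#' @rdname tissue_kinetics
#' @export
vs_true <- function(kin) vnd_true(kin) * bp_true(kin)

#' @export
print.tissue_kinetics <- function(x, ...) {
  cat(sprintf(
    "<tissue_kinetics> K1=%g ml/g/min k2=%g k3=%g k4=%g 1/min vB=%g\n",
    x$K1, x$k2, x$k3, x$k4, x$vB))
  invisible(x)
}

is_tissue_kinetics <- function(x) inherits(x, "tissue_kinetics")
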