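#' Dynamically scaled cavity radii and their position derivatives
#'
#' Scales each atom's base cavity radius by a smooth function of an
#' effective atomic charge:
#'
#'   q_eff_I = q_I * (1 + k_I * CN_I)
#'   f_I     = erf(a_I * (q_eff_I - b_I)) + 1        (strictly in (0, 2))
#'   R_I     = f_I * R0_I
#'
#' where q_I comes from a charge provider ([eeq_charges()] or
#' [fixed_charges()]) and CN_I from [coordination_number()].  Setting the
#' steepness `a` to zero for every element recovers the static-radius model
#' exactly (f = 1, zero Jacobian).
#'
#' The Jacobian chains through both the charges and the coordination
#' numbers:
#'
#'   dR_I/dR_A = (2 R0_I a_I / sqrt(pi)) exp(-(a_I (q_eff_I - b_I))^2)
#'               * (dq_I/dR_A (1 + k_I CN_I) + q_I k_I dCN_I/dR_A)
#'
#' @param mol a [molecule()].
#' @param params a [cpcm_params()] with per-element `r0`, `a`, `b`, `k`.
#' @param charges a charge-provider result (fields `q`, `jacobian`).
#' @param cn a [coordination_number()] result for the same geometry.
#' @param jacobian compute the N x N x 3 radius Jacobian (dimensionless)?
#' @return object of class `"draco_radii"`: list with `radii` (bohr),
#'   `jacobian` (or NULL), `static` (TRUE when the Jacobian is identically
#'   zero), `scaling` (the factors f_I), `q_eff`.
#' @examples
#' mol <- water_molecule()
#' cn <- coordination_number(mol)
#' ch <- eeq_charges(mol, cn = cn)
#' scale_radii(mol, charges = ch, cn = cn)$radii
#' @export
scale_radii <- function(mol, params = cpcm_params(), charges, cn,
                        jacobian = TRUE) {
  n <- mol$n
  r0 <- .per_atom(params, "r0", mol$symbols)
  a <- .per_atom(params, "a", mol$symbols)
  b <- .per_atom(params, "b", mol$symbols)
  k <- .per_atom(params, "k", mol$symbols)
  q_eff <- charges$q * (1 + k * cn$cn)
  u <- a * (q_eff - b)
  f <- erf(u) + 1
  radii <- f * r0
  jac <- NULL
  static <- all(a == 0) ||
    (identical(charges$model, "fixed") && all(k == 0))
  if (jacobian) {
    jac <- array(0, dim = c(n, n, 3L))
    pref <- 2 * r0 * a / sqrt(pi) * exp(-u * u)
    if (any(pref != 0)) {
      if (is.null(charges$jacobian) || is.null(cn$jacobian))
        stop("scale_radii: charge and CN jacobians required")
      for (al in 1:3) {
        inner <- charges$jacobian[, , al] * (1 + k * cn$cn) +
          (charges$q * k) * cn$jacobian[, , al]
        jac[, , al] <- pref * inner
      }
    }
    static <- static || all(jac == 0)
  }
  structure(list(radii = radii, jacobian = jac, static = static,
                 scaling = f, q_eff = q_eff, r0 = r0),
            class = "draco_radii")
}

#' Static (unscaled) cavity radii
#'
#' Convenience constructor for the fixed-radius model: radii equal the base
#' radii and the Jacobian is identically zero.
#'
#' @inheritParams scale_radii
#' @return a `"draco_radii"` object with `static = TRUE`.
#' @export
static_radii <- function(mol, params = cpcm_params()) {
  r0 <- .per_atom(params, "r0", mol$symbols)
  structure(list(radii = r0, jacobian = array(0, c(mol$n, mol$n, 3L)),
                 static = TRUE, scaling = rep(1, mol$n),
                 q_eff = rep(NA_real_, mol$n), r0 = r0),
            class = "draco_radii")
}
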