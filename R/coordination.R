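#' Smooth coordination numbers and their position derivatives
#'
#' The coordination number of atom I counts its neighbours smoothly through a
#' product of two logistic-type falloff functions of the interatomic distance
#' r_IJ relative to the covalent-radius sum:
#'
#'   CN_I = sum_{J != I}  1 / (f1 * f2)
#'   f1 = 1 + exp(-10 * ((4/3) * Rcov_IJ / r_IJ - 1))
#'   f2 = 1 + exp(-20 * (((4/3) * Rcov_IJ + s) / r_IJ - 1))
#'
#' with Rcov_IJ the sum of covalent radii and s the `cn_shift` constant
#' (bohr, default 2).  The second function suppresses spurious long-range
#' contributions.  The analytic Jacobian follows by the chain rule through
#' r_IJ; for every atom I the Jacobian rows sum to zero over displaced atoms
#' (translational invariance).
#'
#' @param mol a [molecule()].
#' @param params a [cpcm_params()] supplying covalent radii and `cn_shift`.
#' @param jacobian also compute the N x N x 3 derivative tensor
#'   `jacobian[I, A, ] = dCN_I / dR_A` (bohr^-1)?
#' @return list with `cn` (length N) and, if requested, `jacobian`.
#' @examples
#' cn <- coordination_number(water_molecule())$cn
#' @export
coordination_number <- function(mol, params = cpcm_params(),
                                jacobian = TRUE) {
  n <- mol$n
  cn <- numeric(n)
  jac <- if (jacobian) array(0, dim = c(n, n, 3L)) else NULL
  if (n == 1L)
    return(list(cn = cn, jacobian = jac))
  rcov <- .per_atom(params, "rcov", mol$symbols)
  pos <- mol$positions
  s <- params$cn_shift
  for (I in seq_len(n - 1L)) {
    for (J in seq.int(I + 1L, n)) {
      d <- pos[I, ] - pos[J, ]
      r <- sqrt(sum(d * d))
      if (r <= 1e-8) stop("geometry error: atoms ", I, " and ", J,
                          " coincide")
      c1 <- (4 / 3) * (rcov[I] + rcov[J])
      c2 <- c1 + s
      e1 <- exp(-10 * (c1 / r - 1))
      e2 <- exp(-20 * (c2 / r - 1))
      f1 <- 1 + e1
      f2 <- 1 + e2
      val <- 1 / (f1 * f2)
      cn[I] <- cn[I] + val
      cn[J] <- cn[J] + val
      if (jacobian) {
        # d f / d r, then distance direction (R_I - R_J)/r picks up the
        # displaced-atom indicator: dr/dR_I = +u, dr/dR_J = -u
        df1 <- e1 * 10 * c1 / r^2
        df2 <- e2 * 20 * c2 / r^2
        dval_dr <- -(df1 / (f1^2 * f2) + df2 / (f1 * f2^2))
        g <- dval_dr * d / r           # dval/dR_I = g; dval/dR_J = -g
        jac[I, I, ] <- jac[I, I, ] + g
        jac[I, J, ] <- jac[I, J, ] - g
        jac[J, I, ] <- jac[J, I, ] + g
        jac[J, J, ] <- jac[J, J, ] - g
      }
    }
  }
  list(cn = cn, jacobian = jac)
}
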