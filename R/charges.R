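# Geometry-dependent atomic partial charges for the radius-scaling scheme.
#
# Two providers share one contract: a list with fields `q` (length N, summing
# to the total molecular charge) and `jacobian` (N x N x 3 array,
# jacobian[I, A, ] = dq_I / dR_A, rows summing to zero over A).  Any charge
# model satisfying the contract can drive the radius scaling.

#' Fixed (geometry-independent) charge provider
#'
#' Degenerate provider whose charges are constants: the Jacobian is
#' identically zero.  Useful for isolating coordination-number contributions
#' in the scaled-radius derivative and for tests.
#'
#' @param mol a [molecule()].
#' @param values per-atom charges; must sum to the molecular total charge.
#' @return charge-provider list with `q` and zero `jacobian`.
#' @export
fixed_charges <- function(mol, values = mol$charges) {
  values <- rep_len(as.numeric(values), mol$n)
  if (abs(sum(values) - mol$total_charge) > 1e-8)
    stop("validation error: fixed charges sum to ", sum(values),
         " but total charge is ", mol$total_charge)
  list(q = values, jacobian = array(0, dim = c(mol$n, mol$n, 3L)),
       model = "fixed")
}

# EEQ interaction matrix (N+1 x N+1, Lagrange row enforcing charge
# conservation) and its Cholesky-free solve
.eeq_matrix <- function(pos, alpha, eta) {
  n <- nrow(pos)
  M <- matrix(0, n + 1L, n + 1L)
  for (I in seq_len(n)) {
    M[I, I] <- eta[I] + sqrt(2 / pi) / alpha[I]
    if (I < n) {
      for (J in seq.int(I + 1L, n)) {
        d <- pos[I, ] - pos[J, ]
        r <- sqrt(sum(d * d))
        gam <- sqrt(alpha[I]^2 + alpha[J]^2)
        M[I, J] <- M[J, I] <- erf(r / gam) / r
      }
    }
  }
  M[n + 1L, seq_len(n)] <- 1
  M[seq_len(n), n + 1L] <- 1
  M
}

#' Electronegativity-equilibration (EEQ) charges
#'
#' Classical partial charges minimising a quadratic electrostatic energy
#' under a total-charge constraint.  The (N+1) x (N+1) symmetric linear
#' system has off-diagonal kernel `erf(r_IJ / sqrt(alpha_I^2 + alpha_J^2)) /
#' r_IJ`, diagonal `eta_I + sqrt(2/pi) / alpha_I`, right-hand side
#' `-chi_I + kappa_I * sqrt(CN_I)`, and a Lagrange row enforcing
#' `sum(q) = total_charge`.  `sqrt(CN)` is smoothed as `sqrt(CN + 1e-14)` so
#' the derivative stays finite for isolated atoms.
#'
#' @param mol a [molecule()].
#' @param params a [cpcm_params()] with per-element `chi`, `eta`, `alpha`,
#'   `kappa`.
#' @param cn optional precomputed [coordination_number()] result (with
#'   Jacobian if `jacobian = TRUE`).
#' @param jacobian also compute the analytic N x N x 3 charge Jacobian
#'   `dq_I / dR_A` by implicit differentiation of the linear system (kernel
#'   derivatives plus the coordination-number chain term)?
#' @return charge-provider list with `q`, `jacobian` (or NULL), `model`.
#' @examples
#' eeq_charges(water_molecule())$q
#' @export
eeq_charges <- function(mol, params = cpcm_params(), cn = NULL,
                        jacobian = TRUE) {
  n <- mol$n
  if (is.null(cn)) cn <- coordination_number(mol, params, jacobian = jacobian)
  chi <- .per_atom(params, "chi", mol$symbols)
  eta <- .per_atom(params, "eta", mol$symbols)
  alpha <- .per_atom(params, "alpha", mol$symbols)
  kappa <- .per_atom(params, "kappa", mol$symbols)
  M <- .eeq_matrix(mol$positions, alpha, eta)
  sq_cn <- sqrt(cn$cn + 1e-14)
  rhs <- c(-chi + kappa * sq_cn, mol$total_charge)
  lu <- tryCatch(solve(M, cbind(rhs)), error = function(e) {
    kap <- tryCatch(kappa(M), error = function(e2) NA_real_)
    stop("numerical error: EEQ system singular (condition estimate ",
         format(kap), ")")
  })
  x <- lu[, 1L]
  q <- x[seq_len(n)]
  jac <- NULL
  if (jacobian) {
    if (is.null(cn$jacobian))
      stop("eeq_charges: need cn with jacobian")
    pos <- mol$positions
    # d(M x) = dB  =>  M dx = dB - dM x ; build all 3N right-hand sides
    rhs_all <- matrix(0, n + 1L, 3L * n)
    for (A in seq_len(n)) {
      for (al in 1:3) {
        col <- 3L * (A - 1L) + al
        db <- c(kappa * 0.5 / sq_cn * cn$jacobian[, A, al], 0)
        dMx <- numeric(n + 1L)
        # kernel derivative: only pairs involving atom A move
        for (I in seq_len(n)) {
          if (I == A) next
          d <- pos[I, ] - pos[A, ]
          r <- sqrt(sum(d * d))
          gam <- sqrt(alpha[I]^2 + alpha[A]^2)
          dK_dr <- 2 / (gam * sqrt(pi)) * exp(-(r / gam)^2) / r -
            erf(r / gam) / r^2
          u_al <- d[al] / r
          # dr/dR_A = -u_al (for pair (I, A) with direction R_I - R_A)
          dM_IA <- dK_dr * (-u_al)
          dMx[I] <- dMx[I] + dM_IA * x[A]
          dMx[A] <- dMx[A] + dM_IA * x[I]
        }
        rhs_all[, col] <- db - dMx
      }
    }
    dx <- solve(M, rhs_all)
    jac <- array(0, dim = c(n, n, 3L))
    for (A in seq_len(n))
      for (al in 1:3)
        jac[, A, al] <- dx[seq_len(n), 3L * (A - 1L) + al]
  }
  list(q = q, jacobian = jac, model = "eeq")
}
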