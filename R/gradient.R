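# Analytical nuclear gradient of the polarization energy.
#
# E_pol = -(f_eps/2) v' A^-1 v  is stationary in the induced charges q, so
# the gradient needs no dq/dR term:
#
#   dE/dR_A = q' (dv/dR_A) + 1/(2 f_eps) * q' (dA/dR_A) q
#
# Every geometric ingredient acquires a radius-chain contribution when the
# cavity radii depend on all nuclear positions: grid points move with their
# sphere's radius (r_i = C_I + R_I u_i with lab-frame-fixed u_i), Gaussian
# widths scale as 1/R_I, and the switching factors see both the moving point
# and the foreign sphere's changing radius.  dA/dR_A is never materialized;
# the off-diagonal contraction is collapsed onto per-point coefficient
# vectors so the O(n^2) pair work is done once, not per atom.

# radius jacobian as an N x (3N) matrix [I, (A-1)*3 + alpha]
.dR_mat <- function(radii, n_at) {
  if (is.null(radii$jacobian)) return(matrix(0, n_at, 3L * n_at))
  matrix(radii$jacobian, n_at, 3L * n_at)
}

#' Jacobian of the grid-point positions for one displaced atom
#'
#' `dr_i/dR_A = u_i (x) dR_I/dR_A + [I(i) = A] Identity`, with `u_i` the
#' fixed unit vector locating point i on its sphere I(i).  With static radii
#' this reduces to the identity for points on atom A's own sphere and zero
#' otherwise.
#'
#' @param cavity a [build_cavity()] result.
#' @param radii a `"draco_radii"` object.
#' @param A displaced atom index.
#' @param active restrict to active points (default).
#' @return n x 3 x 3 array: `[i, beta, alpha] = d r_i[beta] / d R_A[alpha]`.
#' @export
grid_point_jacobian <- function(cavity, radii, A, active = TRUE) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  u <- cavity$u[keep, , drop = FALSE]
  sph <- cavity$sphere[keep]
  n <- nrow(u)
  dR <- radii$jacobian
  J <- array(0, dim = c(n, 3L, 3L))
  for (al in 1:3) {
    s <- if (is.null(dR)) numeric(n) else dR[sph, A, al]
    J[, , al] <- u * s
    J[sph == A, al, al] <- J[sph == A, al, al] + 1
  }
  J
}

#' Derivatives of the Gaussian widths for one displaced atom
#'
#' `d xi_i / dR_A = -(xi_Born / (R_I^2 sqrt(w_i))) dR_I/dR_A
#'                = -(xi_i / R_I) dR_I/dR_A`; the Lebedev weights are
#' constants of the chosen rule, so their derivative is zero.
#'
#' @inheritParams grid_point_jacobian
#' @return n x 3 matrix `d xi_i / d R_A[alpha]` (bohr^-1 per bohr).
#' @export
width_derivatives <- function(cavity, radii, A, active = TRUE) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  xi <- cavity$xi[keep]
  sph <- cavity$sphere[keep]
  if (is.null(radii$jacobian)) return(matrix(0, length(xi), 3L))
  -(xi / cavity$radii[sph]) * radii$jacobian[sph, A, , drop = FALSE][, 1L, ]
}

# geometry-only switching ingredients shared by all displaced atoms:
# distances and directions point -> sphere centre, and the partial
# derivatives of each elementary factor w.r.t. (xi_i, R_J, r_iJ)
.switch_terms <- function(cavity, active = TRUE) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  pos <- cavity$pos[keep, , drop = FALSE]
  xi <- cavity$xi[keep]
  sph <- cavity$sphere[keep]
  n <- nrow(pos)
  n_at <- length(cavity$radii)
  r_iJ <- matrix(0, n, n_at)
  uhat <- array(0, dim = c(n, n_at, 3L))
  a1 <- a2 <- a3 <- finv <- matrix(0, n, n_at)
  for (J in seq_len(n_at)) {
    d <- sweep(pos, 2L, cavity$centers[J, ], "-")
    r <- sqrt(rowSums(d * d))
    r_iJ[, J] <- r
    uhat[, J, ] <- d / r
    RJ <- cavity$radii[J]
    p <- xi * (RJ - r)
    m <- xi * (RJ + r)
    ep <- exp(-p * p)
    em <- exp(-m * m)
    a1[, J] <- -((RJ - r) * ep + (RJ + r) * em) / sqrt(pi)
    a2[, J] <- -xi * (ep + em) / sqrt(pi)
    a3[, J] <- xi * (ep - em) / sqrt(pi)
    own <- sph == J
    a1[own, J] <- 0; a2[own, J] <- 0; a3[own, J] <- 0
    # an elementary factor that underflowed to zero marks a point buried
    # far beyond the screening threshold; its switching value is flat zero
    # in a whole neighbourhood, so its derivative contribution is zero
    f <- cavity$fmat[keep, J]
    finv[, J] <- ifelse(own | f <= 0, 0, 1 / f)
  }
  list(r_iJ = r_iJ, uhat = uhat, a1 = a1, a2 = a2, a3 = a3, finv = finv,
       sph = sph, n = n, n_at = n_at)
}

#' Derivative of the switching values for one displaced atom
#'
#' `dF_i/dR_A = F_i sum_J (1/f_iJ) df_iJ/dR_A`, where each elementary-factor
#' derivative chains through the point's Gaussian width, the foreign
#' sphere's radius, and the point-to-centre distance.
#'
#' @inheritParams grid_point_jacobian
#' @param st optional precomputed [.switch_terms] list (internal reuse).
#' @return n x 3 matrix `d F_i / d R_A[alpha]`.
#' @export
switching_derivative <- function(cavity, radii, A, active = TRUE,
                                 st = NULL) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  Fi <- cavity$F[keep]
  u <- cavity$u[keep, , drop = FALSE]
  sph <- cavity$sphere[keep]
  if (is.null(st)) st <- .switch_terms(cavity, active = active)
  dxi <- width_derivatives(cavity, radii, A, active = active)
  dR <- radii$jacobian
  n <- length(Fi)
  n_at <- st$n_at
  out <- matrix(0, n, 3L)
  for (al in 1:3) {
    # radius-chain displacement of the point itself along u_i
    s_i <- if (is.null(dR)) numeric(n) else dR[sph, A, al]
    acc <- numeric(n)
    for (J in seq_len(n_at)) {
      dRJ <- if (is.null(dR)) 0 else dR[J, A, al]
      dr <- rowSums(st$uhat[, J, ] * u) * s_i
      dr[sph == A] <- dr[sph == A] + st$uhat[sph == A, J, al]
      if (J == A) dr <- dr - st$uhat[, J, al]
      df <- st$a1[, J] * dxi[, al] + st$a2[, J] * dRJ + st$a3[, J] * dr
      acc <- acc + st$finv[, J] * df
    }
    out[, al] <- Fi * acc
  }
  out[Fi <= 0, ] <- 0
  out
}

#' Derivative of the solute potential for one displaced atom
#'
#' Nuclear part of the potential derivative: both the nucleus K = A moves
#' and (through the radius chain) every cavity point moves, so
#' `dv_i/dR_A = -sum_K Z_K r_iK^-3 (r_i - R_K)' (dr_i/dR_A - [K = A] I)`.
#'
#' @inheritParams grid_point_jacobian
#' @param mol the [molecule()] the cavity was built for.
#' @return n x 3 matrix `d v_i / d R_A[alpha]`.
#' @export
potential_derivative <- function(mol, cavity, radii, A, active = TRUE) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  pos <- cavity$pos[keep, , drop = FALSE]
  u <- cavity$u[keep, , drop = FALSE]
  sph <- cavity$sphere[keep]
  n <- nrow(pos)
  dR <- radii$jacobian
  # field-like sum and the displaced-nucleus direct term
  Gv <- matrix(0, n, 3L)
  termA <- matrix(0, n, 3L)
  for (K in seq_len(mol$n)) {
    if (mol$charges[K] == 0 && K != A) next
    d <- sweep(pos, 2L, mol$positions[K, ], "-")
    r3 <- (sqrt(rowSums(d * d)))^3
    if (mol$charges[K] != 0) Gv <- Gv + mol$charges[K] * d / r3
    if (K == A) termA <- mol$charges[K] * d / r3
  }
  out <- matrix(0, n, 3L)
  gu <- rowSums(Gv * u)
  for (al in 1:3) {
    s_i <- if (is.null(dR)) numeric(n) else dR[sph, A, al]
    out[, al] <- -gu * s_i + termA[, al]
    own <- sph == A
    out[own, al] <- out[own, al] - Gv[own, al]
  }
  out
}

#' Assemble the analytical nuclear gradient of the polarization energy
#'
#' Contracts the solved surface charges with the derivative of the potential
#' and of the interaction matrix for every displaced atom:
#' `grad(A) = q' dv/dR_A + 1/(2 f_eps) q' (dA/dR_A) q`.  The diagonal part
#' of the A-contraction chains through the Gaussian widths and switching
#' values; the off-diagonal part through the pair widths and the moving
#' grid-point positions.  All radius-chain terms vanish identically for
#' static radii, recovering the fixed-cavity gradient.
#'
#' @param mol a [molecule()].
#' @param cavity the [build_cavity()] result the solution was computed on.
#' @param radii the `"draco_radii"` used for the cavity.
#' @param solution the [cpcm_solve()] result.
#' @param params the [cpcm_params()] used.
#' @return object of class `"cpcm_gradient"`: `total` (N x 3,
#'   hartree/bohr), `terms` (list of N x 3 components `dv_nuclear`,
#'   `dA_diag`, `dA_offdiag`), `static` flag, `scheme`, `f_min`.
#' @export
cpcm_gradient <- function(mol, cavity, radii, solution,
                          params = cpcm_params()) {
  n_at <- mol$n
  if (length(solution$q) != cavity$n_active)
    stop("state error: solution does not match cavity (point count)")
  tv <- matrix(0, n_at, 3L)
  td <- matrix(0, n_at, 3L)
  to <- matrix(0, n_at, 3L)
  out <- list(total = tv, terms = list(dv_nuclear = tv, dA_diag = td,
                                       dA_offdiag = to),
              static = isTRUE(radii$static), scheme = cavity$scheme,
              f_min = cavity$f_min)
  class(out) <- "cpcm_gradient"
  f_eps <- solution$f_eps
  if (f_eps == 0 || cavity$n_active == 0L) return(out)

  keep <- cavity$active
  q <- solution$q
  xi <- cavity$xi[keep]
  Fi <- cavity$F[keep]
  u <- cavity$u[keep, , drop = FALSE]
  pos <- cavity$pos[keep, , drop = FALSE]
  sph <- cavity$sphere[keep]
  n <- length(q)
  half_f <- 1 / (2 * f_eps)
  st <- .switch_terms(cavity)

  # ---- off-diagonal pair coefficients, computed once -------------------
  dx <- outer(pos[, 1L], pos[, 1L], "-")
  dy <- outer(pos[, 2L], pos[, 2L], "-")
  dz <- outer(pos[, 3L], pos[, 3L], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  diag(r) <- 1                      # dummy, masked below
  xi2 <- xi * xi
  s2 <- outer(xi2, xi2, "+")
  xij <- outer(xi, xi) / sqrt(s2)
  t_ <- xij * r
  G <- 2 / sqrt(pi) * exp(-t_ * t_)
  Aij <- erf(t_) / r
  H <- (G * xij - Aij) / r
  diag(G) <- 0; diag(H) <- 0
  # coefficient of d xi_i: c_i = 2 q_i sum_j q_j G_ij xi_j^3 / s_ij^3
  W <- G * sweep(1 / s2^1.5, 2L, xi^3, "*")   # W_ij = G_ij xi_j^3 / s^3
  c_off <- 2 * q * as.numeric(W %*% q)
  # coefficient of D_i: T_i = 2 q_i sum_j q_j H_ij (r_i - r_j)/r_ij
  Hq <- sweep(H, 2L, q, "*") / r
  Tx <- 2 * q * (as.numeric(Hq %*% rep(1, n)) * pos[, 1L] - as.numeric(Hq %*% pos[, 1L]))
  Ty <- 2 * q * (as.numeric(Hq %*% rep(1, n)) * pos[, 2L] - as.numeric(Hq %*% pos[, 2L]))
  Tz <- 2 * q * (as.numeric(Hq %*% rep(1, n)) * pos[, 3L] - as.numeric(Hq %*% pos[, 3L]))
  Tmat <- cbind(Tx, Ty, Tz)
  Tu <- rowSums(Tmat * u)

  # ---- per-atom assembly ----------------------------------------------
  sq2pi <- sqrt(2 / pi)
  for (A in seq_len(n_at)) {
    dv <- potential_derivative(mol, cavity, radii, A)
    dxi <- width_derivatives(cavity, radii, A)
    dF <- switching_derivative(cavity, radii, A, st = st)
    dR <- radii$jacobian
    for (al in 1:3) {
      # nuclear-potential term
      tv[A, al] <- sum(q * dv[, al])
      # diagonal A term
      dAii <- sq2pi * (dxi[, al] / Fi - xi / Fi^2 * dF[, al])
      td[A, al] <- half_f * sum(q * q * dAii)
      # off-diagonal A term: xi chain + moving points
      s_i <- if (is.null(dR)) numeric(n) else dR[sph, A, al]
      own <- sph == A
      to[A, al] <- half_f *
        (sum(c_off * dxi[, al]) + sum(Tu * s_i) + sum(Tmat[own, al]))
    }
  }
  out$terms <- list(dv_nuclear = tv, dA_diag = td, dA_offdiag = to)
  out$total <- tv + td + to
  out
}

#' @export
print.cpcm_gradient <- function(x, ...) {
  cat("cpcm_gradient (hartree/bohr):\n")
  g <- x$total
  for (A in seq_len(nrow(g)))
    cat(sprintf("  atom %2d  %+.10e %+.10e %+.10e\n", A,
                g[A, 1], g[A, 2], g[A, 3]))
  cat(sprintf("  |max| = %.3e, translational residual = %.3e\n",
              max(abs(g)), max(abs(colSums(g)))))
  invisible(x)
}
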