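#' Solute electrostatic potential at the active cavity points
#'
#' For a classical solute, `v_i = sum_K Z_K / |r_i - R_K|` over the nuclei.
#'
#' @param mol a [molecule()].
#' @param cavity a [build_cavity()] result.
#' @param active restrict to active points (default) or all points.
#' @return numeric vector of potentials (hartree per unit charge).
#' @export
solute_potential <- function(mol, cavity, active = TRUE) {
  pos <- if (active) cavity$pos[cavity$active, , drop = FALSE] else cavity$pos
  v <- numeric(nrow(pos))
  for (K in seq_len(mol$n)) {
    if (mol$charges[K] == 0) next
    d <- sweep(pos, 2L, mol$positions[K, ], "-")
    r <- sqrt(rowSums(d * d))
    if (any(r < 1e-10))
      stop("singularity error: cavity point coincides with nucleus ", K)
    v <- v + mol$charges[K] / r
  }
  v
}

#' Assemble the Gaussian-interaction matrix A
#'
#' Off-diagonal: Coulomb interaction of two spherical Gaussians,
#' `A_ij = erf(xi_ij r_ij) / r_ij` with the pair width
#' `xi_ij = xi_i xi_j / sqrt(xi_i^2 + xi_j^2)`.  Diagonal: Gaussian
#' self-interaction scaled by the switching value,
#' `A_ii = xi_i sqrt(2/pi) / F_i` (a point that is mostly buried has a small
#' F_i, hence a large self-energy, hence carries a small induced charge).
#'
#' @param cavity a [build_cavity()] result.
#' @param active use active points only (default).
#' @return symmetric positive-definite matrix (bohr^-1).
#' @export
assemble_A <- function(cavity, active = TRUE) {
  keep <- if (active) cavity$active else rep(TRUE, cavity$n_points)
  pos <- cavity$pos[keep, , drop = FALSE]
  xi <- cavity$xi[keep]
  Fi <- cavity$F[keep]
  n <- nrow(pos)
  dx <- outer(pos[, 1L], pos[, 1L], "-")
  dy <- outer(pos[, 2L], pos[, 2L], "-")
  dz <- outer(pos[, 3L], pos[, 3L], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r[upper.tri(r)] < 1e-10))
    stop("assembly error: duplicate surface point positions")
  xi2 <- xi * xi
  xij <- outer(xi, xi) / sqrt(outer(xi2, xi2, "+"))
  A <- matrix(0, n, n)
  off <- upper.tri(r)
  A[off] <- erf(xij[off] * r[off]) / r[off]
  A <- A + t(A)
  diag(A) <- xi * sqrt(2 / pi) / Fi
  A
}

#' Solve the conductor-like PCM equations
#'
#' Solves `A q = -f_eps v` for the induced surface charges by a symmetric
#' positive-definite (Cholesky) factorization, with a fall back to a general
#' solve (plus a condition warning) if the factorization fails.  The
#' polarization energy is `E_pol = q' v / 2`, negative for any dielectric
#' with epsilon > 1.
#'
#' @param mol a [molecule()].
#' @param cavity a [build_cavity()] result.
#' @param params a [cpcm_params()]; `epsilon = Inf` gives the conductor
#'   limit f_eps = 1.
#' @return object of class `"cpcm_solution"`: `v`, `q` (active points),
#'   `epol` (hartree), `f_eps`, `A`, `n_active`.
#' @export
cpcm_solve <- function(mol, cavity, params = cpcm_params()) {
  v <- solute_potential(mol, cavity)
  A <- assemble_A(cavity)
  f_eps <- params$f_eps
  q <- if (f_eps == 0) {
    numeric(length(v))
  } else {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      warning("Cholesky factorization failed (condition number ",
              format(kappa(A)), "); using general solve")
      as.numeric(solve(A, -f_eps * v))
    } else {
      as.numeric(backsolve(ch, forwardsolve(t(ch), -f_eps * v)))
    }
  }
  structure(list(v = v, q = q, epol = 0.5 * sum(q * v), f_eps = f_eps,
                 A = A, n_active = cavity$n_active),
            class = "cpcm_solution")
}

#' @export
print.cpcm_solution <- function(x, ...) {
  cat(sprintf("cpcm_solution: E_pol = %.10f hartree (f_eps = %.6f, %d points)\n",
              x$epol, x$f_eps, x$n_active))
  invisible(x)
}

# polarization energy of a single sphere of radius R with a central unit
# charge in the conductor limit, for a given Lebedev order and width
# prefactor xi_born -- the calibration kernel
.born_epol <- function(order, xi_born, R = 1) {
  g <- lebedev_grid(order)
  xi <- xi_born / (R * sqrt(g$weights))
  pos <- g$points * R
  n <- order
  dx <- outer(pos[, 1L], pos[, 1L], "-")
  dy <- outer(pos[, 2L], pos[, 2L], "-")
  dz <- outer(pos[, 3L], pos[, 3L], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  xi2 <- xi * xi
  xij <- outer(xi, xi) / sqrt(outer(xi2, xi2, "+"))
  A <- matrix(0, n, n)
  off <- upper.tri(r)
  A[off] <- erf(xij[off] * r[off]) / r[off]
  A <- A + t(A)
  diag(A) <- xi * sqrt(2 / pi)
  v <- rep(1 / R, n)
  q <- solve(A, -v)
  0.5 * sum(q * v)
}

#' Calibrate the Gaussian width prefactor for a Lebedev order
#'
#' The width prefactor `xi_Born` is fixed, per Lebedev order, by requiring
#' that a single sphere with a central unit charge in a conductor reproduce
#' the exact Born solvation energy `-1/(2R)`.  The root of
#' `epol(xi_Born) + 1/(2R)` is found by bracketed search on [1, 10]; the
#' result is dimensionless and radius-independent (the discretized energy
#' scales exactly as 1/R), and is cached per order for the session.
#'
#' @param order Lebedev order (one of the packaged set).
#' @param tol root tolerance on the energy defect (hartree).
#' @return the calibrated dimensionless `xi_Born`.
#' @examples
#' calibrate_xi_born(194)
#' @export
calibrate_xi_born <- function(order, tol = 1e-12) {
  order <- as.integer(order)
  if (!(order %in% .cavity_orders))
    stop("calibration error: order ", order,
         " cannot carry Gaussian surface charges (negative or missing",
         " Lebedev weights); usable orders: ",
         paste(.cavity_orders, collapse = ", "))
  key <- as.character(order)
  cache <- .swig_env$xi_born
  if (is.null(cache)) cache <- .swig_env$xi_born <- new.env(parent = emptyenv())
  if (!is.null(cache[[key]])) return(cache[[key]])
  gfun <- function(x) .born_epol(order, x) + 0.5
  lo <- 1; hi <- 10
  glo <- gfun(lo); ghi <- gfun(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0)
    stop("calibration error: no sign change for xi_Born in [1, 10] at order ",
         order)
  root <- stats::uniroot(gfun, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  if (abs(gfun(root)) > tol)
    stop("calibration error: residual ", format(gfun(root)), " at order ",
         order)
  cache[[key]] <- root
  root
}
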