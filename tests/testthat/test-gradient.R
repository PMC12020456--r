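# Finite-difference verification of every derivative layer, and of the
# assembled gradient.  The low Lebedev order keeps the suites fast; the
# analytic gradient has to match the finite difference of the same
# discretized energy at any order.

pipeline <- function(mol, p) {
  cn <- coordination_number(mol, p)
  ch <- eeq_charges(mol, p, cn = cn)
  radii <- scale_radii(mol, p, ch, cn)
  cavity <- build_cavity(mol, radii, p)
  list(cn = cn, ch = ch, radii = radii, cavity = cavity)
}

test_that("grid-point jacobian: static reduction and dynamic-radii FD", {
  p <- fast_params()
  mol <- make_cluster(31, n_atoms = 4)
  # static radii: identity for the own sphere, zero otherwise
  rad0 <- static_radii(mol, p)
  cav0 <- build_cavity(mol, rad0, p)
  J <- grid_point_jacobian(cav0, rad0, A = 2, active = FALSE)
  own <- cav0$sphere == 2
  for (i in which(own)[1:3]) expect_equal(J[i, , ], diag(3))
  expect_true(all(J[!own, , ] == 0))

  # dynamic radii: displacement of a *different* atom moves the points
  pp <- pipeline(mol, p)
  for (A in c(1L, 3L)) {
    Jd <- grid_point_jacobian(pp$cavity, pp$radii, A = A, active = FALSE)
    for (al in 1:3) {
      num <- fd_wrt_atom(function(m) pipeline(m, p)$cavity$pos, mol, A, al)
      expect_lt(max(abs(num - Jd[, , al])), 1e-8)
    }
  }
})

test_that("width derivatives: static zero, symmetry, and FD agreement", {
  p <- fast_params()
  mol <- make_cluster(32, n_atoms = 4)
  rad0 <- static_radii(mol, p)
  cav0 <- build_cavity(mol, rad0, p)
  expect_true(all(width_derivatives(cav0, rad0, 1, active = FALSE) == 0))

  pp <- pipeline(mol, p)
  for (A in 1:2) {
    dxi <- width_derivatives(pp$cavity, pp$radii, A, active = FALSE)
    for (al in 1:3) {
      num <- fd_wrt_atom(function(m) pipeline(m, p)$cavity$xi, mol, A, al)
      expect_lt(max(abs(num - dxi[, al])), 1e-8)
    }
  }
  # pair width reduction: equal widths and equal derivatives give
  # d xi_ij = d xi_i / sqrt(2) (from xi_ij = xi_i xi_j / sqrt(xi^2+xi^2))
  xi <- 1.7; dxi_ <- 0.3
  s3 <- (2 * xi^2)^1.5
  dxij <- (xi^3 / s3) * dxi_ + (xi^3 / s3) * dxi_
  expect_equal(dxij, dxi_ / sqrt(2), tolerance = 1e-14)
})

test_that("switching derivative: single sphere zero, overlap FD agreement", {
  p <- fast_params()
  m1 <- molecule("O", matrix(0, 1, 3), charges = -1, total_charge = -1)
  r1 <- static_radii(m1, p)
  c1 <- build_cavity(m1, r1, p)
  expect_true(all(switching_derivative(c1, r1, 1, active = FALSE) == 0))

  mol <- make_cluster(33, n_atoms = 4)
  pp <- pipeline(mol, p)
  keep <- pp$cavity$active      # points that enter the energy
  for (A in 1:2) {
    dF <- switching_derivative(pp$cavity, pp$radii, A, active = FALSE)
    for (al in 1:3) {
      num <- fd_wrt_atom(function(m) pipeline(m, p)$cavity$F, mol, A,
                         al, delta = 1e-3)
      expect_lt(max(abs(num[keep] - dF[keep, al])), 1e-8)
    }
  }

  # far-separated spheres: derivative saturates to zero
  far <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(60, 0, 0)),
                  charges = c(0.2, -0.2))
  rf <- static_radii(far, p)
  cf <- build_cavity(far, rf, p)
  expect_lt(max(abs(switching_derivative(cf, rf, 1, active = FALSE))), 1e-15)
})

test_that("potential derivative: Born reduction and FD agreement", {
  p <- fast_params()
  # central charge in its own sphere: v = Z/R, so under a pure radius
  # change dv = -(Z/R^2) dR; emulate with a one-atom conductor sphere
  m1 <- molecule("O", matrix(0, 1, 3), charges = 1, total_charge = 1)
  cn1 <- coordination_number(m1, p)
  ch1 <- fixed_charges(m1)
  rad1 <- scale_radii(m1, p, ch1, cn1)   # static in effect (single atom CN=0)
  cav1 <- build_cavity(m1, rad1, p)
  dv <- potential_derivative(m1, cav1, rad1, 1, active = FALSE)
  R <- rad1$radii
  dR <- rad1$jacobian[1, 1, ]
  expect_equal(dv, matrix(rep(-(1 / R^2) * dR, each = cav1$n_points),
                          ncol = 3), tolerance = 1e-12)

  mol <- make_cluster(34, n_atoms = 4)
  pp <- pipeline(mol, p)
  keep <- pp$cavity$active      # buried points are excluded from the
                                # energy; near a foreign nucleus their
                                # potential curvature defeats the FD oracle
  for (A in 1:4) {
    dvA <- potential_derivative(mol, pp$cavity, pp$radii, A, active = FALSE)
    for (al in 1:3) {
      num <- fd_wrt_atom(function(m) {
        q <- pipeline(m, p)
        solute_potential(m, q$cavity, active = FALSE)
      }, mol, A, al, delta = 1e-3)
      expect_lt(max(abs(num[keep] - dvA[keep, al])), 1e-8)
    }
  }
})

test_that("assembled gradient matches the four-point oracle (dynamic radii)", {
  p <- fast_params()
  worst_max <- 0; worst_rms <- 0
  for (s in 1:20) {
    n_at <- 3L + (s %% 6L)
    mol <- make_cluster(s + 200, n_atoms = n_at)
    chk <- check_gradient(mol, p, draco = TRUE)
    worst_max <- max(worst_max, chk$max_abs_dev)
    worst_rms <- max(worst_rms, chk$rms_dev)
  }
  expect_lt(worst_max, 1e-7)
  expect_lt(worst_rms, 1e-8)
})

test_that("gradient terms sum to the total and conserve momentum", {
  p <- fast_params()
  mol <- make_cluster(41, n_atoms = 5)
  fit <- cpcm(mol, p)
  g <- fit$gradient
  expect_lt(max(abs(g$total - (g$terms$dv_nuclear + g$terms$dA_diag +
                                 g$terms$dA_offdiag))), 1e-14)
  expect_lt(max(abs(colSums(g$total))), 1e-10)
})

test_that("the A-contraction prefactor is 1/(2 f_eps), not f_eps/2", {
  p <- cpcm_params(epsilon = 4, n_leb = 26)   # f_eps = 0.75, far from 1
  mol <- make_cluster(42, n_atoms = 4)
  fit <- cpcm(mol, p)
  num <- numerical_gradient(function(m) cpcm_energy(m, p), mol)
  ours <- max(abs(fit$gradient$total - num))
  # the alternative typographic reading scales the A terms by f_eps^2
  f2 <- fit$solution$f_eps^2
  wrong <- fit$gradient$terms
  wrong_total <- wrong$dv_nuclear + f2 * (wrong$dA_diag + wrong$dA_offdiag)
  alt <- max(abs(wrong_total - num))
  expect_lt(ours, 1e-8)
  expect_gt(alt, 100 * ours)
})

test_that("mismatched cavity and solution are refused", {
  p <- fast_params()
  mol <- make_cluster(43, n_atoms = 3)
  pp <- pipeline(mol, p)
  sol <- cpcm_solve(mol, pp$cavity, p)
  other <- build_cavity(mol, static_radii(mol, fast_params()),
                        cpcm_params(n_leb = 50))
  expect_error(cpcm_gradient(mol, other, pp$radii, sol, p), "state error")
})
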