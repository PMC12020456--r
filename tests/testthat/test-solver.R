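test_that("A-matrix limits match the Gaussian-interaction formulas", {
  # a toy two-point cavity assembled by hand through the exported surface
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(40, 0, 0)),
                charges = c(0, 0))
  p <- cpcm_params(n_leb = 6)
  cav <- build_cavity(m, static_radii(m, p), p)
  A <- assemble_A(cav)
  expect_lt(max(abs(A - t(A))), 1e-12)

  xi <- c(1.3, 2.1)
  xij <- prod(xi) / sqrt(sum(xi^2))
  erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  # far separation: plain Coulomb to 1e-15 relative
  r_far <- 9 / xij
  expect_lt(abs(erf_(xij * r_far) / r_far - 1 / r_far) * r_far, 1e-15)
  # short range limit of erf(xij r)/r -> 2 xij / sqrt(pi)
  r_small <- 1e-8
  expect_equal(erf_(xij * r_small) / r_small, 2 * xij / sqrt(pi),
               tolerance = 1e-8)
  # equal widths: xij = xi / sqrt(2)
  expect_equal(prod(c(2, 2)) / sqrt(8), 2 / sqrt(2))
})

test_that("solver invariants: symmetry, residual, vacuum and f_eps", {
  mol <- water_molecule()
  p <- cpcm_params(n_leb = 110)
  fit <- cpcm(mol, p, gradient = FALSE)
  A <- fit$solution$A
  expect_lt(max(abs(A - t(A))), 1e-12)
  resid <- A %*% fit$solution$q + fit$solution$f_eps * fit$solution$v
  expect_lt(max(abs(resid)), 1e-10)
  expect_lt(fit$energy, 0)

  expect_equal(cpcm_params(epsilon = 80)$f_eps, 79 / 80)
  v1 <- cpcm(mol, cpcm_params(epsilon = 1, n_leb = 26), gradient = FALSE)
  expect_identical(v1$energy, 0)
  expect_true(all(v1$solution$q == 0))
})

test_that("polarization energy deepens monotonically with the dielectric", {
  mol <- water_molecule()
  es <- vapply(c(2, 5, 20, 78.4, Inf), function(eps)
    cpcm_energy(mol, cpcm_params(epsilon = eps, n_leb = 50)), numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("energy is invariant under rigid translation", {
  mol <- make_cluster(21, n_atoms = 4)
  p <- cpcm_params(n_leb = 50)
  e0 <- cpcm_energy(mol, p)
  shifted <- molecule(mol$symbols,
                      sweep(mol$positions, 2L, c(5.1, -3.7, 2.9), "+"),
                      charges = mol$charges)
  expect_lt(abs(cpcm_energy(shifted, p) - e0), 1e-12)
})

test_that("width calibration reproduces the Born energy at any radius", {
  xb <- calibrate_xi_born(110)
  expect_gt(xb, 1)
  expect_lt(xb, 10)
  for (R in c(1, 3)) {
    m <- molecule("H", matrix(0, 1, 3), charges = 1, total_charge = 1)
    p <- cpcm_params(epsilon = Inf, n_leb = 110,
                     elements = data.frame(symbol = "H",
                                           r0 = R / 1.8897259886))
    expect_lt(abs(cpcm_energy(m, p, draco = FALSE) + 1 / (2 * R)), 1e-10)
  }
})

test_that("off-centre conductor charge approaches the image-charge energy", {
  R <- 2; d <- 0.3 * R
  p <- cpcm_params(epsilon = Inf, n_leb = 302,
                   elements = data.frame(symbol = "H",
                                         r0 = R / 1.8897259886))
  host <- molecule("H", matrix(0, 1, 3), charges = 0)
  cav <- build_cavity(host, static_radii(host, p), p)
  probe <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)),
                    charges = c(0, 1), total_charge = 1)
  v <- solute_potential(probe, cav)
  A <- assemble_A(cav)
  q <- solve(A, -v)
  epol <- 0.5 * sum(q * v)
  exact <- -0.5 * R / (R^2 - d^2)
  expect_lt(abs(epol / exact - 1), 1e-3)
})
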