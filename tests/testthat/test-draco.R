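test_that("radius scaling matches direct scalar evaluation", {
  p <- cpcm_params(elements = data.frame(symbol = "Cl", a = 1, b = 0, k = 0))
  m <- molecule("Cl", matrix(0, 1, 3), charges = 0)
  cn <- coordination_number(m, p)
  # q_eff = b -> f = 1, R = R0
  ch0 <- fixed_charges(m, 0)
  r0 <- scale_radii(m, p, ch0, cn)
  expect_identical(r0$radii, unname(p$r0["Cl"]))
  # strongly negative charge: f = 1 - erf(3), evaluated directly
  m3 <- molecule("Cl", matrix(0, 1, 3), charges = -3)
  ch3 <- fixed_charges(m3, -3)
  r3 <- scale_radii(m3, p, ch3, cn)
  f_expect <- 2 * pnorm(-3 * sqrt(2))
  expect_equal(r3$scaling, f_expect, tolerance = 1e-11)
  expect_equal(r3$radii, f_expect * unname(p$r0["Cl"]), tolerance = 1e-11)
})

test_that("zero steepness recovers static radii with a zero jacobian", {
  tab <- cpcm_params()$elements
  tab$a <- 0
  p <- cpcm_params(elements = tab)
  mol <- make_cluster(2, n_atoms = 5)
  cn <- coordination_number(mol, p)
  ch <- eeq_charges(mol, p, cn = cn)
  res <- scale_radii(mol, p, ch, cn)
  expect_identical(res$radii, res$r0)
  expect_true(res$static)
  expect_true(all(res$jacobian == 0))
})

test_that("scaling factor stays strictly inside (0, 2)", {
  p <- cpcm_params()
  set.seed(99)
  for (rep in 1:50) {
    q <- runif(1, -10, 10)
    m <- molecule("O", matrix(0, 1, 3), charges = q)
    res <- scale_radii(m, p, fixed_charges(m, q), coordination_number(m, p))
    expect_gt(res$scaling, 0)
    expect_lt(res$scaling, 2)
  }
})

test_that("radius jacobian agrees with finite differences (EEQ chain)", {
  p <- cpcm_params()
  worst <- 0
  for (s in 1:10) {
    mol <- make_cluster(s + 100, n_atoms = 5)
    cn <- coordination_number(mol, p)
    ch <- eeq_charges(mol, p, cn = cn)
    res <- scale_radii(mol, p, ch, cn)
    radii_of <- function(m) {
      cnm <- coordination_number(m, p, jacobian = FALSE)
      chm <- eeq_charges(m, p, cn = cnm, jacobian = FALSE)
      scale_radii(m, p, chm, cnm, jacobian = FALSE)$radii
    }
    worst <- max(worst, fd_jacobian_dev(radii_of, res$jacobian, mol))
    for (I in seq_len(mol$n))
      expect_lt(max(abs(colSums(res$jacobian[I, , ]))), 1e-12)
  }
  expect_lt(worst, 1e-8)
})

test_that("with fixed charges only the coordination-number chain survives", {
  p <- cpcm_params()
  mol <- make_cluster(9, n_atoms = 4)
  cn <- coordination_number(mol, p)
  ch <- fixed_charges(mol)
  res <- scale_radii(mol, p, ch, cn)
  # explicit term: (2 R0 a / sqrt(pi)) e^{-u^2} q k dCN/dR_A
  r0 <- res$r0
  a <- unname(p$a[mol$symbols]); k <- unname(p$k[mol$symbols])
  b <- unname(p$b[mol$symbols])
  u <- a * (res$q_eff - b)
  pref <- 2 * r0 * a / sqrt(pi) * exp(-u^2) * ch$q * k
  for (al in 1:3)
    expect_equal(res$jacobian[, , al], pref * cn$jacobian[, , al],
                 tolerance = 1e-14)
  # and it matches finite differences of the same pipeline
  radii_of <- function(m) {
    cnm <- coordination_number(m, p, jacobian = FALSE)
    scale_radii(m, p, fixed_charges(m), cnm, jacobian = FALSE)$radii
  }
  expect_lt(fd_jacobian_dev(radii_of, res$jacobian, mol), 1e-8)
})
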