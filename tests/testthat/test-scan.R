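test_that("four-point formula is exact through degree four", {
  lin <- function(m) 3.25 * m$positions[1, 1]
  cub <- function(m) m$positions[1, 1]^3
  m0 <- molecule("H", matrix(c(0.7, 0, 0), 1, 3))
  g <- numerical_gradient(lin, m0)
  expect_equal(g[1, 1], 3.25, tolerance = 1e-12)
  expect_equal(g[1, 2:3], c(0, 0))
  g3 <- numerical_gradient(cub, m0)
  expect_equal(g3[1, 1], 3 * 0.7^2, tolerance = 1e-10)
  # x^5 at x = 0: leading error term 4 delta^4
  m00 <- molecule("H", matrix(0, 1, 3))
  # shift so the pairwise-distance guard is irrelevant (single atom)
  quint <- function(m) m$positions[1, 1]^5
  g5 <- numerical_gradient(quint, m00, delta = 5e-3)
  expect_equal(abs(g5[1, 1]), 4 * (5e-3)^4, tolerance = 1e-6)
})

test_that("non-finite energies are reported with the displacement", {
  m0 <- molecule("H", matrix(0, 1, 3))
  expect_error(numerical_gradient(function(m) NaN, m0),
               "evaluation error")
})

test_that("random molecules are reproducible and respect the spacing", {
  a <- random_molecule(6, seed = 5, min_dist = 1.5, box = 10)
  b <- random_molecule(6, seed = 5, min_dist = 1.5, box = 10)
  expect_identical(a$positions, b$positions)
  expect_identical(a$symbols, b$symbols)
  expect_gte(min(dist(a$positions)), 1.5)
  # generous box: many draws succeed
  for (s in 1:25)
    expect_s3_class(random_molecule(5, seed = s, min_dist = 1.5, box = 10),
                    "molecule")
  # impossible constraints exhaust the rejection budget
  expect_error(random_molecule(10, seed = 1, min_dist = 5, box = 3,
                               max_tries = 50),
               "budget")
})

test_that("coarse scans reproduce the scheme phenomenology", {
  steps <- seq(0.8, 2.0, by = 0.02)
  iso <- bond_scan(factors = steps, params = cpcm_params(n_leb = 50))
  expect_identical(nrow(iso$records), length(steps))
  expect_identical(length(iso$switch_steps), 0L)   # isogrid never switches
  # dynamic radii respond substantially to the stretch (the sign of the
  # response is a property of the charge-model parametrization; what the
  # scheme comparison needs is that the radii move at all)
  r <- iso$records
  expect_gt(max(r$radius_3) - min(r$radius_3), 0.1)
  expect_gt(max(r$radius_1) - min(r$radius_1), 0.1)

  dens <- bond_scan(factors = steps,
                    params = cpcm_params(scheme = "isodensity"))
  expect_gt(length(dens$switch_steps), 0L)
  # grid switches poison the energy-gradient consistency
  expect_gt(max(dens$consistency[dens$switch_steps]),
            10 * iso$max_inconsistency)

  froz <- bond_scan(factors = steps,
                    params = cpcm_params(scheme = "isodensity-frozen"))
  expect_identical(length(froz$switch_steps), 0L)
  expect_true(all(froz$orders == rep(froz$orders[1, ],
                                     each = nrow(froz$orders))))

  # draco off and on both satisfy the smoothness bound at this step size
  off <- bond_scan(factors = steps, params = cpcm_params(n_leb = 50),
                   draco = FALSE)
  expect_false(isTRUE(all.equal(off$records$epol, iso$records$epol)))
  expect_lt(off$max_inconsistency, 1e-5)
  expect_lt(iso$max_inconsistency, 1e-5)
})
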