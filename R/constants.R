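# Unit conventions: all internal quantities are atomic units
# (bohr, hartree, elementary charge); file I/O uses Angstrom.

#' Unit conversion: 1 Angstrom in bohr
#' @keywords internal
BOHR_PER_ANGSTROM <- 1.8897259886

#' @keywords internal
ANGSTROM_PER_BOHR <- 1 / BOHR_PER_ANGSTROM

# erf/erfc via the normal CDF (pnorm is vectorised C code)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Default per-element parameter table.
#
# r0:   base cavity radius (Angstrom), Bondi van der Waals radius x 1.2
# rcov: covalent radius (Angstrom)
# chi, eta: EEQ electronegativity and hardness (hartree/e, hartree/e^2)
# alpha: EEQ charge-distribution width (bohr)
# kappa: EEQ coordination-number coupling (hartree/e)
# a, b, k: radius-scaling (draco) steepness, charge offset, CN coupling
#
# None of these are universal constants: they are model parameters with
# shipped defaults, overridable through cpcm_params()/load_parameters().
.element_defaults <- function() {
  tab <- data.frame(
    symbol = c("H",   "B",   "C",   "N",   "O",   "F",   "P",   "S",   "Cl",  "Br",  "I"),
    r0     = c(1.44,  2.30,  2.04,  1.86,  1.824, 1.764, 2.16,  2.16,  2.10,  2.22,  2.376),
    rcov   = c(0.32,  0.85,  0.75,  0.71,  0.63,  0.64,  1.11,  1.03,  0.99,  1.14,  1.33),
    chi    = c(1.23,  1.20,  1.26,  1.54,  1.86,  2.00,  1.23,  1.40,  1.61,  1.60,  1.55),
    eta    = c(0.47,  0.36,  0.34,  0.46,  0.54,  0.73,  0.35,  0.41,  0.47,  0.43,  0.44),
    alpha  = c(1.40,  2.20,  2.10,  1.90,  1.80,  1.70,  2.40,  2.30,  2.20,  2.40,  2.60),
    kappa  = c(0.03,  0.04,  0.04,  0.05,  0.07,  0.09,  0.04,  0.05,  0.06,  0.06,  0.06),
    a      = c(0.60,  0.40,  0.40,  0.45,  0.45,  0.50,  0.40,  0.40,  0.45,  0.45,  0.45),
    b      = c(0.10,  0.00,  0.00, -0.05, -0.10, -0.10,  0.00, -0.05, -0.10, -0.10, -0.10),
    k      = c(0.10,  0.10,  0.10,  0.10,  0.10,  0.10,  0.10,  0.10,  0.10,  0.10,  0.10),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$symbol
  tab
}

# Lebedev orders packaged with the grid table
.lebedev_orders <- c(6L, 14L, 26L, 38L, 50L, 74L, 86L, 110L, 146L, 170L,
                     194L, 302L, 350L, 434L, 590L, 770L)

# orders usable for cavity construction: the 74-point rule carries a
# negative weight, which is fine for quadrature but incompatible with the
# Gaussian width xi = xi_Born / (R sqrt(w))
.cavity_orders <- setdiff(.lebedev_orders, 74L)

# package-level mutable state (Lebedev table cache, xi_Born calibration cache)
.swig_env <- new.env(parent = emptyenv())
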