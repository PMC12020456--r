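#' Four-point central-difference gradient oracle
#'
#' Numerical reference gradient: for each atom and Cartesian component,
#'
#'   dE/dx = (-E(x + 2 d) + 8 E(x + d) - 8 E(x - d) + E(x - 2 d)) / (12 d)
#'
#' exact through fourth-degree polynomials (leading error d^4 E^(5) / 30).
#' The energy function receives a complete molecule, so the whole pipeline
#' (charges, coordination numbers, radii, cavity) is rebuilt at every
#' displaced geometry; no translational-invariance shortcut is used.
#'
#' @param energy_fn function(molecule) -> scalar energy (hartree).
#' @param mol the reference [molecule()].
#' @param delta step size in bohr (default 5.0e-3).
#' @return N x 3 matrix of derivatives (hartree/bohr).
#' @export
numerical_gradient <- function(energy_fn, mol, delta = 5.0e-3) {
  n <- mol$n
  g <- matrix(0, n, 3L)
  displace <- function(A, al, h) {
    pos <- mol$positions
    pos[A, al] <- pos[A, al] + h
    molecule(mol$symbols, pos, charges = mol$charges,
             total_charge = mol$total_charge)
  }
  for (A in seq_len(n)) {
    for (al in 1:3) {
      e <- vapply(c(2, 1, -1, -2) * delta, function(h) {
        val <- energy_fn(displace(A, al, h))
        if (!is.finite(val))
          stop("evaluation error: non-finite energy at displacement of atom ",
               A, ", component ", al, ", step ", h, " bohr")
        val
      }, numeric(1))
      g[A, al] <- (-e[1] + 8 * e[2] - 8 * e[3] + e[4]) / (12 * delta)
    }
  }
  g
}

#' Compare analytical and numerical gradients
#'
#' Convenience wrapper running [cpcm()] for the analytical gradient and
#' [numerical_gradient()] over [cpcm_energy()] for the oracle.
#'
#' @inheritParams cpcm
#' @param delta finite-difference step (bohr).
#' @return list with `analytic`, `numeric` (N x 3), `max_abs_dev`,
#'   `rms_dev`.
#' @export
check_gradient <- function(mol, params = cpcm_params(), draco = TRUE,
                           charge_model = c("eeq", "fixed"),
                           delta = 5.0e-3) {
  charge_model <- match.arg(charge_model)
  fit <- cpcm(mol, params, draco = draco, charge_model = charge_model)
  num <- numerical_gradient(function(m)
    cpcm_energy(m, params, draco = draco, charge_model = charge_model),
    mol, delta = delta)
  dev <- fit$gradient$total - num
  list(analytic = fit$gradient$total, numeric = num,
       max_abs_dev = max(abs(dev)), rms_dev = sqrt(mean(dev^2)),
       energy = fit$energy)
}

#' Bond-stretch scan of the solvation potential-energy surface
#'
#' Stretches the bond between two atoms from `factors[1]` to the last factor
#' of its reference length, moving only the second atom along the fixed bond
#' direction, and records the polarization energy, the analytical gradient
#' projected on the scan direction, the number of active surface points and
#' the cavity radii at every step.
#'
#' The step-consistency metric
#' `|E_{k+1} - E_k - (g_k + g_{k+1}) dr / 2|` (trapezoid defect) is the
#' smoothness diagnostic: on a continuous surface it is O(dr^3), while a
#' grid-order switch under the isodensity scheme produces a spike several
#' orders larger.
#'
#' @param mol a [molecule()]; defaults to the water-like triatomic.
#' @param atoms length-2 atom indices: the bond; atom `atoms[2]` moves.
#' @param factors bond-scaling factors (strictly increasing).
#' @param params a [cpcm_params()] (its `scheme` decides isogrid versus
#'   isodensity behaviour; `"isodensity-frozen"` freezes the orders chosen
#'   at the first step).
#' @param draco scale radii dynamically?
#' @param charge_model charge provider for the scaling.
#' @return object of class `"cpcm_scan"`: a data.frame `records` with
#'   columns `factor`, `bond` (bohr), `epol`, `grad_proj`, `n_active`, and
#'   per-atom radii columns; plus `consistency` (per-interval defect,
#'   hartree), `max_inconsistency`, `switch_steps` (intervals where
#'   `n_active` changed).
#' @export
bond_scan <- function(mol = water_molecule(), atoms = c(1L, 3L),
                      factors = seq(0.8, 2.0, by = 0.01),
                      params = cpcm_params(), draco = TRUE,
                      charge_model = c("eeq", "fixed")) {
  charge_model <- match.arg(charge_model)
  stopifnot(length(atoms) == 2L, all(diff(factors) > 0))
  b0 <- mol$positions[atoms[2L], ] - mol$positions[atoms[1L], ]
  len0 <- sqrt(sum(b0 * b0))
  uhat <- b0 / len0
  n_steps <- length(factors)
  frozen <- NULL
  epol <- gproj <- nact <- numeric(n_steps)
  radmat <- matrix(0, n_steps, mol$n)
  ordmat <- matrix(0L, n_steps, mol$n)
  for (k in seq_len(n_steps)) {
    pos <- mol$positions
    pos[atoms[2L], ] <- pos[atoms[1L], ] + factors[k] * len0 * uhat
    mk <- molecule(mol$symbols, pos, charges = mol$charges,
                   total_charge = mol$total_charge)
    fit <- cpcm(mk, params, draco = draco, charge_model = charge_model,
                gradient = TRUE, frozen_orders = frozen)
    if (params$scheme == "isodensity-frozen" && is.null(frozen))
      frozen <- fit$cavity$orders
    epol[k] <- fit$energy
    gproj[k] <- sum(fit$gradient$total[atoms[2L], ] * uhat)
    nact[k] <- fit$cavity$n_active
    radmat[k, ] <- fit$radii$radii
    ordmat[k, ] <- fit$cavity$orders
  }
  dr <- diff(factors) * len0
  consistency <- abs(diff(epol) - 0.5 * (gproj[-1L] + gproj[-n_steps]) * dr)
  records <- data.frame(factor = factors, bond = factors * len0,
                        epol = epol, grad_proj = gproj, n_active = nact)
  colnames(radmat) <- paste0("radius_", seq_len(mol$n))
  records <- cbind(records, radmat)
  order_switch <- which(rowSums(abs(diff(ordmat))) > 0)
  structure(list(records = records, consistency = consistency,
                 max_inconsistency = max(consistency),
                 switch_steps = order_switch, orders = ordmat,
                 scheme = params$scheme, draco = draco),
            class = "cpcm_scan")
}

#' @export
print.cpcm_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("cpcm_scan: %d steps, scheme %s, dynamic radii %s\n",
              nrow(r), x$scheme, x$draco))
  cat(sprintf("  epol range [%.8f, %.8f] hartree\n", min(r$epol),
              max(r$epol)))
  cat(sprintf("  max energy-gradient inconsistency %.3e hartree\n",
              x$max_inconsistency))
  cat(sprintf("  Lebedev-order switches at %d steps\n",
              length(x$switch_steps)))
  invisible(x)
}

#' @export
plot.cpcm_scan <- function(x, ...) {
  r <- x$records
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$bond * ANGSTROM_PER_BOHR, r$epol, type = "l",
                 xlab = "bond / Angstrom", ylab = "E_pol / hartree", ...)
  graphics::plot(r$bond * ANGSTROM_PER_BOHR, r$grad_proj, type = "l",
                 xlab = "bond / Angstrom",
                 ylab = "dE/dr / (hartree/bohr)", ...)
  graphics::plot(r$bond * ANGSTROM_PER_BOHR, r$n_active, type = "s",
                 xlab = "bond / Angstrom", ylab = "active points", ...)
  invisible(x)
}
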