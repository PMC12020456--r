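#' Conductor-like PCM solvation calculation
#'
#' The main entry point: runs the full pipeline for a molecule of classical
#' point charges — coordination numbers, partial charges for the radius
#' scaling, dynamically scaled (or static) cavity radii, switching-Gaussian
#' cavity, CPCM linear system — and, optionally, the complete analytical
#' nuclear gradient of the polarization energy.
#'
#' @param mol a [molecule()].
#' @param params a [cpcm_params()].
#' @param draco scale the cavity radii with the geometry-dependent effective
#'   charges (default) or keep the base radii fixed?
#' @param charge_model charge provider for the radius scaling: `"eeq"`
#'   (default) or `"fixed"` (the molecule's own solute charges, zero
#'   Jacobian).
#' @param gradient compute the analytical gradient?
#' @param frozen_orders optional per-sphere Lebedev orders (see
#'   [build_cavity()]).
#' @return object of class `"cpcm"` with fields `energy` (E_pol, hartree),
#'   `solution`, `cavity`, `radii`, `charges`, `cn`, `gradient` (or NULL),
#'   `molecule`, `params`, `draco`.
#' @examples
#' fit <- cpcm(water_molecule(), cpcm_params(epsilon = 78.4))
#' fit$energy
#' @export
cpcm <- function(mol, params = cpcm_params(), draco = TRUE,
                 charge_model = c("eeq", "fixed"), gradient = TRUE,
                 frozen_orders = NULL) {
  charge_model <- match.arg(charge_model)
  need_jac <- gradient && draco
  cn <- coordination_number(mol, params, jacobian = need_jac)
  charges <- NULL
  radii <- if (draco) {
    charges <- switch(charge_model,
      eeq = eeq_charges(mol, params, cn = cn, jacobian = need_jac),
      fixed = fixed_charges(mol))
    scale_radii(mol, params, charges, cn, jacobian = gradient)
  } else {
    static_radii(mol, params)
  }
  cavity <- build_cavity(mol, radii, params, frozen_orders = frozen_orders)
  solution <- cpcm_solve(mol, cavity, params)
  grad <- if (gradient)
    cpcm_gradient(mol, cavity, radii, solution, params)
  structure(list(energy = solution$epol, solution = solution,
                 cavity = cavity, radii = radii, charges = charges,
                 cn = cn$cn, gradient = grad, molecule = mol,
                 params = params, draco = draco,
                 charge_model = if (draco) charge_model else NA_character_),
            class = "cpcm")
}

#' Polarization energy only (scalar pipeline wrapper)
#'
#' Rebuilds the entire pipeline (charges, coordination numbers, radii,
#' cavity, linear system) at the given geometry and returns E_pol.  This is
#' the energy function handed to the finite-difference oracle: every
#' displaced geometry gets a freshly constructed cavity.
#'
#' @inheritParams cpcm
#' @return polarization energy (hartree).
#' @export
cpcm_energy <- function(mol, params = cpcm_params(), draco = TRUE,
                        charge_model = c("eeq", "fixed"),
                        frozen_orders = NULL) {
  cpcm(mol, params, draco = draco, charge_model = charge_model,
       gradient = FALSE, frozen_orders = frozen_orders)$energy
}

#' @export
print.cpcm <- function(x, ...) {
  cat(sprintf("CPCM%s solvation, %s scheme\n",
              if (x$draco) "+dynamic-radii" else " (static radii)",
              x$cavity$scheme))
  cat(sprintf("  E_pol = %.10f hartree  (f_eps = %.6f)\n", x$energy,
              x$solution$f_eps))
  cat(sprintf("  %d atoms, %d/%d active surface points\n", x$molecule$n,
              x$cavity$n_active, x$cavity$n_points))
  if (!is.null(x$gradient))
    cat(sprintf("  max |gradient| = %.3e hartree/bohr\n",
                max(abs(x$gradient$total))))
  invisible(x)
}

#' @export
summary.cpcm <- function(object, ...) {
  x <- object
  cat("Conductor-like PCM solvation summary\n")
  cat(sprintf("  scheme %s, epsilon = %s, f_eps = %.6f\n", x$cavity$scheme,
              format(x$params$epsilon), x$solution$f_eps))
  cat(sprintf("  E_pol = %.10f hartree = %.4f kcal/mol\n", x$energy,
              x$energy * 627.5094740631))
  tab <- data.frame(
    atom = seq_len(x$molecule$n),
    element = x$molecule$symbols,
    Z = x$molecule$charges,
    CN = round(x$cn, 4),
    q_scale = if (is.null(x$charges)) NA else round(x$charges$q, 4),
    radius_bohr = round(x$radii$radii, 4),
    order = x$cavity$orders)
  print(tab, row.names = FALSE)
  if (!is.null(x$gradient)) {
    cat(sprintf("  gradient: max |component| %.3e, translational residual %.3e\n",
                max(abs(x$gradient$total)),
                max(abs(colSums(x$gradient$total)))))
  }
  invisible(x)
}

#' @export
coef.cpcm <- function(object, ...) object$solution$q

#' Serialize a solvation result as JSON
#'
#' Emits the polarization energy, screening factor, active point count,
#' per-sphere radii and Lebedev orders, and (when present) the per-atom
#' gradient with its term breakdown.
#'
#' @param fit a [cpcm()] result.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
cpcm_json <- function(fit, path = NULL) {
  rec <- list(
    epol = fit$energy,
    f_eps = fit$solution$f_eps,
    n_active = fit$cavity$n_active,
    scheme = fit$cavity$scheme,
    radii_bohr = fit$radii$radii,
    orders = fit$cavity$orders,
    dynamic_radii = fit$draco)
  if (!is.null(fit$gradient)) {
    g <- fit$gradient
    rec$gradient <- list(
      total = g$total,
      dv_nuclear = g$terms$dv_nuclear,
      dA_diag = g$terms$dA_diag,
      dA_offdiag = g$terms$dA_offdiag,
      static_radii = g$static)
  }
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
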