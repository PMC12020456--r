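#' Elementary switching attenuation of one surface point by a foreign sphere
#'
#' A surface Gaussian of width `xi` centred at distance `r_iJ` from the
#' centre of a foreign sphere of radius `R_J` is attenuated by
#'
#'   f = 1 - (erf(xi (R_J - r_iJ)) + erf(xi (R_J + r_iJ))) / 2
#'
#' which goes smoothly to 0 for a point buried deep inside the sphere and to
#' 1 far outside, and increases monotonically in `r_iJ`.
#'
#' @param r_iJ distance point-to-sphere-centre (bohr); vectorised.
#' @param R_J foreign sphere radius (bohr).
#' @param xi Gaussian width of the point (bohr^-1).
#' @return attenuation value(s) in (0, 1).
#' @export
switching_value <- function(r_iJ, R_J, xi) {
  1 - 0.5 * (erf(xi * (R_J - r_iJ)) + erf(xi * (R_J + r_iJ)))
}

#' Build the switching-Gaussian van der Waals cavity
#'
#' Places a Lebedev grid on the sphere of every atom: point i on sphere I
#' sits at `r_i = R_I_center + R_I * u_i` with `u_i` a fixed laboratory-frame
#' unit vector.  Each point carries a spherical-Gaussian charge of width
#' `xi_i = xi_Born / (R_I * sqrt(w_i))`, with `w_i` the unit-sphere Lebedev
#' weight and `xi_Born` the per-order calibration constant from
#' [calibrate_xi_born()].  The switching value `F_i` is the product of
#' [switching_value()] factors over all foreign spheres; points with
#' `F_i < params$f_min` are marked inactive and excluded from the linear
#' system.
#'
#' @param mol a [molecule()].
#' @param radii a `"draco_radii"` object ([scale_radii()] / [static_radii()]).
#' @param params a [cpcm_params()].
#' @param frozen_orders optional integer vector of per-sphere Lebedev orders
#'   overriding the scheme selection (the "isodensity-frozen" mechanism:
#'   compute orders once with [select_order()], then pass them here for
#'   subsequent geometries).
#' @return object of class `"cpcm_cavity"`: per-point fields `sphere`,
#'   `pos` (n x 3), `u` (n x 3), `w`, `xi`, `F`, `active`; per-sphere fields
#'   `orders`, `radii`, `centers`; plus `fmat` (n x N matrix of elementary
#'   switching factors, 1 on the own sphere).
#' @export
build_cavity <- function(mol, radii, params = cpcm_params(),
                         frozen_orders = NULL) {
  n_at <- mol$n
  R <- radii$radii
  if (any(!is.finite(R)) || any(R <= 0))
    stop("geometry error: non-positive cavity radius")
  orders <- if (!is.null(frozen_orders)) {
    as.integer(rep_len(frozen_orders, n_at))
  } else {
    select_order(params$scheme, R, params)
  }
  pts <- vector("list", n_at)
  for (I in seq_len(n_at)) {
    g <- lebedev_grid(orders[I])
    ni <- nrow(g$points)
    xi_b <- calibrate_xi_born(orders[I])
    pts[[I]] <- list(
      sphere = rep(I, ni),
      u = g$points,
      w = g$weights,
      pos = sweep(g$points * R[I], 2L, mol$positions[I, ], "+"),
      xi = xi_b / (R[I] * sqrt(g$weights)))
  }
  sphere <- unlist(lapply(pts, `[[`, "sphere"))
  u <- do.call(rbind, lapply(pts, `[[`, "u"))
  w <- unlist(lapply(pts, `[[`, "w"))
  pos <- do.call(rbind, lapply(pts, `[[`, "pos"))
  xi <- unlist(lapply(pts, `[[`, "xi"))
  n <- length(xi)
  # elementary switching factors f_iJ for every foreign sphere
  fmat <- matrix(1, n, n_at)
  if (n_at > 1L) {
    for (J in seq_len(n_at)) {
      d <- sweep(pos, 2L, mol$positions[J, ], "-")
      r_iJ <- sqrt(rowSums(d * d))
      f <- switching_value(r_iJ, R[J], xi)
      f[sphere == J] <- 1
      fmat[, J] <- f
    }
  }
  Fi <- apply(fmat, 1L, prod)
  active <- Fi >= params$f_min
  structure(list(sphere = sphere, pos = pos, u = u, w = w, xi = xi,
                 F = Fi, active = active, fmat = fmat,
                 orders = orders, radii = R, centers = mol$positions,
                 n_points = n, n_active = sum(active),
                 scheme = params$scheme, f_min = params$f_min),
            class = "cpcm_cavity")
}

#' @export
print.cpcm_cavity <- function(x, ...) {
  cat(sprintf(
    "cpcm_cavity: %d spheres, %d surface points (%d active), scheme %s\n",
    length(x$radii), x$n_points, x$n_active, x$scheme))
  cat("  orders:", paste(x$orders, collapse = " "), "\n")
  cat("  radii (bohr):", paste(sprintf("%.4f", x$radii), collapse = " "),
      "\n")
  invisible(x)
}
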