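# Lebedev quadrature on the unit sphere.
#
# The packaged table (inst/extdata/lebedev-orbits.txt) stores one octahedral
# orbit per line: order, orbit type, up to two generator coordinates, and the
# point weight (normalized so the weights of a rule sum to 1).  Orbit types:
#   a1 (6 points)  : vertices (+-1, 0, 0)
#   a2 (12 points) : edge midpoints (+-1, +-1, 0)/sqrt(2)
#   a3 (8 points)  : face centres (+-1, +-1, +-1)/sqrt(3)
#   b  (24 points) : (l, l, m) with 2 l^2 + m^2 = 1
#   c  (24 points) : (p, q, 0) with p^2 + q^2 = 1
#   d  (48 points) : (r, s, w) general, r^2 + s^2 + w^2 = 1
# The constrained coordinate of b/c/d orbits is recomputed from the norm
# condition at expansion time, so every point is on the sphere to machine
# precision.

.lebedev_table <- function() {
  if (!is.null(.swig_env$lebedev)) return(.swig_env$lebedev)
  path <- system.file("extdata", "lebedev-orbits.txt", package = "swigcpcm",
                      mustWork = TRUE)
  raw <- utils::read.table(path, col.names = c("order", "type", "a", "b", "w"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric", "numeric"))
  .swig_env$lebedev <- split(raw, raw$order)
  .swig_env$lebedev
}

# all 24/48 sign-and-permutation images of one generator triple
.orbit_points <- function(type, a, b) {
  perms3 <- function(v) {
    idx <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    unique(t(apply(idx, 1L, function(i) v[i])))
  }
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  switch(type,
    a1 = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    a2 = {
      s <- 1 / sqrt(2)
      base <- perms3(c(s, s, 0))
      out <- unique(do.call(rbind, lapply(seq_len(nrow(signs)), function(r)
        base * rep(signs[r, ], each = nrow(base)))))
      out
    },
    a3 = {
      s <- 1 / sqrt(3)
      signs * s
    },
    b = {
      l <- a
      m <- sqrt(max(0, 1 - 2 * l * l))
      base <- perms3(c(l, l, m))
      unique(do.call(rbind, lapply(seq_len(nrow(signs)), function(r)
        base * rep(signs[r, ], each = nrow(base)))))
    },
    c = {
      p <- a
      q <- sqrt(max(0, 1 - p * p))
      base <- perms3(c(p, q, 0))
      unique(do.call(rbind, lapply(seq_len(nrow(signs)), function(r)
        base * rep(signs[r, ], each = nrow(base)))))
    },
    d = {
      r_ <- a
      s_ <- b
      w_ <- sqrt(max(0, 1 - r_ * r_ - s_ * s_))
      base <- perms3(c(r_, s_, w_))
      do.call(rbind, lapply(seq_len(nrow(signs)), function(r)
        base * rep(signs[r, ], each = nrow(base))))
    },
    stop("unknown orbit type ", type))
}

#' Lebedev quadrature grid on the unit sphere
#'
#' Returns the points and weights of the Lebedev rule with the given number
#' of points.  Weights are normalized to sum to 1 over the unit sphere, so
#' the rule approximates the spherical *mean* of a function; multiply by
#' `4*pi*R^2` for a surface integral over a sphere of radius R.
#'
#' @param order number of grid points; one of 6, 14, 26, 38, 50, 74, 86,
#'   110, 146, 170, 194, 302, 350, 434, 590, 770.
#' @return list with `points` (order x 3 matrix of unit vectors) and
#'   `weights` (length-order vector summing to 1).
#' @examples
#' g <- lebedev_grid(6)     # octahedron vertices, weights 1/6
#' @export
lebedev_grid <- function(order) {
  order <- as.integer(order)
  key <- as.character(order)
  cache <- .swig_env$grids
  if (is.null(cache)) cache <- .swig_env$grids <- new.env(parent = emptyenv())
  if (!is.null(cache[[key]])) return(cache[[key]])
  tab <- .lebedev_table()
  if (!(key %in% names(tab)))
    stop("no packaged Lebedev rule with ", order, " points; available: ",
         paste(.lebedev_orders, collapse = ", "))
  orb <- tab[[key]]
  pts <- vector("list", nrow(orb))
  wts <- vector("list", nrow(orb))
  for (i in seq_len(nrow(orb))) {
    p <- .orbit_points(orb$type[i], orb$a[i], orb$b[i])
    pts[[i]] <- p
    wts[[i]] <- rep(orb$w[i], nrow(p))
  }
  pts <- do.call(rbind, pts)
  wts <- unlist(wts)
  if (nrow(pts) != order)
    stop("corrupt Lebedev table for order ", order, ": got ", nrow(pts),
         " points")
  g <- list(points = unname(pts), weights = wts)
  cache[[key]] <- g
  g
}

#' Choose the Lebedev order for a sphere under a discretization scheme
#'
#' The isogrid scheme uses one fixed order for every sphere.  The isodensity
#' scheme picks, per sphere, the packaged order closest to the target surface
#' point density `rho_leb` (points per Angstrom^2) times the sphere area,
#' i.e. it minimizes `|n - rho_leb * 4 pi R^2|`.  Because the chosen order
#' jumps as the radius crosses a midpoint between two packaged orders, the
#' isodensity scheme makes the discretized energy discontinuous under radii
#' that change with geometry; see [bond_scan()].
#'
#' @param scheme `"isogrid"`, `"isodensity"` or `"isodensity-frozen"` (the
#'   frozen variant is resolved by [build_cavity()]; here it selects like
#'   isodensity).
#' @param radius sphere radius in bohr (vectorised).
#' @param params a [cpcm_params()] object supplying `n_leb` and `rho_leb`.
#' @return integer vector of Lebedev orders, one per radius.
#' @export
select_order <- function(scheme, radius, params) {
  scheme <- match.arg(scheme, c("isogrid", "isodensity", "isodensity-frozen"))
  if (scheme == "isogrid")
    return(rep(params$n_leb, length(radius)))
  r_ang <- radius * ANGSTROM_PER_BOHR
  target <- params$rho_leb * 4 * pi * r_ang^2
  vapply(target, function(t)
    .cavity_orders[which.min(abs(.cavity_orders - t))], integer(1))
}
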