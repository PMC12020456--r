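#' Model parameter set
#'
#' Collects every tunable quantity of the solvation model: the per-element
#' table (base cavity radii, covalent radii, EEQ charge-model parameters,
#' radius-scaling parameters) and the global settings (solvent dielectric,
#' cavity discretization scheme, Lebedev order, target surface density,
#' switching screening threshold).
#'
#' Radii in the element table are given in Angstrom and converted to bohr
#' here; everything downstream is atomic units.
#'
#' @param epsilon solvent dielectric constant (>= 1); `Inf` selects the
#'   conductor limit (screening factor f_eps = 1).  Default 78.4 (water).
#' @param scheme cavity discretization scheme: `"isogrid"` (one Lebedev order
#'   for every sphere; default), `"isodensity"` (order chosen per sphere to
#'   match `rho_leb`), or `"isodensity-frozen"` (isodensity orders computed
#'   once and then held fixed, see [build_cavity()]).
#' @param n_leb Lebedev order for the isogrid scheme.  Default 194.
#' @param rho_leb target surface-charge density for the isodensity scheme,
#'   in points per Angstrom^2.  Default 7.5.
#' @param f_min switching-function screening threshold: surface points with
#'   switching value below `f_min` are dropped from the linear system.
#'   Default 1e-8.
#' @param cn_shift additive constant (bohr) in the second falloff function of
#'   the coordination number.  Default 2.
#' @param elements optional data.frame overriding or extending the shipped
#'   per-element defaults; must carry a `symbol` column plus any of
#'   `r0`, `rcov` (Angstrom), `chi`, `eta`, `alpha`, `kappa`, `a`, `b`, `k`.
#' @return an object of class `"cpcm_params"`.
#' @examples
#' p <- cpcm_params(epsilon = Inf)
#' p$f_eps
#' @export
cpcm_params <- function(epsilon = 78.4,
                        scheme = c("isogrid", "isodensity",
                                   "isodensity-frozen"),
                        n_leb = 194L, rho_leb = 7.5, f_min = 1e-8,
                        cn_shift = 2, elements = NULL) {
  scheme <- match.arg(scheme)
  tab <- .element_defaults()
  if (!is.null(elements)) {
    elements <- as.data.frame(elements)
    if (is.null(elements$symbol)) stop("elements override needs a 'symbol' column")
    for (i in seq_len(nrow(elements))) {
      sym <- elements$symbol[i]
      if (!(sym %in% rownames(tab))) {
        tab[sym, ] <- NA
        tab[sym, "symbol"] <- sym
      }
      for (col in intersect(names(elements), setdiff(names(tab), "symbol"))) {
        val <- elements[[col]][i]
        if (!is.na(val)) tab[sym, col] <- val
      }
    }
  }
  p <- list(
    epsilon = epsilon, scheme = scheme, n_leb = as.integer(n_leb),
    rho_leb = rho_leb, f_min = f_min, cn_shift = cn_shift,
    elements = tab,
    # element table converted to internal units (bohr)
    r0 = stats::setNames(tab$r0 * BOHR_PER_ANGSTROM, tab$symbol),
    rcov = stats::setNames(tab$rcov * BOHR_PER_ANGSTROM, tab$symbol),
    chi = stats::setNames(tab$chi, tab$symbol),
    eta = stats::setNames(tab$eta, tab$symbol),
    alpha = stats::setNames(tab$alpha, tab$symbol),
    kappa = stats::setNames(tab$kappa, tab$symbol),
    a = stats::setNames(tab$a, tab$symbol),
    b = stats::setNames(tab$b, tab$symbol),
    k = stats::setNames(tab$k, tab$symbol)
  )
  p$f_eps <- if (is.infinite(epsilon)) 1 else (epsilon - 1) / epsilon
  class(p) <- "cpcm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!is.infinite(p$epsilon) && (!is.finite(p$epsilon) || p$epsilon < 1))
    stop("validation error: epsilon must be >= 1 (or Inf for a conductor)")
  if (!(p$n_leb %in% .cavity_orders))
    stop("validation error: n_leb must be one of ",
         paste(.cavity_orders, collapse = ", "),
         " (the 74-point rule has a negative weight and cannot carry",
         " Gaussian surface charges)")
  if (!is.finite(p$rho_leb) || p$rho_leb <= 0)
    stop("validation error: rho_leb must be positive")
  if (!is.finite(p$f_min) || p$f_min < 0 || p$f_min >= 1)
    stop("validation error: f_min must lie in [0, 1)")
  ok <- !is.na(p$elements$r0)
  if (any(p$elements$r0[ok] <= 0))
    stop("validation error: base radii r0 must be positive")
  if (any(p$elements$rcov[!is.na(p$elements$rcov)] <= 0))
    stop("validation error: covalent radii must be positive")
  al <- p$elements$alpha
  if (any(al[!is.na(al)] <= 0))
    stop("validation error: EEQ widths alpha must be positive")
  et <- p$elements$eta
  if (any(et[!is.na(et)] <= 0))
    stop("validation error: EEQ hardness eta must be positive")
  invisible(p)
}

#' @export
print.cpcm_params <- function(x, ...) {
  cat(sprintf(
    "cpcm_params: epsilon = %s (f_eps = %.6f), scheme = %s\n",
    format(x$epsilon), x$f_eps, x$scheme))
  cat(sprintf("  n_leb = %d, rho_leb = %g / A^2, f_min = %g\n",
              x$n_leb, x$rho_leb, x$f_min))
  cat(sprintf("  %d elements parameterised: %s\n", nrow(x$elements),
              paste(x$elements$symbol, collapse = " ")))
  invisible(x)
}

# pull a per-element parameter vector for the atoms of a molecule,
# failing loudly when an element has no entry
.per_atom <- function(params, field, symbols) {
  v <- params[[field]][symbols]
  if (anyNA(v))
    stop("parameter error: no '", field, "' entry for element(s) ",
         paste(unique(symbols[is.na(v)]), collapse = ", "))
  unname(v)
}

#' Load a parameter set from a JSON config file
#'
#' The config is a JSON object whose keys mirror the arguments of
#' [cpcm_params()]; `elements` is an array of records keyed by `symbol`.
#' Missing keys fall back to the shipped defaults.  An empty config file (or
#' `{}`) therefore yields the default parameter set.
#'
#' @param path path to a JSON file.
#' @return a [cpcm_params()] object.
#' @export
load_parameters <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  args <- list()
  for (key in c("epsilon", "scheme", "n_leb", "rho_leb", "f_min",
                "cn_shift")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  if (!is.null(args$epsilon) && identical(args$epsilon, "inf"))
    args$epsilon <- Inf
  if (!is.null(cfg$elements)) args$elements <- cfg$elements
  do.call(cpcm_params, args)
}
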