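#' Construct a molecule of classical point charges
#'
#' A molecule is the solute description used throughout the package: element
#' symbols, Cartesian nuclear positions and fixed per-atom solute charges.
#' The solute charges generate the electrostatic potential on the cavity;
#' they are inputs, independent of geometry (their nuclear derivative is
#' zero).  The geometry-dependent charges used by the radius-scaling scheme
#' are a separate quantity (see [eeq_charges()]).
#'
#' @param symbols character vector of element symbols.
#' @param positions N x 3 numeric matrix of Cartesian coordinates.
#' @param charges per-atom solute charges (elementary charge units); a single
#'   value is recycled.  Defaults to zero on every atom.
#' @param total_charge total molecular charge; defaults to `sum(charges)`.
#' @param units units of `positions`: `"bohr"` (internal standard) or
#'   `"angstrom"`.
#' @return an object of class `"molecule"` with fields `symbols`, `positions`
#'   (bohr), `charges`, `total_charge`, `n`.
#' @examples
#' water_molecule()
#' @export
molecule <- function(symbols, positions, charges = 0, total_charge = NULL,
                     units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  n <- length(symbols)
  if (nrow(positions) != n)
    stop("length(symbols) must match nrow(positions)")
  if (n < 1L) stop("a molecule needs at least one atom")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (units == "angstrom") positions <- positions * BOHR_PER_ANGSTROM
  charges <- rep_len(as.numeric(charges), n)
  if (is.null(total_charge)) total_charge <- sum(charges)
  if (abs(sum(charges) - total_charge) > 1e-8)
    stop("per-atom charges do not sum to total_charge")
  if (n > 1L) {
    dmin <- min(stats::dist(positions))
    if (dmin <= 1e-6)
      stop("coincident atoms: minimum pairwise distance ", format(dmin),
           " bohr")
  }
  structure(
    list(symbols = as.character(symbols), positions = unname(positions),
         charges = charges, total_charge = total_charge, n = n),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, total charge %+g\n", x$n, x$total_charge))
  ang <- x$positions * ANGSTROM_PER_BOHR
  for (i in seq_len(min(x$n, 12L)))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f  q=%+.3f\n", x$symbols[i],
                ang[i, 1], ang[i, 2], ang[i, 3], x$charges[i]))
  if (x$n > 12L) cat("  ...\n")
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom count line, a comment line, then one
#' `symbol x y z` line per atom with coordinates in Angstrom.
#'
#' @param path file path.
#' @param charges charge assignment: a numeric vector of per-atom charges,
#'   or `"zero"` (all atoms neutral).
#' @param total_charge optional total charge (defaults to the charge sum).
#' @return a [molecule()].
#' @export
read_xyz <- function(path, charges = "zero", total_charge = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: invalid atom count '", lines[1L], "'")
  if (length(lines) < n + 2L)
    stop("XYZ parse error: header claims ", n, " atoms but only ",
         max(0L, length(lines) - 2L), " atom lines present")
  symbols <- character(n)
  pos <- matrix(NA_real_, n, 3L)
  known <- .element_defaults()$symbol
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    sym <- tok[1L]
    if (!(sym %in% known))
      stop("unknown element symbol '", sym, "' at line ", ln)
    symbols[i] <- sym
    pos[i, ] <- xyz
  }
  if (identical(charges, "zero")) charges <- rep(0, n)
  molecule(symbols, pos, charges = charges, total_charge = total_charge,
           units = "angstrom")
}

#' Write a molecule to an XYZ file (Angstrom)
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  ang <- mol$positions * ANGSTROM_PER_BOHR
  lines <- c(as.character(mol$n), comment,
             sprintf("%-2s %18.12f %18.12f %18.12f",
                     mol$symbols, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' A water-like triatomic test solute
#'
#' Geometry: O at the origin, O-H bonds of 0.9572 Angstrom at a 104.5 degree
#' angle, with fixed classical charges (O -0.834, H +0.417; a common rigid
#' three-site water charge set).  Used by the continuity scans and as a small
#' gradient test case.
#'
#' @param bond_factor multiplies the length of the *second* O-H bond (the
#'   scanned bond); 1 is equilibrium.
#' @return a [molecule()].
#' @export
water_molecule <- function(bond_factor = 1) {
  r <- 0.9572            # Angstrom
  theta <- 104.5 * pi / 180
  pos <- rbind(c(0, 0, 0),
               c(r, 0, 0),
               bond_factor * c(r * cos(theta), r * sin(theta), 0))
  molecule(c("O", "H", "H"), pos, charges = c(-0.834, 0.417, 0.417),
           units = "angstrom")
}

#' Generate a reproducible random cluster molecule
#'
#' Draws atom positions uniformly in a cubic box by rejection sampling until
#' every pairwise distance exceeds `min_dist`.  Used for property-based and
#' finite-difference tests.
#'
#' @param n_atoms number of atoms.
#' @param elements element pool sampled uniformly.
#' @param box box edge length (bohr).
#' @param min_dist minimum pairwise distance (bohr).
#' @param charges per-atom solute charges ("zero", or numeric vector).
#' @param seed integer seed; geometry is a pure function of the arguments and seed.
#' @param max_tries rejection budget per atom.
#' @return a [molecule()].
#' @export
random_molecule <- function(n_atoms, elements = c("H", "C", "N", "O"),
                            box = 6, min_dist = 2, charges = "zero",
                            seed = 1, max_tries = 10000) {
  stopifnot(n_atoms >= 1, box > 0, min_dist >= 0)
  set.seed(seed)
  symbols <- sample(elements, n_atoms, replace = TRUE)
  pos <- matrix(NA_real_, n_atoms, 3L)
  pos[1L, ] <- stats::runif(3, 0, box)
  for (i in seq_len(n_atoms)[-1L]) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, box)
      d2 <- colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) - cand)^2)
      if (min(d2) > min_dist^2) { pos[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("rejection budget exhausted placing atom ", i,
           " (box too small for min_dist)")
  }
  if (identical(charges, "zero")) charges <- rep(0, n_atoms)
  molecule(symbols, pos, charges = charges)
}
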