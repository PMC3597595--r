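# PotentialField: a queryable scalar electrostatic field in kT/e, backed
# either by an APBS grid (trilinear interpolation) or by a screened-Coulomb
# sum over PQR point charges. The Coulomb backend is a pipeline fallback so
# the method runs without an external Poisson-Boltzmann solver; it is NOT a
# replacement for one.

# e^2/(4*pi*eps0*kB*T*Angstrom) at T = 298 K, in kT/e per (e/Angstrom).
.K_COULOMB <- 561.0

#' Screened-Coulomb potential of a charged atom set
#'
#' Computes, at each query point, the sum over atoms of
#' `k * q_i * exp(-kappa * r_i) / (dielectric * r_i)` with `r_i` in
#' Angstrom, `q_i` in e and `k = 561.0` (the kT/e conversion of
#' e^2/(4 pi eps0 Angstrom) at 298 K; configurable). Distances below
#' `r_min` are clamped to `r_min`, which makes the sum total — querying at
#' an atom position is well defined.
#'
#' @param atoms A `charged_atoms` set from [read_pqr()].
#' @param points Numeric matrix (n x 3) or length-3 vector, Angstrom.
#' @param dielectric Uniform relative dielectric (> 0), default 80
#'   (solvent-like screening).
#' @param kappa Inverse Debye screening length in 1/Angstrom (>= 0),
#'   default 0 (no ionic screening).
#' @param exclude Optional integer vector of atom row indices excluded from
#'   the sum (e.g. a residue's own reactive atom at its own position).
#' @param r_min Clamping distance in Angstrom, default 0.5.
#' @param k Coulomb conversion constant, default 561.0 kT/e * Angstrom / e.
#' @return Numeric vector of potentials in kT/e, one per point.
#' @export
coulomb_potential <- function(atoms, points, dielectric = 80, kappa = 0,
                              exclude = NULL, r_min = 0.5, k = .K_COULOMB) {
  stopifnot(dielectric > 0, kappa >= 0, r_min > 0)
  p <- as_points(points)
  ax <- atoms$x; ay <- atoms$y; az <- atoms$z; q <- atoms$charge
  if (!is.null(exclude) && length(exclude)) {
    ax <- ax[-exclude]; ay <- ay[-exclude]; az <- az[-exclude]; q <- q[-exclude]
  }
  if (!length(q)) return(rep(0, nrow(p)))
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    r <- sqrt((ax - p[i, 1])^2 + (ay - p[i, 2])^2 + (az - p[i, 3])^2)
    r <- pmax(r, r_min)
    out[i] <- k / dielectric * sum(q * exp(-kappa * r) / r)
  }
  out
}

#' Construct a potential field
#'
#' Wraps either a [potential_grid()] (APBS OpenDX output; queried by
#' trilinear interpolation) or a `charged_atoms` set (queried by the
#' built-in screened-Coulomb model) behind a common query interface.
#'
#' @param backend A `potential_grid` or a `charged_atoms` object.
#' @param dielectric,kappa,r_min,k Coulomb-backend parameters, see
#'   [coulomb_potential()]. Ignored for grid backends.
#' @return A `potential_field` object; query it with [query_potential()].
#' @export
potential_field <- function(backend, dielectric = 80, kappa = 0,
                            r_min = 0.5, k = .K_COULOMB) {
  if (inherits(backend, "potential_grid")) {
    f <- list(type = "grid", grid = backend)
  } else if (inherits(backend, "charged_atoms")) {
    f <- list(
      type = "coulomb", atoms = backend,
      dielectric = dielectric, kappa = kappa, r_min = r_min, k = k
    )
  } else {
    stop("backend must be a potential_grid or charged_atoms object", call. = FALSE)
  }
  structure(f, class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  if (x$type == "grid") {
    cat("<potential_field> grid backend\n")
  } else {
    cat(
      "<potential_field> screened-Coulomb backend (dielectric ", x$dielectric,
      ", kappa ", x$kappa, " 1/A)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Query a potential field at points
#'
#' @param field A [potential_field()].
#' @param points Numeric matrix (n x 3) or length-3 vector, Angstrom.
#' @param exclude Coulomb backend only: atom row indices to exclude.
#' @return Numeric vector of potentials in kT/e.
#' @export
query_potential <- function(field, points, exclude = NULL) {
  stopifnot(inherits(field, "potential_field"))
  if (field$type == "grid") {
    interpolate_grid(field$grid, points)
  } else {
    coulomb_potential(
      field$atoms, points,
      dielectric = field$dielectric, kappa = field$kappa,
      exclude = exclude, r_min = field$r_min, k = field$k
    )
  }
}

#' Per-residue potentials at the reactive atoms
#'
#' Evaluates the field at each residue's reactive-atom coordinate. For the
#' Coulomb backend the residue's own reactive-atom charge is excluded from
#' the sum at its own position (a point charge contributes no potential to
#' itself). For the grid backend, residues whose reactive atom falls outside
#' the grid bounding box get `NA` with a warning and are dropped from
#' downstream analysis.
#'
#' @param field A [potential_field()].
#' @param residues A `residue_set` from [resolve_reactive_atoms()].
#' @return Named numeric vector of potentials in kT/e, keyed by residue key;
#'   `NA` marks residues the field could not be evaluated for.
#' @export
residue_potentials <- function(field, residues) {
  stopifnot(inherits(field, "potential_field"), inherits(residues, "residue_set"))
  pts <- cbind(residues$x, residues$y, residues$z)
  n <- nrow(pts)
  pot <- rep(NA_real_, n)

  if (field$type == "grid") {
    inside <- grid_contains(field$grid, pts)
    if (any(inside)) {
      pot[inside] <- interpolate_grid(field$grid, pts[inside, , drop = FALSE])
    }
    if (any(!inside)) {
      warning(
        "reactive atom outside potential grid for residue(s): ",
        paste(residues$label[!inside], collapse = ", "),
        "; dropped from analysis",
        call. = FALSE
      )
    }
  } else {
    # exclusion by identity of the reactive atom itself
    akey <- paste(field$atoms$chain, field$atoms$resno, field$atoms$ins,
                  field$atoms$atom, sep = "\r")
    rkey <- paste(residues$chain, residues$resno, residues$ins,
                  residues$atom, sep = "\r")
    self <- match(rkey, akey)
    for (i in seq_len(n)) {
      excl <- if (is.na(self[i])) NULL else self[i]
      pot[i] <- coulomb_potential(
        field$atoms, pts[i, ],
        dielectric = field$dielectric, kappa = field$kappa,
        exclude = excl, r_min = field$r_min, k = field$k
      )
    }
  }
  names(pot) <- residues$key
  pot
}

grid_contains <- function(grid, points) {
  p <- as_points(points)
  upper <- grid$origin + grid$spacing * (grid$counts - 1L)
  eps <- 1e-9
  (p[, 1] >= grid$origin[1] - eps & p[, 1] <= upper[1] + eps) &
    (p[, 2] >= grid$origin[2] - eps & p[, 2] <= upper[2] + eps) &
    (p[, 3] >= grid$origin[3] - eps & p[, 3] <= upper[3] + eps)
}
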