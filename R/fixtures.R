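# Synthetic holo/apo fixture generator. Builds toy structures with known
# geometry, PQR charges and an analytic potential field, so that every stage
# of the pipeline can be exercised offline and checked against a closed-form
# ground truth. Fixtures use real amino-acid names and a plausible local
# atom layout so the reactive-atom map walks real code paths; they are not
# physically realistic conformations.

# default sequence: cycles through types covering all reactive-atom branches
.FIXTURE_SEQ <- c("SER", "GLY", "HIS", "ASP", "LYS", "ALA", "TYR", "GLU",
                  "ARG", "THR")

#' Specify a synthetic holo/apo fixture
#'
#' The default spec describes a 10-residue linear chain with 5 Angstrom
#' spacing in a gentle affine potential field — at the default 6 Angstrom
#' neighbor radius each interior residue then has exactly two neighbors,
#' which keeps the closed-form expectations legible.
#'
#' @param n_residues Number of residues (default 10).
#' @param geometry `"linear"`, `"helix"` or `"cluster"`.
#' @param spacing Characteristic spacing in Angstrom (default 5): the CA-CA
#'   step for `"linear"`, the axial scale for `"cluster"`; helices use the
#'   canonical 2.3 Angstrom radius / 1.5 Angstrom rise.
#' @param residue_types 3-letter codes, recycled to `n_residues`; default
#'   cycles a set covering side-chain, CB and CA reactive-atom resolution.
#' @param apo_residue_types Optional apo-side types (to emulate point
#'   mutations); default identical to `residue_types`.
#' @param charges Reactive-atom charges in e, recycled; default alternates
#'   +0.5 / -0.5.
#' @param field Analytic field: [field_constant()], [field_affine()] or
#'   [field_coulomb()]; default `field_affine(10, 1, 0.5, -0.25)`.
#' @param injection Named numeric vector of apo potential offsets in kT/e,
#'   names being residue indices (e.g. `c("5" = 10)`); default none.
#' @param displacement Named list of length-3 numeric shifts in Angstrom
#'   applied to all atoms of the named apo residues (for spatial-deviation
#'   tests); default none.
#' @param radius Neighbor radius in Angstrom used for the ground-truth
#'   table, default 6.
#' @param dielectric,kappa Coulomb model parameters used for the
#'   coulomb-backend ground truth, defaults 80 and 0.
#' @param grid_spacing DX grid spacing in Angstrom, default 1.
#' @param seed Integer seed making `"cluster"` geometry deterministic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 10L,
                         geometry = c("linear", "helix", "cluster"),
                         spacing = 5,
                         residue_types = NULL,
                         apo_residue_types = NULL,
                         charges = NULL,
                         field = field_affine(10, 1, 0.5, -0.25),
                         injection = NULL,
                         displacement = NULL,
                         radius = 6,
                         dielectric = 80, kappa = 0,
                         grid_spacing = 1,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2L, spacing > 0, radius > 0, grid_spacing > 0)
  if (is.null(residue_types)) {
    residue_types <- rep_len(.FIXTURE_SEQ, n_residues)
  } else {
    residue_types <- rep_len(toupper(residue_types), n_residues)
  }
  if (is.null(apo_residue_types)) {
    apo_residue_types <- residue_types
  } else {
    apo_residue_types <- rep_len(toupper(apo_residue_types), n_residues)
  }
  if (is.null(charges)) charges <- rep_len(c(0.5, -0.5), n_residues)
  charges <- rep_len(as.numeric(charges), n_residues)

  if (!is.null(injection)) {
    idx <- suppressWarnings(as.integer(names(injection)))
    if (anyNA(idx) || any(idx < 1L | idx > n_residues)) {
      stop("injection names must be residue indices in 1..n_residues", call. = FALSE)
    }
  }
  if (!is.null(displacement)) {
    idx <- suppressWarnings(as.integer(names(displacement)))
    if (anyNA(idx) || any(idx < 1L | idx > n_residues)) {
      stop("displacement names must be residue indices in 1..n_residues", call. = FALSE)
    }
    stopifnot(all(vapply(displacement, length, 0L) == 3L))
  }

  structure(
    list(
      n_residues = as.integer(n_residues), geometry = geometry,
      spacing = spacing, residue_types = residue_types,
      apo_residue_types = apo_residue_types, charges = charges,
      field = field, injection = injection, displacement = displacement,
      radius = radius, dielectric = dielectric, kappa = kappa,
      grid_spacing = grid_spacing, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Analytic field specifications for fixtures
#'
#' `field_constant(v)` is `f(p) = v`; `field_affine(a, b, c, d)` is
#' `f(p) = a + b x + c y + d z`; `field_coulomb()` derives the field from
#' the fixture's own reactive-atom charges via the screened-Coulomb model.
#' Trilinear interpolation reproduces constant and affine fields exactly,
#' so those two give exact ground truth for the grid backend as well.
#'
#' @param v,a,b,c,d Field coefficients (kT/e; slopes in kT/e per Angstrom).
#' @return A `field_spec` list.
#' @name fixture_fields
NULL

#' @rdname fixture_fields
#' @export
field_constant <- function(v) {
  structure(list(type = "constant", v = v), class = "field_spec")
}

#' @rdname fixture_fields
#' @export
field_affine <- function(a, b, c, d) {
  structure(list(type = "affine", coef = c(a, b, c, d)), class = "field_spec")
}

#' @rdname fixture_fields
#' @export
field_coulomb <- function() {
  structure(list(type = "coulomb"), class = "field_spec")
}

eval_field <- function(field, points, charged = NULL, dielectric = 80,
                       kappa = 0, exclude = NULL) {
  p <- as_points(points)
  switch(field$type,
    constant = rep(field$v, nrow(p)),
    affine = field$coef[1] + p %*% field$coef[2:4],
    coulomb = {
      stopifnot(!is.null(charged))
      coulomb_potential(charged, p, dielectric = dielectric, kappa = kappa,
                        exclude = exclude)
    },
    stop("unknown field type", call. = FALSE)
  )
}

# offset distance of the Coulomb-backend injection charge from the reactive
# atom (Angstrom), and its atom name in the apo PQR
.INJ_DIST <- 1.0
.INJ_ATOM <- "QX"

#' Generate a synthetic holo/apo fixture pair
#'
#' Builds matched holo and apo structures (PDB text), charge sets (PQR
#' text), potential grids (DX), and the closed-form ground-truth tables for
#' both potential backends. Deterministic under the spec seed.
#'
#' Injected apo potential offsets are realized differently per backend: the
#' apo DX grid adds the offset to every node of the cell enclosing the
#' residue's reactive atom (exact under trilinear interpolation), while the
#' apo PQR gains one extra point charge (atom `QX`) placed `1 Angstrom`
#' above the reactive atom, scaled so its potential there equals the
#' requested offset. Both realizations are accounted for exactly in the
#' respective ground-truth tables.
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_pair` list: `holo_pdb`, `apo_pdb`, `holo_pqr`,
#'   `apo_pqr` (character vectors of file lines), `holo_grid`, `apo_grid`
#'   ([potential_grid()]s), `truth_grid`, `truth_coulomb` (data frames with
#'   `label`, `key`, `pot_holo`, `pot_apo`, `sum_holo`, `sum_apo`,
#'   `e_perturb`, `spatial_deviation`, `neighbor_count`), and `spec`.
#' @export
make_fixture_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  centers <- fixture_centers(spec)

  map <- reactive_atom_map()
  holo <- build_fixture_atoms(centers, spec$residue_types, map)
  apo <- build_fixture_atoms(centers, spec$apo_residue_types, map)
  if (!is.null(spec$displacement)) {
    for (nm in names(spec$displacement)) {
      i <- as.integer(nm)
      rows <- apo$atoms$resno == i
      shift <- spec$displacement[[nm]]
      apo$atoms$x[rows] <- quantize3(apo$atoms$x[rows] + shift[1])
      apo$atoms$y[rows] <- quantize3(apo$atoms$y[rows] + shift[2])
      apo$atoms$z[rows] <- quantize3(apo$atoms$z[rows] + shift[3])
      apo$reactive[i, ] <- quantize3(apo$reactive[i, ] + shift)
    }
  }

  inj <- numeric(n)
  if (!is.null(spec$injection)) {
    inj[as.integer(names(spec$injection))] <- as.numeric(spec$injection)
  }

  # --- charged atom sets: only reactive atoms carry charge -----------------
  holo_pqr <- fixture_pqr_lines(holo, spec$charges)
  apo_charged_extra <- NULL
  if (any(inj != 0)) {
    d <- .INJ_DIST
    ks <- which(inj != 0)
    qx <- inj[ks] * spec$dielectric * d / (.K_COULOMB * exp(-spec$kappa * d))
    # quantize to the printed PQR precision so truth and parsed file agree
    qx <- as.numeric(sprintf("%.8f", qx))
    apo_charged_extra <- data.frame(
      resno = ks,
      x = apo$reactive[ks, 1], y = apo$reactive[ks, 2],
      z = apo$reactive[ks, 3] + d, charge = qx
    )
  }
  apo_pqr <- fixture_pqr_lines(apo, spec$charges, extra = apo_charged_extra)

  # --- DX grids over the union bounding box --------------------------------
  all_xyz <- rbind(
    as.matrix(holo$atoms[, c("x", "y", "z")]),
    as.matrix(apo$atoms[, c("x", "y", "z")])
  )
  gs <- spec$grid_spacing
  origin <- floor((apply(all_xyz, 2L, min) - 3) / gs) * gs
  upper <- ceiling((apply(all_xyz, 2L, max) + 3) / gs) * gs
  counts <- as.integer(round((upper - origin) / gs)) + 1L

  holo_charged <- read_pqr(holo_pqr)
  nodes <- grid_nodes(origin, gs, counts)
  vals_h <- eval_field(spec$field, nodes, charged = holo_charged,
                       dielectric = spec$dielectric, kappa = spec$kappa)
  holo_grid <- potential_grid(origin, rep(gs, 3L), counts, vals_h)

  vals_a <- vals_h
  if (any(inj != 0)) {
    for (k in which(inj != 0)) {
      rk <- apo$reactive[k, ]
      close <- abs(nodes[, 1] - rk[1]) <= gs + 1e-9 &
        abs(nodes[, 2] - rk[2]) <= gs + 1e-9 &
        abs(nodes[, 3] - rk[3]) <= gs + 1e-9
      vals_a[close] <- vals_a[close] + inj[k]
    }
    # injected residues must be isolated so cells do not overlap neighbors
    other <- apo$reactive[-which(inj != 0), , drop = FALSE]
    for (k in which(inj != 0)) {
      if (nrow(other) &&
          any(apply(abs(sweep(other, 2L, apo$reactive[k, ])), 1L, max) < 2 * gs)) {
        stop("injection at residue ", k,
             " too close to another reactive atom for an exact grid realization",
             call. = FALSE)
      }
    }
  }
  apo_grid <- potential_grid(origin, rep(gs, 3L), counts, vals_a)

  # --- closed-form ground truth -------------------------------------------
  labels <- paste0(spec$residue_types, seq_len(n))
  keys <- res_key(rep("A", n), seq_len(n), rep("", n))

  # grid truth samples the analytic field at the reactive atoms; exact under
  # trilinear interpolation for constant/affine fields, approximate for a
  # coulomb field (where truth_coulomb is the exact reference instead)
  pot_h_grid <- as.numeric(eval_field(
    spec$field, holo$reactive, charged = holo_charged,
    dielectric = spec$dielectric, kappa = spec$kappa
  ))
  pot_a_grid <- as.numeric(eval_field(
    spec$field, apo$reactive, charged = holo_charged,
    dielectric = spec$dielectric, kappa = spec$kappa
  )) + inj

  # coulomb-backend truth: direct sums over reactive charges, excluding self
  pot_h_cb <- fixture_coulomb_pot(holo$reactive, spec$charges, spec)
  pot_a_cb <- fixture_coulomb_pot(apo$reactive, spec$charges, spec,
                                  extra = apo_charged_extra)

  truth_grid <- fixture_truth(labels, keys, holo$reactive, apo$reactive,
                              pot_h_grid, pot_a_grid, spec$radius)
  truth_coulomb <- fixture_truth(labels, keys, holo$reactive, apo$reactive,
                                 pot_h_cb, pot_a_cb, spec$radius)

  structure(
    list(
      holo_pdb = fixture_pdb_lines(holo),
      apo_pdb = fixture_pdb_lines(apo),
      holo_pqr = holo_pqr, apo_pqr = apo_pqr,
      holo_grid = holo_grid, apo_grid = apo_grid,
      truth_grid = truth_grid, truth_coulomb = truth_coulomb,
      spec = spec
    ),
    class = "fixture_pair"
  )
}

#' Write all files of a fixture pair to a directory
#'
#' @param fix A `fixture_pair` from [make_fixture_pair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, named vector of paths (`holo_pdb`, `apo_pdb`,
#'   `holo_pqr`, `apo_pqr`, `holo_dx`, `apo_dx`, `truth`).
#' @export
write_fixture_pair <- function(fix, dir) {
  stopifnot(inherits(fix, "fixture_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    holo_pdb = file.path(dir, "holo.pdb"), apo_pdb = file.path(dir, "apo.pdb"),
    holo_pqr = file.path(dir, "holo.pqr"), apo_pqr = file.path(dir, "apo.pqr"),
    holo_dx = file.path(dir, "holo.dx"), apo_dx = file.path(dir, "apo.dx"),
    truth = file.path(dir, "truth.tsv")
  )
  writeLines(fix$holo_pdb, paths["holo_pdb"])
  writeLines(fix$apo_pdb, paths["apo_pdb"])
  writeLines(fix$holo_pqr, paths["holo_pqr"])
  writeLines(fix$apo_pqr, paths["apo_pqr"])
  write_dx(fix$holo_grid, paths["holo_dx"], comment = "synthetic holo potential (kT/e)")
  write_dx(fix$apo_grid, paths["apo_dx"], comment = "synthetic apo potential (kT/e)")
  utils::write.table(fix$truth_grid, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# ---- internals -------------------------------------------------------------

fixture_centers <- function(spec) {
  n <- spec$n_residues
  switch(spec$geometry,
    linear = cbind(spec$spacing * (seq_len(n) - 1L), 0, 0),
    helix = {
      t_ <- (seq_len(n) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(t_), 2.3 * sin(t_), 1.5 * (seq_len(n) - 1L))
    },
    cluster = {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(spec$seed)
      side <- spec$spacing * max(2, ceiling(n^(1 / 3)) + 1)
      pts <- matrix(NA_real_, n, 3L)
      for (i in seq_len(n)) {
        repeat {
          cand <- stats::runif(3L, 0, side)
          if (i == 1L) { pts[i, ] <- cand; break }
          d <- sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2L, cand)^2))
          if (min(d) >= 3.5) { pts[i, ] <- cand; break }
        }
      }
      pts
    }
  )
}

# quantize to PDB coordinate precision (3 decimals) so that values written
# to PDB/PQR text round-trip exactly and the ground truth matches the
# pipeline to machine precision
quantize3 <- function(v) as.numeric(sprintf("%.3f", v))

# local atom layout around each CA center; returns atoms data frame plus the
# reactive-atom coordinate matrix
build_fixture_atoms <- function(centers, types, map) {
  n <- nrow(centers)
  offs <- list(
    N = c(-1.2, 0.8, 0.0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0.0),
    O = c(1.9, 1.7, 0.3), CB = c(0.0, -1.3, 0.8)
  )
  rows <- list()
  reactive <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ty <- types[i]
    names_i <- c("N", "CA", "C", "O")
    if (ty != "GLY") names_i <- c(names_i, "CB")
    head_atom <- map[[ty]][1]
    if (!head_atom %in% c("CA", "CB")) names_i <- c(names_i, head_atom)
    for (nm in names_i) {
      off <- if (nm %in% names(offs)) offs[[nm]] else c(0.0, -2.6, 1.6)
      rows[[length(rows) + 1L]] <- data.frame(
        atom = nm, resid = ty, chain = "A", resno = i, ins = "",
        x = centers[i, 1] + off[1], y = centers[i, 2] + off[2],
        z = centers[i, 3] + off[3], stringsAsFactors = FALSE
      )
    }
    ract <- if (head_atom %in% names(offs)) offs[[head_atom]] else c(0.0, -2.6, 1.6)
    reactive[i, ] <- centers[i, ] + ract
  }
  atoms <- do.call(rbind, rows)
  atoms$x <- quantize3(atoms$x)
  atoms$y <- quantize3(atoms$y)
  atoms$z <- quantize3(atoms$z)
  reactive[] <- quantize3(reactive)
  list(atoms = atoms, reactive = reactive, types = types)
}

fixture_pdb_lines <- function(fx) {
  at <- fx$atoms
  pad_name <- function(nm) {
    # standard PDB convention: element-aligned, names of <4 chars start col 14
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  body <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), pad_name(at$atom), at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, substr(at$atom, 1, 1)
  )
  c("REMARK synthetic fixture", body, "END")
}

fixture_pqr_lines <- function(fx, charges, extra = NULL) {
  at <- fx$atoms
  reactive_name <- vapply(seq_len(nrow(fx$reactive)), function(i) {
    ty <- fx$types[i]
    reactive_atom_map()[[ty]][1]
  }, character(1))
  q <- numeric(nrow(at))
  for (i in seq_len(nrow(fx$reactive))) {
    q[at$resno == i & at$atom == reactive_name[i]] <- charges[i]
  }
  body <- sprintf(
    "ATOM  %5d %-4s %3s %1s %4d %11.6f %11.6f %11.6f %12.8f %7.4f",
    seq_len(nrow(at)), at$atom, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, q, 1.5
  )
  if (!is.null(extra)) {
    body <- c(body, sprintf(
      "ATOM  %5d %-4s %3s %1s %4d %11.6f %11.6f %11.6f %12.8f %7.4f",
      nrow(at) + seq_len(nrow(extra)), .INJ_ATOM,
      fx$types[extra$resno], "A", extra$resno,
      extra$x, extra$y, extra$z, extra$charge, 0.0
    ))
  }
  c("REMARK synthetic fixture charges", body)
}

grid_nodes <- function(origin, gs, counts) {
  # node coordinates in DX storage order (z fastest)
  xs <- origin[1] + gs * (seq_len(counts[1]) - 1L)
  ys <- origin[2] + gs * (seq_len(counts[2]) - 1L)
  zs <- origin[3] + gs * (seq_len(counts[3]) - 1L)
  cbind(
    rep(xs, each = counts[2] * counts[3]),
    rep(rep(ys, each = counts[3]), times = counts[1]),
    rep(zs, times = counts[1] * counts[2])
  )
}

fixture_coulomb_pot <- function(reactive, charges, spec, extra = NULL) {
  n <- nrow(reactive)
  pot <- numeric(n)
  for (i in seq_len(n)) {
    r <- sqrt(rowSums(sweep(reactive, 2L, reactive[i, ])^2))
    r <- pmax(r, 0.5)
    use <- seq_len(n) != i
    pot[i] <- .K_COULOMB / spec$dielectric *
      sum(charges[use] * exp(-spec$kappa * r[use]) / r[use])
    if (!is.null(extra)) {
      re <- sqrt((extra$x - reactive[i, 1])^2 + (extra$y - reactive[i, 2])^2 +
                   (extra$z - reactive[i, 3])^2)
      re <- pmax(re, 0.5)
      pot[i] <- pot[i] + .K_COULOMB / spec$dielectric *
        sum(extra$charge * exp(-spec$kappa * re) / re)
    }
  }
  pot
}

# direct double-loop evaluation of the neighbor sums; the fixture's own
# statement of the expected pipeline output
fixture_truth <- function(labels, keys, holo_reactive, apo_reactive,
                          pot_h, pot_a, radius) {
  n <- length(pot_h)
  sum_h <- sum_a <- spat <- numeric(n)
  nc <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(holo_reactive, 2L, holo_reactive[i, ])^2))
    nb <- which(d <= radius & seq_len(n) != i)
    nc[i] <- length(nb)
    if (!length(nb)) next
    sum_h[i] <- sum(pot_h[i] - pot_h[nb])
    sum_a[i] <- sum(pot_a[i] - pot_a[nb])
    dh <- sqrt(rowSums(sweep(holo_reactive[nb, , drop = FALSE], 2L, holo_reactive[i, ])^2))
    da <- sqrt(rowSums(sweep(apo_reactive[nb, , drop = FALSE], 2L, apo_reactive[i, ])^2))
    spat[i] <- sum(dh) - sum(da)
  }
  data.frame(
    label = labels, key = keys,
    pot_holo = pot_h, pot_apo = pot_a,
    sum_holo = sum_h, sum_apo = sum_a, e_perturb = sum_h - sum_a,
    spatial_deviation = spat, neighbor_count = nc,
    stringsAsFactors = FALSE
  )
}
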