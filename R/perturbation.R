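# Core arithmetic: electrostatic potential differences (EPDs), holo-defined
# neighbor sets, per-residue perturbation scores and the parallel spatial-
# deviation analysis.
#
# For residue i with holo-defined neighbor set Phi_i:
#   sum_holo_i  = sum_{j in Phi_i} [Pot_h(i) - Pot_h(j)]
#   sum_apo_i   = sum_{j in Phi_i} [Pot_a(i) - Pot_a(j)]   (same Phi_i!)
#   e_perturb_i = sum_holo_i - sum_apo_i
# The neighbor set is always computed on the holo structure so that the holo
# and apo sums range over the same residues even when binding rearranges the
# neighborhood.

#' Electrostatic potential difference between two residues
#'
#' `EPD(a, b) = Pot(a) - Pot(b)` within one structure, in kT/e. Antisymmetric
#' by construction.
#'
#' @param potentials Named numeric vector of residue potentials (kT/e), as
#'   from [residue_potentials()].
#' @param a,b Residue keys (names into `potentials`).
#' @return Numeric scalar, kT/e.
#' @export
epd <- function(potentials, a, b) {
  pa <- unname(potentials[match(a, names(potentials))])
  pb <- unname(potentials[match(b, names(potentials))])
  if (is.na(pa) || is.na(pb)) {
    stop("missing potential for residue ", if (is.na(pa)) a else b,
         call. = FALSE)
  }
  pa - pb
}

#' Holo-defined neighbor sets
#'
#' For each residue, the set of all other residues whose anchor atom lies
#' within `radius` of its anchor atom. Computed on the holo structure only;
#' the same sets are reused for the apo sums.
#'
#' @param residues A `residue_set` (normally the holo one).
#' @param radius Cutoff in Angstrom (> 0), default 6.
#' @param metric Distance anchor: `"reactive"` (reactive atom to reactive
#'   atom, the default), `"ca"` (CA-CA), or `"any"` (closest approach of any
#'   atom pair; requires `atoms`).
#' @param atoms For `metric = "any"`, the full atom data frame of the
#'   structure (`structure$atoms`).
#' @return List of integer vectors, one per residue (row indices into
#'   `residues`), with attributes `radius` and `metric`.
#' @export
neighbor_sets <- function(residues, radius = 6,
                          metric = c("reactive", "ca", "any"), atoms = NULL) {
  stopifnot(inherits(residues, "residue_set"), radius > 0)
  metric <- match.arg(metric)
  n <- nrow(residues)

  if (metric == "any") {
    if (is.null(atoms)) stop("metric = \"any\" requires the atoms data frame", call. = FALSE)
    akey <- res_key(atoms$chain, atoms$resno, atoms$ins)
    groups <- split(seq_len(nrow(atoms)), factor(akey, levels = residues$key))
    nb <- lapply(seq_len(n), function(i) integer(0))
    for (i in seq_len(n)) {
      gi <- groups[[i]]
      for (j in seq_len(n)) {
        if (j == i) next
        gj <- groups[[j]]
        d2 <- outer(atoms$x[gi], atoms$x[gj], `-`)^2 +
          outer(atoms$y[gi], atoms$y[gj], `-`)^2 +
          outer(atoms$z[gi], atoms$z[gj], `-`)^2
        if (min(d2) <= radius^2) nb[[i]] <- c(nb[[i]], j)
      }
    }
  } else {
    pts <- if (metric == "ca") {
      cbind(residues$ca_x, residues$ca_y, residues$ca_z)
    } else {
      cbind(residues$x, residues$y, residues$z)
    }
    if (anyNA(pts)) stop("missing anchor coordinates for metric ", sQuote(metric), call. = FALSE)
    d <- as.matrix(stats::dist(pts))
    nb <- lapply(seq_len(n), function(i) {
      as.integer(which(d[i, ] <= radius & seq_len(n) != i))
    })
  }
  names(nb) <- residues$key
  attr(nb, "radius") <- radius
  attr(nb, "metric") <- metric
  nb
}

#' Per-residue electrostatic perturbation and spatial deviation
#'
#' For each paired residue, sums its EPDs over the holo-defined neighbor set
#' in both forms and reports the difference (`e_perturb`). The identical
#' construction applied to reactive-atom Euclidean distances gives the
#' spatial-deviation score. Residues lacking a potential in either form are
#' dropped from the analysis (as centers and as neighbor members, so holo
#' and apo sums always range over the same residues); in polar-only mode
#' non-polar residues are likewise excluded on both sides.
#'
#' @param paired A `paired_structures` from [pair_structures()].
#' @param pot_holo,pot_apo Named potential vectors from
#'   [residue_potentials()], keyed like `paired$holo$key`.
#' @param neighbors Neighbor sets from [neighbor_sets()] computed on
#'   `paired$holo`; default computes them at 6 Angstrom.
#' @param polar_only Restrict the analysis to polar residues (default off).
#' @param polar_set Residue types counted as polar, default [polar_residues()].
#' @param spatial Spatial-deviation flavor: `"signed"` (default; the literal
#'   transliteration, sum of holo distances minus sum of apo distances) or
#'   `"absolute"` (sum of |d_holo - d_apo| over neighbors).
#' @return A `perturbation_table` data frame with one row per paired
#'   residue: `chain`, `resno`, `ins`, `resid`, `label`, `sum_holo`,
#'   `sum_apo`, `e_perturb` (kT/e), `spatial_deviation` (Angstrom),
#'   `neighbor_count`, and `flag` (`""`, `"no_neighbors"`, `"no_potential"`
#'   or `"nonpolar"`).
#' @export
perturbation <- function(paired, pot_holo, pot_apo,
                         neighbors = neighbor_sets(paired$holo),
                         polar_only = FALSE, polar_set = polar_residues(),
                         spatial = c("signed", "absolute")) {
  stopifnot(inherits(paired, "paired_structures"))
  spatial <- match.arg(spatial)
  h <- paired$holo
  a <- paired$apo
  n <- paired$n
  if (!identical(names(neighbors), h$key)) {
    neighbors <- neighbors[match(h$key, names(neighbors))]
    if (anyNA(names(neighbors))) {
      stop("neighbor sets do not cover the paired residues", call. = FALSE)
    }
  }

  ph <- as.numeric(pot_holo[h$key])
  pa <- as.numeric(pot_apo[a$key])
  usable <- !is.na(ph) & !is.na(pa)
  if (any(!usable)) {
    warning(
      "residue(s) without potentials dropped: ",
      paste(h$label[!usable], collapse = ", "),
      call. = FALSE
    )
  }
  eligible <- usable
  if (polar_only) eligible <- eligible & (h$resid %in% polar_set)

  hx <- cbind(h$x, h$y, h$z)
  ax <- cbind(a$x, a$y, a$z)

  out <- data.frame(
    chain = h$chain, resno = h$resno, ins = h$ins, resid = h$resid,
    label = h$label, key = h$key,
    sum_holo = NA_real_, sum_apo = NA_real_, e_perturb = NA_real_,
    spatial_deviation = NA_real_, neighbor_count = NA_integer_,
    flag = "", stringsAsFactors = FALSE
  )
  out$flag[!usable] <- "no_potential"
  out$flag[usable & !eligible] <- "nonpolar"

  for (i in which(eligible)) {
    nb <- neighbors[[i]]
    nb <- nb[eligible[nb]]
    out$neighbor_count[i] <- length(nb)
    if (!length(nb)) {
      out$sum_holo[i] <- out$sum_apo[i] <- out$e_perturb[i] <- 0
      out$spatial_deviation[i] <- 0
      out$flag[i] <- "no_neighbors"
      next
    }
    out$sum_holo[i] <- sum(ph[i] - ph[nb])
    out$sum_apo[i] <- sum(pa[i] - pa[nb])
    out$e_perturb[i] <- out$sum_holo[i] - out$sum_apo[i]

    dh <- sqrt(rowSums((hx[nb, , drop = FALSE] -
                          matrix(hx[i, ], length(nb), 3L, byrow = TRUE))^2))
    da <- sqrt(rowSums((ax[nb, , drop = FALSE] -
                          matrix(ax[i, ], length(nb), 3L, byrow = TRUE))^2))
    out$spatial_deviation[i] <- if (spatial == "signed") {
      sum(dh) - sum(da)
    } else {
      sum(abs(dh - da))
    }
  }

  attr(out, "radius") <- attr(neighbors, "radius")
  attr(out, "metric") <- attr(neighbors, "metric")
  attr(out, "polar_only") <- polar_only
  attr(out, "spatial") <- spatial
  class(out) <- c("perturbation_table", "data.frame")
  out
}

#' Filter residue pairs for polarity reversal
#'
#' Low-level constructor: given per-pair holo and apo EPDs, keeps pairs
#' whose EPD changes sign (`pd1 * pd2 < 0`) with `|pd1 - pd2| >= threshold`,
#' normalizes orientation so `pd1 > 0` (swapping the residues and negating
#' both EPDs when needed) and reports `delta_pd = pd1 - pd2`.
#'
#' @param residue_a,residue_b Residue labels per pair.
#' @param pd1,pd2 Holo and apo EPDs of each pair, kT/e.
#' @param threshold Minimum |pd1 - pd2| to keep (>= 0), default 150 kT/e.
#' @return A `reversal_set` data frame: `residue_a`, `residue_b`, `pd1`,
#'   `pd2`, `delta_pd`, with attribute `threshold`.
#' @export
reversal_set <- function(residue_a, residue_b, pd1, pd2, threshold = 150) {
  stopifnot(threshold >= 0, length(pd1) == length(pd2))
  keep <- (pd1 * pd2 < 0) & (abs(pd1 - pd2) >= threshold)
  residue_a <- residue_a[keep]; residue_b <- residue_b[keep]
  pd1 <- pd1[keep]; pd2 <- pd2[keep]
  flip <- pd1 < 0
  if (any(flip)) {
    tmp <- residue_a[flip]
    residue_a[flip] <- residue_b[flip]
    residue_b[flip] <- tmp
    pd1[flip] <- -pd1[flip]
    pd2[flip] <- -pd2[flip]
  }
  out <- data.frame(
    residue_a = as.character(residue_a), residue_b = as.character(residue_b),
    pd1 = pd1, pd2 = pd2, delta_pd = pd1 - pd2,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("reversal_set", "data.frame")
  out
}

#' Residue pairs undergoing polarity reversal between holo and apo
#'
#' Enumerates unordered residue pairs, computes their EPD in both forms and
#' applies the sign-change + magnitude filter of [reversal_set()]. By
#' default all pairs among the analyzed residues are tested (reported pairs
#' can span distant sequence positions); `scope = "neighbors"` restricts to
#' holo-defined neighbor pairs.
#'
#' @param paired A `paired_structures`.
#' @param pot_holo,pot_apo Named potential vectors.
#' @param threshold Minimum |delta_pd| in kT/e, default 150.
#' @param scope `"all"` (default) or `"neighbors"`.
#' @param neighbors Required when `scope = "neighbors"`.
#' @return A `reversal_set`, ordered by descending `|delta_pd|`.
#' @export
polarity_reversals <- function(paired, pot_holo, pot_apo, threshold = 150,
                               scope = c("all", "neighbors"), neighbors = NULL) {
  stopifnot(inherits(paired, "paired_structures"))
  scope <- match.arg(scope)
  h <- paired$holo
  ph <- as.numeric(pot_holo[h$key])
  pa <- as.numeric(pot_apo[paired$apo$key])
  ok <- which(!is.na(ph) & !is.na(pa))

  if (scope == "all") {
    if (length(ok) < 2L) {
      return(reversal_set(character(0), character(0), numeric(0), numeric(0), threshold))
    }
    idx <- utils::combn(ok, 2L)
    ia <- idx[1L, ]; ib <- idx[2L, ]
  } else {
    if (is.null(neighbors)) stop("scope = \"neighbors\" requires neighbor sets", call. = FALSE)
    ia <- integer(0); ib <- integer(0)
    for (i in ok) {
      nb <- neighbors[[i]]
      nb <- nb[nb > i & nb %in% ok]
      ia <- c(ia, rep.int(i, length(nb)))
      ib <- c(ib, nb)
    }
  }

  pd1 <- ph[ia] - ph[ib]
  pd2 <- pa[ia] - pa[ib]
  out <- reversal_set(h$label[ia], h$label[ib], pd1, pd2, threshold)
  out <- out[order(-abs(out$delta_pd), out$residue_a, out$residue_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("reversal_set", "data.frame")
  out
}

#' Perturbation tables across a sweep of neighbor radii
#'
#' Recomputes the perturbation table at each radius and summarizes rank
#' stability as the Spearman correlation of `|e_perturb|` between
#' consecutive radii. A well-localized perturbation signal is expected to
#' keep its residue ranking as the neighborhood radius varies.
#'
#' @param paired A `paired_structures`.
#' @param pot_holo,pot_apo Named potential vectors.
#' @param radii Numeric vector of radii in Angstrom, all > 0.
#' @param ... Passed to [perturbation()] (e.g. `polar_only`).
#' @param metric Neighbor metric, see [neighbor_sets()].
#' @return A `radius_sweep`: list with `tables` (named list of
#'   `perturbation_table`s, one per radius) and `stability` (data frame
#'   `radius_from`, `radius_to`, `spearman`; `NA` where the correlation is
#'   undefined, e.g. all-zero perturbations).
#' @export
radius_sweep <- function(paired, pot_holo, pot_apo, radii,
                         metric = c("reactive", "ca"), ...) {
  stopifnot(length(radii) >= 1L, all(radii > 0))
  metric <- match.arg(metric)
  radii <- sort(unique(as.numeric(radii)))
  tables <- lapply(radii, function(r) {
    nb <- neighbor_sets(paired$holo, radius = r, metric = metric)
    perturbation(paired, pot_holo, pot_apo, neighbors = nb, ...)
  })
  names(tables) <- format(radii, trim = TRUE)

  stability <- data.frame(
    radius_from = numeric(0), radius_to = numeric(0), spearman = numeric(0)
  )
  if (length(radii) > 1L) {
    for (i in seq_len(length(radii) - 1L)) {
      v1 <- abs(tables[[i]]$e_perturb)
      v2 <- abs(tables[[i + 1L]]$e_perturb)
      ok <- !is.na(v1) & !is.na(v2)
      rho <- if (sum(ok) >= 2L && stats::sd(v1[ok]) > 0 && stats::sd(v2[ok]) > 0) {
        stats::cor(v1[ok], v2[ok], method = "spearman")
      } else {
        NA_real_
      }
      stability <- rbind(stability, data.frame(
        radius_from = radii[i], radius_to = radii[i + 1L], spearman = rho
      ))
    }
  }
  structure(
    list(tables = tables, stability = stability, radii = radii),
    class = "radius_sweep"
  )
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat("<radius_sweep> radii (A):", paste(x$radii, collapse = ", "), "\n")
  if (nrow(x$stability)) {
    cat("rank stability of |e_perturb| between consecutive radii:\n")
    print(x$stability, row.names = FALSE)
  }
  invisible(x)
}
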