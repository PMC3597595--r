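# Independent brute-force oracles and tiny hand-built inputs. Oracles are
# deliberately written as plain loops over definitions, sharing no code with
# the package internals they check.

# neighbor sets by exhaustive pairwise distance filter
oracle_neighbors <- function(points, radius) {
  n <- nrow(points)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d <= radius) nb <- c(nb, j)
    }
    out[[i]] <- nb
  }
  out
}

# per-residue sums by the literal triple loop over the definitions
oracle_perturbation <- function(points_h, points_a, ph, pa, radius) {
  nb <- oracle_neighbors(points_h, radius)
  n <- length(ph)
  sum_h <- sum_a <- spat <- numeric(n)
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      sum_h[i] <- sum_h[i] + (ph[i] - ph[j])
      sum_a[i] <- sum_a[i] + (pa[i] - pa[j])
      dh <- sqrt(sum((points_h[i, ] - points_h[j, ])^2))
      da <- sqrt(sum((points_a[i, ] - points_a[j, ])^2))
      spat[i] <- spat[i] + (dh - da)
    }
  }
  list(sum_holo = sum_h, sum_apo = sum_a, e_perturb = sum_h - sum_a,
       spatial = spat, n_neighbors = lengths(nb))
}

# all-pairs polarity-reversal filter
oracle_reversals <- function(labels, ph, pa, threshold) {
  rows <- list()
  n <- length(ph)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd1 <- ph[i] - ph[j]
      pd2 <- pa[i] - pa[j]
      if (pd1 * pd2 < 0 && abs(pd1 - pd2) >= threshold) {
        if (pd1 < 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            residue_a = labels[j], residue_b = labels[i],
            pd1 = -pd1, pd2 = -pd2, stringsAsFactors = FALSE
          )
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            residue_a = labels[i], residue_b = labels[j],
            pd1 = pd1, pd2 = pd2, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(residue_a = character(0), residue_b = character(0),
                      pd1 = numeric(0), pd2 = numeric(0)))
  }
  do.call(rbind, rows)
}

# screened-Coulomb sum as a plain double loop
oracle_coulomb <- function(atoms, points, dielectric, kappa, r_min = 0.5,
                           k = 561.0) {
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    acc <- 0
    for (a in seq_len(nrow(atoms))) {
      r <- sqrt((atoms$x[a] - points[p, 1])^2 +
                  (atoms$y[a] - points[p, 2])^2 +
                  (atoms$z[a] - points[p, 3])^2)
      if (r < r_min) r <- r_min
      acc <- acc + atoms$charge[a] * exp(-kappa * r) / r
    }
    out[p] <- k * acc / dielectric
  }
  out
}

# build a residue_set directly from reactive-atom points (bypasses PDB
# parsing; used by the property sweeps where only geometry matters)
make_residue_set <- function(points, types = NULL, chain = "A") {
  n <- nrow(points)
  if (is.null(types)) types <- rep_len(c("ALA", "SER", "LYS", "ASP"), n)
  df <- data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = rep_len(types, n),
    key = sprintf("%s:%d", chain, seq_len(n)),
    atom = "CA", x = points[, 1], y = points[, 2], z = points[, 3],
    ca_x = points[, 1], ca_y = points[, 2], ca_z = points[, 3],
    stringsAsFactors = FALSE
  )
  df$label <- paste0(df$resid, df$resno)
  class(df) <- c("residue_set", "data.frame")
  df
}

pair_self <- function(points, types = NULL) {
  rs <- make_residue_set(points, types)
  pair_structures(rs, rs, max_mutations = 0L)
}

random_points <- function(n, scale = 20) {
  matrix(stats::runif(3 * n, 0, scale), ncol = 3L)
}

# minimal hand-written PDB text: 4 standard residues, one HETATM zinc
tiny_pdb <- function() {
  c(
    "HEADER    SYNTHETIC TEST",
    "ATOM      1  N   SER A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  OG  SER A   1       1.500   2.200   0.300  1.00  0.00           O",
    "ATOM      4  N   GLY A   2       4.000   1.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       5.000   1.000   0.000  1.00  0.00           C",
    "ATOM      6  N   HIS A   3       8.000   1.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  HIS A   3       9.000   1.000   0.000  1.00  0.00           C",
    "ATOM      8  CB  HIS A   3       9.400   2.300   0.500  1.00  0.00           C",
    "ATOM      9  NE2 HIS A   3       9.900   3.600   1.000  1.00  0.00           N",
    "ATOM     10  N   ALA A   4      12.000   1.000   0.000  1.00  0.00           N",
    "ATOM     11  CA  ALA A   4      13.000   1.000   0.000  1.00  0.00           C",
    "ATOM     12  CB  ALA A   4      13.400   2.300   0.500  1.00  0.00           C",
    "HETATM   13 ZN    ZN A 101      10.000  10.000  10.000  1.00  0.00          ZN",
    "END"
  )
}

tiny_pqr <- function() {
  c(
    "REMARK test charges",
    "ATOM      1  CA  ALA A    1    0.000    0.000    0.000  0.5000 1.5000",
    "ATOM      2  CA  GLY A    2    3.000    0.000    0.000 -0.2000 1.2000",
    "ATOM      3  NZ  LYS A    3    0.000    4.000    0.000  1.0000 1.8000"
  )
}
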