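# EPDs, neighbor sets, perturbation scores, polarity reversals, radius sweep

test_that("epd is the potential difference and is antisymmetric", {
  pot <- c("A:1" = 3.5, "A:2" = 3.5, "A:3" = -1.25)
  expect_equal(epd(pot, "A:1", "A:2"), 0)
  expect_equal(epd(pot, "A:1", "A:3"), 4.75)
  expect_error(epd(pot, "A:1", "A:9"), "missing potential")

  set.seed(5)
  for (rep in 1:20) {
    p <- stats::setNames(rnorm(5, sd = 100), paste0("A:", 1:5))
    ij <- sample(names(p), 2L)
    expect_equal(epd(p, ij[1], ij[2]), -epd(p, ij[2], ij[1]))
  }
})

test_that("neighbor sets match the geometric construction and the oracle", {
  # collinear reactive atoms 5 A apart: interior residues have 2 neighbors
  pts <- cbind(5 * (0:9), 0, 0)
  rs <- make_residue_set(pts)
  nb <- neighbor_sets(rs, radius = 6)
  expect_equal(unname(lengths(nb)), c(1L, rep(2L, 8), 1L))
  expect_equal(nb[["A:5"]], c(4L, 6L))

  # radius below the minimum pairwise distance: all sets empty
  expect_equal(unname(lengths(neighbor_sets(rs, radius = 2))), rep(0L, 10))

  # random geometries against the exhaustive distance filter
  set.seed(8)
  for (rep in 1:10) {
    p <- random_points(sample(5:25, 1))
    r <- runif(1, 3, 12)
    got <- neighbor_sets(make_residue_set(p), radius = r)
    expect_equal(unname(lapply(got, as.integer)), oracle_neighbors(p, r))
  }
})

test_that("neighbor sets are monotone in the radius", {
  set.seed(9)
  for (rep in 1:10) {
    p <- random_points(15)
    rs <- make_residue_set(p)
    r1 <- runif(1, 2, 8)
    r2 <- r1 + runif(1, 0, 8)
    n1 <- neighbor_sets(rs, radius = r1)
    n2 <- neighbor_sets(rs, radius = r2)
    for (i in seq_along(n1)) {
      expect_true(all(n1[[i]] %in% n2[[i]]))
    }
  }
})

test_that("perturbation vanishes on self-comparison and under global offsets", {
  set.seed(12)
  p <- random_points(12)
  paired <- pair_self(p)
  pot <- stats::setNames(rnorm(12, sd = 200), paired$holo$key)

  tab <- perturbation(paired, pot, pot)
  expect_equal(tab$e_perturb, rep(0, 12))
  expect_equal(tab$spatial_deviation, rep(0, 12))

  # apo = holo + c: EPDs are offset-invariant so e_perturb stays zero
  tab2 <- perturbation(paired, pot, pot + 137.5)
  expect_equal(tab2$e_perturb, rep(0, 12), tolerance = 1e-10)
  expect_equal(tab2$sum_holo - tab2$sum_apo, tab2$e_perturb)
})

test_that("perturbation equals the brute-force triple loop on random fixtures", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(6:30, 1)
    ph_pts <- random_points(n)
    pa_pts <- ph_pts + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
    rs_h <- make_residue_set(ph_pts)
    rs_a <- make_residue_set(pa_pts)
    paired <- pair_structures(rs_h, rs_a, 0L)
    ph <- stats::setNames(rnorm(n, sd = 150), rs_h$key)
    pa <- stats::setNames(rnorm(n, sd = 150), rs_a$key)
    r <- runif(1, 4, 10)

    tab <- perturbation(paired, ph, pa, neighbors = neighbor_sets(rs_h, radius = r))
    want <- oracle_perturbation(ph_pts, pa_pts, unname(ph), unname(pa), r)
    expect_equal(tab$sum_holo, want$sum_holo, tolerance = 1e-10)
    expect_equal(tab$sum_apo, want$sum_apo, tolerance = 1e-10)
    expect_equal(tab$e_perturb, want$e_perturb, tolerance = 1e-10)
    expect_equal(tab$spatial_deviation, want$spatial, tolerance = 1e-10)
    expect_equal(tab$neighbor_count, want$n_neighbors)
  }
})

test_that("zero-neighbor residues carry zero perturbation and a flag", {
  pts <- rbind(c(0, 0, 0), c(100, 0, 0), c(103, 0, 0))
  paired <- pair_self(pts)
  pot <- stats::setNames(c(10, 20, 30), paired$holo$key)
  tab <- perturbation(paired, pot, pot + c(5, 0, 0),
                      neighbors = neighbor_sets(paired$holo, radius = 6))
  expect_equal(tab$flag[1], "no_neighbors")
  expect_equal(tab$e_perturb[1], 0)
  expect_equal(tab$neighbor_count[1], 0L)
})

test_that("polar-only mode excludes non-polar residues as centers and members", {
  pts <- cbind(5 * (0:5), 0, 0)
  types <- c("ASP", "ALA", "LYS", "LEU", "GLU", "SER")
  rs <- make_residue_set(pts, types)
  paired <- pair_structures(rs, rs, 0L)
  ph <- stats::setNames(c(100, -50, 30, 80, -10, 60), rs$key)
  pa <- stats::setNames(c(0, 25, -40, 15, 90, -75), rs$key)
  tab <- perturbation(paired, ph, pa, polar_only = TRUE,
                      neighbors = neighbor_sets(rs, radius = 6))
  expect_equal(tab$flag[tab$resid %in% c("ALA", "LEU")], c("nonpolar", "nonpolar"))
  expect_true(all(is.na(tab$e_perturb[tab$resid %in% c("ALA", "LEU")])))
  # ASP1's only eligible neighbor set drops the adjacent ALA: no members left
  expect_equal(tab$neighbor_count[1], 0L)
  # LYS3 keeps no polar residues within 6 A either side (ALA2, LEU4 dropped)
  expect_equal(tab$neighbor_count[3], 0L)
})

test_that("residues without potentials are dropped symmetrically", {
  pts <- cbind(5 * (0:4), 0, 0)
  paired <- pair_self(pts)
  ph <- stats::setNames(c(10, 20, NA, 40, 50), paired$holo$key)
  pa <- stats::setNames(c(11, 22, 33, 44, 55), paired$apo$key)
  expect_warning(
    tab <- perturbation(paired, ph, pa,
                        neighbors = neighbor_sets(paired$holo, radius = 6)),
    "dropped"
  )
  expect_equal(tab$flag[3], "no_potential")
  # residues 2 and 4 lose their missing neighbor in both sums
  expect_equal(tab$neighbor_count, c(1L, 1L, NA_integer_, 1L, 1L))
  expect_equal(tab$sum_holo[2], (20 - 10))
  expect_equal(tab$sum_apo[2], (22 - 11))
})

test_that("polarity reversals apply the sign + magnitude filter with pd1 > 0", {
  # direct constructor semantics
  rv <- reversal_set(c("a", "b"), c("x", "y"),
                     pd1 = c(435.8, 100), pd2 = c(-18.2, 40), threshold = 150)
  expect_equal(nrow(rv), 1L) # second pair has no sign change
  expect_equal(rv$delta_pd, 454.0)

  # orientation is normalized so pd1 > 0
  rv2 <- reversal_set("a", "x", pd1 = -200, pd2 = 30, threshold = 150)
  expect_equal(rv2$residue_a, "x")
  expect_equal(rv2$pd1, 200)
  expect_equal(rv2$pd2, -30)

  # boundary: |delta| exactly at the threshold is retained
  rv3 <- reversal_set("a", "x", pd1 = 100, pd2 = -50, threshold = 150)
  expect_equal(nrow(rv3), 1L)

  set.seed(17)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    pts <- random_points(n)
    paired <- pair_self(pts)
    ph <- stats::setNames(rnorm(n, sd = 150), paired$holo$key)
    pa <- stats::setNames(rnorm(n, sd = 150), paired$apo$key)
    thr <- runif(1, 50, 250)
    got <- polarity_reversals(paired, ph, pa, threshold = thr)
    want <- oracle_reversals(paired$holo$label, unname(ph), unname(pa), thr)
    key <- function(d) sort(paste(d$residue_a, d$residue_b))
    expect_equal(key(got), key(want))
    ord <- match(paste(got$residue_a, got$residue_b),
                 paste(want$residue_a, want$residue_b))
    expect_equal(got$pd1, want$pd1[ord], tolerance = 1e-10)
    expect_equal(got$pd2, want$pd2[ord], tolerance = 1e-10)
    expect_equal(got$delta_pd, got$pd1 - got$pd2)
    expect_true(all(got$pd1 > 0 & got$pd1 * got$pd2 < 0))
  }
})

test_that("neighbor-scope reversals are a subset of all-pairs reversals", {
  set.seed(19)
  pts <- random_points(15)
  paired <- pair_self(pts)
  ph <- stats::setNames(rnorm(15, sd = 150), paired$holo$key)
  pa <- stats::setNames(rnorm(15, sd = 150), paired$apo$key)
  nb <- neighbor_sets(paired$holo, radius = 8)
  all_rv <- polarity_reversals(paired, ph, pa, threshold = 50)
  nb_rv <- polarity_reversals(paired, ph, pa, threshold = 50,
                              scope = "neighbors", neighbors = nb)
  expect_true(all(
    paste(nb_rv$residue_a, nb_rv$residue_b) %in%
      paste(all_rv$residue_a, all_rv$residue_b)
  ))
})

test_that("radius sweep reports per-radius tables and rank stability", {
  pts <- cbind(5 * (0:9), 0, 0)
  paired <- pair_self(pts)
  pot <- stats::setNames(rnorm(10, sd = 100), paired$holo$key)

  # identical structures/potentials: all-zero tables, correlation undefined
  sw0 <- radius_sweep(paired, pot, pot, radii = c(5, 6, 7))
  expect_true(all(vapply(sw0$tables, function(t) all(t$e_perturb == 0), TRUE)))
  expect_true(all(is.na(sw0$stability$spearman)))

  # single radius: one table, empty stability summary
  sw1 <- radius_sweep(paired, pot, pot + rnorm(10), radii = 6)
  expect_length(sw1$tables, 1L)
  expect_equal(nrow(sw1$stability), 0L)

  # per-radius tables equal the brute-force oracle at each radius
  set.seed(23)
  pa <- pot + rnorm(10, sd = 20)
  sw <- radius_sweep(paired, pot, pa, radii = c(5, 6, 7, 8))
  for (k in seq_along(sw$radii)) {
    want <- oracle_perturbation(pts, pts, unname(pot), unname(pa), sw$radii[k])
    expect_equal(sw$tables[[k]]$e_perturb, want$e_perturb, tolerance = 1e-10)
  }
})
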