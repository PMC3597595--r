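# PQR/DX parsing, trilinear interpolation and the screened-Coulomb backend

test_that("read_pqr parses both PDB2PQR dialects", {
  at <- read_pqr(tiny_pqr())
  expect_equal(nrow(at), 3L)
  expect_equal(at$charge, c(0.5, -0.2, 1.0))
  expect_equal(at$radius, c(1.5, 1.2, 1.8))
  expect_equal(at$chain, rep("A", 3L))

  # chainless dialect: chain column absent -> blank chain
  chainless <- sub(" A ", " ", tiny_pqr(), fixed = TRUE)
  at2 <- read_pqr(chainless)
  expect_equal(at2$chain, rep("", 3L))
  expect_equal(at2$charge, at$charge)

  bad <- c(tiny_pqr(), "ATOM      4  CA  ALA A    4    garbage")
  expect_error(read_pqr(bad), "line 5")
})

test_that("read_dx round-trips grids and validates counts", {
  g <- potential_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), 0:7)
  expect_equal(read_dx(write_dx(g))$values, as.numeric(0:7))

  g2 <- potential_grid(c(-3.5, 2, 0), c(0.5, 1, 2), c(3, 4, 5),
                       sin(seq_len(60)))
  rt <- read_dx(write_dx(g2))
  expect_equal(rt$origin, g2$origin)
  expect_equal(rt$spacing, g2$spacing)
  expect_equal(rt$values, g2$values, tolerance = 1e-6)

  expect_error(potential_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), 0:6),
               "does not match")
  txt <- write_dx(g)
  txt[2] <- "object 1 class gridpositions counts 2 2 3"
  expect_error(read_dx(txt), "does not match")
})

test_that("trilinear interpolation is exact on nodes, edges and affine fields", {
  g <- potential_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                      c(1, 3, 5, 7, 2, 4, 6, 8)) # z fastest
  # node identity: value at origin node is first stored value
  expect_equal(interpolate_grid(g, c(0, 0, 0)), 1)
  expect_equal(interpolate_grid(g, c(1, 1, 1)), 8)
  # midpoint of the z edge at (0,0): nodes 1 and 3 -> 2
  expect_equal(interpolate_grid(g, c(0, 0, 0.5)), 2)

  # affine fields are reproduced exactly at random interior points
  co <- c(2, 1.5, -0.75, 0.25)
  aff <- function(p) co[1] + p %*% co[2:4]
  nodes <- expand.grid(x = 0:5, y = 0:5, z = 0:5)[, c("x", "y", "z")]
  nodes <- nodes[order(nodes$x, nodes$y, nodes$z), ]
  ga <- potential_grid(c(0, 0, 0), c(1, 1, 1), c(6, 6, 6),
                       as.numeric(aff(as.matrix(nodes))))
  set.seed(7)
  pts <- random_points(50, scale = 5)
  expect_equal(interpolate_grid(ga, pts), as.numeric(aff(pts)),
               tolerance = 1e-9)

  # upper boundary face is inside (closed box); beyond it errors
  expect_equal(interpolate_grid(ga, c(5, 5, 5)), as.numeric(aff(t(c(5, 5, 5)))))
  expect_error(interpolate_grid(ga, c(5.01, 0, 0)), "outside")
})

test_that("interpolation stays within the bounds of the surrounding nodes", {
  set.seed(11)
  vals <- rnorm(27)
  g <- potential_grid(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3), vals)
  for (rep in 1:50) {
    p <- runif(3, 0, 2)
    v <- interpolate_grid(g, p)
    i0 <- pmin(floor(p), 1)
    corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    nodeval <- apply(corners, 1L, function(cn) {
      ix <- i0 + cn
      vals[(ix[1] * 3 + ix[2]) * 3 + ix[3] + 1]
    })
    expect_gte(v, min(nodeval) - 1e-12)
    expect_lte(v, max(nodeval) + 1e-12)
  }
})

test_that("screened-Coulomb potential matches its closed form and oracle", {
  one <- read_pqr(c("ATOM      1  CA  ALA A    1    0.0    0.0    0.0  1.0000 1.5000"))
  # q = +1 e, dielectric 1, kappa 0, r = 561 A -> exactly 1 kT/e
  expect_equal(coulomb_potential(one, c(561, 0, 0), dielectric = 1, kappa = 0), 1.0)

  # symmetry: midpoint of +1/-1 charges is exactly zero
  pm <- read_pqr(c(
    "ATOM      1  CA  ALA A    1   -2.0    0.0    0.0  1.0000 1.5000",
    "ATOM      2  CA  GLY A    2    2.0    0.0    0.0 -1.0000 1.5000"
  ))
  expect_equal(coulomb_potential(pm, c(0, 5, -3)), 0)

  # random configurations against the brute-force double loop
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    at <- data.frame(
      atom = "CA", resid = "ALA", chain = "A", resno = seq_len(n), ins = "",
      x = runif(n, -10, 10), y = runif(n, -10, 10), z = runif(n, -10, 10),
      charge = runif(n, -1, 1), radius = 1.5, stringsAsFactors = FALSE
    )
    class(at) <- c("charged_atoms", "data.frame")
    pts <- random_points(5, scale = 10)
    eps <- sample(c(2, 20, 80), 1)
    kap <- runif(1, 0, 0.3)
    expect_equal(
      coulomb_potential(at, pts, dielectric = eps, kappa = kap),
      oracle_coulomb(at, pts, eps, kap),
      tolerance = 1e-10
    )
    # linearity in charges: superposed charge sets add pointwise
    at2 <- at
    at2$charge <- runif(n, -1, 1)
    at12 <- at
    at12$charge <- at$charge + at2$charge
    expect_equal(
      coulomb_potential(at12, pts, dielectric = eps, kappa = kap),
      coulomb_potential(at, pts, dielectric = eps, kappa = kap) +
        coulomb_potential(at2, pts, dielectric = eps, kappa = kap),
      tolerance = 1e-10
    )
  }
})

test_that("residue_potentials evaluates at reactive atoms with self-exclusion", {
  st <- read_structure(tiny_pdb())
  res <- resolve_reactive_atoms(st)

  # constant grid: every residue gets c
  g <- potential_grid(c(-5, -5, -5), c(25, 25, 25), c(2, 2, 2), rep(4.25, 8))
  pc <- residue_potentials(potential_field(g), res)
  expect_equal(unname(pc), rep(4.25, 4L))
  expect_named(pc, res$key)

  # coulomb backend: hand-computed sums exclude the residue's own reactive atom
  pqr_lines <- c(
    "ATOM      1  OG  SER A    1    1.500    2.200    0.300  0.5000 1.5000",
    "ATOM      2  CA  GLY A    2    5.000    1.000    0.000 -0.3000 1.5000",
    "ATOM      3  NE2 HIS A    3    9.900    3.600    1.000  0.8000 1.5000",
    "ATOM      4  CB  ALA A    4   13.400    2.300    0.500  0.1000 1.5000"
  )
  fld <- potential_field(read_pqr(pqr_lines), dielectric = 80, kappa = 0)
  pot <- residue_potentials(fld, res)
  at <- read_pqr(pqr_lines)
  for (i in 1:4) {
    expected <- oracle_coulomb(at[-i, ], t(c(res$x[i], res$y[i], res$z[i])), 80, 0)
    expect_equal(unname(pot[i]), expected, tolerance = 1e-10)
  }

  # reactive atom outside a small grid -> NA with warning
  gsmall <- potential_grid(c(0, 0, 0), c(3, 3, 3), c(2, 2, 2), 1:8)
  expect_warning(p2 <- residue_potentials(potential_field(gsmall), res),
                 "outside")
  expect_true(anyNA(p2))
})
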