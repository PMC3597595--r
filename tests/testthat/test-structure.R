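# PDB parsing, reactive-atom resolution and holo/apo pairing

test_that("read_structure keeps protein residues in file order and drops HETATM", {
  st <- read_structure(tiny_pdb())
  res <- resolve_reactive_atoms(st)
  expect_equal(nrow(res), 4L)
  expect_equal(res$resid, c("SER", "GLY", "HIS", "ALA"))
  expect_false("ZN" %in% st$atoms$resid)
  expect_equal(unique(st$atoms$chain), "A")
})

test_that("altloc records resolve to highest occupancy, ties alphabetical", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA  GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  st <- read_structure(pdb)
  cb <- st$atoms[st$atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 1.0) # occupancy 0.6 conformer wins

  # equal occupancy: altloc A preferred
  pdb_tie <- sub("0.60", "0.40", pdb, fixed = TRUE)
  st2 <- read_structure(pdb_tie)
  expect_equal(st2$atoms$x[st2$atoms$atom == "CB"], 1.0)
})

test_that("model selection and chain filter work; bad input errors", {
  one <- "ATOM      1  CA  ALA %s   1    %8.3f   0.000   0.000  1.00  0.00           C"
  multi <- c(
    "MODEL        1", sprintf(one, "A", 1.0), "ENDMDL",
    "MODEL        2", sprintf(one, "A", 9.0), "ENDMDL"
  )
  expect_equal(read_structure(multi, model = 2)$atoms$x, 9.0)
  expect_error(read_structure(multi, model = 3), "model 3")

  two_chain <- c(sprintf(one, "A", 1.0), sub(" 1 ", " 2 ", sprintf(one, "B", 2.0)))
  stA <- read_structure(two_chain, chains = "A")
  expect_equal(unique(stA$atoms$chain), "A")
  expect_error(read_structure(two_chain, chains = "Z"), "empty selection")
  expect_error(read_structure("ATOM  garbage line"), "unparseable|no ATOM")
})

test_that("non-standard residues are excluded with a warning", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  MSE A   2       3.000   0.000   0.000  1.00  0.00           C"
  )
  expect_warning(st <- read_structure(pdb), "MSE")
  expect_equal(unique(st$atoms$resid), "ALA")
})

test_that("reactive atoms resolve by preference list with CB/CA fallback", {
  res <- resolve_reactive_atoms(read_structure(tiny_pdb()))
  expect_equal(res$atom, c("OG", "CA", "NE2", "CB"))

  # truncated HIS side chain falls back to CB
  pdb <- tiny_pdb()
  pdb <- pdb[!grepl("NE2", pdb)]
  res2 <- resolve_reactive_atoms(read_structure(pdb))
  expect_equal(res2$atom[res2$resid == "HIS"], "CB")

  # resolution is idempotent: re-resolving the same structure is stable
  res3 <- resolve_reactive_atoms(read_structure(tiny_pdb()))
  expect_identical(res, res3)
})

test_that("missing-atom error names the residue; map file overrides defaults", {
  pdb <- c(
    "ATOM      1  N   SER A   1       0.000   1.000   0.000  1.00  0.00           N"
  )
  expect_error(resolve_reactive_atoms(read_structure(pdb)), "SER A1")

  f <- tempfile()
  writeLines(c("# custom", "SER CB CA", "HIS ND1 CB CA"), f)
  map <- read_reactive_atom_map(f)
  expect_equal(map$SER, c("CB", "CA"))
  res <- resolve_reactive_atoms(read_structure(tiny_pdb()), map)
  expect_equal(res$atom[res$resid == "SER"], "CA") # fixture SER has no CB
})

test_that("pairing is identity-keyed, tolerates mutations, rejects indels", {
  st <- resolve_reactive_atoms(read_structure(tiny_pdb()))
  p <- pair_structures(st, st, max_mutations = 0L)
  expect_equal(p$n, 4L)
  expect_length(p$mutations, 0L)

  mut <- st
  mut$resid[4] <- "VAL" # ALA4 -> VAL4
  expect_error(pair_structures(st, mut, max_mutations = 0L), "max_mutations")
  p2 <- pair_structures(st, mut, max_mutations = 1L)
  expect_equal(p2$mutations, "A:4")

  indel <- st[-2, ]
  class(indel) <- class(st)
  expect_error(pair_structures(st, indel, max_mutations = 5L), "insertion/deletion")
})

test_that("pairing is independent of residue input order", {
  set.seed(42)
  rs <- make_residue_set(random_points(12))
  shuffled <- rs[sample(nrow(rs)), ]
  class(shuffled) <- class(rs)
  p1 <- pair_structures(rs, rs, 0L)
  p2 <- pair_structures(shuffled, rs, 0L)
  expect_identical(p1$holo$key, p2$holo$key)
  expect_identical(p1$apo$key, p2$apo$key)
})
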