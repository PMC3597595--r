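# Reactive-atom resolution: each residue's potential is read at a single
# functionally representative atom (the CLASP-style "reactive atom").

.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.POLAR_AA <- c(
  "ASP", "GLU", "LYS", "ARG", "HIS", "SER", "THR", "ASN", "GLN", "TYR",
  "CYS", "TRP"
)

#' Default reactive-atom preference map
#'
#' Maps each standard residue type to an ordered preference list of atom
#' names. The first atom present in a residue is taken as its reactive atom;
#' every list falls back through CB to CA so that truncated side chains still
#' resolve. The chosen heads are the side-chain functional atoms (SER:OG,
#' HIS:NE2, LYS:NZ, ...); purely hydrophobic residues anchor at CB, glycine
#' at CA.
#'
#' @return A named list: 3-letter residue code -> character vector of atom
#'   names in decreasing preference, ending in "CA".
#' @seealso [read_reactive_atom_map()] to load a user override from file,
#'   [resolve_reactive_atoms()] to apply a map to a structure.
#' @export
#' @examples
#' reactive_atom_map()[["SER"]]
reactive_atom_map <- function() {
  heads <- c(
    SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
    ASP = "OD1", GLU = "OE1", ASN = "OD1", GLN = "OE1",
    HIS = "NE2", LYS = "NZ", ARG = "CZ", TRP = "NE1", MET = "SD"
  )
  m <- list()
  for (aa in .STANDARD_AA) {
    if (aa == "GLY") {
      m[[aa]] <- "CA"
    } else if (aa %in% names(heads)) {
      m[[aa]] <- unique(c(heads[[aa]], "CB", "CA"))
    } else {
      m[[aa]] <- c("CB", "CA") # ALA VAL LEU ILE PHE PRO
    }
  }
  m
}

#' Read a reactive-atom map from a plain-text file
#'
#' File format: one residue per line, whitespace separated —
#' `RES ATOM1 ATOM2 ...`. Lines starting with `#` are ignored. Entries
#' replace the defaults for the named residue types; unlisted types keep the
#' default preference list. A terminal "CA" fallback is appended when absent
#' so resolution stays total.
#'
#' @param path Path to the map file.
#' @return A named list in the same shape as [reactive_atom_map()].
#' @export
read_reactive_atom_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- reactive_atom_map()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2) {
      stop("malformed reactive-atom map line: ", sQuote(ln), call. = FALSE)
    }
    aa <- toupper(parts[1])
    prefs <- toupper(parts[-1])
    if (!"CA" %in% prefs) prefs <- c(prefs, "CA")
    m[[aa]] <- unique(prefs)
  }
  m
}

#' Resolve reactive atoms for every residue of a structure
#'
#' Walks each residue's preference list (from `map`) and picks the first atom
#' present. Residues for which not even the terminal fallback is present
#' raise an error naming the residue.
#'
#' @param structure A `protein_structure` from [read_structure()].
#' @param map A reactive-atom map, default [reactive_atom_map()].
#' @return A `residue_set`: data frame with one row per residue, columns
#'   `chain`, `resno`, `ins`, `resid`, `atom` (reactive atom name),
#'   `x`, `y`, `z` (its coordinates, Angstrom), `key` (internal residue id)
#'   and `label` (e.g. `"HIS106"`).
#' @export
resolve_reactive_atoms <- function(structure, map = reactive_atom_map()) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  key <- res_key(at$chain, at$resno, at$ins)
  ord <- !duplicated(key)
  res <- data.frame(
    chain = at$chain[ord], resno = at$resno[ord], ins = at$ins[ord],
    resid = at$resid[ord], stringsAsFactors = FALSE
  )
  res$key <- res_key(res$chain, res$resno, res$ins)
  idx_by_res <- split(seq_len(nrow(at)), factor(key, levels = res$key))

  pick <- function(i) {
    rows <- idx_by_res[[res$key[i]]]
    prefs <- map[[res$resid[i]]]
    if (is.null(prefs)) prefs <- c("CB", "CA")
    names_here <- at$atom[rows]
    for (p in prefs) {
      j <- rows[names_here == p]
      if (length(j)) return(j[1])
    }
    stop(
      "no reactive atom resolvable for residue ", res$resid[i], " ",
      res$chain[i], res$resno[i],
      " (looked for ", paste(prefs, collapse = ", "), ")",
      call. = FALSE
    )
  }
  j <- vapply(seq_len(nrow(res)), pick, integer(1))
  res$atom <- at$atom[j]
  res$x <- at$x[j]
  res$y <- at$y[j]
  res$z <- at$z[j]

  # CA coordinates kept alongside for the CA-CA neighbor metric
  ca <- vapply(seq_len(nrow(res)), function(i) {
    rows <- idx_by_res[[res$key[i]]]
    k <- rows[at$atom[rows] == "CA"]
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  res$ca_x <- at$x[ca]
  res$ca_y <- at$y[ca]
  res$ca_z <- at$z[ca]

  res$label <- paste0(res$resid, res$resno, ifelse(res$ins == "", "", res$ins))
  class(res) <- c("residue_set", "data.frame")
  res
}

# canonical residue identifier: chain + author number + insertion code
res_key <- function(chain, resno, ins) {
  sprintf("%s:%d%s", chain, resno, ins)
}

#' Polar residue types used by the polar-only analysis mode
#'
#' @return Character vector of 3-letter codes.
#' @export
polar_residues <- function() .POLAR_AA
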