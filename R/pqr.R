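# PQR reader (PDB2PQR output). PQR is whitespace-delimited PDB-like text
# whose last two columns are per-atom charge (e) and radius (Angstrom).
# Both PDB2PQR dialects are handled: with and without the chain-ID column.

#' Read a PQR file
#'
#' Parses ATOM (and HETATM) records of a whitespace-delimited PQR file into
#' a charged atom set. The chain-ID column is optional (PDB2PQR's
#' `--whitespace` output omits it for single-chain proteins); when absent
#' the chain is set to blank.
#'
#' @param source Path to a PQR file, or a character vector of PQR lines.
#' @return A `charged_atoms` data frame: `atom`, `resid`, `chain`, `resno`,
#'   `ins`, `x`, `y`, `z` (Angstrom), `charge` (e), `radius` (Angstrom).
#' @export
read_pqr <- function(source) {
  lines <- read_text_source(source)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  atom_lines <- lines[is_atom]
  lineno <- which(is_atom)
  if (!length(atom_lines)) stop("no ATOM records in PQR input", call. = FALSE)

  parse_one <- function(i) {
    f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    # ATOM serial name resname [chain] resno[ins] x y z charge radius
    if (length(f) == 11L) {
      chain <- f[5]; rest <- f[6:11]
    } else if (length(f) == 10L) {
      chain <- ""; rest <- f[5:10]
    } else {
      stop(
        "malformed PQR record at line ", lineno[i], ": ", sQuote(atom_lines[i]),
        call. = FALSE
      )
    }
    resfield <- rest[1]
    ins <- ""
    if (grepl("^-?[0-9]+$", resfield)) {
      resno <- as.integer(resfield)
    } else if (grepl("^-?[0-9]+[A-Za-z]$", resfield)) {
      resno <- as.integer(sub("[A-Za-z]$", "", resfield))
      ins <- toupper(sub("^-?[0-9]+", "", resfield))
    } else {
      stop(
        "malformed residue number at line ", lineno[i], ": ", sQuote(atom_lines[i]),
        call. = FALSE
      )
    }
    vals <- suppressWarnings(as.numeric(rest[2:6]))
    if (anyNA(vals)) {
      stop(
        "missing/invalid coordinate, charge or radius at line ", lineno[i],
        ": ", sQuote(atom_lines[i]),
        call. = FALSE
      )
    }
    list(
      atom = f[3], resid = toupper(f[4]), chain = chain,
      resno = resno, ins = ins,
      x = vals[1], y = vals[2], z = vals[3], charge = vals[4], radius = vals[5]
    )
  }

  rows <- lapply(seq_along(atom_lines), parse_one)
  at <- data.frame(
    atom = vapply(rows, `[[`, "", "atom"),
    resid = vapply(rows, `[[`, "", "resid"),
    chain = vapply(rows, `[[`, "", "chain"),
    resno = vapply(rows, `[[`, 0L, "resno"),
    ins = vapply(rows, `[[`, "", "ins"),
    x = vapply(rows, `[[`, 0, "x"),
    y = vapply(rows, `[[`, 0, "y"),
    z = vapply(rows, `[[`, 0, "z"),
    charge = vapply(rows, `[[`, 0, "charge"),
    radius = vapply(rows, `[[`, 0, "radius"),
    stringsAsFactors = FALSE
  )
  if (any(at$radius < 0)) stop("negative atomic radius in PQR input", call. = FALSE)
  class(at) <- c("charged_atoms", "data.frame")
  at
}
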