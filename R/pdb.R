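# Minimal fixed-column PDB reader. Only the fields the analysis needs are
# kept; HETATM records, waters and non-standard residues are excluded.
# No installed R package in this stack parses PDB, so the (well-specified,
# fixed-width) record layout is read directly.

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from PDB text
#'
#' Parses ATOM records of one MODEL of a PDB file. HETATM records (ligands,
#' ions, waters) are dropped, as are ATOM records of non-standard residues
#' (with a warning naming them). Alternate locations are resolved to the
#' highest-occupancy conformer; ties go to the alphabetically first altloc.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines
#'   (anything of length > 1, or containing a newline, is treated as text).
#' @param model 1-based index of the MODEL block to read; files without
#'   MODEL records are treated as a single model. Default 1.
#' @param chains Optional character vector restricting the chains kept.
#' @return A `protein_structure`: list with `atoms` (data frame: `atom`,
#'   `altloc`, `resid`, `chain`, `resno`, `ins`, `x`, `y`, `z`, `occ`) and
#'   `source` (the path, or `NA` for in-memory text).
#' @export
read_structure <- function(source, model = 1L, chains = NULL) {
  lines <- read_text_source(source)
  src <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    source
  } else {
    NA_character_
  }

  lines <- select_model(lines, model)
  rec <- substr(lines, 1, 6)
  atom_lines <- lines[trimws(rec) == "ATOM"]
  if (!length(atom_lines)) {
    stop("no ATOM records found for model ", model, call. = FALSE)
  }

  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  at <- data.frame(
    atom   = trimws(substr(atom_lines, 13, 16)),
    altloc = substr(atom_lines, 17, 17),
    resid  = toupper(trimws(substr(atom_lines, 18, 20))),
    chain  = substr(atom_lines, 22, 22),
    resno  = suppressWarnings(as.integer(trimws(substr(atom_lines, 23, 26)))),
    ins    = trimws(substr(atom_lines, 27, 27)),
    x      = num(substr(atom_lines, 31, 38)),
    y      = num(substr(atom_lines, 39, 46)),
    z      = num(substr(atom_lines, 47, 54)),
    occ    = num(substr(atom_lines, 55, 60)),
    stringsAsFactors = FALSE
  )
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z) || anyNA(at$resno)) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z) | is.na(at$resno))[1]
    stop("unparseable ATOM record: ", sQuote(atom_lines[bad]), call. = FALSE)
  }
  at$occ[is.na(at$occ)] <- 1

  if (!is.null(chains)) {
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  at <- at[!(at$resid %in% .WATER_NAMES), , drop = FALSE]

  nonstd <- unique(at$resid[!(at$resid %in% .STANDARD_AA)])
  if (length(nonstd)) {
    warning(
      "excluding non-standard residue type(s): ",
      paste(nonstd, collapse = ", "),
      call. = FALSE
    )
    at <- at[at$resid %in% .STANDARD_AA, , drop = FALSE]
  }
  if (!nrow(at)) {
    stop("empty selection: no standard protein residues left", call. = FALSE)
  }

  at <- resolve_altlocs(at)
  rownames(at) <- NULL
  structure(
    list(atoms = at, source = src),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  nres <- length(unique(res_key(x$atoms$chain, x$atoms$resno, x$atoms$ins)))
  cat(
    "<protein_structure> ", nrow(x$atoms), " atoms, ", nres, " residues, chains: ",
    paste(sort(unique(x$atoms$chain)), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

read_text_source <- function(source) {
  if (!is.character(source)) {
    stop("source must be a file path or character vector of lines", call. = FALSE)
  }
  if (length(source) > 1L || grepl("\n", source[1])) {
    return(unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE))
  }
  if (file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  # a single string that is clearly a record line counts as in-memory text
  if (grepl("^(ATOM|HETATM|REMARK|HEADER|MODEL|object|origin|delta|#)", source)) {
    return(source)
  }
  stop("file not found: ", source, call. = FALSE)
}

select_model <- function(lines, model) {
  starts <- grep("^MODEL ", lines)
  if (!length(starts)) {
    if (model > 1L) stop("model ", model, " not present (single-model file)", call. = FALSE)
    return(lines)
  }
  if (model > length(starts)) {
    stop("model ", model, " not present (file has ", length(starts), ")", call. = FALSE)
  }
  ends <- grep("^ENDMDL", lines)
  from <- starts[model]
  to <- ends[ends > from]
  to <- if (length(to)) to[1] else length(lines)
  lines[from:to]
}

# keep one conformer per (chain, resno, ins, atom name): highest occupancy,
# ties broken by the alphabetically first altloc
resolve_altlocs <- function(at) {
  id <- paste(at$chain, at$resno, at$ins, at$atom, sep = "\r")
  if (!anyDuplicated(id)) return(at)
  keep <- vapply(
    split(seq_len(nrow(at)), factor(id, levels = unique(id))),
    function(rows) rows[order(-at$occ[rows], at$altloc[rows])[1]],
    integer(1)
  )
  at[sort(keep), , drop = FALSE]
}
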