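# Holo/apo residue correspondence. Residues pair by author identity
# (chain, number, insertion code); point mutations are tolerated up to a
# limit, insertions/deletions are not.

#' Pair holo and apo residues
#'
#' Establishes a one-to-one correspondence between the residues of the holo
#' and apo forms, keyed by chain, author residue number and insertion code.
#' Any residue present in only one structure is treated as an
#' insertion/deletion and raises an error — the method compares like with
#' like and never realigns. Residue-type mismatches at paired positions are
#' recorded as point mutations and allowed up to `max_mutations`.
#'
#' @param holo,apo `residue_set` data frames from [resolve_reactive_atoms()].
#' @param max_mutations Maximum number of residue-type mismatches tolerated
#'   (default 5, enough for the usual single/double mutant comparisons).
#' @return A `paired_structures`: list with `holo` and `apo` residue sets
#'   (reordered to the common key order), `mutations` (character vector of
#'   keys where the type differs) and `n` (number of pairs).
#' @export
pair_structures <- function(holo, apo, max_mutations = 5L) {
  stopifnot(inherits(holo, "residue_set"), inherits(apo, "residue_set"))
  if (!nrow(holo) || !nrow(apo)) stop("empty residue set", call. = FALSE)

  only_h <- setdiff(holo$key, apo$key)
  only_a <- setdiff(apo$key, holo$key)
  if (length(only_h) || length(only_a)) {
    stop(
      "insertion/deletion detected: residues without a partner (",
      "holo-only: ", if (length(only_h)) paste(only_h, collapse = ", ") else "none",
      "; apo-only: ", if (length(only_a)) paste(only_a, collapse = ", ") else "none",
      ")",
      call. = FALSE
    )
  }

  # canonical order so that the pairing is independent of input row order
  ord <- order(holo$chain, holo$resno, holo$ins)
  h <- holo[ord, , drop = FALSE]
  a <- apo[match(h$key, apo$key), , drop = FALSE]
  rownames(h) <- rownames(a) <- NULL

  mutations <- h$key[h$resid != a$resid]
  if (length(mutations) > max_mutations) {
    stop(
      length(mutations), " residue-type mismatches exceed max_mutations = ",
      max_mutations, " (", paste(mutations, collapse = ", "), ")",
      call. = FALSE
    )
  }

  structure(
    list(holo = h, apo = a, mutations = mutations, n = nrow(h)),
    class = "paired_structures"
  )
}

#' @export
print.paired_structures <- function(x, ...) {
  cat(
    "<paired_structures> ", x$n, " residue pairs, ",
    length(x$mutations), " mutation(s)",
    if (length(x$mutations)) paste0(" at ", paste(x$mutations, collapse = ", ")),
    "\n",
    sep = ""
  )
  invisible(x)
}
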