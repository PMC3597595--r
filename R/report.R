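# Result serialization: tab-separated tables mirroring the canonical
# polarity-reversal layout (a, b, PD1, PD2, deltaPD) and deterministic PyMOL
# coloring scripts.

#' PyMOL color scheme for perturbation visualization
#'
#' @param positive Color for residues with perturbation above `+threshold`
#'   (default `"red"`).
#' @param negative Color for residues below `-threshold` (default `"blue"`;
#'   used only in signed mode).
#' @param base Color applied to the whole structure first (default
#'   `"gray80"`).
#' @param highlight Optional named character vector of extra per-residue
#'   colors keyed by residue label (e.g. `c(MET10 = "yellow")`); these are
#'   applied last and override the threshold coloring.
#' @return A `color_scheme` list.
#' @export
color_scheme <- function(positive = "red", negative = "blue",
                         base = "gray80", highlight = character(0)) {
  ok <- grepl("^[a-z]+[0-9]*$", c(positive, negative, base, unname(highlight)))
  if (!all(ok)) stop("colors must be valid PyMOL color names", call. = FALSE)
  structure(
    list(positive = positive, negative = negative, base = base,
         highlight = highlight),
    class = "color_scheme"
  )
}

#' Write perturbation and reversal tables
#'
#' Writes the per-residue perturbation table and the polarity-reversal
#' table. The reversal table has exactly the columns `residue_a`,
#' `residue_b`, `PD1`, `PD2`, `deltaPD` with numbers formatted to one
#' decimal; the perturbation table carries residue identity plus the holo
#' and apo EPD sums, `e_perturb`, `spatial_deviation` and `neighbor_count`.
#'
#' @param perturbation A `perturbation_table`.
#' @param reversals A `reversal_set`.
#' @param dir Output directory (created if needed).
#' @param sep Field separator: `"\t"` (default) or `","` (CSV mode; file
#'   extensions switch accordingly).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_tables <- function(perturbation, reversals, dir, sep = "\t") {
  stopifnot(
    inherits(perturbation, "perturbation_table"),
    inherits(reversals, "reversal_set"),
    sep %in% c("\t", ",")
  )
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (sep == "\t") "tsv" else "csv"
  f_pert <- file.path(dir, paste0("perturbation.", ext))
  f_rev <- file.path(dir, paste0("reversals.", ext))

  fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  pt <- data.frame(
    chain = perturbation$chain,
    residue = perturbation$label,
    sum_holo = fmt1(perturbation$sum_holo),
    sum_apo = fmt1(perturbation$sum_apo),
    e_perturb = fmt1(perturbation$e_perturb),
    spatial_deviation = fmt1(perturbation$spatial_deviation),
    neighbor_count = perturbation$neighbor_count,
    flag = perturbation$flag,
    stringsAsFactors = FALSE
  )
  utils::write.table(pt, f_pert, sep = sep, quote = FALSE, row.names = FALSE)

  rv <- data.frame(
    residue_a = reversals$residue_a,
    residue_b = reversals$residue_b,
    PD1 = fmt1(reversals$pd1),
    PD2 = fmt1(reversals$pd2),
    deltaPD = fmt1(reversals$delta_pd),
    stringsAsFactors = FALSE
  )
  utils::write.table(rv, f_rev, sep = sep, quote = FALSE, row.names = FALSE)

  invisible(c(perturbation = f_pert, reversals = f_rev))
}

#' Read back a reversal table written by [write_tables()]
#'
#' @param path Path to the TSV/CSV file.
#' @param sep Field separator used when writing.
#' @return A `reversal_set` data frame.
#' @export
read_reversal_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  out <- data.frame(
    residue_a = as.character(df$residue_a),
    residue_b = as.character(df$residue_b),
    pd1 = as.numeric(df$PD1), pd2 = as.numeric(df$PD2),
    delta_pd = as.numeric(df$deltaPD),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reversal_set", "data.frame")
  out
}

#' Generate a PyMOL script highlighting perturbed residues
#'
#' Emits open-source PyMOL command syntax that loads the holo structure,
#' shows it as cartoon in the base color, and colors every residue whose
#' `|e_perturb|` meets the threshold: a single color in unsigned mode, or
#' red/blue by perturbation sign in signed mode. Highlight residues from
#' the scheme are colored last. Output is deterministic — same inputs,
#' byte-identical script.
#'
#' @param pdb_path Path of the structure file the script should load.
#' @param perturbation A `perturbation_table`.
#' @param threshold Significance threshold on `|e_perturb|` in kT/e,
#'   default 200.
#' @param scheme A [color_scheme()].
#' @param signed Color by sign (`TRUE`, default) or single-color (`FALSE`).
#' @param file Optional path to write the script to.
#' @return Character vector of script lines (invisibly when `file` given).
#' @export
write_pymol_script <- function(pdb_path, perturbation, threshold = 200,
                               scheme = color_scheme(), signed = TRUE,
                               file = NULL) {
  stopifnot(inherits(perturbation, "perturbation_table"), threshold >= 0)
  pt <- perturbation[!is.na(perturbation$e_perturb), , drop = FALSE]
  pt <- pt[order(pt$chain, pt$resno, pt$ins), , drop = FALSE]

  sel <- function(rows) {
    # one selection term per chain: (chain A and resi 5+12+...)
    parts <- vapply(split(rows, rows$chain), function(g) {
      resi <- paste0(g$resno, ifelse(g$ins == "", "", g$ins))
      sprintf("(chain %s and resi %s)",
              ifelse(nzchar(g$chain[1]), g$chain[1], '""'),
              paste(resi, collapse = "+"))
    }, character(1))
    paste(parts, collapse = " or ")
  }

  lines <- c(
    sprintf("load %s, target", pdb_path),
    "hide everything",
    "show cartoon, target",
    sprintf("color %s, target", scheme$base)
  )

  pos <- pt[pt$e_perturb >= threshold, , drop = FALSE]
  neg <- pt[pt$e_perturb <= -threshold, , drop = FALSE]
  if (signed) {
    if (nrow(pos)) {
      lines <- c(lines,
                 sprintf("select perturbed_pos, %s", sel(pos)),
                 sprintf("color %s, perturbed_pos", scheme$positive),
                 "show sticks, perturbed_pos")
    }
    if (nrow(neg)) {
      lines <- c(lines,
                 sprintf("select perturbed_neg, %s", sel(neg)),
                 sprintf("color %s, perturbed_neg", scheme$negative),
                 "show sticks, perturbed_neg")
    }
  } else {
    both <- pt[abs(pt$e_perturb) >= threshold, , drop = FALSE]
    if (nrow(both)) {
      lines <- c(lines,
                 sprintf("select perturbed, %s", sel(both)),
                 sprintf("color %s, perturbed", scheme$positive),
                 "show sticks, perturbed")
    }
  }

  if (length(scheme$highlight)) {
    hl <- scheme$highlight[order(names(scheme$highlight))]
    for (lab in names(hl)) {
      rows <- pt[pt$label == lab, , drop = FALSE]
      if (!nrow(rows)) next
      lines <- c(lines,
                 sprintf("select hl_%s, %s", tolower(lab), sel(rows)),
                 sprintf("color %s, hl_%s", hl[[lab]], tolower(lab)),
                 sprintf("show sticks, hl_%s", tolower(lab)))
    }
  }

  lines <- c(lines, "deselect", "zoom target")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
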