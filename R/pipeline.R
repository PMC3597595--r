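# End-to-end orchestration: parse structures, build the potential fields,
# run the perturbation and polarity-reversal analyses and write artifacts
# (tables, PyMOL script, parameter log).

#' Configuration for a full holo/apo comparison run
#'
#' @param holo_pdb,apo_pdb Paths to the two structures (same protein; point
#'   mutations tolerated, insertions/deletions rejected).
#' @param backend `"dx"` (APBS OpenDX grids + PQR) or `"coulomb"`
#'   (screened-Coulomb fallback from PQR charges alone).
#' @param holo_dx,apo_dx DX grid paths (backend `"dx"`).
#' @param holo_pqr,apo_pqr PQR paths (required for backend `"coulomb"`; for
#'   backend `"dx"` the grid alone suffices since potentials are read at
#'   PDB reactive-atom coordinates).
#' @param radius Neighbor radius P_rad in Angstrom, default 6.
#' @param reversal_threshold Polarity-reversal threshold P_thresh in kT/e,
#'   default 150.
#' @param viz_threshold PyMOL significance threshold on |e_perturb| in
#'   kT/e, default 200.
#' @param polar_only Restrict analysis to polar residues, default `FALSE`.
#' @param reversal_scope `"all"` or `"neighbors"`, default `"all"`.
#' @param max_mutations Tolerated residue-type mismatches, default 5.
#' @param chains Optional chain filter.
#' @param model 1-based model index, default 1.
#' @param metric Neighbor distance metric, see [neighbor_sets()].
#' @param dielectric,kappa Coulomb-backend parameters (defaults 80, 0).
#' @param reactive_map Optional path to a reactive-atom map file.
#' @param signed_colors Signed (red/blue) PyMOL coloring, default `TRUE`.
#' @param csv Write CSV instead of TSV, default `FALSE`.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(holo_pdb, apo_pdb,
                       backend = c("coulomb", "dx"),
                       holo_dx = NULL, apo_dx = NULL,
                       holo_pqr = NULL, apo_pqr = NULL,
                       radius = 6, reversal_threshold = 150,
                       viz_threshold = 200, polar_only = FALSE,
                       reversal_scope = c("all", "neighbors"),
                       max_mutations = 5L, chains = NULL, model = 1L,
                       metric = c("reactive", "ca"),
                       dielectric = 80, kappa = 0,
                       reactive_map = NULL, signed_colors = TRUE,
                       csv = FALSE, out_dir = "eperturb_out") {
  backend <- match.arg(backend)
  reversal_scope <- match.arg(reversal_scope)
  metric <- match.arg(metric)
  stopifnot(radius > 0, reversal_threshold >= 0, viz_threshold >= 0)
  if (backend == "dx" && (is.null(holo_dx) || is.null(apo_dx))) {
    stop("backend \"dx\" requires holo_dx and apo_dx", call. = FALSE)
  }
  if (backend == "coulomb" && (is.null(holo_pqr) || is.null(apo_pqr))) {
    stop("backend \"coulomb\" requires holo_pqr and apo_pqr", call. = FALSE)
  }
  structure(
    list(
      holo_pdb = holo_pdb, apo_pdb = apo_pdb, backend = backend,
      holo_dx = holo_dx, apo_dx = apo_dx,
      holo_pqr = holo_pqr, apo_pqr = apo_pqr,
      radius = radius, reversal_threshold = reversal_threshold,
      viz_threshold = viz_threshold, polar_only = polar_only,
      reversal_scope = reversal_scope, max_mutations = max_mutations,
      chains = chains, model = model, metric = metric,
      dielectric = dielectric, kappa = kappa,
      reactive_map = reactive_map, signed_colors = signed_colors,
      csv = csv, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full holo/apo electrostatic perturbation analysis
#'
#' Reads and pairs the two structures, evaluates per-residue potentials with
#' the configured backend, computes the perturbation table, spatial
#' deviations and polarity reversals, and (optionally) writes the result
#' tables, a PyMOL script and a parameter log to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param write Write artifacts to `config$out_dir` (default `TRUE`).
#' @return Invisibly, a `run_result`: list with `paired`, `pot_holo`,
#'   `pot_apo`, `perturbation`, `reversals`, `files` (paths written, if
#'   any) and `config`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  map <- if (is.null(config$reactive_map)) {
    reactive_atom_map()
  } else {
    read_reactive_atom_map(config$reactive_map)
  }

  holo_st <- read_structure(config$holo_pdb, model = config$model,
                            chains = config$chains)
  apo_st <- read_structure(config$apo_pdb, model = config$model,
                           chains = config$chains)
  holo <- resolve_reactive_atoms(holo_st, map)
  apo <- resolve_reactive_atoms(apo_st, map)
  paired <- pair_structures(holo, apo, max_mutations = config$max_mutations)

  fields <- if (config$backend == "dx") {
    list(
      holo = potential_field(read_dx(config$holo_dx)),
      apo = potential_field(read_dx(config$apo_dx))
    )
  } else {
    list(
      holo = potential_field(read_pqr(config$holo_pqr),
                             dielectric = config$dielectric, kappa = config$kappa),
      apo = potential_field(read_pqr(config$apo_pqr),
                            dielectric = config$dielectric, kappa = config$kappa)
    )
  }
  pot_holo <- residue_potentials(fields$holo, paired$holo)
  pot_apo <- residue_potentials(fields$apo, paired$apo)

  nb <- neighbor_sets(paired$holo, radius = config$radius, metric = config$metric)
  pert <- perturbation(paired, pot_holo, pot_apo, neighbors = nb,
                       polar_only = config$polar_only)
  rev <- polarity_reversals(
    paired, pot_holo, pot_apo,
    threshold = config$reversal_threshold,
    scope = config$reversal_scope,
    neighbors = if (config$reversal_scope == "neighbors") nb
  )

  files <- character(0)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    sep <- if (config$csv) "," else "\t"
    files <- write_tables(pert, rev, config$out_dir, sep = sep)
    pml <- file.path(config$out_dir, "perturbation.pml")
    write_pymol_script(config$holo_pdb, pert,
                       threshold = config$viz_threshold,
                       signed = config$signed_colors, file = pml)
    log <- file.path(config$out_dir, "parameters.log")
    writeLines(format_param_log(config, paired), log)
    files <- c(files, pymol = pml, log = log)
  }

  structure(
    list(paired = paired, pot_holo = pot_holo, pot_apo = pot_apo,
         perturbation = pert, reversals = rev, files = files,
         config = config),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", x$paired$n, " residue pairs analyzed\n", sep = "")
  sig <- sum(abs(x$perturbation$e_perturb) >= x$config$viz_threshold,
             na.rm = TRUE)
  cat("  residues with |e_perturb| >= ", x$config$viz_threshold, " kT/e: ",
      sig, "\n", sep = "")
  cat("  polarity reversals (threshold ", x$config$reversal_threshold,
      " kT/e): ", nrow(x$reversals), "\n", sep = "")
  invisible(x)
}

format_param_log <- function(config, paired) {
  kv <- c(
    backend = config$backend,
    holo_pdb = config$holo_pdb, apo_pdb = config$apo_pdb,
    holo_dx = config$holo_dx %||% "", apo_dx = config$apo_dx %||% "",
    holo_pqr = config$holo_pqr %||% "", apo_pqr = config$apo_pqr %||% "",
    radius_A = format(config$radius),
    reversal_threshold_kTe = format(config$reversal_threshold),
    viz_threshold_kTe = format(config$viz_threshold),
    polar_only = as.character(config$polar_only),
    reversal_scope = config$reversal_scope,
    metric = config$metric,
    dielectric = format(config$dielectric),
    kappa_invA = format(config$kappa),
    max_mutations = format(config$max_mutations),
    chains = paste(config$chains %||% "all", collapse = ","),
    model = format(config$model),
    n_pairs = format(paired$n),
    mutations = paste(paired$mutations, collapse = ",")
  )
  paste0(names(kv), " = ", unname(kv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
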