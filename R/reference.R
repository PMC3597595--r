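#' Published polarity-reversal reference pairs
#'
#' Returns the bundled reference set of residue pairs reported to undergo
#' significant polarity reversal in six holo/apo enzyme comparisons
#' (diphtheria toxin repressor, two hemoglobin variants, fructose
#' 1,6-bisphosphatase, ketosteroid isomerase, Cu-Zn superoxide dismutase).
#' `pd1`/`pd2` are the pair's holo and apo EPDs in kT/e and `delta_pd` the
#' difference as printed in the source table (reversal threshold 150 kT/e).
#' Useful as direct input to [reversal_set()] to check the filter and the
#' `delta_pd = pd1 - pd2` arithmetic; the absolute values themselves are
#' only reproducible with the original Poisson-Boltzmann setup.
#'
#' @return Data frame with columns `system`, `structures`, `res_a`,
#'   `res_b`, `pd1`, `pd2`, `delta_pd`.
#' @export
reversal_reference <- function() {
  path <- system.file("extdata", "polarity_reversal_reference.tsv",
                      package = "eperturb", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
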