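#' Reference per-pair peptide count table (nine-pair transplant cohort)
#'
#' Published per-pair summary counts for nine HLA-matched stem-cell
#' transplant donor-recipient pairs (four matched related donors, MRD:
#' pairs 2, 4, 16 and 23; five unrelated donors, URD: pairs 3, 5, 7, 8 and
#' 10): number of nonsynonymous SNVs with a graft-versus-host vector, and
#' unique peptide-HLA complexes classified presented (IC50 < 500 nM) and
#' strongly presented (IC50 < 50 nM) by a matrix-based (SMM) and a
#' pan-specific predictor, plus the complexes presented under both. Used
#' as the validation fixture for the cohort summary statistics: the
#' package's medians, ranges and exact Mann-Whitney donor-type comparisons
#' are checked against this table.
#'
#' @return data.frame with columns `pair`, `donor_type`, `n_nssnp`,
#'   `smm_presented`, `smm_strong`, `pan_presented`, `pan_strong`,
#'   `shared_presented`; nine rows.
#' @export
reference_pair_counts <- function() {
  path <- system.file("extdata", "drp_reference_counts.csv",
                      package = "allopotential", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$pair <- as.character(tab$pair)
  tab
}
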