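#' Assemble a pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end run. All
#' thresholds default to the pipeline's standard values: presented
#' < 500 nM, strongly presented < 50 nM, alloreactivity-potential cutoff
#' 100 nM, tissue expression threshold REU > 10, flank 8.
#'
#' @param recipient_vcf,donor_vcf variant-call paths.
#' @param gff,genome transcript-model inputs (GFF3 + FASTA); alternatively
#'   `transcript_table` in the simplified TSV dialect.
#' @param transcript_table optional TSV transcript table (used when `gff`
#'   is `NULL`).
#' @param matrix_paths named character vector of scoring-matrix files,
#'   one per HLA allele (names are allele names; unnamed vectors take the
#'   allele recorded inside each file).
#' @param pan_output optional captured pan-predictor output file.
#' @param pan_columns column mapping for [parse_pan_predictor_output()].
#' @param expression_csv optional gene-by-tissue expression CSV.
#' @param recipient_sample,donor_sample sample names in the VCFs.
#' @param presented_nM,strong_nM,auc_cutoff_nM,reu_threshold thresholds.
#' @param flank padded-peptide flank width.
#' @param dedup_counts deduplicate (peptide, allele) complexes for the
#'   count statistics (default `TRUE`).
#' @param auc_dedup deduplicate before the AUC statistic (default
#'   `FALSE`: duplicates retained).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(recipient_vcf, donor_vcf,
                            gff = NULL, genome = NULL,
                            transcript_table = NULL,
                            matrix_paths = character(),
                            pan_output = NULL,
                            pan_columns = c(allele = "HLA", peptide = "Peptide",
                                            affinity = "Aff.nM"),
                            expression_csv = NULL,
                            recipient_sample = NULL, donor_sample = NULL,
                            presented_nM = 500, strong_nM = 50,
                            auc_cutoff_nM = 100, reu_threshold = 10,
                            flank = 8L, dedup_counts = TRUE,
                            auc_dedup = FALSE) {
  if (strong_nM >= presented_nM)
    stop("strong threshold must be below the presented threshold")
  if (any(c(presented_nM, strong_nM, auc_cutoff_nM) <= 0))
    stop("thresholds must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full alloreactivity-potential pipeline
#'
#' Executes the stages in order -- directional variant call (GVH vector),
#' peptide library construction, scoring-matrix prediction across the HLA
#' genotype, optional pan-predictor merge, summary statistics
#' (presentation counts, alloreactivity-potential AUC, power-law fit),
#' and tissue expression counting -- writing one CSV per stage plus a
#' JSON summary into `out_dir`. Re-running with the same configuration
#' and inputs is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results (`gvh`, `library`,
#'   `smm_records`, `pan_records`, `shared`, `summary`, `auc`,
#'   `power_law`, `tissue_counts`) and `summary_json` (the written path).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  log <- list()

  recipient <- stage("read-recipient",
                     read_variant_calls(config$recipient_vcf, config$recipient_sample))
  donor <- stage("read-donor",
                 read_variant_calls(config$donor_vcf, config$donor_sample))
  gvh <- stage("gvh-call", compute_directional_set(recipient, donor, "GVH"))
  log$n_recipient <- nrow(recipient); log$n_donor <- nrow(donor)
  log$n_gvh <- nrow(gvh)
  write_variant_set(gvh, file.path(out_dir, "gvh.csv"), "csv")
  write_variant_set(gvh, file.path(out_dir, "gvh.vcf"), "vcf")

  models <- stage("transcripts", {
    if (!is.null(config$gff)) load_transcript_models(config$gff, config$genome)
    else if (!is.null(config$transcript_table)) load_transcript_table(config$transcript_table)
    else stop("no transcript model input configured")
  })
  lib <- stage("peptides", build_peptide_library(gvh, models, flank = config$flank))
  log$n_padded <- nrow(lib$peptides); log$n_nonamers <- nrow(lib$nonamers)
  write_peptide_library(lib, file.path(out_dir, "peptides.csv"),
                        file.path(out_dir, "nonamers.csv"))

  matrices <- stage("matrices", lapply(config$matrix_paths, load_scoring_matrix))
  if (is.null(names(matrices)) || !all(nzchar(names(matrices))))
    names(matrices) <- vapply(matrices, function(m) m$allele, character(1))
  smm <- stage("score", score_nonamers(lib$nonamers, matrices,
                                       presented_nM = config$presented_nM,
                                       strong_nM = config$strong_nM))
  log$n_smm_records <- nrow(smm)
  utils::write.csv(smm, file.path(out_dir, "binding_smm.csv"),
                   row.names = FALSE, quote = FALSE)

  pan <- NULL; shared <- NULL
  if (!is.null(config$pan_output)) {
    pan <- stage("parse-pan",
                 parse_pan_predictor_output(config$pan_output,
                                            columns = config$pan_columns,
                                            presented_nM = config$presented_nM,
                                            strong_nM = config$strong_nM))
    shared <- stage("merge", shared_complexes(smm, pan, config$presented_nM))
    utils::write.csv(pan, file.path(out_dir, "binding_pan.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(shared, file.path(out_dir, "shared_complexes.csv"),
                     row.names = FALSE, quote = FALSE)
    log$n_pan_records <- nrow(pan); log$n_shared <- nrow(shared)
  }

  smm_counted <- if (config$dedup_counts) deduplicate_complexes(smm) else smm
  counts <- list(
    smm_presented = sum(smm_counted$ic50_nM < config$presented_nM),
    smm_strong = sum(smm_counted$ic50_nM < config$strong_nM))
  if (!is.null(pan)) {
    pan_counted <- if (config$dedup_counts) deduplicate_complexes(pan) else pan
    counts$pan_presented <- sum(pan_counted$ic50_nM < config$presented_nM)
    counts$pan_strong <- sum(pan_counted$ic50_nM < config$strong_nM)
    counts$shared_presented <- nrow(shared)
  }
  auc <- stage("auc", compute_alloreactivity_potential(
    smm, cutoff_nM = config$auc_cutoff_nM, dedup = config$auc_dedup))
  power <- if (nrow(smm) >= 3L) fit_power_law(smm) else NULL

  tissue_counts <- NULL
  if (!is.null(config$expression_csv)) {
    expr <- stage("expression", load_expression_table(config$expression_csv))
    presented <- smm_counted[smm_counted$ic50_nM < config$presented_nM, ,
                             drop = FALSE]
    tissue_counts <- stage("tissue",
                           count_expressed_antigen_genes(presented, expr,
                                                         config$reu_threshold))
    utils::write.csv(tissue_counts, file.path(out_dir, "tissue_counts.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  summary <- c(log, counts,
               list(auc_nM_peptide = auc$auc, auc_n_points = auc$n_points,
                    auc_fallback = auc$fallback,
                    power_law_exponent = if (!is.null(power)) power$exponent else NA,
                    thresholds = list(presented_nM = config$presented_nM,
                                      strong_nM = config$strong_nM,
                                      auc_cutoff_nM = config$auc_cutoff_nM,
                                      reu_threshold = config$reu_threshold)))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(gvh = gvh, library = lib, smm_records = smm,
                 pan_records = pan, shared = shared, counts = counts,
                 auc = auc, power_law = power, tissue_counts = tissue_counts,
                 summary = summary, summary_json = json_path))
}
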