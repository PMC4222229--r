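# fixed amino-acid column order of the matrix dialect
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an additive log-IC50 scoring matrix
#'
#' The matrix model is additive in log10(IC50 nM): a 9-mer's score is the
#' intercept plus one positional cell per residue, and IC50 = 10^score,
#' clipped to `[0.01, 50000]` nM. This is the convention of published
#' stabilized-matrix-method (SMM) matrices for peptide-HLA class I binding.
#'
#' @param allele HLA allele name, e.g. `"HLA-A*02:01"`.
#' @param cells numeric 9 x 20 matrix, columns named by the amino-acid
#'   alphabet `ACDEFGHIKLMNPQRSTVWY`, rows = peptide positions 1..9.
#' @param intercept scalar intercept on the log10 nM scale.
#' @param peptide_length peptide length (fixed at 9 for class I).
#' @return An `smm_matrix` object.
#' @export
smm_matrix <- function(allele, cells, intercept = 0, peptide_length = 9L) {
  cells <- as.matrix(cells)
  if (!all(dim(cells) == c(peptide_length, 20L)))
    stop("scoring matrix must be ", peptide_length, " x 20, got ",
         nrow(cells), " x ", ncol(cells))
  if (is.null(colnames(cells))) colnames(cells) <- AA_ORDER
  if (!identical(colnames(cells), AA_ORDER))
    stop("matrix columns must be in order ", paste(AA_ORDER, collapse = ""))
  if (!all(is.finite(cells)) || !is.finite(intercept))
    stop("scoring matrix cells and intercept must be finite")
  structure(list(allele = allele, peptide_length = as.integer(peptide_length),
                 cells = cells, intercept = as.numeric(intercept)),
            class = "smm_matrix")
}

#' @export
print.smm_matrix <- function(x, ...) {
  cat("smm_matrix for", x$allele, "- additive log10(IC50 nM) model,",
      x$peptide_length, "positions x 20 residues, intercept",
      format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' Read a scoring matrix from the plain-text matrix dialect
#'
#' Dialect: line 1 `allele <name>`, line 2 `length 9`, line 3
#' `intercept <float>`, then 9 rows of 20 whitespace-separated floats in
#' fixed column order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param path matrix file path.
#' @return an `smm_matrix`.
#' @export
load_scoring_matrix <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- function(i, key) {
    parts <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (length(parts) < 2L || parts[1] != key)
      stop("matrix file line ", i, ": expected '", key, " <value>'")
    parts[2]
  }
  allele <- hdr(1, "allele")
  plen <- as.integer(hdr(2, "length"))
  intercept <- as.numeric(hdr(3, "intercept"))
  rows <- ln[-(1:3)]
  if (length(rows) != plen)
    stop("scoring matrix must be ", plen, " x 20: expected ", plen,
         " data rows, found ", length(rows))
  cells <- t(vapply(rows, function(r) {
    v <- as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    if (length(v) != 20L)
      stop("scoring matrix must be ", plen, " x 20: a row has ", length(v), " values")
    v
  }, numeric(20)))
  dimnames(cells) <- list(NULL, AA_ORDER)
  smm_matrix(allele, cells, intercept, plen)
}

#' Write a scoring matrix in the plain-text matrix dialect
#' @param matrix an `smm_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_matrix <- function(matrix, path) {
  ln <- c(paste("allele", matrix$allele),
          paste("length", matrix$peptide_length),
          paste("intercept", format(matrix$intercept, digits = 17)),
          apply(matrix$cells, 1, function(r)
            paste(format(r, digits = 17), collapse = " ")))
  writeLines(ln, path)
  invisible(path)
}

#' Predict IC50 (nM) of 9-mers under an additive scoring matrix
#'
#' score = intercept + sum over positions of cells[position, residue];
#' IC50 = 10^score, clipped to `clip` nM. Lower IC50 means stronger
#' binding.
#'
#' @param peptides character vector of peptides, each of the matrix's
#'   peptide length, standard 20-letter alphabet.
#' @param matrix an `smm_matrix`.
#' @param clip two-element numeric, the IC50 clipping bounds in nM.
#' @return numeric vector of IC50 values in nM.
#' @export
predict_ic50_smm <- function(peptides, matrix, clip = c(0.01, 50000)) {
  plen <- matrix$peptide_length
  bad_len <- nchar(peptides) != plen
  if (any(bad_len))
    stop("peptide length must be ", plen, ": ", peptides[which(bad_len)[1]])
  score <- vapply(peptides, function(p) {
    aa <- strsplit(p, "")[[1]]
    col <- match(aa, AA_ORDER)
    if (anyNA(col)) {
      i <- which(is.na(col))[1]
      stop("nonstandard residue '", aa[i], "' at position ", i, " in ", p)
    }
    matrix$intercept + sum(matrix$cells[cbind(seq_len(plen), col)])
  }, numeric(1), USE.NAMES = FALSE)
  pmin(pmax(10^score, clip[1]), clip[2])
}

#' Classify presentation from IC50
#'
#' Binding classes are nested and the thresholds strict: IC50 < 50 nM is
#' `strongly_presented` (high affinity), 50 <= IC50 < 500 nM is
#' `presented` (intermediate affinity), IC50 >= 500 nM is `none`. Equality
#' at a boundary falls to the weaker class.
#'
#' @param ic50_nM positive numeric vector.
#' @param presented_nM,strong_nM class thresholds (defaults 500 and 50 nM).
#' @return factor with levels `none`, `presented`, `strongly_presented`.
#' @export
classify_presentation <- function(ic50_nM, presented_nM = 500, strong_nM = 50) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0))
    stop("IC50 values must be positive and finite")
  # strictly-less-than, but robust to float round-off at the boundary
  # (a value within 1e-9 relative of the threshold counts as equal to it)
  lt <- function(x, thr) x < thr * (1 - 1e-9)
  cls <- ifelse(lt(ic50_nM, strong_nM), "strongly_presented",
                ifelse(lt(ic50_nM, presented_nM), "presented", "none"))
  factor(cls, levels = c("none", "presented", "strongly_presented"))
}

#' Score a nonamer library against a patient's HLA class I genotype
#'
#' Each distinct allele in the genotype is scored once (homozygous alleles
#' do not double records). Returns one binding record per
#' (nonamer row, allele).
#'
#' @param nonamers data.frame with a `nonamer` column (and optional
#'   provenance columns `gene`, `chrom`, `pos` carried through).
#' @param matrices named list of `smm_matrix`, one per allele; names (or
#'   the matrices' own `allele` fields) identify the alleles.
#' @param predictor label stored in the `predictor` column (default "SMM").
#' @param presented_nM,strong_nM classification thresholds.
#' @return data.frame of binding records: `peptide`, `allele`, `predictor`,
#'   `ic50_nM`, `presentation`, plus any provenance columns present.
#' @export
score_nonamers <- function(nonamers, matrices, predictor = "SMM",
                           presented_nM = 500, strong_nM = 50) {
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m) m$allele, character(1))
  matrices <- matrices[!duplicated(names(matrices))]
  prov_cols <- intersect(c("gene", "transcript", "chrom", "pos"), names(nonamers))
  out <- lapply(names(matrices), function(al) {
    if (nrow(nonamers) == 0L) return(NULL)
    ic50 <- predict_ic50_smm(nonamers$nonamer, matrices[[al]])
    cbind(data.frame(peptide = nonamers$nonamer, allele = al,
                     predictor = predictor, ic50_nM = ic50,
                     presentation = classify_presentation(ic50, presented_nM, strong_nM),
                     stringsAsFactors = FALSE),
          nonamers[, prov_cols, drop = FALSE])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(peptide = character(), allele = character(),
                      predictor = character(), ic50_nM = numeric(),
                      presentation = factor(character(),
                                            levels = c("none", "presented",
                                                       "strongly_presented")),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Parse captured output of a pan-specific peptide-HLA predictor
#'
#' Consumes the whitespace-delimited result table of a pan-specific
#' predictor run in 9-mer mode (the kind of table recovered from saved
#' HTML/CSV result pages). Lines are classified by shape: a header line
#' names the columns; data lines supply one record each. Concatenations of
#' several runs (repeated headers, separator rules, trailing summary
#' lines) are handled; rows whose affinity does not parse as a number are
#' counted and skipped.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param columns named character vector mapping the logical fields
#'   `allele`, `peptide`, `affinity` to the column names used in the file.
#' @param presented_nM,strong_nM classification thresholds.
#' @return data.frame of binding records with `predictor = "PAN"` and a
#'   `"parse_report"` attribute (`n_data`, `n_skipped`).
#' @export
parse_pan_predictor_output <- function(path = NULL, text = NULL,
                                       columns = c(allele = "HLA",
                                                   peptide = "Peptide",
                                                   affinity = "Aff.nM"),
                                       presented_nM = 500, strong_nM = 50) {
  ln <- if (!is.null(text)) text else readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !grepl("^[-=#]+$", ln)]
  needed <- unname(columns[c("allele", "peptide", "affinity")])
  recs <- list(); n_skipped <- 0L
  colmap <- NULL
  for (l in ln) {
    tok <- strsplit(l, "\\s+")[[1]]
    if (all(needed %in% tok)) {            # header line (possibly repeated)
      colmap <- match(needed, tok)
      next
    }
    if (is.null(colmap) || length(tok) < max(colmap)) next
    aff <- suppressWarnings(as.numeric(tok[colmap[3]]))
    pep <- tok[colmap[2]]
    if (!grepl("^[A-Z]+$", pep)) next      # prose/summary line, not a record
    if (is.na(aff)) {
      n_skipped <- n_skipped + 1L          # record-shaped row, bad affinity
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      peptide = pep, allele = tok[colmap[1]], predictor = "PAN",
      ic50_nM = aff, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    stop("no data rows parsed from pan-predictor output (format drift?)")
  out <- do.call(rbind, recs)
  out$presentation <- classify_presentation(out$ic50_nM, presented_nM, strong_nM)
  attr(out, "parse_report") <- list(n_data = nrow(out), n_skipped = n_skipped)
  out
}

#' Shared peptide-HLA complexes presented by both predictors
#'
#' Intersects two predictors' record sets on the (peptide, allele) key,
#' keeping only complexes with IC50 < `presented_nM` under *both*
#' predictors -- the "shared presented" convention used for cross-predictor
#' validation. Inputs are deduplicated on the key first (first record per
#' key wins).
#'
#' @param smm_records,pan_records binding-record data.frames with
#'   `peptide`, `allele`, `ic50_nM`.
#' @param presented_nM presentation threshold (default 500 nM).
#' @return data.frame with `peptide`, `allele`, `ic50_smm`, `ic50_pan`.
#' @export
shared_complexes <- function(smm_records, pan_records, presented_nM = 500) {
  a <- deduplicate_complexes(smm_records)
  b <- deduplicate_complexes(pan_records)
  ka <- paste(a$peptide, a$allele, sep = "|")
  kb <- paste(b$peptide, b$allele, sep = "|")
  m <- match(ka, kb)
  keep <- !is.na(m) & a$ic50_nM < presented_nM & b$ic50_nM[m] < presented_nM
  data.frame(peptide = a$peptide[keep], allele = a$allele[keep],
             ic50_smm = a$ic50_nM[keep], ic50_pan = b$ic50_nM[m[keep]],
             stringsAsFactors = FALSE)
}

#' Correlate the two predictors' IC50 values over shared complexes
#'
#' Pearson correlation between the two predictors' IC50 values over the
#' shared (both-presented) complex set, on the raw nM scale by default or
#' log10 nM with `log10 = TRUE` (affinities are log-distributed, so the
#' log scale is usually the more informative one).
#'
#' @param shared result of [shared_complexes()].
#' @param log10 correlate log10-transformed IC50 instead of raw nM.
#' @return list with `pearson_r`, `p_value`, `n`.
#' @export
correlate_predictions <- function(shared, log10 = FALSE) {
  if (nrow(shared) < 3L)
    stop("need at least 3 shared complexes for a correlation, got ", nrow(shared))
  x <- shared$ic50_smm; y <- shared$ic50_pan
  if (log10) { x <- log10(x); y <- log10(y) }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = nrow(shared))
}

#' Parse an HLA class I genotype
#'
#' @param patient_id identifier.
#' @param alleles character vector of 1-6 allele names; the locus (A, B or
#'   C) must be parsable from each name (e.g. `"HLA-A*02:01"`, `"A*02:01"`,
#'   `"B07:02"`). Homozygous duplicates are retained but scored once.
#' @return An `hla_genotype` list with `patient_id`, `alleles`, `loci`.
#' @export
hla_genotype <- function(patient_id, alleles) {
  if (length(alleles) < 1L || length(alleles) > 6L)
    stop("an HLA class I genotype has 1-6 alleles, got ", length(alleles))
  loci <- hla_locus(alleles)
  if (anyNA(loci))
    stop("cannot parse HLA locus from: ",
         paste(alleles[is.na(loci)], collapse = ", "))
  structure(list(patient_id = patient_id, alleles = alleles, loci = loci),
            class = "hla_genotype")
}

#' Extract the HLA locus (A/B/C) from allele names
#' @param alleles character vector of allele names.
#' @return character vector of `"A"`, `"B"`, `"C"` (NA if unparsable).
#' @export
hla_locus <- function(alleles) {
  vapply(alleles, function(a) {
    mm <- regexec("(?i)^(?:HLA-?)?([ABC])[^A-Za-z]", paste0(a, " "), perl = TRUE)[[1]]
    if (mm[1] == -1) NA_character_ else {
      start <- mm[2] + attr(mm, "match.length")[2] - 1L
      toupper(substring(a, mm[2], start))
    }
  }, character(1), USE.NAMES = FALSE)
}
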