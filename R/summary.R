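#' Ascending IC50-versus-rank series below an affinity cutoff
#'
#' Retains records with IC50 <= `cutoff_nM` (duplicate peptide-HLA
#' complexes retained by default, matching the area-under-curve
#' convention), sorts them ascending by IC50 -- i.e. descending binding
#' affinity -- with ties broken by peptide then allele so runs are
#' reproducible, and assigns ranks 1..N.
#'
#' @param records binding-record data.frame with `ic50_nM` (and, for tie
#'   breaking, `peptide` and `allele`).
#' @param cutoff_nM affinity cutoff in nM (default 100).
#' @param dedup drop duplicate (peptide, allele) complexes first.
#' @return data.frame with `rank` and `ic50_nM`, possibly zero rows.
#' @export
rank_ic50_curve <- function(records, cutoff_nM = 100, dedup = FALSE) {
  stopifnot(cutoff_nM > 0)
  if (dedup) records <- deduplicate_complexes(records)
  keep <- records$ic50_nM <= cutoff_nM
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(rank = integer(), ic50_nM = numeric()))
  pep <- if ("peptide" %in% names(r)) r$peptide else ""
  al <- if ("allele" %in% names(r)) r$allele else ""
  o <- order(r$ic50_nM, pep, al)
  data.frame(rank = seq_len(nrow(r)), ic50_nM = r$ic50_nM[o])
}

#' Ordinary least-squares quadratic fit of IC50 on rank
#'
#' Fits `ic50 = c2 * rank^2 + c1 * rank + c0` by OLS.
#'
#' @param series data.frame from [rank_ic50_curve()] (columns `rank`,
#'   `ic50_nM`), at least 3 points.
#' @return list with `coefficients = c(c2, c1, c0)` and `rmse`.
#' @export
fit_quadratic <- function(series) {
  if (nrow(series) < 3L)
    stop("quadratic fit needs at least 3 points, got ", nrow(series))
  x <- series$rank; y <- series$ic50_nM
  fit <- stats::lm(y ~ I(x^2) + x)
  cf <- stats::coef(fit)
  coefs <- c(c2 = unname(cf["I(x^2)"]), c1 = unname(cf["x"]),
             c0 = unname(cf["(Intercept)"]))
  coefs[is.na(coefs)] <- 0  # rank-deficient (e.g. constant) series
  list(coefficients = coefs, rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Definite integral of a quadratic by the closed-form antiderivative
#'
#' Evaluates `c2 (b^3 - a^3)/3 + c1 (b^2 - a^2)/2 + c0 (b - a)`; no
#' numeric quadrature is involved.
#'
#' @param c2,c1,c0 quadratic coefficients.
#' @param a,b integration bounds, `a <= b`.
#' @return the integral value.
#' @export
integrate_curve <- function(c2, c1, c0, a, b) {
  if (a > b) stop("integration bounds require a <= b, got a = ", a, ", b = ", b)
  c2 * (b^3 - a^3) / 3 + c1 * (b^2 - a^2) / 2 + c0 * (b - a)
}

#' HLA-specific alloreactivity potential (AUC, nM*Peptide)
#'
#' Summarizes a donor-recipient pair's high-affinity peptide burden as the
#' area under its ascending IC50-versus-rank curve: records with IC50 at
#' or below `cutoff_nM` are ranked (all six HLA alleles pooled), a
#' second-order polynomial is fitted to IC50 as a function of rank, and
#' its definite integral is taken in closed form over the rank axis from
#' a = 1 (strongest binder) to b = N (last retained rank). The unit is
#' nM*Peptide: an IC50-scale quantity accumulated across peptides.
#'
#' With fewer than 3 retained records a quadratic cannot be fitted; the
#' trapezoid area of the raw series is reported instead and the
#' `fallback` flag set. An empty series yields an AUC of 0.
#'
#' @param records binding-record data.frame with `ic50_nM`.
#' @param cutoff_nM affinity cutoff in nM (default 100).
#' @param dedup drop duplicate (peptide, allele) complexes before ranking
#'   (default `FALSE`: duplicates from splice isoforms are retained).
#' @return An `auc_result` list: `coefficients` (c2, c1, c0), `a`, `b`,
#'   `auc`, `n_points`, `cutoff_nM`, `fit_rmse`, `fallback`.
#' @export
compute_alloreactivity_potential <- function(records, cutoff_nM = 100,
                                             dedup = FALSE) {
  series <- rank_ic50_curve(records, cutoff_nM = cutoff_nM, dedup = dedup)
  n <- nrow(series)
  if (n >= 3L) {
    fit <- fit_quadratic(series)
    cf <- fit$coefficients
    auc <- integrate_curve(cf[["c2"]], cf[["c1"]], cf[["c0"]], 1, n)
    res <- list(coefficients = cf, a = 1, b = n, auc = auc, n_points = n,
                cutoff_nM = cutoff_nM, fit_rmse = fit$rmse, fallback = FALSE)
  } else {
    auc <- if (n >= 2L) trapezoid_area(series$rank, series$ic50_nM) else 0
    res <- list(coefficients = c(c2 = NA_real_, c1 = NA_real_, c0 = NA_real_),
                a = if (n) 1 else NA_real_, b = if (n) n else NA_real_,
                auc = auc, n_points = n, cutoff_nM = cutoff_nM,
                fit_rmse = NA_real_, fallback = TRUE)
  }
  structure(res, class = "auc_result")
}

trapezoid_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.auc_result <- function(x, ...) {
  cat("alloreactivity potential:", format(x$auc, big.mark = ","),
      "nM*Peptide over", x$n_points, "peptide-HLA records (IC50 <=",
      x$cutoff_nM, "nM)\n")
  if (!x$fallback)
    cat("  quadratic fit c2 =", signif(x$coefficients[["c2"]], 4),
        " c1 =", signif(x$coefficients[["c1"]], 4),
        " c0 =", signif(x$coefficients[["c0"]], 4),
        " rmse =", signif(x$fit_rmse, 4), "\n")
  else cat("  fallback: trapezoid area (fewer than 3 points)\n")
  invisible(x)
}

#' Expression-weighted alloreactivity potential
#'
#' Sums `Re(gene, tissue) * (1 / IC50)` over binding records: each
#' peptide-HLA complex contributes its binding affinity (the reciprocal
#' IC50) weighted by the relative expression of its source gene in the
#' chosen tissue. Records whose gene is absent from the expression table
#' contribute 0 and are counted.
#'
#' @param records binding-record data.frame with `ic50_nM` and `gene`.
#' @param expression an `expression_table` (see [load_expression_table()]).
#' @param tissue tissue name (must be a column of the table).
#' @return list with `value`, `terms` (per-record contributions), and
#'   `n_unmapped` (records with no expression entry).
#' @export
weighted_potential <- function(records, expression, tissue) {
  tissues <- setdiff(names(expression), "gene")
  if (!tissue %in% tissues)
    stop("unknown tissue '", tissue, "' (available: ",
         paste(tissues, collapse = ", "), ")")
  re <- expression[[tissue]][match(records$gene, expression$gene)]
  unmapped <- is.na(re)
  re[unmapped] <- 0
  terms <- re * (1 / records$ic50_nM)
  list(value = sum(terms), terms = terms, n_unmapped = sum(unmapped))
}

#' Power-law fit of the binding-affinity rank-frequency curve
#'
#' Plots the reciprocal IC50 (a direct reflection of binding affinity) in
#' descending order against rank and fits
#' `log10(1/IC50) = intercept + exponent * log10(rank)` by OLS -- the
#' standard log-log regression for a power (Zipf-like) distribution, the
#' same form reported for T-cell clonal frequency distributions.
#'
#' @param records binding-record data.frame with positive `ic50_nM`, or a
#'   numeric vector of IC50 values.
#' @return list with `exponent`, `intercept`, `r_squared`, `n`.
#' @export
fit_power_law <- function(records) {
  ic50 <- if (is.numeric(records)) records else records$ic50_nM
  ic50 <- ic50[is.finite(ic50) & ic50 > 0]
  if (length(ic50) < 3L)
    stop("power-law fit needs at least 3 positive IC50 values, got ", length(ic50))
  aff <- sort(1 / ic50, decreasing = TRUE)
  lr <- log10(seq_along(aff))
  la <- log10(aff)
  fit <- stats::lm(la ~ lr)
  cf <- stats::coef(fit)
  ss_tot <- sum((la - mean(la))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(exponent = unname(cf["lr"]), intercept = unname(cf["(Intercept)"]),
       r_squared = r2, n = length(aff))
}

#' Exact Mann-Whitney U test for small two-group comparisons
#'
#' Computes U as the pairwise comparison count (pairs where a group-A
#' value exceeds a group-B value; ties contribute 1/2). For combined
#' sample sizes up to `exact_max` with no cross- or within-pool ties, the
#' exact null distribution of U is built by complete enumeration of all
#' choose(nA+nB, nA) group labelings and the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. Larger or tied samples fall
#' back to the normal approximation with the usual tie correction (no
#' continuity correction), flagged in `method`.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact_max largest combined sample size for the exact path
#'   (default 20).
#' @return list with `u_statistic`, `p_two_sided`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`, and (exact path only)
#'   `null_distribution`, a data.frame of the enumerated U probabilities.
#' @export
exact_mann_whitney <- function(group_a, group_b, exact_max = 20L) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  nA <- length(group_a); nB <- length(group_b)
  u_of <- function(a, b) {
    # U for the first group: #(a > b) + 0.5 #(a == b) over all pairs
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_of(group_a, group_b)
  pooled <- c(group_a, group_b)
  ties <- anyDuplicated(pooled) > 0L
  if (nA + nB <= exact_max && !ties) {
    labelings <- utils::combn(nA + nB, nA)
    us <- apply(labelings, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
    p <- min(1, 2 * min(p_le, p_ge))
    tab <- table(us) / length(us)
    null_dist <- data.frame(u = as.numeric(names(tab)), p = as.numeric(tab))
    return(list(u_statistic = u, p_two_sided = p, method = "exact",
                n_a = nA, n_b = nB, null_distribution = null_dist))
  }
  # normal approximation with tie correction
  N <- nA + nB
  mu <- nA * nB / 2
  tie_tab <- table(pooled)
  sigma2 <- nA * nB / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (u - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u_statistic = u, p_two_sided = p, method = "normal_approx",
       n_a = nA, n_b = nB)
}

#' Per-pair presentation counts and cohort summary
#'
#' Builds the per-pair summary table (one row per donor-recipient pair:
#' nsSNP count, presented and strongly presented unique peptide-HLA
#' complexes per predictor, shared complexes) and the cohort aggregates:
#' medians (standard order-statistic convention: middle value for odd n,
#' mean of the central two for even n), min-max ranges, per-HLA-locus
#' presented counts, and exact Mann-Whitney comparisons between donor-type
#' groups (matched related, MRD, versus unrelated, URD) for every count
#' column.
#'
#' @param pairs either a precomputed per-pair count data.frame (columns
#'   `pair`, `donor_type`, and count columns), or a named list of per-pair
#'   record lists, each with elements `smm` and optionally `pan`
#'   (binding-record data.frames) and `n_nssnp`.
#' @param donor_types named character vector (`"MRD"`/`"URD"`) keyed by
#'   pair id; ignored when `pairs` is a data.frame with a `donor_type`
#'   column.
#' @param presented_nM,strong_nM classification thresholds.
#' @return A `summary_table` list with `rows` (per-pair data.frame),
#'   `aggregates` (per-column median/min/max), `per_locus` (presented
#'   unique complexes per HLA locus per predictor, when records are
#'   given), and `comparisons` (Mann-Whitney results per count column,
#'   when both donor types are present).
#' @export
summarize_counts <- function(pairs, donor_types = NULL,
                             presented_nM = 500, strong_nM = 50) {
  per_locus <- NULL
  if (is.data.frame(pairs)) {
    rows <- pairs
  } else {
    rows <- list(); locus_acc <- list()
    for (pid in names(pairs)) {
      p <- pairs[[pid]]
      smm <- deduplicate_complexes(p$smm)
      row <- data.frame(pair = pid,
                        donor_type = if (!is.null(donor_types)) donor_types[[pid]] else NA,
                        n_nssnp = if (!is.null(p$n_nssnp)) p$n_nssnp else NA_integer_,
                        smm_presented = sum(smm$ic50_nM < presented_nM),
                        smm_strong = sum(smm$ic50_nM < strong_nM),
                        stringsAsFactors = FALSE)
      loc <- data.frame(pair = pid, predictor = "SMM",
                        locus = hla_locus(smm$allele[smm$ic50_nM < presented_nM]),
                        stringsAsFactors = FALSE)
      if (!is.null(p$pan)) {
        pan <- deduplicate_complexes(p$pan)
        row$pan_presented <- sum(pan$ic50_nM < presented_nM)
        row$pan_strong <- sum(pan$ic50_nM < strong_nM)
        row$shared_presented <- nrow(shared_complexes(smm, pan, presented_nM))
        loc <- rbind(loc, data.frame(pair = pid, predictor = "PAN",
                                     locus = hla_locus(pan$allele[pan$ic50_nM < presented_nM]),
                                     stringsAsFactors = FALSE))
      }
      rows[[pid]] <- row
      locus_acc[[pid]] <- loc
    }
    rows <- do.call(rbind, rows)
    rownames(rows) <- NULL
    loc_all <- do.call(rbind, locus_acc)
    if (nrow(loc_all))
      per_locus <- as.data.frame(table(predictor = loc_all$predictor,
                                       locus = loc_all$locus),
                                 responseName = "n_presented")
  }
  count_cols <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))], "pair")
  aggregates <- do.call(rbind, lapply(count_cols, function(cc) {
    v <- rows[[cc]]
    data.frame(statistic = cc, median = stats::median(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  comparisons <- NULL
  if ("donor_type" %in% names(rows) && !anyNA(rows$donor_type) &&
      length(unique(rows$donor_type)) == 2L) {
    grp <- sort(unique(rows$donor_type))
    comparisons <- lapply(count_cols, function(cc) {
      mw <- exact_mann_whitney(rows[[cc]][rows$donor_type == grp[1]],
                               rows[[cc]][rows$donor_type == grp[2]])
      data.frame(statistic = cc, group_a = grp[1], group_b = grp[2],
                 u = mw$u_statistic, p_two_sided = mw$p_two_sided,
                 method = mw$method, stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, comparisons)
  }
  structure(list(rows = rows, aggregates = aggregates,
                 per_locus = per_locus, comparisons = comparisons),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("summary_table:", nrow(x$rows), "donor-recipient pair(s)\n")
  print(x$rows)
  cat("\naggregates:\n"); print(x$aggregates)
  if (!is.null(x$comparisons)) {
    cat("\ndonor-type comparisons (Mann-Whitney):\n"); print(x$comparisons)
  }
  invisible(x)
}
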