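#' Load a gene-by-tissue expression table
#'
#' CSV with a `gene` column and one column per tissue; values are relative
#' expression units (REU), non-negative. Duplicate gene rows and negative
#' values are load errors.
#'
#' @param path CSV path.
#' @return an `expression_table` data.frame (column `gene` + one numeric
#'   column per tissue).
#' @export
load_expression_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("expression CSV needs a 'gene' column")
  dup <- tab$gene[duplicated(tab$gene)]
  if (length(dup)) stop("duplicate gene row(s) in expression table: ",
                        paste(unique(dup), collapse = ", "))
  vals <- tab[, setdiff(names(tab), "gene"), drop = FALSE]
  if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stop("expression table contains negative values")
  structure(tab, class = c("expression_table", "data.frame"))
}

#' Write an expression table as CSV
#' @param table an `expression_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count antigen-source genes expressed per tissue
#'
#' For each tissue, counts the DISTINCT genes that both contribute at
#' least one presented peptide (IC50 below the presentation threshold,
#' assumed already applied to `presented_records`) and are expressed
#' strictly above `threshold` REU in that tissue. A gene at exactly the
#' threshold is not counted. Source genes absent from the expression
#' table are reported separately as unmapped, not silently dropped.
#'
#' @param presented_records binding-record data.frame with a `gene`
#'   column, already restricted to presented records.
#' @param table an `expression_table`.
#' @param threshold REU threshold (default 10, strict `>`).
#' @return data.frame with `tissue` and `n_genes`, plus attributes
#'   `"unmapped_genes"` (character) and `"n_source_genes"`.
#' @export
count_expressed_antigen_genes <- function(presented_records, table,
                                          threshold = 10) {
  genes <- unique(presented_records$gene)
  tissues <- setdiff(names(table), "gene")
  mapped <- genes[genes %in% table$gene]
  unmapped <- setdiff(genes, mapped)
  idx <- match(mapped, table$gene)
  counts <- vapply(tissues, function(tt)
    sum(table[[tt]][idx] > threshold), integer(1))
  out <- data.frame(tissue = tissues, n_genes = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "unmapped_genes") <- unmapped
  attr(out, "n_source_genes") <- length(genes)
  out
}
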