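#' Build the variant-centered padded peptide for a nonsynonymous consequence
#'
#' Extracts up to `flank` residues on either side of the substituted
#' residue from the transcript's reference protein and swaps in the
#' alternate amino acid, yielding the padded peptide (17-mer at default
#' flank 8 for a mid-protein variant, truncated near the termini). The
#' flank default follows HLA class I biology: the canonical presented
#' peptide is a 9-mer, so 8 residues either side of the variant cover
#' every 9-mer containing it.
#'
#' Synonymous consequences are a contract violation. Variants that create
#' a stop codon, or that fall on the reference stop codon, have no single
#' substituted residue to center a peptide on and return `NULL`.
#'
#' @param consequence a `coding_consequence` from
#'   [annotate_coding_consequence()].
#' @param model the matching `transcript_model`.
#' @param flank maximum flank width in residues (default 8).
#' @return A `padded_peptide` list with `sequence`, `variant_offset`
#'   (1-based position of the variant residue in `sequence`) and the
#'   originating `consequence`; or `NULL` for stop-affecting variants.
#' @export
build_padded_peptide <- function(consequence, model, flank = 8L) {
  if (consequence$synonymous)
    stop("build_padded_peptide() requires a non-synonymous consequence")
  prot <- model$protein_sequence
  plen <- nchar(prot)
  p <- consequence$protein_pos
  if (consequence$alt_aa == "*" || consequence$ref_aa == "*" || p > plen)
    return(NULL)  # nonsense / stop-loss: no substituted residue to center on
  left <- min(flank, p - 1L)
  right <- min(flank, plen - p)
  seqv <- substring(prot, p - left, p + right)
  substring(seqv, left + 1L, left + 1L) <- consequence$alt_aa
  structure(list(sequence = seqv, variant_offset = left + 1L,
                 consequence = consequence),
            class = "padded_peptide")
}

#' Enumerate all 9-mer windows of a padded peptide containing the variant
#'
#' Slides a 9-residue window across the padded peptide and keeps every
#' window that covers the variant residue, ordered by window start. A full
#' 17-mer with the variant at its center yields exactly nine nonamers with
#' the variant at positions 9 down to 1; truncated peptides yield
#' `min(v, L - 8) - max(1, v - 8) + 1` windows for length `L` and variant
#' offset `v`.
#'
#' @param padded a `padded_peptide`.
#' @param width window width (default 9, the HLA class I peptide length).
#' @return data.frame with columns `nonamer`, `variant_pos` (1-based
#'   position of the variant within the window) and `window_start`; empty
#'   (zero rows) when the padded peptide is shorter than `width`.
#' @export
enumerate_nonamers <- function(padded, width = 9L) {
  L <- nchar(padded$sequence)
  v <- padded$variant_offset
  empty <- data.frame(nonamer = character(), variant_pos = integer(),
                      window_start = integer(), stringsAsFactors = FALSE)
  if (L < width) return(empty)
  s0 <- max(1L, v - (width - 1L))
  s1 <- min(v, L - width + 1L)
  if (s0 > s1) return(empty)
  starts <- s0:s1
  data.frame(nonamer = substring(padded$sequence, starts, starts + width - 1L),
             variant_pos = v - starts + 1L,
             window_start = starts, stringsAsFactors = FALSE)
}

#' Build the full candidate-mHA peptide library for a directional variant set
#'
#' Runs every variant against every transcript model: annotates the coding
#' consequence, keeps nonsynonymous substitutions, builds the padded
#' peptide and enumerates its variant-containing 9-mers. Generation is
#' per-transcript, so one variant hitting k transcripts (splice isoforms)
#' yields up to k padded peptides; deduplication of peptide-HLA complexes
#' is a separate downstream stage.
#'
#' @param variants a `variant_set` (e.g. the GVH directional set).
#' @param models named list of `transcript_model`.
#' @param flank flank width passed to [build_padded_peptide()].
#' @return A list with `peptides` (one row per padded peptide:
#'   gene, transcript, chrom, pos, ref, alt, protein_pos, ref_aa, alt_aa,
#'   padded_peptide, variant_offset), `nonamers` (adds `nonamer`,
#'   `variant_pos`), and a `log` data.frame counting variants by fate
#'   (noncoding, synonymous, stop_affecting, nonsynonymous).
#' @export
build_peptide_library <- function(variants, models, flank = 8L) {
  variants <- as_variant_set(variants)
  pep_rows <- list(); non_rows <- list()
  fate <- c(noncoding = 0L, synonymous = 0L, stop_affecting = 0L,
            nonsynonymous = 0L, too_short = 0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- FALSE
    for (m in models) {
      cons <- annotate_coding_consequence(v, m)
      if (is.null(cons)) next
      hit <- TRUE
      if (cons$synonymous) {
        fate["synonymous"] <- fate["synonymous"] + 1L
        next
      }
      pp <- build_padded_peptide(cons, m, flank = flank)
      if (is.null(pp)) {
        fate["stop_affecting"] <- fate["stop_affecting"] + 1L
        next
      }
      fate["nonsynonymous"] <- fate["nonsynonymous"] + 1L
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        gene = cons$gene_id, transcript = cons$transcript_id,
        chrom = cons$chrom, pos = cons$pos, ref = cons$ref, alt = cons$alt,
        protein_pos = cons$protein_pos, ref_aa = cons$ref_aa,
        alt_aa = cons$alt_aa, padded_peptide = pp$sequence,
        variant_offset = pp$variant_offset, stringsAsFactors = FALSE)
      nm <- enumerate_nonamers(pp)
      if (nrow(nm) == 0L) {
        fate["too_short"] <- fate["too_short"] + 1L
        next
      }
      nm$gene <- cons$gene_id; nm$transcript <- cons$transcript_id
      nm$chrom <- cons$chrom; nm$pos <- cons$pos
      nm$ref <- cons$ref; nm$alt <- cons$alt
      nm$padded_peptide <- pp$sequence
      non_rows[[length(non_rows) + 1L]] <- nm
    }
    if (!hit) fate["noncoding"] <- fate["noncoding"] + 1L
  }
  empty_pep <- data.frame(gene = character(), transcript = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          protein_pos = integer(), ref_aa = character(),
                          alt_aa = character(), padded_peptide = character(),
                          variant_offset = integer(), stringsAsFactors = FALSE)
  peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else empty_pep
  nonamers <- if (length(non_rows)) do.call(rbind, non_rows) else {
    cbind(data.frame(nonamer = character(), variant_pos = integer(),
                     window_start = integer(), stringsAsFactors = FALSE),
          empty_pep[, c("gene", "transcript", "chrom", "pos", "ref", "alt",
                        "padded_peptide")])
  }
  rownames(peptides) <- NULL; rownames(nonamers) <- NULL
  list(peptides = peptides, nonamers = nonamers,
       log = data.frame(fate = names(fate), n = unname(fate)))
}

#' Deduplicate peptide-HLA complexes
#'
#' Collapses records to unique (peptide sequence, HLA allele) keys -- the
#' convention under which per-pair presentation counts are reported, where
#' the same nonamer arising from several splice isoforms of a gene counts
#' once per allele. Provenance of merged duplicates is retained.
#'
#' @param records data.frame with at least `peptide` and `allele` columns.
#' @return data.frame of the first record per unique key, with columns
#'   `n_duplicates` (records merged into the row) and a `"provenance"`
#'   attribute mapping `peptide|allele` keys to the row indices merged.
#' @export
deduplicate_complexes <- function(records) {
  if (nrow(records) == 0L) {
    records$n_duplicates <- integer(0)
    return(records)
  }
  key <- paste(records$peptide, records$allele, sep = "|")
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$n_duplicates <- as.integer(table(key)[key[first]])
  attr(out, "provenance") <- split(seq_len(nrow(records)), key)
  rownames(out) <- NULL
  out
}

#' Write the peptide and nonamer library CSVs
#' @param library result of [build_peptide_library()].
#' @param peptide_csv,nonamer_csv output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_peptide_library <- function(library, peptide_csv = NULL, nonamer_csv = NULL) {
  if (!is.null(peptide_csv))
    utils::write.csv(library$peptides, peptide_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(nonamer_csv)) {
    cols <- c("gene", "transcript", "chrom", "pos", "ref", "alt",
              "padded_peptide", "nonamer", "variant_pos")
    utils::write.csv(library$nonamers[, cols], nonamer_csv,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(c(peptide_csv, nonamer_csv))
}
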