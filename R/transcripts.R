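#' Load transcript models from a GFF3 and genome FASTA
#'
#' Builds one transcript model per distinct `transcript_id` from the CDS
#' features of a GFF3 file, splicing the coding sequence out of the genome
#' and translating it with the standard genetic code. Minus-strand
#' transcripts have their segments ordered 3'->5' genomically (5'->3' in
#' transcript orientation) and the spliced sequence reverse-complemented to
#' the sense strand. Models whose total CDS length is not a multiple of 3,
#' or whose translation cannot be computed, are rejected and counted in the
#' attached load report rather than aborting the load.
#'
#' @param gff path to a GFF3 file whose CDS features carry `transcript_id`
#'   (or `Parent`) and `gene_id` attributes.
#' @param genome path to the genome FASTA, or a [Biostrings::DNAStringSet].
#' @return A named list of `transcript_model` objects (see
#'   [transcript_model()]), with a `"load_report"` attribute listing
#'   rejected models.
#' @export
load_transcript_models <- function(gff, genome) {
  gr <- rtracklayer::import(gff)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) stop("no CDS features in ", gff)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  tx_id <- gr$transcript_id
  if (is.null(tx_id)) {
    par <- gr$Parent
    if (is.null(par)) stop("CDS features carry neither transcript_id nor Parent")
    tx_id <- vapply(par, function(p) as.character(p)[1], character(1))
  }
  gene_id <- gr$gene_id
  if (is.null(gene_id)) gene_id <- tx_id

  report <- list()
  models <- list()
  for (tid in unique(tx_id)) {
    idx <- which(tx_id == tid)
    sub <- gr[idx]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    if (!chrom %in% names(genome)) stop("contig '", chrom, "' missing from genome FASTA")
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    o <- order(st)
    segs <- data.frame(chrom = chrom, start = st[o], end = en[o])
    pieces <- Biostrings::DNAStringSet(lapply(seq_len(nrow(segs)), function(i)
      Biostrings::subseq(genome[[chrom]], segs$start[i], segs$end[i])))
    cds <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (strand == "-") {
      cds <- Biostrings::reverseComplement(cds)
      segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]  # 5'->3' in tx orientation
      rownames(segs) <- NULL
    }
    m <- tryCatch(
      transcript_model(transcript_id = tid, gene_id = gene_id[idx][1],
                       strand = strand, cds_segments = segs,
                       cds_sequence = as.character(cds)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(m)) {
      report[[tid]] <- m
    } else {
      models[[tid]] <- m
    }
  }
  structure(models, load_report = report)
}

#' Construct (and validate) a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive genomic coordinates), ordered 5'->3' in transcript
#'   orientation (ascending genomic start on `+`, descending on `-`).
#' @param cds_sequence spliced coding sequence on the sense strand.
#' @return A `transcript_model` list with the fields above plus
#'   `protein_sequence` (terminal stop, if present, not included).
#' @export
transcript_model <- function(transcript_id, gene_id, strand, cds_segments,
                             cds_sequence) {
  stopifnot(strand %in% c("+", "-"))
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  seg_len <- sum(cds_segments$end - cds_segments$start + 1L)
  if (seg_len != n)
    stop("transcript ", transcript_id, ": segment span ", seg_len,
         " != CDS sequence length ", n)
  if (n %% 3L != 0L)
    stop("transcript ", transcript_id, ": CDS length ", n, " not a multiple of 3")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds_sequence),
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
  if (grepl("X", prot, fixed = TRUE))
    stop("transcript ", transcript_id, ": untranslatable codon")
  if (substring(prot, nchar(prot), nchar(prot)) == "*")
    prot <- substring(prot, 1L, nchar(prot) - 1L)
  if (grepl("*", prot, fixed = TRUE))
    stop("transcript ", transcript_id, ": internal stop codon")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 strand = strand, cds_segments = cds_segments,
                 cds_sequence = cds_sequence, protein_sequence = prot),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "(gene", x$gene_id, ") strand", x$strand,
      "\n  CDS:", nchar(x$cds_sequence), "nt in", nrow(x$cds_segments),
      "segment(s); protein:", nchar(x$protein_sequence), "aa\n")
  invisible(x)
}

#' Load transcript models from the simplified tab-separated table dialect
#'
#' Columns: transcript_id, gene_id, strand, chrom, comma-separated CDS
#' segments as `start-end` in transcript orientation, CDS sequence (sense
#' strand). Intended for compact fixtures and round trips.
#'
#' @param path TSV file path.
#' @return named list of `transcript_model` objects, with a `"load_report"`
#'   attribute for rejected rows.
#' @export
load_transcript_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("transcript_id", "gene_id", "strand", "chrom", "segments", "cds_sequence")
  if (!all(needed %in% names(tab)))
    stop("transcript table must have columns: ", paste(needed, collapse = ", "))
  models <- list(); report <- list()
  for (i in seq_len(nrow(tab))) {
    segs <- strsplit(tab$segments[i], ",", fixed = TRUE)[[1]]
    se <- do.call(rbind, strsplit(segs, "-", fixed = TRUE))
    segdf <- data.frame(chrom = tab$chrom[i],
                        start = as.integer(se[, 1]), end = as.integer(se[, 2]))
    m <- tryCatch(
      transcript_model(tab$transcript_id[i], tab$gene_id[i], tab$strand[i],
                       segdf, tab$cds_sequence[i]),
      error = function(e) conditionMessage(e))
    if (is.character(m)) report[[tab$transcript_id[i]]] <- m else models[[tab$transcript_id[i]]] <- m
  }
  structure(models, load_report = report)
}

#' Write transcript models in the simplified table dialect
#' @param models list of `transcript_model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               strand = m$strand, chrom = m$cds_segments$chrom[1],
               segments = paste(paste0(m$cds_segments$start, "-", m$cds_segments$end),
                                collapse = ","),
               cds_sequence = m$cds_sequence, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# genomic position -> 1-based CDS offset (transcript orientation), or NA
cds_offset <- function(model, chrom, pos) {
  segs <- model$cds_segments
  if (segs$chrom[1] != chrom) return(NA_integer_)
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    w <- segs$end[i] - segs$start[i] + 1L
    if (pos >= segs$start[i] && pos <= segs$end[i]) {
      within <- if (model$strand == "+") pos - segs$start[i] + 1L else segs$end[i] - pos + 1L
      return(off + within)
    }
    off <- off + w
  }
  NA_integer_
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate the coding consequence of a SNV on one transcript
#'
#' Maps a genomic SNV to its codon in the transcript's CDS (strand-aware:
#' on minus-strand transcripts the complementary base is substituted),
#' mutates the codon, and translates both codons with the standard genetic
#' code. Returns `NULL` when the position does not fall in any CDS segment
#' of the model.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`, `alt`.
#' @param model a `transcript_model`.
#' @return A `coding_consequence` list with fields `chrom`, `pos`, `ref`,
#'   `alt`, `transcript_id`, `gene_id`, `protein_pos`, `ref_aa`, `alt_aa`,
#'   `synonymous`; or `NULL` if the variant is outside the CDS.
#' @export
annotate_coding_consequence <- function(variant, model) {
  off <- cds_offset(model, variant$chrom, as.integer(variant$pos))
  if (is.na(off)) return(NULL)
  ref_nt <- toupper(variant$ref); alt_nt <- toupper(variant$alt)
  if (model$strand == "-") {
    ref_nt <- COMPLEMENT[[ref_nt]]
    alt_nt <- COMPLEMENT[[alt_nt]]
  }
  have <- substring(model$cds_sequence, off, off)
  if (have != ref_nt)
    stop("reference mismatch at ", variant$chrom, ":", variant$pos,
         " (transcript ", model$transcript_id, "): CDS has ", have,
         ", variant ref (strand-adjusted) is ", ref_nt)
  codon_i <- (off - 1L) %/% 3L          # 0-based codon index
  codon_start <- codon_i * 3L + 1L
  codon <- substring(model$cds_sequence, codon_start, codon_start + 2L)
  within <- off - codon_start + 1L
  mut <- codon
  substring(mut, within, within) <- alt_nt
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                               no.init.codon = TRUE))
  alt_aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                               no.init.codon = TRUE))
  structure(list(chrom = variant$chrom, pos = as.integer(variant$pos),
                 ref = toupper(variant$ref), alt = toupper(variant$alt),
                 transcript_id = model$transcript_id, gene_id = model$gene_id,
                 protein_pos = codon_i + 1L, ref_aa = ref_aa, alt_aa = alt_aa,
                 synonymous = identical(ref_aa, alt_aa)),
            class = "coding_consequence")
}
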