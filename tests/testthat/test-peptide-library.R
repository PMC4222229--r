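test_that("transcript models translate on both strands, across junctions", {
  # plus strand, single exon: ATG AAA TAG -> MK
  m <- toy_model("ATGAAATAG")
  expect_equal(m$protein_sequence, "MK")

  # minus strand: the genome holds the reverse complement
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 10),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGAAATAG"))),
    strrep("T", 10))))
  gff <- tempfile(fileext = ".gff3")
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 19), strand = "-",
                               type = "CDS", transcript_id = "TXM",
                               gene_id = "GM")
  suppressWarnings(rtracklayer::export(gr, gff, format = "gff3"))
  models <- load_transcript_models(gff, genome)
  expect_equal(models$TXM$protein_sequence, "MK")

  # codon split across a two-exon junction, verified by hand splicing
  cds <- "ATGGCCAAATTTGGGTAG"  # MAKFG
  ex1 <- substr(cds, 1, 7); ex2 <- substr(cds, 8, 18)
  genome2 <- Biostrings::DNAStringSet(c(chr2 = paste0(
    strrep("A", 5), ex1, strrep("C", 20), ex2, strrep("A", 5))))
  gr2 <- GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(c(6, 33), c(12, 43)), strand = "+", type = "CDS",
    transcript_id = "TX2", gene_id = "G2")
  gff2 <- tempfile(fileext = ".gff3")
  suppressWarnings(rtracklayer::export(gr2, gff2, format = "gff3"))
  m2 <- load_transcript_models(gff2, genome2)$TX2
  expect_equal(m2$cds_sequence, cds)
  expect_equal(m2$protein_sequence, "MAKFG")
})

test_that("invalid transcript models are rejected with a report, not a crash", {
  expect_error(toy_model("ATGAAAT"), "multiple of 3")
  expect_error(toy_model("ATGTAATAG"), "internal stop")
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tstrand\tchrom\tsegments\tcds_sequence",
               "TGOOD\tG1\t+\tchr1\t11-19\tATGAAATAG",
               "TBAD\tG1\t+\tchr1\t11-17\tATGAAAT"), tab)
  models <- load_transcript_table(tab)
  expect_named(models, "TGOOD")
  expect_match(attr(models, "load_report")$TBAD, "multiple of 3")
})

test_that("coding consequences match codon arithmetic and full-CDS retranslation", {
  m <- toy_model("ATGAAATAG", offset = 11L)  # codon2 = AAA (K) at genomic 14-16
  cons <- annotate_coding_consequence(variant_df("chr1", 14, "A", "C"), m)
  expect_equal(cons[c("protein_pos", "ref_aa", "alt_aa")],
               list(protein_pos = 2L, ref_aa = "K", alt_aa = "Q"))
  expect_false(cons$synonymous)
  cons2 <- annotate_coding_consequence(variant_df("chr1", 16, "A", "G"), m)
  expect_true(cons2$synonymous)
  expect_equal(cons2$alt_aa, "K")
  # outside the CDS -> NULL; wrong reference base -> error
  expect_null(annotate_coding_consequence(variant_df("chr1", 5, "A", "C"), m))
  expect_error(annotate_coding_consequence(variant_df("chr1", 14, "G", "C"), m),
               "reference mismatch")
})

test_that("synonymy labels equal brute-force mutant-CDS retranslation (both strands)", {
  set.seed(11)
  ref <- simulate_reference(simulation_config(seed = 11, n_genes = 6,
                                              minus_strand_fraction = 0.5,
                                              multi_exon_fraction = 0.5))
  genome_chr <- strsplit(as.character(ref$genome[["chr1"]]), "")[[1]]
  checked <- 0L
  for (tid in names(ref$models)) {
    m <- ref$models[[tid]]
    map <- ref$coord_maps[[tid]]
    idxs <- sample(seq_len(length(map) - 3L), 5)
    for (idx in idxs) {
      pos <- map[idx]
      ref_nt <- genome_chr[pos]
      alt_nt <- sample(setdiff(c("A","C","G","T"), ref_nt), 1)
      cons <- annotate_coding_consequence(
        variant_df("chr1", pos, ref_nt, alt_nt), m)
      # oracle: substitute in the full CDS and retranslate the whole protein
      cds <- strsplit(m$cds_sequence, "")[[1]]
      cds[idx] <- if (m$strand == "-") c(A="T",C="G",G="C",T="A")[[alt_nt]] else alt_nt
      prot_mut <- as.character(Biostrings::translate(
        Biostrings::DNAString(paste(cds, collapse = "")),
        no.init.codon = TRUE, if.fuzzy.codon = "X"))
      prot_ref <- paste0(m$protein_sequence, "*")
      expect_equal(cons$synonymous, prot_mut == prot_ref)
      if (!cons$synonymous && cons$alt_aa != "*")
        expect_equal(substring(prot_mut, cons$protein_pos, cons$protein_pos),
                     cons$alt_aa)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 30L)
})

test_that("padded peptides follow the flank-truncation rules", {
  prot30 <- paste(rep("ARNDCQEGHILKMFPSTWYVARNDCQEGHI", 1), collapse = "")
  cds <- paste0("ATG", strrep("GCC", 28), "TAG")  # M + 28 A
  m <- toy_model(cds)
  # mid-protein variant: full 17-mer, variant at offset 9
  cons <- list(chrom = "chr1", pos = 0, ref = "G", alt = "T",
               transcript_id = "TX1", gene_id = "G1",
               protein_pos = 15L, ref_aa = "A", alt_aa = "V", synonymous = FALSE)
  pp <- build_padded_peptide(cons, m)
  expect_equal(nchar(pp$sequence), 17L)
  expect_equal(pp$variant_offset, 9L)
  expect_equal(substring(pp$sequence, 9, 9), "V")
  # N-terminal variant: no left flank
  cons$protein_pos <- 1L; cons$ref_aa <- "M"
  pp1 <- build_padded_peptide(cons, m)
  expect_equal(nchar(pp1$sequence), 9L)
  expect_equal(pp1$variant_offset, 1L)
  # position 5 of a 20-aa protein: 4 + 1 + 8 = 13-mer, matches direct slicing
  cds20 <- paste0("ATG", strrep("TGC", 19), "TAG")
  m20 <- toy_model(cds20)
  cons$protein_pos <- 5L; cons$ref_aa <- "C"
  pp5 <- build_padded_peptide(cons, m20)
  expect_equal(nchar(pp5$sequence), 13L)
  expect_equal(pp5$variant_offset, 5L)
  oracle <- substring(m20$protein_sequence, 1, 13)
  substring(oracle, 5, 5) <- "V"
  expect_equal(pp5$sequence, oracle)
  # synonymous input is a contract violation
  cons$synonymous <- TRUE
  expect_error(build_padded_peptide(cons, m20), "non-synonymous")
  # nonsense substitutions yield no peptide
  cons$synonymous <- FALSE; cons$alt_aa <- "*"
  expect_null(build_padded_peptide(cons, m20))
})

test_that("nonamer windows match the count formula and exhaustive enumeration", {
  mk_pp <- function(L, v) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTWY", "")[[1]], L, TRUE),
               collapse = "")
    structure(list(sequence = s, variant_offset = v), class = "padded_peptide")
  }
  set.seed(3)
  for (L in 9:17) for (v in 1:L) {
    pp <- mk_pp(L, v)
    nm <- enumerate_nonamers(pp)
    expect_equal(nrow(nm), min(v, L - 8L) - max(1L, v - 8L) + 1L,
                 info = sprintf("L=%d v=%d", L, v))
    # exhaustive oracle: all length-9 substrings containing position v
    starts <- 1:(L - 8L)
    oracle <- starts[starts <= v & v <= starts + 8L]
    expect_equal(nm$window_start, oracle)
    expect_equal(nm$nonamer, substring(pp$sequence, oracle, oracle + 8L))
    expect_equal(nm$variant_pos, v - oracle + 1L)
    expect_lte(nrow(nm), 9L)
  }
  # the canonical 17-mer: nine nonamers, variant position descending 9..1
  pp17 <- mk_pp(17, 9)
  expect_equal(enumerate_nonamers(pp17)$variant_pos, 9:1)
  # too-short peptides produce an empty enumeration
  expect_equal(nrow(enumerate_nonamers(mk_pp(9, 1)[c(1, 2)])), 1L)
  pp8 <- structure(list(sequence = "ACDEFGHI", variant_offset = 3L),
                   class = "padded_peptide")
  expect_equal(nrow(enumerate_nonamers(pp8)), 0L)
})

test_that("every emitted nonamer differs from the reference window at one position", {
  ref <- simulate_reference(simulation_config(seed = 5, n_genes = 8))
  pair <- simulate_pair(ref)
  gvh <- compute_directional_set(pair$recipient, pair$donor, "GVH")
  lib <- build_peptide_library(gvh, ref$models)
  expect_gt(nrow(lib$nonamers), 0)
  for (i in seq_len(nrow(lib$nonamers))) {
    row <- lib$nonamers[i, ]
    prot <- ref$models[[row$transcript]]$protein_sequence
    tr_row <- pair$truth[pair$truth$pos == row$pos & pair$truth$alt == row$alt, ]
    refwin <- substring(prot, tr_row$protein_pos - row$variant_pos + 1L,
                        tr_row$protein_pos - row$variant_pos + 9L)
    diffs <- which(strsplit(row$nonamer, "")[[1]] != strsplit(refwin, "")[[1]])
    expect_equal(diffs, row$variant_pos)
  }
  # synonymous truth variants never yield peptides
  syn_pos <- pair$truth$pos[pair$truth$synonymous]
  expect_length(intersect(lib$peptides$pos, syn_pos), 0)
})

test_that("complex deduplication keys on (peptide, allele) and keeps provenance", {
  expect_equal(nrow(deduplicate_complexes(binding_df(numeric(0))[0, ])), 0L)
  recs <- data.frame(peptide = c("AAA", "AAA", "AAA", "BBB"),
                     allele = c("A1", "A1", "A2", "A1"),
                     ic50_nM = c(10, 20, 30, 40), stringsAsFactors = FALSE)
  dd <- deduplicate_complexes(recs)
  expect_equal(nrow(dd), 3L)
  expect_equal(dd$n_duplicates[dd$peptide == "AAA" & dd$allele == "A1"], 2L)
  expect_equal(sort(unname(lengths(attr(dd, "provenance")))), c(1L, 1L, 2L))
  # engineered fixture vs sort-and-scan oracle
  set.seed(9)
  big <- data.frame(peptide = sample(random_peptides(83), 100, replace = TRUE),
                    allele = "A1", stringsAsFactors = FALSE)
  oracle <- sum(!duplicated(paste(sort(paste(big$peptide, big$allele)))))
  expect_equal(nrow(deduplicate_complexes(big)),
               length(unique(paste(big$peptide, big$allele))))
  expect_equal(nrow(deduplicate_complexes(big)), oracle)
})
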