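# in-code fixtures shared across test files

# write a single-sample VCF from (chrom, pos, ref, alt, gt) rows
write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                           sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- vapply(rows, function(r)
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT", r$gt,
          sep = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gt = "0/1") {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt)
}

variant_df <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# a single-exon plus-strand model: CDS starts at genomic position `offset`
toy_model <- function(cds, offset = 11L, tid = "TX1", gene = "G1",
                      strand = "+", chrom = "chr1") {
  transcript_model(tid, gene, strand,
                   data.frame(chrom = chrom, start = offset,
                              end = offset + nchar(cds) - 1L),
                   cds)
}

# uniform-random nonamers
random_peptides <- function(n, width = 9L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, width, replace = TRUE), collapse = ""), character(1))
}

# scoring matrix with every cell zero and a given intercept
flat_matrix <- function(intercept = 0, allele = "HLA-A*01:01") {
  smm_matrix(allele, matrix(0, 9, 20,
                            dimnames = list(NULL, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])),
             intercept)
}

binding_df <- function(ic50, peptide = NULL, allele = "HLA-A*01:01",
                       gene = "G1") {
  n <- length(ic50)
  data.frame(peptide = if (is.null(peptide)) sprintf("PEP%06d", seq_len(n)) else peptide,
             allele = rep_len(allele, n), predictor = rep_len("SMM", n),
             ic50_nM = ic50, gene = rep_len(gene, n),
             stringsAsFactors = FALSE)
}

# strip variant_set attributes for value comparison
plain_vs <- function(x) {
  data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
             stringsAsFactors = FALSE)
}
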