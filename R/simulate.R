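#' Simulation configuration for the synthetic input generator
#'
#' Bundles every knob of the synthetic-data module with defaults chosen to
#' emulate a desk-scale exome comparison with known ground truth: a few
#' dozen compact genes, tens of planted SNVs with a controlled
#' donor/recipient overlap, scoring matrices tuned to realistic
#' presentation rates (about 10% of random nonamers below 500 nM, about 1%
#' below 50 nM), and a 16-tissue lognormal expression table.
#'
#' @param seed integer RNG seed; every generator draws deterministically
#'   from it.
#' @param n_genes number of genes in the synthetic reference.
#' @param transcripts_per_gene isoforms per gene; isoforms beyond the
#'   first are in-frame exon-skipping splice variants of the first.
#' @param cds_length_range two integers, the CDS length range in nt
#'   (rounded to multiples of 3).
#' @param multi_exon_fraction fraction of genes with a two-exon CDS (the
#'   codon may be split across the junction).
#' @param minus_strand_fraction fraction of genes on the minus strand.
#' @param n_recipient_variants,n_donor_variants planted SNV counts.
#' @param shared_fraction fraction of `min(n_recipient, n_donor)` planted
#'   in both samples (these are the variants with neither a GVH nor an
#'   HVG vector).
#' @param fraction_nonsynonymous fraction of planted variants engineered
#'   to change the encoded amino acid. The default 0.75 mirrors the
#'   random-substitution expectation for coding SNVs.
#' @param target_presented_fraction,target_strong_fraction fractions of
#'   random nonamers a simulated scoring matrix should score below
#'   500 nM and 50 nM respectively.
#' @param n_tissues number of tissues in the expression table (up to 16
#'   named body-map-style tissues, then synthetic names).
#' @param expression_meanlog,expression_sdlog lognormal parameters of the
#'   relative-expression-unit draws (default median REU = 10).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 20L,
                              transcripts_per_gene = 1L,
                              cds_length_range = c(150L, 300L),
                              multi_exon_fraction = 0.3,
                              minus_strand_fraction = 0.4,
                              n_recipient_variants = 40L,
                              n_donor_variants = 30L,
                              shared_fraction = 0.5,
                              fraction_nonsynonymous = 0.75,
                              target_presented_fraction = 0.10,
                              target_strong_fraction = 0.01,
                              n_tissues = 16L,
                              expression_meanlog = log(10),
                              expression_sdlog = 1.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              cds_length_range = as.integer(cds_length_range),
              multi_exon_fraction = multi_exon_fraction,
              minus_strand_fraction = minus_strand_fraction,
              n_recipient_variants = as.integer(n_recipient_variants),
              n_donor_variants = as.integer(n_donor_variants),
              shared_fraction = shared_fraction,
              fraction_nonsynonymous = fraction_nonsynonymous,
              target_presented_fraction = target_presented_fraction,
              target_strong_fraction = target_strong_fraction,
              n_tissues = as.integer(n_tissues),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog)
  fr <- c(cfg$shared_fraction, cfg$fraction_nonsynonymous,
          cfg$target_presented_fraction, cfg$target_strong_fraction,
          cfg$multi_exon_fraction, cfg$minus_strand_fraction)
  if (any(fr < 0 | fr > 1)) stop("config fractions must be in [0, 1]")
  if (cfg$target_strong_fraction > cfg$target_presented_fraction)
    stop("target_strong_fraction must not exceed target_presented_fraction")
  if (any(cfg$cds_length_range < 30L)) stop("CDS lengths must be >= 30 nt")
  structure(cfg, class = "simulation_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"), c("T","C","A","G")),
        1, paste, collapse = ""),
  STOP_CODONS)

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# generator-side codon lookup (enumeration table, not the translate() path)
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Simulate a synthetic reference (genome FASTA + GFF3 + protein truth)
#'
#' Places non-overlapping protein-coding genes on one synthetic contig.
#' Each gene's first isoform has a valid CDS (ATG start, stop-free body,
#' terminal stop); a configurable fraction are two-exon (with the splice
#' junction at an arbitrary nucleotide, so codons may span it) and a
#' fraction sit on the minus strand. Additional isoforms skip one
#' in-frame internal block of the first isoform's CDS. All randomness is
#' driven by `config$seed`; two runs with equal configs are identical.
#'
#' @param config a [simulation_config()].
#' @param dir if non-`NULL`, write `genome.fa` and `models.gff3` there.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (named list of `transcript_model`), `proteins` (named character
#'   vector, the truth protein set), `coord_maps` (per transcript, the
#'   integer vector of genomic positions in CDS order -- the generator's
#'   own coordinate bookkeeping), and `paths` when `dir` was given.
#' @export
simulate_reference <- function(config = simulation_config(), dir = NULL) {
  set.seed(config$seed)
  gap <- 120L
  models <- list(); coord_maps <- list(); inserts <- list()
  cursor <- gap
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    lens <- seq(config$cds_length_range[1], config$cds_length_range[2], by = 3L)
    L <- 3L * (lens[sample.int(length(lens), 1)] %/% 3L)
    n_codons <- L %/% 3L
    cds <- paste0("ATG",
                  paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1))
    multi <- stats::runif(1) < config$multi_exon_fraction
    minus <- stats::runif(1) < config$minus_strand_fraction
    strand <- if (minus) "-" else "+"
    if (multi) {
      brk <- sample(seq(10L, L - 10L), 1)        # any nt boundary
      exon_lens <- c(brk, L - brk)
      intron <- rand_dna(sample(30:80, 1))
      region_sense <- paste0(substring(cds, 1, brk), intron,
                             substring(cds, brk + 1, L))
    } else {
      exon_lens <- L
      intron <- ""
      region_sense <- cds
    }
    R <- nchar(region_sense)
    g0 <- cursor                                  # region occupies [g0, g0+R-1]
    # sense position i (1..R) -> genomic coordinate
    sense2gen <- if (minus) g0 + (R - seq_len(R)) else g0 + seq_len(R) - 1L
    tx_sets <- list(seq_len(L))                  # CDS indices kept, isoform 1
    if (config$transcripts_per_gene > 1L && n_codons >= 12L) {
      for (k in 2:config$transcripts_per_gene) {
        # skip one internal in-frame codon block
        skip_from <- sample(2:(n_codons - 6L), 1)
        skip_n <- sample(2:4, 1)
        drop_idx <- ((skip_from - 1L) * 3L + 1L):((skip_from + skip_n - 1L) * 3L)
        tx_sets[[k]] <- setdiff(seq_len(L), drop_idx)
      }
    }
    for (k in seq_along(tx_sets)) {
      keep <- tx_sets[[k]]
      tid <- sprintf("%s.t%d", gene_id, k)
      cds_k <- paste(strsplit(cds, "")[[1]][keep], collapse = "")
      gen_pos <- sense2gen[keep + ifelse(multi & keep > exon_lens[1],
                                         nchar(intron), 0L)]
      # contiguous runs of genomic positions -> CDS segments in tx orientation
      brks <- c(0L, which(diff(gen_pos) != ifelse(minus, -1L, 1L)), length(gen_pos))
      segs_k <- do.call(rbind, lapply(seq_len(length(brks) - 1L), function(i) {
        run <- gen_pos[(brks[i] + 1L):brks[i + 1L]]
        data.frame(chrom = "chr1", start = min(run), end = max(run))
      }))
      models[[tid]] <- transcript_model(tid, gene_id, strand, segs_k, cds_k)
      coord_maps[[tid]] <- gen_pos
    }
    inserts[[length(inserts) + 1L]] <-
      list(at = g0, seq = if (minus)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(region_sense)))
        else region_sense)
    cursor <- g0 + R + gap
  }
  contig_len <- cursor + gap
  contig <- strsplit(rand_dna(contig_len), "")[[1]]
  for (ins in inserts) {
    contig[ins$at:(ins$at + nchar(ins$seq) - 1L)] <- strsplit(ins$seq, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(contig, collapse = ""))
  names(genome) <- "chr1"
  proteins <- vapply(models, function(m) m$protein_sequence, character(1))
  out <- list(genome = genome, models = models, proteins = proteins,
              coord_maps = coord_maps, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa)
    gff_path <- file.path(dir, "models.gff3")
    write_models_gff3(models, gff_path)
    out$paths <- c(genome = fa, gff = gff_path)
  }
  out
}

write_models_gff3 <- function(models, path) {
  grl <- lapply(models, function(m) {
    s <- m$cds_segments
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$end),
                           strand = m$strand, type = "CDS",
                           transcript_id = m$transcript_id,
                           gene_id = m$gene_id)
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

# generator-side consequence of a genomic SNV on one transcript, computed
# from the enumeration coordinate map rather than segment arithmetic
planted_consequence <- function(ref, tid, pos, alt_genomic) {
  m <- ref$models[[tid]]
  map <- ref$coord_maps[[tid]]
  idx <- match(pos, map)
  if (is.na(idx)) return(NULL)
  cds <- strsplit(m$cds_sequence, "")[[1]]
  sense_alt <- if (m$strand == "-") COMPLEMENT[[alt_genomic]] else alt_genomic
  codon_i <- (idx - 1L) %/% 3L
  cod <- paste(cds[(codon_i * 3L + 1L):(codon_i * 3L + 3L)], collapse = "")
  mut <- cod
  substring(mut, idx - codon_i * 3L, idx - codon_i * 3L) <- sense_alt
  list(transcript = tid, gene = m$gene_id, protein_pos = codon_i + 1L,
       ref_aa = codon_aa(cod), alt_aa = codon_aa(mut),
       synonymous = codon_aa(cod) == codon_aa(mut))
}

#' Simulate a donor-recipient variant pair with known ground truth
#'
#' Plants biallelic SNVs in the coding regions of a simulated reference,
#' with a configured number shared between donor and recipient so the true
#' directional sets are known: recipient-only variants carry the GVH
#' vector, donor-only variants the HVG vector. The synonymous /
#' nonsynonymous mix is engineered per `config$fraction_nonsynonymous`
#' (nonsense and stop-loss substitutions are never planted). Writes
#' single-sample VCFs and returns the truth table.
#'
#' @param ref result of [simulate_reference()].
#' @param config a [simulation_config()] (defaults to the one in `ref`).
#' @param dir if non-`NULL`, write `recipient.vcf`, `donor.vcf` and
#'   `truth.csv` there.
#' @return list with `recipient`, `donor` (`variant_set`s), `truth`
#'   (data.frame: chrom, pos, ref, alt, direction in GVH/HVG/shared, and
#'   per-first-isoform consequence columns transcript, gene, protein_pos,
#'   ref_aa, alt_aa, synonymous), and `paths` when `dir` was given.
#' @export
simulate_pair <- function(ref, config = ref$config, dir = NULL) {
  set.seed(config$seed + 1000L)
  n_shared <- round(config$shared_fraction *
                    min(config$n_recipient_variants, config$n_donor_variants))
  n_r_only <- config$n_recipient_variants - n_shared
  n_d_only <- config$n_donor_variants - n_shared
  n_total <- n_shared + n_r_only + n_d_only

  # candidate positions: first-isoform CDS, excluding the terminal stop codon
  first <- grep("\\.t1$", names(ref$models), value = TRUE)
  cand <- do.call(rbind, lapply(first, function(tid) {
    map <- ref$coord_maps[[tid]]
    L <- length(map)
    data.frame(tid = tid, pos = map[seq_len(L - 3L)],
               cds_idx = seq_len(L - 3L), stringsAsFactors = FALSE)
  }))
  if (n_total > nrow(cand))
    stop("requested ", n_total, " variants but only ", nrow(cand),
         " coding positions are available")
  contig <- strsplit(as.character(ref$genome[["chr1"]]), "")[[1]]

  want_nonsyn <- stats::runif(n_total) < config$fraction_nonsynonymous
  rows <- list()
  used <- integer(0)
  i <- 0L
  attempts <- 0L
  while (i < n_total) {
    attempts <- attempts + 1L
    if (attempts > 50L * n_total)
      stop("could not place the requested variant mix; relax the config")
    avail <- setdiff(seq_len(nrow(cand)), used)
    ci <- avail[sample.int(length(avail), 1)]
    tid <- cand$tid[ci]; pos <- cand$pos[ci]
    ref_nt <- contig[pos]
    alts <- setdiff(c("A","C","G","T"), ref_nt)
    effs <- lapply(alts, function(a) planted_consequence(ref, tid, pos, a))
    ok <- vapply(effs, function(e) e$ref_aa != "*" && e$alt_aa != "*", logical(1))
    target_syn <- !want_nonsyn[i + 1L]
    match_cls <- vapply(effs, function(e) e$synonymous, logical(1)) == target_syn
    pick <- which(ok & match_cls)
    if (!length(pick)) next
    j <- pick[sample.int(length(pick), 1)]
    used <- c(used, ci)
    i <- i + 1L
    rows[[i]] <- cbind(data.frame(chrom = "chr1", pos = pos, ref = ref_nt,
                                  alt = alts[j], stringsAsFactors = FALSE),
                       as.data.frame(effs[[j]], stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, rows)
  truth$direction <- rep(c("shared", "GVH", "HVG"),
                         c(n_shared, n_r_only, n_d_only))
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL

  rec_df <- truth[truth$direction %in% c("shared", "GVH"),
                  c("chrom", "pos", "ref", "alt")]
  don_df <- truth[truth$direction %in% c("shared", "HVG"),
                  c("chrom", "pos", "ref", "alt")]
  out <- list(recipient = new_variant_set(rec_df),
              donor = new_variant_set(don_df), truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rv <- file.path(dir, "recipient.vcf")
    dv <- file.path(dir, "donor.vcf")
    tr <- file.path(dir, "truth.csv")
    write_sample_vcf(rec_df, rv, sample = "RECIPIENT")
    write_sample_vcf(don_df, dv, sample = "DONOR")
    utils::write.csv(truth, tr, row.names = FALSE, quote = FALSE)
    out$paths <- c(recipient = rv, donor = dv, truth = tr)
  }
  out
}

# single-sample VCF with heterozygous genotypes
write_sample_vcf <- function(df, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- if (nrow(df)) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".", "GT", "0/1",
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate an HLA scoring matrix tuned to target presentation rates
#'
#' Draws positional cell values at random and solves for a cell scale and
#' intercept such that, over random nonamers, the fraction scoring below
#' 500 nM approximates `target_presented_fraction` and the fraction below
#' 50 nM approximates `target_strong_fraction` (calibrated on a sample of
#' 10,000 uniform-random peptides).
#'
#' @param allele allele name stored in the matrix.
#' @param config a [simulation_config()].
#' @param seed RNG seed for this matrix (default derived from
#'   `config$seed` and the allele name, so different alleles get
#'   different matrices).
#' @param n_calibration calibration sample size.
#' @return an `smm_matrix`.
#' @export
simulate_scoring_matrix <- function(allele, config = simulation_config(),
                                    seed = NULL, n_calibration = 10000L) {
  p_pres <- config$target_presented_fraction
  p_strong <- config$target_strong_fraction
  if (p_strong > p_pres)
    stop("target_strong_fraction must not exceed target_presented_fraction")
  if (is.null(seed))
    seed <- (config$seed + sum(utf8ToInt(allele)) * 131L) %% .Machine$integer.max
  set.seed(seed)
  raw <- matrix(stats::rnorm(9L * 20L, 0, 1), nrow = 9L,
                dimnames = list(NULL, AA_ORDER))
  peps <- matrix(sample.int(20L, 9L * n_calibration, replace = TRUE),
                 ncol = 9L)
  sums <- rowSums(matrix(raw[cbind(rep(1:9, each = n_calibration),
                                   as.vector(peps))],
                         ncol = 9L))
  if (p_pres <= 0) {
    # pin every score far above the presented threshold
    scale <- 0.01; intercept <- log10(50000)
  } else if (p_strong <= 0) {
    scale <- 1
    intercept <- log10(500) - stats::quantile(sums, p_pres, names = FALSE)
  } else {
    q_pres <- stats::quantile(sums, p_pres, names = FALSE)
    q_strong <- stats::quantile(sums, p_strong, names = FALSE)
    scale <- (log10(500) - log10(50)) / (q_pres - q_strong)
    intercept <- log10(500) - scale * q_pres
  }
  smm_matrix(allele, raw * scale, intercept)
}

BODY_MAP_TISSUES <- c("adipose", "adrenal", "brain", "breast", "colon",
                      "heart", "kidney", "liver", "lung", "lymph_node",
                      "ovary", "prostate", "skeletal_muscle", "testis",
                      "thyroid", "white_blood_cells")

#' Simulate a gene-by-tissue expression table
#'
#' Draws i.i.d. lognormal relative expression units per (gene, tissue)
#' under the config's parameters; the default gives a median REU of 10.
#'
#' @param genes character vector of gene identifiers.
#' @param config a [simulation_config()].
#' @return an `expression_table`.
#' @export
simulate_expression <- function(genes, config = simulation_config()) {
  set.seed(config$seed + 2000L)
  tissues <- c(BODY_MAP_TISSUES,
               sprintf("tissue%02d", seq_len(max(0, config$n_tissues - 16L))))
  tissues <- tissues[seq_len(config$n_tissues)]
  vals <- matrix(stats::rlnorm(length(genes) * length(tissues),
                               config$expression_meanlog,
                               config$expression_sdlog),
                 nrow = length(genes), dimnames = list(NULL, tissues))
  tab <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE),
               as.data.frame(vals))
  structure(tab, class = c("expression_table", "data.frame"))
}

#' Emit a complete synthetic input bundle to a directory
#'
#' Generates and writes every pipeline input: genome FASTA, GFF3
#' transcript models, donor and recipient VCFs, one tuned scoring matrix
#' per HLA allele, a gene-by-tissue expression CSV, and the planted-truth
#' table.
#'
#' @param dir output directory.
#' @param config a [simulation_config()].
#' @param alleles HLA class I allele names (default a six-allele A/B/C
#'   genotype).
#' @return list with all file `paths`, the in-memory `ref`, `pair`,
#'   `matrices`, `expression`, and `config`.
#' @export
simulate_bundle <- function(dir, config = simulation_config(),
                            alleles = c("HLA-A*01:01", "HLA-A*02:01",
                                        "HLA-B*07:02", "HLA-B*08:01",
                                        "HLA-C*07:01", "HLA-C*07:02")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config, dir = dir)
  pair <- simulate_pair(ref, config, dir = dir)
  matrices <- lapply(alleles, simulate_scoring_matrix, config = config)
  names(matrices) <- alleles
  mat_paths <- vapply(alleles, function(al) {
    p <- file.path(dir, paste0("matrix_", gsub("[*:]", "", gsub("HLA-", "", al)),
                               ".txt"))
    write_scoring_matrix(matrices[[al]], p)
    p
  }, character(1))
  genes <- unique(vapply(ref$models, function(m) m$gene_id, character(1)))
  expr <- simulate_expression(genes, config)
  expr_path <- file.path(dir, "expression.csv")
  write_expression_table(expr, expr_path)
  list(paths = c(ref$paths, pair$paths, expression = expr_path),
       matrix_paths = mat_paths, ref = ref, pair = pair,
       matrices = matrices, expression = expr, config = config)
}
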