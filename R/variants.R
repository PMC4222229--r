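#' Read single-nucleotide variant calls for one sample from a VCF file
#'
#' Loads a VCF (plain or bgzipped) with \pkg{vcfR} and returns every
#' biallelic SNV record at which the chosen sample carries at least one
#' copy of an ALT allele. Multiallelic sites are decomposed into one
#' variant per ALT allele before genotype membership is tested, so
#' allele-level (not site-level) differences are compared downstream.
#' Non-SNV alleles (indels, MNVs, symbolic or spanning-deletion alleles)
#' are dropped and tallied in the attached load report.
#'
#' "Present" means the genotype string contains the allele index at least
#' once; zygosity is deliberately ignored, since one coding copy suffices
#' to encode a variant peptide. Missing genotypes (`./.`) count as absent
#' by default; with `missing_as_unknown = TRUE` such sites are excluded
#' entirely so they can be removed from *both* sides of a pair comparison.
#'
#' @param path path to a VCF 4.x file.
#' @param sample sample name. May be omitted for single-sample files.
#' @param missing_as_unknown if `TRUE`, sites with a missing genotype are
#'   excluded rather than treated as ALT-absent.
#' @return A `variant_set`: data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt` (one row per variant, unique on the 4-tuple), plus a
#'   `"load_report"` attribute counting records seen, non-SNV alleles
#'   dropped, ALT-absent sites excluded, and missing genotypes.
#' @export
read_variant_calls <- function(path, sample = NULL, missing_as_unknown = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    return(new_variant_set(report = load_report(0L, 0L, 0L, 0L)))
  }

  gt_avail <- !is.null(vcf@gt) && ncol(vcf@gt) >= 2L
  if (gt_avail) {
    samples <- colnames(vcf@gt)[-1L]
    if (is.null(sample)) {
      if (length(samples) != 1L)
        stop("multi-sample VCF: specify `sample` (available: ",
             paste(samples, collapse = ", "), ")")
      sample <- samples[1L]
    } else if (!sample %in% samples) {
      stop("unknown sample '", sample, "' (available: ",
           paste(samples, collapse = ", "), ")")
    }
    gt_raw <- vcf@gt[, sample]
    fmt <- vcf@gt[, 1L]
    gt <- vapply(seq_len(n_rec), function(i) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      vals <- strsplit(gt_raw[i], ":", fixed = TRUE)[[1]]
      k <- match("GT", keys)
      if (is.na(k) || k > length(vals)) NA_character_ else vals[k]
    }, character(1))
  } else {
    # sites-only VCF: every record is taken as present for its nominal sample
    gt <- rep("1/1", n_rec)
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]

  nt <- c("A", "C", "G", "T")
  out <- vector("list", n_rec)
  n_nonsnv <- 0L; n_absent <- 0L; n_missing <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    g <- gt[i]
    miss <- is.na(g) || g %in% c(".", "./.", ".|.")
    if (miss) {
      n_missing <- n_missing + 1L
      next  # absent under both policies; report distinguishes them
    }
    idx <- strsplit(g, "[/|]")[[1]]
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (!(ref[i] %in% nt) || !(a %in% nt)) {
        n_nonsnv <- n_nonsnv + 1L
        next
      }
      if (as.character(j) %in% idx) {
        out[[i]] <- rbind(out[[i]],
                          data.frame(chrom = chrom[i], pos = pos[i],
                                     ref = ref[i], alt = a,
                                     stringsAsFactors = FALSE))
      } else {
        n_absent <- n_absent + 1L
      }
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  vs <- new_variant_set(df, report = load_report(n_rec, n_nonsnv, n_absent, n_missing,
                                                 missing_excluded = missing_as_unknown))
  attr(vs, "missing_sites") <- if (missing_as_unknown) {
    miss_idx <- which(is.na(gt) | gt %in% c(".", "./.", ".|."))
    unique(paste0(chrom[miss_idx], ":", pos[miss_idx]))
  } else character(0)
  vs
}

load_report <- function(n_records, n_nonsnv, n_alt_absent, n_missing_gt,
                        missing_excluded = FALSE) {
  list(n_records = n_records, n_nonsnv_dropped = n_nonsnv,
       n_alt_absent = n_alt_absent, n_missing_gt = n_missing_gt,
       missing_excluded = missing_excluded)
}

new_variant_set <- function(df = NULL, report = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
  }
  df <- unique(df[, c("chrom", "pos", "ref", "alt")])
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("variant_set", "data.frame"), load_report = report)
}

variant_key <- function(vs) paste(vs$chrom, vs$pos, vs$ref, vs$alt, sep = "\r")

#' Directional variant set between a recipient and a donor
#'
#' Computes the set difference of two SNV sets in the transplant-relevant
#' direction: `"GVH"` (graft-versus-host) keeps variants present in the
#' recipient and absent from the donor -- the direction in which donor T
#' cells can recognize recipient tissue; `"HVG"` (host-versus-graft) keeps
#' variants present in the donor and absent from the recipient. Identity is
#' the exact tuple (chrom, pos, ref, alt); the result is order-independent
#' and deduplicated.
#'
#' When either input carries excluded missing-genotype sites (from
#' `read_variant_calls(..., missing_as_unknown = TRUE)`), those sites are
#' removed from the output as well, so that no direction call rests on an
#' uncalled genotype.
#'
#' @param recipient,donor `variant_set` objects (or data.frames with
#'   `chrom`, `pos`, `ref`, `alt` columns).
#' @param direction `"GVH"` or `"HVG"`.
#' @param recipient_id,donor_id optional sample identifiers carried in the result.
#' @return A `directional_variant_set`: a `variant_set` with attributes
#'   `direction`, `recipient_id`, `donor_id`.
#' @export
compute_directional_set <- function(recipient, donor,
                                    direction = c("GVH", "HVG"),
                                    recipient_id = NA_character_,
                                    donor_id = NA_character_) {
  direction <- match.arg(direction)
  recipient <- as_variant_set(recipient)
  donor <- as_variant_set(donor)
  if (direction == "GVH") {
    keep <- !(variant_key(recipient) %in% variant_key(donor))
    res <- recipient[keep, , drop = FALSE]
  } else {
    keep <- !(variant_key(donor) %in% variant_key(recipient))
    res <- donor[keep, , drop = FALSE]
  }
  excl <- union(attr(recipient, "missing_sites"), attr(donor, "missing_sites"))
  if (length(excl)) {
    res <- res[!(paste0(res$chrom, ":", res$pos) %in% excl), , drop = FALSE]
  }
  out <- new_variant_set(res)
  attr(out, "direction") <- direction
  attr(out, "recipient_id") <- recipient_id
  attr(out, "donor_id") <- donor_id
  class(out) <- c("directional_variant_set", class(out))
  out
}

as_variant_set <- function(x) {
  if (inherits(x, "variant_set")) return(x)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  ms <- attr(x, "missing_sites")
  out <- new_variant_set(as.data.frame(x))
  attr(out, "missing_sites") <- ms
  out
}

#' Write a variant set as a minimal VCF or CSV
#'
#' The VCF output carries CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO only
#' (no genotypes); the CSV output has header `chrom,pos,ref,alt`.
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @param format `"vcf"` or `"csv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_variant_set <- function(vs, path, format = NULL) {
  vs <- as_variant_set(vs)
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "vcf"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(vs)[, c("chrom", "pos", "ref", "alt")],
                     path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(vs)) {
      paste(vs$chrom, vs$pos, ".", vs$ref, vs$alt, ".", ".", ".", sep = "\t")
    } else character(0)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
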