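---
title: "Methods: from donor–recipient exomes to HLA-specific alloreactivity potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from donor–recipient exomes to HLA-specific alloreactivity potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopotential)
```

## The model

`allopotential` treats alloreactivity in HLA-matched stem-cell
transplantation as a quantifiable library of candidate minor
histocompatibility antigens (mHA). The chain of assumptions is:

1. Antigenic differences between donor and recipient reduce, at the
   level this pipeline models, to biallelic coding SNVs. A variant
   "present" in a sample means its genotype carries at least one ALT
   copy; zygosity is ignored because a single coding copy suffices to
   encode a variant peptide.
2. The clinically relevant direction is **graft-versus-host (GVH)**:
   variants present in the recipient and absent in the donor, i.e. the
   set difference recipient ∖ donor on the exact (chrom, pos, ref, alt)
   tuple. The reverse difference is the host-versus-graft (rejection)
   vector. Multiallelic sites are decomposed first so comparison is
   allele-level.
3. Each nonsynonymous GVH variant is expanded into all HLA class I
   candidate epitopes containing it: the canonical presented peptide is
   a 9-mer, so the padded peptide takes up to 8 reference residues on
   each side of the substituted one (a 17-mer mid-protein; truncated at
   the termini), and every 9-residue window containing the variant is
   enumerated — `min(v, L−8) − max(1, v−8) + 1` windows for length `L`
   and variant offset `v`, at most nine.
4. Presentation is predicted, not measured. The built-in scorer is an
   additive position-specific matrix in log10(IC50 nM) — the stabilized
   matrix method convention — with classes *presented* (IC50 < 500 nM)
   and *strongly presented* (< 50 nM). A second, pan-specific predictor
   enters only through its captured tabular output; a (peptide, allele)
   complex under 500 nM by **both** predictors is *shared*.
5. Per-pair burden is summarized by the **alloreactivity potential**:
   peptide–HLA records with IC50 ≤ 100 nM, all six alleles pooled, are
   sorted by ascending IC50, a quadratic `f(x) = c₂x² + c₁x + c₀` is
   fitted to IC50 against rank by OLS, and the definite integral
   ∫ₐᵇ f(x) dx is evaluated in closed form with `a = 1`, `b = N`. The
   unit is nM·Peptide.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| presented threshold | 500 | nM IC50 | intermediate-affinity binding cutoff in common predictor usage |
| strong threshold | 50 | nM IC50 | high-affinity binding |
| AUC cutoff | 100 | nM IC50 | restricts the potential to the high-affinity tail that plausibly drives T-cell responses |
| flank width | 8 | residues | covers every 9-mer containing the variant |
| REU threshold | 10 | relative expression units | strict `> 10` defines "expressed in tissue" |
| IC50 clip | [0.01, 50000] | nM | prevents degenerate statistics from extreme matrix sums |

All thresholds are strict (`<`); a value at a boundary falls to the weaker
class. Comparisons tolerate a 1e-9 *relative* float slack at the boundary
so that, e.g., an intercept of exactly log10(500) classifies as the
boundary value 500 rather than tipping on one ulp of `10^x` round-off.

## Numerical and design choices

**Integration axis.** The integral is taken over peptide *rank*
(x = 1…N), not over IC50. Describing the bounds as the strongest binder
and the affinity cutoff is only coherent with the reported unit
(nM·Peptide) and with rank-curve plots when those bounds are mapped onto
the rank axis; integrating over IC50 would produce Peptide·nM of a
different magnitude and shape. This was a genuinely open reading and is
resolved here as a design decision.

**Duplicates.** Counts of presented/strongly presented complexes are
reported over unique (peptide sequence, allele) keys — the same nonamer
arising from several splice isoforms counts once per allele — while the
AUC retains duplicates, reflecting that each transcript context
contributes a presentable molecule. Both behaviors sit behind flags
(`dedup_counts`, `auc_dedup`).

**Degenerate inputs.** An empty rank series yields AUC 0. One or two
points cannot constrain a quadratic; the trapezoid area of the raw series
is reported with a `fallback` flag. A constant series fits (0, 0, c)
exactly, so AUC = c·(N−1), identical to the trapezoid value. Ties in the
rank sort are broken by peptide then allele lexicographically so every
run is byte-reproducible.

**Nonsense variants.** A substitution creating a stop, or removing the
reference stop, has no single substituted residue to center a peptide on;
such variants are excluded from peptide generation and logged. Only the
standard genetic code is supported, applied uniformly (no
initiator-codon special-casing), so codon arithmetic and whole-CDS
retranslation agree.

**Exact Mann–Whitney.** U is the pairwise count #(a > b) + ½·#(a = b).
For combined samples up to 20 with no ties the null distribution is built
by complete enumeration of all C(nA+nB, nA) labelings, and the two-sided
p doubles the smaller tail, capped at 1 — at sizes 4 vs 5 complete
separation gives exactly 2/126 ≈ 0.016. Larger or tied samples use the
tie-corrected normal approximation without continuity correction, flagged
in the result. The enumeration is the package's own; `wilcox.test` serves
as an independent cross-check in the test suite.

**Medians** use the standard order-statistic convention (middle value for
odd n), which is what the packaged nine-pair reference table requires.

**Pearson correlation** between predictors is computed on raw nM by
default, with a log10 option; affinities are log-distributed, so the log
scale is usually more informative, but raw nM is the conservative default
absent a stated transform.

**Missing genotypes** (`./.`) count as absent by default — the pipeline
has no abstention mechanism — with `missing_as_unknown = TRUE` excluding
such sites from both sides of the comparison instead.

## What the simulator emulates — and what it does not

`simulate_reference`/`simulate_pair`/`simulate_scoring_matrix`/
`simulate_expression` generate every pipeline input with known truth:

- compact genes (default 20 genes, CDS 150–300 nt) on one contig, 30%
  two-exon (junctions at arbitrary nucleotides, so codons can span them),
  40% minus-strand; optional in-frame exon-skipping isoforms;
- 40 recipient and 30 donor SNVs with half of the smaller set shared, so
  the true GVH set (25 variants) is known by construction; 75% of planted
  substitutions are nonsynonymous, mirroring the random-substitution
  expectation for coding SNVs; nonsense changes are never planted;
- scoring matrices with N(0,1) cells rescaled and shifted so ~10% of
  random nonamers fall under 500 nM and ~1% under 50 nM (calibrated on
  10,000 random peptides) — rates chosen as realistic for class I
  presentation;
- lognormal expression with median REU 10 across 16 body-map-style
  tissues.

These scales keep the complete test suite near a minute on one CPU; they
are deliberately desk-scale. The simulator does **not** emulate human
allele-frequency or linkage structure, exome-wide variant density
(thousands of nsSNVs per pair), sequencing or variant-calling error,
proteasomal cleavage or TAP transport, or real per-allele binding
chemistry. Passing the recovery tests therefore demonstrates the
pipeline's bookkeeping is exact (directional sets, coordinate/strand
arithmetic, window enumeration, classification and counting), not that
predictions on real exomes are accurate — prediction accuracy is a
property of the scoring matrices supplied, which this package treats as
inputs.

The per-pair count table of the published nine-pair cohort is shipped as
a data fixture; the cohort medians, ranges and exact Mann–Whitney
p-values in the test suite and acceptance script are recomputed from it
at run time.

## Known limitations

- SNVs only: indels, MNVs and frameshifts are dropped at load (counted in
  the load report); splice-site and UTR effects are out of scope.
- HLA class I, 9-mers only; class II presentation and other peptide
  lengths are not modeled.
- Numeric equivalence with any particular historical predictor release is
  not attempted; the matrix dialect fixes the scoring contract instead.
- The expression join is transcript-level relative expression, not
  protein abundance; the question of whether molar abundance or binding
  affinity dominates presentation is discussed in the field but not
  computed here.
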