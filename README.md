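# allopotential

Quantifying the HLA-specific alloreactivity potential of a stem-cell
transplant donor–recipient pair from exome variant calls.

## The problem

In HLA-matched allogeneic stem-cell transplantation, graft-versus-host
disease is driven largely by **minor histocompatibility antigens (mHA)**:
peptides encoded outside the MHC locus that differ between donor and
recipient and are presented by the patient's HLA class I molecules to donor
T cells. `allopotential` implements the full *in silico* pipeline from
paired variant calls to a per-pair summary of this antigenic burden, for
transplant immunologists and computational biologists who want to reproduce
or extend this style of analysis:

1. **Directional variant sets.** Nonsynonymous SNVs present in the
   recipient and absent in the donor carry the graft-versus-host (GVH)
   vector (`compute_directional_set`); the reverse direction (HVG) is the
   graft-rejection vector.
2. **Candidate mHA enumeration.** Each GVH variant is mapped onto
   transcript models, classified synonymous/nonsynonymous, and expanded
   into a variant-centered padded peptide of up to 17 residues (8-residue
   flanks). Sliding a 9-mer window over it yields up to nine nonamers, the
   variant occupying positions 9 down to 1.
3. **Peptide–HLA binding.** Each nonamer is scored against the patient's
   up-to-six HLA class I alleles with an additive log10(IC50) scoring
   matrix (the stabilized-matrix-method convention): IC50(p) =
   10^(b + Σᵢ M[i, pᵢ]) nM. Peptides with IC50 < 500 nM are *presented*,
   < 50 nM *strongly presented* (strict thresholds). Captured output of a
   pan-specific predictor can be merged to form *shared* complexes —
   (peptide, allele) pairs under 500 nM by both predictors.
4. **Summary statistics.** Per-pair counts of unique presented complexes;
   the **alloreactivity potential**: peptides with IC50 ≤ 100 nM are
   ranked by ascending IC50, a second-order polynomial f(x) is fitted to
   IC50 versus rank, and the closed-form definite integral ∫₁ᴺ f(x) dx
   gives an area-under-curve in nM·Peptide; the expression-weighted
   potential Σ Re·(1/IC50); a power-law fit of the affinity rank curve;
   and exact Mann–Whitney U comparisons (complete enumeration of
   labelings) between matched-related (MRD) and unrelated (URD) donor
   groups.

A seeded synthetic-data module (`simulate_bundle`) generates every input —
genome FASTA, GFF3 transcript models, donor/recipient VCFs, tuned scoring
matrices, gene-by-tissue expression — with known ground truth, so the whole
pipeline is testable offline.

## Worked example

The package ships the per-pair count table of a published nine-pair cohort
(`reference_pair_counts()`). Summarizing it:

```r
library(allopotential)
s <- summarize_counts(reference_pair_counts())
s$aggregates
#          statistic median  min   max
# 2    smm_presented  18396 1926 72294
# 3       smm_strong   2254  177 21548
# 4    pan_presented   3962  787  7242
# 5       pan_strong    989  118  2509
# 6 shared_presented   2065  417  4881
s$comparisons
#          statistic group_a group_b u p_two_sided method
# 2    smm_presented     MRD     URD 0  0.01587302  exact
# 4    pan_presented     MRD     URD 2  0.06349206  exact
# 5       pan_strong     MRD     URD 3  0.11111111  exact
```

A median of 18,396 peptide–HLA complexes per pair is predicted presented by
the matrix scorer (2,254 strongly), and unrelated donors carry significantly
more presented peptides than matched related donors (exact two-sided
P = 0.016 from complete enumeration of the 126 group labelings).

An end-to-end run on a synthetic bundle:

```r
d <- tempfile()
bundle <- simulate_bundle(d, simulation_config(seed = 1))
cfg <- pipeline_config(
  recipient_vcf = bundle$pair$paths[["recipient"]],
  donor_vcf     = bundle$pair$paths[["donor"]],
  gff           = bundle$ref$paths[["gff"]],
  genome        = bundle$ref$paths[["genome"]],
  matrix_paths  = bundle$matrix_paths,
  expression_csv = file.path(d, "expression.csv"))
res <- run_pipeline(cfg, file.path(d, "run"))
res$counts
# $smm_presented
# [1] 109
# $smm_strong
# [1] 12
res$auc
# alloreactivity potential: 1,824.324 nM*Peptide over 34 peptide-HLA records (IC50 <= 100 nM)
#   quadratic fit c2 = -0.0403  c1 = 3.994  c0 = 1.383  rmse = 5.329
```

Here 25 GVH-vector variants (planted by the simulator) yield 18
nonsynonymous padded peptides, 109 unique presented peptide–HLA complexes
across six alleles, and an alloreactivity potential of about 1,824
nM·Peptide. The run directory contains one CSV per stage plus
`summary.json`.

A thin command-line wrapper lives at `inst/scripts/allopotential-cli.R`
(subcommands `simulate`, `gvh-call`, `run`).

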