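---
title: "Methods: screening gene neighborhoods for ERV-like ORFs"
author: "ervscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening gene neighborhoods for ERV-like ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Endogenous retroviruses (ERVs) are retroviral sequences fixed in host
genomes. Most copies are degenerate and silent, but loci in
transcriptionally active chromatin can be reactivated, for example under
hypoxia. `ervscan` implements a desk-scale screen for such loci: genes
induced by a hypoxia-mimetic treatment (cobalt chloride in a neuroblastoma
cell model) mark active chromatin neighborhoods, and the 2 Mbp around each
induced gene is searched for long open reading frames whose translation
resembles retroviral proteins — the signature of an env gene that has kept
its coding capacity, as the syncytin loci have.

The chain has five stages, each usable on its own:

1. **Up-regulation calling** (`call_upregulated`). Inputs are processed
   linear intensities (RMA-normalized microarray values); low-level array
   processing is out of scope. A gene is called in a treated condition when,
   in *every* replicate, treated/control fold change is at least 3 **and**
   the treated signal exceeds 100. Conditions (100 and 200 uM doses) are
   analyzed separately; the candidate set is the union, with per-condition
   membership retained (`combine_conditions`).
2. **Neighborhood extraction** (`make_window`, `extract_sequence`): the gene
   body flanked by 1 Mbp on each side, clamped to the chromosome.
3. **ORF scanning** (`find_orfs`): all six frames, runs of codons free of
   TAA/TAG/TGA, minimum 1,000 nt.
4. **Homology scoring** (`search_homology`): exact Smith–Waterman local
   alignment of each translated ORF against a user-supplied protein database
   (for real runs, the proteins of the retro-transcribing viruses), with
   Karlin–Altschul E-values and a two-tier call: E below 10 is reported,
   E at or below 0.01 is *convincing*.
5. **qPCR quantification** (`relative_expression`): the 2^-ddCt method with
   a housekeeping reference and the median sample as calibrator.

## Design choices where the procedure was open

Several conventions are not fully pinned down by the screening recipe; the
package fixes them as follows, each switchable.

* **Which sample the intensity floor applies to.** "Signal intensities above
  100" could mean treated, control, or both. Default: the **treated** sample,
  because an up-regulation call should rest on a reliably detected treated
  signal; `filter_config(intensity_on=)` selects `"control"` or `"both"`.
  Fold comparison is non-strict (`>= 3`), intensity strict (`> 100`).
* **Replicate concordance** is evaluated within each dose separately
  ("found in both replications" of the two-replicate design), then pooled
  across doses as a union.
* **Zero-control folds** return `+Inf` (or use `pseudo_count > 0`); RMA
  linear values are strictly positive in practice, so the default
  pseudo-count is 0.
* **"The 2 Mbp surrounding each gene"** anchors on the gene body: 1 Mbp
  flank per side, total window = gene length + 2 Mbp, clamped. A
  `"centered"` mode (2 Mbp centered on the gene midpoint) is available since
  the phrase also admits that reading. Windows of nearby genes are *not*
  merged — each gene is scanned independently, matching per-gene ORF
  reporting.
* **ORF convention.** Default `between_stops`: maximal stop-free codon runs,
  the conventional output of classic ORF finders; the 1 kb minimum applies
  to the coding run *excluding* flanking stops, with `>=` as the comparison
  (`min_len_op = "gt"` for strictly greater). Runs truncated by window ends
  are included by default. `start_to_stop` mode (first ATG to closing stop)
  is provided because the original tool's setting is not recorded; reported
  ORF counts depend on this choice. Codons containing N never terminate a
  run and translate to `X`.
* **Coordinates** are 0-based half-open internally; GFF3 is converted on
  input; the outfmt-6-style hits table is 1-based inclusive for
  compatibility.

## Alignment statistics

BLASTP's heuristics (word seeding, two-hit extension, composition-based
statistics) are deliberately not reproduced. At the scale of this screen —
tens to hundreds of ORFs against a curated protein set — exact
Smith–Waterman alignment (Gotoh algorithm, affine gaps, C++ kernel) is
feasible and strictly more sensitive, and the E-value tiers keep their
meaning. Scoring defaults are BLOSUM62 with gap open 11 and extension 1 (a
gap of length *g* costs 11 + *g*); the Karlin–Altschul parameters are the
standard published gapped values for that combination, lambda = 0.267,
K = 0.041, both overridable. E-values use raw query and database lengths:
the effective-length edge correction is omitted as second-order at these
lengths, which biases E slightly upward (conservative — the calibration
check in the acceptance suite observes about 0.85–0.9 of the nominal hit
count at E <= 1, within the expected band). Traceback ties break
diagonal > gap-in-query > gap-in-subject, so reported spans are
reproducible. Score-0 pairs produce no hit.

## The synthetic-data module

The generators reproduce the study's design so the whole chain runs with no
downloads; their defaults are the study conditions, not tuning knobs.

* **Expression** (`sim_expression`): 1,000 genes, 2 replicates x 3
  conditions, 5 planted genes at fold 5, multiplicative log-normal noise
  sigma = 0.1. Baselines are log-normal with median 500; the spread
  (sdlog = 0.5, roughly a 10-fold interquartile-ish range) was chosen once
  as typical of RMA linear intensities.
* **Genome** (`sim_genome`): i.i.d. background at GC 0.41 (human-like), two
  annotated 20 kb genes per 4.4 Mbp chromosome at the 1/4 and 3/4 points, so
  neighboring 2 Mbp windows are disjoint and a planted hit can be attributed
  to exactly one window. Plants are realized by mutating the bundled
  synthetic 540-residue seed protein (`mutate_protein`, per-residue
  substitution), reverse-translating with uniform synonymous codons, and
  bracketing with in-frame stops, so the planted coding region is a maximal
  ORF recoverable at exact coordinates on either strand. The preset
  (`sim_dataset`) plants one env-like ORF of 1,602 nt at divergence 0.2 on
  the minus strand and one random-protein decoy, and ships a fixture
  database of the seed protein plus three residue shuffles.
* **Ct tables** (`sim_ct`): groups control/low/high at true folds 1/2/4
  (a plausible dose response for a hypoxia-induced target), Ct noise
  sigma = 0.1 cycles, reference Ct fixed at 18 so noiseless tables recover
  folds exactly.
* **Randomness**: every generator is a pure function of one seed;
  per-component child seeds are derived with a fixed integer recurrence
  (`child_seed`), recorded in `truth.json`.

What the simulation does **not** emulate: repeat landscapes and LTR
structure, codon-usage bias, realistic gene density, probe-level microarray
artifacts, or amplification-efficiency variation in qPCR. Passing the
planted-recovery checks therefore demonstrates the correctness of the
chain's logic and statistics, not performance on real genomes, where
segmental duplications and very gene-dense regions (overlapping windows)
will behave differently.

## Numerical and degenerate-input conventions

* Fold change with 0/0 is defined as 1; x/0 with x > 0 as `+Inf`.
* Technical qPCR replicates are averaged on the Ct scale before dCt; the
  median over samples uses the midpoint convention for even counts, so the
  median of log2 relative expression is exactly 0 (and the median relative
  expression is exactly 1 for odd counts).
* Amplification efficiency is fixed at 2.0 (plain 2^-ddCt).
* Windows of length 0 and empty sequences are rejected; empty ORF sets and
  empty hit tables are valid stage outputs, and an empty candidate set
  yields a complete, valid report.
* Residues outside the substitution matrix score the matrix minimum against
  everything.

## Problem sizes

The test and acceptance runs use the sizes above: 1,000-gene matrices over
10 seeds for filter recovery; 500 random pairs of length <= 30 against an
exhaustive affine-gap oracle; 100 random 10 kb sequences against an
independent stop-codon tokenizer; ten full simulations (three 4.4 Mbp
chromosomes each) for end-to-end planted recovery; 50 x 400-residue decoy
queries against a 5,400-residue shuffled database for E-value calibration.

## Known limitations

* Real-run headline counts (candidate genes from the deposited microarray
  series, per-gene ORF counts on a human assembly) require user-supplied
  external data and matched window/ORF conventions; the package is
  assembly-agnostic and ships no third-party sequence data.
* The search is all-vs-all exact alignment: appropriate for small curated
  databases, not a replacement for indexed heuristics on proteome-scale
  subjects.
* One locus per gene id (the longest feature) — no transcript-isoform
  resolution, no liftover.
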