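---
title: "Scoring and classifying variants from complementation-selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying variants from complementation-selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcscreen)
```

## The experiment this package models

A selection-based deep mutational scan expresses a library of ORF variants —
here generated by error-prone PCR — in a yeast strain whose own essential
gene has been removed, so that only cells carrying a functional human variant
grow once the rescue plasmid is counter-selected. Sequencing the variant
amplicon before and after selection turns the growth phenotype of thousands
of variants into frequency shifts. The package covers everything downstream
of variant counting: it deliberately starts at per-sample SNV count tables
(read trimming and alignment belong to standard external tools) and ends at
per-variant functional calls and concordance reports.

## Enumeration and coding outcomes

`enumerate_snvs()` lists all 3L substitutions of an L-nt ORF with their
consequence under the standard genetic code. Two conventions matter:

* **Coordinates** are 1-based CDS positions and 1-based codon indices, the
  convention in which clinical variant tables are written.
* **The ORF carries no stop codon.** In this screen design the terminal stop
  is supplied by the vector, so the mutagenized sequence must be stop-free
  and *stop-loss is not a possible consequence*; `orf_sequence()` rejects any
  internal stop.

SNVs collapse into *unique coding outcomes* keyed by `(codon, alternate
amino acid | stop | synonymous)`. Synonymous changes are keyed per codon —
one outcome per codon, not per resulting codon — which is what makes
outcomes reachable by 2–4 SNVs (the standard-code degeneracy bound; the test
suite checks that no outcome ever exceeds 4 members). Enumeration order is
by position, then alternate base in A<C<G<T order, chosen once so that
outputs diff stably across runs.

## Scoring

Per sample, an SNV's frequency is `count / coverage` at its position. The
complementation score of an outcome is

$$\mathrm{RCS} = \log_2 \frac{\bar f_{\text{after}}}{\bar f_{\text{before}}}$$

with unweighted means across the selected and unselected replicates
respectively. Two numerical choices are deliberate:

* **Pseudocount (default 0.5 reads).** Selection can drive a variant's
  post-selection count to exactly zero, where the log ratio diverges. We add
  a Haldane-style continuity correction of 0.5 reads to every SNV in every
  sample before dividing by coverage, keeping every library-present SNV
  scorable; `pseudocount = 0` disables it. The correction perturbs scores by
  `O(1/count)` and the scale-invariance test verifies it vanishes as counts
  grow. An SNV with zero raw reads in *all* pre-selection replicates is a
  different situation — it was never in the library — and is flagged
  `missing_in_library` and left unscored rather than pseudocounted into a
  fake score.
* **Aggregation order.** For multi-SNV outcomes we average member
  frequencies first and take one log2, rather than averaging member scores.
  Averaging frequencies weights members by their (shared) coverage structure
  and keeps the outcome score between the member extremes; the alternative
  (`member_stat = "rcs"`) is available and logged in the output metadata.

## The classifier

Internal controls replace external gold standards: premature stops in
codons 1–500 are presumed damaging and synonymous changes in the same span
presumed tolerated. Stops in the last 43 codons are excluded because late
truncation does not impair complementation in this assay — the
`stop_position_contrast()` analysis reproduces that contrast on simulated
data. On these controls `rcs_fit()` fits a one-feature logistic regression
of damaging status on RCS; the decision threshold is the score where the
fitted probability crosses 0.5.

* **Separation handling.** A clean screen separates the control classes
  completely, where the logistic MLE diverges. We minimize the penalized
  negative log-likelihood with a ridge term (default `1e-6`, essentially
  zero for non-separated data — the test suite checks agreement with `glm()`
  there) so coefficients stay finite and the threshold lands between the
  clusters. The fit is deterministic: BFGS from a fixed origin with an
  analytic gradient.
* **Training level.** The model trains on outcome-level scores by default
  (each codon change is one observation, matching how calls are reported);
  SNV-level training is available via `level = "snv"`.
* **No intermediate class.** The screen measures growth rescue and cannot
  resolve intermediate function; probabilities near 0.5 are reported as-is
  and the binary label follows the 0.5 cut exactly.

`evaluate_classifier()` reports the confusion matrix, accuracy, an ROC swept
over the fitted probabilities (ties move along diagonal segments) and the
trapezoid AUC.

## The simulator: what it emulates, and what it does not

`simulate_screen()` exists so the scoring and classification path can be
validated end to end against known truth. Its defaults are the conditions of
the screen it emulates:

| parameter | default | meaning |
|---|---|---|
| `mu` | 0.86/1,000 nt | EP-PCR SNV rate; ≈1.4 SNVs per 1,629-nt clone |
| `epsilon` | 0.097/1,000 nt | background error rate outside mutagenesis |
| `n_clones` | 62,000 | transformant pool size |
| `n_before`, `n_after` | 2, 4 | library aliquots / independent screens |
| `read_equivalents` | 2.5×10⁶ | per-sample sequencing depth |
| `selected_pool` | 28,000 | colonies surviving each selection |
| `damaging_fraction` | 0.242 | ground-truth damaging missense fraction |

Per-clone variant counts are Poisson — the screen reports only a mean
burden, and Poisson is the maximum-entropy choice for independent
mutagenesis events. The substitution spectrum is ordinal (G>A weighted up,
T>G and G>C down, others uniform) because only the rank order of classes is
known; all 12 weights are configurable. Background errors are independent
per-read-base events, not clone-borne, mirroring their observation outside
the mutagenized region. Selection is `hard` (a clone dies iff it carries any
damaging variant) or `soft` (survival = product of per-variant fitness);
survivors are resampled with replacement to the selected pool size, which is
the single bottleneck we model — the real experiment's multi-stage
bottlenecks (bacterial transformation, outgrowth, plating) are collapsed
into this one step. Hitchhiking is emergent, not programmed: a tolerated
variant sharing a clone with a damaging one is lost with its clone, and the
test suite checks the resulting depletion against the closed-form marginal
survival expectation. One mandatory seed drives every stage through derived
substreams, so replicates are independent but the whole screen is
reproducible from one integer.

Deliberately *not* modeled: read-level sequencing (FASTQ, alignment), PCR
jackpots and duplicates, multi-nucleotide or indel events, replicate
overdispersion beyond multinomial sampling (no variance components are
reported for the real screen, so none are invented). Passing tests on
synthetic data therefore demonstrate the correctness of the analysis given
these generative assumptions — not that real screens meet them; real data
with, e.g., jackpot amplification or batch effects between replicates would
need scrutiny the simulator cannot provide.

## Concordance analyses

External comparisons use protein-level HGVS keys; `normalize_hgvs_p()`
reconciles one-letter, three-letter and `Ter`/`stop`/`X`/`*` conventions
before any join. Group contrasts (e.g. clinical classes) use Welch's
unequal-variance t test — group sizes and variances differ by an order of
magnitude between annotation classes, so the pooled-variance test is
inappropriate; the test suite pins the implementation to the hand-evaluated
Welch formulas. Pairwise assay agreement counts an `intermediate` call
against a binary call as a disagreement by default (the arithmetic used when
comparing binary screen calls with three-class assays), with an `exclude`
policy available; predictor (VEP) concordance binarizes 0–1 scores at 0.5
and compares only damaging/tolerated variants, excluding intermediates.
Consensus across ≥2 assays is a majority vote with exact ties left
unresolved rather than broken arbitrarily.

## Region annotation

`region_map()` ships the domain architecture of the 543-residue checkpoint
kinase (SCD 19–69, FHA 92–205 structural / 113–175 by alignment, kinase
220–486, activation loop 368–394, NLS 515–523) with two presets for the
terminal disordered regions: the default (N 1–69, C 506–543) and the
narrower disorder-prediction delimitation (N 1–66, C 506–538) — both appear
in the literature, so both are shipped and the choice is explicit. The
ATP-pocket residue set defaults to empty because no authoritative residue
list is bundled; supply your own.

## Degenerate inputs and error behavior

Empty control classes, constant training scores, all-clone-eliminating
selection, zero-coverage positions with nonzero counts, empty replicate
sets, and annotation joins with no shared keys all raise immediate, specific
errors rather than propagating NaNs. Unscorable variants are always carried
through as flagged records — reports account for every possible SNV.

## Problem sizes used in validation

The shipped tests validate enumeration against an independent brute-force
translator on 100 random ORFs of up to 30 codons, spectrum recovery on >10⁵
simulated substitutions, and the full pipeline on one default-scale screen
(62,000 clones, 6 samples of 2.5×10⁶ read-equivalents) plus one reduced
screen (60 codons, 3,000 clones) for structural checks — sizes chosen so the
whole suite, including the paper-scale run, completes in well under a
minute while still exercising the study-scale regime.

## Known limitations

* Scores are point estimates; no per-variant standard error or
  replicate-dispersion shrinkage is computed.
* The classifier is intentionally single-feature; it cannot flag variants
  whose scores are unreliable for reasons invisible to RCS (e.g. positional
  coverage artifacts).
* A complementation screen measures one function in a heterologous system;
  variants damaging only functions not required for rescue will be called
  tolerated. The concordance tools exist precisely to surface such
  assay-specific blind spots.
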