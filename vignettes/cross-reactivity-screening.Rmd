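---
title: "Screening a proteome for TCR cross-reactive peptides"
author: "xreact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a proteome for TCR cross-reactive peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xreact)
```

## The problem

A therapeutic TCR recognizes a short peptide — here a nonamer — presented on
a class I HLA molecule. Because TCR recognition is degenerate, a TCR
selected against a tumor epitope may also recognize peptides derived from
normal human proteins. The in silico arm of a preclinical safety program
asks: *which peptides in the proteome resemble the cognate epitope closely
enough, in the positions the TCR actually reads, to deserve wet-lab
testing?* `xreact` produces that candidate list, with provenance, from
three inputs: the epitope, a positional substitution scan of it, and a
proteome in FASTA.

## From scan to motif

A positional scan substitutes each epitope position in turn (alanine, or
glycine where the wild type is already alanine) and records two readouts per
variant: the T cell response (e.g. IFN-γ in coculture supernatant at a
single high peptide concentration) and the predicted HLA binding of the
variant peptide. The two readouts separate two mechanisms of response loss:

- a variant that loses *predicted binding* by at least `theta_b`-fold marks
  an **anchor** position — its side chain holds the peptide in the HLA
  groove, and the response loss says nothing about TCR contact;
- a variant that keeps binding but loses the *response* to at most
  `theta_r` of wild type marks a **contact** position;
- everything else is **tolerant**.

Anchor precedence over contact is deliberate: without presentation there is
no readout of recognition. The response threshold is inclusive
(`response <= theta_r * wt`), so a variant sitting exactly on the cutoff is
called a contact; the same inclusiveness applies to `theta_b`. Both
thresholds travel with the classification object, since "contact" is only
meaningful relative to them.

**Defaults.** `theta_r = 0.1`: an order-of-magnitude loss is the natural
reading of a response that is "almost completely" abolished, and in
practice scans are bimodal — variants either retain most of the response or
drop near assay background — so any cutoff in roughly 0.05–0.3 gives the
same answer (the monotonicity tests formalize this: lowering `theta_r`
never adds contacts). `theta_b = 5`: a five-fold affinity loss is
comfortably outside prediction noise yet far below the ~100-fold losses
typical of true anchor-residue substitutions. Neither value is estimated
from data; both are recorded parameters the user can move.

The binding readout's *orientation* must be declared (`"affinity"`:
lower = stronger, like an IC50; `"score"`: higher = stronger), and the
fold-worsening is computed accordingly — silent misorientation would
swap anchors and tolerants, so the table carries the declaration.

The **recognition motif** constrains contact positions to the wild-type
residue and leaves anchor and tolerant positions fully open. Anchors are
*not* encoded in the motif: what matters downstream is not that a candidate
shares the epitope's anchors but that it can bind the HLA at all, which the
binding filter checks directly. A scan with zero contacts is rejected — a
motif with no constraints would match every window, which signals a failed
scan, not a permissive TCR.

## The three searches

- **Search 1** scans every k-mer window for an exact contact-motif match
  (vectorized per-position set membership; windows containing ambiguity
  codes X/B/Z/U are skipped, and selenocysteine U is treated as ambiguity
  rather than mapped to C).
- **Search 2** repeats the scan after relaxing each contact residue to its
  physicochemical class. The default partition —
  {A,G}, {I,L,M,V}, {F,W,Y}, {K,R,H}, {D,E}, {N,Q}, {S,T}, {C}, {P} —
  is the conventional chemistry-based grouping; it is a configuration
  value, not a claim, and any partition of the alphabet can be supplied.
  Only constrained positions are expanded: expanding open positions would
  be a no-op, and anchor compatibility is the filter's job. By
  construction the Search 2 language contains the Search 1 language, a
  property the test suite checks over random motif/proteome pairs.
- **Search 3** is an exhaustive Smith–Waterman local alignment of the
  epitope against every window, with BLOSUM62 and affine gap costs
  (open 11, extend 1, a length-L gap costing 11 + L). For a 9-mer query,
  heuristic database search adds nothing: the exhaustive scan is exact,
  deterministic and fast (a compiled per-window Gotoh kernel; ~10⁶ DP cells
  per 10⁴-residue protein). Word-seeded heuristics and E-value statistics
  are therefore deliberately out of scope. The default acceptance
  threshold, 60% of the query self-score rounded down (26 for
  FLSNDTVQL's self-score of 44), is recorded in the provenance; because
  BLOSUM62's diagonal entries are row maxima, no equal-length window can
  out-score the query itself, which pins the threshold to a meaningful
  scale. Traceback ties are broken diagonal-first, then vertical, then
  horizontal, and the best-cell tie by smallest query, then target index —
  arbitrary but fixed, so runs are reproducible.

Hits identical to the query are flagged `is_self` and excluded from
candidate counts (the source protein is in the proteome by construction);
they remain visible in the merged window table.

## Binding plausibility and assembly

Candidates are scored by a **binding predictor contract**: any deterministic
function from 9-mers to scores with higher = stronger, named so outputs are
attributable. The shipped default is an additive 9 × 20 position weight
matrix encoding canonical HLA-A\*02:01 preferences — strong weights for L/M
at position 2 and V/L/I at position 9, penalties for proline and charged
residues at the anchors, small weights elsewhere. This is a declared
simplification: it captures the anchor logic that the screen needs
(anchor-destroyed peptides must fail, anchor-bearing ones must pass) without
bundling an external neural predictor; users with NetMHC-class tools wrap
them in the same contract and nothing else changes.

Scores become **percentile ranks** against a background of windows sampled
(seeded, with replacement, weighted by protein length) from the proteome
under analysis — self-contained, reproducible, and matched to the search
space, at the cost of mild proteome dependence. The rank is the percentage
of background peptides scoring *strictly* higher, so ties never penalize a
candidate and rank 0 is best. The default cutoff of 2.0 is the conventional
"binder" percentile-rank threshold. The default background size of 10⁵
keeps rank resolution at 0.001 percentage points; ranks are computed by
binary search on the sorted background, so the cost is negligible.

Assembly merges the three window sets, erroring if the same
(protein, offset) coordinate carries different peptides across inputs —
that can only happen when the searches ran on different proteomes. The
candidate table is keyed by peptide sequence, sorted, with `found_by` the
sorted union of search labels, and the provenance snapshot (thresholds,
classes, matrix, seeds, proteome digest) suffices to reproduce the TSV
byte-for-byte; the test suite asserts this end to end.

## Dose translation

`mouse_equivalent_dose()` is plain weight-proportional scaling
(cells/kg × mouse mass), with 0.02 kg as the default adult mouse mass;
body-surface-area or allometric scaling is intentionally not implemented,
as cell doses are prescribed per kilogram. `fold_excess()` is the ratio of
a model-therapeutic dose to such a proportional dose. With human CAR-T
doses of 0.5–1 × 10⁶ cells/kg, the proportional mouse doses are 1–2 × 10⁴
cells, and a 5 × 10⁶ cells/mouse model dose is 250–500-fold above them.

## What the synthetic data does and does not emulate

`generate_proteome()` draws i.i.d. residues (uniform by default; any
frequency vector may be given) and plants labelled peptides at
non-overlapping recorded coordinates. The default plant set exercises every
search channel for the FLSNDTVQL motif: exact-motif peptides
(`ALSNDTVQL`, `FLSNDTVQV`), within-class contact variants (`FLTNDTVQL`,
`FLSQDTVQL`), an out-of-class but high-scoring alignment decoy
(`FLANDTVQL`), and an anchor-destroyed non-binder (`FPSNDTVQP`, proline at
both anchors) that the filter must remove. The default scale — 50 proteins
of 200–500 residues, ~17,000 residues — makes a full screen run in well
under a second while still yielding occasional genuine background hits.

`generate_scan_table()` plants the anchor/contact structure directly:
contact (and anchor) variants keep `contact_response_frac = 0.02` of the
wild-type response, tolerant ones keep `tolerant_response_frac = 0.9`,
anchors worsen binding `anchor_binding_fold = 100`-fold, and every readout
is multiplied by log-normal noise `exp(N(0, noise_sd))`. At the default
thresholds the noise margins are enormous (a tolerant position would need
an 11-σ excursion at σ = 0.2 to be miscalled a contact), which is why
recovery across 1000 seeded replicates is effectively 100%.

What this does **not** emulate: real proteomes are not i.i.d. (repeats,
homologous families, biased composition), real scans have correlated
assay error and partial responses, and the PSSM is not a modern binding
predictor. Passing the planted-recovery tests therefore demonstrates that
the machinery is correct — recall of what the rules define as findable —
not that the default thresholds are biologically optimal for any
particular TCR.

## Numerical and testing choices

Everything random takes an explicit integer seed and restores the caller's
RNG state. The test suite cross-checks each search against an independently
coded oracle — a PCRE lookahead regex scan for the motif searches, a
window-vectorized R implementation of the same Gotoh recurrence for the
alignment search (plus Biostrings `pairwiseAlignment` spot checks), and
sort-based rank computation for the filter — at sizes chosen to finish in
seconds (50 proteomes of 10⁴ residues for the oracle-equivalence sweep,
1000 replicates for scan recovery). Candidate counts are reported with
provenance but never asserted against a fixed number: they depend on the
proteome, the thresholds and the predictor, which is precisely why the
screen records all three.

## Known limitations

- One peptide length per screen (default and tested: 9); multi-length
  screens are runs of the pipeline per k.
- The default predictor is allele-specific to HLA-A\*02:01 and
  matrix-additive; position couplings and non-anchor binding contributions
  are ignored.
- No post-translational modification or splicing awareness; the proteome
  is screened as linear sequence.
- Search 2 expands contact positions only; a TCR that tolerates
  non-conservative contact substitutions is covered by Search 3's
  alignment channel, not by the class expansion.
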