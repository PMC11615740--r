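---
title: "Zero-shot Hamiltonian design: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot Hamiltonian design: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zshscan)
```

## The model

`zshscan` ranks double mutants of a target protein by how plausible the
mutated sequence looks to its own evolutionary record. The score is a
negative log-likelihood Hamiltonian: given an L×20 matrix $M$ of
per-position amino-acid log-probabilities conditioned on a multiple
sequence alignment (MSA), and the one-hot encoding $oh$ of a gap-free
sequence $s$,

$$H(s) \;=\; -\sum_{i=1}^{L}\sum_{j=1}^{20} oh_{ij}\,M_{ij}
       \;=\; -\sum_{i=1}^{L} M_{i,\,\mathrm{aa}(s_i)} .$$

The working assumption is zero-shot: positions and residue combinations
that evolution tolerates across deep homology are more likely to fold and
remain stable, so a *lower* Hamiltonian (higher likelihood) predicts a
more stable variant. No stability-labeled data enter the score. $H$ is
additive over positions for a fixed $M$, dimensionless, and in natural-log
units; with a uniform $M$ it equals $L\ln 20$ for every sequence, a useful
analytic anchor used in the tests.

Candidate sites are not chosen uniformly: double mutations are only
enumerated at position pairs whose contact-map signal is strong, on the
reasoning that coupled, spatially proximal pairs are where a coordinated
double substitution can create new stabilizing interactions.

## Pipeline and parameters

`zsh_scan()` runs two stages:

1. **Context construction.** Gap filtering removes every non-query
   sequence with gap ratio strictly greater than `max_gap_ratio`
   (default **0.15**; a ratio exactly at the threshold is kept — the
   filter reads "exceeding"). Greedy max-min subsampling then keeps
   `context_size` sequences (default **64**): starting from the query, each
   step adds the sequence with the largest minimum Hamming distance to the
   selection, gap counted as a 21st symbol. Ties break by input order, so
   the context is reproducible without a seed. The query is exempt from
   filtering and always first: it defines the mutable coordinate system and
   must be gap-free.
2. **Scan.** The backend's contact map over the context is ranked;
   the `top_pairs` strongest pairs (default **1000**) are scanned with all
   399 double mutants each (20×20 minus the double wild type), scored, and
   the `top_variants` lowest-Hamiltonian candidates (default **20**)
   reported.

The defaults mirror a realistic design campaign on a single enzyme with a
deep bacterial alignment; on the synthetic fixtures used in the tests,
`top_pairs` is reduced to 5 so a full run stays under a second.

Two deliberate enumeration choices: self-substitutions at one position of
a pair are legal (only the double wild type is excluded), because a
contact pair may be best repaired by changing one side while the model
still evaluates the pair jointly — a scan that forbade wild-type-retained
candidates like `H287H/Q288Y` would miss those designs; and no minimum
sequence separation is imposed on pairs, since sequence-adjacent contacts
are legitimate design sites.

## The baseline backend

The scoring contract has two methods — `contact_map(msa)` and
`likelihoods(variant_sequence, context)` — plus `name`, `deterministic`
and `sequence_dependent` fields. The bundled baseline is:

* **Likelihoods**: Laplace-smoothed column frequencies,
  $p(i,a) = (n_{ia} + \kappa)/(n_i + 20\kappa)$ with pseudocount
  $\kappa = 1$ by default (configurable; it keeps unobserved residues at
  finite log-probability), gaps excluded from both counts; $M = \log p$,
  so each row satisfies $\operatorname{logsumexp} = 0$. The baseline $M$
  does not depend on the variant sequence; `score_variants()` exploits
  this and computes per-mutant Hamiltonians by the exact two-position
  decomposition
  $\Delta H = -(M_{i,a_i}-M_{i,wt_i}) - (M_{j,a_j}-M_{j,wt_j})$.
* **Contacts**: mutual information between columns (gap as 21st symbol,
  no pseudocount, empirical plug-in estimate) followed by average-product
  correction, the standard suppression of phylogenetic and entropic
  background: $\mathrm{APC}(i,j) = \mathrm{MI}(i,j) -
  \bar m_i \bar m_j / \bar m$ with means over off-diagonal entries. The
  corrected matrix is min-max rescaled to $[0,1]$ so entries read as
  contact probabilities; rescaling is monotone and therefore does not
  affect which pairs are selected. A constant matrix (no signal) maps to
  the all-zero map.

A sequence-conditioned model (an MSA-conditioned protein language model
with a contact head) slots into the same contract with
`sequence_dependent = TRUE`; scoring then recomputes $M$ per mutant. Such
a backend is the higher-fidelity option; the baseline exists so the whole
pipeline is deterministic, dependency-free, and testable offline. One
caveat is reported rather than hidden: when $M$ is recomputed per mutant,
raw Hamiltonians of different mutants are each conditioned on their own
sequence, so the report carries both the raw value and
`delta_vs_wildtype` against a fixed wild-type reference.

## The synthetic generator

`simulate_msa()` emulates exactly the features the pipeline consumes:
background residue composition (default uniform), a tunable per-cell gap
rate applied to homologs, and planted pairwise couplings. Each planted
pair draws, with probability `coupling`, one of two equiprobable
residue-pair states $\{(A_1,B_1),(A_2,B_2)\}$ with $A_1\neq A_2$,
$B_1\neq B_2$; otherwise two independent background residues. The
two-state table is the simplest model with an analytic mutual-information
limit — $\ln 2$ at coupling 1 and no gaps — which the tests verify by
simulation at depth 2048 (tolerance 0.05, well above binomial error at
that depth). Gaps are applied post hoc and independently per cell: enough
to exercise gap filtering and the 21-symbol conventions, with no claim to
model indel evolution.

What passing tests therefore show: the estimators recover planted
covariation above background (5 pairs at coupling 0.9, depth 512, gap rate
0.02 — recovered in ≥18/20 replicates), the scan enumerates and ranks
exactly as specified, and the pipeline is byte-reproducible. What they do
not show: real MSAs carry phylogenetic correlation, alignment errors and
composition bias that the generator omits, and mutual information is a
weaker contact estimator than a trained model on real data. Recovery on
synthetic alignments is a correctness check, not a performance claim.

## Numerical and interface choices

* Natural log throughout; the base only rescales the Hamiltonian and no
  ranking changes.
* The amino-acid column order is the fixed alphabetical one-letter code
  `ACDEFGHIKLMNPQRSTVWY`; all matrices and one-hot encodings use it.
* Positions are 1-based everywhere in the R interface and in mutation
  labels (`F237R/S240G` means positions 237 and 240).
* A3M ingestion deletes lowercase letters and `.` (insertion states) from
  every record independently; afterwards every record must match the
  query's match-column count, and violations name the offending record.
  Gap filtering operates on these canonicalized match columns.
* Ambiguity codes (X, B, Z, U, O) cannot be one-hot encoded in a 20-letter
  alphabet; they map to the gap symbol by default, with a strict mode that
  rejects them (`noncanonical = "error"`). A pair whose wild-type residue
  ends up non-canonical is skipped with a warning rather than aborting the
  scan.
* Degenerate inputs have defined outcomes: an all-gap column yields the
  uniform likelihood row with a warning; a filter that removes every
  homolog returns the query-only alignment with a warning; a zero-signal
  contact matrix yields the all-zero map.
* All orderings are total: pairs by probability descending then $(i,j)$;
  mutants in alphabet order; ranked variants by Hamiltonian then
  $(i, j, aa_i, aa_j)$. Reports print 6 decimal places, making reruns
  byte-identical and diffable.

Where the field leaves the design genuinely open, this package picks one
option and documents it: the greedy diversity selection is seeded with the
query (not a random record), filtering happens after canonicalization, and
the diversity metric is raw Hamming distance on match columns. These
choices favor determinism and simplicity; none of them changes the
contract of any downstream stage.

## Problem sizes and limitations

The test suite and the acceptance script run on synthetic alignments of
40–50 columns and 128–2048 sequences, scanning 2–5 pairs (≈800–2000
mutants); the end-to-end reference run completes in well under a minute on
one CPU, and a full 1000-pair scan with the baseline backend is a few
seconds more since the likelihood matrix is shared across mutants.

Known limitations: the Hamiltonian predicts no physical quantity (no Tm or
ΔTm in degrees), says nothing about expression or activity, and scores
only double substitutions — no indels, no higher-order combinations. The
baseline contact estimate degrades on shallow or highly redundant
alignments (no sequence reweighting is applied), and designs at poorly
aligned positions inherit the alignment's errors.
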