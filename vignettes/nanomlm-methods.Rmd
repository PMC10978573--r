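---
title: "Masked language models of nanobody repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked language models of nanobody repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nanobodies (VHH, single-domain antibodies) are camelid heavy-chain-only
variable domains. Engineering them — humanization, liability removal,
affinity design — needs a *mutational map*: for each position of a candidate
sequence, which residues are biologically plausible there. For conventional
human antibodies such maps can be built per germline gene, as position
specific scoring matrices (PSSMs) over millions of NGS sequences sharing a
germline. For nanobodies this route is unreliable: the camelid germline
reference is incomplete, gene assignment of VHH repertoires is poor, and
hypermutation is broader than in human chains. A germline-agnostic
residue-level masked language model (MLM) sidesteps gene assignment
entirely and, unlike a PSSM, conditions on the whole sequence context.

`nanomlm` implements this methodology end to end at desk scale, with a
synthetic repertoire simulator supplying ground truth for every stage:

1. **repertoire simulation** — germline scaffolds + somatic hypermutation
   (SHM) + CDR3 resampling + sequence-dependent property labels;
2. **IMGT numbering** by alignment to numbered scaffolds, with region
   segmentation (FW1–4, CDR1–3) and hallmark-motif extraction;
3. **a BERT-style encoder** trained with the masked-LM objective;
4. **positional infilling benchmarking** by IMGT region, against a PSSM
   baseline;
5. **nativeness scoring** and species-separation experiments;
6. **fine-tuning heads** for species classification and thermostability
   regression;
7. **germline diagnostics**: closest-gene assignment, gene frequency
   tables, and FW2+FW3 edit-distance curves.

## The model

Sequences are sentences and residues are words. The vocabulary has the 20
canonical residues plus `[MASK]`, `[PAD]`, `[CLS]`, `[SEP]`, `[UNK]`. The
encoder is a standard pre-LayerNorm transformer: learned token and position
embeddings, `n_layers` blocks of multi-head self-attention and a GELU
feed-forward, a final LayerNorm, and a linear vocabulary head. Training
minimizes cross-entropy at corrupted positions only, with the standard
BERT corruption scheme (15% of residue positions; 80% `[MASK]`, 10% random
residue, 10% unchanged), AdamW, and linear warmup/decay. The forward and
backward passes are written directly in R matrix algebra; gradients are
verified against finite differences in the test suite.

Three presets are provided. `"tiny"` (2 layers, 2 heads, embedding 32,
~24k parameters) is the desk-scale workhorse used by every experiment in
the tests; it trains on a 20 000-sequence corpus in minutes on one CPU.
`"small"` (10 layers, embedding 320, ~12.4M parameters) and `"big"`
(12 layers, embedding 768, ~85M parameters) match the published scales of
nanobody/antibody language models; the layer counts were chosen to land on
those parameter budgets given the embedding sizes. They are instantiable
(the test suite checks their parameter counts) but not trained by any test.

**Infilling** (`predict_position`) masks one position, runs a forward pass
and softmaxes over the 20 residue logits (special-token mass is excluded
and renormalized). **Nativeness** is computed under the same per-position
masking: with `z_i` the final-layer logit of the observed residue at
position `i`, the score is `sum_i exp(-z_i)` — a sum of inverse exponents,
lower for sequences closer to the training distribution. The formula is
deliberately exposed in two variants (`"invexp"`, and the
pseudo-log-likelihood `"pll"` = `sum_i -log p_i`) because either reading is
defensible; both are monotone decreasing in the observed-residue logit, and
the package claims neither as canonical. Raw scores are sums, so they
confound length with nativeness; a length-normalized variant is available
(`normalize = TRUE`) but off by default to keep the raw definition.

## The simulator: what it emulates, and what it does not

`simulate_repertoire` draws a germline per record (configurable mixing
weights), mutates the germline-derived segment position-by-position, and
replaces CDR3 entirely with an i.i.d. per-position sample at a sampled
length. Defaults:

* **SHM base rate 0.02 per residue** with hotspot multipliers of 3 on CDR1
  and CDR2 — a few mutations per sequence, concentrated in the hypervariable
  loops, in the range typical of mature repertoires.
* **CDR3 lengths** discretized normal, 8–16 peaking at 12 (species A in
  `make_species_pair` shifts to 10–18 peaking at 14, reflecting the longer
  VHH loops), with a loop residue composition enriched for G/S/Y/D/R.
* **Substitution matrix** uniform over the 19 alternatives with zero
  diagonal (a mutation always changes the residue).

The two built-in species differ at the FW2 hallmark positions (IMGT
42/49/50/52: F/E/R/F in the nanobody-like set versus V/G/L/W in the
human-like set), at a handful of FW3/FW4 positions, and in CDR3 statistics.
Each species ships five hand-built scaffolds; these are synthetic, not real
IGHV alleles, so the package is self-contained. Within a species, genes
differ by three framework substitutions each (any two genes by at least
six), which keeps closest-germline assignment identifiable under SHM.

Deliberately **not** modelled: clonal lineage structure, insertion/deletion
SHM, paired light chains, position-dependent hotspot motifs (WRCY etc.),
and sequencing error. Consequently, passing tests show that the methods
behave correctly when their assumptions hold — they do not certify
performance on real NGS data, where germline uncertainty, indels and
lineage correlation all bite.

The **property model** (synthetic melting temperatures) is linear:
intercept 65 °C plus effects for specific (IMGT position, residue) pairs
plus Gaussian noise (SD 1 °C). The default effects sit on the allelic
framework positions that actually vary between the built-in genes (IMGT 3,
78, 83, 87) and on CDR3 arginine content, so the signal is recoverable from
sequence by construction — the point of the fixture is to make "can
fine-tuning extract a known signal?" a well-posed question, not to mimic
real thermostability biophysics.

## IMGT numbering by scaffold alignment

Full HMM-based numbering is out of scope; instead a query is
Needleman–Wunsch-aligned (match 2, mismatch −1, gap −2, deterministic
diagonal-up-left tie-breaking) to every scaffold, and the best scaffold's
IMGT labels are transferred through aligned columns. The region table is
the standard IMGT unique-numbering convention (FW1 1–26, CDR1 27–38, FW2
39–55, CDR2 56–65, FW3 66–104, CDR3 105–117, FW4 118–128). Query
insertions get lettered sub-positions within the enclosing region. Because
a query CDR3 rarely matches the scaffold loop, alignment places the
surplus residues ambiguously around the FW3/CDR3/FW4 boundary; the
numberer therefore renumbers everything between the last aligned position
≤ 104 and the first aligned position ≥ 118 as a contiguous CDR3 (lengths
beyond 13 receive lettered insertions after position 111 — a simplified
convention, not full IMGT insertion-code fidelity). Sequences whose best
alignment has framework identity below 0.5 are rejected as unnumberable,
and all consumers count rather than silently drop them.

## Benchmarks and their aggregation rules

The infilling benchmark obscures one position at a time, counts a match
when the top prediction equals the original residue (ties broken
alphabetically and flagged), and reports accuracy per region as matches
divided by the number of positions the sequence has in that region, with
aggregates `V` (all positions), `FW` and `CDRs`. Region means are
**unweighted means over sequences** that have the region, not pooled
positions — the per-sequence reading of "percentage of matches for each
sequence divided by its length"; the alternative pooled-position reading
would weight long CDR3s more. The whole harness is verified against an
independent brute-force recomputation in the tests.

The PSSM baseline predicts the training-frequency row of a position
regardless of context. Two experiments give the method contrasts:

* **Context advantage**: on a corpus where position 30's residue is a
  deterministic function of position 10's (both marginals 50/50), a PSSM
  can never beat 50% at position 30 while the trained tiny MLM exceeds
  90% — the operational content of "context matters".
* **Cross-species ordering**: a model trained on species A infills
  held-out A sequences better than B sequences, and vice versa.

For the context experiment the training uses a 25% masking rate rather
than 15%: with a 6 000-sequence corpus, a higher corruption rate simply
gives more labelled positions per epoch, and the experiment asserts the
capability of the converged model, not a particular training protocol.

## Fine-tuning protocol

A four-layer dense head (hidden sizes d, d/2, d/4, ReLU) sits on the
mean-pooled final hidden states over residue positions (CLS is excluded —
the MLM objective never trains it; CLS pooling is available by flag).
Sigmoid output + binary cross-entropy for classification; linear output +
MSE for regression, with targets min-max scaled to [0, 1] on the training
split only. Data are split 8:1:1 with a 90% identity filter applied
between train and val∪test (identity = matched columns over global
alignment length); the filter is deliberately not applied within train.
Fine-tuning is two-stage: the randomly initialized head is first trained
for a few epochs against the frozen encoder (cheap, since the pooled
features are cached), and only then is the encoder unfrozen and trained
jointly at 0.3× the head learning rate. Starting joint training from a
sensible head instead of random weights markedly reduces run-to-run
variance — gradients from a random head otherwise tear up the pre-trained
representation before the head has learned anything. `freeze_encoder =
TRUE` trains the head alone throughout, which is also the "no
pre-training" baseline when given a randomly initialized encoder. Regression is repeated five times with distinct seeds on a fixed
split — re-seeding training rather than re-splitting, so the repeat SD
reflects optimization variance, not split variance — and reported as
mean/SD of test Pearson r alongside a uniform-random baseline.

On the standard synthetic thermostability fixture (n = 400) the expected
ordering is: fine-tuned pre-trained encoder > head-only on a random
encoder > random baseline. The head-only arm is not a straw man — with a
bag-of-residues-like pooled representation it captures the CDR3
composition effects — but it lacks the positional precision that
pre-trained contextual embeddings provide for the allelic framework
effects.

## Germline diagnostics

`assign_genes` assigns each numbered sequence to the germline with the
highest framework identity (FW2/FW3 required, exclusions counted, ties
flagged and broken by gene order). `distance_curve` reproduces the
gene-assignment sanity check: extract each chain's concatenated FW2+FW3,
take the most frequent clone as the empirical germline proxy, and plot
total and top-unique-clone frequency against Levenshtein distance to it.
Under a single correctly assigned germline the curve is unimodal with mass
concentrated at distance ≤ 1 and a monotone tail (mutation counts are
binomial); a hidden, unmapped germline in the data produces a secondary
bump at the inter-germline distance. Both regimes are exercised in the
tests with planted ground truth. Both per-read and per-unique-clone
frequency series are reported, since either convention is defensible.

## Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; identical
  (config, seed) reproduce byte-identical repertoires, masks and models.
* Evaluation-mode forward passes are deterministic; dropout only applies
  in training when configured (the tiny preset trains without it).
* Prediction ties are broken alphabetically and flagged.
* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12; non-finite training loss aborts with a
  diagnostic rather than propagating NaNs.
* Non-canonical residues tokenize to `[UNK]` with a warning, are excluded
  from nativeness sums, and never count as masked-LM labels.
* Degenerate cases error early with actionable messages: empty corpora,
  non-stochastic PSSM rows, zero-variance regression targets, identity
  filters that empty a split, single-class classification splits.

## Problem sizes

The test suite and the acceptance script train only `"tiny"` models, with
corpora of 3 000–20 000 sequences, evaluation sets of 20–60 sequences,
n = 3 000 for gene-frequency recovery, n = 2 000 per distance curve and
n = 400 for the fine-tuning fixture, five repeats. These sizes were chosen
as the smallest at which the assertions are statistically stable (binomial
and permutation bounds are quoted in the tests) while keeping a full run
in the tens of minutes on a single CPU core.

## Known limitations

* The scaffold-alignment numberer assumes reasonably clean, full-length
  variable domains; heavily truncated NGS reads will be rejected rather
  than partially numbered.
* Simplified CDR3 insertion labels diverge from full IMGT insertion codes
  for long loops.
* The simulator's i.i.d. SHM and CDR3 models understate the correlation
  structure of real repertoires; distribution-recovery results on
  simulated data are therefore an upper bound on what identical training
  would achieve on real data.
* The `"small"`/`"big"` presets are provided untrained; training them is a
  GPU-scale undertaking outside the package's test envelope.
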