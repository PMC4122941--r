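---
title: "Models and methods behind retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscape)
```

# The problem

Genomes too large to assemble are usually characterized from ~1% shotgun
coverage: reads are masked against de-novo repeat consensus sequences, and
everything downstream — how much of the genome each TE superfamily occupies,
how old the copies of a family are, how fast decaying DNA is being deleted —
is computed from the resulting copy-vs-consensus alignments. `retroscape`
implements that downstream computation as a tested, reusable package, with a
simulator that generates families under the same evolutionary model the
estimators assume.

# Age distributions under the master-gene model

A repeat family's consensus approximates the ancestral ("master") sequence.
Under the master-gene model a few active elements spawn mostly-inactive
copies; a copy born at age $a$ then decays neutrally, so its corrected
divergence from the ancestor estimates $a$ (in substitutions/site — we never
convert to years, since absolute substitution rates are unavailable in the
taxa of interest).

Two corrections are applied to the observed per-copy mismatch proportion
$p$ (computed over columns with an unambiguous base in both rows; `N` and
gap columns carry no signal and enter neither numerator nor denominator):

* **Multiple hits:** $d = -\tfrac34\ln(1-\tfrac{4p}{3})$ (Jukes–Cantor).
  The domain ends at $p = 0.75$; saturated copies get `NA` distances in
  `divergence_records()` and are in practice removed by the identity filter.
* **Master-lineage substitutions:** if several sequentially active masters
  generated the family, copies inherit the substitutions that occurred on
  the active lineage before their birth. These are recognizable because the
  *same* base change at the *same* consensus position recurs across copies.
  `detect_master_substitutions()` flags, for every group of `min_copies`
  copies, the full set of jointly shared substitution keys
  (position, derived base) whenever that set has at least `min_shared_subs`
  (default 2) members; flagged keys are excluded from the refined estimate
  ($p_\text{refined} \le p_\text{raw}$ always).

Copies are filtered before binning: strictly longer than 100 bp and at
least 80% identical to the consensus (identity is $1 - p_\text{raw}$,
i.e. pre-refinement, matching what a masking tool reports). Histograms use
half-open bins $[k\%, (k{+}1)\%)$ of width 1%, range 0–20% (the identity
filter bounds divergence), weighted by copy bp by default; `read_count`
weighting is available because "percent of total reads" is ambiguous between
the two conventions in the source literature.

## The group-size threshold, and why it is configurable

The pairwise default (`min_copies = 2`) is the most exclusion-prone reading
of the published rule and is what small copy sets should use. It has a
sharp failure mode at scale, which we measured with the simulator: the
probability that a genuinely private substitution key recurs in at least
one other copy by chance is $1-e^{-(n-1)p/3}$ for $n$ copies at divergence
$p$ — at $n = 200$, $p = 0.02$ that is ~0.73 — and once two copies share
two or more *inherited* keys (almost every pair does, when master
substitutions exist), every chance-shared private key rides along into the
flagged set. The refined divergence is then biased low by far more than its
Monte-Carlo standard error.

`scaled_min_copies()` therefore scales the group size to 5% of the copy
number. Master-lineage substitutions are inherited by every copy younger
than the event — on the order of half the family — so they still form
qualifying groups with probability ~1, while the probability that a private
key reaches a 5%-of-$n$ group by chance is negligible (Poisson tail at mean
$(n-1)p/3$). Under this setting the parameter-recovery suite finds the
refined estimator unbiased (within 3 MC SE at $n = 200$) across seeds,
where the pairwise default fails systematically. The pipeline uses the
scaled threshold; `detect_master_substitutions()` keeps the literal
pairwise default for compatibility with small families.

# DNA loss through small indels

Decaying non-LTR retrotransposon copies are a neutral record of the
insertion/deletion process. Per copy, each maximal run of `-` in the copy
row is one deletion, each maximal run in the consensus row one insertion;
events longer than 30 bp are discarded (the method deliberately measures
*small* indels only — large indels have different mechanisms and cannot be
reliably bounded by short-read alignments). The statistic is

$$\text{loss rate} = \frac{\text{bp deleted} - \text{bp inserted}}
{\text{substitutions (JC-corrected)}}$$

with the correction applied per copy and then summed, because JC is
nonlinear and copies differ in divergence.

Three filters precede the tally:

* **Consensus acceptance** (`accept_consensus()`): consensus >330 bp,
  supported by ≥5 copies each >300 bp and ≥80% identical. Length thresholds
  are strict (`>`), identity inclusive (`≥`), mirroring the stated rule
  exactly. Copies of accepted families all enter the tally (the per-copy
  thresholds gate acceptance only).
* **Codon-position χ²** (`chi_square_uniform()`): substitutions pooled per
  family across copies, assigned to codon positions by
  $((\text{pos}-1-\text{offset}) \bmod 3)+1$ against a consensus trimmed to
  its coding region (the frame offset is an input; `pick_orf_frame()`
  offers the longest-stop-free-frame heuristic when it is unknown).
  Families with $P < 0.05$ (df = 2, uniform expectation $n/3$) carry
  selection-era/master-lineage signal and are excluded. Zero-substitution
  families are retained and flagged (`applicable = FALSE`). A per-copy mode
  exists behind `per_copy_chisq` but pooling is the default — per-family is
  what the master-lineage rationale implies, and per-copy counts are too
  small for the asymptotics.
* **Homopolymer artifacts** (`flag_homopolymer_indels()`): pyrosequencing
  miscalls homopolymer lengths, so a mononucleotide indel whose bases plus
  adjacent same-base consensus neighbours form a run ≥5 bp is discarded.
  Five is where 454-style length-call error rates become substantial; it is
  configurable.

## Calibration of the χ² filter

The type-I suite simulates neutrally decaying families and checks the
exclusion fraction at $\alpha = 0.05$. One modelling subtlety: real (and
simulated) substitutions occupy *distinct sites*, so codon-position counts
are hypergeometric-like with variance slightly below multinomial, and the
Pearson statistic is conservative when substitutions are dense relative to
sites (measured ~0.034 at 12% divergence vs ~0.045 at 3.5%). The
calibration scenario therefore uses low density (900 bp consensus, ~3.5%
divergence), which is also the realistic regime for recently decaying
copies. Power against a 6:1 third-position bias exceeds 0.95 at
$n_\text{total} \ge 60$, as the noncentral χ² predicts.

# Repeat landscapes

Annotations are per-read intervals (0-based half-open in files) labelled
with a superfamily and a category. Overlaps are resolved by precedence
known TE > unknown repeat > simple repeat (the order in which a
masking pipeline assigns them), ties by longer annotation then
lexicographic label; lower-precedence annotations are trimmed to the
uncovered positions, splitting if necessary, so bp are conserved exactly.
Percent of dataset, Gb of genome
($\text{percent}/100 \times \text{genome Gb}$) and coverage
($100 \times \text{dataset bp}/\text{genome bp}$) follow. Genome sizes are
configuration inputs, never constants in code.

# The simulator: what it emulates, and what it does not

`simulate_family()` draws a uniform-random master sequence (the consensus),
a time-ordered Poisson sequence of master-lineage substitutions (expected
`master_sub_count` over the family age span, third codon positions favoured
`codon_bias`-fold), and copies born at ages from `age_model`:

* ages are parameterized directly in expected-divergence units, avoiding an
  unknown years-per-substitution calibration;
* a copy inherits exactly the master substitutions older than its birth —
  the truth record keeps the realized key sets, and a property test
  verifies that re-parsing the emitted alignments reproduces them
  byte-for-byte;
* private substitutions are placed uniformly *with replacement* and move
  the base to one of the three alternatives — true multi-hit mechanics, so
  Jukes–Cantor is the exact inverse model and parameter-recovery tests
  exercise the estimator, not a convenient shortcut;
* indel events are Poisson in `del_rate`/`ins_rate` with geometric sizes;
  placements are non-overlapping and non-adjacent so every event remains
  one maximal gap run (the count-level ground truth stays exact);
  insertions never land inside a deletion run (which would split it);
* an optional injector adds spurious 1-bp indels inside consensus
  homopolymer runs ≥5 to exercise the artifact filter (off by default);
* `shred_to_reads()` cuts copies into normal-length (mean 400, sd 100,
  truncated ≥50 bp — 454-like) fragments whose sub-alignments are consistent
  with the parent.

Default indel parameters are taken from a published large decaying non-LTR
copy tally: event rates 29,755/658,447 deletions and 39,258/658,447
insertions per substitution, geometric mean sizes 2.60 and 1.47 bp. The
preset catalog spans the qualitative proliferation regimes: `ongoing`
(exponential ages, mean 1.5% — mode at the present), `old_burst` (normal
burst at 6% ± 1.5% — a past proliferation peak), `two_burst` (2% and 10% —
a bimodal, horizontal-transfer-like control).

What the simulator does **not** model: sequencing error beyond homopolymer
indels, alignment error (emitted alignments are exact by construction, so a
green test says nothing about aligner artifacts), coalescent copy
genealogies (copies are independent given the master lineage), indel
clustering, and CpG or transition/transversion rate structure (hence no
Kimura-style corrections are offered). Landscape inputs are taken as given;
repeat discovery and homology classification are out of scope.

# Numerical conventions and degenerate inputs

* Consensus coordinates are 1-based inclusive; minus-strand hits are stored
  reverse-complemented so all downstream math runs in consensus orientation.
* Histogram bins are half-open; a divergence exactly on an edge falls in
  the upper bin.
* `jukes_cantor()` errors at $p \ge 0.75$; `divergence_records()` degrades
  to `NA` instead so one junk copy cannot kill a batch, and `loss_rate()`
  skips saturated copies with a logged count.
* Copies with zero aligned sites are skipped with a logged count; families
  with fewer than two copies yield an empty flagged set (not an error).
* Deletion:insertion ratio with zero insertions, and loss rate with zero
  substitutions (but nonzero indels), are reported as missing (`NA`);
  zero indels with substitutions give a loss rate of exactly 0.
* RepeatMasker parsing is best-effort: blocks that fail to parse or violate
  alignment invariants are skipped and counted, because `.align` dialects
  drift across versions; zero parseable blocks is an error.
* The canonical alignment format is bit-exact under write-then-read, which
  the suite asserts on generated records.

# Known limitations

* The shared-substitution exclusion keys on (position, derived base) — the
  stricter reading of "shared substitution"; keying on position alone would
  exclude more and is not offered.
* The pairwise exclusion default over-excludes for large $n$ (see above);
  use `scaled_min_copies()` beyond a few dozen copies.
* The χ² filter assumes the consensus is correctly trimmed to a coding
  region; a wrong frame offset weakens it toward uniformity (conservative
  for exclusion, anti-conservative for the loss tally).
* The loss-rate denominator treats every aligned copy as fully neutral
  after the family-level filters; residual selection inflates substitutions
  and deflates the rate.
* Acceptance tests compare against the simulator's own ground truth and
  published worked-example arithmetic only; nothing here validates the
  biology of any particular genome.
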