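---
title: "Methods: tracking an AM fungal inoculum and its niche competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking an AM fungal inoculum and its niche competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`amfniche` analyzes field trials in which a commercial arbuscular
mycorrhizal (AM) fungal inoculum is introduced into soils that already
carry an indigenous AM community, using LSU rDNA D2 amplicon reads from
root samples of replicated block designs. This vignette is the
package's own account of the models and the numerical choices behind
each stage. All empirical statements here are the ones the test suite
and `scripts/acceptance.R` actually compute.

## Read processing

Paired 300-cycle amplicon reads are processed natively rather than
through external trimming/merging tools, so the behaviour is fixed by
the package:

* **3' quality trimming** removes terminal bases until the terminal
  base reaches QV 30. This is a plain terminal scan, not a sliding
  window: the rule is "no bad 3' terminal", and interior low-quality
  bases are left for the alignment stage to absorb.
* **Length floor**: mates shorter than 200 nt after trimming are
  rejected. The floor is applied per mate, before merging — a merged
  fragment is only as trustworthy as its mates — and both the floor
  and its placement are configurable.
* **Merging** reverse-complements mate 2 and scans every ungapped 3'
  overlap of 10–300 nt; the overlap with the fewest mismatches wins,
  ties going to the longest. The consensus takes the base of the mate
  with the higher QV (mate 1 on equal QV). Gapped merging is
  deliberately not attempted: the amplicon is a fixed locus and indel
  handling belongs to the affine-gap aligner in the next stage. A
  `max_mismatch_rate` of 0.1 in the overlap (not dictated by the
  protocol; configurable) rejects spurious overlaps.

## Classification

Merged reads are assigned by best local alignment against a two-group
reference set: AM fungal OTU sequences and non-AM (outgroup)
sequences. Alignment is Smith–Waterman with affine gaps
(Biostrings is the engine), scored BLASTN-like: match +2, mismatch −3,
gap open 5, gap extend 2, both strands searched. The E-value is
`E = K·m·n·exp(−λS)` with K = 0.41, λ = 0.625, `m` the read length and
`n` the total length of the searched group. A best hit is accepted only
if E ≤ 1e-100, identity ≥ 95% (identities over alignment columns
including gaps, as BLAST reports), and the alignment spans ≥330 nt for
AM OTUs or ≥220 nt for outgroup records. "E-value ≤ −100" in pipeline
shorthand is read as `1e-100`, since an expectation cannot be negative.
A read whose best hit is an outgroup record but fails the outgroup
criteria is `no_hit`, not an AM failure; only criteria-passing reads
are assigned. Strictly best-hit assignment is used (ties broken by
lower E-value, then lexicographic OTU id, to keep runs deterministic).

The batch classifier shortlists candidates by shared 12-mers, ranks
them by score-only alignment on the k-mer-preferred strand, and runs
the full alignment only for each read's winning candidate. This is the
usual seed-and-extend economy; `prescreen = FALSE` gives the
exhaustive both-strand search, and the test suite checks that the two
paths agree and that scores match a brute-force dynamic-programming
oracle.

Counts are made comparable by rarefaction to 10,000 reads per sample —
drawing without replacement, seeded — because subsampling preserves the
integer, mean-preserving character the downstream binomial model
expects. Proportional scaling (largest-remainder rounding) is available
as `rarefy(..., method = "scale")` for sensitivity checks.

## Tracking the inoculum

Sequencing the inoculum alone defines the marker: every OTU detected in
that sample (threshold `min_share = 0`, i.e. any read) forms the
inoculum-type set, and the summed reads of the set per field sample,
over the rarefaction depth, is the tracked share. Reads of these OTUs
cannot be split into inoculum-origin and indigenous-origin fractions —
indigenous communities can carry the same OTUs — so the package reports
the combined signal only, and the share is interpreted as evidence of
dominance rather than a census of the introduced strain.

## Ecological statistics

* **Yield response** of an inoculated plot is its yield relative to the
  mean of matched control plots. Controls are matched within trial × P
  level, the pairing the design creates; a trial-wide match is a flag
  away.
* **Commonness** (Levins niche breadth) of an indigenous OTU is
  `1/Σ_i P_ij²` over its trial shares `P_ij`, computed from control
  plots only so the index describes the undisturbed community. OTUs
  under 0.2% mean relative abundance are excluded, as are
  inoculum-type OTUs (their origin is ambiguous). The same OTU universe
  (rare filter included) is used for **robustness** — the
  inoculated/control ratio of trial-mean abundance — so the two indices
  are computed for the same organisms; the filter can be disabled for
  robustness alone. Zero control means make robustness undefined and
  are flagged, never coerced to zero.
* **PERMANOVA** uses the McArdle–Anderson partitioning of the
  Bray–Curtis dissimilarity matrix with sequential (Type I) sums of
  squares, factors ordered trial then inoculation (the order is
  configurable but must be fixed for determinism). Sample labels are
  permuted freely by default, with an optional within-block
  restriction. `p = (1 + #{F* ≥ F})/(1 + n_perm)` for sampled
  permutations; `permutations = "exact"` enumerates all labellings of
  up to 8 samples and reports the exact proportion. The implementation
  is native so the permutation stream is fully caller-controlled; the
  tests cross-check the statistics against `vegan::adonis2` and the
  exact p against complete enumeration.
* **Regressions.** Yield responses (pooled over trials) are regressed
  on the tracked share, entered as percent of AM reads, plus
  environmental covariates; bidirectional stepwise search from the full
  model minimizes AIC, and standardized partial regression coefficients
  come from refitting the selected model on z-scored variables. If the
  greedy search ends above the null or full model's AIC, the better of
  those is returned, so the selected model never loses to either
  anchor. The tracked reads themselves are modeled as binomial
  `(tracked, depth − tracked)` counts with a logit link and a Gaussian
  random block intercept, fitted by adaptive Gauss–Hermite quadrature
  (lme4); odds ratios are `exp(coefficient)`. A zero-variance path
  (`re_variance = "zero"`) reduces the model to a plain binomial GLM —
  the limiting case the tests verify against an independent IRLS
  implementation. Read-level pseudo-replication makes these binomial
  counts overdispersed on real data; effect signs and ranking are the
  robust outputs, and the pipeline standardizes GLMM covariates so the
  optimizer is not fighting scale differences of 10⁴. Log transforms
  replace zeros by 0.5 before taking natural logs (monotone on counts;
  base and pseudo-count are free choices the data cannot pin down).

## MPN estimation

The dilution bioassay is modeled as Poisson exposure: a pot receiving
soil volume `v` (mL) at dilution `d` from a source of density λ
(propagules/mL) is colonized with probability `1 − exp(−λ d v)`. The
likelihood over all levels is unimodal in λ and is maximized on the log
scale over [1e−8, 1e4] propagules/mL, a bracket spanning any
field-realistic density; the 95% CI is profile-likelihood. All-negative
series estimate zero with a one-sided upper bound; all-positive series
are flagged with a lower bound only. The assay volume is a required
input — it depends on the potting protocol and defaulting it would
silently rescale every estimate — and a soil bulk density (g/mL) can be
supplied to express results per gram. A maximum-likelihood estimator
was chosen over classical MPN lookup tables because the likelihood is
the model, works for any dilution scheme, and yields intervals. With
few plants per level the block-level MLE is right-skewed (a common
small-sample feature of MPN assays), which is why per-trial summaries
average replicate blocks.

## The synthetic study generator

`synth_config()` defines the simulated study; its defaults are the
operating point of the whole validation suite, chosen once:

* **Design**: 3 trials × 4 blocks × two P levels (0, 100 kg P₂O₅/ha) ×
  {control, inoculated}, a randomized complete block layout; one extra
  inoculum-only sequencing sample.
* **Propagule densities** 0.02, 0.02, 0.2 propagules/mL soil: two
  low-density (bare-fallow-like) trials and one an order of magnitude
  higher (previous host cropping).
* **Inoculum share link**: for inoculated plots,
  `share = plogis(−2.21 − 0.845·log(density))` plus plot-level logit
  noise (s.d. 0.4). The intercept and slope are calibrated so that
  low-density trials give shares above 70% (inoculum dominance) and the
  high-density trial around 30% (limited colonization) — the regimes
  the method is meant to distinguish. Controls carry a 10% background
  share of inoculum-type OTUs; the mechanism (indigenous look-alikes
  versus contamination) is deliberately left open, so the background is
  a free parameter rather than a modeled process.
* **Yield model**: `3000 + 600·share + N(0, 100)` kg/ha, a ~20% ceiling
  effect over baseline at full dominance and a plot noise typical of
  grain-yield SEs; with the noise at zero, per-plot yield responses are
  exactly proportional to the centered share, which the tests exploit.
* **Reads**: 5,000 pairs per sample, mates of 230 nt from 360-nt
  reference templates (overlap 100 nt), per-base substitution errors at
  a mean 1% realized as a Q40/Q12 quality mixture so quality strings
  encode the true per-base error probabilities; 2% outgroup-derived and
  2% random junk pairs interleaved. Reference OTUs descend from a
  common ancestor at 15% divergence (inoculum OTUs form a 5% subclade),
  which keeps all AM pairs below 95% identity — verified by global
  alignment at generation time — so best-hit assignment has a margin.
  Local-alignment identity is meaningless for judging divergence of
  unrelated sequences (short perfect segments always exist), hence the
  global yardstick here.
* **Bioassay**: dilutions 2⁻¹, 2⁻³, 2⁻⁵, 2⁻⁷, 20 mL soil per pot,
  8 plants per level.

The generator does **not** simulate chimeras, indel errors, primer-site
mismatch bias, or PCR template-amount bias. Passing tests therefore
demonstrate that the pipeline recovers what this error model and
community model encode — classifier margins, share orderings,
regression signs, density contrasts — not that it is robust to every
artifact of real amplicon libraries.

Determinism is end to end: one master seed fans out to per-stage seeds
through a fixed affine map, and rerunning any generator function or the
whole pipeline with the same configuration is byte-identical.

## Problem sizes used in validation

The test suite runs the simulation-based checks at these sizes, chosen
to give the binomial standard errors the assertions need: 2,000 null
simulations for the PERMANOVA type-I-error calibration (at n = 20,
where the permutation p-value is uniform; very small designs are
intrinsically conservative because a visible fraction of relabellings
preserves the grouping), 500 stepwise-selection simulations at n = 48,
200 GLMM sign-recovery simulations, 200 MPN recovery simulations at
1,000 plants per level, a 5,000-read-pair classifier fixture, and
scaled-down demo pipelines (2 trials × 2 blocks, ~80 read pairs per
sample) for the byte-identity checks, since determinism does not depend
on size.

## Known limitations

* Tracked shares conflate inoculum-origin and indigenous reads of
  shared OTUs; the method is informative only when the inoculum has
  specific OTUs or shows dramatic increases on inoculation.
* Binomial GLMM p-values ignore read-level overdispersion; treat them
  as ranking evidence.
* The MPN MLE is biased upward at high densities when few plants are
  tested per level; widen the series or add plants when densities near
  the top of the assay's range.
* Rarefaction discards reads; the proportional-scaling alternative
  keeps them but breaks the integer sampling model.
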