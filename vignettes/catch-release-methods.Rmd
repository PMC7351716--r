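---
title: "Designing and evaluating sequence-selective catch-and-release pulldowns"
author: "catchRelease maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating sequence-selective catch-and-release pulldowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(Biostrings)
  library(catchRelease)
})
```

## The system being modeled

A methanol-responsive, oligonucleotide-grafted polyacrylamide copolymer can
pull DNA targets out of solution: the polymer carries universal *anchor
strands*, a programmable *catcher strand* hybridizes each target to an
anchor, and adding methanol precipitates the polymer together with
everything bound to it. Captured targets are recovered either
non-selectively (denaturation) or selectively by toehold-mediated strand
displacement (TMSD), in which a *release strand* nucleates at a
single-stranded toehold on the catcher and branch-migrates through the
binding duplex, evicting the target.

`catchRelease` implements the computational side of this workflow:

1. **Probe design** — tiling target transcripts with catcher binding
   sites, assembling the three-domain catchers, designing release strands,
   and screening for off-target capture.
2. **Process simulation** — a stochastic model of the dual-selection
   catch-and-release experiment.
3. **Depletion evaluation** — per-base and per-gene quantification of a
   targeted depletion from coverage tracks and TPM tables.
4. **Polymer characterization** — the conformation and capacity
   arithmetic used to describe the carrier material.
5. **Synthetic data** — seeded generators so that every step above is
   testable without external data.

## Catcher strand architecture and tiling

A catcher strand read 5'→3' is

```
[release site (toehold), 10 nt] [binding site, 38 nt] [adapter, 22 nt]
```

The adapter is shared by all catchers of a library and is complementary to
the polymer's anchor strand; the binding site is complementary to one
38-nt segment of a target; the optional toehold is where the release
strand nucleates. The domain order puts the toehold at the free 5' end,
away from the anchor-hybridized adapter, so it stays sterically
accessible. Both the order and all three lengths are parameters
(`designParams()`); the defaults are the geometry used in the depletion
experiments that motivated the package.

`tileRegion()` places contiguous, non-overlapping tiles of exactly
`bindingLen` from the region start and drops a trailing remainder, so
every binding site has identical length (uniform hybridization) and the
tile count is `floor(regionLength / bindingLen)`. Consecutive catchers
alternate between binding the sense and the antisense strand of the
target. Alternation matters for double-stranded (cDNA) targets: after
thermal denaturation, sense- and antisense-binding catchers occupy both
strands, blocking their re-hybridization, and fragmented molecules are
still caught because tiles cover the whole region. The starting strand is
not dictated by the chemistry; it defaults to sense and is configurable.
A `tileStep` different from `bindingLen` yields gapped or overlapping
designs for users who want them.

```{r design}
set.seed(7)
target <- DNAStringSet(setNames(
  paste(sample(c("A", "C", "G", "T"), 760, TRUE), collapse = ""), "tx1"))
csl <- designCSL(target, seed = 11)
csl
```

### Toehold generation

Release-site sequences are not dictated by the target; they only need to
be single-stranded in its presence. The generator rejection-samples random
toeholds and accepts one when its longest exact complementarity with any
target (either strand) is at most `releaseMaxComplement` (default 6 nt).
A stricter cap sounds attractive but is combinatorially unavailable:
essentially every 4-mer occurs in a few-hundred-nt target, so demanding,
say, ≤ 3 nt of complementarity for a 10-nt toehold has no solutions. Six
complementary bases are far below the stability needed to trap a toehold
at annealing-relevant temperatures. If no candidate passes within 200
draws the best one seen is used, with a warning.

The default 22-nt adapter (`defaultAdapter()`) is a synthetic placeholder
constant: real libraries must use the complement of the anchor strand
actually grafted to their polymer, which is batch-specific.

### Uniqueness and the off-target screen

Binding-site uniqueness is a hard invariant of `CatcherLibrary` (a
duplicate means two catchers address the same sequence, which breaks
subset-selective release), so duplicated targets fail at design time with
the collision listed. `screenOfftargets()` reports, for every
catcher × transcript pair, the longest exact substring shared on either
strand (engine: a dynamic-programming scan implemented in C++, verified in
the test suite against a quadratic brute-force oracle). The motivating
failure mode is a readthrough transcript that embeds a targeted segment
verbatim and is therefore co-captured; the synthetic transcriptome
generator can reproduce exactly this situation (`embedShared = TRUE`).
The default reporting threshold of 16 shared nucleotides is conservative:
shorter duplexes are unlikely to survive stringent annealing, and the
threshold is a parameter.

## The stochastic catch-and-release model

The simulator treats each molecule as an independent Bernoulli trial —
the experiments it emulates report ensemble efficiencies, not kinetics,
so no rate equations are fitted. Per `simParams()`:

| parameter | default | meaning |
|---|---|---|
| `eCapture` | 0.88 | capture probability, targeted ssDNA |
| `eCaptureDs` | 0.898 | capture probability, targeted duplex |
| `eRelease` | 0.90 | TMSD release probability (release strand present) |
| `pNonspecific` | 0.02 | capture probability, non-targets |
| `pNonspecificRelease` | 0 | release probability, nonspecifically captured |
| `minMatch` | 20 nt | contiguous complementarity defining "targeted" |

The single-strand and duplex capture efficiencies are kept as separate
parameters rather than pooled: they come from different experiments and
the duplex value folds in the sense/antisense re-hybridization
competition, which is not modeled mechanistically. Members known to
adsorb nonspecifically can be given a per-member override
(`pNonspecificOverride`), mirroring the one library strand that showed
consistent low-level background binding; no default value is assumed for
it. A member is "targeted" when it shares at least `minMatch` contiguous
complementary bases with some binding site; its best-matching catcher is
the one whose release strand later frees it.

Capture sends each molecule to the pellet (with the appropriate
probability) or leaves it in the supernatant; release moves pellet
molecules of release-addressed catchers into the released pool. Counts
are conserved per member by construction, and the class validity check
enforces it. The two stages draw from seeded, restored RNG streams
(`seed` and `seed + 1`), so runs are exactly reproducible and do not
disturb the caller's RNG state.

The *dual selection* property is the point of the architecture: capture
selects on the binding site, release selects again on the release site.
With `pNonspecificRelease = 0`, nonspecifically adsorbed molecules stay
in the pellet no matter how large `pNonspecific` is, so the released pool
contains only targeted members — the property tests sweep
`pNonspecific` up to 0.5 to verify purity stays at 100%.

```{r sim}
mix <- makeSsdnaLibrary(fixtureConfig(seed = 3))
seqs <- memberSeqs(mix)
tnames <- names(seqs)[order(width(seqs), decreasing = TRUE)][1:3]
csl2 <- designCSL(seqs[tnames], seed = 103)
res <- simulateCapture(mix, csl2, simParams(seed = 5))
rel <- simulateRelease(res, designReleaseStrands(csl2))
rel
head(summarizePulldown(rel), 4)
```

`expectedFractions()` gives the closed-form counterparts (depletion
`eCapture`, retention `1 - pNonspecific`, yield `eCapture * eRelease`,
purity from the abundance-weighted released amounts); the Monte-Carlo
results converge to them within binomial standard errors, which the test
suite checks at 10^5 molecules per member over 20 seeds.

## Evaluating a depletion experiment

**TPM.** `tpmFromCounts()` is the standard length-normalized rate scaled
to a million; quantification from reads (pseudo-alignment etc.) is
upstream and out of scope — count tables are consumed as inputs.

**Relative base count.** For a depleted transcript,
`r_i = (treated_i / N_t) / (control_i / N_c)` per base, with library-size
factors `N` computed from *untargeted* transcripts only: removing
high-abundance targets shrinks the library, and normalizing on untouched
transcripts keeps non-target profiles at ratio ~1. Positions with control
depth below `minCov` (default 10) are masked `NA` rather than producing
infinite or noise-dominated ratios. An optional odd moving-average window
smooths the trace (default 1 = off; the exact windowing used for the
published per-base figures is not specified, so smoothing is left to the
user). The per-transcript efficiency is `1 - mean(r_i)` over a
configurable evaluation interval — whole transcript by default, because
the averaging interval behind published per-transcript summaries is
likewise not printed.

**TPM-level efficiency.** Depleting an abundant gene renormalizes
everyone else's TPM upward, so the naive treated/control ratio is biased.
`depletionEfficiencyFromTpm()` rescales the treated column by the median
treated/control ratio over reference (untargeted) genes before computing
`1 - ratio`, clipped to [0, 1]. The median is robust to a few responsive
reference genes.

**QC.** `correlationQC()` computes Spearman and Pearson correlations on
`log10(TPM + 1)` excluding the depleted targets (the pseudocount is a
parameter); `countExpressedGenes()` uses a strict `> threshold`
comparison, matching the conventional "detected at > 1 TPM".
`unpairedTTest()` is the pooled-variance Student test with
`df = n_a + n_b - 2` — for triplicates vs triplicates, df = 4 — with
degenerate zero-variance inputs handled explicitly instead of erroring.

## Polymer characterization

The carrier is characterized by flow fractionation with light scattering;
the package implements the downstream arithmetic in fixed canonical units
(nm, µm³, g/cm³, g/mol):

- `apparentVolume(Rh)` = (4/3)πR_h³. (The volume is cubic in the radius
  as dimensional analysis requires; the formula is sometimes typeset
  without the exponent.)
- `apparentDensity(Mw, V)` = M_w / (V·N_A), with N_A the exact SI
  Avogadro constant.
- `waterFraction(ρ)` = 100·(1 − ρ/ρ_solution): multi-MDa coils occupying
  ~10⁻³ µm³ are ≥ 99.5% water, which is why interior anchor strands stay
  accessible.
- `fitScalingExponent(M, Rg)` fits `Rg = K·M^ν` by ordinary least squares
  in log-log space (ν ≈ 0.33 compact sphere, ≈ 0.5 theta-solvent chain).
  Instrument-level elution-curve fitting is out of scope; the fit applies
  to an already-extracted mass/radius series.
- `theoreticalCapacity(o, Mw)` = anchors per chain over chain mass, in
  nmol/mg; `capacityUtilization()` relates a measured capacity to it.
  Note the two capacity routes are deliberately both exposed: a nominal
  synthesis stoichiometry (~100 anchors on a ~5 MDa chain → 20 nmol/mg)
  and the fractionation-derived composition (~130 anchors on 8.47 MDa →
  ~15.3 nmol/mg) disagree, and the package does not guess a
  reconciliation.

```{r polymer}
characterizePolymer(polymerSpec("variant-10", Mw = 5.73e6),
                    VumCubed = 2.7e-3)
```

## What the synthetic data emulate — and what they do not

The generators (`fixtureConfig()` defaults) reproduce the *structure* of
the study inputs:

- a 10-member ssDNA mixture named A–J with lengths in 20–190 nt,
  rejection-sampled to < 16 nt pairwise cross-complementarity, equal
  molecule counts (10⁵ each by default);
- toy transcriptomes of uniform-composition random sequence (20 genes,
  0.5–2 kb), optionally with a readthrough-style shared segment;
- cDNA-style fragment pools with lengths uniform in 150–700 nt, 10⁵
  fragments per library, under a uniform or "dominated" abundance model
  (one gene consuming a configurable fraction of reads, half by default,
  standing in for the handful of genes that can consume most of a
  sequencing library);
- matched control/treated coverage pairs, where each fragment overlapping
  a binding-site interval by ≥ `minMatch` (20 nt, the simulator's
  targeting threshold) is removed with the capture probability.

Real data differ in ways the generators deliberately ignore: base
composition and GC structure (the design logic is composition-agnostic),
sequencing error and quality, PCR and fragmentation bias, non-uniform
fragment-length distributions, and isoform structure. Passing tests on
these fixtures therefore validate the *algorithms* — tiling arithmetic,
selection logic, normalization, estimator consistency, the
distance-decay of depletion around targeted regions (fragments reaching
into a targeted region drag their whole footprint down with probability
`e`, so depletion decays to zero over one maximum fragment length) — not
the wet-lab efficiencies themselves, which enter the simulator as
parameters.

## Numerical and design choices

- **Problem sizes.** The validation suite runs the simulator at 10⁵
  molecules per member across 20 seeds and coverage simulations at 10⁵
  fragments on 3-kb transcripts; TPM-recovery checks use 10⁶ multinomial
  reads. These sizes put Monte-Carlo standard errors well inside the
  tolerances being asserted while keeping the whole suite fast on one
  core.
- **Exact substring search.** The C++ dynamic program is O(|a|·|b|) with
  O(|b|) memory and deterministic tie-breaking (smallest start in the
  first sequence, then in the second, forward strand preferred). At probe
  (≤ 100 nt) against transcript (kb) scale this is faster than any index
  worth building; correctness is pinned to the brute-force oracle on
  ≤ 200-nt inputs.
- **Strict alphabet.** Degenerate IUPAC codes are rejected at
  construction everywhere — synthesis sheets must be unambiguous, and a
  silent `N` in a binding site would corrupt complementarity arithmetic.
- **Coordinates.** BED and bedGraph interfaces are 0-based half-open;
  internally everything is 1-based closed `GRanges`/`IRanges`, converted
  only at the I/O boundary. Off-target hits are reported in forward
  transcript coordinates even when the match lies on the reverse strand.
- **Seeds.** Every stochastic routine takes an explicit seed, uses a
  local RNG state, and restores the caller's; identical seeds give
  byte-identical outputs, which the order-sheet and simulation tests
  assert literally.
- **Degenerate inputs.** Zero-molecule mixtures summarize to empty
  reports; empty region sets give empty libraries; all-zero count columns
  give all-zero TPM with a warning; zero control coverage is masked, not
  divided by.

## Known limitations

- No hybridization thermodynamics: melting temperatures, toehold-length →
  rate curves and branch-migration kinetics are not modeled; capture and
  release are single-parameter Bernoulli processes.
- The off-target screen is exact-match only; near-matches with mismatches
  or gaps (which can still capture at permissive stringency) are not
  scored.
- Per-transcript depletion efficiencies depend on the evaluation
  interval; the default (whole transcript) mixes directly and indirectly
  targeted regions.
- The fragment model samples uniformly within transcripts; real coverage
  has 3'/5' bias under poly-dT priming.
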