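---
title: "Quantifying DNA methyltransferase flanking-sequence preferences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA methyltransferase flanking-sequence preferences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankpref)
```

# The scientific problem

De novo DNA methyltransferases (DNMT3A/B/C) do not methylate all CpG sites
equally: the bases flanking the target site modulate catalytic rates by up to
two orders of magnitude. `flankpref` implements the computational side of a
deep-enzymology workflow for measuring these preferences and relating them to
genomes: (i) processing of hairpin-bisulfite reads from substrate libraries
with randomized flanks, (ii) observed/expected (o/e) base-enrichment profiles
of the methylated product pool, (iii) fitting of the 256 NNCGNN rate
constants on a shared latent time axis, (iv) correlation of biochemical
preferences with whole-genome bisulfite methylomes, and (v) scanning of
retrotransposon-like sequences for CpG sites in a CCCG/CGGG context — the
double-stranded motif matching a C(-2)/C(-1) flanking preference. A synthetic
data module generates every input with known ground truth, so the full
pipeline is testable end to end without any external download.

# Hairpin-bisulfite reads and reconstitution

A substrate molecule is a duplex with a single central CpN site embedded in
10 randomized bases on either side, between fixed arms
(`substrate_layout()`). A hairpin oligonucleotide (27-mer) covalently joins
the two strands, so after bisulfite conversion a single read carries both:
the converted upper strand, the converted linker, and the converted lower
strand read back 5'→3' from the ligation point. The aligned partner of
upper-strand position $i$ is read position $2U + \ell + 1 - i$ (1-based,
$U$ = upper-strand length, $\ell$ = linker length).

Bisulfite chemistry maps each duplex position to a pair of read bases
$(u, v)$, and the pair is exactly invertible:

| upper $u$ | lower $v$ | original | note |
|---|---|---|---|
| A | T | A | |
| G | C or T | G | lower C converts when unmethylated |
| C | G | C | central site: **methylated** |
| T | G | C | central site: **unmethylated** |
| T | A | T | |

Any other pair is chemically impossible; reads containing one inside the
analysis window are discarded whole rather than position-masked (the
simplest defensible rule; the rate is logged and the count conservation
`input = survivors + dropped` is asserted in tests). Preprocessing follows
the standard recipe: trim to 128 nt, quality-filter at Phred ≥ 20 (strict
per-base minimum by default, with a mean-quality switch), and remove exact
duplicate read strings after alphabetical sorting. Deduplication operates on
the full trimmed string, so reads differing only in their methylation
pattern are *not* duplicates.

The central site is classified by the base at +1 (CpG/CpA/CpT/CpC). For CpA
and CpT substrates, calls whose original sequence matches CCWGG at
(-1..+3) are excluded: that motif overlaps the *E. coli* dcm
methyltransferase present in typical expression strains, so its methylation
cannot be attributed to the enzyme under study.

# o/e flanking profiles

For the methylated product pool, the frequency of each base at each position
in -8..+8 (excluding the fixed central dinucleotide) is divided by its
frequency in the *total* analysed pool. Using the total pool as the
expectation (rather than a theoretical 0.25, which is available as an
option) makes the profile robust to library composition bias; the synthetic
library exposes a composition-bias parameter precisely to exercise this. The
construction guarantees the normalisation identity
$\sum_b f_{\text{total}}(b,p)\, \mathrm{oe}(b,p) = 1$ at every position,
which the tests assert to 1e-9 on both uniform and biased libraries.
The window is restricted to -8..+8 because positions further out approach
the fixed arms and carry no flank information.

Replicate profiles are merged by pooling raw base counts and recomputing o/e
(count-weighted), not by averaging o/e values; an averaging mode exists for
comparison. Pairwise Pearson correlations of the inputs are reported with
the merge so that discordant replicates are visible.

# The virtual-time kinetic model

Each methylation reaction $j$ (its own enzyme concentration and incubation
time) methylates context $i$ as a first-order progress curve

$$ m_{ij} = P\,\bigl(1 - e^{-k_i \tau_j}\bigr), $$

where $k_i$ is the context's rate constant, $\tau_j$ a latent per-reaction
"virtual time" absorbing concentration and duration, and $P$ the plateau
(fixed at 1 by default; a single fitted plateau is available for incomplete
conversion). Only the products $k_i\tau_j$ are identified, so the gauge is
fixed by scaling the geometric mean of the fitted $k$ to 1 — symmetric in
the contexts and directly interpretable as *relative* rates; virtual times
are rescaled inversely. Tests assert exact invariance of the gauge-fixed
output under $(k, \tau) \to (ck, \tau/c)$ for $c \in \{0.1, 10\}$.

Fitting minimises the weighted least squares
$\sum_{ij} w_{ij}\,(m_{ij} - P(1-e^{-k_i\tau_j}))^2$ with weights equal to
per-context read counts, since levels estimated from few reads are noisier
(binomial). Contexts need at least `min_count = 10` reads in at least two
reactions to enter the fit; a context observed in a single reaction is
excluded and reported, because its rate and the reaction's time are
confounded. The optimiser alternates Gauss–Newton blocks for $k$ (256
independent 1-D problems) and $\tau$ with backtracking line search, starting
from the single-reaction closed form $k = -\ln(1-m)/\tau$ and iterating to a
relative SSE change below 1e-10. This serial refinement is run from three
restarts (multiplicative log-normal jitter, sd 0.3) and the fit is flagged
converged only when all restarts agree in SSE within 1e-6 relative — the
restart agreement is the convergence validation, and the alternating scheme
reaches the same stationary point as a joint Newton step at far lower cost.
Degenerate contexts are flagged with sentinels rather than fitted: all-zero
levels give $k = 0$, all-at-plateau levels give $k = +\infty$.

With one reaction and $\tau$ frozen, the fitter reproduces
$k = -\ln(1 - m)$ exactly, which tests use as an independent closed-form
oracle. On noise-free 4-reaction data the fit recovers rates to machine
precision; on reads the recovery property is tested at 4 reactions × 50 000
reads with true rates log-uniform over two decades, where the Spearman
correlation of true and fitted rates exceeds 0.95 and the dynamic range
(fitted rate ratio at the true extreme contexts) is recovered within ±25%.
The extreme-value ratio $\max_i \hat k_i / \min_i \hat k_i$ is *not* used
for that check: a maximum over 256 noisy estimates is biased upward by
selection (winner's curse), so the ratio at the true extremes is the honest
parameter-recovery measure.

The simulated reaction series uses virtual times (0.08, 0.35, 1.5, 6.5) —
geometrically spaced so that every rate in the two-decade range has at least
two reactions in the informative part of its progress curve (roughly 20–90%
methylation), which is how real reaction series are designed.

Class-level (CpG vs CpA/CpT/CpC) rates use the same model at 4-class
granularity, optionally with virtual times frozen from the CpG fit, and are
reported relative to CpG = 1. Radioactive-assay progress curves are handled
by ordinary least squares on the initial linear phase; the difference of
hm - fm substrate slopes isolates the central-site rate with its standard
error propagated in quadrature.

# Genomic methylomes

`load_methylome()` joins a bedGraph-like call table (a Bismark-coverage
dialect reader is included) with the genome, keeps CpG cytosines with
coverage ≥ 5, and annotates each with its 22-nt context. Each strand's
cytosine is a separate record with a reverse-complemented context — lossless
with respect to strand-specific methylation — and a `collapse_strands`
switch merges CpG pairs for strand-symmetric analyses. Per-context means are
unweighted across sites ("average methylation level per site"), with a
coverage-weighted mode available; o/e is the context mean over the overall
mean, which makes it invariant under global rescaling of levels.

The local-correlation analysis slides a window of 22 consecutive CpG sites
(step 1) along a chromosome and computes the Pearson correlation between
per-site methylation and per-site biochemical preference; windows with a
constant vector are skipped and counted. Significance uses a randomization
test: the 256 preference values are permuted *among the context keys* (not
among sites — site-level shuffling would break the context structure being
tested), the analysis is repeated (≥ 20 rounds), and
$Z = (\mathrm{obs} - \mu_{\text{null}})/\sigma_{\text{null}}$ with an
upper-tail normal p. The default statistic is the mean window $r$;
the positive-minus-negative window count is available as an alternative.
Null calibration is itself tested: on methylomes whose preferences are
shuffled before analysis, $|Z| < 3$ in ≥ 99% of 100 seeds (50
randomizations per seed, where the Z statistic's null tail is close to
normal).

The synthetic methylome draws an i.i.d. genome (GC 0.42, mouse-like) and
gives every CpG cytosine a true level proportional to its context
preference, scaled to a target mean of 1.5% — the order of magnitude of a
DNMT3C-only (6KO) methylome — then samples counts binomially at
Poisson-distributed coverage (mean 10). What it deliberately does *not*
emulate: CpG islands and regional methylation domains, strand-asymmetric
maintenance, coverage biases correlated with composition, or
hydroxymethylation. Passing tests therefore demonstrate correctness of the
statistical machinery under a per-site independence model, not robustness
to the spatial structure of real methylomes.

# Repeat-element motif scanning

Motif counting is a sliding exact match with overlaps allowed (a CCCGGG
hexamer contributes one CCCG and one CGGG; the double-count is deliberate
and recorded, since occurrences are defined independently per strand
pattern). Expectations use the element's own mononucleotide composition:
$E[\mathrm{CG}] = n\,f_C f_G$, $E[\mathrm{CCCG}] = n\,f_C^3 f_G$,
$E[\mathrm{CGGG}] = n\,f_C f_G^3$ with $n$ the number of start positions.
A Markov-1 background is a known refinement but the mononucleotide model is
the stated reference here; because composition only enters through
$\{f_C, f_G\}$ swapping under reverse complement, the combined CCCG+CGGG
o/e is exactly strand-invariant (tested to 1e-12). The "fraction" statistic
— the proportion of CpG sites in a CCCG or CGGG context, normalised by
$f_C^2 + f_G^2$ — asks specifically whether CpGs *cluster* in the preferred
flank context beyond what CpG and composition alone predict.

Windowed profiles use non-overlapping 50-bp tiles (a sliding mode exists),
with the final partial tile kept when ≥ 25 bp, and the whole-element
composition as expectation so tiles are comparable along the element.
Group comparisons of element-level fraction o/e use a two-sided Welch
t-test (unequal variances, Welch–Satterthwaite df). Promoter/sub-region
boundaries must be supplied explicitly; the package does not infer them.

# Numerical and design choices

* Extreme-decile composition summaries take the top/bottom ⌈0.10·N⌉
  contexts with ties broken by lexicographic context order after the value
  sort — determinism over elegance.
* Coordinates are 0-based half-open internally and in call tables; 1-based
  only inside R string manipulation. The central C is position 0; the CpN
  partner is +1; flanks are -10..-1 and +2..+11; analyses use -8..+8.
* All simulators take explicit integer seeds and are byte-reproducible;
  every stochastic test fixes its seed.
* Problem sizes used by the test-suite and the acceptance script — 10 000
  reads for round-trip identity, 4 × 50 000 reads for rate recovery, a 1 Mb
  methylome at coverage 10, 100 kb i.i.d. sequence for motif calibration,
  100 seeds for null calibration — were chosen as the smallest scales at
  which the binomial/permutation error bands quoted above are meaningful.

# Known limitations

* The virtual-time model assumes independent first-order site methylation;
  processivity, substrate depletion and multi-site kinetics are out of
  scope.
* Rates stuck at sentinels (0 or ∞) are reported but cannot be ranked
  within the fitted set.
* The read simulator emits substitution noise only; indels and paired-end
  structure are not modelled, and the reconstitution assumes fixed layout
  coordinates (it verifies the linker rather than aligning).
* The genomic Z-test calibration assumes exchangeability of the 256
  preference values under the null; preferences correlated with regional
  genome composition could inflate Z on real data.
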