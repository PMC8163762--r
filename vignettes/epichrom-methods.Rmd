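---
title: "Models and methods in epichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in epichrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epichrom)
```

`epichrom` re-implements, as a tested pipeline, the computational layers of a
synthetic-methylome experiment: budding yeast (which has no native cytosine
methylation, no methyl-DNA readers, and a Rabl nuclear arrangement with the
sixteen centromeres clustered at the spindle pole) is given the mammalian DNA
methyltransferases, and the consequences are read out by bisulfite and
nanopore sequencing, MNase-seq and Hi-C. Each analysis layer here consumes
simple text formats and is verifiable end to end against the package's own
synthetic-data generators, which emit every input with known ground truth.

This vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic tests do and do not establish
about real data.

## Read-level methylation mixtures

A long read assaying $n$ CpG sites with $m$ methylated calls is modeled as a
binomial mixture,
$$ m \mid c \sim \mathrm{Binomial}(n, p_c), \qquad \Pr(c) = w_c , $$
with three components by default (unmethylated, lowly methylated, highly
methylated). `fit_mixture()` maximizes the likelihood by EM on $(n, m)$
profiles collapsed to unique rows, so the cost per iteration is independent
of library size. Numerical choices:

* Rates are clipped to $[10^{-6}, 1-10^{-6}]$ inside E-steps; the reported
  rates are raw M-step values, so boundary components converge to exactly 0
  or 1, and the final log-likelihood is evaluated with a negligible clip
  ($10^{-12}$) so boundary fits score their exact likelihood.
* Twenty random restarts (quantile-spread initial rates, Dirichlet(1)
  weights) plus one deterministic restart at the pooled-rate stationary
  point. The deterministic restart guarantees the $C$-component fit is never
  worse than the nested one-component fit, so the likelihood-ratio statistic
  is nonnegative by construction.
* Reads with fewer than 5 assayed CpGs are dropped by default: they carry
  almost no information about small rate differences and destabilize the
  low-rate component.

`lrt_homogeneity()` tests one rate against a $C$-component mixture with
$\Lambda = 2(\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})$. The null lies on
the boundary of the mixture parameter space, so the nominal $\chi^2_{2(C-1)}$
reference is not trustworthy; the default reference is a parametric
bootstrap. Two properties of this statistic matter for interpretation:

* **The null atom.** A binomial mixture can only add overdispersion relative
  to a single binomial. For an underdispersed null sample the alternative
  MLE coincides with the null and $\Lambda = 0$ exactly; empirically this
  happens for roughly 40-50% of homogeneous datasets. Bootstrap p-values
  therefore pile mass at 1 and are *valid* (rejection rates at small
  $\alpha$ are calibrated) but not marginally uniform.
* **Exchangeability.** The observed statistic and every bootstrap statistic
  are computed by an identical capped procedure (same restart recipe, same
  EM iteration cap), and bootstrap datasets are drawn on the collapsed
  profile scale (multinomial over $m = 0..n$ per unique $n$). Because the
  near-null likelihood ridge converges sublinearly, the cap
  (`boot_max_iter`, default 30) saves most of the EM cost; calibration is
  unaffected because all $B+1$ statistics share the budget.

## DNMT sequence specificity

Contexts are the two bases on each side of a CpG (6-mers with a central CG,
256 possible). With the motif as the only categorical predictor of pooled
methylated/unmethylated counts, the logistic-regression MLE per motif is the
empirical log-odds; `fit_motif_effects()` uses the Jeffreys-smoothed closed
form $\log\{(n_1 + \tfrac12)/(n_0 + \tfrac12)\}$ with delta-method standard
error $\sqrt{1/(n_1+\tfrac12) + 1/(n_0+\tfrac12)}$, which stays finite at
all-methylated or all-unmethylated motifs and avoids an arbitrary reference
level. Sites need at least 10 mapped reads (configurable).

A motif is flagged significant when its deviation from the across-motif mean
effect exceeds **both** two per-motif standard errors and two across-motif
standard deviations of the effects. The first condition is statistical
(the deviation is real), the second makes the flag an outlier criterion: at
high coverage every standard error shrinks toward zero and a pure 2-se rule
would flag ~5% of null motifs per table, which defeats the purpose of
singling out strong contexts. `vs_zero = TRUE` switches the center from the
mean effect to zero. Cross-sample agreement (`compare_effects()`) is a
Pearson correlation over shared motifs, inverse-variance weighted by
default.

## Restraint-based 3D chromosome models from Hi-C

The pipeline is: iterative correction, power-law conversion of contact
frequencies to target distances, a harmonic restraint system, annealed
sampling, and greedy ensemble selection.

**Balancing.** `ice_balance()` divides by the outer product of row marginals
until unmasked per-bin coverage is uniform within `tol`, preserving the
total count; all-zero bins are auto-masked.

**Conversion.** For frequencies above twice the median of all trans
(inter-chromosomal) counts, $d_{ij} = \gamma / f_{ij}^{\alpha}$. $\gamma$
sets the length scale (real applications match it to a measured nuclear
diameter; the default scales the median consecutive-bead distance to one
model unit — all recovery statistics used in the tests are scale-free).
Pairs below the cutoff are recorded as non-interacting. A single-chromosome
matrix has no trans counts; the cutoff then falls back to a cis quantile
(default 0.75) with a warning.

**Restraints.** Consecutive beads get harmonic restraints with a force
constant $10^5$ times the interaction constant; gaps over masked bins get
proportionally longer equilibrium distances. Interaction restraints use a
flat-welled parabola $E = k(r - r')^2$ that is zero within one bead radius
of $r_0$ and quadratic outside. Every pair receives a purely repulsive
truncated-shifted Lennard-Jones excluded volume with its minimum at one bead
radius (well depth $0.1\,k\,r_\mathrm{bead}^2$), and non-interacting pairs a
one-sided quadratic keeping them beyond the largest converted distance. The
bead radius defaults to half the median consecutive-bead distance. A
*violation* is an interaction restraint whose realized distance falls
outside $r_0 \pm r_\mathrm{bead}$.

**Sampling.** `sample_structures()` alternates normalized steepest-descent
steps (backtracking line search, step capped at a few bead radii) with
Metropolis-accepted random bead perturbations under a geometric temperature
schedule. The potential, not the integrator, carries the physics; a
deterministic, seedable optimizer makes every test reproducible.
Initializations: a distance-geometry embedding (all observed frequencies
converted to distances, shortest-path completion, classical MDS — the
standard start for restraint-based structure calculation), an extended
conformation, or a random localization; `"mixed"` cycles all three. The
distance-geometry start is what lets desk-scale budgets reach the
restraint-consistent basin; naive starts alone need an order of magnitude
more steps. Note that pairwise distances cannot fix chirality: a model and
its mirror image satisfy the same restraints.

**Ensemble selection.** `select_ensemble()` implements the greedy rule
exactly: discard candidates with more violations than the candidate mean;
seed with the fewest-violations candidate; repeatedly add the candidate
satisfying the most restraints not yet satisfied by any selected member;
stop when no candidate adds a new restraint. Ties break by lower total
energy, then input order. The suite checks the implementation against an
independent brute-force restatement of the rules on hundreds of random
instances.

**Fitting $\alpha$.** `fit_alpha()` runs reduced-budget models over a grid.
The default objective is the interaction-violation fraction with a
"largest feasible exponent" rule: exponents below the truth always embed
more easily (a power below 1 of a metric is still nearly a metric, while a
power above 1 breaks triangle inequalities), so feasibility identifies
$\alpha$ from above, and the rule returns the largest grid value within a
margin (0.08) of the minimum violation fraction. A map-correlation
objective is retained for comparison (`method = "map_pearson"`) but
discriminates poorly: on the log scale the power law is a linear
reparameterization for every exponent, so map-vs-log-count correlations are
nearly $\alpha$-invariant and react mostly to noise.

**What balancing does to synthetic round trips.** In data generated from a
single known structure, per-bin coverage variation *is* distance
information. Iterative correction removes it: balanced frequencies are
$f_{ij}/(b_i b_j)$, i.e. converted distances acquire per-bin multiplicative
factors. With noiseless expected counts the rank correlation between
converted and true distances is 1.000 before balancing and about 0.66 after
(4-chromosome toy, Rabl strength 0.8); at the default simulated depth the
unbalanced ceiling is ~0.93. The modeled ensembles reach — and, thanks to
the 3D embedding rejecting part of this unembeddable distortion, sometimes
slightly exceed — the balanced ceiling, but no pipeline with full iterative
correction can recover truth ranks beyond it. On real Hi-C data the
balanced estimate is the better one, because there the marginal variation
is dominated by technical bias; the synthetic round trip deliberately
reports both the map correlation and the distance-rank correlation so this
ceiling stays visible.

**Metrics.** `structure_metrics()` reports the radius of gyration of beads
within 100 kb of each centromere (mean ± SE over members), per-bead
flexibility as the RMSD after Kabsch superposition of each member onto the
iterated ensemble mean shape, all pairwise telomere-bead distances divided
by their grand mean (mean exactly 1 by construction), and named locus-pair
distances.

## Nucleosome fibers from MNase coverage

**Deconvolution.** The expected pileup of center-trimmed fragments (50 bp,
matching the trimmed-fragment convention) around a dyad is a Gaussian
positional spread convolved with the fragment box; `deconvolve_coverage()`
uses exactly this composite kernel in a matching-pursuit loop (best single
kernel fit to the residual, subtract, stop when the residual peak falls
below `min_weight` of the global maximum), followed by joint nonnegative
least squares on the amplitudes. Width and height scores normalize the
fitted spread and amplitude; calls with width score > 0.6 and height score
> 0.4 are well-positioned, the published thresholds. The spread bounds
default to 10-60 bp.

**Families.** `enumerate_families()` forms maximal subsets of placements
whose adjacent dyads are at least $147 - 80 = 67$ bp apart (80 bp maximum
footprint overlap); fuzzy calls branch into placements at $\mu$ and
$\mu \pm \sigma$. Family weight is proportional to the product of member
occupancies. `select_families()` then greedily keeps the families whose
weighted expected coverage best correlates with the observed track — a
stand-in for the unpublished clustering objective, chosen because it is
deterministic and its greedy structure guarantees the kept set scores at
least as well as any discarded single family.

**Fiber model.** Linker DNA is represented per base-pair step by six
helical parameters (shift, slide, rise, tilt, roll, twist) with harmonic
stiffness around an average B-DNA equilibrium (rise 3.4 Å, twist 34.3°,
others 0; stiffnesses in kT per squared unit chosen so thermal standard
deviations are ~0.2 Å in rise and ~4.5° in twist/roll/tilt). Nucleosomes
are rigid: 147 bp on a left-handed superhelix (radius 41.8 Å, pitch
25.9 Å, 1.65 turns) attached at the current tangent. Debye-Hückel
electrostatics (one charge site per 5 bp, screening length 8 Å ≈ 150 mM
monovalent salt) and excluded-volume terms between charge sites and
nucleosome centers prevent overlaps; moves creating hard overlaps are
rejected outright. All of these constants are surfaced in
`fiber_geometry()` so alternative parameterizations need no code changes;
the force constants are this package's configuration, not published
values, so parameter-recovery tests target the configured values only.

`mc_sample_fiber()` is plain Metropolis over single-parameter Gaussian
perturbations. Elastic energy updates are local; the path is rebuilt for the
nonbonded terms. Incremental energies are checked against full
recomputation every 1000 steps (drift must stay below $10^{-6}$), and
acceptance below 1% over a 500-move window halves the step sizes with a
warning. At zero temperature only energy-decreasing moves are accepted, so
an equilibrium start stays put — the fixed-point sanity check.

## Profiles

`anchored_profile()` averages per-bp signal in ±`flank` windows (default
850 bp) around anchors, reversing minus-strand windows;
`gene_body_profile()` rescales each gene to 137 bins by length-proportional
index mapping (genes shorter than 137 bp spread single base pairs over
several bins); `dyad_methylation_profile()` reports, per offset from the
dyad, the fraction of CpGs with methylation level above 0.01 and the mean
level, per call class and optionally per strand;
`promoter_stratified_nfr()` stratifies genes by mean promoter methylation
(TSS ± 850 bp, the same flank as the figures, since no separate promoter
window is published) into top/bottom deciles and the 45-55% band, and
measures nucleosome-free-region widths as the dyad distance of the -1/+1
calls minus 147 bp. Methylation probability per site is operationalized as
`n_meth / depth`; the standard call filter (more than 10 reads, level above
0.1) and the 500x coverage cap are applied by `apply_site_filters()` and
are configurable.

## Synthetic data: what it does and does not emulate

The generators draw mixture reads, context tables, MNase fragment pileups,
self-avoiding bead chains in a spherical nucleus with a Rabl-like
centromere bias and optional local compaction, and Poisson Hi-C counts from
the inverse power law, each deterministic given (parameters, seed) and each
emitting its hidden truth. Defaults mirror the study conditions: 5 kb
bins, a four-chromosome 150-400 kb toy genome (30-80 beads per chromosome)
so full pipelines run in minutes, 20-100 CpG sites per read as in long-read
libraries, 50 bp trimmed fragments, and three-component mixtures with
rates near 0/0.08/0.30.

They deliberately omit: bisulfite conversion errors and sequencing error
models, restriction-fragment-level Hi-C biases (a multiplicative per-bin
bias vector is available to exercise balancing, but no fragment/GC model),
sequence-dependent DNA elasticity, and positional correlation of
methylation along a read. Passing tests therefore establish that the
estimators recover the truth *under the stated generative models*; on real
data the additional noise sources will widen every tolerance, and the
iterative-correction ceiling discussed above applies specifically to
polymer-derived synthetic maps.

## Problem sizes used in the tests

The suite and the acceptance script run, per invocation: 20,000-read
mixture recoveries; 200 (tests) or 60 (script) null LRT datasets of 5,000
reads with 199 bootstrap replicates each; 6,400-site context tables over 64
motifs with 50-100 planted-motif replicates; one four-chromosome Hi-C round
trip at depth $10^6$ with ten annealed replicas per chromosome; ten seeded
exponent-recovery runs on a single 250 kb chromosome; 500 random
ensemble-selection instances; and fiber samplers of a few hundred bp for
tens of thousands of Monte Carlo moves. These sizes were chosen so each
stage completes in minutes on a single core while leaving the recovery
margins comfortably away from their thresholds.
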