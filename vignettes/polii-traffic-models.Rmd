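---
title: "Models and methods: polymerase traffic under methyl-CpG protein binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: polymerase traffic under methyl-CpG protein binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative assay models, the mechanistic gene-expression models, the
simulation engine, and the places where a design had to be chosen because
the underlying methodology leaves it open.

## 1. The quantitative setting

A methyl-CpG binding protein occupies a fraction *p* of the mCG
dinucleotides of the genome, with *p* proportional to its cellular level
*M* (wild type = 1). Its effect on expression is read out as the log2 fold
change (Log2FC) of each gene against a control line, binned by the
gene-body mCG density ρ~mCG~ (mCGs per 100 bp). Because absolute mRNA
amounts are not measured, every binned curve is shifted by a single
additive constant so that the gene-weighted average Log2FC over
ρ~mCG~ ∈ [1, 6] is zero (`bin_log2fc()`); all model comparisons therefore
align curves by a free additive constant before scoring
(`align_curves()`).

Coordinates are 0-based and half-open throughout; an mCG is anchored at
the position of its C on the forward strand, and methylation is treated as
symmetric at CG, so only the forward-strand C is recorded.

## 2. Synthetic data

`generate_genome()` places a requested number of CG dinucleotides
(density × length) at uniform non-overlapping positions in a random
background of the requested GC content, then mutates any accidental CG so
the emitted methylome enumerates *every* CG in the sequence — the
downstream assay models rely on that completeness. Each CG is methylated
independently with probability `meth_frac`.

`simulate_read_calls()` draws per-site coverage from a Poisson
distribution (the methodology this emulates does not specify a coverage
law; Poisson is the neutral choice) and methylated-read counts from a
binomial with a symmetric per-read error. `call_methylation()` then applies
the strict call rule: methylated only when all reads agree and coverage is
at least 5; unmethylated only when no read reports methylation (at least
one read required — zero coverage is ambiguous, a deliberate tightening of
"no read showed methylation", which is vacuous at zero coverage).

`generate_gene_panel()` lays genes end to end on a virtual contig with a
2-kb promoter window upstream of each TSS (the promoter interval is not
pinned down by the methodology; 2 kb is a common operational choice and is
configurable). mCG positions are placed uniformly inside each body, and
`n_mcg`/`rho_mcg` are recomputed from the placed positions, so
ρ = 100·N/L holds exactly for every gene.

**What the generator does not emulate:** nucleosomes and CpG islands,
non-CG methylation, real genomic coordinate structure, mappability, and
the correlated replicate structure of real sequencing noise. Passing tests
on this synthetic data therefore demonstrates the correctness and
internal consistency of the estimators and the discrimination logic, not
their robustness to every artefact of real libraries.

## 3. In-silico ChIP-seq and ATAC-seq

Binding is Bernoulli per site with probability *p* × affinity(motif)
(`simulate_binding()`). The affinity table ships with placeholder values
(mCG = 1, mCA = 0.35, CG = 0) because calibrated relative affinities are
not available here; only the mCG entry matters for the shipped analyses.

**ChIP** (`simulate_chip_library()`): fragments with truncated-normal
lengths (mean 200 bp, sd 50, min 50 — a typical sonication profile; the
distribution is not specified by the methodology and is configurable) are
retained with probability 1 if they cover a bound position and *p*~bg~
otherwise; the input library is the same operation with no bound sites and
*p*~bg~ = 1. GC and length retention biases are available as
exponential-tilt weights but default to off; their functional forms are
declared interpretations, not calibrated models.

**ATAC** (`simulate_atac()`): candidate insertion sites are drawn with
mean density *t* per bp, weighted by 1 + (b − 1)·GC₁₀ (GC fraction in a
centred 10-bp window; b = 6 by default) — one admissible reading of a
scalar "GC bias" — and rejected inside the protected span (11 bp, centred
on the bound mC). A Tn5 sequence-motif bias hook exists but defaults to
off.

Profiles (`profile_counts()`) accumulate read-overlap counts (ChIP,
radius 500) or insertion counts (ATAC, radius 100) around anchors,
skipping anchors within one radius of a contig end rather than padding.
`normalize_flanks()` divides by the flank mean (offsets ±[301, 500]/400
for ChIP, ±[41, 50]/20 for ATAC), making the flank mean exactly 1.
Enrichment is the flank-normalized ratio minus one; the footprint is the
natural log of the flank-normalized insertion ratio against the knockout
control. Log-ratios of profiles containing zeros receive a 0.5
pseudo-count on both sides (with a warning): it keeps the estimator finite
while perturbing the flank normalization only at second order.

### Fitting

Both fitters (`fit_chip_model()`, `fit_footprint()`) are seeded grid
searches minimizing the mean squared deviation between simulated and
observed profiles, with ties broken toward smaller *p* (the conservative
direction). Two numerical choices matter:

* **Common random numbers.** All grid points share the same replicate
  seeds, so simulated curves vary smoothly along the grid and the argmin
  is driven by the observed data's noise rather than by independent
  simulation noise at every grid point. The full objective surface is
  returned, and `fit_chip_model()` reports a near-optimal set using the
  replicate-to-replicate spread of the objective at the minimizer as the
  noise floor — occupancy can be genuinely flat over a range of small *p*,
  and the surface keeps that visible instead of collapsing it to a point
  estimate.
* **Quadratic refinement.** When the minimizing *p* is interior,
  `fit_footprint()` interpolates a parabola through the three neighbouring
  objective values to produce a continuous `p_refined` alongside the grid
  minimizer `p_hat`. This decouples estimate precision from grid spacing;
  the wild-type occupancy (~0.006) would otherwise be quantized at any
  affordable grid.

Because flank normalization removes overall insertion density, the
footprint shape is nearly independent of *t*: `t_hat` is weakly identified
by design and is reported as such.

`occupancy_relation()` fits *p* = *k*·*M* through the origin by least
squares; `evaluate_occupancy()` clips predictions to [0, 1].
`accessibility()` implements the peak-over-background ratio: peaks are
positions with n~i~ > 4·n̄ and a = Σ~peaks~ n~i~ / n̄ (zero when no peak;
an all-zero gene is an error because the background is undefined).

## 4. The TASEP engine

A gene is a chain of L sites, one site = 60 bp ≈ the Pol II footprint, so
a particle occupies exactly one site. Particles enter at site 1 with rate
α when it is free, hop forward under hard-core exclusion with rate
v = 1 s⁻¹ (≈60 bp/s), and exit from site L with rate β = 1 s⁻¹. Three
variants represent protein-bound mCGs:

* **slow sites** — static sites with out-hop rate v~s~ = 0.05 s⁻¹, placed
  with per-site density p·ρ~mCG~·0.6 (`site_density()`);
* **dynamical obstacles** — a second species binding free mCG sites with
  rate k~u~·p and unbinding with rate k~u~ = 0.04 s⁻¹ (mean residence
  25 s). A bound obstacle blocks hops into its site; obstacles never bind
  a site occupied by a polymerase or another obstacle, and blocked binding
  attempts are discarded, not queued;
* **slow-down obstacles** — identical kinetics, but a particle on an
  obstacle-bearing site hops out at v~s~ instead of being blocked, so the
  two species may transiently co-occupy a site.

The engine (`src/tasep.cpp`) is an exact continuous-time Gillespie
simulation with event classes (entry, exit, fast hops, slow hops, bind,
unbind) maintained incrementally in O(1) per event. Rates are given in
s⁻¹, which makes the exact event-driven scheme the natural choice over
discrete random-sequential updates and keeps closed-form oracles
(J = α(1−α) in the low-density phase, J = 1/4 on the maximal-current
plateau, stationary obstacle occupancy p/(1+p)) directly comparable.
Exclusion is asserted inside the engine at every hop. It uses R's RNG, so
`set.seed()` (via the config seed) makes every run reproducible.

Unit conversion: the defining relation ρ~s~ = p·ρ~mCG~ leaves the per-site
basis implicit; this package converts per-100-bp densities to the 60-bp
lattice by ×0.6 and says so everywhere a density crosses that boundary.
Since ρ~mCG~·0.6 exceeds 1 for ρ~mCG~ > 1.67, a lattice site may hold
several mCGs (`mcg_site_layout()`): the obstacle-binding rate at a free
site scales with its mCG count m, one obstacle blocks the whole site, and
the stationary occupancy becomes pm/(1+pm). For the dynamical variant the
obstacle density is p = M/M~OE11x~ = M/11, clipped to [0, 1] for
hypothetical levels above the calibration point.

Defaults: burn-in 10·L/v, measurement 50·L/v with 10 batch means for the
current's standard error (no protocol is prescribed by the methodology;
these lengths put the batch-mean error well under the quenched-layout
spread discussed below). Obstacles start in their stationary occupancy
("equilibrium" initialization) so the burn-in does not need to cover the
slow k~u~ timescale; "none" and "all" initializations are available for
frozen-limit and blockade experiments.

### Quenched disorder and replicate averaging

For a single gene the mCG layout is fixed — quenched disorder. At desk
scale the current through one layout fluctuates from layout to layout far
more than from run to run, so `predict_log2fc()` averages currents over
`n_rep` independent layouts (default 6), sharing the seed between the two
cell lines within each replicate (the lines differ only in obstacle
density, so ρ~mCG~ = 0 or p~X~ = p~Y~ gives exactly zero). Averaging over
layouts is the in-silico counterpart of the experimental averaging over
the many genes of a density bin.

`fit_initiation()` fits one α per density bin on a grid, using one
representative lattice length per bin (the panel median, ≈9 kb = 150
sites) rather than per-gene simulation — matching the "average initiation
rate per density bin" reading at tractable cost. A bin is flagged
non-identifiable when the predicted Log2FC varies less across the α grid
than twice its Monte Carlo error; this happens by construction when
p~X~ = p~Y~, and in practice at high density where both currents saturate
(the congested phase), leaving α only weakly constrained. The fitted α
table is then reused, without refitting, to predict every other line pair
(`predict.tasep_fit()`).

## 5. Expression models and the discrimination protocol

* **Detachment**: Log2FC~X/Y~ = const − γ(M~X~/M~Y~ − 1)·n, linear in the
  total mCG count n; `fit_detachment()` recovers γ and the constant by
  ordinary least squares from one training pair and is exact on noiseless
  formula-generated data.
* **Condensation**: the predicted curve for a pair is the per-gene
  log2 accessibility ratio, binned with the same zero-shift convention;
  it needs no training pair and is scored directly.
* **Congestion** (both TASEP variants): α fitted per bin on the
  highest-overexpression pair, predictions generated for all others.

`discriminate_models()` scores every candidate by the mean
constant-aligned squared deviation over held-out pairs only (the training
pair is excluded from the congestion and detachment scores), ranks by
score, and breaks ties in a fixed declared order. Training pairs follow
the conventions of the study design this emulates: detachment trains on
the knockout pair, congestion on the highest-overexpression pair; both are
configurable.

The forward generator (`forward_generate()`) defines the study
conditions:

* seven lines at M = 0, 0.3, 0.6, 1, 2, 4, 11 (knockout, two knockdowns,
  wild type, three overexpressions), each against a control at M = 1;
* additive Gaussian per-gene Log2FC noise, sd 0.3 — a typical replicate
  scatter for moderately expressed genes in a two-condition comparison;
* a single true initiation rate α = 0.06 s⁻¹ for the TASEP truths, inside
  the sensitive (pre-saturation) part of the J(α) curve;
* detachment γ = 2.5×10⁻⁴ (an 11-fold line represses a 400-mCG gene by
  ~1 Log2FC unit — the scale of the binned curves being emulated);
* condensation accessibility a = exp(−η·M·ρ) with η = 0.05 when
  condensation is the truth, and a weak residual coupling η = 0.005
  otherwise (accessibility correlates only weakly with protein level when
  the true mechanism lies elsewhere), with log-normal per-gene scatter
  (sd 0.1);
* slow-sites occupancy p = 0.0058·M (the fitted linear relation);
  dynamical-obstacle density p = M/11.

Default analysis bin width is 0.25 mCG/100 bp over ρ ∈ [0, 8]
(`bin_log2fc()`); the pipeline bins at 0.5 to keep the per-bin TASEP
budget modest. The maximum-slope estimator uses a sliding window of 5 bins
with inverse-SEM² weights (bins with zero or undefined SEM receive the
largest finite weight in the window; a fully degenerate window falls back
to unweighted least squares) and returns the most negative slope — the
"maximum slope" of a repression curve.

## 6. Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every estimator's sampling error is
comfortably below the effect it measures: 20–100-kb genomes, 1 200–1 500
gene panels, lattices of 100–500 sites with measurement windows of
3 000–60 000 s, 150–1 200 accumulated ATAC libraries for the footprint
fits, and 10 seeded replicates of the full discrimination protocol. The
footprint-recovery experiment gives the observed side a larger replicate
count than the model side: the observed profile is two libraries (cheap to
average), while the model side benefits from common random numbers across
the grid.

## 7. Known limitations

* The assay bias models (GC, length, Tn5 motif) are declared heuristic
  forms, defaulting to off; they exist so the fitting machinery can be
  exercised with biases on, not as calibrated instrument models.
* `t_hat` from footprint fitting is weakly identified (flank normalization
  removes density); only `p_hat` is quantitatively meaningful.
* α recovery is reliable only where the Log2FC responds to α; in the
  congested regime the fit reports a valid current ratio but a weakly
  constrained α (flagged per bin).
* The two congestion variants make very similar predictions — the
  blocking and slow-down mechanisms are alternative readings of the same
  data at this resolution; the discrimination protocol separates the
  congestion family cleanly from detachment and condensation, and the
  in-family ranking relies on the density calibration (p = M/11 vs
  p = 0.0058·M).
* Pol II pausing/backtracking, termination inside the body (beyond the
  detachment model), nucleosome dynamics and mRNA degradation are out of
  scope; Log2FC as a current ratio assumes degradation cancels between the
  lines of a pair.
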