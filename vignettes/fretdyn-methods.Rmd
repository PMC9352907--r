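---
title: "Models and methods behind fretdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdyn)
```

# The scientific problem

Protein disulfide isomerase (PDI) and many other multidomain enzymes
exchange between a small number of conformational ensembles on the
sub-millisecond timescale. Diffusion-based single-molecule FRET resolves
this exchange: individual dye-labeled molecules diffuse through a confocal
volume (dwelling about half a millisecond), emit a burst of photons under
pulsed interleaved excitation (PIE), and the photon record carries, per
photon, the arrival time on the experiment clock (macrotime), the delay
after the excitation pulse (microtime), and the detection channel.

`fretdyn` implements the analysis chain this kind of experiment uses —
burst selection, corrected FRET efficiency/stoichiometry, subpopulation
lifetime decomposition, dynamic photon distribution analysis (PDA), and
species-filtered fluorescence correlation spectroscopy (fFCS) — together
with a synthetic photon-stream generator so every stage is testable
without access to raw instrument files. The package's presets describe the
PDI 88/467 system: three states O1/O2/C at interdye distances 80/55/42 Å,
donor lifetimes 2.75/0.91/0.25 ns against a donor-only lifetime of 3.2 ns,
Förster radius 62.3 Å, and the published three-state rate matrices for
oxidized and reduced PDI (WT and five variants), bundled as a CSV fixture.

# The kinetic model

States form a continuous-time Markov chain with off-diagonal rates
$k_{ij}$ (ms$^{-1}$); the generator $Q$ has $Q_{ij} = k_{ij}$ and
$Q_{ii} = -\sum_j k_{ij}$. Equilibrium occupancies solve $\pi Q = 0$; we
use a null-space (SVD) solve, which is exact at this size, after an
explicit irreducibility check that names absorbing states. The two-state
exchange relaxation is $\tau_R = (k_{ab} + k_{ba})^{-1}$ and the general
relaxation spectrum is the negated reciprocal nonzero eigenvalues of $Q$.
Rates map to activation free energies through the Kramers relation
$\Delta G_{ij} = \ln(A / k_{ij})$ in $k_BT$ units, with the pre-exponential
$A = 10^5\,\mathrm{s}^{-1}$ by default (a deliberately conservative
convention for protein domain motion; the absolute barrier scale shifts
with $A$ but barrier differences do not).

Detailed balance is *not* enforced on rate matrices: globally fitted rates
from real data generally violate it slightly, and the published WT rates
do. The `cycle_flux()` diagnostic reports the forward/backward cycle
product ratio instead. Published state fractions are likewise carried as
independent fitted quantities in the bundled table, not recomputed from
the rates, because the two disagree for some variants.

Two distance parameterizations of the same three states are exposed:
the fixed PDA set (80/55/42 Å) and the set implied by the lifetimes
through $E = 1 - \tau/\tau_D$ and $R = R_0((1-E)/E)^{1/6}$
(84.2/53.4/41.3 Å). The O2 state is 55 Å by default; the 57 Å label used
in some published tables is accepted as an alias when parsing.

# The synthetic-data generator

The generator emulates the acquisition conditions of the source
experiments: 20 MHz PIE (50 ns cycle, donor pulse at 0, acceptor pulse at
25 ns), exponential confocal transits with mean 0.5 ms, three-state
Gillespie switching inside each transit, per-state FRET efficiencies from
$\sigma$-broadened distances (one Gaussian draw per burst and state,
SD $= \sigma R$, $\sigma = 0.045$ — matching PDA's quasi-static
distance-distribution assumption), donor brightness 200 detected
counts/ms at $E = 0$, spectral crosstalk $Lk = 0.08$, acceptor direct
excitation $DE = 0.05$, detection factor $g = 0.85$, Poisson background
(1.7 kHz total over four detection channels — a typical confocal value;
the per-channel rates are configuration keys), and donor-only /
acceptor-only contaminant molecules (10 % / 5 % of transits by default).
Channel rates are constructed so that the standard ALEX correction
formulas recover the ground-truth efficiency: for a state with efficiency
$E$, donor-excitation donor and acceptor channels detect
$c\,(1-E)$ and $c\,(gE + Lk(1-E) + DE\,g)$ counts/ms, and the
acceptor-excitation channel $g\,c$, so that the corrected stoichiometry of
doubly labeled molecules is 0.5. Microtimes are exponential lifetime draws
(state lifetime for donor photons, 3.5 ns for acceptor photons) convolved
with a Gaussian IRF (250 ps FWHM, a typical SPAD response; the width was
not published and is a configuration key), folded into the correct PIE
half-window. Polarization is a fixed 50:50 split with no depolarization
physics — anisotropy analysis is out of scope.

What the generator does *not* emulate: 3-D Gaussian-beam diffusion (the
transit is constant-intensity with an exponential duration, so the
diffusion term of correlation functions has an exponential rather than the
confocal $(1+\tau/\tau_d)^{-1}(1+\tau/(\rho^2\tau_d))^{-1/2}$ shape),
acceptor dark states (photoblinking), detector afterpulsing and dead time,
and out-of-focus molecules. Passing tests therefore demonstrate
correctness of the photon statistics, the state kinetics and the
analysis algebra — not robustness to instrument artifacts present in real
data.

With exponential transits at mean 0.5 ms and brightness 200 counts/ms,
about a third of transits carry fewer than the 40 photons the burst search
requires; planted-burst recall is therefore measured among transits that
actually yielded enough photons, where it exceeds 98 %.

# Burst analysis

The all-photon burst search is the sliding-window variant: a photon
belongs to a burst region when at least $M = 20$ photons fall inside the
surrounding 0.5 ms window (the published analysis states the window and
the total threshold but not the local-rate parameter, so $M$ is a
configuration key); maximal runs of qualifying photons form bursts and
only bursts with strictly more than 40 photons survive. Corrected
efficiency and stoichiometry use the standard ALEX accounting
($F_A = N_{DA} - Lk\,N_{DD} - DE\,N_{AA}$,
$E = F_A/(F_A + g N_{DD})$, $S = (F_A + g N_{DD})/(F_A + g N_{DD} +
N_{AA})$). Quality filters: stoichiometry window 0.25–0.75, the
ALEX-2CDE kernel-density asymmetry score (exponential kernel, 100 µs time
constant — also unpublished, hence a configuration key; threshold < 14;
the per-photon density ratio is regularized by adding one to the same-slot
kernel density so that isolated photons cannot dominate a burst score),
and the duration-normalized |T$_{DX}$–T$_{AA}$| mean-time difference
(< 0.5; normalizing by burst duration makes the printed threshold
dimensionless). The cascade is a conjunction, hence order-invariant, and
removal counts per criterion are logged.

Per-burst donor lifetime is the intensity-weighted mean microtime of
donor-excitation donor-channel photons minus the IRF mean — the
first-moment estimator; per-burst maximum likelihood is unstable below
~100 photons and E-vs-τ diagnostics only need a centroid.

# Lifetime analysis and FRET lines

Pooled subpopulation decays are fitted by Poisson maximum likelihood of an
IRF-convolved multi-exponential plus flat background, using the
exponentially-modified-Gaussian closed form on the log scale for
stability. Model order is chosen by the reduced-χ² sequence: on a
two-lifetime mixture the 1→2 component step drops χ² several-fold while
2→3 changes it marginally.

The static FRET line is the locus of non-exchanging species in the
(τ, E) plane. With no linker broadening it is exactly $E = 1 - \tau/\tau_D$.
With the 5 Å apparent linker, each mean distance carries a Gaussian
distance distribution; the species-averaged efficiency pairs with the
*fluorescence-weighted* lifetime $\langle\tau^2\rangle/\langle\tau\rangle$,
and the resulting curve is represented as a cubic polynomial in τ
(within 0.005 of the numerically integrated curve over the working
range — the published pipeline's internal functional form is not printed,
so the construction is validated by its boundary behavior: E → 1 as
τ → 0 and E → 0 at τ = τ_D). Dynamic FRET lines connect two exchanging
states: as the fractional time $x$ in state A sweeps 0→1, the species
lifetime is $x\tau_a + (1-x)\tau_b$, the efficiency
$E = 1 - (x\tau_a + (1-x)\tau_b)/\tau_D$, and the measured
(fluorescence-weighted) lifetime
$(x\tau_a^2 + (1-x)\tau_b^2)/(x\tau_a + (1-x)\tau_b)$ — which bows the
curve to the right of the static line, the classic signature of
within-burst exchange. The curve is validated generatively: simulated
two-state bursts fall on it within shot noise.

# Dynamic PDA

PDA operates on the raw proximity ratio PR $= N_{DA}/(N_{DA}+N_{DD})$ of
donor-excitation photons per time bin, so photon counting statistics stay
exactly binomial; corrections, σ-broadening and background are folded into
the forward model rather than applied to the data. Burst photon trains are
cut into consecutive windows at 0.25/0.5/0.75/1 ms; incomplete trailing
windows are discarded (every retained bin then has the same duration,
which is what the forward model simulates) and windows with fewer than 10
donor-excitation photons are dropped; the PR histogram uses a grid of 100.

The forward model is Monte-Carlo over state paths (no closed form exists
for three-state dynamic PDA): each sample draws a photon count from the
empirical bin-count library of the measured data, one σ-broadened distance
per state, and a Gillespie path over the bin; the intensity-weighted mean
proximity ratio follows from the per-state channel rates, and the *exact*
binomial distribution of the acceptor count is accumulated onto the PR
grid (a Rao-Blackwellized estimate — only the path and distance draws are
stochastic). This keeps the Monte-Carlo noise of the predicted histogram
far below the data's counting noise at the default 3×10⁴ samples, which
matters because the fitter treats the prediction as exact.

The global fit minimizes the summed Pearson χ² across bin times over the
six log-rates (distances and σ stay fixed). Expected counts are floored
at half a count per bin so that isolated outlier windows in bins the
model leaves empty (filter leakage, coincident molecules) cannot dominate
the objective. Optimization proceeds in three stages: pairwise coordinate
descent over each forward/backward rate couple in its own 2-D simplex
(the full 6-D simplex alone stalls in the long flat valley coupling the
dominant exchange rates), a full-dimensional simplex, and a short polish
at a quadrupled forward sample count. The forward model uses common
random numbers with a fixed per-sample draw budget: every Monte-Carlo
sample consumes the same number of random draws whatever its state path,
so the (seed-fixed) Monte-Carlo error varies smoothly with the rates.
Without this, the simplex drifts along weakly identified directions to
align the forward noise realization with the data — in testing this
inflated the closed-state exchange rates severalfold. Bin-level χ² values exceed one per degree of freedom
even at the generating parameters because consecutive windows of the same
burst share a σ-draw and a continuing state path — the objective is a
fitting criterion here, not a calibrated goodness-of-fit statistic. Initial-bin state
probabilities are tied to the stationary distribution of the candidate
rates by default; an option floats them independently (useful where
fitted fractions and rates disagree, as for some published variants).
Robustness follows the published protocol: restarts from uniform initial
rates 1, 0.5 and 0.75 ms$^{-1}$ with bounds 0–10 ms$^{-1}$, reported as
mean ± SD over the three determinations; restarts disagreeing by more
than 50 % (relative) on any rate flag the result as multi-modal.

Problem sizes: the bundled analyses and tests use 10⁴ simulated transits
(~6×10³ selected bursts, ~1.5×10⁴ windows at the shortest bin time) and
1.5–3×10⁴ forward samples — enough for the dominant exchange rates and
the equilibrium fractions to be recovered within the restart scatter
while a full robustness run stays in the minutes range. The small rates
of the triangle (≲0.4 ms⁻¹) are the most weakly constrained, as their
published uncertainties already suggest.

# Species-filtered FCS

Microtime patterns for two FRET sub-ensembles are taken from the
donor-excitation photons of bursts selected by corrected-efficiency
windows (O1: 0.17–0.25, O2: 0.65–0.75), stacked over the four detection
channels (64 coarse microtime bins each); the background pattern comes
from inter-burst photons. Filters are the variance-minimizing
weighted-least-squares unmixing weights
$F = (M W M^\top)^{-1} M W$ with normalized patterns $M$ and $W$ built
from the fitted mixture, which makes the filters unbiased
($F M^\top = I$: applying filter $s$ recovers species-$s$ counts in
expectation) and complete (weights across species + background sum to one
in every bin — exactly, because the weighting is constructed from a
mixture inside the pattern span). Near-collinear patterns abort with the
condition number.

Filter-weighted photon streams are binned at 2 µs and correlated with a
multi-tau correlator (16 lags per cascade, doubling bin width), separately
in 10 equal-duration blocks; curves are block means and errors are block
standard errors. The four curves (two sACFs, two sCCFs) are globally
fitted with
$G(\tau) = G_0 \, (1+\tau/\tau_d)^{-1} (1+\tau/(\rho^2\tau_d))^{-1/2}
(1 + A e^{-\tau/\tau_R})$, sharing one relaxation time, fixing
$\tau_d = 469$ µs and $\rho = 4.6$ (calibration quantities in the source
experiments) and letting cross-correlation amplitudes go negative;
weighted Levenberg–Marquardt supplies parameter covariances. Because the
simulator's transit correlation is exponential rather than confocal, the
fixed diffusion shape is a deliberate model mismatch. The fit therefore
uses lags from 4 µs up to 300 µs by default: well below the diffusion
time the diffusion factor is slowly varying and nearly shape-independent,
so it cannot trade against the relaxation term, while the exchange
relaxation of interest (tens of µs) is fully resolved. Widening the lag
range toward the diffusion time progressively biases the fitted
relaxation upward on exponential-transit data; on confocal data the range
is a configuration choice like any other fit window.

# Numerical and design choices

- All randomness flows through R's RNG; every simulation entry point takes
  a `seed` and restores the caller's RNG state. Identical seeds give
  byte-identical streams.
- Times are seconds inside photon streams (macrotime in integer PIE-cycle
  ticks), ms/µs/ns at interfaces, with unit-suffixed argument and config
  names.
- The photon container is a plain-text format: a commented YAML header
  (schema version, PIE period, microtime resolution, IRF, duration) over a
  CSV photon table; readers validate the schema, monotone macrotimes and
  the microtime range, and refuse truncated files. Vendor file ingestion
  is an extension point, not a dependency.
- Degenerate inputs error early and specifically: absorbing schemes name
  the state, empty filter results refuse to histogram, equal-lifetime
  dynamic lines refuse to draw, collinear fFCS patterns report the
  condition number, single-slot bursts get infinite filter scores.
- The decay fitter pins the first amplitude and uses a softmax for the
  rest, with lifetimes on the log scale; the PDA fitter uses log-rates
  with a hard bound rejection at 10 ms⁻¹.

# Known limitations

- The PDA forward model draws the bin photon count independently of the
  state path, as the standard histogram-library approach does; in truth
  the detected intensity varies slightly with the state (through $g$, $Lk$
  and $DE$), so count and mean proximity are weakly correlated. At the
  default correction values the induced bias is small compared to the
  restart scatter.
- fFCS curves inherit the exponential-transit diffusion shape (see above);
  absolute amplitudes and the effective $N$ are therefore not
  interpretable against the confocal model, only the relaxation term is.
- No acceptor photophysics by default; the residual asymmetry real
  measurements show at low PR (attributed to acceptor dark states) is
  reproduced neither by the generator nor by the forward model.
- Anisotropy, burst-variance analysis, 2-D lifetime-efficiency MLE and
  model counts beyond three states are out of scope.
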