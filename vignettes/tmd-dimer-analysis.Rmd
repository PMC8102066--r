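---
title: "Quantifying transmembrane-domain dimerization: interface kinetics, stoichiometry and conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transmembrane-domain dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdimer)
```

## Scope and scientific background

Metabotropic glutamate receptors (mGluRs) are dimeric family C GPCRs whose
seven-helix transmembrane domains (TMDs) associate through a set of
interchangeable helix-helix interfaces. Closely related subtypes such as
mGluR2 and mGluR3 differ markedly in how strongly their TMDs dimerize, and
receptor activation is accompanied by reorientation between interfaces
(e.g. from a TM4-containing inactive interface toward a TM6 active
interface). `tmdimer` implements the quantitative analyses used to study
this system:

* discretization of coarse-grained dimer trajectories into **interface
  microstates** by a residue-contact rule;
* **Markov state model** (MSM) estimation with implied-timescale
  validation and an equilibrium dimeric-fraction statistic;
* **PCCA+** aggregation of microstates into metastable macrostates, with
  interface-probability profiles, macrostate labels and contact matrices;
* **transition path theory** (TPT) reactive flux between interface
  classes, after symmetrizing labels over protomer exchange;
* **Jarzynski** free-energy estimation from steered-pull work samples;
* **single-molecule pulldown (SiMPull)** photobleaching quantification
  with min-max dimerization normalization;
* **FRET / calcium** response normalization and four-parameter logistic
  concentration-response fits;
* **chemical-class sequence conservation** over residue subsets;
* a seeded **synthetic-data module** that generates inputs with known
  ground truth for every stage.

The package analyzes trajectories and measurements; it does not run
molecular dynamics, detect spots in images, or build sequence alignments.

## Interface microstates from residue contacts

A frame of a two-protomer trajectory is reduced to a label as follows.
For every residue pair (one residue per protomer) the *minimal distance
over all bead pairs* is computed; a pair is in contact when this distance
is at most the labeling cutoff (default **1.0 nm**, stored internally in
nm; Angstrom input is converted on load). Contacts are then counted per
domain — helices TM1-TM7, loops and termini all participate — and a domain
enters the protomer's side of the label when it forms **strictly more than
20** contacts with the other protomer. A frame in which neither protomer
contributes a domain is monomeric.

Two counting conventions are plausible readings of "number of residue
contacts formed by each helix": counting contacting *residue pairs*
(default, `count_mode = "residue_pairs"`) or counting *residues with at
least one contact* (`"residues"`). Pair counting is the default because a
strict >20 threshold on whole-residue counts would require nearly a full
helix face to participate before any domain were labeled; the residue mode
is retained for sensitivity analysis. Similarly, the contact test is
inclusive at the boundary (`<=` cutoff); the boundary convention only
matters on a measure-zero set of geometries.

Labels are *ordered* pairs — protomer A and B kept distinct — so
asymmetric interfaces such as `TM1|TM4` are separate microstates from
`TM4|TM1`. Symmetrization happens only later, in the flux analysis.

Each microstate also carries a domain-level contact matrix `C[D, D']`: the
fraction of the microstate's frames in which *any* residue of domain D
(protomer A) lies within **0.9 nm** of *any* residue of domain D'
(protomer B). The any-pair domain event was chosen (rather than averaging
over residue pairs) because the matrix is indexed by domains; both the
0.9 nm cutoff and the event definition are configurable.

The distance kernel forms coordinate differences with `outer()`, which
makes its floating-point arithmetic identical to a scalar bead-pair loop;
the test suite exploits this to require *exact* equality with an
independent brute-force oracle on random frames. No periodic-boundary
minimum-image correction is applied: inputs are assumed unwrapped, which
holds for the synthetic generator and for typical post-processed dimer
trajectories. Frames with missing beads are rejected rather than imputed.

## Markov state models

Transition counts are sliding-window (`C[i,j] = #{t: s_t = i, s_{t+lag} =
j}`), never crossing trajectory boundaries; sliding counting maximizes
data use at the cost of slightly correlated counts, which does not bias
the maximum-likelihood estimate. Estimation is restricted to the largest
strongly connected component of the count graph — the standard
prerequisite for a well-defined stationary distribution.

The default estimator enforces detailed balance by self-consistent
iteration on the symmetric flow matrix, converging when the maximum
absolute parameter change drops below `1e-10`. Reversibility is the
physically appropriate assumption for equilibrium simulations and
guarantees the real spectrum PCCA+ requires; the plain row-normalized
estimator is retained for diagnostics (`reversible = FALSE`), and the two
agree within sampling error on detailed-balance data.

Implied timescales are `t_i = -tau / log(lambda_i)` for eigenvalues in
(0, 1), sorted by modulus with ties broken by real part; the stationary
eigenvalue carries no timescale, and negative or complex eigenvalues are
reported without one. `lag_scan()` tabulates `t_i(tau)` and flags the
smallest lag after which the slowest timescale changes by <10% between
successive lags — a reported convergence heuristic, not an enforced gate.
Fractional lags are rejected; a default lag of 20 ns is expressed in
frames through the trajectory's frame spacing.

The **dimeric fraction** is the stationary probability of all states whose
label is non-empty on either protomer.

## PCCA+ macrostates

Memberships come from the inner-simplex construction on the first
`n_macro` right eigenvectors of the reversible transition matrix
(pi-orthonormalized via the symmetrized matrix): the eigenvector rows span
a simplex; the rows farthest from the span of previously chosen vertices
are taken as vertices, and barycentric coordinates give row-stochastic
fuzzy memberships. Tiny negative coordinates are clipped and rows
renormalized. No subsequent objective optimization is performed (the
Röblitz-Weber inner-simplex scheme alone); full PCCA+ objective refinement
changes memberships only marginally for well-separated spectra and is out
of scope. A degenerate eigenvalue pair at the spectral cut raises an
error suggesting a different `n_macro`.

The macrostate count itself is a user decision, guided by
`propose_n_macro()`, which finds the largest gap `t_m / t_(m+1)` in the
timescale spectrum and suggests `m + 1` macrostates.

Macrostate statistics use the **crisp** (argmax-membership, ties to the
lowest index) assignment, matching the set notation `pi_I = sum_{i in I}
pi_i`. The interface-probability profile of macrostate I is

`p[D, a, I] = sum_{i in I, D in label_ia} pi_i / pi_I`

and the macrostate label reports the domains with `p >= 0.4` (a 40%
interface-probability threshold, configurable). Macrostate contact
matrices are membership-weighted averages of the microstate matrices; the
raw membership-weighted *sum* depends on how many microstates a macrostate
happens to contain, so the normalized form (weights `pi_i rho_i(I)`,
normalized) is the default contract — it is a convex combination, reduces
to `C^i` for singleton macrostates — and the raw form remains available
(`normalize = FALSE`).

## Interface classes, committors, reactive flux

For flux analysis, microstate labels are canonicalized by dropping
non-helix domains and unordering the protomer pair; two labels share an
interface class iff their canonical forms agree. This single
canonicalization simultaneously merges labels that differ only in loop
content and labels related by protomer exchange. A narrower variant that
only merges label pairs satisfying both conditions *pairwise*
(`strict_and = TRUE`) is retained for comparison; it aggregates almost
nothing on realistic label sets, which is why the canonicalization is the
default.

`tpt_flux()` solves the forward committor linear system on intermediate
states, takes the backward committor from the time-reversed chain (exactly
`1 - q+` under detailed balance), and assembles gross flux `f_ij = pi_i
q-_i P_ij q+_j`, net flux `max(0, f_ij - f_ji)`, and the total A→B flux
per lag step and per ns. Net flux is conserved at every intermediate state
and the total is invariant under any refinement of the class partition;
both are asserted by the tests at `1e-12`. Source and sink sets are user
inputs (typically the monomeric class and a named interface class).

## Jarzynski free energies

`jarzynski_free_energy()` evaluates `dF = -kT log < exp(-W/kT) >` by
log-sum-exp. The estimator is exponentially biased when few pulls dominate
the average, so the exponential-weight effective sample size is reported
(with a warning below 10) along with a seeded bootstrap spread (default
200 resamples). `dF <= mean(W)` (Jensen) holds for every estimate. For
Gaussian work with mean mu and variance sigma^2 (in kT), the estimate
converges to `mu - sigma^2/2`, which the tests verify at mu = 10 kT,
sigma^2 = 2 kT^2, N = 1e6 draws. Temperatures convert through the molar
gas constant; work may be supplied in kT or kJ/mol.

## SiMPull photobleaching quantification

The input contract is a table of manually (or automatically) classified
spots with 1-4 bleaching steps or a discarded flag. Per movie, fractions
are taken over analyzed (non-discarded) spots and `%2-step = n_2 /
n_analyzed * 100`; spots with 3+ steps stay in the denominator but not the
numerator. Percent dimerization is the min-max normalization
`(observed - 5) / (55 - 5) * 100`, where 5% is the fluorescence-background
floor and 55% the %2-step of a full-length obligate dimer; both constants
are arguments, values are not clipped, and no expression-level correction
is applied. Aggregation across movies uses unweighted per-movie means with
s.e.m. over movies — which is why a pooled-count computation can differ
from the reported per-condition means. Two-color pulldown efficiency is
the background-subtracted prey/bait spot ratio normalized to the same-day
homodimer ratio.

The automated step counter (optional plumbing; the primary contract is
pre-classified counts) fits a piecewise-constant model by binary
segmentation with a BIC-style penalty (`3 log(n) sigma^2` per change
point), merges levels closer than 3 noise standard deviations, and counts
downward transitions; traces with upward jumps, more than four steps, no
clear steps, or non-positive intensity throughout are discarded. At step
amplitudes of 8 noise s.d. it is >95% accurate on synthetic traces.

The binomial labeling model (label efficiency `p`: dimers show two steps
with probability p^2, one with 2p(1-p); monomers one with p; only labeled
spots are visible) yields a closed-form dimer-fraction estimator from the
two-step fraction among 1-/2-step spots, `f_d = q / (p - q(1-p))`.
Coincidental colocalization is modeled as appended spots with 3+ steps
(rate 0.03 per visible spot by default, mimicking the small observed
3+-step population), which by construction does not bias that estimator.

## Response quantification and Hill fits

The FRET index is `I_A / (I_D + I_A)`; points with both channels zero are
flagged undefined. Window responses are means over an application window
minus the mean of a pre-application baseline (default width 10 samples,
configurable — the baseline convention is a free choice since recordings
normalize "to solution without drug" without a stated width), normalized
to the saturating reference response in the same recording; gain and
offset changes of the whole recording cancel exactly. Antagonist/basal
responses come out as signed fractions of the reference.

Concentration-response curves are fit with the four-parameter logistic
`r(c) = bottom + (top - bottom)/(1 + (EC50/c)^n)` in log10-concentration
space (Levenberg-Marquardt via minpack.lm, multi-start over the sampled
concentration range and slope signs, replicates averaged per
concentration, equal weights). The bottom is fit by default rather than
pinned to 0 because basal/antagonist data can be negative relative to
baseline; `pin_bottom = TRUE` restores the constrained fit. EC50 is
reported with its log-space standard error. Flat data raise a
"no dynamic range" error rather than returning a meaningless fit.

## Sequence conservation

Conservation uses six side-chain chemical classes — aliphatic (G, A, V, L,
I), hydroxyl/sulfur (S, C, T, M), cyclic (P), aromatic (F, Y, W), basic
(H, K, R), acidic and amides (D, E, N, Q). A column is *identical* when
all sequences agree and *conserved* when all residues share one class, so
identity never exceeds conservation; a gap anywhere makes a column
neither (a conservative choice — the alternative of ignoring gapped
sequences would inflate both statistics). Ambiguity codes (B, Z, X, U) are
rejected rather than silently classed. Subsets (e.g. a helix, or its
outward-facing residues) are column-index lists, with a helper to map
ungapped residue numbers of a reference sequence to alignment columns;
outward-facing definitions are user input because they derive from
structural models, not from the alignment.

As a worked example, the three outward-facing residues at the cytosolic
end of TM4 that differ between mGluR2 (A677, A681, A685) and mGluR3 (S686,
F690, G694) score 0% identity and 33.3% conservation — only the A/G column
is class-conserved (both aliphatic):

```{r tm4}
aln <- alignment_view(c(mGluR2 = "AAA", mGluR3 = "SFG"))
subset_stats(aln, 1:3, name = "3xTM4")
```

## The synthetic-data module

Every generator is seeded (identical seed, identical output; the caller's
RNG stream is never disturbed) and emits its ground truth:

* `simulate_chain()` — exact Markov trajectories from a known transition
  matrix, started from the stationary distribution.
* `build_toy_dimer()` — an idealized dimer: 7 single-bead-per-residue
  helix columns (6 residues each) on a 1.2 nm ring plus loop stubs, with
  protomer B rotated/translated so that exactly the scheduled helix pair
  faces at 0.5 nm (24 residue contacts, comfortably above the >20
  threshold, with the nearest non-scheduled pair at 1.34 nm, outside both
  cutoffs); monomer segments separate the protomers by more than three
  labeling cutoffs. The geometry is idealized rather than physical — the
  analysis only observes which domains fall within the distance cutoffs,
  which is the contract under test. Each segment is verified internally
  against the contact-labeling rule before the trajectory is returned.
* `simulate_photobleaching()` — the binomial labeling model above, with
  optional piecewise-constant noisy traces.
* `simulate_dose_response()` — 4PL responses with multiplicative Gaussian
  noise.
* `simulate_alignment()` — columns planted as identical, class-conserved,
  or free (guaranteed non-conserved).
* `simulate_work()` — Gaussian work samples in kT.

What passing tests on these generators shows — and what it does not: the
generators reproduce the *statistical structure* each stage assumes
(metastable exchange between discrete interface states, binomial
labeling, logistic dose dependence, Gaussian work). They do not reproduce
force-field geometry, camera noise, spot overlap, photophysics such as
blinking, or alignment phylogeny; agreement on synthetic data validates
the estimators, not any particular biological conclusion.

## Numerical choices and problem sizes

Invariants are enforced at explicit tolerances: row-stochasticity and
membership row sums at 1e-12, stationarity and detailed balance at 1e-10,
committor and flux-conservation identities at 1e-12. Membership argmax
ties break to the lowest macrostate index. Eigenvalue sorting is by
modulus, ties by real part. The reversible-MLE iteration stops at a 1e-10
max-abs parameter change.

The test and acceptance problem sizes were chosen so each statistical
check is decisively powered while the whole suite runs in well under a
minute of compute per stage: 200 random frames for the contact oracle, 20
trajectories of 50,000 steps for MSM recovery (sampling error ~1e-3 per
matrix entry against a 0.01 acceptance band), a 9-state/3-block chain for
PCCA+, 1e6 Gaussian work draws (estimator spread well inside the 0.2 kT
band), 2,000 spots for dimer-fraction recovery and 20,000 for the
obligate-dimer calibration consistency check (sampling s.d. ~0.35
percentage points), 100 seeds for noisy Hill-fit recovery, and 500
synthetic traces for the step counter.

## Known limitations

* No Bayesian MSM error bars, hidden Markov models, or
  Chapman-Kolmogorov testing beyond the implied-timescale lag scan.
* No non-reversible coarse-graining (GPCCA); PCCA+ requires the
  reversible estimate.
* No minimum-image treatment of periodic boxes in the contact kernel.
* The step counter ignores blinking and partial bleaching.
* Crooks/BAR estimators are not provided; Jarzynski only.
* Printed literature values that depend on unpublished inputs (helix
  boundary definitions, raw imaging data, full trajectory sets) are not
  asserted by the tests; the suite asserts formulas, oracles, and
  synthetic-recovery properties instead.
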