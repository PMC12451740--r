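---
title: "Bottom-up folding collective variables: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up folding collective variables: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcv)
```

## The model

Protein folding is driven by the formation of many individually weak,
microscopic interactions: backbone and side-chain hydrogen bonds, and the
packing of side chains into a hydrophobic core. Collective variables (CVs)
built from global descriptors (radius of gyration, backbone RMSD, Cα
distances) are degenerate — many distinct states map to the same CV value —
and in particular cannot tell a protein–protein hydrogen bond from the
protein–water bond that replaces it when the native contact breaks.

`foldcv` builds two complementary CVs bottom-up from microscopic features:

$$s^{HB} = \sum_i F_i^{HB,F} - F_i^{HB,U}, \qquad
  s^{SC} = \sum_i F_i^{SC,F} - F_i^{SC,U}$$

Features harvested from a short unbiased **folded**-basin trajectory
(native contacts, superscript $F$) enter with coefficient $+1$; features
harvested from the **unfolded** basin (non-native contacts, superscript
$U$) enter with coefficient $-1$. Each feature acts as a switch: about 1
when the native contact is formed, about 0 when absent, and negative when
a competing (non-native) interaction has taken its place. A folded
configuration therefore maximizes both CVs, while misfolded states —
which satisfy non-native contacts — are pushed to *negative* values
instead of aliasing onto the native signal.

**Hydrogen-bond features.** For a native donor–acceptor pair the feature is

$$F^{HB} = S(r_{DA})\,A(\theta_{DHA})
  \;-\; \lambda_w \big[W(D) + W(A)\big]
  \;-\; \lambda_p \sum_{c} S(r_{Dc})$$

where $S$ is a rational switching function of the donor-heavy-atom to
acceptor distance, $A$ an angular term on the D–H···A angle, $W(\cdot)$
the summed switch over all water oxygens around the donor and the
acceptor (the protein–water competition), and the last sum runs over
competing protein acceptors that can seize the donor. Non-native
hydrogen-bond contacts harvested from the unfolded basin are bare
$S\cdot A$ switches of their own geometry, subtracted at CV level.

**Side-chain features.** A rational switch on the minimum-image distance
between the two residues' side-chain centers of mass (mass-weighted,
non-backbone atoms including their hydrogens). Glycine, which has no side
chain, is represented by its Cα so that it can still participate in
hydrophobic-core packing.

## Switching functions

All switches use the rational (PLUMED `RATIONAL`) form

$$S(r) = \frac{1 - x^n}{1 - x^m}, \quad x = \frac{r - d_0}{r_0},$$

which is total on $r \ge 0$: 1 for $r \le d_0$, $n/m$ at the removable
singularity $x = 1$ (evaluated through a second-order expansion inside
$|x-1| < 10^{-6}$), and monotonically decaying to 0. A hard outer cutoff
`d_max` truncates the switch to exactly zero, with the inner part rescaled
so the function stays continuous (PLUMED's `D_MAX` stretching). The finite
`d_max` is not cosmetic: it makes every feature strictly local, so that
rigid-body motions and periodic-image relabelings far away cannot perturb
feature values even at the $10^{-9}$ level, and it bounds the cost of the
water-competition sums.

The angular term is a rational switch on the bounded coordinate
$u = (1 + \cos\theta_{DHA})/2 \in [0, 1]$ ($u = 0$ for the ideal collinear
bond), so it is smooth and differentiable everywhere — a requirement for
biased simulations. Its reference value $u_0 = (1+\cos 150^\circ)/2$ makes
the term $0.6$ at $\theta = 150^\circ$ and below $0.01$ at
$\theta = 120^\circ$, i.e. only near-linear arrangements count as
hydrogen bonds.

Default parameters (all exposed through `harvest_config()` /
`switch_params()`, never hard-wired):

| switch | r0 | n | m | d0 | d_max |
|---|---|---|---|---|---|
| HB distance (donor heavy–acceptor) | 3.0 Å | 6 | 10 | 0 | 9 Å |
| water competition (polar–Ow) | 3.0 Å | 6 | 10 | 0 | 9 Å |
| side-chain COM–COM | 6.5 Å | 6 | 10 | 0 | 19.5 Å |
| angular, on $u$ | 0.06699 | 6 | 10 | 0 | — |

These are standard hydrogen-bond and side-chain contact length scales;
they are configuration choices of this package and are recorded in every
feature-set manifest so a CV definition is always traceable to the
thresholds that produced it. The competition weights $\lambda_w,
\lambda_p$ default to 1 and are not weighted differently — there is no
evidence either term should dominate, and the ablation analysis (below)
is the tool for probing their individual roles.

## Harvesting and the LDA-like filter

Candidate contacts are enumerated from the topology: every (donor N/O/S
with a bonded hydrogen, acceptor N/O/S) pair and every residue pair, at a
minimum sequence separation of 2 residues. Adjacent-residue contacts are
near-always formed, carry no discriminative signal, and would be removed
by the filter anyway; pre-filtering them saves quadratic work. Hydrogens
are assigned to donors by covalent distance (< 1.2 Å) because PDB files
routinely lack bond tables.

A contact is *formed* in a frame when its raw switch value exceeds 0.5 —
occupancy and evaluation share one geometry definition, so there is no
separate distance cutoff to keep consistent. Classification thresholds:

* native: folded-basin occupancy ≥ 0.6;
* non-native: unfolded-basin occupancy ≥ 0.25 **and** folded occupancy ≤ 0.1.

Frames are weighted uniformly within each end-state trajectory (they are
unbiased runs; nothing to reweight). Each surviving candidate is scored
with a per-feature Fisher discriminant,

$$J = \frac{(\mu_F - \mu_U)^2}{\sigma_F^2 + \sigma_U^2 + \varepsilon},
  \qquad \varepsilon = 10^{-6},$$

the one-dimensional realization of a linear-discriminant-analysis filter:
it is symmetric in the basins, invariant under rescaling of a feature,
and $\varepsilon$ keeps degenerate (zero-variance) features finite rather
than infinitely ranked. Features with $J \ge 1$ (default) are retained,
ranked by score with deterministic lexicographic tie-breaks. Competing
protein acceptors attached to each native feature are those within 6 Å of
the donor in at least 5% of unfolded-basin frames, capped at the 4 most
frequent — this bounds both the CV cost and the size of the emitted
PLUMED file.

## Ablation variants

`ablate()` reproduces the CV variants used to probe the role of
non-native information: `native_only` empties the non-native list and
zeroes both competition weights (the abridged, native-contacts-only CV);
`no_water_nonnative` zeroes only $\lambda_w$; `no_protein_nonnative`
zeroes $\lambda_p$ and drops the harvested non-native features. The full
CV is never above the native-only CV on any frame, because every
competition term is non-negative — a property the test suite asserts.

## Landscape analysis

* **State assignment** uses a hysteretic dual-cutoff rule on the Cα RMSD:
  the state flips to folded only after the RMSD has stayed at or below the
  folded cutoff for a full time window (10 ns in the reference protocol;
  1.5/2.5 Å cutoffs for a β-hairpin mini-protein, 4.0/6.0 Å for a
  20-residue one), and symmetrically for unfolding. The window is
  interpreted as a *minimum dwell before the flip commits* — entry-side
  windowing; the alternative (exit-side) reading is a documented
  interpretation risk, which is why the window and cutoffs are plain
  arguments rather than constants. Frames before the first commitment are
  `transit`; hysteresis guarantees the transition count never exceeds a
  naive single-cutoff crossing count.
* **Thermodynamics**: $\Delta F = -k_B T \ln(P_F/P_U)$ with
  $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹ (negative = folded favoured), and
  $\Delta H = \langle E \rangle_U - \langle E \rangle_F$ from partitioning
  a per-frame energy series by basin. Transit frames are excluded from
  populations, consistent with a two-basin ratio; the energy column is
  whatever the caller supplies (the potential vs total-energy choice in
  NVT partitioning is upstream of this package).
* **FES**: $F(\text{bin}) = -kT\ln(w_\text{bin}/w_\text{tot})$, shifted to
  min 0, empty bins $+\infty$; biased samples are reweighted with
  $w = e^{V/kT}$ from a COLVAR bias column. Default 2D binning is 50×50
  over the observed range.
* **Replica aggregation**: element-wise mean and *population* standard
  deviation over independent replicas (the convention of multi-replica
  free-energy protocols); bins empty in any replica are flagged, never
  silently averaged.

## The synthetic fixture: what it emulates, and what it does not

The generator builds a 6-residue alanine/glycine peptide with explicit
3-site waters in a 40 Å cubic box, in two deterministic reference
conformations: an antiparallel-hairpin-like *folded* frame in which every
planted native hydrogen bond is ideal (D–A = 2.85 Å, collinear D–H···A)
and every planted side-chain pair sits at $0.8\,r_0$, and a parallel
*misfolded* frame in which planted non-native contacts are satisfied
instead. Trajectories are reference frames plus isotropic Gaussian noise
(default σ = 0.05 Å — deliberately small relative to the switch widths so
planted contacts stay committed, which is what makes occupancy
ground-truth exact); bulk water positions are resampled every frame, so
water identity carries no information and permutation invariance is
exercised by construction. Two-state `telegraph` sampling switches basins
as a Markov chain with stationary folded probability $p_\text{fold}$,
giving the closed-form ground truth
$\Delta F = -k_B T\ln\!\big(p_\text{fold}/(1-p_\text{fold})\big)$ and
exponential residence times.

These fixtures are geometric constructions, not molecular dynamics. They
validate the featurization geometry, the selection statistics, the
estimators and the file formats — they say nothing about force fields,
real solvent structure, or whether 100 ns end-state runs suffice for a
given protein. Passing tests demonstrate correctness of the machinery,
not transferability to any particular system.

## Numerical choices

* Units: Å, ps, kcal/mol, radians internally; conversions only at I/O
  boundaries (GRO is nm; PLUMED files carry `UNITS LENGTH=A` so emitted
  switch parameters match the internal evaluator exactly).
* Orthorhombic boxes with minimum-image distances; triclinic cells are
  out of scope.
* 0-based atom/residue indices internally; 1-based serials only in PDB
  and PLUMED output, which is what those formats require.
* The switch singularity at $x = 1$ uses a second-order expansion within
  $|x - 1| < 10^{-6}$ (error $O(10^{-12})$, verified against a
  geometric-sum identity that has no singularity).
* Ties in feature ranking break lexicographically on contact identity, so
  a feature set is a deterministic function of inputs and configuration;
  manifests are byte-reproducible and hashed (MD5) into the PLUMED header.
* Degenerate inputs fail loudly: empty basins give errors (not infinite
  $\Delta F$ values), an all-filtered feature set is an explicit "no
  discriminative features" error, zero transitions leave residence times
  absent rather than zero.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
fixtures: 200-frame end-state runs for harvesting, a $10^5$-frame
telegraph trajectory for the free-energy recovery (recovering
$-k_BT\ln(7/3) \approx -0.57$ kcal/mol at 340 K to better than 0.1
kcal/mol), 2000 frames for dual-cutoff kinetics, and $2\times10^5$ draws
for the double-well FES reconstruction (per-bin error well under 0.1 kT).
These sizes give Monte-Carlo errors comfortably inside the asserted
tolerances while keeping the whole suite desk-scale.

## Known limitations

* XTC trajectories are not readable (no XDR reader among the package's
  dependencies); use DCD or multi-frame PDB. Binary trajectory *writing*
  is out of scope.
* PLUMED files are emitted from primitive actions (`COORDINATION`,
  `ANGLE`, `COM`, `CUSTOM`, `COMBINE`) for portability, and their
  structure is tested; numerical equivalence against an external `plumed
  driver` requires the PLUMED binary and is not exercised here.
* The hydrogen-bond angular expression emitted to PLUMED contains the
  rational form verbatim; PLUMED evaluates the $x=1$ point only on a
  measure-zero set, where its own arithmetic applies.
* Enhanced-sampling bias machinery (OPES and its multi-replica variants)
  is deliberately not generated — users append bias actions to the
  emitted file.
* The Fisher filter is a per-feature (univariate) criterion; multiclass
  or nonlinear feature combination is out of scope.

## A worked miniature

```{r example}
spec <- fixture_spec(n_waters = 10, n_frames = 80, p_fold = 0.7, seed = 3)
fit <- fold_cv(sample_trajectory(spec, "folded"),
               sample_trajectory(spec, "unfolded"))
summary(fit)

shb_F <- mean(predict(fit, sample_trajectory(spec, "folded"))$sHB)
shb_U <- mean(predict(fit, sample_trajectory(spec, "unfolded"))$sHB)
tele <- sample_trajectory(spec, "telegraph", n_frames = 1e5)
cv <- predict(fit, tele)
pF <- mean(cv$sHB > (shb_F + shb_U) / 2)
c(recovered = -kB_kcal() * 340 * log(pF / (1 - pF)),
  planted   = -kB_kcal() * 340 * log(0.7 / 0.3))
```
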