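# foldcv — bottom-up collective variables for protein folding

`foldcv` builds folding collective variables (CVs) for enhanced-sampling
molecular dynamics the way a structural biophysicist would by hand, but
automatically: from the microscopic contacts that actually hold a protein
together. It is aimed at practitioners of CV-based enhanced sampling
(metadynamics/OPES-style workflows driven by PLUMED) who need CVs that
resolve native states, misfolded traps and solvent-mediated intermediates
instead of collapsing them onto one backbone-RMSD value.

## The model

Two complementary CVs are assembled from switch-like features harvested
from two short unbiased end-state trajectories — one in the folded basin,
one in the unfolded basin:

    sHB = Σᵢ Fᵢ^HB,F − Fᵢ^HB,U        sSC = Σᵢ Fᵢ^SC,F − Fᵢ^SC,U

* **Hydrogen-bond features** `F^HB`: a rational switch on the
  donor–acceptor distance times an angular term on the D–H···A angle,
  minus protein–water competition (summed switches to all water oxygens
  around donor and acceptor) and protein–protein competition (switches to
  acceptors that can seize the donor). A formed native bond scores ≈ 1,
  an absent one ≈ 0, a bond replaced by water or by a wrong partner goes
  *negative*.
* **Side-chain features** `F^SC`: a rational switch on the distance
  between side-chain centers of mass (glycine is represented by its Cα).

Features from the folded basin (native contacts) enter with coefficient
+1, features from the unfolded basin (non-native contacts) with −1.
Candidates are classified by basin occupancy, scored with a per-feature
Fisher (LDA-like) discriminant `(μ_F−μ_U)²/(σ_F²+σ_U²+ε)`, and the
discriminative ones are retained. The fitted object evaluates the CVs on
trajectories and emits ready-to-run PLUMED input.

The package also implements the reference analysis protocol around such
CVs: Cα-RMSD (Kabsch), hysteretic dual-cutoff state assignment with a
minimum-dwell window, transition counting and residence times,
ΔF = −k_B T ln(P_F/P_U) and ΔH from energy partitioning, 1D/2D
free-energy surfaces with bias reweighting, and multi-replica
mean/standard-deviation aggregation — plus a fully synthetic two-state
peptide-in-water fixture generator with planted contacts and closed-form
thermodynamics, so everything is testable offline.

## Worked example

```r
library(foldcv)

spec <- fixture_spec(n_waters = 10, n_frames = 80, p_fold = 0.7, seed = 3)
fit <- fold_cv(sample_trajectory(spec, "folded"),
               sample_trajectory(spec, "unfolded"))
summary(fit)
#> Retained features (6 of 6 candidates), provenance 17cb14ce
#>                        id type      class occ_folded occ_unfolded score
#> 1            sc:0000-0003   sc non-native          0            1  6853
#> 2            sc:0000-0005   sc     native          1            0  6761
#> 3            sc:0002-0005   sc non-native          0            1  1000
#> 4 hb:000027-000028-000004   hb non-native          0            1   569
#> 5 hb:000047-000048-000014   hb     native          1            0   483
#> 6 hb:000037-000038-000004   hb     native          1            0   465
```

The fit recovered exactly the planted contacts of the synthetic peptide:
two native backbone hydrogen bonds and one native side-chain pair (all
with folded occupancy 1, unfolded 0, coefficient +1), and the planted
misfold contacts (occupied only in the unfolded basin, coefficient −1).
`coef(fit)` returns those ±1 coefficients; `plot(fit)` shows the score
spectrum; `write_plumed_input(fit, "plumed.dat")` emits the PLUMED file
(with a `UNITS LENGTH=A` header and the manifest's MD5 provenance hash).

Evaluating `sHB` on a long two-state telegraph trajectory whose true
stationary folded probability is 0.7 and reading the folding free energy
off the basin populations at 340 K:

```r
shb_F <- mean(predict(fit, sample_trajectory(spec, "folded"))$sHB)
shb_U <- mean(predict(fit, sample_trajectory(spec, "unfolded"))$sHB)
tele  <- sample_trajectory(spec, "telegraph", n_frames = 1e5)
pF    <- mean(predict(fit, tele)$sHB > (shb_F + shb_U) / 2)
-kB_kcal() * 340 * log(pF / (1 - pF))
#> [1] -0.6036209        # planted value: -0.5724763 kcal/mol
```

The CV alone classifies folding states well enough to recover the planted
free-energy difference to within Monte-Carlo error.

A thin command-line wrapper ships in `inst/cli/foldcv.R`
(`foldcv.R build|evaluate|analyze`), covering CV construction, trajectory
post-processing to COLVAR files, and dual-cutoff/ΔF/FES analysis.

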