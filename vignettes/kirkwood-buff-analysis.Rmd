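---
title: "Kirkwood-Buff analysis of cosolvent solutions with kbsolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kirkwood-Buff analysis of cosolvent solutions with kbsolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbsolv)
```

## Scope and model

`kbsolv` implements the analysis machinery used to validate and apply a
force field for hydroxypropyl-beta-cyclodextrin (HPbCD) in water and in the
presence of amino acids and short peptides. The thermodynamic backbone is
Kirkwood-Buff (KB) theory: for species $i, j$ the KB integral

$$G_{ij} = 4\pi \int_0^\infty \left[ g_{ij}(r) - 1 \right] r^2\, dr$$

measures the net excess ($G_{ij} > 0$, accumulation) or depletion
($G_{ij} < 0$, exclusion) of $j$ around $i$ relative to an ideal fluid at
the same bulk density. The package computes $G_{ij}$ from two independent
directions:

* **from particle configurations** — radial distribution functions,
  finite-size correction, running integrals, windowed estimates with
  block-averaged errors (`compute_rdf()`, `correct_rdf_finite_size()`,
  `running_kbi()`, `estimate_kbi()`);
* **from experimental binary-solution data** — densities, partial molar
  volumes, compressibility and activity coefficients inverted through the
  exact KB fluctuation relations (`invert_thermo_to_kbi()`,
  `f33_from_kbi()`).

On top of these sit the ternary-system metrics: the preferential-interaction
coefficient $\gamma = G_{23} - G_{12}$ for a
water(1)-solute(2)-cosolvent(3) system, its side-chain/backbone
decomposition, geometric hydrogen-bond and cavity-inclusion counters, and
the ADD force-field parameter patch for CHARMM36-style HPbCD topologies.

Units follow the conventions of molecular simulation in this area:
coordinates and cutoffs in nm, per-molecule KBIs in nm$^3$, molar KBIs and
partial molar volumes in cm$^3$/mol (`kbi_nm3_to_cm3mol()` converts),
energies in kJ/mol, charges in elementary charge units.

## RDFs, the finite-size correction, and KBI estimates

`compute_rdf()` histograms minimum-image pair distances in uniform,
half-open bins $[r, r+\Delta r)$ reported at bin centres, normalising per
frame by the ideal-gas expectation $N_i\,(N_j/V)\,V_\mathrm{shell}$ from the
instantaneous box volume. Self-pairs are excluded from the counts when the
two selections coincide, while the density stays $N_j/V$. That pairing of
conventions is deliberate: it is exactly the convention under which the
closed-system correction below removes the like-species $1/N$ bias, and it
is what common MD analysis tools produce.

Closed (NVT/NpT) simulations deplete the apparent tail of $g_{ij}(r)$
because a particle found near the reference is a particle missing from the
reservoir; integrating that depressed tail biases $G_{ij}$ by a term of
order $V/N$. `correct_rdf_finite_size()` applies the standard excess-count
rescaling

$$g^{\mathrm{cor}}_{ij}(r) = g_{ij}(r)\,
  \frac{N_j\left(1 - V(r)/V\right)}
       {N_j\left(1 - V(r)/V\right) - \Delta N_{ij}(r) - \delta_{ij}}$$

with $V(r) = \tfrac{4}{3}\pi r^3$ and $\Delta N_{ij}(r)$ the mean excess
number of $j$ particles inside radius $r$ (`excess_counts()`). For an ideal
gas with $i = j$ the factor is exactly $N_j/(N_j - 1)$-shaped and restores
$g \equiv 1$; the test suite verifies both this and that the uncorrected
estimate carries the $O(V/N)$ offset. The operation refuses already
corrected curves: the rescaling is not idempotent, and double application
would silently bias results.

`running_kbi()` evaluates $G(R)$ cumulatively by the trapezoid rule on the
bin grid with the exact point $G(0) = 0$ prepended (the integrand vanishes
at the origin). Trapezoid quadrature is second order; the suite checks that
halving $\Delta r$ shrinks the error on smooth analytic inputs by about
four. Two numerical caveats are worth knowing. First, a hard-core
discontinuity is resolved at the midpoint between the straddling bin
centres, so analytic step tests should place the core radius on a bin edge.
Second, for an exponential excess $g = 1 + A e^{-r/\lambda}$ the running
integral reaches its asymptote $8\pi A \lambda^3$ slowly: the remaining
tail is $e^{-x}(1 + x + x^2/2)$ of the total at $x = R/\lambda$, still
12.5% at $R = 5\lambda$ and within 2% only beyond about $8\lambda$. Window
choices should respect this.

The convergence window itself is a user decision. Published work states
only that the average is taken "where convergence is reached"; rather than
automating that judgement we default to a window of 1.5-2.5 nm (sensible
for 8 nm boxes) and attach a warning whenever the mean slope of $G(R)$
across the window exceeds a configurable flatness threshold
(0.5 nm$^3$/nm by default). Uncertainty comes from block averaging over
frames — five contiguous blocks by default (`block_running_kbis()`), the
standard error being the spread of per-block window means. The simulation
literature this package supports reports no KBI error bars; block averaging
is the minimal honest substitute, and stochastic tests need it.

Boxes are orthorhombic only. The systems this package targets are cubic
8 nm boxes; triclinic minimum-image support would add complexity without
coverage.

## Inverting solution thermodynamics

For a binary water(1)-cosolvent(3) mixture the package uses the exact KB
fluctuation relations. With
$\Delta = G_{11} + G_{33} - 2G_{13}$,
$\eta = \rho_1 + \rho_3 + \rho_1\rho_3\Delta$ and the dimensionless
derivative $D = (x_3/RT)(\partial\mu_3/\partial x_3)_{p,T} = \rho/\eta$:

$$V_1 = \frac{1 + \rho_3 (G_{33} - G_{13})}{\eta}, \qquad
  V_3 = \frac{1 + \rho_1 (G_{11} - G_{13})}{\eta}, \qquad
  RT\beta_T = \frac{\zeta}{\eta},$$

with $\zeta = 1 + \rho_1 G_{11} + \rho_3 G_{33} +
\rho_1\rho_3(G_{11}G_{33} - G_{13}^2)$. Solving for the integrals gives the
inversion route implemented in `invert_thermo_to_kbi()`:

$$G_{13} = RT\beta_T - \frac{\rho V_1 V_3}{D}, \qquad
  G_{33} = G_{13} + \frac{\eta V_1 - 1}{\rho_3}, \qquad
  G_{11} = G_{13} + \frac{\eta V_3 - 1}{\rho_1},$$

and the activity-coefficient derivative predicted back from the integrals
(`f33_from_kbi()`):

$$f_{33} \equiv \left(\frac{\partial \ln f_3}{\partial \ln x_3}\right)_{p,T}
 = \frac{-\rho_1 x_3 \Delta}{1 + \rho_1 x_3 \Delta}.$$

The two routes close on each other identically — $f_{33} = D - 1$ — which
is the property the test suite asserts to $10^{-6}$ relative across dilute
composition grids. All algebra runs in SI internally; the interfaces speak
mol/L, cm$^3$/mol and 1/Pa, and a metamorphic test confirms the results are
invariant under the unit representation.

Activity data usually arrive on the molal scale;
`molal_to_molefraction_activity()` applies the dilute relation
$f_{3,m} = x_3 f_3$. Differentiating $\ln f_3(x_3)$ is done by a cubic
smoothing spline with GCV-selected smoothing (overridable; a natural
interpolating spline is used below four points) because the source work
does not state its differentiation scheme, and smoothing-spline
differentiation is the conservative default for sparse experimental grids.
The constants $V_1 = 18.07$ cm$^3$/mol and
$\beta_T = 4.52\times 10^{-10}$ Pa$^{-1}$ are treated as
composition-independent, which is appropriate for the dilute regime
(cosolvent below about 0.2 mol/L) this machinery targets.

### The forward generator and its closure modes

`gen_binary_thermo_dataset()` manufactures datasets that are *exactly*
consistent with a chosen KBI profile so the inversion can be tested without
digitising experimental tables. A design subtlety: a fully prescribed
triple $(G_{11}, G_{13}, G_{33})$ together with constant $V_1$ **and**
constant $\beta_T$ overdetermines the exact relations — once the triple and
$V_1$ fix the density (through a quadratic in $\rho$), the compressibility
is implied. The generator therefore supports two consistent closures:

* **full-triple mode** — the profile gives all three integrals; $V_1$
  anchors the density and each state carries the *derived* $\beta_T$.
  This supports the quasi-ideal fixed point (all-zero profile, $f_3
  \equiv 1$, density $1/V_1$) exactly.
* **compressibility mode** — the profile gives $G_{13}, G_{33}$ and leaves
  $G_{11}$ as `NA`; the supplied $\beta_T$ closes the system and $G_{11}$
  is derived. This mirrors how experimental inversions actually use a
  literature compressibility, and with water-like constants it lands on
  physically sensible values ($G_{11} \approx -17$ cm$^3$/mol and, for
  HPbCD-like $G_{13}, G_{33}$, a solute partial molar volume near 700
  cm$^3$/mol).

Activity coefficients are produced by quadrature of the closed-form
$d\ln f_3/dx_3$ from infinite dilution, so the generated $f_3$, $f_{3,m}$
and $\partial\mu_3/\partial x_3$ columns are mutually consistent to
integration tolerance. Profiles must remain inside the physical region
($\zeta > 0$, positive density root); the generator rejects offending
compositions by name rather than returning complex or negative
intermediates.

## Preferential interactions and the constant-increment method

`gamma_from_kbis()` records $\gamma = G_{23} - G_{12}$ with the sign
convention attached (negative = preferential exclusion). Error propagation
from KBI standard errors is available but off by default — the works this
package accompanies report no $\gamma$ error bars, and inventing them by
default would misrepresent the data.

Side chains are isolated by glycine subtraction
(`side_chain_gamma()`), assuming additivity of backbone and side-chain
contributions. The per-residue backbone term uses the constant-increment
method (`backbone_fit()`): for an N-acetyl-(glycine)$_x$-amide series,
$\gamma(x) = \gamma^{eg} + \gamma^{bb} x$, fitted by ordinary least squares
(no weights — the method fits a plain straight line) with the conventional
$R^2 = 1 - SS_{res}/SS_{tot}$. The generator `gen_gamma_series()` plants
exact lines plus Gaussian noise; the suite verifies machine-precision
recovery at zero noise and estimator unbiasedness (within two Monte-Carlo
standard errors over 500 replicate series) at realistic noise, using the
published backbone slopes 1.20 and 2.33 nm$^3$ as planted truths.

## Structural metrics

**Hydrogen bonds** (`detect_hbonds()`) use the geometric criterion:
donor-acceptor distance strictly below 0.35 nm and angle strictly below
30 degrees. The published phrasing of the angle ("between the hydrogen atom
and the line joining donor and acceptor") is ambiguous about the vertex; we
read it as the standard proton-deviation criterion — the angle at the
*donor* between the donor-to-H vector and the donor-to-acceptor line — and
make the vertex configurable (`hbond_criterion(vertex = "hydrogen")`)
for users who prefer the other reading. Donor/acceptor chemistry is the
user's selection; nothing is inferred from element types.

The $\chi$ percentage (`chi_parameter()`) is defined here as the percentage
of the cosolvent's hydrogen bonds that involve the solute, pooled over
frames: $\chi = 100 \sum_f n^{23}_f / \sum_f n^{tot}_f$. This matches the
published gloss ("percentage of hydrogen bonds established between the
cosolvent and the amino acids"), is monotone in the solute-cosolvent count
at fixed normalisation, and is defined as 0 (with a warning) when no bonds
are present at all.

**Inclusion** (`inclusion_fraction()`) counts, per frame, cyclodextrins
with at least one guest centre of mass strictly closer than 0.5 nm to the
CD centre of mass — a CD hosting two guests counts once, because the
quantity is "CDs involved in inclusions", not guests included. The
per-frame counts are averaged and normalised by the CD count. Centres of
mass are mass-weighted with group unwrapping relative to the group's first
atom, so molecules split across periodic boundaries are handled.

**Orientation** metrics (`rim_orientation_rdf_max()`,
`backbone_sidechain_rdf_max()`) reduce to RDF maxima between rim atoms (or
backbone/side-chain atoms) and centres of mass, reusing the RDF engine via
centre-of-mass pseudo-trajectories. An empty side-chain selection (glycine)
is reported as *absent*, not as zero — a zero maximum would be a
qualitatively wrong statement about a residue that has no side chain. One
practical warning: on sparse synthetic systems the innermost bins of an RDF
hold very few ideal-gas counts and are correspondingly noisy, so maxima
should be interpreted against the curve, which the functions return
alongside the maximum.

## The force-field patch

`load_topology()` reads a strict itp-like subset (moleculetype, atomtypes,
atoms, optional embedded tags), denormalises $\varepsilon/\sigma$ onto
atoms — necessary because the CHARMM36 variant assigns different hydroxyl-O
$\varepsilon$ to the glucopyranose and hydroxypropyl moieties — validates
neutrality to $10^{-6}$ e, and pairs every hydroxyl H with its bonded O.
`apply_add_patch()` then sets each hydroxyl H charge from 0.42 e to 0.33 e,
moves the +0.09 e deficit onto the bonded O, and replaces the four hydroxyl
$\varepsilon$ values (glucopyranose O 0.804 to 0.450, H 0.192 to 0.120;
hydroxypropyl O 0.636 to 0.450, H 0.192 to 0.120 kJ/mol), leaving $\sigma$
and everything else untouched; `diff_topologies()` certifies that scope.
Patching an already ADD topology is an error, never a silent double shift.

The local O redistribution is the *minimal* neutrality-preserving choice,
and it is clearly a fallback: the published figure distributes the deficit
over its own charge set, which the text available to us does not tabulate.
An explicit per-atom charge map (YAML or named vector) therefore overrides
the redistribution as the authoritative source when the user has transcribed
it. The bundled topology (`inst/extdata/hpbcd_charmm36_synthetic.itp`) is
*synthetic* — plausible CHARMM36-style charges, neutral per subunit, correct
hydroxyl classes — and is labelled as such; it exercises the machinery but
is not the published parameter set.

## What the synthetic generators do and do not emulate

The generators give every pipeline an input with known ground truth:

* `gen_ideal_gas()` — uncorrelated uniform particles, every KBI zero.
* `gen_structured_fluid()` — pair density $1 + A e^{-r/\lambda}$ around
  centers, with the closed-form KBI $8\pi A \lambda^3$ recorded. Positive
  amplitudes superpose a fixed-count excess population on a uniform
  background; negative ones rejection-sample the target density field
  exactly. Both keep the particle count constant across frames; the planted
  amplitude is rescaled so the target holds under the realised total
  density (residual bias below one part in the partner count, and a
  rounding of at most half an excess particle).
* `gen_hbond_fixture()` / `gen_inclusion_fixture()` — planted geometries
  with hard margins (5 pm / 2 degrees / 20 pm) around the 0.35 nm, 30
  degree and 0.5 nm decision boundaries, so binning can never flip a label.
* `gen_gamma_series()` — exact lines plus Gaussian noise.
* `gen_binary_thermo_dataset()` — described above.

These are *statistical stand-ins*, not molecules. They contain no excluded
volume, no hydrogen-bond network, no real cyclodextrin geometry, and no
force field. Passing tests therefore demonstrate that the estimators are
correct — unbiased where they should be, exact where they can be — not that
any particular simulation is converged or any force field accurate. Those
are properties of the trajectories a user brings.

All generators draw from R's RNG under an explicit integer seed through a
save/restore wrapper, so they are bit-reproducible and never perturb the
session's RNG state.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run at desk scale, chosen to
make the statistical assertions decisive: about $10^4$ partner
particle-frames for the exponential-excess KBI (estimate within three
combined standard errors of the closed form), $6\times10^3$ for the
closed-system correction contrast, 20-point composition grids for the
thermodynamic closure at $10^{-6}$ relative tolerance, and 500 replicate
series for the slope-recovery Monte Carlo. Production analyses of real
trajectories (tens of thousands of frames, $8^3$ nm$^3$ boxes) use the
same code paths with larger inputs.

Degenerate inputs are rejected loudly rather than patched: empty
selections, non-neutral molecules, windows outside the integration grid,
compositions where a KB denominator vanishes (named in the error), decay
lengths too long for the minimum image, already-corrected RDFs,
already-patched topologies.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* The RDF engine is a straightforward $O(N_i N_j)$ pair loop per frame —
  ample for the target systems, not tuned for millions of atoms.
* The KB inversion is binary; ternary inversions (which would need
  osmometry-grade data) are out of scope, as is converting $\gamma$ values
  into transfer free energies or m-values.
* The thermodynamic machinery assumes the dilute regime in which $V_1$ and
  $\beta_T$ are constants; it refuses compositions above $x_3 = 0.05$.
* No automatic equilibration detection: users select the frames they
  analyse.
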