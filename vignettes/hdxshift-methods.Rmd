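---
title: "Differential HDX-MS analysis of conformational equilibria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS analysis of conformational equilibria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxshift)
library(dplyr)
```

## The problem

Secondary transporters of the major facilitator superfamily (MFS) cycle
between outward-facing (OF) and inward-facing (IF) conformations. A
point mutation or a change in the surrounding lipids can shift the
population balance between the two states without changing the protein's
fold. Bottom-up hydrogen–deuterium exchange mass spectrometry (HDX-MS)
detects such shifts: when a transporter spends more time inward-open,
its intracellular loops become more solvent-exposed (take up more
deuterium) while its extracellular loops become more protected — and
vice versa. The diagnostic signature of an equilibrium shift is
therefore an *anti-correlated* uptake difference between the two faces
of the membrane, with the transmembrane core silent.

hdxshift implements the peptide-level differential analysis that turns
two replicate uptake datasets (a control state and a variable state)
into that signature: per-timepoint and summed uptake differences, a
global pooled-variance significance threshold combined with a t-test,
binary classification, residue-level consolidation for structural
mapping, and Woods-plot exports. A companion module computes the
intracellular gate distance on MD trajectory frames, the orthogonal
geometric observable for the same open/closed transition.

## Statistical model

For a peptide $a$ at exposure time $t$, the measured uptake is
$Y_{a,t}$ (Da), with $n$ replicates per (peptide, state, time) group.
The relative fractional uptake is

$$\mathrm{RFU}_a = \frac{Y_{a,t}}{\mathrm{MaxUptake}_a \times D},$$

where $\mathrm{MaxUptake}_a$ counts the exchangeable backbone amides
(peptide length minus one for the N-terminal residue, minus internal
prolines) and $D$ is the deuterium fraction of the labeling mix after
dilution ($D = 0.95$ for the standard 5 µL-into-95 µL scheme).
Differences are computed in Da, not RFU: summed uptake differences and
their thresholds live naturally in mass units, and RFU is carried as an
auxiliary column. No back-exchange correction is applied — only
relative differences between states measured identically are
interpreted, so a common multiplicative loss cancels.

The differential for each peptide and timepoint is
$\Delta_{a,t} = \bar{Y}^{var}_{a,t} - \bar{Y}^{ctl}_{a,t}$ (variable
minus control; positive = more deuteration in the variable state), and
the summed differential is $\Sigma\Delta_a = \sum_t \Delta_{a,t}$ over
the $k$ timepoints.

**Significance gate 1 (global confidence threshold).** Replicate SDs
are pooled as the root mean square over every (peptide, state,
timepoint) group, $\sigma_p$. The SE of one per-timepoint difference is
$\sqrt{2}\,\sigma_p/\sqrt{n}$, and the symmetric threshold on the
summed differential is

$$T = t_{1-\alpha/2,\,\nu}\,\sqrt{k}\,\frac{\sqrt{2}\,\sigma_p}{\sqrt{n}},
\qquad \nu = \sum_g (n_g - 1),$$

with $\alpha = 0.01$ by default (a 99% confidence threshold). Pooling
across all peptides assumes homoscedastic replicate noise, the standard
assumption behind global HDX significance thresholds; the per-peptide
SE is also reported so heteroscedastic outliers remain visible.

**Significance gate 2 (t-test).** Per replicate, uptake is summed
across timepoints within the replicate; the two states are compared by
an unpaired two-sided $t$-test ($n = 3$ per state by default,
equal-variance with $\nu = n_v + n_c - 2$; Welch available via
`var_equal = FALSE`).

A peptide is classified `positive` when $\Sigma\Delta_a > +T$ *and*
$p \le \alpha$, `negative` for the mirrored condition, `none`
otherwise. Requiring both gates is the conservative reading of a
protocol that states a CI threshold and a t-test side by side; whether
they were intended as one procedure or two is ambiguous, and the dual
gate can only lower the false-positive rate (the null-calibration test
confirms it stays below the nominal level). No multiple-testing
correction is applied by default, matching standard practice for
peptide-level HDX significance maps; Benjamini–Hochberg is available
through `p_adjust = "BH"`.

If replicate groups are incomplete they are flagged at validation and
skipped by the statistics with a warning, never silently imputed.
Mismatched exposure-time schemes between the two states are a hard
error rather than a silent intersection.

## Residue consolidation and structural mapping

Peptide classifications are painted onto residues over the full peptide
span: a residue is `positive` if covered by at least one positive and
no negative peptide, `negative` conversely, `none` if covered only by
non-significant peptides, and `no_coverage` if no peptide covers it.
Where positive and negative peptides overlap, the majority of
significant peptides decides; an exact tie resolves to `none` and the
conflict is logged loudly — real differential maps rarely contain such
segments, and a silent resolution would hide a genuine inconsistency.
The color scheme is deliberately binary (sign only, no magnitude
gradient), written into the PDB B-factor column as +1.00 / −1.00 /
0.00 / 99.00 in the fixed-width `%6.2f` convention so any molecular
viewer can reproduce the red/blue/white/gray maps; a magnitude-graded
TSV is available for diagnostics. Because significant peptides may
straddle a loop/helix boundary, transmembrane residues adjacent to an
affected loop are legitimately painted — segment-level mapping shows
segments, not residues, and the per-residue TSV carries the supporting
peptide counts so the provenance of every color is inspectable.

## The synthetic-data generator

Real differential HDX data for these transporters requires the
deposited raw MS runs; the simulator instead generates uptake tables
from an explicit two-state kinetic model so every downstream stage can
be tested against known ground truth.

Residues of an $N$-residue protein are partitioned into a 12-helix MFS
topology: 14-residue transmembrane blocks alternating with
intracellular/extracellular loops (termini intracellular), loop sizes
balanced to fill $N$. Each residue $i$ carries an intrinsic exchange
rate $k^{int}_i$ (log-uniform in $1$–$10^3\ \mathrm{min}^{-1}$,
spanning the 30 s–150 min observation window; a hook accepts
user-supplied sequence-specific rates) and one protection factor per
conformation. Under fast conformational exchange (EX2) the observed
rate is the population-weighted mixture

$$k^{obs}_i = k^{int}_i\left[\frac{f_{IF}}{P^{IF}_i} +
\frac{1 - f_{IF}}{P^{OF}_i}\right], \qquad
u_i(t) = 1 - e^{-k^{obs}_i t},$$

and a peptide's noiseless uptake is $D \sum_i u_i(t)$ over its
exchangeable amides. EX2 is the right regime here because the analysis
operates on centroid uptake only; slow-exchange (EX1) bimodal envelopes
are out of scope. Defaults encode the study conditions the pipeline is
meant to resolve: loops at baseline protection $10^2$, transmembrane
residues at $10^4$, affected loops 1.0 log₁₀ unit more protected in
their closed state (intracellular closed in OF, extracellular closed in
IF), control equilibrium 50/50, variant shifted by
$\Delta f_{IF} = 0.3$, three replicates with Gaussian noise of SD
0.05 Da truncated at zero (typical instrument repeatability), and the
two exposure-time schemes 30 s / 5 min / 30 min (detergent) and
5 / 30 / 150 min (nanodiscs). The 1.0-unit protection contrast is a
tunable of the simulator, chosen so a 0.3 population shift yields
summed differentials comfortably above threshold at that noise level —
it is a property of the synthetic conditions, not a measured quantity.
In-silico digestion draws random peptides of length 5–25 until a target
sequence coverage (default 80%, matching realistic membrane-protein
coverage of roughly 76–85%) is reached.

What the generator does *not* emulate: back-exchange (deliberately,
since the analysis is uncorrected relative data), EX1 kinetics,
sequence-dependent intrinsic rates, peptide-length-dependent noise,
and chromatographic artifacts. Passing tests therefore demonstrate
that the statistics and classification logic are correct and
calibrated, not that any specific real transporter behaves this way.

## Gate geometry

The intracellular gate distance is the mass-weighted center-of-mass
distance between two groups of Cα atoms flanking the cytoplasmic
opening. The default groups are the XylE intracellular gate: residues
75–80, 149–154, 160–165 (TM2/TM3 side) versus 332–337, 391–397,
404–410 (TM10/TM11 side); both are configurable in compact range
syntax. For an open transporter this distance sits near 13 Å and drops
to about 9 Å when the intracellular side closes. Trajectories are read
from multi-model PDB or a documented plain-text frames table; binary MD
formats are out of scope to keep the dependency footprint small, and
frame times are never guessed — they come from an explicit per-frame
column or a stated frame interval. The trailing-window distribution
(default: the last 200 ns) is a histogram normalized to unit integral,
which makes runs of different lengths and frame counts comparable.
Masses default to standard atomic masses by element; with a Cα-only
selection this is nearly uniform weighting, but mass-weighting is kept
so the metric is a true center-of-mass distance.

## Numerical and design choices

- **Determinism.** Every stochastic component (scenario, digestion,
  noise) is a pure function of its seed; commands dump their resolved
  configuration (including generated seeds) as YAML next to their
  outputs.
- **Exposure units.** Seconds internally; readers accept `s`/`min`
  suffixes, and bare numbers are minutes in the DynamX-style
  `cluster_csv` dialect and seconds in `long_tsv`.
- **Mean+SD imports.** A `cluster_csv` file carrying only means and SDs
  is expanded to placeholder replicates $\{\bar{Y}-s, \bar{Y},
  \bar{Y}+s\}$ — which reproduce the stated mean and SD exactly — and
  every such row is flagged `reconstructed` so downstream users can
  exclude them.
- **Degenerate t-tests.** When both replicate sets have zero variance
  the statistic is defined directly: $p = 1$ for equal means (exactly
  the no-difference case), $p = 0$ otherwise. This only arises in
  noise-free simulations.
- **Thresholds at zero noise.** Zero pooled SD yields a zero-width
  threshold, so any nonzero summed differential is significant; this is
  the correct limiting behavior and is exercised by the noise-free
  monotonicity test.
- **Problem sizes.** The bundled validation runs use 300-residue
  scenarios with ~60 peptides for the pattern-recovery checks and 1000
  peptides for null calibration — large enough for stable fractions,
  small enough to run interactively.

## A worked run

```{r example}
scenario <- default_transporter_scenario(300, "toward_IF", seed = 7)
peptides <- digest_in_silico(scenario$sequence, 0.8, seed = 8,
                             min_peptides = 60)
cond <- labeling_conditions("detergent")
control <- simulate_dataset(scenario, peptides, cond, "control",
                            noise_model(0.05, 9))
variant <- simulate_dataset(scenario, peptides, cond, "variant",
                            noise_model(0.05, 9))

diff <- run_differential(control, variant, alpha = 0.01)
glance(diff)
```

```{r woods, fig.width = 7, fig.height = 3.5}
autoplot(diff)
```

```{r map, fig.width = 7, fig.height = 1.8}
res_map <- consolidate_to_residues(diff, 300)
autoplot(res_map)
```

The Woods plot shows the anti-correlated signature: intracellular-loop
peptides above the +99% threshold line (red), extracellular-loop
peptides below the − line (blue), transmembrane-core peptides inside
the band (gray).

## Known limitations

- Protection factors and populations are not estimated from data; the
  package tests for equilibrium shifts, it does not fit exchange models.
- Residue consolidation maps full peptide spans; it does not attempt
  overlap-based sub-peptide resolution, so boundaries are soft by one
  peptide length.
- The gate metric is purely geometric; it does not align frames, detect
  state transitions, or compute lipid contacts.
- The simulator's calibration properties (false-positive rate at the
  nominal level, ≥90% sign recovery at the default effect size) are
  statements about the synthetic conditions, not guarantees for any
  particular instrument or protein.
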