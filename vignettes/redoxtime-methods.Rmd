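---
title: "Methods: quantifying the redox timeline of chronologically aging yeast"
author: "redoxtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the redox timeline of chronologically aging yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxtime)
```

## The measurement model

Differential thiol trapping (OxICAT) labels every in vivo *reduced*
cysteine with the light (^12^C) isotope-coded affinity tag and every
in vivo *oxidized* cysteine — after chemical re-reduction — with the heavy
(^13^C) tag. A tryptic peptide with $n$ cysteines therefore appears in a
centroided spectrum as up to $n+1$ isotopologue envelopes spaced by one
light/heavy mass difference per label, $\Delta = 9.0302$ Da (9 Da
nominally), at

$$ m/z_k = m/z_{\mathrm{red}} + k\,\Delta / z, \qquad k = 0,\dots,n, $$

where $m/z_{\mathrm{red}}$ is the all-light monoisotopic peak and $z$ the
charge. Because the ratio of the envelope pair is internal to the peptide,
percent oxidation is independent of protein abundance. `redoxtime`
integrates each envelope as the sum of the most intense peak within
`mz_tolerance` (default 0.1 Da, MALDI-TOF scale) of each of the first
five isotopologue positions, and computes

$$ \%\,\mathrm{ox} = 100\cdot\frac{\sum_k k\, I_k}{n \sum_k I_k}. $$

Two quantification modes are provided. `two_state` (the default) uses
only $k \in \{0, n\}$ and is appropriate when the cysteines of a peptide
oxidize as a unit, as for an intramolecular disulfide couple such as the
glycolytic GapDH active-site pair — the canonical worked example, where a
2-cysteine peptide at $m/z$ 2161.13 gains 18 Da when fully heavy-labelled
(2179.13) and an intensity split of 30:70 reads out as 70% oxidized.
`full` weights every labelling state and reduces to `two_state` exactly
when the intermediate envelopes are empty; both are tested against the
formula directly and against spectra synthesized at known oxidation
fractions. No correction for isotopic overlap between labelling states is
attempted: at 9 Da per label and five isotopologues the envelopes are
disjoint at the default tolerance.

Replicates are aggregated per peptide and day by arithmetic mean and
sample SD, and a peptide-day is masked missing unless quantified in at
least `min_replicates` biological replicates (default 3, the published
reproducibility rule). An optional strict filter retains only peptides
observed at every day in every replicate.

## Trajectory classes and classification

The central biological observation is that oxidation trajectories fall
into seven classes: the general collapse classes A and B (low during log
phase, jumping past 50% on the collapse day or one day later), the
high-start class C, the early risers D and E (at least 1.5-fold above the
day-0 level one or two days *before* the collapse), and the flat classes
F (always reduced) and G (always oxidized). The package provides both
unsupervised k-means (Euclidean distance, best of 10 restarts, seeded —
`stats::kmeans` behind `kmeans_trajectories()`) and a deterministic rule
classifier that operationalizes the class definitions; the two are
cross-tabulated by `classify_trajectories()`, with the rule classifier
treated as authoritative because the class definitions are stated as
threshold rules.

The rule thresholds live in `cluster_rules()` with these defaults:
`low_start = 30` (the class-A/B log-phase ceiling; the source material
states both 30% and 20% in different places, and the figure-legend value
30 is used), `high_ox = 50`, `high_start = 40` and a 15-point minimum
rise for class C (the published "~50% start, significant increase" has no
numeric rule; 40/15 is this package's operationalization),
`early_fold = 1.5`, `early_abs_min = 10` (an absolute floor that
suppresses spurious 1.5-fold calls on near-zero baselines, on which the
source is silent), and `flat_range = 15` / `oxidized_floor = 50` for F/G.
Rules are evaluated in the fixed priority order F, G, D, E, A, B, C so
that labels are mutually exclusive and an early riser that would also
pass the general-collapse test stays D/E, which is how the published
early-target table segregates its entries from the general pattern.

Named days come from `timepoint_schedule()`: standard cultures are
sampled on days 0–4 with early days 1 and 2 and collapse on day 3;
caloric restriction on days 0–5 and 7 with early days 3 and 4, collapse
on day 5, and the late day (nominally 6) mapped to the first sampled day
at or after it, day 7, because day 6 is unsampled.

Missing values are imputed before clustering by a k-nearest-neighbour
rule that preserves the published contract (five neighbours, rows kept
only when more than 30% of their values are known): each missing entry
becomes the mean of that column in the `k` nearest rows observed on the
column, with RMS distance over shared observed days. The imputer is
hand-written because the original imputation tool is an external service;
kNN with the stated parameters is the closest self-contained equivalent.
Imputed values are clipped to [0, 100].

## Early targets and sequence context

`flag_cells()` implements the early-target day criterion literally: a day
is flagged when it is at least 2-fold the day-0 value, or at least
1.5-fold *and* strictly above 60% total oxidation ("exceeding" is read as
strict; same for the "more than 45%" day-2 summary threshold). Folds with
a zero day-0 baseline are reported undefined rather than infinite.
Early-target membership is the union of D/E calls across conditions,
because targets qualify under either cultivation regime. On the packaged
29-peptide reference panel this yields 28 targets (all panel rows except
the general-pattern comparison peptide, with FAS2 qualifying only via its
caloric-restriction trajectory), 5 of which carry the peroxide-sensitive
annotation. The panel recount of day-2 oxidation above 45% gives 19;
the published prose says 20, the printed trajectories do not exactly
support it, and `summarize_early()` simply reports the computed count.

Sequence context uses 11-residue windows (five residues up- and
downstream of the identified cysteine, truncated without padding at
protein termini). Residues map to six types — cysteine, positive
(K, R, H), negative (D, E), polar (S, T, N, Q), nonpolar
(A, V, L, I, M, P, G), aromatic (F, W, Y); histidine-as-positive and
glycine-as-nonpolar are this package's assignments, configurable via
`aa_type_map()`. Enrichment is frequency-based (counts of positions, not
per-window presence), normalized to the whole window library, central
cysteine always excluded. Class comparisons use Pearson's chi-square on
the 2 × k type-count table (df 5 with cysteine, df 4 without) through
`stats::chisq.test(correct = FALSE)`, with a from-first-principles
$\sum (O-E)^2/E$ oracle in the test suite. Counts, not rescaled
frequencies, enter the test. Logo output is a per-position frequency
table rather than a rendered graphic.

## Redox metabolites and the timeline

The glutathione-couple potential is the two-electron Nernst equation

$$ E_\mathrm{GSH} = E_0 + \frac{RT}{2F}\,
   \ln\frac{[\mathrm{GSSG}]}{[\mathrm{GSH}]^2}, \qquad E_0 = -240\ \mathrm{mV}, $$

with molar concentrations, $R = 8.314462$ J mol⁻¹ K⁻¹,
$F = 96485.332$ C mol⁻¹ and $T$ defaulting to 303.15 K — the 30 °C
cultivation temperature; the temperature actually used for the published
potentials is not stated, so it is configurable. The slope is 13.062 mV
per ln-unit at 303.15 K (12.846 at 298.15 K). `egsh_shift_day()` reports
the first day at least 15 mV above day 0; `nadph_decline_onset()` the
first day after the NADPH maximum at which the level has dropped by
`drop_frac` (default 0.2 — the published account says only "rapidly
decreased", so the 20% drop is this package's operationalization);
`condition_delay()` converts onset differences to hours.

`build_timeline()` assembles five events — NADPH decline, E~GSH~ shift,
early-oxidation onset, redox collapse, 50% viability — per condition.
Early-oxidation onset is the first of the schedule's early days on which
any D/E peptide passes the early-rise criterion (the same criterion, at
the same days, that defines the classes); the collapse day is the first
day the median oxidation of the A∪B peptides exceeds 50%; mean lifespan
is the linear interpolation of the first 50% viability crossing. These
last two are numeric operationalizations of events the source describes
narratively. Event days are fractional only where interpolation applies
(viability); the others are sampled days, so lags are multiples of 24 h.

## What the synthetic generator emulates

`gen_trajectories()` draws each peptide from one of seven archetype
trajectories per condition (`oxidation_archetypes()`), adds iid Gaussian
noise per replicate observation (default SD 5 percentage points), clips
to [0, 100] and masks cells missing independently (default rate 0.1,
4 replicates). The archetypes are constructed so that (i) each satisfies
its own class rule exactly at zero noise, and (ii) the early-day values
of the non-early classes sit several noise SDs clear of the D/E
thresholds, mirroring the published general-pattern trajectories whose
day-1/2 folds are far below 1.5 (e.g. 28% vs 26% at day 2); without that
margin, noise rather than class identity would drive early calls. Class
proportions default to the published distribution (A 0.35, B 0.15,
C 0.20, D/E 0.05 each, F 0.08, G 0.12: the collapse classes hold >70%,
early risers ~10%, ~8% stay reduced). Under the water condition the
archetypes stay reduced through day 10 — the biology the condition is
meant to show — so their class labels are deliberately not recoverable
there. No published noise magnitude exists for the oxidation
percentages; the 5-point default is a placeholder consistent with the
printed replicate SDs being small relative to the class structure.

`gen_spectrum()` emits the label-state envelopes with a two-state weight
model by default (the worked spectra show only the 0- and $n$-label
envelopes; binomial mixed states are the `full` option), an
averagine-like binomial envelope shape with the isotopologue probability
proportional to peptide mass, and multiplicative per-peak Gaussian noise
(default relative SD 0.05), truncated at zero. `gen_peptide_library()`
plants the cysteine-proximity signal by multiplying the cysteine
probability (background 1.3%, approximate yeast proteome frequencies in
`background_aa_freqs()`) by a configurable boost inside D/E flanking
windows. `gen_metabolites()` reproduces the qualitative physiology:
NADPH peaks at the diauxic shift (~12 h) and declines from day 1
(standard) or day 3 (caloric restriction; the unexplained day-4 NADP(H)
rebound of standard cultures is included as a shape feature), E~GSH~
shifts ≥15 mV by day 1 / day 3, ATP holds at or above the day-0 level
through day 5 / day 7, and viability is logistic with 50% crossings near
days 7, 11 and 16 (standard, caloric restriction, water). The logistic
lifespan parameterization and all anchor values between the stated
landmarks are this package's choices.

What passing tests on these data do **not** show: the generator has no
chimeric spectra, retention-time structure, charge-state mixtures,
peptide-dependent noise, or correlated missingness, and its archetypes
are cleaner than real trajectory classes; recovery rates on it are upper
bounds, not estimates, for real MS data.

## Numerical and design notes

* All generators take explicit seeds and restore RNG state
  (`withr::with_seed`); equal configuration implies byte-identical
  output, which the suite checks end to end.
* Class counts are apportioned from proportions by largest remainder, so
  label counts are deterministic, not multinomial.
* `locate_envelope()` reports an absent monoisotopic peak as a flagged
  zero, never an error; quantification with all envelopes absent yields
  a flagged non-result rather than a number.
* Ties and boundaries: "exceeding"/"more than" thresholds are strict
  (>); class-rule thresholds follow the stated inequalities (e.g. G
  requires min ≥ 50). A trajectory matching no rule is `unassigned`.
* The reference panel is stored as plain TSV with `nd` for conditions
  not determined; rows with no caloric-restriction data simply drop out
  of that condition's matrix.
* Test and example problem sizes (hundreds of trajectories, hundreds of
  spectra, ~20 seeds for the power check) are chosen so the whole suite
  runs in well under a minute while keeping binomial/chi-square
  approximations comfortable.

## Known limitations

* Peptide identification, FDR control, LC alignment and cross-run
  normalization are out of scope; reduced-form m/z values are inputs.
* The chi-square comparison needs expected counts above zero in every
  cell and errors otherwise with advice to merge sparse types.
* At the yeast-like 1.3% cysteine background, detecting a 3-fold planted
  proximity signal needs on the order of a hundred windows per merged
  class; the suite's power check uses 300 per group.
* Published dataset-wide counts (286/263/100 reproducibly identified
  peptides), database-overlap percentages and printed chi-square
  p-values depend on the full study data, which are not distributed;
  they are covered by property-based checks on synthetic data instead.
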