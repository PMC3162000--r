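---
title: "Predicting coiled-coil regions and oligomerization state with a chain MRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting coiled-coil regions and oligomerization state with a chain MRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilmrf)
```

## The problem

Coiled coils are bundles of two or more alpha helices wound around each
other, encoded in sequence by the seven-residue heptad repeat
`abcdefg`, with predominantly hydrophobic residues at the `a` and `d`
core positions.  Given a protein sequence, `coilmrf` answers two
questions per residue: is it part of a coiled coil, and if so, is the
bundle a dimer (two helices) or a trimer (three)?  Telling dimers from
trimers is difficult because both share the same heptad architecture;
the discriminating signal lives in subtle composition differences at
the core positions (e.g. beta-branched Ile/Val at `a`/`d` favour
trimers, Leu at `d` and the polar Asn-at-`a` marker favour dimers) and
in correlations between nearby residues.

## The model

### Hidden states

Each residue carries a hidden state: one non-coil state, or a coil
state labelled by oligomer class (dimer/trimer), heptad letter `a`–`g`,
and a location label 1–9.  Locations 1–7 mark the first seven residues
of a coil, 8 any middle residue, and 9 the last.  That makes
`1 + 2 x 7 x 9 = 127` states.  The location labels do two jobs:

* they force every coil to run `1,2,...,7,8,...,8,9`, so no predicted
  coil can be shorter than 9 residues;
* they tell each position how many of the pairwise-correlation
  distances `k = 1..7` reach back into the same coil (`k < p` for
  `p` in 1..7; all seven for locations 8 and 9), so correlation terms
  never cross a coil boundary.

The joint distribution over states `y` and residues `x` is a chain
Markov random field: a product over positions of singleton potentials
`psi1(y_i, x)` and 0/1 transition indicators `psi2(y_i, y_{i+1})`,
normalized by `Z`.  Transitions encode: heptads advance cyclically by
one; a coil is entered from non-coil at any heptad but only at location
1 and left only from location 9; the class cannot change inside a coil;
and two consecutive coils are separated by at least one non-coil
residue.  Sequences must start in non-coil or a location-1 state and
end in non-coil or a location-9 state; a truncated coil running off the
sequence edge is therefore not representable (a documented limitation —
posteriors near the ends of a sequence that genuinely clips a coil will
be conservative).

### Features and potentials

Eight features summarize an annotated segment: summed log
probabilities of each residue given its heptad under the dimer, trimer
and (heptad-free) background tables; pooled distance-1..7 correlation
statistics under each table set, where the statistic for a pair
`(x_{i-k}, x_i)` is the log of its joint probability over the product
of its marginals; and Eisenberg-scale hydrophobicity summed over `a`
and `d` positions.  A class-weighted multinomial logistic regression
(non-coil as reference class) turns these into two linear scores with
coefficients `alpha` (dimer), `beta` (trimer) and one constant per
class.

Because every feature is a sum of per-position terms — with the
correlation terms gated by the location label as above — the segment
score factorizes exactly into per-position contributions.  The
singleton potential of a coil state at position `i` is the dot product
of its class coefficients with that position's contribution vector,
plus the class constant exactly at location-1 states (so every coil
path collects it once).  The package asserts this factorization to
1e-10 in its tests; it is what makes the regression-learned score and
the MRF the same model.

### Decoding

Per-residue posteriors are exact marginals computed by the
forward-backward algorithm over the 127-state chain, entirely in log
space with log-sum-exp (no scaling-factor variant), so no input can
overflow and the forward and backward normalizers must agree — which is
asserted, along with agreement with a brute-force path-enumeration
oracle on short sequences.  The per-residue dimer (trimer) probability
is the posterior summed over that class's 63 states.  A register letter
is displayed when the total coil posterior exceeds 0.5 (a presentation
threshold only; the probabilities are the contract).

## Training protocol

* **Positives** are the annotated coil segments of dimer and trimer
  records.
* **Negatives** are windows of non-coil sequences with a random assumed
  register: window length uniform on 0–249 (redrawn below 9, since such
  windows cannot host a valid coil path and would contribute degenerate
  features), truncated to the sequence, register starting at a uniform
  heptad.  One window is drawn per negative sequence.
* **Weights**: the dimer and trimer classes each total weight 1; the
  non-coil class totals 1000, encoding the prior that non-coil residues
  dominate natural sequences.
* **Offset**: summing over paths yields many coil interpretations per
  residue but only one non-coil one, biasing posteriors toward coils;
  20 is subtracted from both class constants to compensate.  The value
  is a conventional operating point, exposed as a parameter, and the
  package asserts that increasing it can only lower coil posteriors
  (exactly so on sequences short enough to host a single coil).

### Numerical choices

* **Fitting**: Newton's method with step-halving on the weighted
  log-likelihood, so the objective trace is non-decreasing by
  construction; non-convergence is an error carrying the gradient norm.
* **Ridge**: an L2 penalty on the 16 feature coefficients (never the
  constants) guards against perfect separation.  The default is 1e-3:
  clean training sets are often linearly separable, and with a
  vanishing penalty the fitted direction is noise-driven and can grow
  arbitrarily large — large-magnitude coefficients are then exploited
  by the MRF's free register choice, which cherry-picks shifted
  registers that harvest whatever feature got a wild weight.  1e-3 is
  the smallest order of magnitude that keeps coefficients O(1) and fold
  directions stable; it is far below any value that would visibly bias
  a well-determined fit.
* **Smoothing**: single-residue tables use additive smoothing
  (default pseudocount 1 per cell), which keeps every potential finite.
  Pair tables are smoothed with a Dirichlet prior *centered on the
  product of the slice's single-residue marginals* (same total prior
  mass as the additive scheme).  A pair slice has 400 cells and, on
  moderate training sets, often fewer observed pairs than that; a
  uniform-centered prior would drag joints toward uniform and hand the
  log joint-over-marginals statistic large spurious values precisely
  where data are sparse.  Centering on independence shrinks the
  correlation statistic toward zero instead, leaving it unbiased where
  counts are plentiful.
* **Unknown residues**: codes outside the 20-letter alphabet map to
  `X`; `X` contributes no counts when tallying and receives the
  column-average probability at lookup, and hydrophobicity 0, so it
  can never dominate a potential.
* **Ties**: a dimer/trimer statistic exactly at the threshold is called
  dimer (configurable); a trimer score of 0 maps the statistic to
  `+Inf`.

## Cross-validation

Families are the unit of held-out evaluation: `leave_family_out()`
trains on `n-1` families and predicts the held-out one, after pooling
families of four or fewer sequences into a single miscellaneous family.
Because the regression consumes *features*, which themselves depend on
frequency tables, the protocol is nested: the features of each training
family `G` are computed from tables over the other `n-2` training
families, so the regression is fit on features of exactly the
"unseen-family" kind it will meet at test time; inference tables for
the held-out family use all `n-1` training families.  Every fold
records the identities of all records feeding its tables and its
regression, and the test suite audits that the held-out family appears
in none of them.

A sequence is classified by the ratio statistic: per coil residue, the
dimer ratio `p_dimer / (p_dimer + p_trimer)`; the dimer and trimer
scores are the sums of the ratios and their complements over the
annotated coil, and their ratio is compared to a threshold (default 1).
Detection uses the total coil probability: a positive sequence counts
as found when every annotated coil residue exceeds the cutoff, a
negative as a false positive when some 28-residue window lies entirely
above it (sequences shorter than 28 residues can never false-positive
under this rule).

For the residue-level detection ROC reported by the recovery
experiment, held-out coil residues pooled across folds provide the
positive scores; negative-sequence residues are scored under a model
trained on all families, since negatives are never a held-out family
and already participate in every fold's background tables.

## The synthetic data generator

No external database ships with the package; `synthetic_spec()` /
`sample_dataset()` generate register-annotated families and negative
sequences so that tallying, regression, inference and cross-validation
are all exercised end to end.  The generator emulates, at reduced
scale, a curated coiled-coil family database: by default 6 families per
class with 15 sequences each (180 annotated coils) plus 150 negative
background sequences; coils of 21–49 residues inside background flanks;
families are small log-normal perturbations (sd 0.15) of their class
composition, emulating family-level drift — held-out families are
genuinely unseen compositions, the "twilight zone" situation
leave-family-out is meant to probe.

Compositions are a device to make the classes learnable, not a claim
about biology, but they follow the known motif structure so that the
method's assumptions hold: dimer cores are Leu-dominated with the
Asn-at-`a` marker; trimer cores are beta-branched (Ile-heavy `a`,
Val-heavy `d`); `e`/`g` positions carry a charge signature shared by
both classes.  Within-class `a` vs `d` asymmetry matters: it is what
pins the register phase, since class-shared signals receive almost no
weight on the learned class discriminant.  An optional coupling plants
genuine distance-`k` correlations (a residue copies its in-coil
neighbour `k` back with the given probability), used to verify that the
correlation features respond; it is off by default.

What the generator does **not** emulate: heptad discontinuities (skips
and stutters), antiparallel orientation, tetramers and higher states,
realistic family phylogenies (sequences within a family are i.i.d.
given the family composition), shared homology between families, and
real negative sets (negatives are i.i.d. background draws with no
structure).  Passing the recovery experiment therefore demonstrates
that the estimator recovers planted structure under its own model
assumptions — it does not certify performance on real proteomes, where
the discriminating signal is weaker and annotation noise exists.

## Problem sizes

The shipped experiments are sized for a desk run: the recovery
experiment cross-validates 12 families (180 sequences, plus 150
negatives) in well under a minute per fold's work; the
oracle-equivalence suite checks 200 random sequence/model pairs at
length up to 12, where exhaustive path enumeration is still a few
hundred paths; tally-consistency checks draw about 50,000 coil residues
per class.  All randomness is seeded.

## Limitations

* Coils truncated by the sequence boundary are unrepresentable
  (initial/final state restriction), so edge posteriors are
  conservative.
* No skip/stutter handling: a real coil with a heptad discontinuity
  will be seen as two coils or partially missed.
* Dimer vs trimer only; tetramers and antiparallel topologies are out
  of scope.
* The detection operating point (cutoff, offset) is a convention, not a
  calibrated false-positive-rate guarantee; calibrating it requires a
  reference negative database.
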