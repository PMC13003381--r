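---
title: "Methods: constructive annotation of extended archaeal tetraether lipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructive annotation of extended archaeal tetraether lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extether)
library(dplyr)
```

## The problem

Archaeal membranes are built from ether lipids: diether archaeols (AR, one
glycerol, two C20 phytanyl chains) and membrane-spanning tetraethers (GDGTs:
two glycerols bridged by two C40 biphytanyl chains; GTGTs: the trialkyl
biosynthetic intermediate with one bridge and two pendant chains). A further
structural theme is *chain extension*: extra C5 isoprenoid units on one chain
only, long known in extended archaeols (C25 pendants) and recently also found
in tetraethers (C45/C50 bridges, C25 pendants on GTGTs). Extended tetraethers
are scarce, sit ~70 Da above abundant homologs, and are only identifiable
from exact mass, elution order and diagnostic MS² ions together. This package
implements that identification chain constructively, so that every reported
mass is derivable from a structural recipe.

## Formula and mass model

A descriptor holds the core type, chain carbon numbers, cyclopentane ring
count and hexose count. The neutral formula is assembled by condensation:
glycerols (1 for AR, 2 for tetraethers) plus pendant chains as saturated
alcohols CnH(2n+2)O and bridging chains as diols CnH(2n+2)O2, minus one H2O
per ether bond (2 / 4), minus H2 per ring, minus H2 for the GMGT carbon-carbon
bridge, plus C6H10O5 per hexose. Useful consequences that double as checks:

```{r}
f_gdgt <- build_formula(lipid_descriptor("GDGT", bridges = c(40, 40)))
f_gtgt <- build_formula(lipid_descriptor("GTGT", bridges = 40,
                                         pendants = c(20, 20)))
format_formula(formula_subtract(f_gtgt, f_gdgt))  # trialkyl offset: +H2
```

Each extension step adds exactly C5H10 within a series, and the GTGT-0 of a
series is H2 heavier than the matching GDGT-0 — which is why the first mass
increment of the observed ladder is ~72 Da (C5H12) and subsequent ones ~70 Da
(C5H10).

Atomic masses are pinned in source (C 12, H 1.00782503, N 14.00307401,
O 15.99491462, Na 22.98976928; electron 0.00054858). Adduct m/z uses
electron-corrected cation masses; without the electron correction the
protonated masses come out ~0.0005 Da high and stop matching printed
theoretical values at the third decimal. Reported m/z is rounded half-even to
3 decimals; all internal arithmetic is full double precision. Supported
adducts are the three abundant positive species +H, +NH4, +Na; only singly
charged ions are modelled. Published *observed* masses may still differ from
our theoretical values by up to a few mDa (instrument calibration); such
discrepancies are expected and are never absorbed by adjusting constants.

## Fragmentation model

Product ions follow the loss chemistry seen for these lipids in positive
mode: pendant chains leave as alkenes CnH2n, bridging chains as dienes
CnH(2n-2), glycerol as C3H8O3 (alone or combined with a chain loss), water
once or twice, and each hexose as C6H10O5. The complementary
glycerol-monoalkyl cations C(n+3)H(2n+8)O3 (m/z 373.368 for C20, 443.446 for
C25) are the most diagnostic ions: the di-extended GTGT shows the C25 ion but
*lacks* the C23H48O3 ion, which is what distinguishes two C25 pendants from
one. Ammoniated precursors are assumed to yield protonated product ions;
sodiated precursors are not fragmented (their chemistry differs and was not
needed). Intensities are not predicted — matching is mass-only — and every
emitted fragment carries its complementary loss formula so element
conservation can be asserted mechanically.

Spectrum matching assigns each theoretical fragment its nearest peak within
`max(10 ppm, 0.005 Da)` by default; the Da floor reflects the few-mDa scatter
of printed fragment masses. Ties resolve deterministically (lower-m/z peak;
output in fragment-table order). The match score is a weighted fraction of
matched fragments with the diagnostic chain ions (glycerol-monoalkyl and
chain losses) counted twice — a pragmatic operationalisation of "the
diagnostic pattern supports the structure", not a probability.

## Series detection

A homolog series is a maximal chain of features whose consecutive m/z
differences equal one repeat unit (C5H10 or C5H12, masses always derived from
the formula) within a tolerance, and whose retention times are strictly
monotone in the configured direction: extension homologs elute *later* in
reversed phase and *earlier* in normal phase (default: increasing). The
difference tolerance defaults to 15 ppm — deliberately looser than the 5 ppm
MS1 tolerance because two features' mass errors compound in a difference.
Chains are maximal (not extendable at either end); overlapping chains are all
reported rather than greedily pruned, favouring discovery recall; two members
suffice to report, three mark a series "strong". The detector is validated
against a brute-force subset-enumeration oracle on random tables.

The GTGT/GDGT hypothesis uses the H2 offset: a co-occurring feature 2.016 Da
below the series root (within the MS1 tolerance, the paper-level convention
for this offset being unstated) labels the root a GTGT series. We added the
symmetric case — a partner above the root labels it a GDGT series — since the
offset is directionless evidence; with no partner the call is "unknown".

## Semi-quantification

Amounts are computed relative to a co-injected standard:
`amount_i = (area_i / std_area) * std_amount / rf(class_i)` with a 2 ng
default standard amount, and relative abundances are percentages of ng
amounts (not of raw areas — areas are ionisation-biased, which is what the
response factor corrects). Response factors are through-origin least-squares
slopes of area vs amount, normalised by the injection standard's slope;
through-origin because zero analyte must give zero area and the ratio formula
presumes proportionality. Four class standards map to the four lipid classes
(2G-AR for glycosidic ARs, AR for core ARs, 1G-iGDGT-0 for glycosidic
tetraethers, the GTGT-C46 standard for core tetraethers). The package ships
rf = 1 defaults and expects a user calibration file for real work; all
outputs are semi-quantitative by construction.

## Synthetic data: what it does and does not emulate

The generator exists so every stage is testable without raw data. It
emulates: one feature per lipid per adduct with multiplicative Gaussian mass
error (default sigma = 1 ppm, matching sub-ppm instrument calibration); a
linear, monotone retention-time model (reversed phase anchored at
iGDGT-0 = 24.4 min, +1 min per extension, hexoses eluting earlier; normal
phase reversed) — annotation only consumes the *ordering*, so the linear form
is deliberate; areas proportional to amount x response factor x adduct yield
with small lognormal noise (CV 2%); MS² peaks at predicted fragment m/z with
a fixed per-kind intensity profile in which glycerol-monoalkyl ions dominate
and scale with chain length (so the C25 ion is the base peak of extended
lipids), plus optional labelled decoy peaks. One explicit seed drives all
draws.

It does **not** emulate isotope envelopes, chromatographic peak shapes,
co-elution interference, ion suppression, in-source fragmentation or ion
mobility. Passing round-trip tests therefore demonstrates the pipeline's
internal consistency — correct masses, tolerances, bookkeeping and
arithmetic — not robustness to real-matrix artefacts.

## Design choices where the design was open

* The di-extended GDGT is modelled as C40 + C50 bridges (one conserved
  biphytanyl chain), matching the structural trend of the di-extended GTGT;
  the mass-identical C45 + C45 isomer is representable and shown
  indistinguishable by mass in the tests.
* Rings are a total count attributed to bridging chains without positional
  detail; the default library excludes ring-bearing *extended* lipids (no
  observation supports them) though descriptors permit the combination.
* GMGT is carried as a mass-only variant (GDGT − H2); head groups are fixed
  to hexose, and phospho head groups, hydroxylation, unsaturation and
  alternative backbones (BDGT/PDGT) are out of scope.
* Relative abundances are computed on ng amounts rather than
  response-corrected areas; with a common injection standard the two differ
  only by the rf normalisation, and amounts are the quantity reported.
* The candidate ranking on annotation ties prefers fewer structural
  modifications (extensions + rings + hexoses) — parsimony as a tie-break,
  determinism guaranteed by a final name sort.
* No command-line wrapper is provided: the exported functions compose in a
  few lines of R, which is how this audience works.

## Problem sizes and numerical checks in the test suite

The default library is 48 lipids x 3 adducts (pairwise m/z separation
≥ 47 ppm, so 5 ppm annotation is unambiguous). Oracle equivalence for the
series detector runs 100 random tables of up to 30 features with planted
ladders; end-to-end recovery uses a 13-component mixture at 1 ppm mass noise
and asserts zero mis-identifications at 5 ppm and composition recovery
within 2 percentage points. Degenerate inputs are defined, not fatal: empty
spectra match nothing, empty feature tables yield empty series tables, and
empty libraries, non-positive standard areas and sub-2-point calibrations
are errors.

## Known limitations

Mass-identical structures (e.g. ring vs GMGT bridge, C40+C50 vs C45+C45) are
indistinguishable by MS1 alone; the package reports both candidates ranked,
and disambiguation needs MS² or chromatography. Negative-ion mode, multiply
charged species and isotope-pattern scoring are not implemented. Response
factors for the extended lipids are approximations by structural class —
true per-species factors would require standards that do not exist.
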