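---
title: "Discovering non-coenzyme thiamin targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering non-coenzyme thiamin targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiamintargets)
library(tibble)
```

## The problem this package addresses

Thiamin (vitamin B1) is best known through its coenzyme form, thiamin
diphosphate (ThDP). A recurring observation in neuropharmacology is that
high thiamin doses act on the brain without raising ThDP levels or
ThDP-dependent enzyme activities, implying protein targets beyond the
coenzyme role. Identifying such targets combines four kinds of evidence:

1. **Affinity proteomics.** Synaptosomal proteins retained on sorbents
   carrying thiamin or a thiazolium bait (DMHT,
   3-decyloxycarbonylmethyl-4-methyl-5-(2-hydroxyethyl) thiazolium) are
   eluted and identified; yields and the fraction of already-documented
   binders quantify the specificity of the pull-down.
2. **Binding-pattern construction.** Residues contacting thiamin or its
   thiazole ring in solved complexes (a thiamin diphosphokinase, the
   periplasmic thiamin-binding protein ThiB, the thiazole kinase ThiM)
   are generalized across homologs into PROSITE-dialect sequence
   patterns and scanned against candidate sequences.
3. **3D validation.** Sequence hits are mapped back onto structures and
   judged by backbone conformation (does the hit adopt the geometry of
   the source motif?) and proximity to functional sites.
4. **Inhibition kinetics.** For candidates (pyridoxal kinase here),
   initial-rate inhibition data discriminate competitive,
   non-competitive, uncompetitive and mixed mechanisms and yield Ki.

The package implements each stage as composable, data-frame-first
functions, and pairs every stage with a seeded synthetic-data generator
so the full pipeline is testable with no downloads and known ground
truth.

## Pattern engine

The dialect covers what the four shipped patterns use: exact residues,
classes `[ST]`, the wildcard `x`, and repeats `(n)` / `(n,m)`;
PROSITE's `{..}` exclusions, `<`, `>` and `-` separators are accepted
and normalized away. Parsing canonicalizes class residues
alphabetically, so `parse -> serialize -> parse` is the identity on
canonical forms.

Scan semantics were genuinely open (web scanners do not document their
greediness for `x(n,m)`), and we chose **completeness**: every distinct
`(start, end)` window admitting a valid element assignment is reported,
including overlaps and nested windows. Hits are sparse enough in
practice that the policy rarely matters, and a complete scanner can be
checked exactly against a brute-force enumeration oracle (the suite does
this on 1,000 random pattern/sequence pairs). Where one window admits
several element tilings, the reported per-element spans take the
leftmost-shortest assignment, a deterministic convention. An `X` in a
scanned sequence (unknown residue) matches wildcards only — never a
class or exact element — so unknown positions cannot fabricate hits.
Positions are 1-based inclusive throughout.

```{r}
thiamin_patterns("tpk_thib")
scan_sequence(thiamin_patterns("tpk_thib"), "AISSTNA", "demo")
```

## Structure module

`read_structure()` (a thin normalization over `bio3d::read.pdb()`)
keeps the first model, drops waters, and resolves alternate locations to
the highest-occupancy copy (ties to the alphabetically first altloc).

**Contacts.** A binding motif starts from the residues near the ligand:
every protein residue with a heavy atom within a cutoff of any ligand
heavy atom. The default cutoff is **4.0 Å**, a conventional threshold
spanning hydrogen bonds and van der Waals contacts; no criterion is
canonical, so the value is an exposed argument rather than a constant.
Hydrogens are always ignored.

**Pattern derivation.** Consecutive contact residues become pattern
positions; a sequence gap of length *g* becomes `x(g)`. Supplying a
multiple sequence alignment of homologs widens each position to the
residue set observed in its column and the wildcards to the min/max gap
across rows — this is how motif variability across organisms enters the
pattern. Contacts drawn from several chains (trimeric interface sites)
yield one pattern per chain plus a note, since a linear pattern cannot
span chains. A derived pattern always re-matches its source sequence at
the source location (a tested round-trip invariant).

**Conformation.** Classification uses phi/psi boxes only (helix
phi ∈ [−100°, −30°], psi ∈ [−80°, −5°]; strand phi ∈ [−170°, −70°],
psi ∈ [90°, 180°] ∪ [−180°, −170°]; otherwise loop), deliberately
avoiding a DSSP dependency: box classification is self-contained,
configurable, and exactly testable against generated geometry. Residues
lacking a neighbour for a dihedral are `undefined` and excluded from the
fractions; majority ties resolve to `loop` (the non-committal class).

**Numbering.** Sequence-to-structure numbering is supplied explicitly
(an offset or a mapping table); the pipeline never guesses database
numbering conventions. Site proximity is quantified as the minimum
heavy-atom pairwise distance between two selections
(`min_site_distance()`), the measure we also use when relating derived
patterns to coenzyme/substrate sites.

## Kinetics

All four single-substrate reversible-inhibition laws reduce to
Michaelis–Menten at `I = 0`:

* competitive: `v = Vmax S / (Km (1 + I/Ki) + S)`
* uncompetitive: `v = Vmax S / (Km + S (1 + I/Ki))`
* non-competitive: `v = Vmax S / ((1 + I/Ki) (Km + S))`
* mixed: `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/Ki'))`

**Fractional-activity titrations.** At quasi-saturating substrates the
activity ratio is fitted to the one-parameter hyperbola
`Y = Ki_app / (Ki_app + I)`, which is anchored at `Y(0) = 1` and
`Y(Ki_app) = 1/2`. A partial-inhibition variant
`Y = (1 − f) Ki/(Ki + I) + f` is available behind a flag (default
`f = 0`): full inhibition is the parsimonious default and the
one-parameter form is identifiable from a six-point titration, while the
floor needs data at much higher saturation.

**Mechanism classification.** Lineweaver–Burk analysis (per-level OLS on
1/v vs 1/S plus secondary replots of slopes and intercepts against I) is
computed and reported for fidelity to how such data are conventionally
summarized — the replot x-intercepts sit at −Ki and −Ki′ — but the
headline estimates come from a **global nonlinear least-squares fit** of
each rate law to all points, seeded by the LB estimates. The
double-reciprocal transform distorts the error structure; the global fit
does not. On noise-free data the two estimators agree to 1e−6 relative
(a tested contract), which is what justifies reporting both.

Model choice is by corrected AIC (computed from the residual sum of
squares; the RSS is floored at a scale-relative epsilon, `n·(1e−7·max v)²`,
so that exact fits from nested models compare by parameter count rather
than by rounding noise). Among models within 2 AICc of the best, the one
with the fewest parameters wins and the result is flagged `ambiguous`.
The parsimony window matters: a strict argmin lets the 4-parameter mixed
law absorb roughly 15% of noisy one-Ki datasets (the chi-square(1)
exceedance of a ~2-point penalty), whereas the window keeps
classification accuracy at or above 95% under the assay design at 2%
noise — the property the test suite enforces with 200 seeded replicates
per mechanism.

Concentrations are mM throughout; rates are treated as relative
(unit-free) for fitting.

```{r}
sim <- gen_kinetics("competitive", Km = 0.1, Vmax = 1, Ki = 2.2,
                    noise_cv = 0.02, seed = 7)
glance(classify_mechanism(sim$data))
```

## Proteome accounting and enrichment

`purification_summary()` reproduces step-wise elution accounting:
combined yield is the sum of the per-step percent column, with an
independent mg-based cross-check. In the packaged table, one step's
printed percent and mg disagree beyond rounding (1.1 mg of 110 mg is
1.0%, printed 1.3%) — an internal inconsistency of the source table —
so the mismatch is a warning by default (`strict = TRUE` upgrades it to
an error) and the percent column, from which the published combined
yields derive, is authoritative. Because the load fraction's specific
activity is not recorded, a fold-purification is deliberately not
computed.

`known_binder_fraction()` is plain counting:
100 × (documented binders flagged `+` for a proteome) / proteome size.
With the packaged 16-row binder table this gives 10.0% of the 150
thiazolium-eluted proteins and 12.3% of the 57 thiamin-eluted ones.

`term_enrichment()` is a transparent local statistic: a one-sided
(greater) Fisher exact test per annotation term against a user-supplied
background, with Benjamini–Hochberg adjustment across terms. It is
**not** a replica of web annotation servers (whose modified scores and
backgrounds are database-version dependent, so their printed p-values
are not reproduction targets); BH is added because a reusable tool
should control FDR, and raw p-values are reported alongside.
Percentages are displayed rounded to one decimal; tests compare
unrounded values.

## Synthetic-data generators

Each generator is deterministic under a single integer seed (the
caller's RNG state is saved and restored) and records its ground truth:

* `gen_sequences()`: i.i.d. background residues (uniform by default,
  which keeps false-positive expectations closed-form; a custom
  frequency table is accepted) with uniformly sampled pattern
  realizations planted at recorded positions. Scanner recall of planted
  instances is 100% by construction and tested.
* `gen_backbone()`: N/CA/C/O placed by sequential internal-coordinate
  construction (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ω = 180°,
  standard angles — conventional constants, exposed as configuration)
  with per-class dihedrals: helix −57°/−47°, strand −120°/+120°, loops
  drawn from a configurable left-handed-region range ([45°, 90°] ×
  [−30°, 60°]) that can never classify as helix or strand. An optional
  single-atom ligand is placed along the clearest outward ray so its
  minimum distance to a chosen residue equals the requested value to
  within 1e−3 Å; any placement bringing two atoms closer than 1.5 Å is
  an error.
* `gen_kinetics()`: the chosen rate law over a substrate × inhibitor
  grid with multiplicative Gaussian noise of given CV, redrawn per point
  while non-positive. Defaults follow the assay design: inhibitor levels
  0–15 mM (six levels), six substrate levels, three replicates.
* `gen_proteomes()`: two proteomes (defaults 150 and 57, the eluate
  sizes) drawn from a background universe with a controlled overlap,
  exactly-planted known-binder flags, and per-term annotations whose
  frequency in proteome A is a chosen multiple of the background
  frequency.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: sequences have no homology or compositional
bias, so real-database hit rates (which depend on protein families and
database release) are out of reach; backbones have no side chains,
packing or experimental coordinate error, so classification accuracy on
generated geometry is an upper bound; kinetic noise is purely
multiplicative with no systematic (pipetting, drift) component; and
annotation draws are independent across terms, unlike correlated real
ontologies.

## Numerical choices and degenerate inputs

* PDB text stores coordinates to 0.001 Å, so dihedrals survive a
  write/read round-trip only to about 0.1°; the torsion routine itself
  agrees with an independent implementation to 1e−6° on exact
  coordinates. Classification is unaffected (box margins are degrees).
* Nonlinear fits use the Levenberg–Marquardt implementation in
  `minpack.lm` with positivity bounds and tight tolerances
  (`ftol = ptol = 1e−14`); a non-converging model receives infinite
  AICc rather than aborting the comparison, and classification errors
  only if no law converges.
* Flat titrations (activity ≈ 1 everywhere, or a fitted `Ki_app` more
  than 1e4 times the largest tested concentration) raise a
  no-inhibition condition instead of returning an unbounded constant.
* Zero-length matches of all-optional patterns are dropped; empty
  contact sets are a valid result of a contact search but an error when
  a pattern is to be derived from them; overlapping selections in a
  site-distance query error under `strict` (or return 0 when
  explicitly allowed).
* Problem sizes in the test suite were chosen to keep the full suite
  around a minute while leaving Monte-Carlo margins wide: 200 seeded
  replicates per mechanism-recovery study (the recovery criterion is a
  median over replicates), 1,000 random cases for the scanner oracle,
  300 random plus exhaustive small-margin tables for the Fisher oracle.

## Interface design

The package is tidyverse-shaped: tabular arguments come first, results
are tibbles (or small S3 objects with `tidy()`/`glance()`/`autoplot()`
methods), and stages compose with the pipe. The orchestration layer of
the pipeline is therefore the functions themselves together with the
schema-checked TSV readers/writers (`read_table_checked()`,
`write_table()`) and the packaged fixtures; no shell entry point is
shipped, as every operation is a single function call away in a script.

## Known limitations

* The scanner is a pattern matcher, not a profile/PSSM scorer; borderline
  motif variants scored by position-specific methods are out of scope.
* Only PDB-format input is parsed (no mmCIF), first model only, and
  symmetry mates are not generated, so contacts across crystallographic
  interfaces are invisible unless the file already contains them.
* The kinetics module covers single-substrate laws; two-substrate
  (bi-bi) global mechanisms and progress curves are out of scope, as is
  any multi-site nucleotide model for glutamate dehydrogenase (no data
  to constrain one).
* Enrichment assumes the user supplies a sensible background; with a
  biased background the Fisher test inherits the bias.
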