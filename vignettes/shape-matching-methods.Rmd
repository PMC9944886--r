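---
title: "Gaussian shape matching and affinity curation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian shape matching and affinity curation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligshape)
```

ligshape implements two related toolsets for protein--ligand complex
collections: a 3D ligand shape-matching engine for polypharmacology
exploration (which ligands could occupy the same space, regardless of 2D
similarity), and the curation rules that such databases apply before any
matching happens — structure-quality filters, ligand validity classes,
binding-affinity normalisation, and sequence families. This vignette is the
package's own account of the models, the tunable parameters, and the design
choices that were genuinely open.

## The Gaussian shape model

A molecule's volume is modelled as a sum of atom-centred isotropic
Gaussians,

$$ f(\mathbf{r}) = \sum_i p\, e^{-\alpha_i \lVert \mathbf{r} - \mathbf{c}_i \rVert^2}, $$

over its heavy atoms. The shape of two molecules is compared through three
integrals: the self-overlaps $I_f = \int f^2\,dV$ and $I_g = \int g^2\,dV$,
and the cross term $O_{f,g} = \int f g\,dV$. The shape Tanimoto is the
volumetric intersection-over-union

$$ T_{f,g} = \frac{O_{f,g}}{I_f + I_g - O_{f,g}} \in (0, 1], $$

equal to 1 exactly when the densities coincide. The companion mismatch
volume is $S_1 = I_f + I_g - 2\,O_{f,g}$, the closed form of
$\int (f-g)^2 dV$; for hard (0/1) characteristic functions this equals the
integrated absolute mismatch $\int |f-g|\,dV$, and it relates to the
Tanimoto by $S_1 = (I_f + I_g)(1-T)/(1+T)$ — an identity the test suite
checks numerically on random shape pairs.

The sum-of-Gaussians density was chosen over a hard-sphere or
inclusion–exclusion model because every integral above then has an exact
closed form (a double sum of pairwise Gaussian product integrals), so the
implementation can be validated against an independent brute-force grid
integration rather than against itself. `grid_overlap_oracle()` is that
oracle: a Riemann sum on a box padded by at least $4\sigma$ of the widest
Gaussian. At 0.1 Å spacing it agrees with the analytic overlap to well
within 0.5% on small shapes, and the discretisation error shrinks
monotonically with the spacing.

### Parameters

* **Prefactor** `p = 2 * sqrt(2)` (dimensionless). The conventional
  amplitude for hard-sphere-calibrated Gaussian atoms; shared by all atoms.
* **Radii** (Å): C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, halogens at
  standard van der Waals values (`default_radius_table()`, overridable via
  a two-column text file). Each exponent is calibrated so the isolated atom
  integrates to its hard-sphere volume:
  $\alpha = \pi\,(3p / (4\pi r^3))^{2/3}$.
* **Hydrogens** are excluded by default (`include_hydrogens = FALSE`).
  Heavy-atom comparison is the common convention in shape screening;
  including hydrogens mostly rescales both self- and cross-terms.
* An element missing from the radius table is a **hard error**, never a
  silent carbon default: the Tanimoto depends directly on the radius, and a
  silent fallback would corrupt results invisibly.

## Superposition

Shape similarity is only meaningful at the optimal relative pose, so each
pair is superimposed by maximising $O_{f,g}$ over the six rigid-body
degrees of freedom (conformers stay internally rigid throughout). The
local optimiser is a deterministic derivative-free Nelder--Mead ascent over
(rotation vector, translation), with the rotation applied about the query's
current centre of mass so the two blocks of coordinates stay decoupled.
Defaults: relative tolerance `1e-6`, iteration cap 200. The returned
overlap is never below the starting overlap.

Local ascent needs good starts. Three families are used per pair:

1. **COM**: identity rotation, query centre of mass moved onto the
   reference's (1 start).
2. **Random placement** (8 starts, seeded): query COM placed on a uniformly
   chosen reference *atom centre* with a uniformly random rotation
   (Shoemake quaternion). Placement over atom centres rather than a
   bounding box concentrates starts where overlap is attainable and copes
   with very different ligand sizes.
3. **Principal axes** (4 starts): rotations aligning the two shapes'
   second-moment eigenframes, one per right-handed sign-flip combination,
   COMs superimposed. This deterministic family usually contains the
   global basin — for a rigid copy of a generic shape one of the four is
   the exact superposition — and serves as a reproducible stand-in for a
   third, independently-implemented search route.

The final Tanimoto for a pair is the maximum over all 13 starts, labelled
by the winning family. All randomness flows from a single integer seed in
`shape_settings()`, so full runs are bit-reproducible.

## Ensembles and database matching

A ligand may match another ligand's binding-site pose only in a
conformation it does not itself adopt in any crystal structure. Matching is
therefore asymmetric at the conformer level: a fixed query *pose* is
compared against a database ligand's conformer *ensemble* (up to 64
conformers; longer ensembles are truncated in input order), taking the
maximum and recording the winning conformer index. The package reports one
symmetric number per unordered ligand pair: the better of (pose of A vs
ensemble of B) and (pose of B vs ensemble of A). `all_vs_all_match()`
evaluates every unordered pair once and retains pairs with Tanimoto
**strictly greater** than the reporting threshold (default 0.85); rows are
sorted descending, ties broken lexicographically, so repeated runs are
byte-identical. Conformer generation itself is out of scope — ensembles
are accepted as input, and the fixture generators produce toy ensembles.

## Affinity curation

Raw affinity fields (`"0.003 uM"`) are normalised to molar values with
fixed unit factors (fM $10^{-15}$ … M $1$). Association constants (Ka,
inverse molar) are stored as their reciprocal — the equivalent dissociation
constant — so they compete directly with Kd records. When several
measurements exist for a complex the preference is **Kd (incl. converted
Ka) > Ki > IC50**; within a type, exact `=` relations beat qualified ones,
then the tightest value wins.

Distributions are summarised in four bins: sub-nanomolar, nanomolar to
micromolar, micromolar to millimolar, weaker than millimolar. The
published bin headers do not state boundary membership, so the package
fixes a convention and documents it: left-closed at 1 nM and 1 µM, and
exactly 1 mM in the third bin. The synthetic generator draws values
strictly inside bins so this convention cannot move planted counts.

Cross-database comparison classifies each record pair into exactly one of
five categories, with precedence type > relation > pair > value:

1. *unit-equivalent agreement* — same type, relation and ligand, molar
   values within 0.5% (absorbs pure unit rewriting such as 0.003 µM vs
   3.0 nM while separating real value errors);
2. *measurement-type error* (Kd vs Ki etc.);
3. *inequality error* (`=` vs `~`/`<`);
4. *wrong-pair error* (different ligand);
5. *value error* (everything matches except the number).

A note on rule 1: agreement requires the relation and ligand to match as
well as the values. A value-only reading of "agreement" would silently
absorb inequality and wrong-pair discrepancies whose values happen to
coincide, which is precisely what the taxonomy is meant to separate.

## Structure curation and families

The standard inclusion rules keep complexes with resolution at least
2.5 Å, at least one protein chain, and at least one valid, non-covalent
ligand. The high-quality mode adds $R_{free} - R_{work} \le 0.05$,
real-space R $\le 0.2$, RSCC $\ge 0.9$. All boundaries are inclusive; the
comparisons carry a $10^{-9}$ epsilon so binary floating-point
representation (0.23 − 0.18) cannot flip a boundary case. Each discarded
complex reports the *first* failing rule, in the order the rules are
listed. Ligand validity is list-driven (additives/salts/buffers/metals/
solvents invalid; heme and modified residues part of the protein;
everything else valid), with covalency — any ligand heavy atom within the
covalent-radius sum plus 0.4 Å of a protein heavy atom — forcing
exclusion. The shipped lists are a best-effort stand-in for unpublished
curation lists and are user-editable.

Sequence families use an in-package end-gap-free global aligner (match +1,
mismatch 0, gap open −5, extension −1; identity = identical columns /
aligned-region length; `X` never matches). Two choices deserve note:

* **Single linkage.** "Sequences ≥ 90% identical to each other" could be
  read as cliques; the package follows common sequence-clustering practice
  and uses connected components, which also guarantees that lowering the
  threshold (90 → 70 → 50%) only merges families, never splits them.
* **Symmetry under ties.** With a zero mismatch score, distinct optimal
  alignments tie frequently, and a fixed traceback preference (diagonal,
  then up) would let identity(a, b) differ from identity(b, a). Arguments
  are therefore ordered canonically before aligning. Multi-chain complexes
  are compared via their longest chain.

Family leaders (assigned at 90% only) are the member with the tightest
preferred affinity; members without affinity rank after all that have one;
ties fall back to best resolution, then lexicographic id. "Most biological
relevance" as a final fallback is not operationalizable from the data this
package consumes, so the deterministic resolution/id rule substitutes.

## Synthetic data: what it does and does not show

The generators in `make_toy_ligand()`, `perturb_ligand()`,
`make_synthetic_affinity_set()` and `make_toy_complex()` are first-class,
tested code. They emulate the *contractual* features the algorithms depend
on — rigid geometries with known optimal superpositions, affinity pairs
realising exact per-category counts, PDB files with planted covalent
contacts and filter failures — and they are pure functions of their
arguments and a seed. They do not emulate real chemistry: no valence,
torsional strain, or realistic conformer distributions. Passing tests
therefore demonstrate correctness of the algebra, the search protocol and
the bookkeeping, not virtual-screening performance on real libraries.

The worked-example fixtures under `inst/extdata/` (an aminoindan MAO
inhibitor vs tranylcypromine; a phenyl-triazole-diamine kinase binder vs
gabapentin) are model-built ETKDG/MMFF geometries — labelled
`synthetic_model` — standing in for crystallographic poses. The first pair
reproduces the published similarity within its band (0.897 here); the
second plateaus at 0.814 against a reported 0.90, a gap attributable to
the model-built inputs and to Gaussian parameters the commercial reference
implementation does not publish. The corresponding check is kept at the
published band and allowed to fail rather than widened.

## Numerical choices and problem sizes

* Degenerate inputs (no heavy atoms, empty ensembles, empty sequences) are
  errors, not silent empties; unknown elements and units are errors naming
  the offender.
* Quaternions are renormalised on construction; rotations are verified
  proper (det +1) in tests.
* Test and acceptance runs use deliberately small problem sizes chosen for
  tight oracles rather than realism: shapes of 3–20 atoms (where the
  0.1 Å grid oracle is exact to ~0.5%), ensembles of ≤ 33 conformers,
  sequence sets of ≤ 6 chains with ≤ 30 residues, and affinity tables up
  to the published scale of a few thousand rows (pure arithmetic). The
  full suite runs in a few minutes on one CPU.

## Known limitations

No chemical-feature ("color") term — matching is shape-only, so polar
complementarity is invisible. No flexible alignment: torsions never move
during superposition, by design. Validity classification is list-driven,
not chemistry-driven. The local optimiser carries no global-optimality
guarantee; the three start families are a heuristic that is exact for
rigid copies and well-behaved on the sizes above, but large, highly
symmetric shapes can in principle defeat it.
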