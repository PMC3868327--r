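---
title: "Mapping post-translational modifications onto protein surfaces: methods and design"
author: "ptmsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping post-translational modifications onto protein surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmsurf)
```

## The problem

Closely related protein paralogs — the motivating case is the vertebrate
translation elongation factor pair eEF1A1/eEF1A2, 92% identical with
mutually exclusive tissue expression — can differ sharply in how they are
post-translationally modified. Two mechanisms produce such differences: a
sequence variant can remove or create the modifiable side chain itself
(isoform-altered modifiability), and variants clustered on one surface of
the folded protein can change the local landscape that modifying enzymes
recognise, so that modification sites concentrate near the variant
clusters. `ptmsurf` operationalises both questions for any protein with a
3-D model, a curated modification table, and a list of paralog sequence
differences:

1. map curated PTM positions onto the model and split off the unmodelled
   C-terminal tail;
2. classify every residue as buried or exposed from solvent accessibility;
3. partition the surface into a *variable face* (the hemisphere carrying
   the surface variant clusters) and a *conserved face*;
4. count modified residues and modifications per face, measure which sites
   lie within a cutoff radius of a variant, and
5. test the apparent concentration of sites near variants against a
   permutation null.

## Solvent accessibility

Exposure is computed with the Shrake–Rupley method. For every heavy atom,
`n_points` test points are placed on the sphere of radius
$r_\mathrm{vdW} + r_\mathrm{probe}$; a point survives if it lies outside
the expanded sphere of every neighbouring atom, and the atom's SASA is the
surviving fraction times the sphere area. Residue SASA is the exact sum
over its atoms. Design choices:

* **vdW radii** C 1.70, N 1.55, O 1.52, S 1.80 Å (Bondi-style), probe
  1.4 Å (water). Only heavy atoms are modelled; hydrogens are skipped at
  load.
* **Deterministic point set.** Points come from a golden-section spiral,
  not random sampling, so SASA is bit-reproducible and no RNG state enters
  the geometry module. At the default `n_points = 960` the two-sphere
  benchmark against the analytic spherical-cap formula is accurate to a
  fraction of a percent of the sphere area, and accuracy improves
  monotonically with more points (92 → 960 → 4000).
* **Relative accessibility** divides by the Gly-X-Gly theoretical maxima
  (Tien et al. 2013 values, `max_asa_reference()`). A residue is *buried*
  below 5% relative SASA — the common "completely buried" convention; the
  threshold is a configuration knob (`buried_below`), since the literature
  offers no single value. Between 5% and 25% a residue is reported
  `partly_exposed`; analyses that need a binary call treat everything
  non-buried as exposed ("largely or partly exposed").

## Proximity and faces

All distances are minimum heavy-atom-to-heavy-atom distances — no
centroids and no C$\beta$ shortcuts — because a "sphere-radius probe"
around a residue in a molecular viewer measures atoms. The default radius
is 5 Å, the conventional contact-shell cutoff for calling a site
structurally proximal to a variant. The neighbour search is exactly
equivalent to the brute-force all-pairs scan (this equivalence is asserted
against an independent double-loop oracle in the test suite).

The face partition replaces a by-eye split of two structure views with a
reproducible construction: the axis runs from the all-atom centroid of the
model to the centroid of the side-chain atoms of the surface-exposed
variants; residues whose side-chain centroid points along the axis
(positive dot product) form the variable face, everything else — including
exact ties, which occur with measure zero — the conserved face. Glycine
falls back to C$\alpha$ for its side-chain centroid. The partition is
invariant under rigid-body motion of the model because the axis co-rotates.

The charge-environment annotation is deliberately simple: it lists D/E
(negative) and K/R (positive) residues within the radius of a site and
flags those whose two paralog alleles differ in formal charge sign.
Continuum electrostatics is out of scope.

## Modification chemistry and evidence

Nine side-chain chemistries are encoded (`ptm_rules()`): phosphorylation
S/T/Y; acetylation K; methylation K/R; ubiquitination K; S-nitrosylation
and S-glutathionylation C; O-glucosylation S; ethanolamination E;
carbonylation K/R/P/T (the standard metal-catalysed-oxidation targets —
kept configurable because residue-level evidence for carbonylation is
typically peptide-resolved only). N-terminal acetylation is deliberately
excluded: the package models side-chain events. Records violating these
rules are flagged at load and reported, never silently dropped, and every
filter preserves `pass + fail = total` per modification type.

Isoform-altered modifiability at a variant `X{pos}Y` splits the observed
modification types at `pos` into those compatible only with the first
isoform's residue and only with the second's; a type compatible with both
(methylation across a K→R change) appears in neither set. Positions are
expressed in a single canonical numbering (the first isoform's), which is
well defined when the two paralogs align without internal gaps.

The reliability filter implements the evidence-tier convention of curated
PTM databases: a record passes if a targeted site-specific experiment
confirmed it or if it carries at least `min_citations = 5`
mass-spectrometry citations.

## The permutation test

The statistic is $T$, the number of observed modified residues satisfying
a hit predicate (variant-proximal within the radius, or variable-face).
The null keeps the number of modified residues fixed and redraws their
positions uniformly without replacement from the candidate pool. The pool
defaults to the surface-exposed residues — modifying enzymes reach only
the surface, so permuting over buried positions would overstate
enrichment; a flag widens the pool to all residues. When
$\binom{|pool|}{|sites|} \le 10^5$ the null is enumerated exactly;
otherwise `n_perm = 10000` Monte-Carlo draws are used with the add-one
correction $p = (1 + \#\{T^* \ge T\})/(n_\mathrm{perm} + 1)$, which avoids
zero p-values at the cost of slight conservatism. A seed is mandatory —
there is no wall-clock fallback — so identical inputs reproduce identical
results bit for bit. Fold enrichment is reported as the observed hit
fraction over the pool hit fraction; note this is a residue-count ratio,
not a face-area-normalised density.

## What the synthetic generators emulate

Because headline analyses of real proteins depend on externally built
homology models and database exports, every stage is validated on
synthetic data with known ground truth:

* `generate_globule()` builds a compact self-avoiding chain on a jittered
  cubic lattice (3.8 Å C$\alpha$ spacing) with one side-chain pseudo-atom
  per residue, 1.5 Å along the outward normal, its element (and hence vdW
  radius) set by residue class. Residues whose 26 lattice neighbours are
  all occupied form a designated interior that the accessibility engine
  must recover as buried; interior residues draw from a hydrophobic
  alphabet, as in real cores. The chain must be long enough for the
  lattice block to enclose at least one cell (48 residues always suffices;
  a full 27-cube also works).
* `plant_variants()` grows one or two spatially contiguous clusters of
  exposed variants on a single hemisphere, with substitution pairs that
  include capability-change (S→A, C→T, K→R) and charge-change (D→A, Q→E)
  cases.
* `sample_ptms()` turns each chemically modifiable shell residue into a
  site with probability `p_near` within 5 Å of a variant and `p_far`
  elsewhere (defaults 0.7/0.35, a planted two-fold rate ratio), draws the
  modification uniformly among the residue's compatible types, and samples
  citation counts from a two-component geometric mixture (means 12 and
  1.5, equal weights) with a 10% targeted-confirmation rate, so the
  reliability filter has realistic work to do.
* `generate_alignment()` mutates orthologs at a chosen rate while holding
  planted site positions fixed everywhere except a designated distant row
  — the pattern of sites conserved among close orthologs but altered in a
  distant homolog.

These fixtures are deliberately idealised: pseudo-atom side chains, no
loops or secondary structure, i.i.d. substitutions, no correlated
mass-spectrometry sampling biases. Passing tests therefore demonstrate
algorithmic correctness — geometry, accounting, calibration — not that any
particular biological dataset will show enrichment.

## Statistical validation at fixed experiment sizes

The test suite and the acceptance script run three designed experiments,
sized to finish in minutes on one CPU:

* **Exactness.** Wherever exhaustive enumeration applies, the permutation
  p equals the hypergeometric tail computed independently via `phyper()`
  (machine precision).
* **Type-I calibration.** 1000 uniform-null datasets drawn from a pool of
  200 positions with 80 hits and 60 sites each, tested at `n_perm = 1999`:
  the rejection rate at $\alpha = 0.05$ must lie in $0.05 \pm 0.02$. The
  expected rate of the add-one-corrected test in this design is 0.041 —
  slightly conservative by construction, as is standard for permutation
  p-values; enlarging the design does not move it materially.
* **Power and recovery.** 200 replicates of a 512-residue globule with two
  six-variant clusters and `p_near/p_far = 0.9/0.45` (ratio 2, about 70
  sites each): the test must reject at $\alpha = 0.05$ in at least 80% of
  replicates (measured: ~0.96) and the mean fold estimate must land within
  15% of 2. The fold statistic is attenuated below the generative rate
  ratio whenever the proximal pool fraction is not small — with hit
  fraction $q = K/N$ and rate ratio $\rho$, the expected fold is
  $\rho / (1 + q(\rho - 1))$, about 1.8 here — so the recovery criterion
  is evaluated against that expectation, not naively against $\rho$.

## Degenerate inputs and numerical corners

* Reading resolves alternate locations to the first conformer, skips
  hydrogens, solvent and HETATM records, warns and records non-standard
  residues, and refuses insertion codes (model coordinates never carry
  them).
* An isolated residue can exceed 100% relative SASA against the Gly-X-Gly
  maxima; the value is reported as observed.
* Faces are undefined without at least one exposed variant (hard error,
  not a silent all-conserved partition). Dot-product ties go to the
  conserved face.
* The enrichment test refuses an observed set larger than its pool and a
  Monte-Carlo run without a seed; `min_citations < 0`, `radius <= 0` and
  probabilities outside $[0,1]$ are rejected at the configuration layer
  with the parameter named.
* Pipeline stages fail with a stage-named error and partial outputs are
  removed, so an output directory is either complete or absent.

## Known limitations

* The face construction assumes variants cluster on one hemisphere; for
  variants spread uniformly the axis direction is unstable (and the
  biological question ill-posed).
* Canonical single-numbering breaks down for paralog pairs with internal
  indels; mapping through an explicit pairwise alignment would be needed.
* SASA is computed on a static model; conformational burial/exposure
  (discussed qualitatively for buried modified residues) is outside the
  geometry engine's scope.
* The permutation null treats sites as exchangeable across the pool; it
  conditions on the number of sites but not on, e.g., residue-type
  composition. A residue-type-stratified null would be a natural
  extension.
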