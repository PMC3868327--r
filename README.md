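# ptmsurf

Structure-based mapping and enrichment analysis of protein
post-translational modification (PTM) sites.

## What it is for

Closely related paralogs — the motivating case is the vertebrate
translation elongation factor pair **eEF1A1/eEF1A2**, 92% identical
proteins with mutually exclusive tissue expression — can be regulated very
differently even where their sequences agree. `ptmsurf` is for structural
bioinformaticians who have (i) a 3-D model of a protein in PDB format,
(ii) a curated table of experimentally observed modifications
(PhosphoSitePlus-style: position, residue, modification type, citation
count, targeted-experiment flag), and (iii) the sequence differences
between two paralogs in `X123Y` notation, and who want quantitative,
reproducible answers to:

* Which modified positions fall on the modelled structure, and which in
  the disordered C-terminal tail?
* Which sites are buried and which surface-exposed?
* Do modified residues concentrate on the *variable face* — the hemisphere
  carrying the surface clusters of inter-paralog variation — relative to
  the *conserved face*?
* Which sites lie within 5 Å of a variant residue, and is that proximity
  more than chance?
* Which modifications are chemically possible in only one paralog
  (e.g. a T→A change abolishing a phosphosite)?

## The statistics at its core

**Solvent accessibility** is Shrake–Rupley: for each heavy atom, test
points on the sphere of radius r_vdW + 1.4 Å are checked against all
neighbouring expanded spheres; atom SASA is the accessible fraction times
the sphere area. Points come from a deterministic golden-section spiral,
so results are bit-reproducible. Relative accessibility
RSA = SASA / maxASA(residue type) is classified buried below 5%.

**Proximity** is the minimum heavy-atom distance between residues with a
5 Å cutoff, exactly equivalent to a brute-force all-pairs scan.

**Enrichment** of modified residues for a structural property (variant
proximity, variable-face membership) is tested by permutation: with
T = #(observed sites that are hits), the null redraws the same number of
sites uniformly without replacement from the surface-exposed pool;

    p = (1 + #{T* >= T}) / (n_perm + 1),   fold = (T/k) / (K/N)

with exact enumeration replacing sampling whenever C(N, k) <= 1e5. See
`vignette("ptm-surface-mapping")` for derivations, parameter defaults, and
the validation experiments.

## Worked example

Every stage runs on synthetic data with known ground truth — a compact
462-residue lattice globule with two planted surface clusters of variants
and modification sites sampled at a two-fold higher rate within 5 Å of a
variant:

```r
library(ptmsurf)

g  <- generate_globule(462, seed = 4)
v  <- plant_variants(g$model, n_clusters = 2, cluster_size = 6, seed = 5)
sp <- sample_ptms(g$model, v, seed = 6)
head(v, 3)
#>   position aa_A1 aa_A2 label cluster exposed
#> 1      450     P     A P450A       1    TRUE
#> 2      449     Q     E Q449E       1    TRUE
#> 3      451     T     A T451A       1    TRUE

cfg <- pipeline_config(structure = g$model, ptm_table = sp$table,
                       variants = v, seed = 7, out_dir = tempfile())
led <- run_pipeline(cfg, verbose = FALSE)
print(led)
#> PTM surface-mapping ledger
#>   positions: 59 total = 59 mapped + 0 C-terminal tail
#>   exposure:  59 exposed / 0 buried of 59 mapped
#>   faces:     41 residues / 41 modifications variable, 18 / 18 conserved
#>   reliable faces: 17 variable / 9 conserved residues
#>   multi-modified positions: 0
#>   reliable records: 26 of 59
#>   variant-proximal: 12 of 59 sites (20.3%)
#>   enrichment: fold 1.75, p = 0.0187 (monte-carlo)
```

Reading the ledger: all 59 sampled sites fall on the modelled chain and
none is buried (sites were planted on the shell); 41 modified residues sit
on the variable face against 18 on the conserved face; 12 of 59 sites lie
within 5 Å of a planted variant, a 1.75-fold enrichment over the
surface-pool expectation that the permutation test calls significant
(p ≈ 0.019) — the planted signal, recovered. The run also writes
`ledger.json`, an annotated site table (`sites.tsv`), per-residue metrics
(`residues.tsv`), and an annotated PDB with a PyMOL colouring script.

Isoform-specific modifiability comes from the same objects:

```r
head(detect_altered_capability(v, sp$table), 3)
#>   position label     mods_only_A1 mods_only_A2
#> 1      450 P450A    carbonylation
#> 2      451 T451A  phosphorylation
#> 3      264 E264Q ethanolamination
```

so the planted T451A variant, for instance, can only be phosphorylated in
the first paralog.

A thin command-line front end over the same functions is installed at
`inst/scripts/ptmsurf.R` (subcommands `run`, `simulate`, `sasa`,
`enrich`).

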