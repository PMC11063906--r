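# structcomp

Quantitative structural comparison of multi-domain protein complexes from
crystallographic coordinates, in tidy R.

`structcomp` grew out of the analysis of bacterial endoglycosidase–IgG1 Fc
complexes — enzymes such as EndoS2 of *Streptococcus pyogenes* that cleave
the N-linked glycan at Asn 297 of the antibody Fc. Understanding how such
an enzyme captures its substrate requires three kinds of measurement that
the package implements as a reusable pipeline:

1. **Inter-domain rearrangement.** Conformers of a multi-domain protein
   are superposed by a least-squares rigid-body (Kabsch) fit on the Cα
   atoms of a reference domain; every other domain is then characterised
   by its displacement RMSD (no re-fitting) and by the total rotation
   angle θ = arccos((tr **R** − 1)/2) of its local best-fit rotation
   **R**. This is the standard vocabulary for statements like "aligned on
   the catalytic domain, the adjacent domain is offset by 10°, displacing
   the distal domains by 8.2 and 19.4 Å".
2. **Interface characterisation.** Solvent-accessible surface areas are
   computed with a deterministic Shrake–Rupley engine (golden-spiral
   sphere points, NACCESS/Chothia-style radii, 1.4 Å probe). The buried
   interface area is the PISA convention
   (SASA(A) + SASA(B) − SASA(A∪B))/2; a solvation free-energy gain
   Σ σ(class)·ΔASA with Eisenberg–McLachlan-style atomic solvation
   parameters, residue contacts (4.5 Å heavy-atom cutoff) and hydrogen
   bonds (3.5 Å donor–acceptor, template-typed, no explicit-hydrogen
   geometry) complete the report.
3. **Glycan geometry.** N-glycans are detected by a covalent walk from the
   Asn ND2 atom, each linkage annotated with glycosidic torsions
   (heavy-atom convention Φ = O5–C1–Ox–Cx, Ψ = C1–Ox–Cx–C(x+1)) and each
   pyranose ring with Cremer–Pople puckering parameters (Q, θ, φ₂) and the
   nearest canonical conformer (chair, boat, skew-boat, ...).

Everything takes and returns tibbles, so results chain with the pipe;
fitted objects have `tidy()`/`glance()` methods and result tables have
`autoplot()` methods.

## Worked example

Build a four-domain toy protein in two conformations with a known 10°
rotation of the LRR domain and a 4° + (2, −1, 3) Å move of the CBM, then
ask the pipeline what moved:

```r
library(structcomp)

toy <- make_multidomain_toy(
  transforms = list(LRR = list(angle = 10, axis = c(0, 1, 1)),
                    CBM = list(angle = 4, translation = c(2, -1, 3))),
  atoms_per_domain = 100, seed = 7)

domain_rearrangement(toy$reference, toy$transformed, "A", "A",
                     default_scheme("endos2"), reference = "GH")
#> # A tibble: 3 × 4
#>   domain rotation_deg displacement_rmsd n_matched
#>   <chr>         <dbl>             <dbl>     <int>
#> 1 LRR     10.00                2.02e+ 0       100
#> 2 hIg      0.00000171          3.47e-14       100
#> 3 CBM      4.00                3.82e+ 0       100
```

The applied rotations come back exactly; the untouched hIg domain shows
numerical zero. The LRR's 2.0 Å displacement RMSD is the rigid-body
consequence of rotating a ~8 Å-radius domain by 10° about its own
centroid.

Glycan detection and geometry on an idealised fucosylated chitobiose core
whose GlcNAc-β1,4-GlcNAc linkage was built at the distorted Φ = 5.9°:

```r
g <- make_nglycan(phi = c(-97, 5.9), psi = c(178, -120), fucose = TRUE)
tree <- detect_glycan(g, chain = "A", asn = 297)
tree$linkages[, 4:8]
#>   donor_resid acceptor_resid acceptor_atom linkage         phi   psi
#> 1 NAG         ASN            ND2           N-glycosidic -97      178
#> 2 NAG         NAG            O4            1-4            5.90  -120
#> 3 FUC         NAG            O6            1-6          -80      175

ring_puckers(g, tree)[, c("resno", "resid", "Q", "theta", "conformer")]
#>   resno resid     Q    theta conformer
#> 1     1 NAG    0.57 2.74e-14 4C1
#> 2     2 NAG    0.57 7.13e-14 4C1
#> 3     3 FUC    0.57 4.01e-14 4C1
```

A Φ of 5.9° sits far outside the −74° ± 8.4 range of relaxed β1,4
linkages seen in crystal-structure surveys — the kind of distortion an
endoglycosidase imposes on the scissile bond. All rings are ideal ⁴C₁
chairs by construction (θ ≈ 0).

Buried area of the smallest possible "interface", two carbon atoms 2 Å
apart, which has a closed-form answer of 40.90 Å²:

```r
rt <- radii_table("element", custom = c(C = 1.70))
a <- make_sphere_cluster(rbind(c(0, 0, 0)), "C")
b <- make_sphere_cluster(rbind(c(2, 0, 0)), "C", chain = "B")
interface_area(a, b, rt)
#> [1] 40.95
```

For real structures, `run_config()` + `run_report()` orchestrate the full
comparison (per-copy rearrangement, total and domain-restricted
interfaces, ΔG, contacts, hydrogen bonds, glycan torsions and puckers,
inter-domain distances, Cγ2 separation, loop-deviation profiles) and
write `reproduction.tsv`, `interfaces.json`, `rearrangement.tsv`,
`glycan.tsv` and `run.log` to an output directory, every row carrying the
chains and windows it was computed from.

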