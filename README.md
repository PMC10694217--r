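# frlpsi

Comparative molecular evolution of far-red-light photosystem I.

Certain cyanobacteria acclimate to far-red light (FRL, 700–800 nm) by
upregulating a dedicated gene cluster (FaRLiP) that swaps six photosystem I
subunits — PsaA, PsaB, PsaF, PsaJ, PsaI and PsaL — for FRL-specific
paralogs (PsaA2, PsaB2, …) and installs the red-shifted pigment
chlorophyll *f* in specific antenna sites. `frlpsi` implements, as a
tested and reusable pipeline, the comparative sequence–structure analysis
used to characterise this remodeling and to infer which features the
*ancestral* FRL photosystem I already possessed:

1. **Group-specific residue classification.** Given a multiple sequence
   alignment whose rows are labelled FRL, VL (visible-light) or outgroup,
   a column is *FRL-specific* when, after discarding residues at
   within-group frequency ≤ *f*ₙ (default 0.05) and columns with gap
   fraction > 0.5 in either group, the FRL residue set is disjoint from
   the VL set and consists of a single residue (or one conservative
   class among ILVM, FYW, ST, DE, KR, NQ) at frequency ≥ *d* (default
   0.90).
2. **Marginal ancestral sequence reconstruction.** On a fixed rooted tree
   with branch lengths, under an empirical amino-acid model (LG by
   default; `q_ij = s_ij π_j`, scaled to one expected substitution/site,
   optional discrete-gamma rates), the per-site posterior
   `P(x at node | data) ∝ L_below(x) · L_above(x)` is computed by
   Felsenstein pruning plus an outside pass; the FaRLiP ancestor is the
   MRCA of the FRL-labelled leaves.
3. **Ancestral conservation.** A specific column counts as
   ancestral-conserved when the ancestor's MAP state lies in its FRL
   residue set.
4. **Structural geometry.** Kabsch (SVD) local superposition on backbone
   atoms within 12 Å of a cofactor; total-least-squares ring-plane fits;
   the chlorophyll rotation angle measured between the in-plane NA→NC
   axes of the two tetrapyrroles after projection into their bisecting
   plane, with the pivot ring identified as the ring whose centroid moves
   least; hydrogen bonds inferred from heavy-atom N/O/S geometry
   (distance ≤ 3.5 Å, acceptor angle 90–180°, quality = |angle − 120°|).
5. **Spatial clustering.** Single-linkage clustering (connected
   components at a 15 Å Cα cutoff) of the specific residues mapped onto a
   structure.
6. **Ancestral site calls.** A candidate chlorophyll-*f* site is called
   ancestral (Y) iff every H-bond-donor/cavity support residue is
   group-specific *and* ancestral-conserved and at least half of its
   stabilizers are conserved.

Every stage can be exercised offline: the `generate_*` functions produce
alignments with planted specific columns, sequences simulated down known
trees, spatial blobs, and synthetic chlorin structures with known
rotations, all with their ground truth attached.

## Worked example

```r
library(frlpsi)

g   <- generate_grouped_alignment(n_specific = 10, retained_fraction = 0.7,
                                  seed = 1)
cls <- classify_columns(g$aln, specificity_rule())
sc  <- score_ancestral_conservation(cls, g$ancestral_sequence)
table(cls$status)
#> GROUP_SPECIFIC       VARIABLE
#>             10            190
sprintf("%d of %d specific columns ancestral-conserved (%.0f%%)",
        sc$n_conserved, sc$n_specific, 100 * sc$fraction)
#> "7 of 10 specific columns ancestral-conserved (70%)"

pair <- generate_rotated_cofactor_pair(rotation_deg = 5, pivot_ring = "E")
measure_cofactor_rotation(pair$ref, pair$mobile, pair$site)
#> Cofactor rotation: 5.00 deg (plane normals 0.00 deg), pivot ring E
#> Per-ring centroid shifts (A): A=0.77 B=0.57 C=0.21 D=0.57 E=0.00
```

All ten planted columns are recovered as group-specific with no false
positives; the ancestor retains seven of them, exactly as planted; and the
5° rotation applied about the isocyclic ring E is measured back with the
correct pivot. The site demonstration integrates these layers into the
eight-site evidence matrix (extant structure rows are an input evidence
table; the `Ancestral` row is computed from residue conservation):

```r
res <- run_site_demo(generate_site_demo(seed = 1))
res$matrix
#>                         A0B_rotation B7  B37 B38 B30 A21 A23 B19
#> 7LX0_F_thermalis        "Y"          "Y" "Y" "Y" "Y" "Y" "N" "N"
#> 7S3D_Synechococcus_7335 "Y"          "Y" "Y" "Y" "Y" "Y" "N" "Y"
#> 6KMX_H_hongdechloris    "Y"          "Y" "Y" "Y" "Y" "Y" "Y" "N"
#> Ancestral               "Y"          "Y" "Y" "N" "Y" "N" "N" "N"
```

The ancestral row says: the A0B rotation and chlorophyll *f* in sites B7,
B37 and B30 were already present in the ancestral FRL photosystem I; B38
(whose Trp→Phe cavity replacement occurs in only half of the FRL
sequences, with Trp ancestral), A21 (most loop stabilizers not
ancestral), and the species-variable A23/B19 were not.

`run_pipeline()` orchestrates the full chain (classify → reconstruct →
conserve → cluster → geometry → sites) from a YAML/list configuration and
writes TSV/FASTA/JSON reports plus the resolved configuration.

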