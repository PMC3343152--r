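# polyqconf

Statistical analysis of conformational ensembles of polyglutamine (polyQ) and
polyQ–polyproline peptides from backbone dihedral angles and coordinates.

Monomeric polyQ chains are largely disordered, yet their aggregation behaviour
is thought to depend on rare extended motifs — β- and α-sheet-like strands and
hairpins — and on how far along the chain the conformational states of
glutamine residues influence one another. `polyqconf` quantifies both from an
ensemble of conformations of a single peptide chain:

* **Ramachandran regions.** Every defined (φ, ψ) pair is assigned to one of
  four regions of the torus — αR (right-handed helical), αL (left-handed
  helical), PPII (polyproline II) and β (extended) — either by hard boundary
  rectangles with nearest-center completion or by per-residue wrapped k-means
  clustering, so the four regions always partition the data.
* **Secondary structure and motifs.** A DSSP-style subset (codes H, G, I, E,
  B, T, S, C) is computed from Kabsch–Sander hydrogen-bond energies,
  `E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a bond
  below −0.5 kcal/mol. On top of it the package detects the rare motifs of
  interest: isolated β/α̃ strands (an α̃ strand is a run of residues strictly
  alternating between αR and αL), PPII runs, β/α̃ hairpins (two strands, a
  turn-shaped connector, and at least one cross-strand hydrogen bond), helix
  segments, and typed turns.
* **Odds-ratio correlation profiles.** For a binary residue property X (e.g.
  membership in the αR region), association between residues i and i+r is
  measured by the odds ratio OR = (p00·p11)/(p01·p10) of the pooled 2×2 table,
  reported as a free-energy-like score `ΔΔG = k_B T ln OR` (kcal/mol) with the
  asymptotic standard error `k_B T √(Σ 1/n_xy)`. Profiles over sequence
  distance r come with end-residue trimming, a Pearson ψ-angle profile for
  cross-checking, a periodogram-based dominant-period estimate, and a
  long-range-correlation diagnostic of the profile tail.
* **Radius of gyration.** Rg over glutamine Cα atoms (proline segments
  excluded), histogramming, Gaussian-mixture decomposition by
  Levenberg–Marquardt with Poisson-weighted reduced χ², chain-length scaling
  exponents ν from Rg ∝ N^ν, and prolyl cis/trans sub-ensemble splits from the
  ω torsions preceding prolines.
* **Synthetic ensembles.** A latent-Gaussian copula generator with a
  damped-cosine correlation kernel
  `k(d) = a · exp(−d/λ) · cos(2πd/P) + (1−a)·[d=0]` gives independent control
  over per-residue region marginals, correlation decay length λ and
  oscillation period P, plus ideal-geometry backbone reconstruction — so the
  whole pipeline is testable without molecular-dynamics input.

Ensembles enter as multi-model PDB files (`read_multimodel_pdb()`), plain
dihedral tables (`read_dihedral_table()`), or from the generator.

## Worked example

```r
library(polyqconf)

# a Q40-like ensemble with injected long-range, period-7 correlation
spec <- q40_like(n_conformations = 1000, a = 0.8, lambda = 50, period = 7,
                 seed = 42)
ens  <- generate_ensemble(spec, backbone = TRUE)$ensemble
summ <- run_summary(ens, analysis_config(seed = 42))
print(summ)
```

```
Summary of 'synthetic' (1000 conformations)
Region populations (% of Gln residues):
     alphaR      alphaL        PPII        beta alpha_tilde
      80.03        4.92        7.19        7.86       10.96
Secondary structure (% of Gln residues):
helix_pct  turn_pct other_pct
    58.07     22.38     19.55
Helical content: 54.79% (alpha 47.86%, 3-10 6.93%)
Motif prevalence (% of conformations):
                type min_len prevalence_pct
         beta_strand       3            9.8
  alpha_tilde_strand       3           46.9
            ppii_run       3            3.1
        beta_hairpin       3            0.2
 alpha_tilde_hairpin       3            1.5
         beta_strand       4            0.1
  alpha_tilde_strand       4            1.8
alphaR profile: dominant period 7.00 residues, long-range flag TRUE (tail mean -0.1234 kcal/mol)
Rg: 12.80 +/- 2.62 Angstrom
```

The region populations reproduce the generator's marginals (80/5/7/8%); the
dominant period of the αR odds-ratio profile recovers the injected kernel
period of 7 residues, and the long-range flag reports that the profile tail
(r ≥ 10) stays away from zero by more than twice its standard error. Motif
prevalences count the fraction of conformations containing at least one
instance of each motif within the polyQ portion; the α̃-strand prevalence is
high here because the αR/αL alternation that the injected kernel favours is
the building block of α̃ repeats.

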