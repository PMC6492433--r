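# perilad

Quantitative analysis of chromatin tethering at the plant nuclear periphery
(NP). In *Arabidopsis*, lamin-like proteins (CRWN1/CRWN4) are candidates for
anchoring specific chromatin domains at the nuclear envelope, the plant
counterpart of metazoan lamina-associated domains. Testing that hypothesis
takes four quantitative pipelines, all implemented here:

1. **3D FISH positioning** — segment 2C nuclei from DAPI, compute an
   anisotropy-aware Euclidean distance-to-periphery field, measure each
   signal spot's barycenter distance to the "edge of DAPI staining", and
   compare Green vs Red probe classes with a two-sided Mann-Whitney *U*
   test (summaries formatted `mean ± sd, n`).
2. **Chromosome painting** — per-nucleus cumulative signal as a function of
   distance to the NP, with the bottom two z-slices excluded; the headline
   statistic is *P*₀.₅, the fraction of a channel's signal within 0.5 µm of
   the periphery, compared Green-vs-Red per nucleus with a Wilcoxon
   signed-rank test.
3. **Hi-C compartmentalization** — iterative correction (ICE) of binned
   contact matrices to marginal uniformity (eps < 1e-4),
   observed/expected (O/E) transform, A/B compartment calls from the
   leading eigenvector of the O/E row-correlation matrix, and
   cross-compartment interaction strength within 1 Mb (the O/E values of
   A–B bin pairs; weaker compartmentalization pushes the mean toward 1).
4. **NP-interaction regression and PLAD calling** — LASSO models
   (glmnet, tenfold CV, `lambda.1se`) of periphery-interaction signal from
   epigenomic features with and without a distance-to-pericentromere
   feature, evaluated on held-out chromosomes; and a SICER-style window/gap
   island caller (W = 500, G = 1500, FDR < 0.01) whose replicate
   intersection defines PLADs, followed by accessibility contrasts inside
   PLADs vs their 1-kb flanks.

A first-class synthetic-data module generates ellipsoidal nuclei with
uniform or boundary-biased signal, contact matrices with tunable
compartment strength `s` and power-law distance decay, linear
feature-driven interaction signal, and Poisson read-count tracks with
planted enrichment domains — so every stage is testable end to end with no
external data.

## Worked example

The numbered scripts under `analysis/` run the five pipelines on synthetic
genotypes. For example, `analysis/04_hic_compartments.R` contrasts a
wild-type-like genotype (compartment strength s = 0.6) with a
lamin-mutant-like one (s = 0.3) on the same A/B labels:

```
ICE converged: wt TRUE (eps 5.7e-05), mutant TRUE (eps 8.1e-05)
mutant A/B labels agree with wild type at 100.0% of bins
mean cross-compartment O/E within 1 Mb: wt 0.574, mutant 0.802 (MW p = 0)
trans-contact fraction: wt-like 0.039, mutant-like 0.108
```

Compartment identity is preserved while the A–B contact depletion relaxes
from 0.57 toward 1 and trans contacts rise — the attenuation signature.
Similarly `analysis/01_fish_distances.R` prints Mann-Whitney tables per
genotype:

```
wild_type   Green 0.29 ± 0.20, 50 | Red 0.66 ± 0.48, 50 | p = 9.76e-06 (**)
crwn1_like  Green 0.64 ± 0.46, 50 | Red 0.66 ± 0.43, 50 | p = 0.712 (ns)
kaku4_like  Green 0.30 ± 0.21, 48 | Red 0.64 ± 0.48, 49 | p = 5.09e-05 (**)
```

Differential Green/Red positioning is detected exactly where the generator
planted it, and lost when both channels share one radial model. Each script
writes its tables under `results/`.

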