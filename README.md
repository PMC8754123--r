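# nanclust

Detection and evolutionary analysis of sialic acid catabolism (*nan*) gene
clusters in bacterial genome collections.

Sialic acids (e.g. Neu5Ac) coat animal cell surfaces, and the ability to
catabolize them is classically viewed as a trait of host-associated
bacteria. Scattered homologs of the first two pathway genes are nearly
universal, so gene presence alone is a poor predictor of the pathway:
what marks a functional system is the *genomic clustering* of the three
core genes — *nanA* (N-acetylneuraminate lyase), *nanK* (ManNAc kinase) and
*nanE* (ManNAc-6P epimerase). `nanclust` implements that neighborhood logic
and the comparative analyses built on it, for anyone profiling an accessory
catabolic pathway across thousands of annotated genomes.

## What it computes

* **Role calling** — gene roles are assigned from domain-hit evidence
  (Pfam, CDD, reference-protein BLAST, COG, IS) under strict thresholds:
  Pfam/CDD at E < 1e-10 with two-source confirmation required for
  *nanA/K/E*; BLAST roles (NanE-II, RokA, NanOx) at E < 1e-5 and identity
  > 30%; COG assignments at E < 1e-5, coverage > 50%, identity > 50%.
  The role→accession map is a shipped, editable config.
* **Cluster detection** — a genome is SAC-positive iff it carries
  *nanA/K/E* within a 10-ORF window (canonical paradigm; max − min contig
  ordinal of the triple ≤ 10) or clustered *nanA* + *nanE-II* with *rokA*
  anywhere in the genome (*Bacteroidetes*-like paradigm). Clusters are typed
  consecutive/inconsecutive and annotated with sialic-acid transporter
  families (ST3 = ABC/SBP_bac_5, ST7 = ABC/SBP_bac_1, ST1 = MFS,
  ST5 = SSS), regulators (COG K within 3 ORFs), *nagA/B*, sialidase and
  IT-sialidase, *nanOx*, IS and mobilome context, and contig-boundary flags.
* **Distribution statistics** — per-taxon positive-rate tables with
  half-up rounding and an "ND" rule for taxa with fewer than 5 members;
  habitat-association testing with an exact two-sided Fisher test
  (point-probability method, log-space safe for large counts).
* **Gain/loss reconstruction** — Wagner parsimony (Sankoff DP with
  separate gain and loss penalties, multifurcation-safe) of cluster
  presence/absence over a species tree, with total and terminal-branch
  ("species-level") event counts, validated against an exhaustive oracle.
* **Genome QC and dereplication** — completeness/contamination/marker-gene
  filtering and single-linkage ANI dereplication (type strains exempt).
* **Synthetic data** — a seed-reproducible generator that plants clusters,
  decoy scattered homologs and near-miss evidence with a full ground-truth
  table, so every stage is testable end to end.

## Worked example

The `analysis/` scripts run the whole chain on a synthetic collection of
500 genomes (≈13% planted cluster prevalence):

```sh
Rscript analysis/01_simulate.R       # gene/evidence/metadata tables + tree
Rscript analysis/02_call_clusters.R  # role calling + cluster detection
Rscript analysis/03_stats.R          # rate tables + habitat test
Rscript analysis/04_gainloss.R       # Wagner parsimony on the species tree
```

Step 2 prints, for seed 101:

```
SAC-positive genomes: 72 / 500
cluster structures: consecutive 53, inconsecutive 19
transporter families: ND 2, ST1 6, ST3 62, ST5 2
verdict agreement with planted truth: 1
```

i.e. 72 genomes carry a detected cluster, mostly of the consecutive
*nanA/K/E* arrangement with ABC/ST3 transporters, and every verdict matches
the generator's ground truth. Step 3 then shows why clustering (not
presence) is the right signal — scattered *nanA*/*nanK* are near-universal
(99.80% / 98.40% of genomes) while *nanE* tracks the clusters (14.40%) —
and recovers the planted habitat skew (24.83% positive among
animal-associated vs 10.23% among non-animal; Fisher p ≈ 6.6e-05). Step 4
reconstructs the cluster history on the species tree; with an i.i.d.
planted profile it infers 72 gains, all on terminal branches.

Equivalent calls in R:

```r
library(nanclust)
ds    <- generate_dataset(sim_config(n_genomes = 500, seed = 101))
roles <- assign_roles(ds$genes, ds$evidence)
res   <- call_genomes(ds$genes, roles)
positive_rates(res$calls, ds$meta, rank = "order")
habitat_association(res$calls, ds$meta)
wagner_parsimony(ds$tree, ds$profile)
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch against the installed package:
it simulates a 500-genome collection under the given seed, calls roles and
clusters, computes the rate and habitat statistics, and runs the
gain/loss reconstruction (including the lower-bound check against the
simulated true history), then writes the JSON report to `--out`.
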