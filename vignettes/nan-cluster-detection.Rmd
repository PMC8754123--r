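---
title: "Detecting and analysing sialic acid catabolism gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing sialic acid catabolism gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanclust)
```

## The problem and the model

Sialic acid catabolism (SAC) lets bacteria use host-derived sugars such as
Neu5Ac as carbon and nitrogen sources. The canonical route runs NanA
(lyase) → NanK (kinase) → NanE (epimerase) into the NagA/NagB
amino-sugar pathway; an alternative route, first described in
*Bacteroidetes*, replaces NanK/NanE with NanE-II and the kinase RokA.
Because scattered homologs of *nanA* and *nanK* moonlight in other
pathways and are nearly ubiquitous, the package's unit of inference is the
**gene cluster**, not the gene:

* **canonical paradigm** — one *nanA*, one *nanK* and one *nanE* whose
  contig-local gene ordinals satisfy `max − min <= max_span` (default 10,
  i.e. the triple fits into 11 consecutive ORFs);
* **alternative paradigm** — *nanA* and *nanE-II* within the same window,
  plus *rokA* anywhere in the genome (its position is recorded, not
  constrained).

Ordinals are 0-based positions in the per-contig gene order recomputed from
start coordinates, so detection is invariant to input row order. ORF
distance is undefined across contigs, hence clusters never span them.

## Role calling

Roles are assigned from a domain-evidence table under strict thresholds
(pass iff `evalue < evalue_max`, `identity > identity_min`,
`coverage > coverage_min`): Pfam and CDD at E < 1e-10, reference-protein
BLAST roles (NanE-II/RokA/NanOx) at E < 1e-5 with identity > 30% (no
coverage cut — none is stated for these searches), IS elements at
E < 1e-5, and COG assignments at E < 1e-5 with coverage and identity > 50%.
The three core roles additionally require both a passing Pfam hit and a
passing CDD confirmation; accessory roles need a single source. We apply
the two-source rule to core roles only, since that is where a false
positive flips a genome verdict.

The role→accession map ships as an editable config
(`default_role_map()`, `read_role_map()`/`write_role_map()`). The exact
accession set used originally is not public, so the defaults are a
documented reconstruction around the four published anchors — SBP_bac_5
(PF00496, ST3), SBP_bac_1 (PF01547, ST7), BPD_transp_1 (PF00528, partial
ABC), and COG categories K/X — plus widely cited families for the enzyme
roles (e.g. PF00701 for the NanA lyase, PF00480/ROK for NanK, PF04131 for
NanE). The rule engine is independent of these choices; swapping the map
re-targets the whole pipeline.

A sialidase gene is subtyped as an intramolecular trans-sialidase (IT)
iff the same gene carries a passing segmented RgNanH-type domain hit;
building that segment model from CAZy GH33 is an upstream step outside this
package — we consume its hit table.

## Window semantics and tie-breaks

"Within 10 ORFs of each other" is read as the max-span rule: all three
core genes inside one window (`max − min <= 10`). This matches the "within
10 consecutive ORFs" phrasing of the alternative paradigm and is
order-independent. A chain reading (each gene within 10 of *some* other
core gene, connected components) is strictly more permissive and is exposed
as `rule = "chain"`; the default is `"max_span"`.

Each *nanE* is matched to the nearest feasible *nanA* and *nanK*
(ties to the lower ordinal, for determinism). Candidate triples sharing a
core gene are merged, so no two reported clusters share a gene; a merged
cluster can legitimately span more than the window, but always contains at
least one in-window triple. The tests enforce exact equivalence of
verdicts with a brute-force enumeration of all triples.

Context annotation searches outward from the core span: transporters, IS
and mobilome genes up to 5 ordinals beyond the span (the source work
quantifies only the regulator distance, 3 ORFs; 5 is our documented default
for "around the cluster", configurable); regulators within 3; sialidase,
IT-sialidase, *nanOx*, *nagA* and *nagB* flags record in-span presence,
with *nanOx* additionally flagged genome-wide (anhydro-SAC capability does
not require in-cluster placement). Transporter→ST mapping: ABC/SBP_bac_5 →
ST3, ABC/SBP_bac_1 → ST7, MFS → ST1 (left ND when an ABC system is also
present, the undetermined mixed case), SSS → ST5, a lone BPD_transp_1
permease → partial ABC, family ND. A span within 10 ordinals of a contig
end sets `contig_boundary`, our operationalisation of "located only at
contig boundaries" where transporter genes may simply be missing from the
assembly.

## Statistics

Per-taxon positive rates are percentages rounded **half-up** to two
decimals (no printed rate in the reference tables is a .xx5 tie; R's
banker's rounding would differ on such ties, so the mode is fixed and a
1e-9 relative epsilon guards binary representation of exact halves).
Taxa with fewer than 5 members report the literal string `"ND"`. Species
are equated with type strains, the standard de-biasing for unevenly
sequenced genera.

The habitat test is an exact two-sided Fisher test implemented by the
point-probability method: with margins fixed, p is the sum of
hypergeometric point probabilities not exceeding the observed one, with a
relative guard of 1e-7 (the convention of the common statistical
environments). Probabilities are computed via `dhyper(log = TRUE)`, so
counts up to 1e5 are safe. `stats::fisher.test` serves only as an
independent cross-check in the tests.

## Gain/loss reconstruction

`wagner_parsimony()` is a Sankoff dynamic program over the two states with
separate gain and loss penalties (defaults 1:1, the usual Wagner setting),
handling multifurcations natively. Tie policy, which the original tooling
does not document: on a cost tie a node takes its parent's state
(minimising change on the incoming branch), and a root tie resolves to
absence — the conservative default for an accessory cluster that is absent
from most deep lineages; the number of ties is reported so users can see
when the policy mattered. `brute_force_parsimony()` (exhaustive over
internal states, ≤ 20 internal nodes) is the test oracle; the suite checks
DP = oracle on hundreds of random trees with mixed costs, the
complement/cost-swap symmetry, and the lower-bound property against
simulated histories. Reference full-dataset event counts depend on a
~2,000-species tree that is not reproducible at desk scale; correctness
here is established by these properties, not by value matching.

## The synthetic world

`generate_dataset()` emulates the statistical structure of a large
actinobacterial collection rather than its sequences:

* cluster prevalence 0.13 of species; 99% canonical, the alternative
  paradigm a rare exception;
* 79% of canonical cores consecutive; in-span accessory genes (*nagA*
  0.28, *nagB* 0.48, sialidase 0.32 with 0.15 IT fraction, *nanOx* 0.02)
  are realised in the gaps of inconsecutive cores — a consecutive triple
  has no in-span room by construction;
* transporter mix dominated by ABC/ST3 (0.84), with ST7, MFS/ST1, SSS/ST5,
  mixed ABC+MFS, partial and transporter-free clusters at the small
  observed frequencies; regulator present at 0.95; IS context 0.95;
  mobilome 0.10;
* scattered decoy *nanA*/*nanK* at 0.996/0.977 of genomes (the
  near-universality that motivates cluster-based calling), decoy sialidase
  0.31, genome-wide *nanOx* 0.18; decoys are placed > 10 ordinals from any
  complementary core gene so they can never complete a window;
* habitat skew: P(animal | positive) = 0.59 vs 0.27 otherwise, 2% unknown;
* genome sizes (2 contigs of 65–95 genes) and the taxonomy shape
  (5 orders × 4 genera) are desk-scale choices, not reference values.

Decoy evidence is generated both as wrong-accession hits and as
right-accession hits failing the e-value cut by 1–2 orders of magnitude,
so threshold logic is exercised, not just accession matching. Each
generator section draws from its own seed-derived stream, so adding an
output never perturbs the others.

What a green end-to-end test establishes: the detector, annotator and
statistics recover exactly what was planted under the stated rules. What
it does not establish: performance on real annotation noise (split or
missed ORFs, divergent domains scoring near thresholds, misassembly),
since no sequences are simulated.

## Numerical and degenerate-input choices

* QC cuts are strict as printed: completeness > 95, contamination < 5;
  the marker rule keeps a genome at exactly 75% of markers.
* Dereplication is genus-restricted single-linkage at ANI ≥ 99.5 with the
  lexicographically smallest id as representative — a deterministic
  stand-in for dRep's unstated scoring; type strains are always retained.
  The original wording is ambiguous about genus restriction; we restrict
  and document it.
* A zero margin in the 2×2 habitat table returns p = 1 with a warning.
* Copy-number summaries cover carrier genomes only; a role absent
  everywhere yields an empty (NA) summary, not zeros.
* An empty subset denominator yields "ND", mirroring the rate rule.
* Genomes with missing QC metrics are excluded with a warning rather than
  guessed.

## Known limitations

* The role map defaults are reconstructions; analyses of real data should
  review them against a current domain database before trusting role-level
  results.
* "Around the cluster" distances beyond the regulator rule are not
  quantified in the source; the 5-ORF flank is a documented choice.
* The generator plants at most one cluster per genome; multi-cluster
  genomes (a rare real phenomenon) are covered by hand-built fixtures in
  the tests instead.
* Wagner parsimony reports one optimal labelling under the stated tie
  policy, not the full set of optima (the oracle enumerates those in
  tests).
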