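---
title: "Inferring community functional profiles from 16S surveys via lineage pangenomes"
author: "panfun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community functional profiles from 16S surveys via lineage pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfun)
```

## The problem

A 16S rRNA amplicon survey tells you *who* is in a microbial community —
an OTU-by-sample table of read counts, each OTU carrying a taxonomy
string — but not *what the community can do*. Shotgun metagenomics answers
the functional question directly but is far more expensive at the breadth
and depth large study designs need. `panfun` bridges the gap: it predicts
a KEGG Orthology (KO) term abundance profile per sample from the OTU table
alone, using only the OTUs' taxonomic lineages and a collection of
functionally annotated reference genomes. Because it keys on lineages
rather than on reference 16S sequences, it works with any OTU-picking
strategy (de novo, open- or closed-reference alike).

## The model

For each OTU the method builds a **pangenome**: the multiset union of
annotated genes over all reference organisms pooled at the OTU's
taxonomic lineage. The pangenome's functional profile, normalized by the
pool size $O_i$, is assigned to the lineage:

$$fq(\mathrm{lineage}_i, KO_j) = \frac{1}{O_i}\,
  \mathrm{occurrence}(KO_j \in \mathrm{pangenome}_i)$$

Occurrences count gene–KO annotation pairs: a gene annotated with several
KO terms contributes one occurrence to each term, and a multi-copy gene
family contributes once per gene copy. $fq$ is therefore the *mean
per-genome occurrence* of a term — above 1 for universal multi-copy
families — and is never clamped to $[0,1]$. We chose accumulation over
per-genome presence/absence because the pangenome is described as a
superset of all genes whose functional compositions are accumulated;
under either reading, terms shared by more organisms score higher.

OTU abundances are made comparable in two normalization steps. First,
because 16S read counts over-represent organisms with many rRNA operon
copies, each OTU's abundance is divided by the **median 16S copy number**
of the organisms pooled at its lineage (even pools take the mean of the
two middle values). Second, each sample column is divided by its sample
size so per-sample frequencies sum to one. The resulting
$fq(OTU_i, \mathrm{sample}_j)$ are collapsed by lineage,

$$fq(\mathrm{lineage}_i, \mathrm{sample}_j) =
  \sum_{OTU_k\,\mathrm{has\,lineage}} fq(OTU_k, \mathrm{sample}_j),$$

and the function-sample table weights each lineage's pangenome profile by
its abundance:

$$fq(KO_i, \mathrm{sample}_j) = \sum_{\mathrm{lineage}_k}
  fq(\mathrm{lineage}_k, \mathrm{sample}_j)\times
  fq(\mathrm{lineage}_k, KO_i).$$

### Preparing lineages

Two preparation steps make the reference genomes usable for arbitrary OTU
taxonomies.

**Reconciliation.** OTU pipelines often carry taxonomy strings that
disagree with the current reference hierarchy. `reconcile_lineage()`
locates the lowest rank of the OTU's lineage that the reference taxonomy
recognizes and replaces the lineage with that taxon's reference ancestor
chain, correcting stale upper ranks and removing unrecognized ranks below
the match. Where the design was genuinely open we chose to override *all*
upper ranks from the lowest recognized taxon upward, recognized or not —
the reference hierarchy is treated as authoritative once any anchor is
found. Homonyms (the same name at the same rank under different parents)
resolve to the candidate whose ancestry shares the most rank–name pairs
with the input; a tie leaves the lineage unreconciled rather than guess.
Unreconciled lineages still proceed to trimming: pooling is decided by
the genome index, not by the taxonomy.

**Trimming.** `trim_lineage()` removes trailing ranks while the lowest
(rank, name) has no genome in the coverage-filtered database, so every
retained OTU pools at least one genome. An OTU whose lineage cannot keep
a phylum-level designation is dropped (and logged); its reads do not
count toward the sample size. This makes the method robust to reference
incompleteness — an OTU resolved to an unsequenced genus simply borrows
its family's pangenome.

### The reference database

A genome record is the merged, chromosomally encoded gene set of one
organism with its gene→KO map, total gene count and 16S copy count
(plasmids are excluded upstream because of their outsized role in
horizontal transfer). **Functional coverage** — annotated genes over total
genes — guards against poorly annotated genomes dragging pangenome
frequencies down: genomes below `min_coverage = 0.30` are excluded. The
cutoff is exposed as a parameter; predicted profiles are insensitive to
it over a wide range because most curated genomes sit well above it. 16S
copy counts of 0 or NA are treated as unknown and excluded from medians;
an all-unknown pool falls back to copy number 1 with a warning, i.e. no
correction rather than a fabricated one.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 0.30 | minimum fraction of genes with a KO annotation for a genome to enter pangenomes |
| `sample_size` | `"corrected"` | divisor of the per-sample normalization: copy-corrected totals (default) or raw read totals |
| `dialect` | `"auto"` | taxonomy string dialect; auto-detection picks Greengenes `x__` prefixes when ≥ 50% of fields carry them, else `rank:` pairs, else positional names |
| `B`, `alpha` | 100, 0.05 | bootstrap replicates and CI tail mass |

The order of the two normalization sub-steps is ambiguous in principle
(divide by raw or by copy-corrected totals). The default performs copy
correction first and normalizes by the corrected totals, so that profiles
estimate *organismal* relative abundance and are invariant to rescaling
any sample's reads; `sample_size = "raw"` provides the other reading.

## Uncertainty: the row bootstrap

Under the assumption that OTUs contribute independently,
`bootstrap_intervals()` resamples the OTU table's rows (an OTU with its
whole abundance vector and taxonomy) with replacement, as many rows as
the table has, and reruns the *entire* chain — trimming through profile —
on each of `B = 100` replicates; resampling changes sample sizes, so
normalization cannot be reused. Per (KO, sample) cell the empirical 2.5%
and 97.5% quantiles over replicates form a 95% percentile interval.
Numerical choices: quantiles use linear interpolation over order
statistics (`stats::quantile` type 7, recorded in the result's metadata);
a KO term absent from a replicate's profile contributes 0, because the
estimate of an unobserved function is zero, not missing; a single seeded
generator drives all replicates in order, so a run is bit-reproducible
from its seed. Point estimates come from the original table and are
reported even when they fall outside their interval — we report, never
filter.

## Comparing profiles

Profiles produced by different approaches cover different KO
vocabularies, so `spearman_shared_nonzero()` compares two profiles only
on KO terms with non-zero values in both, with average ranks for ties.
Fewer than two shared terms leaves the correlation undefined (`NA`,
flagged) rather than erroring. The statistic is symmetric and invariant
to strictly monotone transforms of either profile — properties the test
suite checks directly.

## The synthetic world and what it does (not) show

Because the published reference snapshots behind the original validation
are unreproducible, correctness is established against **synthetic
worlds with exact ground truth**. `fixture_config()` describes a
rank-complete taxonomy (default 3 phyla, branching 2 per rank), genomes
attached to genera (2 per genus, 60–120 genes, annotation coverage
uniform on 0.5–0.95 with a 10% minority drawn poorly annotated to
exercise the coverage filter, 16S copies uniform on 1–15), and an OTU
table whose deepest resolved rank is drawn from a mixture emulating
mock-community surveys (24% species, 62% genus, 10% family, 3% order,
1% class), with log-normal read counts (meanlog 4, sdlog 1.2). Three
deliberate corruptions exercise the preparation steps: ghost genera
present in the taxonomy but without genomes (trimming), class names
absent from the taxonomy (reconciliation), and empty taxonomies
(dropping). Ground truth is computed at generation time by
`direct_function_profile()` — an independent code path written as plain
per-OTU enumeration, kept deliberately separate from the pipeline so the
comparison is a genuine oracle rather than a tautology.

The generator emulates the *arithmetic* of real surveys, not their
biology: KO assignments are uniform rather than phylogenetically
autocorrelated, abundances are i.i.d. log-normal with no compositional
structure, and taxa are balanced. Passing tests therefore demonstrate
that the implementation computes the stated model exactly and behaves
correctly under taxonomic incompleteness — not that the model's
predictions match real metagenomes, which depends on reference breadth
and annotation quality.

Validation problem sizes: the oracle-equivalence suite runs 50 seeded
fixtures up to 500 OTUs × 8 samples over a 200-term vocabulary; the
bootstrap check uses a 50-OTU × 4-sample survey at B = 100. A canonical
three-genome toy world (`toy_reference_db()`), small enough to verify
every stage by hand, is committed under `inst/extdata/toy/` and threaded
through the documentation.

## Degenerate inputs and tie-breaks

* An all-zero sample column is left untouched with a warning (0/0 is
  never formed).
* An empty taxonomy yields an empty lineage; the OTU is dropped and
  logged, and a run in which *every* OTU is dropped fails loudly.
* Duplicate resampled OTU ids are suffixed `.b<k>` to preserve row-id
  uniqueness.
* Taxon matching is exact string equality after whitespace squishing and
  case-folding; no fuzzy matching.
* Serialization uses 6 significant digits by default (configurable);
  all arithmetic is double precision; output ordering is deterministic
  (KO terms lexicographic, samples in input order), so identical inputs
  give bit-identical files.

## Known limitations

* Functional inference can never resolve strain-level gene differences
  below the rank the OTU pools at; a family-level OTU receives the
  family's average gene complement.
* The reference-database model is format-level: building `organisms.tsv`
  / `annotations.tsv` from public genome dumps (merging chromosomes,
  excluding plasmids, counting 16S loci) is the builder's responsibility.
* Bootstrap intervals quantify resampling uncertainty of the OTU table
  only, not reference-database annotation error.

## A worked three-genome example

```{r toy}
toy <- toy_reference_db()
db <- genome_db(toy$organisms, toy$annotations)
ref <- ref_taxonomy(toy$taxonomy)
prof <- infer_functional_profile(toy$otu, db, ref = ref)
prof$function_table
glance(prof)
```

The single OTU is annotated to the genus *Kurthia*, which has no genome
in the database; trimming falls back to the family Planococcaceae, whose
two genomes (after the 30% coverage filter removes the third record)
give $O_i = 2$, occurrences K1:2, K2:2, K3:1, hence
$fq = (1.0, 1.0, 0.5)$, a copy median of 5, a copy-corrected abundance
of $10/5 = 2$ and a normalized lineage weight of 1 — so the profile is
exactly the pangenome row.
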