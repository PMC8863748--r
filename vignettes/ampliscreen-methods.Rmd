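---
title: "Screening 16S primer pairs for species-collapsing amplicon similarity"
author: "ampliscreen"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the pipeline answers

Clustering 16S rRNA amplicons into OTUs at ≥97% similarity assumes that
97% is a species boundary. For many prokaryotic genera it is not: two
distinct species can carry gene segments that are nearly identical over
the region a given primer pair amplifies, and the shorter the amplified
region, the more often this happens. `ampliscreen` measures, per primer
pair and genome collection, how many species would be merged by a
97%-threshold analysis, and which taxonomic ranks those merges cross.

The unit of evidence is an **amplicon similarity relation (ASI97)**: an
alignment between in-silico amplicons of two *different* species, with
100% query coverage and percent identity ≥ 97. The per-primer report is
built from the binary species × species matrix of these relations.

# Pipeline model and assumptions

## Genome QC

Complete-genome assemblies mark low-coverage positions with non-ACGT
characters. A genome is discarded when it contains a run of **strictly
more than 20** consecutive non-ACGT characters (`max_ambiguous_run`,
default 20; the boundary is exact: a run of 20 is kept, 21 is not).
"Ambiguous" means any non-ACGT character, including IUPAC codes other
than N.

## Zero-mismatch degenerate matching

A primer written with IUPAC codes denotes the Cartesian product of its
per-position base sets. A genome position matches a primer code when it
is a concrete base in the code's base set; a genome-side ambiguity code
matches only the *identical* primer code (so a genome `N` matches primer
`N` but not primer `A`, and never satisfies a primer `R`). This is the
strictest reading of "zero mismatch": QC has already removed long
ambiguous runs, and treating leftover ambiguity codes as wildcards would
manufacture primer sites that may not exist. On plain A/C/G/T genomes the
rule coincides exactly with scanning every expanded concrete primer
realization, which is how the test oracles verify it. All overlapping
occurrences are reported (the scan advances one base at a time), and both
strands are scanned, since rRNA operons occur in either orientation.

## Amplicon extraction

For every forward-primer site and every downstream reverse-primer site
(the reverse complement of the reverse primer) on the same strand, the
pipeline emits the inclusive span as an amplicon when its reported
length — last base of the reverse site minus first base of the forward
site — lies **strictly** between 100 and 2300 nt. The extracted sequence
is the full span (reported length + 1 bases, both primer sites
included); minus-strand amplicons are reverse complemented so all
sequences read forward-primer-first. The length convention is forced by
the packaged catalog's arithmetic, where every defined amplicon length
equals `r_last − f_first` (e.g. 356 − 9 = 347 for OP_F053–KP_R020).

When a primer matches several loci, *all* forward × reverse combinations
within the window are emitted, including nested ones; the within-species
variant collapse removes the duplicates that matter downstream. Within a
species, amplicons from all strains are pooled and identical sequences
are collapsed; distinct sequences (≥1 nt difference) get variant numbers
`V1, V2, …` in order of first appearance (accession, then coordinate).
Species identifiers `SPn` follow first appearance in the metadata table,
making all identifiers deterministic for a given input.

## Alignment

The contract the similarity filter needs — full query coverage and a
BLAST-style `pident` — is a property of the alignment, not of a seeded
search heuristic. The aligner is therefore an exact semiglobal dynamic
program: the full query must align against any contiguous region of the
subject, with free end gaps on the subject only, so `qcovs = 100` holds
by construction (and `qcovhsp`/`qcovus` coincide with it, the alignment
being a single segment). Scoring mirrors the megablast defaults: match
+1, mismatch −2, and a linear gap cost of −2 per base (no opening cost);
all three are configurable via `align_scoring()`. Ambiguity codes
mismatch everything, including themselves. `pident` counts identical
columns over all alignment columns, gaps included in the denominator.

Tie-breaking is deterministic: among optimal-score alignments, fewer gap
columns win, then the leftmost subject start. Two numerical notes:

* For equal-length sequences differing only by substitutions, the
  gapless alignment gives `pident = 100·(L−m)/L` exactly. This is the
  regime of the ≥97% decisions. At high divergence (roughly >8%
  substitutions) a gapped alignment can legitimately score higher and
  raise `pident` by a few tenths of a point; the synthetic designs keep
  all identities ≥0.5 points away from 97 so decisions never depend on
  this.
* The threshold test uses `pident ≥ 97 − 1e−9`. Identities and columns
  are integers, so ties are exact in practice; the guard only protects
  the division.

## Relation selection

From the all-vs-all results (every ordered pair, self included) the
filter drops self-alignments (same `SPn.Vn`), within-species alignments
(same `SPn`) and symmetric duplicates, then keeps alignments with
`pident ≥ 97`. When several variant pairs of one species pair remain,
**one representative alignment is chosen uniformly at random** under the
run seed; the *set* of species pairs is seed-invariant, only the recorded
evidence varies. Per-pair seeds derive from the run seed as
`(seed + 7919·pair_index) mod (2^31 − 1)`.

## Statistics

With `n_total` evaluated species per domain (the count of distinct
species in the input genome set, configurable), the per-primer summary
reports `SC = 100·detected/n_total`, `SC-ASI97` (detected species with
≥1 relation), `SC-NASI97` (detected, none), `non-SC`, relation counts
and mean/max relations per species. `SC-ASI97 + SC-NASI97 = SC` and
`SC + non-SC = 100` hold exactly before rounding; percentages are
rounded to two decimals only at presentation.

The mean relations per species divides by the species having at least
one relation. The alternative — dividing by all detected species — is
defensible too; it is available via `mean_denominator = "detected"`.

Cross-rank tallies classify relations by whether the two species share
the label at a rank (genus, family, order, class). When aggregating
across primer pairs the tally counts relation-*occurrences* (one per
primer pair in which the species pair appears), which matches how
pooled two-on-two relationship percentages are usually quoted; the
distinct-pair universe is available by tallying the frequency table
instead, and `pair_frequency()` emits both shapes.

## Potential OTUs

A "potential OTU" is a connected component (≥2 species) of the graph
whose edges are the relations — the single-linkage interpretation: the
pipeline draws all pairwise ≥97% links and reports the clusters without
committing to any particular OTU-clustering algorithm, whose choice
would otherwise add its own artefacts. Isolated detected species are
exactly the SC-NASI97 species and are reported separately, not as
components. Per component, the report counts distinct genera, families,
orders and classes; for a hierarchy-consistent taxonomy these satisfy
`n_genera ≥ n_families ≥ n_orders ≥ n_classes`.

# The synthetic-community generator

`community_spec()`/`generate_community()` produce genome sets whose
correct analysis is known in closed form. Each covered species' genome
(per strain) embeds one segment: a concrete forward-primer realization,
a species core, and the reverse complement of a concrete reverse-primer
realization, inserted at a random locus on a random strand in i.i.d.
uniform (GC 50%) background; placements creating spurious primer sites
are rejected and resampled. Cores descend from per-block ancestors with
**substitution-only** divergence at globally disjoint positions, so every
pairwise amplicon identity is an exact, designed number: within-block
identity (default 98.5%) and between-block identity (default 90%) are
realized to the nearest feasible substitution counts and the realized
matrix is recorded in the ground truth. Designs whose realized identities
come within 0.5 percentage points of the 97% threshold are rejected at
specification time, so recovery is never decided by a coin-flip at the
boundary. Optional knobs plant coverage gaps (species without primer
sites) and QC casualties (25-nt `N` runs), with 50%-GC backgrounds of
3 kb per genome by default — long enough to exercise the scanners, small
enough to keep tests fast.

What the generator deliberately does **not** emulate: multiple rRNA
operon copies per genome, indel divergence, chimeric amplicons, primer
mismatch tolerance, and realistic 16S base composition or phylogenetic
correlation. Passing recovery tests therefore demonstrates that the
pipeline's bookkeeping (matching, windowing, collapsing, aligning,
filtering, counting) is exact under the stated model — not that the
biological conclusions for any real community are reproduced. Indel
robustness is exercised separately by the alignment oracles, without
exact ground truth.

The ground truth's expected summary is computed with independent plain
arithmetic (union-find components, degree counts), never by calling the
pipeline's own matrix/summary code, so end-to-end tests compare two
separate routes. The test suite runs 20 seeded communities of 6–34
species across four design families (including zero-edge and
QC-casualty designs) and requires exact recovery of the edge set,
component sizes and every summary field; these sizes keep the whole
suite under half a minute while covering every code path.

# The synthetic 16S reference

The packaged catalog places primers by coordinates on the *E. coli* 16S
rRNA gene. To support coordinate-recovery checks without network access,
`synthetic_reference_16s()` builds a 1542-nt reference by intersecting
the base-set constraints of every cataloged primer with defined
positions (forward primers anchored at their first position, reverse
complements of reverse primers anchored at their last) and filling the
unconstrained positions with seeded random bases, resampling if the fill
creates a spurious site. All overlapping catalog constraints are
mutually consistent, so the construction is exact. This object is a
**synthetic stand-in**: it reproduces the catalog's positional geometry
(KP_F078 at 514, KP_F078–OP_R010 → 291 bp, KP_F034–KP_R065 → 1504 bp,
OP_F053–KP_R020 → 347 bp), not the true gene sequence, and supports no
biological inference.

# Design choices made where the design was open

* **Exact DP instead of a seeded heuristic** for alignment: at desk
  scale the exact optimum is affordable, and it makes the qcovs/pident
  contract provable rather than approximate. The heuristic's gap
  parameters beyond reward/penalty are not standardised; the linear gap
  cost is recorded and configurable.
* **Catalog quirks preserved**: a few catalog rows carry printed
  coordinate inconsistencies (a reverse primer whose span is one short
  of its length; a forward-primer last position from another row).
  Validation deliberately checks only the forward-first/reverse-last
  arithmetic that defines amplicon lengths, and preserves the rest as
  shipped.
* **All F×R combinations emitted** when primers match multiple loci;
  nested amplicons are real sequences a PCR could in principle produce,
  and the variant collapse keeps the output canonical.
* **Genome-side ambiguity matches only the identical code** (see
  above); the alternative — wildcard genome ambiguity — would count
  unsupported sites as detections.
* **Amplicons carry both primer sequences** (inclusive span). Since all
  amplicons of a primer pair share near-identical primer flanks, this
  slightly raises pairwise identity relative to core-only comparison;
  it matches the catalog length convention and affects all pairs
  equally.
* **No shell entry point**: the package's functions (`asi_screen()`,
  `run_all()`) and the scripts are the interface; a YAML config drives
  file-based runs.

# Known limitations

* All-vs-all alignment is quadratic in the number of variants per primer
  pair; the exact aligner targets catalogs and communities of hundreds
  of amplicons, not de-novo read sets.
* The 97% relation is assessed on one randomly chosen representative
  alignment per species pair; alignment statistics other than the
  edge itself (e.g. recorded pident) therefore vary with the seed.
* `pident` near the threshold depends on the gap model at high
  divergence; decisions are only guaranteed stable for the ≥0.5-point
  margins the synthetic designs enforce (small penalty perturbations,
  ±1, are covered by tests in exactly this regime).
* Species identifiers are dataset-relative (metadata order), so `SPn`
  labels are not comparable across different genome collections.
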