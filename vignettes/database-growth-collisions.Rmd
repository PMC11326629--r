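---
title: "Quantifying interspecies sequence collisions in growing marker-gene databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interspecies sequence collisions in growing marker-gene databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcollide)
```

## The problem

Marker genes — the 16S rRNA gene and panels of universal single-copy
protein-coding genes — are used as proxies for an organism's species
identity. That use rests on an assumption: that sequences from different
species are distinguishable at a species-proxy identity threshold (95, 97,
99 or 100% identity, depending on convention). As reference databases grow,
that assumption degrades: more and more sequence pairs from *different*
species are identical or nearly identical, so clusters built at those
thresholds increasingly mix species. We call a cluster containing sequences
labeled with two or more distinct species a **multi-species cluster**
(MSC); sequences from distinct species similar enough to co-cluster are
**interspecies sequence collisions**. At 100% identity an MSC means that
byte-identical sequences carry divergent species labels, so *no* sequence
feature can separate them.

`seqcollide` measures this degradation as a function of database size. The
procedure:

1. **Filter** the database: remove records with incomplete taxonomic labels
   or organelle (mitochondrial/plastid) lineages, and records whose length
   is below half or above twice the mean length of their marker family
   (likely annotation artifacts).
2. **Simulate database growth**: draw random subsets of each marker
   family's records over a size grid (e.g. 1,000–5,000 sequences in
   1,000-sequence steps), with bootstrap replication.
3. **Cluster** each simulated database at several identity thresholds with
   a greedy incremental clusterer requiring that the shorter sequence align
   fully to the longer one.
4. **Count** multi-species clusters, the sequences and species in them, the
   species pairs that co-occur, and the relation between a genus' species
   richness and its collision involvement.
5. **Fit** the power law \(Y = cX^m\) (ordinary least squares of
   \(\log Y\) on \(\log X\)), where \(X\) is database size and \(Y\) the
   number of sequences in multi-species clusters. The exponent \(m\) is the
   *rate* of resolution loss; \(m > 1\) is super-linear growth.

Because the real reference databases require large downloads and external
gene predictors, the package ships a synthetic database generator with
fully known taxonomy and *planted* collision structure; every downstream
stage is validated against that ground truth.

## The clustering model

Records are sorted by length descending (ties broken lexicographically by
sequence and then by record id, making the output a function of the input
multiset only). Each record either joins the first existing cluster — in
cluster-creation order — whose representative it meets at or above the
identity threshold, or founds a new cluster. This mirrors the classic
greedy incremental scheme of tools like CD-HIT; we match the *contract*
(representatives are maximal-length; members meet the threshold against
their representative; no representative meets the threshold against an
earlier representative), not any particular tool's heuristics, word sizes
or output.

**Identity convention.** For a shorter sequence \(S\) and longer \(L\),
identity is computed from the best end-gap-free alignment of \(S\) against
\(L\) (end gaps on \(L\) are free, so containment is legal):

\[\mathrm{identity}(S, L) = \frac{\max(\text{matches} - \text{internal gap
columns},\, 0)}{|S|}.\]

Mismatches contribute zero; every internal gap column is penalised one
match-equivalent. The penalty matters: if gap columns were free, the
optimum would degenerate to the longest common *subsequence* and identity
1.0 would no longer mean contiguous containment. Under this convention
`identity == 1` exactly when \(S\) is a substring of \(L\), which is also
what the 100%-threshold fast path computes by direct string search.
Sequences are opaque strings: nucleotide, protein and ambiguity codes are
compared verbatim, and the denominator is always the shorter sequence's
length.

Two performance devices never change results: a conservative shared 8-mer
screen (an alignment at threshold \(t\) forces at least
\(t|S| - ((1-t)|S| + 1)(k-1)\) of \(S\)'s \(k\)-mers to occur verbatim in
\(L\), so counting below that bound proves the pair cannot reach \(t\));
and a banded dynamic program for the join decision (any alignment scoring
\(\geq t|S|\) has at most \((1-t)|S|\) gap columns, which confines its path
to a provable diagonal band). Both are property-tested against the full
dynamic program, and `verify_clustering()` re-checks every promise of a
clustering by brute force without either device.

## The synthetic generator

`synthetic_config()` describes a community: genera containing species,
species containing genomes, and per-genome marker genes. Evolution is
per-site substitution only (Jukes–Cantor-like uniform replacement with one
of the three other bases, no indels): each genus has one random ancestral
gene per family; each species' gene derives from it at
`inter_species_divergence` expected substitutions per site; each genome
copy derives from the species gene at `intra_species_divergence`. The
identity-threshold analysis only sees substitution distance, so indel
realism would add nothing testable; length variation instead enters through
*artifact* records (truncations to a quarter, or tandem-duplication-like
elongations to four times the family mean, at `artifact_rate`), which is
exactly the class of record the half-to-twice length filter exists to
remove.

Interspecies divergence can be made heterogeneous with
`divergence_spread`: each species' branch divergence is multiplied by a
uniform draw from `[1 - spread, 1 + spread]` (mean divergence unchanged).
This matters whenever the divergence scale sits near a clustering
threshold. With every species pair at exactly the same expected identity,
an entire genus can straddle a threshold knife-edge, and cluster
composition at that threshold becomes unstable in a way no real database
is: in real genera some congener pairs are nearly identical while others
are clearly separated, so each pair is firmly inside or firmly outside a
given threshold. The default spread is 0 (exact, homogeneous divergence —
the right setting for analytically predictable tests); the Listeria-like
preset uses 0.8.

Collisions are planted *verbatim*: with probability `collision_rate` a
species' gene for a family is replaced byte-for-byte by the gene of a
previously generated congener, and the event is recorded in the ground
truth. Verbatim (rather than near-identity) planting makes the expected
number of multi-species clusters at the 100% threshold exactly enumerable.
A single RNG stream per `generate_synthetic_db()` call is consumed in a
fixed documented order (structure counts → per-genus ancestral genes →
per-species divergence/collision draws → per-genome copy and artifact
draws), so identical configurations are byte-identical.

`listeria_like_config()` encodes the deeply sampled single-genus case used
throughout the tests: 34 species, 5,014 genomes by default with 4,439 in
one dominant species (the *Listeria monocytogenes* pattern in RefSeq), and
very low interspecies divergence — 0.5% expected substitutions per site
with spread 0.8, and 0.2% within species — so pairwise interspecies
identities range roughly 98.2–99.8%: congeneric *Listeria* marker genes
sit at or above the species-proxy identity thresholds, which is precisely
why the genus loses resolution as sampling deepens. The default
marker family is a single-copy, 450 nt ribosomal-protein-like gene; an
optional 16S-like family is multi-copy (1–9 copies per genome, mean
1,550 nt). Where the growth experiments need at least 5,000 records *after*
filtering, a run generates a small surplus of genomes (5,100), since the
length filter removes the planted artifact records from the pool.

**What the generator does not emulate:** real divergence distributions of
curated databases (unknown, and not published), phylogenetic tree
structure, chimeras, sequencing error, codon structure, and taxonomic
mislabeling beyond the planted verbatim collisions. Passing tests
therefore demonstrate that the pipeline measures collision structure
correctly where the truth is known — not that any particular real database
has a particular collision rate.

## Filters and their conventions

* **Taxonomy**: a record is dropped when its lineage is incomplete for its
  dialect, or contains an organelle keyword (case-insensitive
  `mitochondri*`, `chloroplast`, `plastid`) at any rank. SILVA-style
  headers require all seven ranks (domain through species); GTDB-style
  headers carry only a `marker=` field and an `s__Genus species` binomial,
  so completeness there means a well-formed binomial (a seven-rank test
  would discard every GTDB record). Organelle keywords are matched against
  the lineage rather than a curated accession list so the filter is
  reproducible without external resources. Placeholder species labels
  ("uncultured" and kin) can optionally be treated as incomplete; the
  default keeps them, since operationalizations differ between databases.
* **Length**: per family, the arithmetic mean length is computed once on
  the unfiltered records and the band `[mean/2, 2*mean]` applied in a
  single pass. Whether such filters should iterate is ambiguous; a single
  pass is deterministic and is what the filter report documents. Records
  near the band edge of a family whose mean was dragged by extreme
  artifacts are thus judged against the pre-filter mean.
* Species identity is the full binomial string; genus is the genus-rank
  string (derived from the binomial in the GTDB dialect). Counts are over
  *records*: the source databases are deliberately not deduplicated, so
  identical sequences from one species each count — this inflates
  sequences-in-MSC counts relative to a unique-sequence convention, and is
  intentional.

## Subsampling and seeds

Subsets are drawn uniformly without replacement from a family's records.
Each subset's RNG seed is a platform-stable polynomial hash of
`(master seed, family, size, replicate)`, so any subset is reproducible in
isolation and evaluation order cannot affect results. By default each size
is drawn independently (matching the notion of independent random subsets);
`nested = TRUE` instead slices prefixes of one permutation per replicate,
which reduces growth-curve variance but changes the estimand slightly and
is therefore opt-in. Sizes exceeding a family's record count are skipped
and reported, never silently shrunk.

## Statistics and the rate fit

Per clustering, `collision_summary()` reports cluster counts, MSC counts,
sequences in MSCs, and the percentage of species involved; the species
universe for the percentage is the species present in that simulated
database, not the full source (each size's percentage is then comparable
across sizes). Species-pair counts increment once per cluster per
unordered pair — a cluster with species {A, B, C} yields one count each
for (A,B), (A,C), (B,C) — a scale-invariant convention preferable to
per-sequence-pair counting, which would square with cluster size. The
genus-richness relation is computed on one designated clustering (by
convention the largest size, first replicate: the final iteration of the
growth experiment), with a Pearson correlation; fewer than three species
or zero variance are reported as undefined rather than coerced to a
number.

Replicates are aggregated by the median (the reporting convention for the
growth curves), with means and quartiles also emitted. `fit_rate()`
regresses \(\log Y\) on \(\log X\) with `stats::lm`; points with \(Y = 0\)
are excluded and counted rather than patched with a pseudocount — an
arbitrary constant would bias \(m\), while exclusion is transparent.
Natural logs are used internally; \(m\) is base-invariant. Fits with fewer
than two distinct positive-\(Y\) sizes are reported undefined. `fit_all()`
fits per (marker, threshold) on the per-size medians by default, with an
all-replicate-points mode for variance inspection.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run the single-genus growth
experiment at 1,000–5,000 sequences in 1,000-sequence steps with 10
bootstrap replicates on the 450 nt single-copy family — sizes chosen so a
full run completes in minutes on one core while the growth trend and the
super-linear rate remain clearly measurable. The replicate count and the
grid are configuration, not constants: `run_config()` accepts the
200,000-sequence, 100-replicate scale directly. Contract verification uses
at least 100 random instances of up to 200 sequences (lengths 50–500) at
all four thresholds, against the brute-force verifier.

## Known limitations

* The greedy join rule is first-eligible, not best-matching; as in the
  tools it mirrors, cluster composition near a threshold boundary can
  depend on cluster-creation order (the order itself is deterministic
  here).
* Cluster membership at 100% is containment into the representative, not
  transitive closure: two short sequences can each be substrings of a long
  representative without being substrings of each other. Byte-identical
  sequences always co-cluster.
* The identity convention (shorter-sequence denominator, gap = mismatch
  plus one) is one of several in circulation; comparisons with tools using
  alignment-length denominators will differ near thresholds.
* The power-law model is assumed, not selected: saturating alternatives
  are out of scope, and \(R^2\) in log-log space is the only diagnostic
  reported.
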