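---
title: "Metaproteomic spectral-count analysis with protein metaclusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaproteomic spectral-count analysis with protein metaclusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapep)
```

## The analysis model

`metapep` analyses shotgun metaproteomics of microbial communities
quantified by spectral counting: the abundance proxy for any feature
(peptide, protein group, metacluster, taxon) is the number of tandem-MS
spectra assigned to it. The pipeline assumes its inputs are (a) a
multi-organism protein database whose headers carry accession, gene
name, UniRef50 cluster id, a four-rank lineage
(family → genus → species → strain) and decoy/host flags, and (b) PSM
tables listing, per identified spectrum, the stripped peptide sequence,
every database protein containing that tryptic peptide, and a search
score. All counting is per peptide *sequence*: modification tags are
stripped on input, because post-translational variants of one sequence
carry no extra taxonomic or functional information at this resolution.

### Decoy-based FDR filtering

A PSM is a decoy hit when every matched accession is a decoy (reversed
sequence). Scanning score cutoffs from high to low, the filter keeps
the lowest cutoff at which the estimated FDR among surviving PSMs,
$d/\max(t,1)$, is at or below the target (default 1.6%), maximising
the retained set; surviving decoy hits are then discarded. The simple
ratio estimator is the conservative classical choice; the concatenated
estimator $2d/(t+d)$ is available via `estimator = "concatenated"`.
Filtering is applied at the PSM level. The protein-level decoy rate at
the chosen threshold (distinct decoy accessions hit, relative to
reported groups) is recorded in the run manifest; it is substantially
higher than the PSM-level rate — the familiar inflation of
identification error when aggregating to proteins — and a probabilistic
protein-posterior model that would control it directly is out of scope.
If no threshold achieves the target, the filter returns an empty
retained set with a warning rather than an error, so drivers can report
an empty run.

### Parsimony protein inference

The reported protein list is the simplest explanation of the retained
peptides, derived in three deterministic steps: (1) proteins with
identical observed-peptide sets merge into one indistinguishable group;
(2) groups whose peptide set is a strict subset of another group's are
removed — their peptides remain explained; (3) a greedy set cover
(largest number of still-uncovered peptides first, ties broken by the
lexicographically smallest member accession) selects the reported
groups. Greedy cover is not guaranteed minimal; the test suite checks
it stays within one group of an exhaustive minimal cover on random
instances of up to 10 proteins. Shared peptides count once in every
reported group containing them; unique-peptide counts (peptides in
exactly one group) are tallied separately, and the rank profiles below
handle uniqueness per level.

### Metaclustering

Two protein groups are related when any members share a characterized
gene name (case-insensitive), when their peptide sets intersect, or
when any members share a UniRef50 id. Metaclusters are the connected
components under the union of the three relations — "and/or" is read as
transitive closure, because mixed chains (gene edge, then UniRef edge)
are unavoidable and a single partition of the groups is required.
Because shared-peptide edges are absorbed into components, the
peptide → metacluster map is a function, column sums of the metacluster
count matrix equal the number of retained spectra, and the accounting
strata are disjoint. Three further choices:

* A gene name counts as *characterized* (useful annotation) when
  non-empty and not matching the locus-tag pattern
  `^[A-Z]{1,4}_?\d{3,}$` (configurable); locus tags neither form gene
  edges nor count as annotation.
* Host and microbial groups are clustered in separate strata, so host
  evidence can never bridge bacterial clusters; a metacluster mixing
  host and microbial members is a hard error in the accounting step.
* "Shared peptide evidence" means any intersection (minimum
  intersection size configurable via `min_shared_peptides`).

In the original eight-infant cohort this accounting reported 1033
annotated + 889 unannotated bacterial metaclusters (1922) plus 212 host
metaclusters, i.e. a strata total of 2134, while the same study's
summary elsewhere states 2154; the package reports strata sums and
flags the 20-cluster discrepancy here rather than choosing a side.

### Per-rank taxonomic profiles

A peptide is unique at a rank iff the set of rank-level taxa of all
non-decoy database proteins containing it has size one; uniqueness is
evaluated independently at each rank, and against the full non-decoy
database, not merely the parsimonious list — possible assignment, not
reported assignment, is what makes a peptide taxon-specific. Uniqueness
at a rank implies uniqueness at every coarser rank, so per-subject
totals grow monotonically from strain to family (asserted on every
synthetic run). Host peptides are excluded from microbial matrices and
reported as a separate QC channel. Downstream conveniences follow the
field's reporting habits: strain detection tiers at ≥1/≥2/≥5 unique
spectra, species roll-ups by summing strain counts (optionally
restricted to one genus and normalized to fractions), and an abundant
strain filter keeping strains with at least 20 spectra (default) in at
least one subject.

### Community and pathway comparisons

The proteomics-vs-16S comparison aligns the two genus × subject
matrices on shared subjects and the union of taxa (zeros for taxa one
method misses), flattens the cells and reports Spearman (average ranks
on ties) and Pearson coefficients on raw counts; the pairing scheme is
a package choice, as is excluding the "unknown/others" remainder row
that `heatmap_matrix()` appends. Genera whose assignment differs
systematically between methods (the Enterobacteriaceae genera) can be
collapsed into one family row first. Pairwise subject comparisons use
Pearson $r^2$ over metaclusters detected in at least one of the two
subjects (union support), on raw counts (a `log1p` option exists);
fewer than three supporting features is an error, as the correlation
would be meaningless.

For pathway contrasts, metacluster counts are first deduplicated at
the genus level: within a metacluster, each spectrum contributes once
per distinct *genus* whose member proteins contain its peptide, rather
than once per protein. An alternative reading — collapsing
genus-duplicate metaclusters — exists; the within-metacluster
deduplication implemented here is the more local operation and never
exceeds the per-protein redundant count. Only metaclusters with useful
annotation join pathways, via case-insensitive gene-name lookup in a
packaged gene-to-pathway table (a local join; no web service). The
verdict rule is invented, since no published criterion exists: a
pathway is "higher" in the treated subject when the treated count
exceeds the untreated mean + 1 SD (SD with $n-1$ denominator over
untreated subjects) for a strict majority of members, "lower"
symmetrically, else "equivalent"; both the band and the majority
threshold are arguments.

## The synthetic community generator

The generator is first-class, tested code; its defaults encode the
study conditions the package validates against. `infant_community()`
builds an eight-subject cohort (ids C, T, B, P, M, N, E, R): a
*Bifidobacterium*-dominated majority with subject-specific species
mixes over four species × two strains, identical profiles for the twin
pair M and N, an Enterobacteriaceae-dominated antibiotic subject R
(*Klebsiella*/*Escherichia*/*Citrobacter*), host spectra at 18% of
depth, a 1% decoy hit rate, and lognormal 16S noise with SD 0.25 on
the log scale.

Proteomes are organised into UniRef50-like homolog families: each
family has a random template sequence (200–320 residues) and members
are point-mutated copies (3% per-residue substitution, well above the
80% identity floor), so tryptic peptides are frequently shared within
families — the structure metaclustering exploits. Families are homed in
genera with probability proportional to the genus' strain count (every
genus hosts at least one family), 30% of families span genera, and 60%
of families carry a characterized gene name shared by all members;
unannotated families get a locus tag or nothing. Genus gene pools give
*Bifidobacterium* a urea-cycle/nitrogen repertoire and the
Enterobacteriaceae genera a fatty-acid-biosynthesis repertoire, while
cross-genus families carry TCA-cycle genes — this is what lets the
pathway contrast reproduce the expected higher/lower pattern for the
antibiotic subject. Decoys are whole-sequence reversals, one per
target record, the convention implied by a reversed decoy database.
Host proteins form their own *Homo sapiens* lineage branch so every
pipeline stage treats host uniformly as a taxon.

Spectral sampling draws, per subject, `depth` spectra: decoy-only
noise with probability `decoy_hit_rate`, otherwise host with
probability `host_spectrum_fraction`, otherwise a strain by abundance,
a protein uniformly within the strain, and a tryptic peptide (trypsin,
up to 2 missed cleavages, length 6–30) uniformly within the protein.
Matched accessions are exact tryptic-peptide membership across the
whole database — mirroring how search engines assign shared peptides —
so sharing arises only through sequence homology. Scores are Gaussian
(targets N(60, 6), decoys N(40, 6)); no published score model exists,
and only the ordering and overlap of the two distributions matter to
the FDR filter.

What the generator does *not* emulate: real mass spectra, retention
times or m/z values; modified peptides; chimeric 16S reads;
database-incompleteness effects (every sampled peptide exists in the
database); and realistic database scale (hundreds, not millions, of
proteins). Passing tests therefore demonstrate the correctness of the
algorithms under the assumed data structure, not search-engine
behaviour on real spectra.

## Numerical and reproducibility choices

All randomness flows through explicit integer seeds, restored after
use, and identical spec + seed yields byte-identical FASTA/TSV/JSON
outputs (asserted in the suite). Deterministic tie-breaks: greedy
cover ties by smallest accession; metacluster ids ordered by smallest
member accession. TSVs are UTF-8, tab-separated, unquoted, with tabs
forbidden inside fields. Degenerate inputs are handled explicitly: an
all-decoy PSM table yields an empty retained set (warning, not error);
a zero-PSM run writes an all-zero accounting table; constant vectors
make correlations an error rather than NaN. Abundance profiles must
sum to one within 1e-9.

Problem sizes in the shipped tests and acceptance script are chosen to
exercise the statistics at desk scale: the default preset runs at
3,000 spectra per subject over a 19-strain, ~250-record database;
parameter-recovery checks run one deep simulation at 20,000 spectra
per subject; the twin-ordering property uses 100 seeded replicates at
1,200 spectra per subject against a fixed database. The ±2-percentage-
point genus recovery check is run without cross-genus homology
(`cross_genus_fraction = 0`), since cross-genus families make a
(truth-dependent) fraction of spectra genus-shared, biasing
genus-unique profiles by several points — with homology present the
recovery criterion is the rank correlation (Spearman ≥ 0.9), which is
robust to that bias.

## Known limitations

Real-data headline numbers from the original cohort (e.g. cross-method
correlations of 0.719/0.795 and twin $r^2$ of 0.84) depended on the
deposited raw data and a 2014 database snapshot and are not
reproducible at desk scale; the package reproduces the study's
arithmetic identities exactly and its qualitative contrasts
(twins > unrelated > antibiotic; fatty-acid up / urea down in the
treated subject) on synthetic cohorts. Shared peptides are never
fractionally allocated (no LCA-style splitting); spectral counts are
not normalized by protein length or proteome size; and the pathway
verdict rule is a descriptive classification, not a statistical test —
no p-values are attached, by design.
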