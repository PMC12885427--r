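---
title: "Methods: from panning reads to candidate nanobodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from panning reads to candidate nanobodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panvhh)
```

`panvhh` turns paired amplicon reads from a nanobody (VHH) biopanning
campaign into a ranked list of candidate binders. This vignette documents
the model behind each stage, the parameters that matter, the numerical
conventions, and what the built-in simulator does and does not emulate.

## The underlying model

Biopanning is iterative selection: clones that bind the antigen survive
each round and are amplified; non-binders wash away. Sequencing round zero
(the pre-selection library) and each subsequent round yields per-clone
counts whose round-on-round growth identifies binders. Two modelling
commitments follow:

* **The CDR3 is the clone key.** Nanobody specificity is dominated by the
  third complementarity-determining region, so reads are collapsed to
  clones by CDR3 amino-acid sequence. Nucleotide-level synonyms pool their
  counts; distinct CDR3 proteins are distinct clones.
* **Abundance is compositional.** Each sample is a multinomial draw from
  clone frequencies, so counts are normalised to counts per million (CPM)
  before any cross-sample comparison, and enrichment is a fold change of
  CPM, not of counts.

## Preprocessing

Read pairs are merged by scanning candidate overlaps between `min_overlap`
(10 bp) and `max_overlap` (250 bp) and choosing the overlap with the lowest
mismatch density, ties going to the longer overlap; the pair merges when
that density is at most `max_mismatch_density` (0.25). The 250 bp cap
prevents adapter dimers from masquerading as fully-overlapping fragments on
2×300 bp chemistry. At each overlap disagreement the higher-Phred base
wins, ties going to read 1. Unmerged pairs are dropped: only full-length
nanobody sequences continue. With 300 bp reads the mergeable fragment range
is 350–550 bp, which brackets the ~360–410 bp of a VHH amplicon.

"Exact reconstruction" of a fragment from an error-carrying pair is judged
against the quality-aware consensus of the true alignment: errors in the
region covered by only one mate are unfixable by any merger, so the merger
is held to choosing the right overlap and resolving every disagreement
toward the higher-quality base.

Single-read mode (a samplesheet row with no `r2`) bypasses merging, so
pre-merged, Sanger or long reads enter the same downstream path.

## Annotation

Annotation is anchor-based rather than alignment-to-germline:

1. **Survey.** `survey_size` (1000) reads are sampled without replacement
   (seeded, default 0) and matched against every V-gene reference at an
   edit budget of `v_error_rate` (20%) of the reference length, both
   strands. The `num_v_genes` (15) most frequently hit references are kept.
   The survey matches the *full* reference; the 20% budget is generous
   enough that the cysteine-containing tail does not change the ranking.
   This shortcut assumes an enriched panning library uses few V genes — it
   is explicitly not a general repertoire annotator.
2. **Cysteine trim.** Each shortlisted reference is truncated immediately
   before its last in-frame TGT/TGC codon — the conserved cysteine that
   precedes CDR3. References with no in-frame cysteine are dropped with a
   warning.
3. **Excision.** Each read is matched against every trimmed reference at an
   edit budget of `anchor_error_rate` (30%) of the trimmed length, both
   strands, and reoriented to the V strand. The FWR4 anchor is then matched
   (same 30% rate) downstream of the cysteine codon that follows the V-gene
   hit. The CDR3 is everything strictly between that cysteine codon and the
   FWR4 match start — the IMGT-style junction convention: the conserved
   cysteine itself is *not* part of the CDR3. The full sequence runs from
   the V-gene match start through the FWR4 match end and is translated in
   the V-gene frame.
4. **Productivity.** A read is productive when its full translation has no
   stop codon, its CDR3 length is a multiple of three, and the CDR3
   translation is a substring of the full translation (the frame-agreement
   check). Codons containing N translate to `X`, and `X` never matches in
   the substring check, so N-contaminated CDR3s are unproductive. Edit
   budgets are `ceiling(rate × pattern length)` — rates in the interface,
   absolute budgets internally.

Approximate matching is semi-global (pattern global, text local) Levenshtein
matching. The exported `approximate_match()` is a full dynamic program with
deterministic tie-breaks (fewest edits, then leftmost start, then shortest
span). The annotation hot path uses a blocked bit-parallel (Myers) variant
that returns the same minimal edit count with the leftmost end, recovering
the start by a reverse pass; the two implementations are property-tested
against each other and against an independent DP oracle. `N` never matches
anything, including another `N`.

## Quantification and enrichment

Within each sample, clones with a count of exactly 1 are removed before
normalisation — a single read supporting a CDR3 is more likely a sequencing
error than a real clone — and the CPM denominator runs over the retained
clones only. Enrichment for every clone still present (count > 1) at a
pan's final round is

$$\mathrm{logFC} = \log_2 \frac{\mathrm{CPM}_{final} + 10}{\mathrm{CPM}_{round\,0} + 10}$$

with `pseudocount` = 10 CPM damping the fold changes of lowly abundant
clones whose counts are unreliable. A clone is enriched when logFC ≥
`enrich_logfc` (1.5; the threshold is inclusive). With replicates the fold
change is computed per replicate (each against its own round-zero sample
when present, else the mean round-zero CPM) and at the combined CPM level;
`replicate_combine` chooses the combiner (mean by default, max exposed
because the right summary for heterogeneous replicates is genuinely
unsettled).

A consequence worth knowing: sequencing errors mint low-count CDR3 variants
that are absent at round zero, and a variant seen twice at the final round
already reaches logFC ≈ 1.58. Clone-level enrichment calls therefore
contain a cloud of error-derived false positives by construction. The
100-CPM cluster floor downstream is the mechanism that absorbs them — they
ride along only when they cluster with a genuinely abundant parent.

## Clustering, embedding, selection

Enriched clones are clustered greedily: sorted by final-round CPM
(descending; ties longer-then-lexicographic), each clone joins the first
cluster whose *representative* passes both `cluster_identity` (0.80) and
`cluster_length_ratio` (0.80, as min/max length), else founds a cluster.
Identity is identical aligned positions under a match-maximising global
alignment, divided by the shorter length — the convention of
greedy-incremental clustering tools, adopted because the cited defaults
name "80%" without defining the denominator. Because abundance ordering is
total and the joining rule consults representatives only, the clustering is
deterministic, and every member is guaranteed ≥ 80% identity to its
representative (re-verified post hoc in the tests by an independent
oracle). Word-filter speedups of the classical tools are deliberately
omitted: inputs here are hundreds of sequences, and the exact scan
guarantees identical assignments.

Clusters whose summed final-round CPM (replicate-mean) falls below
`min_cluster_cpm` (100) are discarded as empirically likely false
positives. Representatives of the survivors are aligned all-vs-all with
BLOSUM62, gap open −10, gap extension −1 (a length-L gap costs 10 + L).
The resulting similarity matrix is embedded by principal components of its
centred rows — the score matrix itself, not a distance transform, is
decomposed, matching the use of a PCA routine on the raw all-vs-all result;
whether a distance transform would be preferable is an open question we
resolved in favour of the simpler, reported behaviour. Axis signs follow a
fixed convention (largest-magnitude loading positive) so embeddings are
reproducible. The cladogram is average-linkage clustering on
`max(S) − S[i, j]`, written as Newick; by default it covers the
final-round-abundance-ranked representatives.

The top-`top_n` (100) list is drawn in three tiers: one pick — the
cluster's most abundant clone — per *priority* cluster (max logFC >
`priority_logfc` = 2.5, or final CPM > `priority_cpm` = 1000 (both strict,
"greater than"), or CPM non-decreasing across all sequenced rounds with
final > round zero, our formalisation of "consistently increasing");
then one pick per remaining cluster; then further members of
already-selected clusters by CPM until the list fills. Within tiers,
clusters are ordered by number of replicates enriched (descending), then
final CPM, then representative lexicographically — replicate support
deliberately dominates abundance, synthesising the two stated priorities.
Ranking priority clusters by CPM rather than logFC is a design choice
(abundance is the quantity the intra-cluster pick already uses); both
orderings are defensible.

## Multi-pan comparison

For overlap and subtraction analyses, all clones enriched in *any* pan are
pooled and re-clustered at the same identity threshold, so similar but
non-identical clones selected in different pans land in one pooled cluster.
Cluster membership (which pans contributed a member) defines the overlap
classes — the data of an UpSet plot — and subtraction retains clusters
whose membership includes the target pan and excludes every subtracted pan.

## The simulator

`simulate_library()` builds clones as V-gene body (96 codons) + conserved
cysteine codon + random stop-free CDR3 (8–20 aa) + FWR4 anchor
(WGQGTQVTVSS, 33 nt) + 12 nt constant tail: ~360–410 bp, so 2×300 bp pairs
overlap by ~190–240 bp, inside the 250 bp cap. Initial frequencies are
log-normal (σ = 1), the skewed clone-size distribution typical of panning
libraries. Binders multiply their frequency by `enrichment_factor` each
round (multiplicative selection, then renormalisation); counts are
multinomial at `depth_per_round`; substitution errors are applied per
fragment at `subst_error_rate` before splitting into mates, so a read
pair's overlap is internally consistent and each read has a well-defined
true CDR3. Replicates are independent multinomial draws, optionally with
replicate-specific factors.

What the simulator does **not** emulate: indel sequencing errors,
position-dependent quality profiles, phage amplification bias (the
library-preparation protocol this pipeline accompanies is PCR-free),
chimeric reads, and cross-round carry-over. Passing tests on simulated data
therefore demonstrate the correctness of the computational chain under a
clean substitution-error model, not robustness to indel-heavy platforms.

Default simulation conditions (1000 clones, 50 binders at factor 4, 3
rounds + round zero, 100,000 reads per round, 0.5% error, 5 V genes) are
the package's reference campaign; the test suite and `scripts/acceptance.R`
run it at exactly this scale, with smaller configurations for unit-level
checks.

## Numerical conventions and degenerate inputs

* CPM columns sum to 1,000,000 within 1e-3 per sample (floating-point
  summation is the only slack).
* `approximate_match()` ties: fewest edits, leftmost start, shortest span.
  Merge ties: longer overlap; equal-quality disagreements: read 1.
  Survey ties: reference input order. Selection ties: lexicographic
  representative.
* Empty inputs: an empty FASTQ is an empty tibble; a pan with no enriched
  clones yields empty cluster/selection tables and a warning; fewer than
  two replicates yields an empty concordance table (not an error); a
  samplesheet pan without a round-zero entry is an error at parse time.
* MDS requires `n_components` < number of labels; cladograms require ≥ 2
  labels; both error informatively below that.
* Report rendering is pure: the same campaign renders to byte-identical
  HTML (figures are embedded base64 PNG).

## Known limitations

The annotator assumes enriched, low-V-gene-diversity panning output and a
single configurable FWR4 anchor; it is not a general repertoire annotation
tool and does not delineate FR1–FR3/CDR1–CDR2. Enrichment is a point
estimate without a variance model — replicate support, not a test
statistic, is the robustness mechanism. Clone keys are CDR3 amino-acid
sequences, so CDR1/CDR2 variants sharing a CDR3 are pooled. V-gene calls on
reads are best-effort anchors for excision, not allele-level assignments.
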