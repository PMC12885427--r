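# panvhh

Analysis of nanobody (VHH) phage-display panning campaigns from
next-generation sequencing data.

## The problem

Nanobodies are selected from large display libraries by biopanning:
repeated rounds of binding, washing and amplification against a target
antigen. Sequencing the library before selection ("round zero") and after
each round profiles the whole selection process, but turning hundreds of
thousands of raw amplicon read pairs into a shortlist of candidate binders
requires a chain of specialised steps. `panvhh` implements that chain
end-to-end, for bench scientists and bioinformaticians running panning
campaigns:

1. **Preprocess** — paired 2×300 bp reads are adapter-trimmed and merged by
   overlap (maximum overlap 250 bp, mismatch-density scoring,
   disagreements resolved toward the higher Phred base).
2. **Annotate** — an error-tolerant annotator surveys 1000 reads to find
   the most common V genes (matched at a 20% error rate against a germline
   reference the user supplies), trims each to just before its last
   conserved cysteine, then locates the V gene and an FWR4 anchor in every
   read (30% error rate, both strands, bit-parallel approximate matching)
   and excises the CDR3 between the conserved cysteine and FWR4. Reads
   with stop codons or an out-of-frame CDR3 are unproductive.
3. **Quantify** — productive reads collapse into clones keyed by CDR3
   amino-acid sequence; per-sample singletons are removed as likely
   sequencing errors; counts become counts per million (CPM); enrichment
   per clone is the pseudocounted log fold change

   logFC = log2( (final-round CPM + 10) / (round-zero CPM + 10) )

   and clones with logFC ≥ 1.5 are called enriched.
4. **Cluster** — enriched CDR3s are greedy-clustered at 80% identity and
   80% length ratio (most abundant member = representative); clusters
   below 100 CPM at the final round are discarded; representatives are
   aligned all-vs-all (BLOSUM62, gap open −10 / extend −1), embedded by
   MDS and drawn as an average-linkage cladogram.
5. **Select** — a ranked top-100 list, prioritising clusters with
   logFC > 2.5, final CPM > 1000 or consistently increasing abundance,
   ordered by replicate support then abundance, then filled from enriched
   clusters and finally from within selected clusters.
6. **Compare** — multi-pan campaigns pool all enriched clones, re-cluster
   them and classify each pooled cluster by pan membership (cross-reactive
   vs private), with subtraction ("binds X but not Y") on top. Replicated
   pans get all-vs-all CPM concordance tables.

A built-in simulator (`sim_config()`, `simulate_campaign()`) generates
panning campaigns with known ground truth — clone libraries over a V-gene
pool, multiplicative per-round enrichment of designated binders,
multinomial sequencing depth, substitution errors, fragmentation into
overlapping read pairs — so every stage is testable without external data.

All user-facing functions take a data frame first and return tibbles;
results plot with `autoplot()` and summarise with `tidy()`/`glance()`.

## Worked example

Simulate a small campaign (200 clones, 20 binders enriching 4-fold per
round, two selection rounds, 10k reads per round, 0.5% error), then run the
full analysis from the written samplesheet:

```r
library(panvhh)

cfg <- sim_config(n_clones = 200, n_binders = 20, enrichment_factor = 4,
                  rounds = 2, depth_per_round = 10000,
                  subst_error_rate = 0.005, n_v_genes = 3, seed = 42)
sim <- simulate_campaign(cfg, out_dir = "sim_campaign")

campaign <- pan_run(
  file.path("sim_campaign", "samplesheet.csv"),
  v_refs  = file.path("sim_campaign", "v_genes.fasta"),
  fwr4_nt = sim$truth$fwr4_nt,
  out_dir = "results"
)
campaign
#> <pan_campaign> 3 samples, 1 pan(s)
#>   clones retained: 556
#>   enriched clones: 214
#>   pan panA: 37 clusters, top-100 list of 100

glance(campaign)
#> # A tibble: 1 × 6
#>   n_samples n_pans n_clones n_enriched n_clusters n_selected
#>       <int>  <int>    <int>      <int>      <int>      <int>
#> 1         3      1      556        214         37        100
```

556 distinct CDR3 clones survive singleton removal (error-derived variants
inflate this beyond the 200 library clones); 214 clones pass the logFC ≥ 1.5
enrichment call, and after clustering and the 100-CPM floor, 37 clusters
remain, from which a ranked list of 100 candidate sequences is drawn:

```r
head(tidy(campaign), 3)
#> # A tibble: 3 × 6
#>   pan    rank clone               full_aa                       cluster_id tier
#>   <chr> <int> <chr>               <chr>                              <int> <chr>
#> 1 panA      1 APSVSPNQVCNCIPGVWPT LGLVRRGTTPALLVVTRARIQNVSVEDF…          1 prio…
#> 2 panA      2 GEIVNLSGALPCPPSN    LGLVRRGTTPALLVVTRARIQNVSVEDF…          2 prio…
#> 3 panA      3 YRKSPRIVREQSRWIT    RTYPHWGWASLSGLYLVSRTEHRFDLRL…          3 prio…
```

All 20 designated binders are present in the candidate list. `results/`
holds the clone CPM matrix, cluster table, candidate list, MDS coordinates,
Newick cladogram and a self-contained HTML report.

## Command line

A thin CLI over the same functions ships in `inst/cli/panvhh.R`:

```sh
Rscript inst/cli/panvhh.R simulate --out sim --seed 1 --clones 500
Rscript inst/cli/panvhh.R run --samplesheet sim/samplesheet.csv \
    --vref sim/v_genes.fasta --out results
```
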