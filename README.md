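# progeval

Proteogenomic quality control of prokaryotic structural annotation: evaluate
gene callers with mass-spectrometry peptide evidence.

## The problem

Ab initio gene callers (Prodigal, GeneMarkS, Glimmer3 and post-processors
such as GenePRIMP) disagree substantially about where protein-coding genes
start and even whether they exist. Identified peptides give direct,
annotation-independent evidence of translation: a peptide maps onto the
genome wherever its sequence occurs in one of the six translation frames,
and its position relative to a gene call either supports the call or
contradicts it. `progeval` implements this evaluation as a reusable,
fully tested pipeline for anyone comparing prokaryotic gene-call sets —
annotation pipeline maintainers, gene-caller developers, and proteogenomics
groups.

## The method

1. **Peptide mapping.** Each peptide is searched for *exact, unique*
   occurrences across all six translation frames (genetic code 11) of every
   replicon. Peptides with several genomic matches are discarded as
   ambiguous; peptides with none as unmatched.
2. **Support and conflicts.** A mapped peptide *supports* a gene call when
   it lies wholly inside one of the call's CDS fragments on the same strand
   and in the same reading frame. All other mapped peptides *conflict* and
   are labelled by geometry: `overlaps_out_of_frame`, `extends_upstream`,
   `spans_boundary`, or `outside_all`. Per caller,
   `supporting + conflicting = mapped` always holds.
3. **Error classification.** With at least *k* = 2 non-redundant peptides
   (distinct genomic intervals):
   - **wrong** — a call overlapped by peptides that agree with each other
     but not with the call's frame;
   - **short** — in-frame peptides extend 5′ of the annotated start, each
     inside the call's maximal in-frame upstream ORF extension (no in-frame
     stop between peptide and start); the implied interval extends the call
     to the 5′-most peptide;
   - **missed** — peptides in a maximal stop-to-stop ORF containing no
     in-frame call; the ORF is reported as the implied gene.
   Pseudogene-tagged calls whose retained CDS fragments contain ≥ *k*
   confirming in-frame peptides are re-scored as **missed** (the peptides
   refute the pseudogene call); untagged frameshifted calls with confirming
   peptides are good calls. With a per-peptide FDR *q*, the probability
   that *k* independent supporting peptides are all false is *q^k* — at
   *q* = 0.3 % and *k* = 2 this is 9×10⁻⁶ (0.0009 %).
4. **Caller comparison.** Two calls are *identical* only if replicon,
   strand, start and stop all coincide; *stop-consensus* calls share the
   3′-terminal coordinate on the coding strand but differ in start.
   Consensus percentages are reported under each caller's own total.
5. **Synthetic data.** A seeded generator produces replicons with a planted
   truth gene set, caller-specific perturbations (start truncations,
   deletions, wrong-frame calls, pseudogene mis-tags) with a planted-error
   ledger, and in-silico tryptic peptide evidence with configurable
   expression (default 40 % of genes), detection and false-match (default
   0.3 %) rates — so every stage is testable without external data.

## Worked example

Build a benchmark with two synthetic callers (4 deleted genes, 4 truncated
starts, 2 wrong-frame calls planted for `callerA`; 6/6/4 for `callerB`),
then evaluate both from the files on disk:

```r
library(progeval)

b <- make_benchmark("bench_demo", sim_params(genome_length = 50000, n_genes = 40),
  profiles = list(
    error_profile("callerA", n_miss_gene = 4L, n_start_truncate = 4L, n_wrong_frame = 2L),
    error_profile("callerB", n_miss_gene = 6L, n_start_truncate = 6L, n_wrong_frame = 4L)),
  det = detection_params(1, 1, c(6L, 50L), 0), seed = 11)

res <- run_evaluation(b$paths$genome, b$paths$calls, b$paths$peptides,
                      out_dir = "demo_out")
print(res)
#> evaluation_result: 2 callers, 781/781 peptides mapped
#>   callerA: 650 supporting / 131 conflicting; coverage 94.4%
#>   callerB: 582 supporting / 199 conflicting; coverage 88.2%
#>   errors:
#>     callerA missed: 4
#>     callerA short: 4
#>     callerA wrong: 2
#>     callerB missed: 6
#>     callerB short: 6
#>     callerB wrong: 4
print(res$consensus)
#> consensus_summary over 2 callers: callerA, callerB
#>   calls per caller: callerA=36, callerB=34
#>   identical in all: 17 (47.2/50.0% of each caller)
#>   stop-consensus (start varies) in all: 8
#>   unique calls: callerA=19, callerB=17
```

All 781 peptides map uniquely; every planted error is recovered, with the
exact category and count, for both callers. The error table carries the
implied coordinates and the supporting peptides, e.g. for `callerA`:

```r
head(res$errors[, c("category", "caller_id", "gene_id",
                    "implied_start", "implied_end", "n_nonredundant")])
#>   category caller_id  gene_id implied_start implied_end n_nonredundant
#> 1   missed   callerA     <NA>          7457        8345             13
#> 2   missed   callerA     <NA>         22185       22986             19
#> 3   missed   callerA     <NA>         27348       28038             16
#> 4   missed   callerA     <NA>         28054       28975             17
#> 5    short   callerA tgene013         13146       14364              2
#> 6    short   callerA tgene014         14530       15457              4
```

`missed` rows report the implied gene as the maximal stop-to-stop ORF
(`gene_id` is `NA`: there is no call to attach them to); `short` rows name
the truncated call and extend `implied_start` to the 5′-most upstream
peptide. `demo_out/` contains the TSV tables, per-caller conflict GFF3
tracks and a `summary.json` with the same numbers.

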