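# ficcseq

Single-nucleotide mapping of RNA-modification target sites from
truncation-based crosslinking sequencing (FICC-Seq, miCLIP, UV iCLIP),
for people who want to know *which base* an RNA methyltransferase
modifies — here, m5U54 in the T-loop of cytosolic tRNAs — rather than
merely which transcript it binds.

## The method in brief

Covalent enzyme–RNA crosslinks terminate reverse transcription, so the
5' ends of sequenced cDNAs encode the crosslink position. The package
implements the full computational arm of that assay:

* **Read processing** — in-line barcode demultiplexing, UMI extraction,
  unique-mapping filtering, and PCR-duplicate collapsing on the
  (sample, chromosome, strand, 5' position, UMI) key.
* **Crosslink extraction** — the annotated site is the nucleotide
  immediately preceding the cDNA 5' end in transcript orientation; one
  unique cDNA contributes one count.
* **Significance calling** — per-region permutation FDR: each of 100
  permutations redistributes the region's truncation events uniformly;
  `FDR(k)` = mean permuted positions with count ≥ k over observed
  positions with count ≥ k, monotonised; sites with `FDR < 0.05` pass.
* **Peaks** — gap-based clustering of significant sites, local-maxima
  refinement (the characteristic major peak + sub-peak pattern),
  replicate merging, overlap counting, median-of-ratios size factors,
  log-scale Pearson replicate correlation, cross-experiment overlap
  tables.
* **tRNA structural consensus** — intron-aware projection of sites onto
  a region-wise consensus coordinate system (the metagene view), plus
  the catalytic **+1 inference**: for read-through chemistries the
  methylated base is the annotated peak position plus one in transcript
  orientation, turning the annotated peak at consensus 53 into the U54
  call, 4 nt upstream of the m1A58 stall sub-peak.
* **Motif recovery** — ±50 nt flanks, anchored k-mer enrichment against
  dinucleotide-preserving shuffles, crosslink-anchored PWM (expected:
  the universal T-loop motif `GTTCGAA`).
* **Simulator** — a first-class, tested generator of synthetic genomes,
  annotations, UMI-tagged FASTQ reads and exact-placement SAM with
  per-cDNA ground truth for every crosslink mode, so the entire
  pipeline is verifiable offline.

## Worked example

Simulate six tRNA genes at 500 reads per gene per replicate, run the
chain to final peaks, and read off the T-loop geometry:

```r
library(ficcseq)
library(dplyr)

cfg    <- sim_config(n_trna_genes = 6, n_other_genes = 2,
                     reads_per_gene = 500, seed = 42)
ref    <- build_reference(cfg)
sim    <- simulate_reads(ref, cfg)
tagged <- demultiplex_trim(sim$reads, cfg$barcode_map, cfg$umi_len)
aln    <- align_synthetic(filter(tagged, sample != "undetermined"),
                          ref, sim$truth)
cdnas  <- dedup(aln)
sites  <- extract_crosslinks(cdnas)
called <- call_significant(sites, ref$genes, n_perm = 100,
                           alpha = 0.05, seed = 42)
final  <- merge_replicates(refine_maxima(cluster_sites(
            filter(called, significant))))
cons   <- build_consensus(ref)
peak_geometry(final, ref$genes, cons)
#> # A tibble: 6 × 6
#>   gene_id major_ann_cons major_meth_cons sub_ann_cons dist_ann dist_meth_sub
#>   <chr>            <int>           <int>        <int>    <int>         <int>
#> 1 tRNA-01             53              54           58        5             4
#> 2 tRNA-02             53              54           58        5             4
#> 3 tRNA-03             53              54           58        5             4
#> 4 tRNA-04             53              54           58        5             4
#> 5 tRNA-05             53              54           58        5             4
#> 6 tRNA-06             53              54           58        5             4
```

Every gene shows the annotated major peak at consensus 53, the inferred
methylated base at **U54**, the m1A-stall sub-peak annotated at **A58**
— 5 nt from the annotated major peak and 4 nt from the inferred
methylated base. The projected metagene concentrates essentially all
signal on those two coordinates:

```r
project_sites(final, ref$genes, cons) |>
  as_tibble() |> arrange(-count) |> head(3)
#> # A tibble: 3 × 3
#>   cons_pos region           count
#>      <int> <chr>            <dbl>
#> 1       53 t_loop            4802
#> 2       58 t_loop             888
#> 3        1 acceptor_stem_5p     0
```

and motif discovery on the peak flanks returns the T-loop motif:

```r
discover_motif(extract_flanks(final, ref$genome), seed = 42)
#> top 7-mer: GTTCGAA  enrichment 10.91x  shuffle p = 0.009901 (14 seqs, 100 shuffles)
```

`run_pipeline(run_config(), outdir = "out")` executes the same chain
end to end with per-stage TSV reports, bedGraph/BED tracks and a YAML
manifest; `inst/scripts/ficc.R` wraps it for the shell
(`Rscript inst/scripts/ficc.R run --outdir out --seed 1`). Result
objects carry `tidy()` / `glance()` / `autoplot()` methods
(consensus profiles, anchored PWMs, correlation heatmaps, per-gene
browser-style tracks).

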