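---
title: "Methods: truncation-based mapping of RNA modification sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: truncation-based mapping of RNA modification sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Catalytic-crosslinking sequencing (FICC-Seq with 5-fluorouracil, or
miCLIP with a catalytic-mutant enzyme) traps an RNA methyltransferase
covalently on its substrate base. During library preparation, reverse
transcription runs 3'→5' along the RNA and terminates at or near the
crosslinked nucleotide, so the genomic coordinate of a cDNA 5' end
carries single-nucleotide information about the enzyme's target. The
package works from one geometric rule and one correction:

* **Annotated crosslink site.** The truncation-annotated site is the
  nucleotide immediately preceding the cDNA 5' end in transcript
  orientation (`extract_crosslinks()`: genomic −1 on the plus strand,
  +1 on the minus strand). This is the standard iCLIP convention, which
  assumes the polymerase stalls just before the crosslinked base.
* **Catalytic +1 correction.** In catalytic chemistries the crosslinked
  base itself is usually copied before termination, so the methylated
  base is the annotated site **plus one** in transcript orientation
  (`infer_methylated_base(mode = "catalytic")`). Under UV crosslinking
  no correction applies (`mode = "uv"`).

For cytosolic tRNAs this predicts a characteristic T-loop signature.
With the T-loop motif `GTTCGAA` at mature positions 53–59, the m5U
target sits at 54 and the universally m1A-modified adenosine at 58.
Read-through truncations annotate position 53, whose +1 correction
recovers U54; reverse transcription additionally stalls immediately
before m1A58, producing a secondary sub-peak annotated exactly at 58.
The two annotated peaks are therefore 5 consensus nt apart, and the
inferred methylated base lies 4 nt before the sub-peak. The package
reports **both** distances (`peak_geometry()`): the 4-nt figure refers
to the corrected methylated base (54→58), the 5-nt figure to the two
annotated maxima (53→58) — the two readings of "distance between major
peak and sub-peak" that coexist in this assay's literature.

## Pipeline stages and their parameters

1. **Demultiplex and trim** (`demultiplex_trim()`): in-line layout
   `UMI + sample barcode + insert` at the read 5' end. Barcode
   mismatches tolerated: 1 by default (conservative single-substitution
   rescue; ambiguous assignments go to `undetermined`).
2. **Deduplicate** (`dedup()`): unique cDNAs are identity classes of
   (sample, chromosome, strand, 5' position, UMI); only uniquely
   mapping reads are admitted. No UMI edit-distance clustering is
   attempted — duplicates are discarded by identity.
3. **Crosslink extraction** (`extract_crosslinks()`): one count per
   unique cDNA (PCR support is never multiplied in); sites whose
   coordinate would leave the chromosome are dropped and tallied.
4. **Significance calling** (`call_significant()`): permutation FDR per
   annotated region, `n_perm = 100`, `alpha = 0.05`. See below.
5. **Peaks** (`cluster_sites()`, `refine_maxima()`,
   `merge_replicates()`): significant sites within `max_gap = 15` nt
   form clusters; local maxima above `rel_threshold` of the cluster
   maximum and separated by `min_dist = 2` nt are reported; replicate
   peaks within `merge_tol = 3` nt are unified, the representative
   position being the one with the largest summed count.
6. **Counting and normalisation** (`count_clusters()`,
   `normalize_counts()`): any-overlap same-strand unique-cDNA counts
   per cluster per replicate; clusters with summed counts below
   `min_total = 10` are dropped; size factors by median-of-ratios
   (default) or total-count ratio; Pearson correlation on
   `log2(count + 1)`.
7. **Consensus projection** (`build_consensus()`, `project_sites()`):
   intron-aware mapping of each site to a structural consensus
   coordinate; catalytic +1 inference on peaks.
8. **Motif** (`extract_flanks()`, `discover_motif()`,
   `filter_anchor()`): ±50 nt flanks, k = 7 k-mer enrichment against
   100 dinucleotide-preserving shuffles, anchored PWM.

### Why `rel_threshold = 0.1`

The sub-peak eligibility threshold is the one refinement parameter with
real leverage. Under the default library composition — 80% read-through
events against 15% m1A stalls — the A58 sub-peak carries roughly 19% of
the major peak's counts. A threshold of 0.3 (a common default for
generic sub-peak suppression) would silently delete the one sub-peak
this assay is known to produce, while uniform background contributes
well under 1% of the maximum per position at these depths. 0.1 keeps
the documented two-peak geometry resolvable and still rejects
background fluctuations by an order of magnitude.

## The permutation FDR estimator

Within a region of length $L$ holding $C$ unique-cDNA truncations, the
null redistributes the $C$ events uniformly over the $L$ positions
(multinomial; truncation events, not sites, are the exchangeable unit).
For each observed count value $k$:

$$\widehat{FDR}(k) = \frac{\mathbb{E}_{perm}\,\#\{pos: X_{pos} \ge k\}}
{\#\{pos: x_{pos} \ge k\}}$$

clipped to $[0,1]$ and made monotone non-increasing in $k$ by a
step-down pass (each value is raised to the maximum over larger $k$, a
conservative correction that removes Monte-Carlo inversions). A site is
significant when $\widehat{FDR}(\text{count}) < \alpha$. Sites in
overlapping annotations are assigned to the shorter region
(lexicographic tie-break) so each site is tested exactly once; the
permutation universe is strictly per-region — no pooling of null
statistics across regions of similar depth is attempted, and the
estimator is pinned against an independent 10^5-permutation Monte-Carlo
oracle in the test suite.

One estimator subtlety: a *perfectly flat* observed profile occupies
every position of its region, which is more occupancy than a random
multinomial draw achieves (a null draw leaves ~37% of positions empty
at $C = L$), so the estimate for count 1 in that degenerate case sits
near 0.63 rather than at 1. Nothing is called either way; the behaviour
is documented rather than patched.

## The motif score

The top k-mer is ranked by observed occurrences divided by mean shuffle
occurrences **plus a pseudocount of 1**; without it, any singleton
k-mer absent from the shuffles would outrank a genuinely recurrent
motif. The reported p-value compares the winner's observed count with
the null distribution of the *best* k-mer count per shuffle replicate —
an empirical maximum statistic that absorbs the selection over all
$4^k$ candidates, which a per-k-mer marginal p-value would not (under
pure noise the marginal p of the selected best k-mer is almost always
small; the maximum statistic is calibrated). Dinucleotide-preserving
shuffles use the Altschul–Erickson construction (random last-edge tree
into the terminal vertex, remaining edges permuted, Eulerian walk
rebuilt); runs of non-ACGT characters are held fixed and each ACGT run
is shuffled independently. Reverse-complement scanning is off: the
libraries are strand-specific.

## What the simulator emulates — and what it does not

`sim_config()` / `build_reference()` / `simulate_reads()` generate one
synthetic chromosome of tRNA and non-tRNA genes with random spacers,
place each gene on a random strand, force `GTTCGAA` at mature 53–59 of
every tRNA, optionally insert a 15-nt intron after mature position 37
(the canonical tRNA intron location) in a quarter of the genes, and
draw reads in four modes: read-through truncation at the m5U target,
m1A-style stall, UV-style stall, and uniform background. Non-tRNA
genes model "binding-only" loci: UV-stall geometry at a fixed mid-gene
site plus background, with at least one such gene always on the minus
strand. Defaults are the package's standard study conditions: 20 tRNA
genes, 5000 reads per gene per replicate, two replicates, 80% / 15% /
5% read-mode mix — the paper-scale geometry checks and the acceptance
script both run at exactly these sizes, and the full run completes in
about a minute on one CPU.

Deliberate idealisations, which bound what a passing test demonstrates
about real data:

* **No sequencing errors or quality profiles.** Deduplication keys on
  exact (position, UMI) identity, so error modelling would only blur a
  contract that is exact by design.
* **UMI keys are collision-free by construction.** Each simulated
  unique cDNA receives a UMI drawn by rejection so that its
  (sample, position, UMI) key is unique: at realistic per-site depths
  (thousands of cDNAs stacked on one nucleotide) random 8–10-nt UMIs
  would collide with near-certainty, and the simulator treats that
  under-counting as a measurement artifact it chooses not to model.
  Consequently "unique cDNAs after dedup = truth rows" is exact.
* **PCR duplication is Poisson** (`1 + Poisson(pcr_dup_mean)`); any
  over-dispersed alternative would satisfy the same dedup contract.
* **cDNAs run contiguously through introns** (precursor-like reads),
  keeping synthetic alignments ungapped; truncation 5' ends, which
  carry all the positional signal, are unaffected.
* **The exact-placement aligner** puts each read at its true locus and
  flags a read multi-mapping iff its sequence occurs more than once in
  the reference (either strand) — a stand-in for a real aligner's
  unique-mapping filter, not a model of mapping error.

## Numerical and layout choices

* Coordinates are 0-based half-open everywhere internally (BED
  convention); consensus coordinates are 1-based in reports to match
  U54/A58 nomenclature; mature positions are 1-based.
* The canonical region table totals 76 nt with a 5-nt 3' tail
  (discriminator + CCA-like end) following the acceptor stem, which
  keeps the T-loop at 53–59.
* Consensus region lengths are `round(mean)` over genes; within-region
  offsets map by `floor(o * l_cons / l)` — deterministic,
  order-preserving, and exactly enumerable in tests. Base ties become
  IUPAC ambiguity codes.
* Maxima plateaus report their leftmost position; merged-peak ties
  break leftmost; overlapping-region ties break to the shorter, then
  lexicographically first region.
* Size factors: the median-of-ratios estimator (geometric-mean
  pseudo-reference over clusters with all-positive counts) is the
  default; the literal total-count-ratio estimator is selectable, and
  is the automatic fallback (with a warning) when no cluster has
  all-positive counts. Scaling one sample's counts by $c$ scales its
  size factor *relative to the others* by exactly $c$; the factors'
  absolute level depends on the pseudo-reference, as in any
  median-of-ratios scheme.
* Degenerate inputs: empty site sets produce valid empty outputs;
  regions of length 0 and region tables inconsistent with the mature
  length are configuration errors; +1 inference that leaves the gene is
  flagged as a boundary case rather than projected.

## Known limitations

Mitochondrial and other non-canonical tRNAs (e.g. lacking a T-loop) are
out of scope for the consensus model; differential testing between
conditions is intentionally delegated to dedicated count-model packages
(the cluster × replicate count matrix is exported for that purpose);
motif discovery is anchored k-mer enrichment, not EM over PWMs, which
suffices for a fixed-register motif like the T-loop but would not
replace a general motif suite on heterogeneous binding data.
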