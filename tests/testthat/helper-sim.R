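# Shared small simulation, built once per test run.
small_cfg <- function(...) {
  args <- list(
    n_trna_genes = 6L, n_other_genes = 2L, reads_per_gene = 300L,
    pcr_dup_mean = 1, seed = 42L
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

.small_cache <- new.env(parent = emptyenv())

small_run <- function() {
  if (is.null(.small_cache$run)) {
    cfg <- small_cfg()
    ref <- build_reference(cfg)
    sim <- simulate_reads(ref, cfg)
    tagged <- demultiplex_trim(sim$reads, cfg$barcode_map, cfg$umi_len)
    aln <- align_synthetic(
      dplyr::filter(tagged, sample != "undetermined"), ref, sim$truth
    )
    cdnas <- dedup(aln)
    sites <- extract_crosslinks(cdnas)
    .small_cache$run <- list(
      cfg = cfg, ref = ref, sim = sim, tagged = tagged, aln = aln,
      cdnas = cdnas, sites = sites
    )
  }
  .small_cache$run
}

# independent Monte-Carlo oracle for the permutation FDR of the maximal
# count in one region: per permutation, each of C truncation events picks
# a uniform position; FDR(k) = mean #positions with count >= k divided by
# the observed number of positions with count >= k
oracle_fdr_max <- function(counts, L, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  C <- sum(counts)
  k <- max(counts)
  obs_ge <- sum(counts >= k)
  exceed <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tab <- tabulate(sample.int(L, C, replace = TRUE), nbins = L)
    exceed[i] <- sum(tab >= k)
  }
  min(mean(exceed) / obs_ge, 1)
}

# dinucleotide count table of a string, for shuffle invariance checks
dinuc_table <- function(s) {
  x <- strsplit(s, "")[[1]]
  table(paste0(x[-length(x)], x[-1]))
}

# full-condition FICC simulation (20 tRNA genes x 5000 reads x 2
# replicates, 80/15/5 read-mode mix), cached; used by the acceptance
# checks
full_run <- function() {
  if (is.null(.small_cache$full)) {
    cfg <- sim_config(seed = 101L)
    ref <- build_reference(cfg)
    sim <- simulate_reads(ref, cfg)
    tagged <- demultiplex_trim(sim$reads, cfg$barcode_map, cfg$umi_len)
    aln <- align_synthetic(
      dplyr::filter(tagged, sample != "undetermined"), ref, sim$truth
    )
    cdnas <- dedup(aln)
    sites <- extract_crosslinks(cdnas)
    called <- call_significant(sites, ref$genes, n_perm = 100,
                               alpha = 0.05, seed = 101L)
    peaks <- refine_maxima(
      cluster_sites(dplyr::filter(called, significant), max_gap = 15)
    )
    final <- merge_replicates(peaks, merge_tol = 3)
    cons <- build_consensus(ref)
    geom <- peak_geometry(final, ref$genes, cons)
    .small_cache$full <- list(
      cfg = cfg, ref = ref, sim = sim, aln = aln, cdnas = cdnas,
      sites = sites,
      called = called, peaks = peaks, final = final, cons = cons,
      geom = geom
    )
  }
  .small_cache$full
}

# one spiked-signal calling round: 100 regions of 100 nt, 200 cDNA
# truncations each, half stacked on one true site, half uniform; returns
# the false-discovery proportion among called sites
spiked_fdp <- function(seed) {
  set.seed(seed)
  n_regions <- 100L
  L <- 100L
  rows <- lapply(seq_len(n_regions) - 1L, function(i) {
    true_pos <- sample.int(L, 1) - 1L
    bg <- tabulate(sample.int(L, 100, replace = TRUE), nbins = L)
    cnt <- bg
    cnt[true_pos + 1L] <- cnt[true_pos + 1L] + 100L
    local_pos <- which(cnt > 0) - 1L
    tibble::tibble(
      sample = "s", chrom = "c", strand = "+",
      pos = local_pos + i * L, count = cnt[local_pos + 1L],
      true_site = local_pos == true_pos
    )
  })
  sites <- dplyr::bind_rows(rows)
  regions <- tibble::tibble(
    region_id = sprintf("r%03d", seq_len(n_regions)),
    chrom = "c", start = (seq_len(n_regions) - 1L) * L,
    end = seq_len(n_regions) * L, strand = "+"
  )
  out <- call_significant(
    dplyr::select(sites, -true_site), regions,
    n_perm = 100, alpha = 0.05, seed = seed + 7L
  )
  out <- dplyr::left_join(
    out, dplyr::select(sites, pos, true_site), by = "pos"
  )
  called <- dplyr::filter(out, significant)
  if (nrow(called) == 0) return(0)
  mean(!called$true_site)
}
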