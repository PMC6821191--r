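sig <- function(pos, count, sample = "a", strand = "+") tibble::tibble(
  sample = sample, chrom = "c", strand = strand,
  pos = as.integer(pos), count = as.integer(count)
)

test_that("clustering joins sites within max_gap and partitions all sites", {
  one <- cluster_sites(sig(c(100, 104), c(3, 5)), max_gap = 10)
  expect_equal(unique(one$cluster_id), "a:c:+:100-105")
  expect_equal(unique(one$start), 100L)
  expect_equal(unique(one$end), 105L)
  two <- cluster_sites(sig(c(100, 150), c(3, 5)), max_gap = 10)
  expect_equal(dplyr::n_distinct(two$cluster_id), 2L)
  # partition: every site appears exactly once
  run <- small_run()
  called <- call_significant(run$sites, run$ref$genes, seed = 5)
  cl <- cluster_sites(dplyr::filter(called, significant), max_gap = 15)
  expect_equal(nrow(cl), sum(called$significant))
  expect_true(all(cl$pos >= cl$start & cl$pos < cl$end))
})

test_that("maxima refinement finds peaks, sub-peaks and plateau lefts", {
  mk <- function(counts, ...) {
    pos <- which(counts > 0) - 1L
    refine_maxima(cluster_sites(sig(pos, counts[counts > 0]),
                                max_gap = length(counts)), ...)
  }
  single <- mk(c(0, 5, 0))
  expect_equal(single$pos, 1L)
  # major peak plus smaller sub-peak, both above the relative threshold
  both <- mk(c(0, 100, 0, 0, 0, 40, 0), rel_threshold = 0.3, min_dist = 2)
  expect_equal(sort(both$pos), c(1L, 5L))
  expect_equal(both$pos[both$rank == 1], 1L)
  # below-threshold sub-peak is dropped
  dropped <- mk(c(0, 100, 0, 0, 0, 20, 0), rel_threshold = 0.3,
                min_dist = 2)
  expect_equal(dropped$pos, 1L)
  # plateau reports its leftmost position
  plateau <- mk(c(0, 7, 7, 0))
  expect_equal(plateau$pos, 1L)
})

test_that("refined maxima are invariant under uniform count scaling", {
  set.seed(3)
  pos <- sort(sample.int(60, 12)) - 1L
  cnt <- stats::rpois(12, 20) + 1L
  base <- refine_maxima(cluster_sites(sig(pos, cnt), max_gap = 60))
  scaled <- refine_maxima(cluster_sites(sig(pos, cnt * 7L), max_gap = 60))
  expect_equal(scaled$pos, base$pos)
  expect_equal(scaled$rank, base$rank)
})

test_that("replicate merging unifies nearby peaks with provenance", {
  pk <- function(sample, pos, count) tibble::tibble(
    sample = sample, chrom = "c", strand = "+",
    cluster_id = paste0(sample, pos), start = pos - 2L, end = pos + 3L,
    pos = as.integer(pos), count = as.integer(count), rank = 1L
  )
  same <- merge_replicates(dplyr::bind_rows(pk("A", 999, 10),
                                            pk("B", 999, 12)))
  expect_equal(nrow(same), 1L)
  expect_equal(same$pos, 999L)
  expect_equal(same$samples, "A,B")
  near <- merge_replicates(dplyr::bind_rows(pk("A", 999, 10),
                                            pk("B", 1001, 30)),
                           merge_tol = 3)
  expect_equal(nrow(near), 1L)
  expect_equal(near$pos, 1001L)  # largest summed count wins
  disjoint <- merge_replicates(dplyr::bind_rows(pk("A", 100, 5),
                                                pk("B", 300, 6)),
                               merge_tol = 0)
  expect_equal(nrow(disjoint), 2L)
  # commutative in replicate order
  sw <- merge_replicates(dplyr::bind_rows(pk("B", 1001, 30),
                                          pk("A", 999, 10)),
                         merge_tol = 3)
  expect_equal(sw, near)
  expect_equal(nrow(merge_replicates(pk("A", 1, 1)[0, ])), 0L)
})

test_that("cluster counting uses same-strand interval overlap", {
  clusters <- tibble::tibble(
    chrom = "c", strand = "+", start = 100L, end = 105L, pos = 102L,
    total_count = 10L, n_replicates = 1L, samples = "r1"
  )
  cdnas <- tibble::tibble(
    sample = c("r1", "r1", "r2"), chrom = "c",
    strand = c("+", "-", "+"),
    start = c(95L, 95L, 104L), end = c(130L, 130L, 120L),
    five_prime_pos = c(95L, 129L, 104L), umi = c("A", "C", "G"),
    support = 1L
  )
  out <- count_clusters(clusters, cdnas)
  expect_equal(out$r1, 1L)  # spanning read counted, opposite strand not
  expect_equal(out$r2, 1L)  # 1-base overlap counted
})

test_that("median-of-ratios matches the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  mat <- matrix(stats::rpois(200, 40) + 1L, ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  got <- normalize_counts(mat, min_total = 0)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
})

test_that("size factors behave under identity, scaling and pre-filtering", {
  mat <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  idn <- normalize_counts(mat, min_total = 0)
  expect_equal(unname(idn$size_factors), c(1, 1))
  doubled <- cbind(a = mat[, 1], b = 2 * mat[, 1])
  dd <- normalize_counts(doubled, min_total = 0)
  expect_equal(unname(dd$size_factors[2] / dd$size_factors[1]), 2)
  expect_equal(dd$normalized[, 1], dd$normalized[, 2])
  # scale equivariance: scaling one sample by c scales factor ratios by c
  set.seed(2)
  m <- matrix(stats::rpois(120, 30) + 1, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  f0 <- normalize_counts(m, min_total = 0)$size_factors
  m2 <- m
  m2[, 2] <- m2[, 2] * 5
  f1 <- normalize_counts(m2, min_total = 0)$size_factors
  expect_equal(unname(f1[2] / f1[1]), unname(5 * f0[2] / f0[1]),
               tolerance = 1e-12)
  # pre-filter removes low-count clusters before estimation
  m3 <- rbind(m, c(1, 1, 1))
  expect_equal(nrow(normalize_counts(m3, min_total = 10)$counts),
               sum(rowSums(m3) >= 10))
  # all-zero-containing rows force the total-count fallback
  mz <- matrix(c(0, 5, 8, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(fb <- normalize_counts(mz, min_total = 0), "total-count")
  expect_equal(unname(fb$size_factors), c(5, 8) / 6.5)
})

test_that("correlations are computed on log2 counts with NA for zero variance", {
  x <- c(3, 8, 1, 20, 5)
  m <- cbind(a = x, b = x, c = 2 * x)
  r <- correlate_counts(m)
  expect_equal(r["a", "b"], 1)
  expect_gt(r["a", "c"], 0.999)  # log-scale shift, not exactly affine
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  mz <- cbind(a = x, z = rep(2, 5))
  rz <- correlate_counts(mz)
  expect_true(is.na(rz["a", "z"]))
  expect_equal(diag(rz), c(a = 1, z = 1))
})

test_that("independent simulated replicates correlate above 0.9", {
  run <- small_run()
  called <- call_significant(run$sites, run$ref$genes, seed = 5)
  peaks <- refine_maxima(cluster_sites(dplyr::filter(called, significant)))
  final <- merge_replicates(peaks)
  counts <- count_clusters(final, run$cdnas)
  r <- correlate_counts(counts)
  expect_gte(r["rep1", "rep2"], 0.9)
})

test_that("peak-set overlap reports Venn counts and reference recovery", {
  pk <- function(pos, count = 10L) tibble::tibble(
    chrom = "c", strand = "+", pos = as.integer(pos),
    count = as.integer(count)
  )
  idsets <- list(X = pk(c(10, 50, 90)), Y = pk(c(10, 50, 90)))
  idr <- overlap_peaks(idsets, min_count = 5, merge_tol = 0)
  expect_equal(idr$table$subset, "X&Y")
  expect_equal(unname(idr$reference_fraction), 1.0)
  disj <- overlap_peaks(list(X = pk(10), Y = pk(500)), merge_tol = 0)
  expect_equal(unname(disj$reference_fraction), 0.0)
  partial <- overlap_peaks(
    list(A = pk(seq(0, 900, by = 100)),
         B = pk(c(seq(0, 800, by = 100), 2000))),
    min_count = 5, merge_tol = 0
  )
  expect_equal(unname(partial$reference_fraction), 0.9)
  # min_count filter removes weak peaks before matching
  weak <- overlap_peaks(list(X = pk(10, count = 4), Y = pk(10, count = 4)))
  expect_equal(nrow(weak$table), 0L)
})

test_that("annotation classes match simulated truth proportions", {
  run <- small_run()
  trna_genes <- run$ref$genes[run$ref$genes$class == "tRNA", ]
  inside <- tibble::tibble(
    chrom = trna_genes$chrom, strand = trna_genes$strand,
    pos = mature_to_genomic(trna_genes, trna_genes$gene_id, 54L),
    count = 10L
  )
  all_trna <- annotate_peaks(inside, run$ref$genes)
  expect_equal(all_trna$class, "tRNA")
  expect_equal(all_trna$peak_fraction, 1)
  expect_equal(nrow(annotate_peaks(inside[0, ], run$ref$genes)), 0L)
  # read-count fractions follow the simulated class proportions
  sites <- run$sites
  ann <- annotate_peaks(
    dplyr::rename(sites, count = count), run$ref$genes
  )
  truth_frac <- mean(grepl("tRNA", run$sim$truth$gene_id))
  got <- ann$count_fraction[ann$class == "tRNA"]
  expect_lt(abs(got - truth_frac), 0.02)
})
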