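#' Cluster significant crosslink sites
#'
#' Same-strand significant sites within `max_gap` nt of each other are
#' joined into one cluster; the cluster interval spans its member sites
#' (0-based half-open).
#'
#' @param sig_sites Significant-site tibble (e.g. the `significant` rows
#'   of [call_significant()] output), with `sample`, `chrom`, `strand`,
#'   `pos`, `count`.
#' @param max_gap Maximum nt gap joining two sites into one cluster.
#' @return The input with a `cluster_id` column, plus cluster `start` /
#'   `end` columns repeated per member site.
#' @examples
#' s <- tibble::tibble(sample = "a", chrom = "c", strand = "+",
#'                     pos = c(100L, 104L, 150L), count = c(3L, 5L, 2L))
#' dplyr::distinct(cluster_sites(s, 10), cluster_id, start, end)
#' @export
cluster_sites <- function(sig_sites, max_gap = 15L) {
  sig_sites |>
    dplyr::arrange(.data$sample, .data$chrom, .data$strand, .data$pos) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$strand) |>
    dplyr::mutate(
      .new = c(TRUE, diff(.data$pos) > max_gap),
      .grp = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$.grp, .add = TRUE) |>
    dplyr::mutate(start = min(.data$pos), end = max(.data$pos) + 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster_id = sprintf(
      "%s:%s:%s:%d-%d", .data$sample, .data$chrom, .data$strand,
      .data$start, .data$end
    )) |>
    dplyr::select(-".new", -".grp")
}

#' Refine clusters to their most over-represented crosslink positions
#'
#' Within each cluster the per-position count vector is scanned for local
#' maxima (plateau runs count once, reported at their leftmost position).
#' Maxima below `rel_threshold` x the cluster maximum are dropped, and
#' reported maxima are separated by at least `min_dist` nt (greedy from
#' the highest count, ties to the leftmost). The global maximum is always
#' reported.
#'
#' @param clustered Output of [cluster_sites()].
#' @param rel_threshold Eligibility threshold as a fraction of the
#'   cluster maximum.
#' @param min_dist Minimum nt separation between reported maxima.
#' @return Peak tibble: `sample`, `chrom`, `strand`, `cluster_id`,
#'   cluster `start`/`end`, peak `pos`, `count`, and `rank` (1 = cluster
#'   maximum) ordered by descending count within cluster.
#' @export
refine_maxima <- function(clustered, rel_threshold = 0.1, min_dist = 2L) {
  stopifnot(rel_threshold >= 0, rel_threshold <= 1, min_dist >= 0)
  clustered |>
    dplyr::group_by(.data$sample, .data$chrom, .data$strand,
                    .data$cluster_id, .data$start, .data$end) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      v <- integer(d$end[1] - d$start[1])
      v[d$pos - d$start[1] + 1L] <- d$count
      keep <- local_maxima(v)
      keep <- keep[v[keep] >= rel_threshold * max(v)]
      keep <- keep[order(-v[keep], keep)]
      sel <- integer(0)
      for (i in keep) {
        if (all(abs(i - sel) >= min_dist)) sel <- c(sel, i)
      }
      tibble::tibble(
        sample = d$sample[1], chrom = d$chrom[1], strand = d$strand[1],
        cluster_id = d$cluster_id[1], start = d$start[1], end = d$end[1],
        pos = d$start[1] + sel - 1L, count = v[sel],
        rank = seq_along(sel)
      )
    }) |>
    dplyr::bind_rows()
}

# leftmost indices of local-maximum runs in a non-negative vector
local_maxima <- function(v) {
  r <- rle(v)
  n <- length(r$values)
  starts <- cumsum(c(1L, r$lengths))[seq_len(n)]
  left <- c(-Inf, r$values[-n])
  right <- c(r$values[-1], -Inf)
  starts[r$values > left & r$values > right & r$values > 0]
}

#' Merge per-replicate peaks into a final cluster list
#'
#' Peaks from all replicates on the same chromosome and strand lying
#' within `merge_tol` nt of each other are unified. The representative
#' position is the member position with the largest count summed across
#' replicates (ties to the leftmost); the merged interval is the union of
#' the contributing cluster intervals, and provenance records which
#' replicates contributed.
#'
#' @param peaks Peak tibble from [refine_maxima()] over >= 1 replicate
#'   (replicates distinguished by `sample`).
#' @param merge_tol Maximum nt distance joining peaks across replicates.
#' @return Final cluster tibble: `chrom`, `strand`, `start`, `end`,
#'   `pos` (representative), `total_count`, `n_replicates`, `samples`
#'   (comma-joined, sorted).
#' @export
merge_replicates <- function(peaks, merge_tol = 3L) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(
      chrom = character(), strand = character(), start = integer(),
      end = integer(), pos = integer(), total_count = integer(),
      n_replicates = integer(), samples = character()
    ))
  }
  peaks |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos, .data$sample) |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(.grp = cumsum(c(TRUE, diff(.data$pos) > merge_tol))) |>
    dplyr::group_by(.data$.grp, .add = TRUE) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      pos = {
        s <- tapply(.data$count, .data$pos, sum)
        as.integer(names(s)[which.max(s)])  # which.max ties -> first/left
      },
      total_count = sum(.data$count),
      n_replicates = dplyr::n_distinct(.data$sample),
      samples = paste(sort(unique(.data$sample)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

#' Count unique cDNAs overlapping each final cluster per replicate
#'
#' A cDNA counts toward a cluster when its aligned interval overlaps the
#' cluster interval on the same strand (any overlap).
#'
#' @param clusters Final cluster tibble from [merge_replicates()].
#' @param cdnas Deduplicated alignments ([dedup()] output) across all
#'   replicates.
#' @return Tibble with one row per cluster: `cluster`, interval columns,
#'   and one count column per sample.
#' @export
count_clusters <- function(clusters, cdnas) {
  clusters <- dplyr::mutate(
    clusters,
    cluster = sprintf("%s:%s:%d-%d@%d", .data$chrom, .data$strand,
                      .data$start, .data$end, .data$pos)
  )
  gr_c <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start + 1L, clusters$end),
    strand = clusters$strand
  )
  gr_r <- GenomicRanges::GRanges(
    cdnas$chrom, IRanges::IRanges(cdnas$start + 1L, cdnas$end),
    strand = cdnas$strand
  )
  ov <- GenomicRanges::findOverlaps(gr_c, gr_r)
  hits <- tibble::tibble(
    cluster = clusters$cluster[S4Vectors::queryHits(ov)],
    sample = cdnas$sample[S4Vectors::subjectHits(ov)]
  ) |>
    dplyr::count(.data$cluster, .data$sample) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L)
  out <- dplyr::left_join(clusters, hits, by = "cluster")
  samp_cols <- setdiff(names(out), names(clusters))
  out[samp_cols] <- lapply(out[samp_cols], function(x) {
    ifelse(is.na(x), 0L, x)
  })
  for (s in unique(cdnas$sample)) {
    if (!s %in% names(out)) out[[s]] <- 0L
  }
  out
}

#' Size-factor normalisation of a cluster count matrix
#'
#' Pre-filters clusters whose summed counts fall below `min_total`, then
#' estimates one size factor per sample. The default estimator is
#' median-of-ratios: each sample's factor is the median, over clusters
#' with all-positive counts, of the ratio of its count to the geometric
#' mean across samples (factors are reported as estimated, without
#' rescaling). The alternative `"total"` estimator uses the ratio of each
#' sample's total counts to the mean total. If no cluster has
#' all-positive counts the estimator falls back to `"total"` with a
#' warning. Normalised value = count / size factor.
#'
#' @param mat Numeric matrix (clusters x samples) or a
#'   [count_clusters()] tibble (sample columns auto-detected).
#' @param min_total Minimum summed count for a cluster to be kept.
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return List with `size_factors` (named numeric), `counts` (filtered
#'   matrix) and `normalized` (filtered matrix / size factors).
#' @export
normalize_counts <- function(mat, min_total = 10, method = c("median_ratio",
                                                             "total")) {
  method <- match.arg(method)
  if (!is.matrix(mat)) {
    samp_cols <- setdiff(
      names(mat),
      c("cluster", "chrom", "strand", "start", "end", "pos",
        "total_count", "n_replicates", "samples")
    )
    rn <- if ("cluster" %in% names(mat)) mat$cluster else NULL
    mat <- as.matrix(mat[samp_cols])
    rownames(mat) <- rn
  }
  if (ncol(mat) < 2) stop("need counts for >= 2 samples", call. = FALSE)
  mat <- mat[rowSums(mat) >= min_total, , drop = FALSE]
  sf <- switch(method,
    median_ratio = median_ratio_factors(mat),
    total = total_count_factors(mat)
  )
  if (anyNA(sf)) {
    warning("no cluster with all-positive counts; ",
            "falling back to total-count size factors", call. = FALSE)
    sf <- total_count_factors(mat)
  }
  list(
    size_factors = sf,
    counts = mat,
    normalized = sweep(mat, 2, sf, "/")
  )
}

median_ratio_factors <- function(mat) {
  log_geo <- rowMeans(log(mat))
  ok <- is.finite(log_geo)
  if (!any(ok)) {
    return(stats::setNames(rep(NA_real_, ncol(mat)), colnames(mat)))
  }
  sf <- apply(mat, 2, function(col) {
    exp(stats::median(log(col[ok]) - log_geo[ok]))
  })
  stats::setNames(sf, colnames(mat))
}

total_count_factors <- function(mat) {
  tot <- colSums(mat)
  stats::setNames(tot / mean(tot), colnames(mat))
}

#' Pearson correlation of peak counts across samples
#'
#' Correlates `log2(count + 1)`-transformed columns over the union of
#' peak positions (rows); a zero-variance column yields `NA` against the
#' others while the diagonal stays 1.
#'
#' @param mat Numeric matrix (positions/clusters x samples) or a
#'   [count_clusters()] tibble.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlate_counts <- function(mat) {
  if (!is.matrix(mat)) {
    samp_cols <- setdiff(
      names(mat),
      c("cluster", "chrom", "strand", "start", "end", "pos",
        "total_count", "n_replicates", "samples")
    )
    mat <- as.matrix(mat[samp_cols])
  }
  lm2 <- log2(mat + 1)
  r <- suppressWarnings(stats::cor(lm2, method = "pearson"))
  diag(r) <- 1
  r
}

#' Cross-experiment peak overlap table
#'
#' Filters each experiment's peaks by a minimum crosslink count, matches
#' positions across experiments within `merge_tol` nt on the same strand,
#' and tabulates exclusive/shared peak-group counts per experiment
#' subset (Venn counts). Also reports, for a designated reference
#' experiment, the fraction of its retained peaks found in at least one
#' other experiment.
#'
#' @param peak_sets Named list of peak tibbles (`chrom`, `strand`, `pos`,
#'   `count` or `total_count`).
#' @param min_count Minimum crosslink count for a peak to be considered
#'   (default 5).
#' @param merge_tol Matching tolerance in nt.
#' @param reference Name of the reference experiment (default: first).
#' @return List with `table` (tibble: `subset`, `n`) and
#'   `reference_fraction` (named scalar in \[0, 1\], `NA` if the
#'   reference has no retained peak).
#' @export
overlap_peaks <- function(peak_sets, min_count = 5, merge_tol = 3L,
                          reference = names(peak_sets)[1]) {
  stopifnot(length(peak_sets) >= 2, !is.null(names(peak_sets)))
  pk <- purrr::imap(peak_sets, function(p, nm) {
    cnt <- if ("count" %in% names(p)) p$count else p$total_count
    tibble::tibble(experiment = nm, chrom = p$chrom, strand = p$strand,
                   pos = p$pos, count = cnt)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$count >= min_count)
  if (nrow(pk) == 0) {
    return(list(table = tibble::tibble(subset = character(), n = integer()),
                reference_fraction = stats::setNames(NA_real_, reference)))
  }
  grouped <- pk |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos) |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(.grp = cumsum(c(TRUE, diff(.data$pos) > merge_tol))) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = paste(.data$chrom, .data$strand, .data$.grp))
  membership <- grouped |>
    dplyr::distinct(.data$group, .data$experiment) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      subset = paste(sort(unique(.data$experiment)), collapse = "&"),
      .groups = "drop"
    )
  tab <- dplyr::count(membership, .data$subset, name = "n")
  ref_groups <- grouped |>
    dplyr::filter(.data$experiment == reference) |>
    dplyr::distinct(.data$group, .data$pos)
  frac <- if (nrow(ref_groups) == 0) NA_real_ else {
    shared <- membership$group[
      vapply(strsplit(membership$subset, "&", fixed = TRUE),
             function(s) reference %in% s && length(s) > 1, logical(1))
    ]
    mean(ref_groups$group %in% shared)
  }
  list(table = tab,
       reference_fraction = stats::setNames(frac, reference))
}

#' Annotation-class proportions of peaks and their counts
#'
#' Assigns each peak to the class of the gene it falls in (tRNA vs
#' other; peaks outside any gene count as `"other"`) and reports both the
#' peak-number and the count-weighted proportions per class.
#'
#' @param peaks Peak or cluster tibble with `chrom`, `strand`, `pos` and
#'   `count` (or `total_count`).
#' @param genes Gene tibble from [build_reference()] (`class` column).
#' @return Tibble: `class`, `n_peaks`, `peak_fraction`, `counts`,
#'   `count_fraction`.
#' @export
annotate_peaks <- function(peaks, genes) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(class = character(), n_peaks = integer(),
                          peak_fraction = numeric(), counts = numeric(),
                          count_fraction = numeric()))
  }
  cnt <- if ("count" %in% names(peaks)) peaks$count else peaks$total_count
  gr_p <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$pos + 1L, peaks$pos + 1L),
    strand = peaks$strand
  )
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  ov <- GenomicRanges::findOverlaps(gr_p, gr_g, select = "first")
  cls <- ifelse(is.na(ov), "other", genes$class[ov])
  tibble::tibble(class = cls, count = cnt) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_peaks = dplyr::n(), counts = sum(.data$count),
                     .groups = "drop") |>
    dplyr::mutate(
      peak_fraction = .data$n_peaks / sum(.data$n_peaks),
      count_fraction = .data$counts / sum(.data$counts)
    ) |>
    dplyr::select("class", "n_peaks", "peak_fraction", "counts",
                  "count_fraction")
}
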