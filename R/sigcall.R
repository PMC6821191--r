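#' Permutation-based FDR calling of significant crosslink sites
#'
#' Tests the enrichment of crosslinked nucleotides at specific positions
#' against random permutations within each annotated region. For a region
#' of length L holding C unique cDNA truncations, each permutation
#' redistributes the C events uniformly at random over the L positions
#' (multinomial null). For every observed count value k the FDR estimate
#' is the mean permuted number of positions with count >= k divided by
#' the observed number of positions with count >= k, clipped to \[0, 1\]
#' and made monotone non-increasing in k; a site is significant when
#' `FDR(count) < alpha`.
#'
#' Sites are assigned to exactly one region (same chromosome and strand,
#' position inside the interval); where regions overlap, the shorter one
#' wins, ties broken by lexicographically smaller `region_id`. Sites in
#' no region are ignored and tallied in the `"n_unassigned"` attribute.
#'
#' @param sites Site tibble from [extract_crosslinks()] (one sample, or
#'   grouped per sample by the caller).
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`. Gene tables from [build_reference()]
#'   are accepted (`gene_id` is used as `region_id`).
#' @param n_perm Number of permutations (default 100).
#' @param alpha FDR threshold (default 0.05).
#' @param seed Integer seed; results are deterministic given it.
#' @return The input sites restricted to assigned ones, with `region_id`,
#'   `fdr` and `significant` columns appended.
#' @export
call_significant <- function(sites, regions, n_perm = 100L, alpha = 0.05,
                             seed = 1L) {
  stopifnot(n_perm >= 1L, alpha > 0, alpha < 1)
  if (!"region_id" %in% names(regions) && "gene_id" %in% names(regions)) {
    regions <- dplyr::rename(regions, region_id = "gene_id")
  }
  if (any(regions$end <= regions$start)) {
    stop("region with non-positive length", call. = FALSE)
  }
  withr::local_seed(seed)

  assigned <- assign_regions(sites, regions)
  attr_unassigned <- sum(is.na(assigned$region_id))
  assigned <- dplyr::filter(assigned, !is.na(.data$region_id))

  out <- assigned |>
    dplyr::group_by(.data$sample, .data$region_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      L <- regions$end[match(d$region_id[1], regions$region_id)] -
        regions$start[match(d$region_id[1], regions$region_id)]
      d$fdr <- region_fdr(d$count, L, n_perm)
      d
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(significant = .data$fdr < alpha) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$pos)
  attr(out, "n_unassigned") <- attr_unassigned
  out
}

# deterministic region assignment: overlap on chrom+strand, shortest
# region first, then lexicographic region_id
assign_regions <- function(sites, regions) {
  gr_s <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L),
    strand = sites$strand
  )
  gr_r <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end),
    strand = regions$strand
  )
  ov <- GenomicRanges::findOverlaps(gr_s, gr_r)
  cand <- tibble::tibble(
    site = S4Vectors::queryHits(ov),
    region_id = regions$region_id[S4Vectors::subjectHits(ov)],
    len = regions$end[S4Vectors::subjectHits(ov)] -
      regions$start[S4Vectors::subjectHits(ov)]
  ) |>
    dplyr::arrange(.data$site, .data$len, .data$region_id) |>
    dplyr::distinct(.data$site, .keep_all = TRUE)
  sites$region_id <- NA_character_
  sites$region_id[cand$site] <- cand$region_id
  sites
}

# FDR per observed count value within one region; returns per-site FDR
region_fdr <- function(counts, L, n_perm) {
  C <- sum(counts)
  ks <- sort(unique(counts))
  perm <- stats::rmultinom(n_perm, C, rep(1 / L, L))
  # mean number of permuted positions with count >= k, per k
  exceed_perm <- vapply(ks, function(k) mean(colSums(perm >= k)),
                        numeric(1))
  exceed_obs <- vapply(ks, function(k) sum(counts >= k), numeric(1))
  raw <- pmin(pmax(exceed_perm / exceed_obs, 0), 1)
  mono <- rev(cummax(rev(raw)))  # non-increasing in k
  mono[match(counts, ks)]
}
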