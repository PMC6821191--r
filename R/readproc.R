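#' Demultiplex in-line barcodes and extract UMIs
#'
#' Reads carry a 5' in-line layout of UMI then sample barcode
#' (`NNN...BBB...`) ahead of the cDNA insert. Each read is assigned to the
#' sample whose barcode matches within `max_mismatch` substitutions;
#' ambiguous or unmatched reads go to the `"undetermined"` bin. The
#' emitted sequence has barcode and UMI removed.
#'
#' @param reads Tibble with `read_id` and `sequence`, or a FASTQ path.
#' @param barcode_map Named character vector, sample -> barcode.
#' @param umi_len UMI length (nt) at the extreme 5' end.
#' @param max_mismatch Barcode mismatches tolerated (default 1).
#' @return Tibble `read_id`, `sample`, `umi`, `sequence`; reads shorter
#'   than UMI + barcode are dropped and counted in the
#'   `"n_too_short"` attribute. Attribute `"sample_counts"` holds the
#'   per-sample read tally.
#' @examples
#' r <- tibble::tibble(read_id = "r1", sequence = "ACGTTACGTGCAAA")
#' demultiplex_trim(r, c(s1 = "ACGT"), umi_len = 5)
#' @export
demultiplex_trim <- function(reads, barcode_map, umi_len,
                             max_mismatch = 1L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  bc_len <- unique(nchar(barcode_map))
  stopifnot(length(bc_len) == 1L, umi_len > 0)
  min_len <- umi_len + bc_len
  too_short <- nchar(reads$sequence) < min_len + 1L
  n_short <- sum(too_short)
  if (n_short > 0) {
    warning(n_short, " read(s) shorter than UMI+barcode discarded",
            call. = FALSE)
    reads <- reads[!too_short, ]
  }
  umi <- substr(reads$sequence, 1L, umi_len)
  bc <- substr(reads$sequence, umi_len + 1L, min_len)
  insert <- substr(reads$sequence, min_len + 1L, nchar(reads$sequence))

  bc_mat <- matrix(0L, nrow = length(bc), ncol = length(barcode_map))
  obs <- strsplit(bc, "")
  for (j in seq_along(barcode_map)) {
    ref <- strsplit(barcode_map[[j]], "")[[1]]
    bc_mat[, j] <- vapply(obs, function(o) sum(o != ref), integer(1))
  }
  best <- max.col(-bc_mat, ties.method = "first")
  best_d <- bc_mat[cbind(seq_along(best), best)]
  n_best <- rowSums(bc_mat == best_d)
  sample <- ifelse(best_d <= max_mismatch & n_best == 1L,
                   names(barcode_map)[best], "undetermined")

  out <- tibble::tibble(
    read_id = reads$read_id, sample = sample, umi = umi,
    sequence = insert
  )
  counts <- dplyr::count(out, .data$sample, name = "n_reads")
  attr(out, "sample_counts") <- counts
  attr(out, "n_too_short") <- n_short
  out
}

#' Collapse PCR duplicates into unique cDNAs
#'
#' Deduplicates aligned reads by identity of
#' (sample, chrom, strand, 5' position, UMI); reads flagged multi-mapping
#' (`n_hits > 1`) are excluded first, matching the unique-mapping-only
#' contract. The 5' position is taken in transcript orientation: on the
#' minus strand it is the rightmost aligned genomic base.
#'
#' @param aln Alignment tibble with columns `sample`, `chrom`, `strand`,
#'   `start`, `end`, `umi` and either `five_prime_pos` or enough to
#'   derive it, plus `n_hits` (1 = unique).
#' @return Tibble of unique cDNAs: key columns plus aligned `start`/`end`
#'   and `support` (number of reads collapsed). `sum(support)` equals the
#'   number of admitted (uniquely mapping) alignments.
#' @export
dedup <- function(aln) {
  if (!"five_prime_pos" %in% names(aln)) {
    aln$five_prime_pos <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  }
  if ("n_hits" %in% names(aln)) {
    aln <- dplyr::filter(aln, .data$n_hits == 1L)
  }
  aln |>
    dplyr::group_by(.data$sample, .data$chrom, .data$strand,
                    .data$five_prime_pos, .data$umi) |>
    dplyr::summarise(
      start = dplyr::first(.data$start),
      end = dplyr::first(.data$end),
      support = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$five_prime_pos)
}

#' Read exact-placement SAM records back into an alignment tibble
#'
#' Converts the SAM to BAM via Rsamtools and restores the columns
#' [dedup()] needs, parsing `id#sample#UMI` read names and the `NH` tag.
#'
#' @param path SAM file written by [write_sam()] (or any SAM whose read
#'   names follow the same convention).
#' @return Alignment tibble as produced by [align_synthetic()].
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"),
    tag = "NH"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  parts <- stringr::str_split_fixed(x$qname, "#", 3L)
  strand <- ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+")
  start <- x$pos - 1L
  end <- start + x$qwidth
  tibble::tibble(
    read_id = parts[, 1], sample = parts[, 2], umi = parts[, 3],
    chrom = as.character(x$rname), strand = strand,
    start = start, end = end,
    five_prime_pos = ifelse(strand == "+", start, end - 1L),
    n_hits = as.integer(x$tag$NH)
  )
}
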