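#' Extract single-nucleotide crosslink sites from unique cDNAs
#'
#' The annotated crosslink (truncation) site is the nucleotide
#' immediately preceding the cDNA 5' end in transcript orientation:
#' genomic position minus one on the plus strand, plus one on the minus
#' strand. Counts aggregate unique cDNAs per site - PCR support is not
#' multiplied in (one cDNA, one count). cDNAs whose site would fall
#' outside the chromosome are skipped and tallied in the `"n_skipped"`
#' attribute.
#'
#' @param cdnas Unique-cDNA tibble from [dedup()].
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   skip off-end sites on the minus strand.
#' @return Site tibble: `sample`, `chrom`, `strand`, `pos` (0-based),
#'   `count`.
#' @examples
#' x <- tibble::tibble(sample = "s", chrom = "c", strand = "+",
#'                     five_prime_pos = 1000L, umi = "A", support = 3L)
#' extract_crosslinks(x)$pos  # 999
#' @export
extract_crosslinks <- function(cdnas, chrom_sizes = NULL) {
  pos <- ifelse(cdnas$strand == "+", cdnas$five_prime_pos - 1L,
                cdnas$five_prime_pos + 1L)
  bad <- pos < 0L
  if (!is.null(chrom_sizes)) {
    bad <- bad | pos >= unname(chrom_sizes[cdnas$chrom])
  }
  n_skipped <- sum(bad)
  out <- tibble::tibble(
    sample = cdnas$sample[!bad], chrom = cdnas$chrom[!bad],
    strand = cdnas$strand[!bad], pos = as.integer(pos[!bad])
  ) |>
    dplyr::count(.data$sample, .data$chrom, .data$strand, .data$pos,
                 name = "count") |>
    dplyr::arrange(.data$sample, .data$chrom, .data$pos)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write crosslink tracks as strand-split bedGraph and BED6
#'
#' One bedGraph per strand per sample (`<sample>.plus.bedgraph`,
#' `<sample>.minus.bedgraph`) and one BED6 per sample with the count in
#' the score column; all coordinates 0-based half-open.
#'
#' @param sites Site tibble from [extract_crosslinks()].
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_tracks <- function(sites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(sites$sample)
  if (length(samples) == 0) samples <- "all"
  paths <- character(0)
  for (s in samples) {
    ss <- dplyr::filter(sites, .data$sample == s)
    for (st in c("+", "-")) {
      tag <- if (st == "+") "plus" else "minus"
      p <- file.path(dir, sprintf("%s.%s.bedgraph", s, tag))
      con <- file(p, "w")
      writeLines(sprintf("track type=bedGraph name=\"%s %s strand\"",
                         s, tag), con)
      sst <- dplyr::filter(ss, .data$strand == st)
      if (nrow(sst) > 0) {
        writeLines(sprintf("%s\t%d\t%d\t%d", sst$chrom, sst$pos,
                           sst$pos + 1L, sst$count), con)
      }
      close(con)
      paths <- c(paths, p)
    }
    bed <- file.path(dir, sprintf("%s.sites.bed", s))
    readr::write_tsv(
      dplyr::transmute(ss, .data$chrom, start = .data$pos,
                       end = .data$pos + 1L,
                       name = sprintf("site_%d", dplyr::row_number()),
                       score = .data$count, .data$strand),
      bed, col_names = FALSE
    )
    paths <- c(paths, bed)
  }
  invisible(paths)
}

#' Read a BED6 site track back into a site tibble
#'
#' Inverse of the BED6 output of [write_tracks()].
#'
#' @param path BED6 file; the score column holds the crosslink count.
#' @param sample Sample name to attach.
#' @return Site tibble matching [extract_crosslinks()] output.
#' @export
read_sites_bed <- function(path, sample = "all") {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  tibble::tibble(
    sample = sample, chrom = x$chrom, strand = x$strand,
    pos = as.integer(x$start), count = as.integer(x$score)
  ) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$pos)
}
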