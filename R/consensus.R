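#' Build a structural consensus coordinate system for mature tRNAs
#'
#' Introns are excised, each gene is segmented into its annotated
#' secondary-structure regions, and per region the consensus length is
#' the rounded mean length over the gene set. A mature offset `o`
#' (0-based) inside a region of length `l` maps to consensus offset
#' `floor(o * l_cons / l)`, giving a deterministic, order-preserving
#' per-gene offset map. The consensus sequence takes, at each consensus
#' position, the most frequent base over all gene positions mapping
#' there (ties become IUPAC ambiguity codes). Consensus coordinates are
#' 1-based in reports, matching the U54/A58 nomenclature.
#'
#' @param ref A [build_reference()] object, or a list with `genes`,
#'   `regions`, `genome` components of the same shape.
#' @return An object of class `ficc_consensus`: list with `regions`
#'   (tibble `region`, `length`, `cons_start`, `cons_end`), `sequence`
#'   (IUPAC string), `offset_map` (tibble `gene_id`, `mature_pos`,
#'   `region`, `cons_pos`) and `n_genes`.
#' @export
build_consensus <- function(ref) {
  genes <- dplyr::filter(ref$genes, .data$class == "tRNA")
  regions <- dplyr::semi_join(ref$regions, genes, by = "gene_id")
  if (nrow(regions) == 0) stop("no tRNA gene with region segmentation",
                               call. = FALSE)
  bad <- regions |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(tot = sum(.data$mature_end - .data$mature_start + 1L),
                     .groups = "drop") |>
    dplyr::left_join(genes[c("gene_id", "mature_len")], by = "gene_id") |>
    dplyr::filter(.data$tot != .data$mature_len)
  if (nrow(bad) > 0) {
    stop("region lengths do not sum to mature length for: ",
         paste(bad$gene_id, collapse = ", "), call. = FALSE)
  }

  region_order <- unique(regions$region[order(regions$gene_id,
                                              regions$mature_start)])
  cons_regions <- regions |>
    dplyr::mutate(len = .data$mature_end - .data$mature_start + 1L) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(length = as.integer(round(mean(.data$len))),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$region, region_order)) |>
    dplyr::mutate(
      cons_end = cumsum(.data$length),
      cons_start = .data$cons_end - .data$length + 1L
    )

  offset_map <- regions |>
    dplyr::left_join(cons_regions, by = "region") |>
    dplyr::mutate(l = .data$mature_end - .data$mature_start + 1L) |>
    purrr::pmap(function(gene_id, region, mature_start, mature_end,
                         length, cons_start, l, ...) {
      o <- seq(mature_start, mature_end) - mature_start
      tibble::tibble(
        gene_id = gene_id, region = region,
        mature_pos = mature_start + o,
        cons_pos = cons_start + as.integer(floor(o * length / l))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$gene_id, .data$mature_pos)

  cons_len <- sum(cons_regions$length)
  seqs <- mature_sequences(ref, genes)
  base_at <- offset_map |>
    dplyr::mutate(base = substr(seqs[.data$gene_id], .data$mature_pos,
                                .data$mature_pos))
  consensus <- vapply(seq_len(cons_len), function(p) {
    b <- base_at$base[base_at$cons_pos == p]
    if (length(b) == 0) return("N")
    tb <- table(b)
    top <- sort(names(tb)[tb == max(tb)])
    iupac_code(top)
  }, character(1))

  structure(
    list(
      regions = cons_regions[c("region", "length", "cons_start",
                               "cons_end")],
      sequence = paste(consensus, collapse = ""),
      offset_map = base_at[c("gene_id", "mature_pos", "region",
                             "cons_pos")],
      n_genes = nrow(genes)
    ),
    class = "ficc_consensus"
  )
}

# mature (spliced, transcript-orientation) sequence per gene
mature_sequences <- function(ref, genes = ref$genes) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom_seq <- as.character(ref$genome[[g$chrom]])
    pos <- sort(mature_to_genomic(g, g$gene_id, seq_len(g$mature_len)))
    b <- strsplit(substr(chrom_seq, min(pos) + 1L, max(pos) + 1L),
                  "")[[1]]
    s <- paste(b[pos - min(pos) + 1L], collapse = "")
    if (g$strand == "-") s <- revcomp_chr(s)
    s
  }, character(1))
  stats::setNames(out, genes$gene_id)
}

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(
    A = "A", C = "C", G = "G", T = "T",
    AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
    ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
  )
  unname(codes[key])
}

#' Project crosslink sites onto the tRNA structural consensus
#'
#' Converts each genomic site to its gene's mature coordinate (strand-
#' and intron-aware; intronic sites are dropped and tallied), then to the
#' consensus coordinate through the model's offset map, and aggregates
#' counts per consensus position.
#'
#' @param sites Site or peak tibble with `chrom`, `strand`, `pos` and
#'   `count` (peaks from [refine_maxima()]/[merge_replicates()] use their
#'   `count`/`total_count`).
#' @param genes Gene tibble from [build_reference()].
#' @param model A [build_consensus()] object.
#' @param mode Label stored on the profile: `"annotated_site"` (default)
#'   or `"inferred_methylation"`.
#' @return An object of class `ficc_profile`: tibble `cons_pos`,
#'   `region`, `count` covering every consensus position, with
#'   attributes `n_genes`, `mode`, `n_dropped` (intronic or unmappable
#'   sites).
#' @export
project_sites <- function(sites, genes, model,
                          mode = c("annotated_site",
                                   "inferred_methylation")) {
  mode <- match.arg(mode)
  cnt <- if ("count" %in% names(sites)) sites$count else sites$total_count
  trna <- dplyr::filter(genes, .data$class == "tRNA")
  gr_s <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L),
    strand = sites$strand
  )
  gr_g <- GenomicRanges::GRanges(
    trna$chrom, IRanges::IRanges(trna$start + 1L, trna$end),
    strand = trna$strand
  )
  hit <- GenomicRanges::findOverlaps(gr_s, gr_g, select = "first")
  keep <- !is.na(hit)
  mat <- rep(NA_integer_, length(hit))
  mat[keep] <- genomic_to_mature(trna, trna$gene_id[hit[keep]],
                                 sites$pos[keep])
  df <- tibble::tibble(
    gene_id = ifelse(keep, trna$gene_id[hit], NA_character_),
    mature_pos = mat, count = cnt
  )
  n_dropped <- sum(is.na(df$gene_id) | is.na(df$mature_pos))
  df <- dplyr::filter(df, !is.na(.data$gene_id), !is.na(.data$mature_pos)) |>
    dplyr::inner_join(model$offset_map, by = c("gene_id", "mature_pos"))

  cons_len <- max(model$regions$cons_end)
  values <- tibble::tibble(cons_pos = seq_len(cons_len)) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(df, .data$cons_pos),
                       count = sum(.data$count), .groups = "drop"),
      by = "cons_pos"
    ) |>
    dplyr::mutate(
      count = ifelse(is.na(.data$count), 0, .data$count),
      region = cons_region_of(.data$cons_pos, model)
    ) |>
    dplyr::select("cons_pos", "region", "count")
  structure(values, class = c("ficc_profile", class(values)),
            n_genes = model$n_genes, mode = mode, n_dropped = n_dropped)
}

cons_region_of <- function(cons_pos, model) {
  idx <- findInterval(cons_pos, model$regions$cons_start)
  model$regions$region[idx]
}

#' Infer the methylated base from an annotated crosslink peak
#'
#' For catalytic crosslinking chemistries (FICC, miCLIP) reverse
#' transcription usually copies the crosslinked base before truncating,
#' so the methylated base is the annotated peak position plus one in
#' transcript orientation (genomic +1 on the plus strand, -1 on the
#' minus strand). For UV crosslinking the annotated site already is the
#' contact base and the position is unchanged. The consensus coordinate
#' is recomputed for the shifted position; shifts that leave the gene are
#' reported with `NA` coordinates and flagged `boundary`.
#'
#' @param peaks Peak tibble with `chrom`, `strand`, `pos`.
#' @param genes Gene tibble from [build_reference()].
#' @param model A [build_consensus()] object (optional; `NULL` skips the
#'   consensus column).
#' @param mode `"catalytic"` or `"uv"`.
#' @return The input with `meth_pos` (genomic), `gene_id`, `mature_pos`,
#'   `cons_pos` and `boundary` columns appended.
#' @export
infer_methylated_base <- function(peaks, genes, model = NULL,
                                  mode = c("catalytic", "uv")) {
  mode <- match.arg(mode)
  shift <- if (mode == "catalytic") {
    ifelse(peaks$strand == "+", 1L, -1L)
  } else {
    0L
  }
  peaks$meth_pos <- as.integer(peaks$pos + shift)
  gr_p <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$meth_pos + 1L, peaks$meth_pos + 1L),
    strand = peaks$strand
  )
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  hit <- GenomicRanges::findOverlaps(gr_p, gr_g, select = "first")
  peaks$gene_id <- ifelse(is.na(hit), NA_character_, genes$gene_id[hit])
  peaks$mature_pos <- NA_integer_
  ok <- !is.na(hit)
  if (any(ok)) {
    peaks$mature_pos[ok] <- genomic_to_mature(
      genes, peaks$gene_id[ok], peaks$meth_pos[ok]
    )
  }
  peaks$boundary <- is.na(peaks$gene_id) | is.na(peaks$mature_pos)
  if (!is.null(model)) {
    peaks <- dplyr::left_join(
      peaks,
      dplyr::select(model$offset_map, "gene_id", "mature_pos", "cons_pos"),
      by = c("gene_id", "mature_pos")
    )
  }
  peaks
}

#' @export
print.ficc_consensus <- function(x, ...) {
  cat("tRNA structural consensus over", x$n_genes, "genes\n")
  cat("consensus length:", max(x$regions$cons_end), "nt in",
      nrow(x$regions), "regions\n")
  cat("sequence:", x$sequence, "\n")
  invisible(x)
}

#' Tidy a tRNA consensus model
#'
#' @param x A `ficc_consensus` object.
#' @param ... Unused.
#' @return Tibble of consensus regions with their 1-based consensus
#'   coordinate spans and consensus subsequence.
#' @method tidy ficc_consensus
#' @export
tidy.ficc_consensus <- function(x, ...) {
  dplyr::mutate(
    x$regions,
    sequence = substr(rep(x$sequence, nrow(x$regions)),
                      x$regions$cons_start, x$regions$cons_end)
  )
}

#' Summarise a tRNA consensus model in one row
#'
#' @inheritParams tidy.ficc_consensus
#' @return One-row tibble: `n_genes`, `n_regions`, `length`, `sequence`.
#' @method glance ficc_consensus
#' @export
glance.ficc_consensus <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes, n_regions = nrow(x$regions),
    length = max(x$regions$cons_end), sequence = x$sequence
  )
}

#' Per-gene T-loop peak geometry summary
#'
#' For each tRNA gene with at least two refined peaks, identifies the
#' major (highest-count) and secondary peak, projects their annotated
#' positions onto the consensus, applies the catalytic +1 inference to
#' the major peak, and reports both distances of interest: annotated
#' major to annotated sub-peak, and inferred methylated base to
#' annotated sub-peak. With canonical T-loop geometry the annotated
#' distance is 5 consensus nt (53 to 58) and the methylated-base
#' distance is 4 (54 to 58).
#'
#' @param final Final cluster tibble from [merge_replicates()] (or a
#'   peak tibble with `chrom`, `strand`, `pos` and `count` /
#'   `total_count`).
#' @param genes Gene tibble from [build_reference()].
#' @param model A [build_consensus()] object.
#' @return Tibble with one row per tRNA gene holding >= 2 peaks:
#'   `gene_id`, `major_ann_cons`, `major_meth_cons`, `sub_ann_cons`,
#'   `dist_ann`, `dist_meth_sub`.
#' @export
peak_geometry <- function(final, genes, model) {
  cnt <- if ("count" %in% names(final)) final$count else final$total_count
  ann <- infer_methylated_base(
    dplyr::mutate(final, .count = cnt), genes, model, mode = "uv"
  )
  meth <- infer_methylated_base(
    dplyr::mutate(final, .count = cnt), genes, model, mode = "catalytic"
  )
  ann$meth_cons <- meth$cons_pos
  ann |>
    dplyr::filter(!is.na(.data$gene_id),
                  genes$class[match(.data$gene_id, genes$gene_id)] ==
                    "tRNA") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(dplyr::desc(.data$.count), .data$pos,
                   .by_group = TRUE) |>
    dplyr::summarise(
      major_ann_cons = .data$cons_pos[1],
      major_meth_cons = .data$meth_cons[1],
      sub_ann_cons = .data$cons_pos[2],
      dist_ann = .data$cons_pos[2] - .data$cons_pos[1],
      dist_meth_sub = .data$cons_pos[2] - .data$meth_cons[1],
      .groups = "drop"
    )
}
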