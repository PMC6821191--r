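#' Canonical tRNA structural region table
#'
#' Ordered secondary-structure regions of a mature cytosolic tRNA with the
#' region lengths used as the simulator default. The layout places the
#' T-loop at mature positions 53-59 so that the universally methylated
#' uridine (m5U) sits at position 54 and the m1A-modified adenosine at 58,
#' the canonical coordinates of the `GTTCGAA` T-loop motif. A 5-nt 3' tail
#' (discriminator plus CCA-like end) completes the 76-nt mature length.
#'
#' @return A tibble with columns `region` and `length` (nt). Lengths sum
#'   to 76.
#' @examples
#' canonical_regions()
#' sum(canonical_regions()$length)
#' @export
canonical_regions <- function() {
  tibble::tibble(
    region = c(
      "acceptor_stem_5p", "d_stem_5p", "d_loop", "d_stem_3p", "linker",
      "ac_stem_5p", "ac_loop", "ac_stem_3p", "var_loop",
      "t_stem_5p", "t_loop", "t_stem_3p", "acceptor_stem_3p",
      "three_prime_tail"
    ),
    length = c(7L, 4L, 8L, 4L, 2L, 5L, 7L, 5L, 5L, 5L, 7L, 5L, 7L, 5L)
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic read simulator. The defaults
#' describe a FICC-mode library over canonical 76-nt tRNA genes: most
#' cDNAs reverse-transcribe through the crosslinked (methylated) base and
#' truncate immediately afterwards (`frac_major`), a minority stall one
#' nucleotide before the m1A58 modification (`frac_m1a`), and the rest
#' truncate uniformly over the gene body (`frac_background`). An optional
#' UV-stall fraction (`frac_uv`, truncation immediately before the
#' crosslinked base itself) supports simulating UV-iCLIP geometry.
#'
#' @param n_trna_genes Number of tRNA genes to simulate.
#' @param n_other_genes Number of non-tRNA ("binding-only") genes; these
#'   receive UV-stall geometry at a fixed per-gene site plus background.
#' @param mature_len Mature tRNA length in nt; must equal the sum of
#'   `region_table$length`.
#' @param region_table Ordered tibble of `region`, `length` pairs; default
#'   [canonical_regions()].
#' @param other_len Length of non-tRNA genes (nt).
#' @param reads_per_gene Unique cDNAs simulated per gene per sample.
#' @param frac_major,frac_m1a,frac_background,frac_uv Read-mode fractions;
#'   must sum to 1.
#' @param intron_frac Fraction of tRNA genes that receive an intron.
#' @param intron_len Intron length (nt); inserted after mature position 37
#'   (3' of the anticodon loop, the canonical tRNA intron position).
#' @param pcr_dup_mean Mean extra PCR copies per unique cDNA; each cDNA is
#'   emitted `1 + Poisson(pcr_dup_mean)` times.
#' @param umi_len UMI length (nt).
#' @param barcode_map Named character vector, sample name -> in-line
#'   barcode. All barcodes must share one length.
#' @param read_len cDNA read length (nt) before clipping at the gene 3'
#'   end.
#' @param seed Integer seed; every simulator draw depends on it.
#' @return A validated list of class `ficc_sim_config`.
#' @examples
#' cfg <- sim_config(n_trna_genes = 4, reads_per_gene = 100, seed = 1)
#' cfg$mature_len
#' @export
sim_config <- function(n_trna_genes = 20L,
                       n_other_genes = 4L,
                       mature_len = 76L,
                       region_table = canonical_regions(),
                       other_len = 300L,
                       reads_per_gene = 5000L,
                       frac_major = 0.80,
                       frac_m1a = 0.15,
                       frac_background = 0.05,
                       frac_uv = 0,
                       intron_frac = 0.25,
                       intron_len = 15L,
                       pcr_dup_mean = 1,
                       umi_len = 10L,
                       barcode_map = c(rep1 = "ATCG", rep2 = "GCTA"),
                       read_len = 30L,
                       seed = 1L) {
  barcode_map <- unlist(barcode_map)
  if (is.list(region_table)) region_table <- tibble::as_tibble(region_table)
  fracs <- c(frac_major, frac_m1a, frac_background, frac_uv)
  if (abs(sum(fracs) - 1) > 1e-9) {
    stop("read-mode fractions must sum to 1 (got ", sum(fracs), ")",
         call. = FALSE)
  }
  if (any(fracs < 0)) stop("read-mode fractions must be >= 0", call. = FALSE)
  stopifnot(
    n_trna_genes >= 0, n_other_genes >= 0,
    mature_len > 0, other_len > 0, reads_per_gene > 0,
    umi_len > 0, read_len > 0, intron_len > 0, pcr_dup_mean >= 0
  )
  if (sum(region_table$length) != mature_len) {
    stop("region_table lengths sum to ", sum(region_table$length),
         " but mature_len is ", mature_len, call. = FALSE)
  }
  if (any(region_table$length <= 0)) {
    stop("all region lengths must be > 0", call. = FALSE)
  }
  if (!("t_loop" %in% region_table$region)) {
    stop("region_table must contain a 't_loop' region", call. = FALSE)
  }
  if (length(unique(nchar(barcode_map))) > 1) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (is.null(names(barcode_map)) || any(names(barcode_map) == "")) {
    stop("barcode_map must be a named vector (sample -> barcode)",
         call. = FALSE)
  }
  structure(
    list(
      n_trna_genes = as.integer(n_trna_genes),
      n_other_genes = as.integer(n_other_genes),
      mature_len = as.integer(mature_len),
      region_table = region_table,
      other_len = as.integer(other_len),
      reads_per_gene = as.integer(reads_per_gene),
      frac_major = frac_major, frac_m1a = frac_m1a,
      frac_background = frac_background, frac_uv = frac_uv,
      intron_frac = intron_frac, intron_len = as.integer(intron_len),
      pcr_dup_mean = pcr_dup_mean, umi_len = as.integer(umi_len),
      barcode_map = barcode_map, read_len = as.integer(read_len),
      seed = as.integer(seed)
    ),
    class = "ficc_sim_config"
  )
}

# mature coordinate (1-based) of the T-loop m5U target and the m1A site:
# second and sixth base of the forced GTTCGAA motif.
tloop_coords <- function(cfg) {
  rt <- cfg$region_table
  start <- cumsum(c(0L, rt$length))[match("t_loop", rt$region)] + 1L
  list(tloop_start = start, u54 = start + 1L, a58 = start + 5L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic reference genome and annotation
#'
#' Generates one synthetic chromosome carrying `n_trna_genes` tRNA genes
#' and `n_other_genes` non-tRNA genes separated by random spacers. Every
#' tRNA gene gets the T-loop motif `GTTCGAA` forced at mature positions
#' 53-59 (second base, the m5U target, at 54; the m1A adenosine at 58),
#' a random strand, and - for a configurable subset - an intron inserted
#' after mature position 37. At least one non-tRNA gene is placed on the
#' minus strand so the strand-symmetric code paths are always exercised.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `ficc_reference` with elements
#'   * `genome`: a [Biostrings::DNAStringSet] with one chromosome,
#'   * `genes`: tibble of gene intervals (0-based half-open `start`/`end`,
#'     `strand`, `class`, intron bookkeeping as `intron_after` in mature
#'     coordinates and `intron_len`),
#'   * `regions`: tibble of per-gene structural regions in mature
#'     coordinates (1-based inclusive `mature_start`, `mature_end`).
#' @examples
#' ref <- build_reference(sim_config(n_trna_genes = 2, seed = 7))
#' ref$genes
#' @export
build_reference <- function(cfg) {
  stopifnot(inherits(cfg, "ficc_sim_config"))
  withr::local_seed(cfg$seed)

  tl <- tloop_coords(cfg)
  rt <- cfg$region_table
  n_genes <- cfg$n_trna_genes + cfg$n_other_genes

  gene_ids <- c(
    if (cfg$n_trna_genes > 0) sprintf("tRNA-%02d", seq_len(cfg$n_trna_genes)),
    if (cfg$n_other_genes > 0) sprintf("gene-%02d", seq_len(cfg$n_other_genes))
  )
  classes <- rep(c("tRNA", "other"), c(cfg$n_trna_genes, cfg$n_other_genes))

  # mature (transcript) sequence per gene; tRNAs get the forced T-loop motif
  mature_seqs <- vapply(seq_len(n_genes), function(i) {
    if (classes[i] == "tRNA") {
      s <- random_dna(cfg$mature_len)
      substr(s, tl$tloop_start, tl$tloop_start + 6L) <- "GTTCGAA"
      s
    } else {
      random_dna(cfg$other_len)
    }
  }, character(1))

  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (cfg$n_other_genes > 0 &&
      !any(strands[classes == "other"] == "-")) {
    strands[which(classes == "other")[1]] <- "-"
  }

  n_intron <- round(cfg$intron_frac * cfg$n_trna_genes)
  has_intron <- rep(FALSE, n_genes)
  if (n_intron > 0) has_intron[seq_len(n_intron)] <- TRUE
  intron_after <- ifelse(has_intron, 37L, NA_integer_)
  intron_len <- ifelse(has_intron, cfg$intron_len, NA_integer_)

  # genomic locus sequence = transcript with intron inserted, rev-comped
  # for minus-strand genes
  locus_seqs <- vapply(seq_len(n_genes), function(i) {
    s <- mature_seqs[i]
    if (has_intron[i]) {
      s <- paste0(
        substr(s, 1L, intron_after[i]), random_dna(intron_len[i]),
        substr(s, intron_after[i] + 1L, nchar(s))
      )
    }
    if (strands[i] == "-") s <- revcomp_chr(s)
    s
  }, character(1))

  spacer_len <- 100L
  chrom_parts <- character(2L * n_genes + 1L)
  chrom_parts[1L] <- random_dna(spacer_len)
  starts <- integer(n_genes)
  at <- spacer_len
  for (i in seq_len(n_genes)) {
    starts[i] <- at
    chrom_parts[2L * i] <- locus_seqs[i]
    chrom_parts[2L * i + 1L] <- random_dna(spacer_len)
    at <- at + nchar(locus_seqs[i]) + spacer_len
  }
  chrom_seq <- paste(chrom_parts, collapse = "")

  genes <- tibble::tibble(
    gene_id = gene_ids,
    class = classes,
    chrom = "chrS",
    start = starts,
    end = starts + nchar(locus_seqs),
    strand = strands,
    mature_len = ifelse(classes == "tRNA", cfg$mature_len, cfg$other_len),
    intron_after = intron_after,
    intron_len = intron_len
  )

  regions <- if (cfg$n_trna_genes > 0) {
    ends <- cumsum(rt$length)
    tidyr::crossing(
      gene_id = gene_ids[classes == "tRNA"],
      tibble::tibble(
        region = rt$region,
        mature_start = ends - rt$length + 1L,
        mature_end = ends
      )
    ) |>
      dplyr::arrange(.data$gene_id, .data$mature_start)
  } else {
    tibble::tibble(
      gene_id = character(), region = character(),
      mature_start = integer(), mature_end = integer()
    )
  }

  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrS"
  structure(
    list(genome = genome, genes = genes, regions = regions, config = cfg),
    class = "ficc_reference"
  )
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert mature (transcript) positions to genomic coordinates
#'
#' Mature positions are 1-based along the spliced transcript; genomic
#' positions are 0-based. Positions downstream of an intron shift by the
#' intron length; on the minus strand the transcript runs right to left.
#'
#' @param genes Gene tibble from [build_reference()].
#' @param gene_id,mature_pos Parallel vectors.
#' @return Integer vector of 0-based genomic positions.
#' @export
mature_to_genomic <- function(genes, gene_id, mature_pos) {
  n <- max(length(gene_id), length(mature_pos))
  gene_id <- rep_len(gene_id, n)
  mature_pos <- rep_len(as.integer(mature_pos), n)
  i <- match(gene_id, genes$gene_id)
  if (anyNA(i)) stop("unknown gene_id", call. = FALSE)
  t0 <- mature_pos - 1L
  shift <- !is.na(genes$intron_after[i]) & mature_pos > genes$intron_after[i]
  t0 <- t0 + ifelse(shift, genes$intron_len[i], 0L)
  as.integer(ifelse(genes$strand[i] == "+",
                    genes$start[i] + t0,
                    genes$end[i] - 1L - t0))
}

#' Convert genomic coordinates to mature (transcript) positions
#'
#' Inverse of [mature_to_genomic()]. Intronic positions map to `NA`.
#'
#' @inheritParams mature_to_genomic
#' @param pos 0-based genomic positions.
#' @return Integer vector of 1-based mature positions (`NA` for intronic
#'   or out-of-gene positions).
#' @export
genomic_to_mature <- function(genes, gene_id, pos) {
  n <- max(length(gene_id), length(pos))
  gene_id <- rep_len(gene_id, n)
  pos <- rep_len(as.integer(pos), n)
  i <- match(gene_id, genes$gene_id)
  if (anyNA(i)) stop("unknown gene_id", call. = FALSE)
  t0 <- ifelse(genes$strand[i] == "+", pos - genes$start[i],
               genes$end[i] - 1L - pos)
  out <- t0 + 1L
  ia <- genes$intron_after[i]
  il <- genes$intron_len[i]
  intronic <- !is.na(ia) & t0 >= ia & t0 < ia + il
  shifted <- !is.na(ia) & t0 >= ia + il
  out[shifted] <- out[shifted] - il[shifted]
  out[intronic] <- NA_integer_
  out[t0 < 0 | out > genes$mature_len[i]] <- NA_integer_
  as.integer(out)
}

#' Simulate truncation reads with ground truth
#'
#' Draws `reads_per_gene` unique cDNAs per gene per sample, assigning each
#' a read mode by the configured fractions. Truncation geometry in
#' transcript orientation:
#' * `ficc_readthrough` - reverse transcription copies the crosslinked
#'   (methylated) base and truncates, so the read 5' end sits on the
#'   methylated base itself; downstream +1 inference must recover it.
#' * `uv_stall` - RT stalls immediately before the crosslink; the 5' end
#'   is one base 3' of the crosslinked nucleotide.
#' * `m1a_stall` - RT stalls immediately before m1A58; the 5' end is one
#'   base 3' of the adenosine.
#' * `background` - uniform truncation over the gene body.
#'
#' Each unique cDNA receives a UMI drawn so that the
#' (sample, position, UMI) key is unique - UMI collisions are a
#' measurement artifact the simulator does not model - and is emitted
#' `1 + Poisson(pcr_dup_mean)` times; PCR copies share UMI and position.
#' The FASTQ-ready sequence is `UMI + sample barcode + insert`.
#'
#' @param ref A [build_reference()] object.
#' @param cfg The same [sim_config()]; defaults to `ref$config`.
#' @return List with `reads` (one row per FASTQ record: `read_id`,
#'   `sample`, `sequence`) and `truth` (one row per unique cDNA:
#'   `read_id`, `sample`, `gene_id`, `mode`, `umi`, genomic
#'   `five_prime_pos`, `read_start`/`read_end`, `methylated_base`,
#'   `expected_annotated_site`; coordinates 0-based).
#' @export
simulate_reads <- function(ref, cfg = ref$config) {
  stopifnot(inherits(ref, "ficc_reference"))
  withr::local_seed(cfg$seed + 1L)
  tl <- tloop_coords(cfg)
  genes <- ref$genes
  chrom_len <- Biostrings::width(ref$genome)[[1]]
  chrom_seq <- as.character(ref$genome[[1]])

  per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$class == "tRNA") {
      modes <- sample(
        c("ficc_readthrough", "m1a_stall", "background", "uv_stall"),
        cfg$reads_per_gene, replace = TRUE,
        prob = c(cfg$frac_major, cfg$frac_m1a, cfg$frac_background,
                 cfg$frac_uv)
      )
      mat5 <- dplyr::case_when(
        modes == "ficc_readthrough" ~ tl$u54,
        modes == "m1a_stall" ~ tl$a58 + 1L,
        modes == "uv_stall" ~ tl$u54 + 1L,
        TRUE ~ NA_integer_
      )
      meth_mat <- dplyr::case_when(
        modes == "ficc_readthrough" ~ tl$u54,
        modes == "m1a_stall" ~ tl$a58,
        modes == "uv_stall" ~ tl$u54,
        TRUE ~ NA_integer_
      )
    } else {
      # binding-only gene: UV-stall at a fixed mid-gene site + background
      site <- as.integer(g$mature_len %/% 2L)
      modes <- sample(
        c("uv_stall", "background"), cfg$reads_per_gene, replace = TRUE,
        prob = c(cfg$frac_major + cfg$frac_m1a + cfg$frac_uv,
                 cfg$frac_background)
      )
      mat5 <- ifelse(modes == "uv_stall", site + 1L, NA_integer_)
      meth_mat <- rep(NA_integer_, cfg$reads_per_gene)
    }
    bg <- is.na(mat5)
    mat5[bg] <- sample.int(g$mature_len, sum(bg), replace = TRUE)
    tibble::tibble(
      gene_id = g$gene_id, mode = modes,
      mature_five = as.integer(mat5), meth_mat = meth_mat
    )
  })
  base <- dplyr::bind_rows(per_gene)

  truth <- tidyr::expand_grid(sample = names(cfg$barcode_map), base) |>
    dplyr::arrange(.data$sample, .data$gene_id)
  n <- nrow(truth)
  truth$read_id <- sprintf("rd%07d", seq_len(n))
  truth$five_prime_pos <- mature_to_genomic(
    genes, truth$gene_id, truth$mature_five
  )
  truth$methylated_base <- ifelse(
    is.na(truth$meth_mat), NA_integer_,
    mature_to_genomic(genes, truth$gene_id,
                      ifelse(is.na(truth$meth_mat), 1L, truth$meth_mat))
  )
  gi <- match(truth$gene_id, genes$gene_id)
  strand <- genes$strand[gi]
  truth$strand <- strand
  truth$chrom <- genes$chrom[gi]
  # expected annotated site: one base 5' (transcript) of the read 5' end
  truth$expected_annotated_site <- ifelse(
    truth$mode == "background", NA_integer_,
    as.integer(ifelse(strand == "+", truth$five_prime_pos - 1L,
                      truth$five_prime_pos + 1L))
  )

  # read extent: transcript orientation from the 5' end, clipped at the
  # gene 3' end (contiguous through intronic sequence)
  truth$read_start <- as.integer(ifelse(
    strand == "+", truth$five_prime_pos,
    pmax(truth$five_prime_pos - cfg$read_len + 1L, genes$start[gi])
  ))
  truth$read_end <- as.integer(ifelse(
    strand == "+",
    pmin(truth$five_prime_pos + cfg$read_len, genes$end[gi]),
    truth$five_prime_pos + 1L
  ))

  # UMIs unique per (sample, chrom, strand, 5' position)
  truth$umi <- draw_unique_umis(
    paste(truth$sample, truth$chrom, truth$strand, truth$five_prime_pos),
    cfg$umi_len
  )

  insert <- substr(
    rep(chrom_seq, n), truth$read_start + 1L, truth$read_end
  )
  minus <- strand == "-"
  if (any(minus)) {
    insert[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(insert[minus])
    ))
  }
  full_seq <- paste0(truth$umi, cfg$barcode_map[truth$sample], insert)

  copies <- 1L + stats::rpois(n, cfg$pcr_dup_mean)
  idx <- rep.int(seq_len(n), copies)
  reads <- tibble::tibble(
    read_id = sprintf("%s.%d", truth$read_id[idx],
                      sequence(copies)),
    cdna_id = truth$read_id[idx],
    sample = truth$sample[idx],
    sequence = full_seq[idx]
  )

  truth <- dplyr::select(
    truth, "read_id", "sample", "gene_id", "mode", "umi", "chrom",
    "strand", "five_prime_pos", "read_start", "read_end",
    "mature_five", "methylated_base", "expected_annotated_site"
  )
  list(reads = reads, truth = truth)
}

draw_unique_umis <- function(group_key, umi_len) {
  n <- length(group_key)
  umi <- vapply(seq_len(n), function(i) random_dna(umi_len), character(1))
  repeat {
    dup <- duplicated(paste(group_key, umi))
    if (!any(dup)) break
    umi[dup] <- vapply(seq_len(sum(dup)), function(i) random_dna(umi_len),
                       character(1))
  }
  umi
}

#' Place simulated reads at their true loci (exact-placement aligner)
#'
#' A fixture stand-in for a genomic aligner: each trimmed read is placed
#' at the locus it was simulated from, and any read whose insert sequence
#' occurs more than once in the reference (either strand) is flagged
#' multi-mapping (`n_hits > 1`) so the downstream unique-only filter is
#' exercised.
#'
#' @param tagged Tibble from [demultiplex_trim()] (`read_id`, `sample`,
#'   `umi`, `sequence`).
#' @param ref A [build_reference()] object.
#' @param truth Truth table from [simulate_reads()].
#' @return Alignment tibble: `read_id`, `sample`, `umi`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `five_prime_pos`,
#'   `n_hits`, `sequence`.
#' @export
align_synthetic <- function(tagged, ref, truth) {
  stopifnot(inherits(ref, "ficc_reference"))
  cdna <- sub("\\.\\d+$", "", tagged$read_id)
  ti <- match(cdna, truth$read_id)
  if (anyNA(ti)) stop("read not derivable from reference: ",
                      tagged$read_id[which(is.na(ti))[1]], call. = FALSE)
  aln <- tibble::tibble(
    read_id = tagged$read_id,
    sample = tagged$sample,
    umi = tagged$umi,
    chrom = truth$chrom[ti],
    strand = truth$strand[ti],
    start = truth$read_start[ti],
    end = truth$read_end[ti],
    five_prime_pos = truth$five_prime_pos[ti],
    sequence = tagged$sequence
  )
  # verify placement and count genomic occurrences per unique insert
  chrom_seq <- ref$genome[[1]]
  uniq <- unique(aln$sequence)
  fwd <- Biostrings::DNAStringSet(uniq)
  hits <- vapply(seq_along(uniq), function(i) {
    p <- fwd[[i]]
    Biostrings::countPattern(p, chrom_seq) +
      Biostrings::countPattern(Biostrings::reverseComplement(p), chrom_seq)
  }, integer(1))
  aln$n_hits <- hits[match(aln$sequence, uniq)]
  ref_span <- as.character(Biostrings::subseq(
    ref$genome[[1]], min(aln$start) + 1L, max(aln$end)
  ))
  check <- sample(nrow(aln), min(nrow(aln), 50L))
  for (j in check) {
    s <- substr(as.character(ref$genome[[1]]), aln$start[j] + 1L, aln$end[j])
    if (aln$strand[j] == "-") s <- revcomp_chr(s)
    if (s != aln$sequence[j]) {
      stop("internal consistency error: read ", aln$read_id[j],
           " does not match the reference at its truth locus",
           call. = FALSE)
    }
  }
  aln
}

#' @name write_reference
#' @title Write simulator outputs in standard formats
#' @description `write_reference()` writes the genome FASTA, a BED6 gene
#'   annotation (0-based half-open; score = 0) and a tab-separated
#'   structural region table. `write_fastq()` writes Phred+33 FASTQ with
#'   constant quality. `write_sam()` writes exact-placement SAM records
#'   with `@SQ` headers, flag 16 for minus-strand placements, `NH` tags
#'   carrying the hit count, and read names `id#sample#UMI`.
#'   `write_truth()` writes the ground-truth table as TSV.
#' @param ref A [build_reference()] object.
#' @param dir Output directory (created if needed).
#' @return The written file path(s), invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome, fa)
  bed <- file.path(dir, "genes.bed")
  readr::write_tsv(
    dplyr::transmute(ref$genes, .data$chrom, .data$start, .data$end,
                     name = .data$gene_id, score = 0L, .data$strand),
    bed, col_names = FALSE
  )
  reg <- file.path(dir, "regions.tsv")
  rg <- ref$regions
  rg$genomic_start <- mature_to_genomic(ref$genes, rg$gene_id,
                                        rg$mature_start)
  rg$genomic_end <- mature_to_genomic(ref$genes, rg$gene_id, rg$mature_end)
  readr::write_tsv(rg, reg)
  invisible(c(fa, bed, reg))
}

#' @rdname write_reference
#' @param reads Read tibble from [simulate_reads()].
#' @param path Output file path.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_reference
#' @param aln Alignment tibble from [align_synthetic()].
#' @export
write_sam <- function(aln, ref, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
            Biostrings::width(ref$genome))
  )
  seq_fwd <- aln$sequence
  minus <- aln$strand == "-"
  if (any(minus)) {
    seq_fwd[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq_fwd[minus])
    ))
  }
  rec <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
    paste(aln$read_id, aln$sample, aln$umi, sep = "#"),
    ifelse(minus, 16L, 0L),
    aln$chrom,
    aln$start + 1L,
    ifelse(aln$n_hits > 1L, 0L, 255L),
    aln$end - aln$start,
    seq_fwd,
    strrep("I", nchar(seq_fwd)),
    aln$n_hits
  )
  readr::write_lines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_reference
#' @param truth Truth tibble from [simulate_reads()].
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Read FASTQ into a tibble
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x)
  )
}
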