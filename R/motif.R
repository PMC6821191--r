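#' Extract fixed-width flanks around crosslink peaks
#'
#' Takes `flank` nt upstream and downstream of each peak position
#' (window width `2 * flank + 1`, crosslink at the centre), strand-aware:
#' minus-strand windows are reverse-complemented so all sequences read in
#' transcript orientation. Windows truncated at chromosome ends are
#' padded with `N` and flagged.
#'
#' @param peaks Peak tibble with `chrom`, `strand`, `pos` (0-based).
#' @param genome A [Biostrings::DNAStringSet] (the simulator genome or
#'   any reference).
#' @param flank Flank width in nt (default 50).
#' @return Tibble `peak_id`, `chrom`, `strand`, `pos`, `sequence`,
#'   `padded`.
#' @export
extract_flanks <- function(peaks, genome, flank = 50L) {
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  left <- peaks$pos - flank
  right <- peaks$pos + flank
  lo <- pmax(left, 0L)
  hi <- pmin(right, chrom_len[peaks$chrom] - 1L)
  core <- as.character(Biostrings::subseq(
    genome[peaks$chrom], start = lo + 1L, end = hi + 1L
  ))
  seqs <- paste0(strrep("N", lo - left), core, strrep("N", right - hi))
  minus <- peaks$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])
    ))
  }
  tibble::tibble(
    peak_id = sprintf("peak_%d", seq_len(nrow(peaks))),
    chrom = peaks$chrom, strand = peaks$strand, pos = peaks$pos,
    sequence = seqs,
    padded = (lo > left) | (hi < right)
  )
}

#' Discover the top enriched k-mer against dinucleotide shuffles
#'
#' Counts all k-mers over the flank sequences (same strand only; reverse
#' complements are not scanned) and ranks them by the ratio of observed
#' occurrences to their mean occurrences (plus a pseudocount of 1) in
#' `n_shuffles` dinucleotide-preserving per-sequence shuffles. The
#' reported score is the empirical shuffle p-value of the winning k-mer
#' against the null distribution of the best k-mer count per shuffle
#' replicate, `(1 + #shuffles whose maximal k-mer count >= the winner's
#' observed count) / (n_shuffles + 1)`, with floor `1 / (n_shuffles +
#' 1)`; comparing against the per-replicate maximum corrects for
#' selecting the most enriched of all 4^k candidates.
#'
#' @param flanks Tibble from [extract_flanks()] (or any tibble with a
#'   `sequence` column).
#' @param k Motif width (default 7).
#' @param n_shuffles Number of shuffle replicates (default 100).
#' @param seed Integer seed.
#' @param min_seqs Minimum number of usable sequences (default 10).
#' @return Object of class `ficc_motif`: list with `kmer`, `ratio`,
#'   `pvalue`, `observed`, `shuffle_mean`, `k`, `n_shuffles`, `n_seqs`.
#'   All-N input yields an empty result (`kmer = NA`).
#' @export
discover_motif <- function(flanks, k = 7L, n_shuffles = 100L, seed = 1L,
                           min_seqs = 10L) {
  stopifnot(k >= 4L, n_shuffles >= 1L)
  seqs <- flanks$sequence
  usable <- vapply(seqs, function(s) {
    any(gregexpr("[ACGT]+", s)[[1]] > 0) &&
      max(attr(gregexpr("[ACGT]+", s)[[1]], "match.length")) >= k
  }, logical(1))
  empty <- structure(
    list(kmer = NA_character_, ratio = NA_real_, pvalue = NA_real_,
         observed = NA_real_, shuffle_mean = NA_real_, k = k,
         n_shuffles = n_shuffles, n_seqs = sum(usable)),
    class = "ficc_motif"
  )
  if (sum(usable) == 0) return(empty)
  if (sum(usable) < min_seqs) {
    stop("need >= ", min_seqs, " usable sequences (got ", sum(usable), ")",
         call. = FALSE)
  }
  seqs <- seqs[usable]
  withr::local_seed(seed)

  obs <- kmer_counts(seqs, k)
  shuf_tot <- numeric(length(obs))
  shuf_max <- numeric(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    sc <- kmer_counts(vapply(seqs, dinuc_shuffle, character(1)), k)
    shuf_tot <- shuf_tot + sc
    shuf_max[i] <- max(sc)
  }
  shuf_mean <- shuf_tot / n_shuffles
  # +1 pseudocount on the shuffle mean: keeps singleton k-mers that never
  # appear in shuffles from outranking genuinely recurrent motifs
  ratio <- obs / (shuf_mean + 1)
  cand <- which(obs > 0)
  if (length(cand) == 0) return(empty)
  # max ratio; ties -> larger observed count, then lexicographic k-mer
  ord <- cand[order(-ratio[cand], -obs[cand], names(obs)[cand])]
  top <- ord[1]
  structure(
    list(
      kmer = names(obs)[top],
      ratio = unname(ratio[top]),
      pvalue = unname((1 + sum(shuf_max >= obs[top])) / (n_shuffles + 1)),
      observed = unname(obs[top]),
      shuffle_mean = unname(shuf_mean[top]),
      k = k, n_shuffles = n_shuffles, n_seqs = length(seqs)
    ),
    class = "ficc_motif"
  )
}

kmer_counts <- function(seqs, k) {
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k
  )
  colSums(m)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: the sequence is viewed as an Eulerian walk
#' on the dinucleotide transition multigraph; a random last-edge tree
#' into the terminal vertex is drawn (rejection sampling over uniform
#' last-edge choices), remaining out-edges are permuted, and the walk is
#' rebuilt. First and last characters and all dinucleotide counts are
#' preserved exactly. Runs of non-ACGT characters (e.g. `N` padding) are
#' held fixed and each ACGT run is shuffled independently.
#'
#' @param seq A nucleotide string.
#' @return A shuffled string of the same length.
#' @export
dinuc_shuffle <- function(seq) {
  m <- gregexpr("[ACGT]+", seq)[[1]]
  if (m[1] == -1) return(seq)
  out <- seq
  for (i in seq_along(m)) {
    s <- m[i]
    e <- s + attr(m, "match.length")[i] - 1L
    substr(out, s, e) <- dinuc_shuffle_run(substr(seq, s, e))
  }
  out
}

dinuc_shuffle_run <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  if (n <= 3L) return(s)
  verts <- unique(x)
  from <- x[-n]
  to <- x[-1]
  last <- x[n]
  edges <- split(to, factor(from, levels = verts))
  inner <- setdiff(verts, last)
  # rejection-sample a last-edge choice per non-terminal vertex forming a
  # tree into the terminal vertex (<= 4 vertices: acceptance is high)
  for (attempt in seq_len(10000L)) {
    pick <- vapply(inner, function(v) {
      ev <- edges[[v]]
      ev[sample.int(length(ev), 1L)]
    }, character(1))
    reach <- vapply(inner, function(v) {
      seen <- character(0)
      while (v != last && !(v %in% seen)) {
        seen <- c(seen, v)
        v <- if (v %in% inner) pick[[v]] else break
      }
      identical(v, last)
    }, logical(1))
    if (all(reach)) break
    if (attempt == 10000L) return(s)  # pathological; give up unshuffled
  }
  new_edges <- lapply(verts, function(v) {
    ev <- edges[[v]]
    if (v %in% inner) {
      idx <- which(ev == pick[[v]])[1]
      rest <- ev[-idx]
      c(rest[sample.int(length(rest))], ev[idx])
    } else {
      ev[sample.int(length(ev))]
    }
  })
  names(new_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- x[1]
  v <- x[1]
  for (i in 2:n) {
    nxt <- new_edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Anchor-filter motif matches and build a PWM
#'
#' Finds exact occurrences of `kmer` in each flank sequence, records each
#' match's start offset relative to the window centre (the crosslink
#' site, offset 0), determines the modal offset `m`, and retains matches
#' with offset in `{m-1, m, m+1}` whose motif span contains the centre.
#' The position-weight matrix is built from the retained, aligned match
#' windows.
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param kmer Motif string (e.g. from [discover_motif()]).
#' @param flank Flank width used to build the windows (centre index);
#'   default inferred from the sequence width.
#' @return List of class `ficc_anchor`: `pwm` (4 x k matrix, columns sum
#'   to 1), `anchor_offset` (modal offset), `n_matches` (retained),
#'   `matches` (tibble `peak_id`, `offset`, `window`). No match spanning
#'   the centre yields an empty result with a warning.
#' @export
filter_anchor <- function(flanks, kmer, flank = NULL) {
  k <- nchar(kmer)
  if (is.null(flank)) flank <- (nchar(flanks$sequence[1]) - 1L) %/% 2L
  hits <- purrr::map2(flanks$sequence, flanks$peak_id, function(s, id) {
    g <- gregexpr(kmer, s, fixed = TRUE)[[1]]
    if (g[1] == -1) return(NULL)
    tibble::tibble(peak_id = id, offset = as.integer(g) - 1L - flank)
  }) |>
    dplyr::bind_rows()
  empty <- list(
    pwm = matrix(numeric(0), nrow = 4, ncol = 0,
                 dimnames = list(c("A", "C", "G", "T"), NULL)),
    anchor_offset = NA_integer_, n_matches = 0L,
    matches = tibble::tibble(peak_id = character(), offset = integer(),
                             window = character())
  )
  class(empty) <- "ficc_anchor"
  if (nrow(hits) == 0) {
    warning("no motif match found", call. = FALSE)
    return(empty)
  }
  tb <- table(hits$offset)
  modal <- as.integer(names(tb)[which.max(tb)])
  keep <- hits |>
    dplyr::filter(
      abs(.data$offset - modal) <= 1L,
      .data$offset <= 0L, .data$offset + k > 0L  # span contains centre
    )
  if (nrow(keep) == 0) {
    warning("no anchored match spans the crosslink centre", call. = FALSE)
    empty$anchor_offset <- modal
    return(empty)
  }
  keep$window <- substr(
    flanks$sequence[match(keep$peak_id, flanks$peak_id)],
    flank + 1L + keep$offset, flank + keep$offset + k
  )
  pwm <- window_pwm(keep$window)
  structure(
    list(pwm = pwm, anchor_offset = modal, n_matches = nrow(keep),
         matches = keep),
    class = "ficc_anchor"
  )
}

window_pwm <- function(windows) {
  k <- nchar(windows[1])
  mat <- matrix(0, nrow = 4, ncol = k,
                dimnames = list(c("A", "C", "G", "T"), seq_len(k)))
  chars <- do.call(rbind, strsplit(windows, ""))
  for (j in seq_len(k)) {
    tb <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    mat[, j] <- as.numeric(tb) / sum(tb)
  }
  mat
}

#' @export
print.ficc_motif <- function(x, ...) {
  if (is.na(x$kmer)) {
    cat("no motif (empty or all-N input)\n")
  } else {
    cat(sprintf(
      "top %d-mer: %s  enrichment %.2fx  shuffle p = %.4g (%d seqs, %d shuffles)\n",
      x$k, x$kmer, x$ratio, x$pvalue, x$n_seqs, x$n_shuffles
    ))
  }
  invisible(x)
}

#' Tidy a motif-discovery result
#'
#' @param x A `ficc_motif` object.
#' @param ... Unused.
#' @return One-row tibble of the top k-mer and its statistics.
#' @method tidy ficc_motif
#' @export
tidy.ficc_motif <- function(x, ...) {
  tibble::tibble(
    kmer = x$kmer, ratio = x$ratio, pvalue = x$pvalue,
    observed = x$observed, shuffle_mean = x$shuffle_mean
  )
}

#' Summarise a motif-discovery run in one row
#'
#' @inheritParams tidy.ficc_motif
#' @return One-row tibble: `k`, `n_shuffles`, `n_seqs`, `kmer`, `pvalue`.
#' @method glance ficc_motif
#' @export
glance.ficc_motif <- function(x, ...) {
  tibble::tibble(k = x$k, n_shuffles = x$n_shuffles, n_seqs = x$n_seqs,
                 kmer = x$kmer, pvalue = x$pvalue)
}

#' Tidy an anchored-PWM result
#'
#' @param x A `ficc_anchor` object.
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `probability`.
#' @method tidy ficc_anchor
#' @export
tidy.ficc_anchor <- function(x, ...) {
  if (ncol(x$pwm) == 0) {
    return(tibble::tibble(position = integer(), base = character(),
                          probability = numeric()))
  }
  tibble::tibble(
    position = rep(seq_len(ncol(x$pwm)), each = 4L),
    base = rep(rownames(x$pwm), ncol(x$pwm)),
    probability = as.numeric(x$pwm)
  )
}
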