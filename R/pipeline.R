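#' Full pipeline configuration
#'
#' Collects every stage parameter in one nested list so a run is a pure
#' function of (config, seed). Every parameter the underlying method
#' leaves open is surfaced here with its default. The structure is
#' YAML-serialisable; see [read_run_config()].
#'
#' @param sim Simulation block; a [sim_config()] or a named list of
#'   overrides for it.
#' @param demux List: `max_mismatch` (barcode mismatches tolerated).
#' @param call List: `n_perm`, `alpha` (permutation FDR caller).
#' @param peaks List: `max_gap`, `rel_threshold`, `min_dist`,
#'   `merge_tol`, `min_total`, `min_count`, `norm_method`.
#' @param motif List: `flank`, `k`, `n_shuffles`.
#' @param seed Master seed; stage seeds derive from it.
#' @return A validated list of class `ficc_run_config`.
#' @export
run_config <- function(sim = list(),
                       demux = list(max_mismatch = 1L),
                       call = list(n_perm = 100L, alpha = 0.05),
                       peaks = list(max_gap = 15L, rel_threshold = 0.1,
                                    min_dist = 2L, merge_tol = 3L,
                                    min_total = 10, min_count = 5,
                                    norm_method = "median_ratio"),
                       motif = list(flank = 50L, k = 7L,
                                    n_shuffles = 100L),
                       seed = 1L) {
  known <- function(x, allowed, block) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop("unknown ", block, " config key(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (!inherits(sim, "ficc_sim_config")) {
    known(sim, names(formals(sim_config)), "sim")
    sim$seed <- sim$seed %||% seed
    sim <- do.call(sim_config, sim)
  }
  defaults <- formals(run_config)
  for (blk in c("demux", "call", "peaks", "motif")) {
    d <- eval(defaults[[blk]])
    x <- get(blk)
    known(x, names(d), blk)
    d[names(x)] <- x
    assign(blk, d)
  }
  structure(
    list(sim = sim, demux = demux, call = call, peaks = peaks,
         motif = motif, seed = as.integer(seed)),
    class = "ficc_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the nested blocks of [run_config()]; unknown keys
#' are a validation error naming the key.
#'
#' @param path YAML file.
#' @return A `ficc_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(y), c(names(formals(run_config))))
  if (length(known) > 0) {
    stop("unknown config key(s): ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

#' Run the full synthetic pipeline end to end
#'
#' Executes simulate -> demultiplex -> align -> dedup -> crosslink
#' extraction -> permutation FDR calling -> clustering/refinement ->
#' replicate merging -> cluster counting -> normalisation ->
#' correlation -> consensus projection -> methylated-base inference ->
#' motif discovery -> annotation, writing each stage's report under
#' `outdir` as TSV (plus FASTA/BED/FASTQ/SAM/bedGraph for the simulated
#' inputs and tracks) and a YAML manifest recording parameters and
#' seeds. Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config A [run_config()] object (or YAML path).
#' @param outdir Output directory.
#' @param write_files Write per-stage files (default `TRUE`); `FALSE`
#'   runs in memory only.
#' @return A list of all stage results, invisibly when writing.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         write_files = !is.null(outdir)) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ficc_run_config"))
  if (write_files && is.null(outdir)) {
    stop("outdir required when write_files = TRUE", call. = FALSE)
  }
  cfg <- config$sim
  res <- list(config = config)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res$ref <- step("simulate", build_reference(cfg))
  sim <- step("simulate", simulate_reads(res$ref, cfg))
  res$truth <- sim$truth
  if (write_files) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_reference(res$ref, file.path(outdir, "reference"))
    write_fastq(sim$reads, file.path(outdir, "reads.fastq"))
    write_truth(sim$truth, file.path(outdir, "truth.tsv"))
  }

  res$tagged <- step("demux", demultiplex_trim(
    sim$reads, cfg$barcode_map, cfg$umi_len,
    max_mismatch = config$demux$max_mismatch
  ))
  res$aln <- step("align", align_synthetic(
    dplyr::filter(res$tagged, .data$sample != "undetermined"),
    res$ref, sim$truth
  ))
  if (write_files) {
    write_sam(res$aln, res$ref, file.path(outdir, "aligned.sam"))
  }

  res$cdnas <- step("dedup", dedup(res$aln))
  res$sites <- step("xlink", extract_crosslinks(
    res$cdnas,
    chrom_sizes = stats::setNames(Biostrings::width(res$ref$genome),
                                  names(res$ref$genome))
  ))
  if (write_files) {
    write_tracks(res$sites, file.path(outdir, "tracks"))
  }

  res$called <- step("call", call_significant(
    res$sites, res$ref$genes,
    n_perm = config$call$n_perm, alpha = config$call$alpha,
    seed = config$seed + 101L
  ))
  sig <- dplyr::filter(res$called, .data$significant)
  res$peaks <- step("peaks", refine_maxima(
    cluster_sites(sig, max_gap = config$peaks$max_gap),
    rel_threshold = config$peaks$rel_threshold,
    min_dist = config$peaks$min_dist
  ))
  res$final <- step("peaks", merge_replicates(
    res$peaks, merge_tol = config$peaks$merge_tol
  ))
  res$counts <- step("peaks", count_clusters(res$final, res$cdnas))
  res$norm <- step("peaks", if (length(cfg$barcode_map) >= 2) {
    normalize_counts(res$counts, min_total = config$peaks$min_total,
                     method = config$peaks$norm_method)
  })
  res$correlation <- step("compare", if (length(cfg$barcode_map) >= 2) {
    correlate_counts(res$counts)
  })
  res$annotation <- step("annotate", annotate_peaks(res$final,
                                                    res$ref$genes))
  res$overlap <- step("compare", if (length(cfg$barcode_map) >= 2) {
    overlap_peaks(
      split(res$peaks, res$peaks$sample),
      min_count = config$peaks$min_count,
      merge_tol = config$peaks$merge_tol
    )
  })

  if (cfg$n_trna_genes > 0) {
    res$consensus <- step("consensus", build_consensus(res$ref))
    res$profile <- step("consensus", project_sites(
      res$final, res$ref$genes, res$consensus, mode = "annotated_site"
    ))
    res$methylation <- step("consensus", infer_methylated_base(
      res$final, res$ref$genes, res$consensus, mode = "catalytic"
    ))
  }

  res$flanks <- step("motif", extract_flanks(
    res$final, res$ref$genome, flank = config$motif$flank
  ))
  if (nrow(res$flanks) >= 10) {
    res$motif <- step("motif", discover_motif(
      res$flanks, k = config$motif$k,
      n_shuffles = config$motif$n_shuffles, seed = config$seed + 202L
    ))
    res$anchor <- step("motif", if (!is.na(res$motif$kmer)) {
      filter_anchor(res$flanks, res$motif$kmer,
                    flank = config$motif$flank)
    })
  } else {
    message("motif stage skipped: fewer than 10 peak flanks")
  }

  if (write_files) {
    w <- function(x, f) readr::write_tsv(x, file.path(outdir, f))
    w(res$called, "significant_sites.tsv")
    w(res$peaks, "peaks_per_replicate.tsv")
    w(res$final, "final_clusters.tsv")
    w(res$counts, "cluster_counts.tsv")
    if (!is.null(res$norm)) {
      sf <- tibble::tibble(sample = names(res$norm$size_factors),
                           size_factor = res$norm$size_factors)
      w(sf, "size_factors.tsv")
      norm <- tibble::as_tibble(res$norm$normalized, rownames = "cluster")
      w(norm, "normalized_counts.tsv")
    }
    if (!is.null(res$correlation)) {
      w(tibble::as_tibble(res$correlation, rownames = "sample"),
        "correlation.tsv")
    }
    w(res$annotation, "annotation_classes.tsv")
    if (!is.null(res$profile)) {
      w(tibble::as_tibble(res$profile), "consensus_profile.tsv")
      w(tidy(res$consensus), "consensus_regions.tsv")
    }
    if (!is.null(res$methylation)) w(res$methylation, "methylation.tsv")
    if (!is.null(res$motif) && !is.na(res$motif$kmer)) {
      w(tidy(res$motif), "motif.tsv")
      if (!is.null(res$anchor) && ncol(res$anchor$pwm) > 0) {
        pwm <- tibble::as_tibble(res$anchor$pwm, rownames = "base")
        w(pwm, "motif_pwm.tsv")
      }
    }
    manifest <- list(
      package = "ficcseq",
      version = as.character(utils::packageVersion("ficcseq")),
      seed = config$seed,
      sim = config$sim[setdiff(names(config$sim),
                               c("region_table", "barcode_map"))],
      barcodes = as.list(config$sim$barcode_map),
      demux = config$demux, call = config$call,
      peaks = config$peaks, motif = config$motif
    )
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  if (write_files) invisible(res) else res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
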