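test_that("identical canonical layouts give the identity consensus", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  expect_equal(max(cons$regions$cons_end), 76L)
  expect_equal(substr(cons$sequence, 53, 59), "GTTCGAA")
  # identity offset map, bijective per gene
  om <- cons$offset_map
  expect_true(all(om$cons_pos == om$mature_pos))
  per_gene <- dplyr::count(om, gene_id, cons_pos)
  expect_true(all(per_gene$n == 1L))
})

test_that("a single gene reproduces its own layout verbatim", {
  cfg <- small_cfg(n_trna_genes = 1L, n_other_genes = 0L,
                   reads_per_gene = 10L, intron_frac = 0)
  ref <- build_reference(cfg)
  cons <- build_consensus(ref)
  expect_equal(cons$n_genes, 1L)
  expect_equal(cons$sequence,
               unname(ficcseq:::mature_sequences(ref)))
  expect_equal(cons$regions$length, canonical_regions()$length)
})

test_that("unequal D-loops average to the rounded mean with floor scaling", {
  # two genes; D-loops of 7 and 9 nt -> consensus D-loop of 8
  rt7 <- canonical_regions()
  rt7$length[rt7$region == "d_loop"] <- 7L
  rt9 <- canonical_regions()
  rt9$length[rt9$region == "d_loop"] <- 9L
  cfg7 <- sim_config(n_trna_genes = 1L, n_other_genes = 0L,
                     mature_len = 75L, region_table = rt7,
                     reads_per_gene = 10L, intron_frac = 0, seed = 1)
  cfg9 <- sim_config(n_trna_genes = 1L, n_other_genes = 0L,
                     mature_len = 77L, region_table = rt9,
                     reads_per_gene = 10L, intron_frac = 0, seed = 2)
  r7 <- build_reference(cfg7)
  r9 <- build_reference(cfg9)
  r9$genes$gene_id <- "tRNA-99"
  r9$regions$gene_id <- "tRNA-99"
  merged <- list(
    genome = Biostrings::DNAStringSet(c(
      chrS = as.character(r7$genome[[1]]),
      chrT = as.character(r9$genome[[1]])
    )),
    genes = dplyr::bind_rows(
      r7$genes, dplyr::mutate(r9$genes, chrom = "chrT")
    ),
    regions = dplyr::bind_rows(r7$regions, r9$regions)
  )
  cons <- build_consensus(merged)
  dl <- cons$regions[cons$regions$region == "d_loop", ]
  expect_equal(dl$length, 8L)
  # hand-enumerated floor(o * 8 / l) mappings within the D-loop
  om <- cons$offset_map
  g7 <- om[om$gene_id == "tRNA-01" & om$region == "d_loop", ]
  expect_equal(g7$cons_pos - dl$cons_start,
               floor((0:6) * 8 / 7))
  g9 <- om[om$gene_id == "tRNA-99" & om$region == "d_loop", ]
  expect_equal(g9$cons_pos - dl$cons_start,
               floor((0:8) * 8 / 9))
  # order preserved, total length = sum of rounded means
  expect_equal(max(cons$regions$cons_end), 76L)
})

test_that("projection conserves mass and hits U54/A58 in simulation", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  trna <- run$ref$genes[run$ref$genes$class == "tRNA", ]
  in_trna <- dplyr::semi_join(
    run$sites,
    tibble::tibble(chrom = trna$chrom),
    by = "chrom"
  )
  prof <- project_sites(run$sites, run$ref$genes, cons)
  expect_s3_class(prof, "ficc_profile")
  expect_equal(nrow(prof), 76L)
  # mass conservation: projected mass + dropped = tRNA-overlapping mass
  gr_s <- GenomicRanges::GRanges(
    run$sites$chrom,
    IRanges::IRanges(run$sites$pos + 1L, run$sites$pos + 1L),
    strand = run$sites$strand
  )
  gr_g <- GenomicRanges::GRanges(
    trna$chrom, IRanges::IRanges(trna$start + 1L, trna$end),
    strand = trna$strand
  )
  hit <- GenomicRanges::findOverlaps(gr_s, gr_g, select = "first")
  total_in <- sum(run$sites$count[!is.na(hit)])
  dropped_mass <- total_in - sum(prof$count)
  expect_gte(dropped_mass, 0)
  # annotated-site maxima at consensus 53 (major) and 58 (sub-peak)
  ord <- prof$cons_pos[order(-prof$count)]
  expect_equal(ord[1], 53L)
  expect_equal(ord[2], 58L)
})

test_that("minus-strand genes project like their plus-strand twins", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  genes <- run$ref$genes
  trna <- genes[genes$class == "tRNA", ]
  plus <- trna[trna$strand == "+", ][1, ]
  minus <- trna[trna$strand == "-", ][1, ]
  site_at <- function(g, mature) tibble::tibble(
    sample = "s", chrom = g$chrom, strand = g$strand,
    pos = mature_to_genomic(genes, g$gene_id, mature), count = 4L
  )
  p1 <- project_sites(site_at(plus, 53L), genes, cons)
  p2 <- project_sites(site_at(minus, 53L), genes, cons)
  expect_equal(p1$count, p2$count)
  expect_equal(p1$count[p1$cons_pos == 53], 4)
})

test_that("intronic sites are dropped and logged", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  genes <- run$ref$genes
  gi <- genes[!is.na(genes$intron_after) & genes$class == "tRNA", ][1, ]
  before <- mature_to_genomic(genes, gi$gene_id, gi$intron_after)
  intron_pos <- if (gi$strand == "+") before + 1L else before - 1L
  s <- tibble::tibble(sample = "s", chrom = gi$chrom, strand = gi$strand,
                      pos = intron_pos, count = 3L)
  prof <- project_sites(s, genes, cons)
  expect_equal(sum(prof$count), 0)
  expect_equal(attr(prof, "n_dropped"), 1L)
})

test_that("catalytic +1 inference recovers the methylated base", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  genes <- run$ref$genes
  trna <- genes[genes$class == "tRNA", ]
  # annotated major site at mature 53 -> methylated base at 54
  ann <- tibble::tibble(
    chrom = trna$chrom, strand = trna$strand,
    pos = mature_to_genomic(trna, trna$gene_id, 53L)
  )
  cat53 <- infer_methylated_base(ann, genes, cons, mode = "catalytic")
  expect_true(all(cat53$mature_pos == 54L))
  expect_true(all(cat53$cons_pos == 54L))
  expect_false(any(cat53$boundary))
  # minus-strand transcript +1 is genomic -1
  m <- cat53[cat53$strand == "-", ]
  expect_true(all(m$meth_pos == m$pos - 1L))
  p <- cat53[cat53$strand == "+", ]
  expect_true(all(p$meth_pos == p$pos + 1L))
  # UV mode leaves the annotated position unchanged
  uv <- infer_methylated_base(ann, genes, cons, mode = "uv")
  expect_true(all(uv$meth_pos == uv$pos))
  expect_true(all(uv$cons_pos == 53L))
  # +1 beyond the gene end is a boundary case
  last <- tibble::tibble(
    chrom = trna$chrom[1], strand = trna$strand[1],
    pos = mature_to_genomic(trna, trna$gene_id[1],
                            trna$mature_len[1])
  )
  out <- infer_methylated_base(last, genes, cons, mode = "catalytic")
  expect_true(out$boundary)
  expect_true(is.na(out$cons_pos))
})

test_that("sub-peak geometry: 5 nt between annotated sites, 4 after +1", {
  run <- small_run()
  cons <- build_consensus(run$ref)
  called <- call_significant(run$sites, run$ref$genes, seed = 5)
  peaks <- refine_maxima(cluster_sites(dplyr::filter(called, significant)))
  final <- merge_replicates(peaks)
  meth <- infer_methylated_base(final, run$ref$genes, cons,
                                mode = "catalytic")
  trna <- dplyr::filter(meth, grepl("tRNA", gene_id))
  per_gene <- trna |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      major_meth = cons_pos[which.max(total_count)],
      sub_ann = {
        ann <- genomic_to_mature(
          run$ref$genes, gene_id, pos
        )
        ann[which.min(total_count)]
      },
      dist_ann = max(
        genomic_to_mature(run$ref$genes, gene_id, pos)
      ) - min(genomic_to_mature(run$ref$genes, gene_id, pos)),
      dist_meth_sub = sub_ann - major_meth
    )
  expect_true(all(per_gene$major_meth == 54L))
  expect_true(all(per_gene$sub_ann == 58L))
  expect_true(all(per_gene$dist_ann == 5L))
  expect_true(all(per_gene$dist_meth_sub == 4L))
})
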