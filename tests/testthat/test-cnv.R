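make_cov <- function(id, counts, bin = 1000L, chrom = "chr1") {
  tibble::tibble(
    sample_id = id, chrom = chrom,
    start = (seq_along(counts) - 1L) * bin, end = seq_along(counts) * bin,
    read_count = counts
  )
}

test_that("identical test and control give an all-zero track", {
  set.seed(1)
  counts <- rpois(50, 100)
  trk <- log2_ratio_track(make_cov("T", counts), make_cov("N", counts))
  expect_true(all(trk$log2_ratio == 0))
})

test_that("library-size normalization cancels any per-track scaling exactly", {
  set.seed(2)
  t_counts <- rpois(60, 120)
  n_counts <- rpois(60, 80)
  base <- log2_ratio_track(make_cov("T", t_counts), make_cov("N", n_counts))
  doubled_control <- log2_ratio_track(make_cov("T", t_counts),
                                      make_cov("N", n_counts * 2L))
  scaled_test <- log2_ratio_track(make_cov("T", t_counts * 7L),
                                  make_cov("N", n_counts))
  expect_equal(doubled_control$log2_ratio, base$log2_ratio, tolerance = 1e-12)
  expect_equal(scaled_test$log2_ratio, base$log2_ratio, tolerance = 1e-12)
})

test_that("group contrast is exactly antisymmetric under group swap", {
  set.seed(3)
  g1 <- dplyr::bind_rows(
    make_cov("A1", rpois(40, 100)), make_cov("A2", rpois(40, 150))
  )
  g2 <- dplyr::bind_rows(
    make_cov("B1", rpois(40, 90)), make_cov("B2", rpois(40, 200))
  )
  fwd <- group_contrast_track(g1, g2)
  rev <- group_contrast_track(g2, g1)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio, tolerance = 1e-12)
})

test_that("binning mismatches are rejected", {
  expect_error(
    log2_ratio_track(make_cov("T", rpois(10, 50)), make_cov("N", rpois(12, 50))),
    "binning"
  )
})

test_that("segments tile the binned territory and a flat track is all neutral", {
  set.seed(4)
  trk <- log2_ratio_track(
    dplyr::bind_rows(make_cov("T", rpois(50, 500)),
                     make_cov("T2", rpois(50, 500), chrom = "chr2")) |>
      dplyr::mutate(sample_id = "T"),
    dplyr::bind_rows(make_cov("N", rpois(50, 500)),
                     make_cov("N", rpois(50, 500), chrom = "chr2"))
  )
  seg <- call_segments(trk, 1.0)
  expect_true(all(seg$state == "neutral"))
  per_chrom <- tapply(seg$end - seg$start, seg$chrom, sum)
  expect_true(all(per_chrom == 50 * 1000))
  # segments are disjoint and sorted within each chromosome
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    expect_true(all(diff(s$start) > 0))
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  }
})

test_that("a planted 2x amplification is recovered with Jaccard >= 0.9 at cutoff 1.0", {
  set.seed(11)
  n_bins <- 400
  mult <- rep(1, n_bins)
  planted <- 101:130
  mult[planted] <- 2
  trk <- log2_ratio_track(
    make_cov("T", rpois(n_bins, 300 * mult)),
    make_cov("N", rpois(n_bins, 300))
  )
  seg <- call_segments(trk, cutoff = 1.0)
  amp <- seg[seg$state == "amplified", ]
  expect_gte(nrow(amp), 1)
  planted_iv <- c((min(planted) - 1) * 1000, max(planted) * 1000)
  inter <- sum(pmax(0, pmin(amp$end, planted_iv[2]) - pmax(amp$start, planted_iv[1])))
  union <- sum(amp$end - amp$start) + diff(planted_iv) - inter
  expect_gte(inter / union, 0.9)
  expect_gt(amp$mean_log2[1], 0.5)
})

test_that("unstable runs beyond the SD band are not called", {
  # mean log2 well above cutoff but wildly fluctuating: stability filter
  vals <- rep(c(2.5, 0.6), 10)
  trk <- tibble::tibble(
    chrom = "chr1", start = (0:19) * 1000L, end = (1:20) * 1000L,
    log2_ratio = vals
  )
  seg <- call_segments(trk, cutoff = 1.0, sd_band = 0.5)
  expect_true(all(seg$state == "neutral"))
  # the same run with the fluctuation removed is called
  trk$log2_ratio <- rep(1.05, 20)
  seg2 <- call_segments(trk, cutoff = 1.0, sd_band = 0.5)
  expect_true(any(seg2$state == "amplified"))
})

test_that("short runs below min_bins stay neutral and cutoff is validated", {
  trk <- tibble::tibble(
    chrom = "chr1", start = (0:19) * 1000L, end = (1:20) * 1000L,
    log2_ratio = c(rep(0, 8), rep(1.2, 4), rep(0, 8))
  )
  expect_true(all(call_segments(trk, 1.0, min_bins = 5)$state == "neutral"))
  expect_true(any(call_segments(trk, 1.0, min_bins = 3)$state == "amplified"))
  expect_error(call_segments(trk, -1), "positive")
  expect_error(call_segments(trk, 0.4, sd_band = 0.5), "exceed sd_band")
})

test_that("an amplification present in both groups yields no contrast segment", {
  set.seed(12)
  n_bins <- 60
  mult <- rep(1, n_bins)
  mult[20:45] <- 2 # same event in every sample of both groups
  mk_group <- function(ids, scale = 1) {
    dplyr::bind_rows(lapply(ids, function(s) {
      make_cov(s, rpois(n_bins, 200 * mult * scale))
    }))
  }
  # different intensity per group (different library scale) cancels
  ctr <- group_contrast_track(mk_group(c("S1", "S2", "S3"), 1.4),
                              mk_group(c("L1", "L2", "L3"), 0.8))
  seg <- call_segments(ctr, cutoff = 0.8)
  expect_true(all(seg$state == "neutral"))
})

test_that("segment gene annotation equals brute-force interval overlap", {
  seg <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), start = c(0L, 5000L, 100L),
    end = c(3000L, 9000L, 900L), state = "amplified",
    mean_log2 = 1, sd_log2 = 0.1, n_bins = 5L
  )
  set.seed(21)
  genes <- tibble::tibble(
    gene = sprintf("g%d", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    start = sample(0:9500, 40)
  )
  genes$end <- genes$start + sample(100:800, 40, replace = TRUE)
  ann <- annotate_segments(seg, genes)
  brute <- oracle_overlaps(seg, genes)
  expect_equal(nrow(ann), length(brute))
  brute_pairs <- sort(vapply(brute, function(h) paste(h["i"], h["gene"]), ""))
  got_pairs <- sort(paste(match(
    paste(ann$chrom, ann$start), paste(seg$chrom, seg$start)
  ), ann$gene))
  expect_equal(got_pairs, brute_pairs)
})

test_that("half-open convention: an abutting gene does not overlap", {
  seg <- tibble::tibble(
    chrom = "chr1", start = 1000L, end = 2000L, state = "deleted",
    mean_log2 = -1.2, sd_log2 = 0.1, n_bins = 5L
  )
  genes <- tibble::tibble(
    gene = c("inside", "abut_right", "abut_left", "one_base"),
    chrom = "chr1",
    start = c(1200L, 2000L, 500L, 1999L),
    end = c(1300L, 2500L, 1000L, 2500L)
  )
  ann <- annotate_segments(seg, genes)
  expect_setequal(ann$gene, c("inside", "one_base"))
})

test_that("expression concordance flags planted discordant genes", {
  co <- generate_cohort(cohort_config(seed = 8))
  man <- co$manifest
  tum <- co$coverage$tumor
  ctr <- group_contrast_track(
    tum[tum$sample_id %in% man$sample_id[man$group == "S"], ],
    tum[tum$sample_id %in% man$sample_id[man$group == "L"], ]
  )
  seg <- call_segments(ctr, 0.8)
  ann <- annotate_segments(seg, co$gene_model)
  conc <- cnv_expression_concordance(ann, co$expression, co$manifest)
  expect_true(all(conc$concordant[conc$gene %in% co$truth$cnv$concordant_genes]))
  expect_true(all(!conc$concordant[conc$gene %in% co$truth$cnv$discordant_genes]))
  empty <- cnv_expression_concordance(ann[0, ], co$expression, co$manifest)
  expect_equal(nrow(empty), 0L)
})
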