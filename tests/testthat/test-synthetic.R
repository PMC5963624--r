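test_that("the generator is deterministic in its seed", {
  a <- generate_cohort(cohort_config(seed = 101))
  b <- generate_cohort(cohort_config(seed = 101))
  expect_identical(a$variants, b$variants)
  expect_identical(a$expression, b$expression)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(seed = 102))
  expect_false(identical(a$variants, c$variants))
  # planted structure sizes are seed-independent
  expect_equal(lengths(c$truth$exclusive_shared_keys),
               lengths(a$truth$exclusive_shared_keys))
  expect_equal(length(c$truth$universal_keys), length(a$truth$universal_keys))
})

test_that("planted group-exclusive structures never leak into the other group", {
  co <- generate_cohort(cohort_config(seed = 103))
  man <- co$manifest
  l_samples <- man$sample_id[man$group == "L" & man$wes]
  s_samples <- man$sample_id[man$group == "S" & man$wes]
  l_keys <- unique(variant_key(co$variants[co$variants$sample_id %in% l_samples, ]))
  s_keys <- unique(variant_key(co$variants[co$variants$sample_id %in% s_samples, ]))
  expect_length(intersect(co$truth$exclusive_shared_keys$S, l_keys), 0)
  expect_length(intersect(co$truth$exclusive_shared_keys$L, s_keys), 0)
  l_genes <- unique(co$variants$gene[co$variants$sample_id %in% l_samples])
  s_genes <- unique(co$variants$gene[co$variants$sample_id %in% s_samples])
  expect_length(intersect(co$truth$exclusive_genes$S, l_genes), 0)
  expect_length(intersect(co$truth$exclusive_genes$L, s_genes), 0)
  # universal keys really are in every exome-sequenced sample
  for (s in c(s_samples, l_samples)) {
    ks <- variant_key(co$variants[co$variants$sample_id == s, ])
    expect_true(all(co$truth$universal_keys %in% ks))
  }
})

test_that("an all-zero configuration produces an empty, flat cohort", {
  cfg <- cohort_config(
    seed = 104, n_shared_genes = 0L, n_s_only = 0L, n_l_only = 0L,
    hyper = NULL, recurrent_s_k = integer(), recurrent_l_k = integer(),
    n_excl_shared_s = 0L, n_excl_shared_l = 0L, n_universal = 0L,
    noise_sd = 0,
    venn = c(sl_only = 0L, sm_only = 0L, ml_only = 0L, sl_sm = 0L,
             sl_ml = 0L, sm_ml = 0L, triple = 0L),
    cnv_regions = tibble::tibble(
      chrom = character(), start = double(), end = double(),
      fold = double(), scope = character()
    ),
    n_concordant = 0L, n_discordant = 0L
  )
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$variants), 0L)
  # flat expression: every gene constant across samples
  vals <- as.matrix(co$expression[, -1])
  expect_true(all(apply(vals, 1, function(r) max(r) - min(r)) == 0))
})

test_that("contradictory configurations fail before generation", {
  expect_error(cohort_config(n_genes = 1e6), "capacity")
  expect_error(cohort_config(n_shared_genes = 1000L), "exceed")
  expect_error(cohort_config(recurrent_s_k = c(3L, 3L, 3L)), "WES group size")
  expect_error(
    cohort_config(hyper = tibble::tibble(s_count = 60L, l_count = 0L)),
    "shared genes"
  )
  expect_error(cohort_config(n_concordant = 100L), "sl_only")
})

test_that("the full contrast pipeline recovers the planted truth exactly", {
  co <- generate_cohort(cohort_config(seed = 105))
  cr <- contrast_report(co$variants, co$manifest)
  expect_equal(cr$gene_sets$groups$S, co$truth$mutated_genes$S)
  expect_equal(cr$gene_sets$groups$L, co$truth$mutated_genes$L)
  expect_equal(cr$exclusive_genes$S, co$truth$exclusive_genes$S)
  expect_equal(cr$exclusive_genes$L, co$truth$exclusive_genes$L)
  expect_equal(cr$hypermutated$S, co$truth$hypermutated$S)
  expect_equal(cr$hypermutated$L, co$truth$hypermutated$L)
  expect_setequal(cr$recurrent_genes$S$gene, co$truth$recurrent$S$gene)
  expect_setequal(cr$recurrent_genes$L$gene, co$truth$recurrent$L$gene)
  expect_equal(cr$exclusive_shared_variants$S, co$truth$exclusive_shared_keys$S)
  expect_equal(cr$exclusive_shared_variants$L, co$truth$exclusive_shared_keys$L)
  expect_equal(cr$universal_variants, co$truth$universal_keys)
  # per-group distinct counts of the planted hypermutators are exact
  counts <- co$truth$hyper_counts
  for (i in seq_len(nrow(counts))) {
    pg <- cr$burden$per_group
    expect_equal(pg$n_distinct[pg$gene == counts$gene[i] & pg$group == "S"],
                 counts$s_count[i])
    expect_equal(pg$n_distinct[pg$gene == counts$gene[i] & pg$group == "L"],
                 counts$l_count[i])
  }
})

test_that("paper-scale burden totals are calibrated to their targets", {
  co <- generate_cohort(paper_scale_config(seed = 106))
  s <- summarize_burden(co$variants, co$manifest)
  targets <- co$config$target_totals
  for (g in c("S", "L")) {
    expect_equal(s$n_total[s$group == g], targets[[g]][["total"]],
                 tolerance = 0.02)
    expect_equal(s$n_coding[s$group == g], targets[[g]][["coding"]],
                 tolerance = 0.03)
    expect_equal(s$n_deleterious[s$group == g], targets[[g]][["deleterious"]],
                 tolerance = 0.03)
  }
})
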