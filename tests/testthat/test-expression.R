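test_that("BH q-values match the longhand step-up rule on random inputs", {
  set.seed(88)
  for (i in 1:30) {
    n <- sample(1:20, 1)
    p <- runif(n)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("q-values dominate p-values and are monotone in rank order", {
  co <- generate_cohort(cohort_config(seed = 5, noise_sd = 0.5))
  deg <- differential_expression(co$expression, co$manifest, "S", "L")
  expect_true(all(deg$q_value >= deg$p_value - 1e-12))
  ord <- order(deg$p_value)
  expect_true(all(diff(deg$q_value[ord]) >= -1e-12))
})

test_that("identical groups with no noise yield no significant genes", {
  cfg <- cohort_config(
    seed = 9, noise_sd = 0,
    venn = c(sl_only = 0L, sm_only = 0L, ml_only = 0L, sl_sm = 0L,
             sl_ml = 0L, sm_ml = 0L, triple = 0L),
    n_concordant = 0L, n_discordant = 0L
  )
  co <- generate_cohort(cfg)
  deg <- differential_expression(co$expression, co$manifest, "S", "L")
  expect_equal(sum(deg$significant), 0L)
  expect_true(all(deg$p_value == 1))
})

test_that("a side with fewer than two samples is rejected", {
  co <- generate_cohort(cohort_config(seed = 9))
  man <- co$manifest
  man$wts[man$group == "L"][-1] <- FALSE
  expect_error(differential_expression(co$expression, man, "S", "L"), ">= 2 samples")
})

test_that("planted DEGs are recovered with high sensitivity and controlled FDR", {
  cfg <- cohort_config(
    seed = 42, noise_sd = 0.5, effect = 3,
    venn = c(sl_only = 30L, sm_only = 0L, ml_only = 0L, sl_sm = 0L,
             sl_ml = 0L, sm_ml = 0L, triple = 0L),
    n_concordant = 0L, n_discordant = 0L
  )
  co <- generate_cohort(cfg)
  deg <- differential_expression(co$expression, co$manifest, "S", "L")
  hits <- significant_genes(deg)
  truth <- co$truth$deg$sl_only
  sensitivity <- length(intersect(hits, truth)) / length(truth)
  fdr <- if (length(hits) == 0) 0 else length(setdiff(hits, truth)) / length(hits)
  expect_gte(sensitivity, 0.95)
  expect_lte(fdr, 0.1)
})

test_that("per-gene type-I error is near nominal under label permutation", {
  cfg <- cohort_config(
    seed = 43, noise_sd = 0.5,
    venn = c(sl_only = 0L, sm_only = 0L, ml_only = 0L, sl_sm = 0L,
             sl_ml = 0L, sm_ml = 0L, triple = 0L),
    n_concordant = 0L, n_discordant = 0L
  )
  co <- generate_cohort(cfg)
  man <- co$manifest
  set.seed(99)
  props <- replicate(40, {
    perm <- man
    perm$group <- sample(perm$group)
    # permuted labels deliberately break the RFS ordering warning
    deg <- suppressWarnings(differential_expression(co$expression, perm, "S", "L"))
    mean(deg$p_value < 0.05)
  })
  expect_gt(mean(props), 0.02)
  expect_lt(mean(props), 0.09)
})

test_that("venn partition equals brute-force membership enumeration", {
  co <- generate_cohort(cohort_config(seed = 12))
  deg_sl <- differential_expression(co$expression, co$manifest, "S", "L")
  deg_sm <- differential_expression(co$expression, co$manifest, "S", "M")
  deg_ml <- differential_expression(co$expression, co$manifest, "M", "L")
  vp <- venn_partition(deg_sl, deg_sm, deg_ml, names = c("SL", "SM", "ML"))
  sets <- list(
    SL = significant_genes(deg_sl),
    SM = significant_genes(deg_sm),
    ML = significant_genes(deg_ml)
  )
  union_genes <- sort(unique(unlist(sets)))
  expect_equal(sum(vp$regions$n), length(union_genes))
  for (g in union_genes) {
    in_sets <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    expect_equal(
      vp$membership$region[vp$membership$gene == g],
      paste(in_sets, collapse = "&")
    )
  }
  # row order of the input tables must not matter
  shuffle <- function(d) {
    out <- d[sample(nrow(d)), ]
    attributes(out)$comparison <- attr(d, "comparison")
    out
  }
  set.seed(4)
  vp2 <- venn_partition(shuffle(deg_sl), shuffle(deg_sm), shuffle(deg_ml),
                        names = c("SL", "SM", "ML"))
  expect_equal(vp2$regions, vp$regions)
  # disjoint significant sets produce only pure regions
  mk <- function(genes, sig) {
    out <- tibble::tibble(gene = genes, significant = genes %in% sig)
    out
  }
  genes <- sprintf("g%d", 1:9)
  vp3 <- venn_partition(
    mk(genes, genes[1:2]), mk(genes, genes[4:5]), mk(genes, genes[7:8]),
    names = c("A", "B", "C")
  )
  expect_equal(vp3$regions$n, c(2L, 2L, 2L, 0L, 0L, 0L, 0L))
  expect_error(
    venn_partition(mk(genes, genes[1]), mk(genes[-1], genes[2]), mk(genes, genes[3])),
    "gene universe"
  )
})

test_that("common DEGs are the intersection of two significant sets", {
  genes <- sprintf("g%d", 1:10)
  mk <- function(sig) tibble::tibble(gene = genes, significant = genes %in% sig)
  expect_equal(common_degs(mk(genes[1:4]), mk(genes[3:6])), c("g3", "g4"))
  expect_length(common_degs(mk(character()), mk(genes[1:5])), 0)
  expect_error(common_degs(mk(genes[1]), tibble::tibble(gene = genes[-1],
                                                        significant = FALSE)),
               "gene universe")
})

test_that("integrated report joins mutation, CNV and expression per gene", {
  co <- generate_cohort(cohort_config(seed = 6))
  b <- gene_burden(co$variants, co$manifest)
  flags <- flag_hypermutated(b)
  showcase <- co$truth$showcase_gene
  quiet <- setdiff(co$gene_model$gene, unique(co$variants$gene))[1]
  cnv_states <- tibble::tibble(gene = showcase, group = "S", state = "amplified")
  rep <- integrate_report(
    c(showcase, quiet, "NOT_A_GENE"), b, flags, co$expression, co$manifest,
    cnv_states = cnv_states
  )
  expect_equal(nrow(rep), 3L)
  row_sc <- rep[rep$gene == showcase, ]
  expect_gt(row_sc$n_variants_S, 0L)
  expect_equal(row_sc$n_variants_L, 0L) # S-private by construction
  expect_equal(row_sc$cnv_state_S, "amplified")
  expect_gt(row_sc$mean_fpkm_S, row_sc$mean_fpkm_L) # planted S-up DEG
  row_q <- rep[rep$gene == quiet, ]
  expect_equal(row_q$n_variants_S, 0L)
  expect_equal(row_q$cnv_state_S, "neutral")
  expect_false(row_q$hypermutated_S)
  # unknown gene: no silent drop, FPKM fields flagged missing
  row_na <- rep[rep$gene == "NOT_A_GENE", ]
  expect_true(is.na(row_na$mean_fpkm_S))
  expect_true(is.na(row_na$expression_tier))
})
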