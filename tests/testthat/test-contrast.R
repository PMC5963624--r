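test_that("exclusive gene sets are set differences in both directions", {
  sets <- list(groups = list(S = c("A", "B", "C"), L = c("B", "C", "D")),
               union = c("A", "B", "C", "D"))
  ex <- exclusive_genes(sets)
  expect_equal(ex$S, "A")
  expect_equal(ex$L, "D")
  same <- list(groups = list(S = c("A", "B"), L = c("A", "B")), union = c("A", "B"))
  ex0 <- exclusive_genes(same)
  expect_length(ex0$S, 0)
  expect_length(ex0$L, 0)
  expect_error(exclusive_genes(sets, "S", "X"), "unknown group")
})

test_that("variant set operations equal brute-force set computations", {
  for (seed in 101:115) {
    mc <- random_mini_cohort(seed)
    man <- mc$manifest
    sets <- oracle_key_sets(mc$variants, man$sample_id)
    s_samples <- man$sample_id[man$group == "S"]
    l_samples <- man$sample_id[man$group == "L"]

    shared_s <- shared_variant_keys(mc$variants, man, "S")
    expect_equal(shared_s, oracle_intersect_all(sets[s_samples]))

    excl <- exclusive_shared_variants(mc$variants, man, "S", "L")
    in_l <- unique(unlist(sets[l_samples]))
    in_s <- unique(unlist(sets[s_samples]))
    expect_equal(excl$S, sort(setdiff(oracle_intersect_all(sets[s_samples]), in_l)))
    expect_equal(excl$L, sort(setdiff(oracle_intersect_all(sets[l_samples]), in_s)))

    uni <- universal_variants(mc$variants, man)
    expect_equal(uni, oracle_intersect_all(sets))

    b <- gene_burden(mc$variants, man)
    gs <- mutated_gene_sets(b)
    ex <- exclusive_genes(gs)
    genes_of <- function(samples) unique(mc$variants$gene[mc$variants$sample_id %in% samples])
    expect_equal(ex$S, sort(setdiff(genes_of(s_samples), genes_of(l_samples))))
    expect_equal(ex$L, sort(setdiff(genes_of(l_samples), genes_of(s_samples))))

    # brute-force triple condition for recurrent group-private genes
    rec <- recurrent_group_genes(b, "S", "L", min_variants = 1L)
    key <- paste0(mc$variants$chrom, ":", mc$variants$pos)
    brute <- character()
    for (g in unique(mc$variants$gene)) {
      in_gene <- mc$variants$gene == g
      n_distinct_s <- length(unique(key[in_gene & mc$variants$sample_id %in% s_samples]))
      all_s <- all(vapply(
        s_samples, function(s) any(in_gene & mc$variants$sample_id == s), logical(1)
      ))
      none_l <- !any(in_gene & mc$variants$sample_id %in% l_samples)
      if (n_distinct_s > 1 && all_s && none_l) brute <- c(brute, g)
    }
    expect_setequal(rec$S$gene, brute)
  }
})

test_that("single-sample groups and partial sharing behave as documented", {
  man <- small_manifest(1, 2)
  v <- dplyr::bind_rows(
    variant_row("S1", "A", 10),
    variant_row("S1", "B", 20),
    variant_row("L1", "A", 10),
    variant_row("L2", "A", 10),
    variant_row("L1", "C", 30)
  )
  expect_length(shared_variant_keys(v, man, "S"), 2) # full key set of S1
  expect_equal(shared_variant_keys(v, man, "L"), "chr1:10:A>G")
  expect_equal(universal_variants(v, man), "chr1:10:A>G")
  # a key in only 1 of 2 L samples is not shared
  expect_false("chr1:30:A>G" %in% shared_variant_keys(v, man, "L"))
})

test_that("exclusive-shared containment invariants hold on random cohorts", {
  for (seed in 121:126) {
    mc <- random_mini_cohort(seed)
    excl <- exclusive_shared_variants(mc$variants, mc$manifest, "S", "L")
    uni <- universal_variants(mc$variants, mc$manifest)
    for (g in c("S", "L")) {
      sh <- shared_variant_keys(mc$variants, mc$manifest, g)
      expect_true(all(excl[[g]] %in% sh))
      expect_true(all(uni %in% sh))
    }
  }
})

test_that("recurrent gene rule excludes genes missing from any group sample", {
  man <- small_manifest(4, 2)
  v <- dplyr::bind_rows(
    # gene covered by 3 of 4 S samples with 6 distinct variants: excluded
    lapply(1:6, function(i) variant_row(sprintf("S%d", (i - 1) %% 3 + 1), "PARTIAL", 100 + i)),
    # gene covered by all 4 S samples with 5 distinct variants: included
    lapply(1:5, function(i) variant_row(sprintf("S%d", (i - 1) %% 4 + 1), "FULL", 300 + i))
  )
  rec <- recurrent_group_genes(gene_burden(v, man), "S", "L", 4L)
  expect_equal(rec$S$gene, "FULL")
  expect_equal(rec$S$n_distinct, 5L)
  # the same gene with a single L-sample variant becomes disqualified
  v2 <- dplyr::bind_rows(v, variant_row("L1", "FULL", 999))
  rec2 <- recurrent_group_genes(gene_burden(v2, man), "S", "L", 4L)
  expect_equal(nrow(rec2$S), 0L)
})

test_that("chi-square matches the textbook statistic and the printed p-value reading", {
  set.seed(55)
  for (i in 1:20) {
    cells <- rpois(4, 40) + 1
    ct <- contingency_test(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ct$statistic, oracle_chi2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
    expect_equal(ct$p_value, pchisq(ct$statistic, df = 1, lower.tail = FALSE))
    # swapping rows with columns (transpose) leaves the statistic unchanged
    swapped <- contingency_test(cells[1], cells[3], cells[2], cells[4])
    expect_equal(ct$statistic, swapped$statistic, tolerance = 1e-12)
  }
  flat <- contingency_test(10, 20, 10, 20)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_test(0, 0, 5, 5), "degenerate")
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  set.seed(66)
  for (i in 1:25) {
    cells <- rpois(4, 6) + 1
    ft <- contingency_test(cells[1], cells[2], cells[3], cells[4], method = "fisher")
    expect_equal(
      ft$p_value,
      oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-9
    )
  }
})

test_that("the association report builds the three documented tables", {
  mc <- random_mini_cohort(77)
  b <- gene_burden(mc$variants, mc$manifest)
  gs <- mutated_gene_sets(b)
  rep <- burden_association_report(
    gs, flag_hypermutated(b, 2), exclusive_genes(gs)
  )
  expect_equal(rep$name, c("mutated_genes", "hypermutated_genes", "exclusive_genes"))
  expect_equal(rep$a[1] + rep$b[1], length(gs$union))
  expect_equal(rep$a[2] + rep$b[2], length(gs$groups$S))
  expect_equal(rep$a[3] + rep$b[3], length(gs$groups$S))
})
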