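#' Group-exclusive mutated genes
#'
#' Genes mutated in one group and wild type in the other: the set difference
#' of the two groups' mutated-gene sets, in both directions.
#'
#' @param gene_sets Output of [mutated_gene_sets()].
#' @param g1,g2 Group labels to contrast (default S vs L).
#' @return Named list of two character vectors, one per group.
#' @export
exclusive_genes <- function(gene_sets, g1 = "S", g2 = "L") {
  sets <- gene_sets$groups
  for (g in c(g1, g2)) {
    if (!g %in% names(sets)) abort(paste0("unknown group: ", g))
  }
  out <- list(
    sort(setdiff(sets[[g1]], sets[[g2]])),
    sort(setdiff(sets[[g2]], sets[[g1]]))
  )
  names(out) <- c(g1, g2)
  out
}

.group_samples <- function(manifest, group, wes_only = TRUE) {
  if (wes_only) manifest <- manifest[manifest$wes, ]
  s <- manifest$sample_id[manifest$group == group]
  if (length(s) == 0) abort(paste0("group ", group, " has no (sequenced) samples"))
  s
}

#' Recurrent group-private genes
#'
#' Lists genes that carry more than `min_variants` distinct variants within a
#' group, are mutated in every one of that group's sequenced samples, and are
#' wild type in every sample of the other group; symmetrically for the other
#' group.
#'
#' @param burden A `gene_burden` object.
#' @param g1,g2 Group labels (default S vs L).
#' @param min_variants Strict lower bound on the per-group distinct count
#'   ("more than 4 variants" with the default 4).
#' @return Named list of tibbles (`gene`, `n_distinct`), ordered by
#'   decreasing count.
#' @export
recurrent_group_genes <- function(burden, g1 = "S", g2 = "L", min_variants = 4L) {
  stopifnot(inherits(burden, "gene_burden"))
  if (min_variants < 0) abort("min_variants must be >= 0")
  one_side <- function(ga, gb) {
    sa <- .group_samples(burden$samples, ga, wes_only = FALSE)
    .group_samples(burden$samples, gb, wes_only = FALSE) # existence check
    grp <- burden$per_group[burden$per_group$group == ga, ]
    cand <- grp$gene[grp$n_distinct > min_variants]
    covered <- burden$per_sample %>%
      dplyr::filter(.data$group == ga, .data$gene %in% cand) %>%
      dplyr::count(.data$gene) %>%
      dplyr::filter(.data$n == length(sa)) %>%
      dplyr::pull("gene")
    other <- unique(burden$per_group$gene[burden$per_group$group == gb])
    keep <- setdiff(covered, other)
    grp %>%
      dplyr::filter(.data$gene %in% keep) %>%
      dplyr::select("gene", "n_distinct") %>%
      dplyr::arrange(dplyr::desc(.data$n_distinct), .data$gene)
  }
  out <- list(one_side(g1, g2), one_side(g2, g1))
  names(out) <- c(g1, g2)
  out
}

.keys_by_sample <- function(variants, samples) {
  v <- variants[variants$sample_id %in% samples, ]
  split(variant_key(v), factor(v$sample_id, levels = samples))
}

#' Variant keys shared by every sample of a group
#'
#' @param variants Variant tibble.
#' @param manifest Cohort manifest.
#' @param group Group label.
#' @param wes_only Restrict to exome-sequenced samples (default `TRUE`).
#' @return Character vector of `chrom:pos:ref>alt` keys present in every
#'   sample of the group.
#' @export
shared_variant_keys <- function(variants, manifest, group, wes_only = TRUE) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  samples <- .group_samples(manifest, group, wes_only)
  sets <- .keys_by_sample(variants, samples)
  sort(Reduce(intersect, sets))
}

#' Variant keys universally shared within one group and absent from the other
#'
#' Keys present in every sample of `g1` and in no sample of `g2`, and
#' symmetrically.
#'
#' @inheritParams shared_variant_keys
#' @param g1,g2 Group labels (default S vs L).
#' @return Named list of two character key vectors.
#' @export
exclusive_shared_variants <- function(variants, manifest, g1 = "S", g2 = "L",
                                      wes_only = TRUE) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  one_side <- function(ga, gb) {
    shared <- shared_variant_keys(variants, manifest, ga, wes_only)
    sb <- .group_samples(manifest, gb, wes_only)
    other <- unique(variant_key(variants[variants$sample_id %in% sb, ]))
    sort(setdiff(shared, other))
  }
  out <- list(one_side(g1, g2), one_side(g2, g1))
  names(out) <- c(g1, g2)
  out
}

#' Variant keys shared by every analyzed sample
#'
#' @inheritParams shared_variant_keys
#' @param groups Groups whose samples are pooled (default: all groups in the
#'   manifest with sequenced samples).
#' @return Character vector of keys present in every sample.
#' @export
universal_variants <- function(variants, manifest, groups = NULL, wes_only = TRUE) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  if (wes_only) manifest <- manifest[manifest$wes, ]
  if (is.null(groups)) groups <- unique(manifest$group)
  samples <- manifest$sample_id[manifest$group %in% groups]
  if (length(samples) == 0) abort("no samples to intersect")
  sets <- .keys_by_sample(variants, samples)
  sort(Reduce(intersect, sets))
}

#' 2x2 contingency test
#'
#' Tests a 2x2 table laid out as rows `(a, b)` and `(c, d)`. The default is
#' the Pearson chi-square statistic without continuity correction (df = 1);
#' a Yates-corrected chi-square and Fisher's exact test are available.
#'
#' @param a,b,c,d Non-negative cell counts (row-wise).
#' @param method `"chi2"` (default), `"chi2_yates"` or `"fisher"`.
#' @param name Optional label carried into the result.
#' @return A one-row tibble: `name`, `a`, `b`, `c`, `d`, `method`,
#'   `statistic` (chi-square statistic, or the odds-ratio estimate for
#'   Fisher), `p_value`.
#' @export
contingency_test <- function(a, b, c, d,
                             method = c("chi2", "chi2_yates", "fisher"),
                             name = NA_character_) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("contingency cells must be non-negative")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: a row or column margin is zero")
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    stat <- unname(ft$estimate)
    p <- ft$p.value
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = method == "chi2_yates"))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  tibble(
    name = name, a = a, b = b, c = c, d = d,
    method = method, statistic = stat, p_value = p
  )
}

#' The three burden-association contingency tests
#'
#' Builds and tests the three 2x2 tables contrasting two groups: (i) mutated
#' versus non-mutated genes out of the mutated-gene union, (ii) hypermutated
#' versus non-hypermutated genes out of each group's mutated genes, and
#' (iii) group-exclusive versus shared mutated genes out of each group's
#' mutated genes.
#'
#' @param gene_sets Output of [mutated_gene_sets()].
#' @param hyper_flags Output of [flag_hypermutated()].
#' @param exclusive Output of [exclusive_genes()].
#' @param union_size Size of the gene universe for test (i); defaults to the
#'   size of the union of the groups' mutated-gene sets.
#' @param g1,g2 Group labels (default S vs L).
#' @param method Test method, as in [contingency_test()].
#' @return A three-row tibble of test results.
#' @export
burden_association_report <- function(gene_sets, hyper_flags, exclusive,
                                      union_size = NULL, g1 = "S", g2 = "L",
                                      method = "chi2") {
  n1 <- length(gene_sets$groups[[g1]])
  n2 <- length(gene_sets$groups[[g2]])
  if (is.null(union_size)) union_size <- length(gene_sets$union)
  # a degenerate table (zero margin, e.g. an empty cohort) is reported as a
  # skipped test with the reason, not an error
  safe <- function(a, b, c, d, name) {
    tryCatch(
      dplyr::mutate(
        contingency_test(a, b, c, d, method = method, name = name),
        note = "ok"
      ),
      error = function(e) {
        tibble(
          name = name, a = a, b = b, c = c, d = d, method = method,
          statistic = NA_real_, p_value = NA_real_,
          note = paste0("skipped: ", conditionMessage(e))
        )
      }
    )
  }
  dplyr::bind_rows(
    safe(n1, union_size - n1, n2, union_size - n2, "mutated_genes"),
    safe(
      length(hyper_flags[[g1]]), n1 - length(hyper_flags[[g1]]),
      length(hyper_flags[[g2]]), n2 - length(hyper_flags[[g2]]),
      "hypermutated_genes"
    ),
    safe(
      length(exclusive[[g1]]), n1 - length(exclusive[[g1]]),
      length(exclusive[[g2]]), n2 - length(exclusive[[g2]]),
      "exclusive_genes"
    )
  )
}

#' Full two-group contrast report
#'
#' Runs the whole gene- and variant-level set algebra for a two-group exome
#' contrast and the three association tests on the resulting counts.
#'
#' @param variants Variant tibble.
#' @param manifest Cohort manifest.
#' @param g1,g2 Groups to contrast (default S vs L).
#' @param min_variants Threshold for [recurrent_group_genes()].
#' @param hyper_threshold Threshold for [flag_hypermutated()].
#' @param method Contingency-test method.
#' @param union_size Optional gene-universe override for the mutated-gene test.
#' @return An object of class `contrast_report` with elements `gene_sets`,
#'   `exclusive_genes`, `hypermutated`, `recurrent_genes`,
#'   `exclusive_shared_variants`, `universal_variants`, `tests`, `groups`.
#' @export
contrast_report <- function(variants, manifest, g1 = "S", g2 = "L",
                            min_variants = 4L, hyper_threshold = 50L,
                            method = "chi2", union_size = NULL) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  wes <- manifest[manifest$wes & manifest$group %in% c(g1, g2), ]
  v2 <- variants[variants$sample_id %in% wes$sample_id, ]
  burden <- gene_burden(v2, wes)
  sets <- mutated_gene_sets(burden)
  excl <- exclusive_genes(sets, g1, g2)
  hyper <- flag_hypermutated(burden, hyper_threshold)
  recurrent <- recurrent_group_genes(burden, g1, g2, min_variants)
  excl_shared <- exclusive_shared_variants(v2, wes, g1, g2)
  universal <- universal_variants(v2, wes)
  tests <- burden_association_report(
    sets, hyper, excl,
    union_size = union_size, g1 = g1, g2 = g2, method = method
  )
  structure(
    list(
      gene_sets = sets, exclusive_genes = excl, hypermutated = hyper,
      recurrent_genes = recurrent, exclusive_shared_variants = excl_shared,
      universal_variants = universal, tests = tests, groups = c(g1, g2),
      burden = burden
    ),
    class = "contrast_report"
  )
}

#' @export
print.contrast_report <- function(x, ...) {
  g <- x$groups
  cat("<contrast_report> ", g[1], " vs ", g[2], "\n", sep = "")
  cat(
    "  mutated genes:            ",
    length(x$gene_sets$groups[[g[1]]]), " / ",
    length(x$gene_sets$groups[[g[2]]]),
    " (union ", length(x$gene_sets$union), ")\n", sep = ""
  )
  cat(
    "  exclusive genes:          ",
    length(x$exclusive_genes[[g[1]]]), " / ",
    length(x$exclusive_genes[[g[2]]]), "\n", sep = ""
  )
  cat(
    "  hypermutated genes:       ",
    length(x$hypermutated[[g[1]]]), " / ", length(x$hypermutated[[g[2]]]),
    "\n", sep = ""
  )
  cat(
    "  recurrent private genes:  ",
    nrow(x$recurrent_genes[[g[1]]]), " / ", nrow(x$recurrent_genes[[g[2]]]),
    "\n", sep = ""
  )
  cat(
    "  exclusive shared variants:",
    length(x$exclusive_shared_variants[[g[1]]]), "/",
    length(x$exclusive_shared_variants[[g[2]]]), "\n"
  )
  cat("  universal variants:       ", length(x$universal_variants), "\n")
  print(x$tests[, c("name", "method", "statistic", "p_value")])
  invisible(x)
}

#' @export
tidy.contrast_report <- function(x, ...) x$tests

#' @export
glance.contrast_report <- function(x, ...) {
  g <- x$groups
  tibble(
    g1 = g[1], g2 = g[2],
    n_mutated_g1 = length(x$gene_sets$groups[[g[1]]]),
    n_mutated_g2 = length(x$gene_sets$groups[[g[2]]]),
    n_union = length(x$gene_sets$union),
    n_exclusive_g1 = length(x$exclusive_genes[[g[1]]]),
    n_exclusive_g2 = length(x$exclusive_genes[[g[2]]]),
    n_hypermutated_g1 = length(x$hypermutated[[g[1]]]),
    n_hypermutated_g2 = length(x$hypermutated[[g[2]]]),
    n_recurrent_g1 = nrow(x$recurrent_genes[[g[1]]]),
    n_recurrent_g2 = nrow(x$recurrent_genes[[g[2]]]),
    n_exclusive_shared_g1 = length(x$exclusive_shared_variants[[g[1]]]),
    n_exclusive_shared_g2 = length(x$exclusive_shared_variants[[g[2]]]),
    n_universal = length(x$universal_variants)
  )
}

#' Write a contrast report to disk
#'
#' Emits `contrast_report.json` (all sets, with per-gene counts) and
#' `tests.tsv` (name, cells, method, statistic, p).
#'
#' @param x A `contrast_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_contrast_report <- function(x, dir) {
  stopifnot(inherits(x, "contrast_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    groups = x$groups,
    gene_sets = x$gene_sets,
    exclusive_genes = x$exclusive_genes,
    hypermutated = x$hypermutated,
    recurrent_genes = x$recurrent_genes,
    exclusive_shared_variants = x$exclusive_shared_variants,
    universal_variants = x$universal_variants
  )
  jsonlite::write_json(
    payload, file.path(dir, "contrast_report.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  readr::write_tsv(x$tests, file.path(dir, "tests.tsv"), progress = FALSE)
  invisible(dir)
}
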