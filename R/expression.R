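# Vectorized Welch t-test over the rows of a matrix. Degenerate rows (zero
# variance on both sides) carry no sampling noise: the test degenerates to
# exact mean comparison (p = 1 when equal, p = 0 otherwise).
.welch_rows <- function(x1, x2) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  stat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  degenerate <- se2 == 0
  zero_diff <- abs(diff) < 1e-12
  p[degenerate] <- ifelse(zero_diff[degenerate], 1, 0)
  stat[degenerate] <- ifelse(zero_diff[degenerate], 0, Inf * sign(diff[degenerate]))
  df[degenerate] <- NA_real_
  list(mean1 = m1, mean2 = m2, diff = diff, statistic = stat, df = df, p = p)
}

.expr_matrix <- function(expr, samples) {
  expr <- validate_expression(expr)
  missing <- setdiff(samples, names(expr))
  if (length(missing) > 0) {
    abort(paste0("samples absent from expression matrix: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(expr[, samples, drop = FALSE])
  rownames(m) <- expr$gene
  m
}

#' Two-sided differential expression between groups
#'
#' Welch's t-test on `log2(FPKM + 1)` for each gene, comparing one RFS group
#' against another (or against the rest of the cohort pooled), with
#' Benjamini-Hochberg FDR control. Genes with zero variance on both sides
#' are treated as exact: p = 1 when the side means agree and p = 0 when they
#' differ (no sampling noise to test against).
#'
#' @param expr Expression matrix tibble (see [read_expression()]).
#' @param manifest Cohort manifest.
#' @param g1 First group label.
#' @param g2 Second group label, or `NULL` to compare `g1` against all other
#'   samples pooled.
#' @param alpha_fdr FDR level defining the significant set (default 0.05).
#' @param wts_only Restrict to transcriptome-sequenced samples.
#' @return A `deg_table` tibble: `gene`, `mean_fpkm_1`, `mean_fpkm_2`,
#'   `log2_fc` (difference of mean `log2(FPKM+1)`, side 1 minus side 2),
#'   `statistic`, `df`, `p_value`, `q_value`, `significant`.
#' @export
differential_expression <- function(expr, manifest, g1, g2 = NULL,
                                    alpha_fdr = 0.05, wts_only = TRUE) {
  manifest <- validate_manifest(manifest)
  if (wts_only) manifest <- manifest[manifest$wts, ]
  s1 <- manifest$sample_id[manifest$group == g1]
  s2 <- if (is.null(g2)) {
    manifest$sample_id[manifest$group != g1]
  } else {
    manifest$sample_id[manifest$group == g2]
  }
  if (length(s1) < 2 || length(s2) < 2) {
    abort("each side of a differential-expression comparison needs >= 2 samples")
  }
  m <- .expr_matrix(expr, c(s1, s2))
  lx <- log2(m + 1)
  w <- .welch_rows(lx[, s1, drop = FALSE], lx[, s2, drop = FALSE])
  out <- tibble(
    gene = rownames(m),
    mean_fpkm_1 = rowMeans(m[, s1, drop = FALSE]),
    mean_fpkm_2 = rowMeans(m[, s2, drop = FALSE]),
    log2_fc = w$diff,
    statistic = w$statistic,
    df = w$df,
    p_value = w$p
  )
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha_fdr
  attr(out, "comparison") <- paste0(g1, "_vs_", if (is.null(g2)) "rest" else g2)
  attr(out, "alpha_fdr") <- alpha_fdr
  class(out) <- c("deg_table", class(out))
  out
}

#' Three-group one-way ANOVA screen
#'
#' One-way F-test on `log2(FPKM + 1)` across all groups in the manifest,
#' with the same degenerate-variance convention as
#' [differential_expression()].
#'
#' @inheritParams differential_expression
#' @return A `deg_table`-like tibble with `gene`, `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
anova_screen <- function(expr, manifest, alpha_fdr = 0.05, wts_only = TRUE) {
  manifest <- validate_manifest(manifest)
  if (wts_only) manifest <- manifest[manifest$wts, ]
  groups <- split(manifest$sample_id, manifest$group)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2) abort("ANOVA screen needs >= 2 groups with >= 2 samples")
  samples <- unlist(groups, use.names = FALSE)
  lx <- log2(.expr_matrix(expr, samples) + 1)
  n <- length(samples)
  k <- length(groups)
  grand <- rowMeans(lx)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    sub <- lx[, g, drop = FALSE]
    mg <- rowMeans(sub)
    ssb <- ssb + length(g) * (mg - grand)^2
    ssw <- ssw + rowSums((sub - mg)^2)
  }
  stat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(stat, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw == 0
  flat <- ssb < 1e-12
  p[degenerate] <- ifelse(flat[degenerate], 1, 0)
  stat[degenerate] <- ifelse(flat[degenerate], 0, Inf)
  out <- tibble(gene = rownames(lx), statistic = stat, p_value = p)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha_fdr
  attr(out, "comparison") <- "anova"
  attr(out, "alpha_fdr") <- alpha_fdr
  class(out) <- c("deg_table", class(out))
  out
}

#' Significant genes of a differential-expression table
#'
#' @param deg A `deg_table`.
#' @return Character vector of significant genes.
#' @export
significant_genes <- function(deg) {
  deg$gene[deg$significant]
}

#' @export
glance.deg_table <- function(x, ...) {
  tibble(
    comparison = attr(x, "comparison") %||% NA_character_,
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    alpha_fdr = attr(x, "alpha_fdr") %||% NA_real_
  )
}

#' @export
autoplot.deg_table <- function(object, ...) {
  df <- as_tibble(object)
  df$p_plot <- pmax(df$p_value, 1e-300)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$log2_fc, y = -log10(.data$p_plot), colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change (log2(FPKM+1) scale)", y = "-log10 p",
      colour = paste0("FDR < ", attr(object, "alpha_fdr") %||% 0.05)
    ) +
    ggplot2::theme_minimal()
}

#' Seven-region Venn partition of three DEG tables
#'
#' Partitions the union of the three significant sets into the seven regions
#' of a three-set Venn diagram.
#'
#' @param deg_1,deg_2,deg_3 `deg_table`s over the same gene universe.
#' @param names Labels for the three comparisons; defaults to each table's
#'   `comparison` attribute.
#' @return An object of class `venn_partition`: a list with `membership`
#'   (per union gene, logical flags per comparison and a `region` label) and
#'   `regions` (tibble of the 7 region counts, zero-filled).
#' @export
venn_partition <- function(deg_1, deg_2, deg_3, names = NULL) {
  tabs <- list(deg_1, deg_2, deg_3)
  if (is.null(names)) {
    names <- purrr::map_chr(
      seq_along(tabs),
      function(i) attr(tabs[[i]], "comparison") %||% paste0("set", i)
    )
  }
  universe <- sort(tabs[[1]]$gene)
  for (t in tabs[-1]) {
    if (!identical(sort(t$gene), universe)) {
      abort("venn_partition inputs must share one gene universe")
    }
  }
  sets <- purrr::map(tabs, significant_genes)
  union_genes <- sort(unique(unlist(sets)))
  mem <- tibble(gene = union_genes)
  for (i in 1:3) mem[[names[i]]] <- union_genes %in% sets[[i]]
  flags <- as.matrix(mem[, names, drop = FALSE])
  region_of <- function(row) paste(names[row], collapse = "&")
  mem$region <- apply(flags, 1, region_of)
  all_regions <- c(
    names,
    paste(names[c(1, 2)], collapse = "&"),
    paste(names[c(1, 3)], collapse = "&"),
    paste(names[c(2, 3)], collapse = "&"),
    paste(names, collapse = "&")
  )
  regions <- mem %>%
    dplyr::count(region = factor(.data$region, levels = all_regions), name = "n") %>%
    tidyr::complete(region = factor(all_regions, levels = all_regions), fill = list(n = 0L)) %>%
    dplyr::mutate(region = as.character(.data$region))
  structure(
    list(membership = mem, regions = regions, names = names),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> ", nrow(x$membership), " genes in union\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' @export
tidy.venn_partition <- function(x, ...) x$regions

#' @export
glance.venn_partition <- function(x, ...) {
  tibble(n_union = nrow(x$membership), n_regions_nonzero = sum(x$regions$n > 0))
}

#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- object$regions
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Genes significant in both of two DEG tables
#'
#' @param deg_a,deg_b `deg_table`s over the same gene universe.
#' @return Character vector: the intersection of the two significant sets.
#' @export
common_degs <- function(deg_a, deg_b) {
  if (!identical(sort(deg_a$gene), sort(deg_b$gene))) {
    abort("common_degs inputs must share one gene universe")
  }
  sort(intersect(significant_genes(deg_a), significant_genes(deg_b)))
}

#' Integrated per-gene mutation / CNV / expression report
#'
#' Joins, for a requested gene list, the per-group distinct-variant counts
#' and hypermutation flags, the per-group CNV state, and per-group mean FPKM
#' with an expression tier (tertiles of `log2(mean FPKM + 1)` over the
#' report's genes). Genes absent from the expression matrix keep their row
#' with missing FPKM fields.
#'
#' @param genes Character vector of genes to report.
#' @param burden A `gene_burden` object.
#' @param hyper_flags Output of [flag_hypermutated()].
#' @param expr Expression matrix tibble.
#' @param manifest Cohort manifest.
#' @param cnv_states Optional tibble `gene`, `group`, `state` (see
#'   [gene_cnv_states()]); absent genes get state `"neutral"`.
#' @return A tibble with one row per requested gene.
#' @export
integrate_report <- function(genes, burden, hyper_flags, expr, manifest,
                             cnv_states = NULL) {
  manifest <- validate_manifest(manifest)
  present <- sort(unique(burden$samples$group))
  out <- tibble(gene = genes)
  counts <- burden$per_group %>%
    dplyr::filter(.data$gene %in% genes) %>%
    tidyr::pivot_wider(
      names_from = "group", values_from = "n_distinct",
      values_fill = 0L, names_prefix = "n_variants_"
    )
  out <- dplyr::left_join(out, counts, by = "gene")
  for (g in present) {
    ncol_g <- paste0("n_variants_", g)
    if (!ncol_g %in% names(out)) out[[ncol_g]] <- 0L
    out[[ncol_g]][is.na(out[[ncol_g]])] <- 0L
    out[[paste0("hypermutated_", g)]] <- out$gene %in% hyper_flags[[g]]
  }
  cnv_groups <- if (is.null(cnv_states)) character() else unique(cnv_states$group)
  for (g in union(present, cnv_groups)) {
    col <- paste0("cnv_state_", g)
    if (is.null(cnv_states)) {
      out[[col]] <- "neutral"
    } else {
      st <- cnv_states[cnv_states$group == g, c("gene", "state")]
      out[[col]] <- st$state[match(out$gene, st$gene)]
      out[[col]][is.na(out[[col]])] <- "neutral"
    }
  }
  wts <- manifest[manifest$wts, ]
  expr <- validate_expression(expr)
  for (g in sort(unique(wts$group))) {
    sg <- intersect(wts$sample_id[wts$group == g], names(expr))
    mean_g <- rowMeans(as.matrix(expr[, sg, drop = FALSE]))
    out[[paste0("mean_fpkm_", g)]] <- mean_g[match(out$gene, expr$gene)]
  }
  fpkm_cols <- grep("^mean_fpkm_", names(out), value = TRUE)
  overall <- rowMeans(as.matrix(out[, fpkm_cols, drop = FALSE]))
  lt <- log2(overall + 1)
  qs <- stats::quantile(lt, probs = c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  out$expression_tier <- dplyr::case_when(
    is.na(lt) ~ NA_character_,
    lt <= qs[1] ~ "low",
    lt <= qs[2] ~ "mid",
    TRUE ~ "high"
  )
  out
}
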