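#' Per-group mutational burden summary
#'
#' Counts molecular alterations per RFS group at the occurrence level: each
#' record (one variant observed in one sample) counts once, so a variant
#' carried by four samples contributes four. Alongside the totals the coding
#' and deleterious sub-totals and their fractions are reported.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param manifest Cohort manifest (see [read_manifest()]).
#' @param wes_only Restrict to exome-sequenced samples (`wes` column of the
#'   manifest). Default `TRUE`, matching a design in which only a subset of
#'   the cohort was exome sequenced.
#' @return A tibble with one row per group present: `group`, `n_total`,
#'   `n_coding`, `n_deleterious` and the three derived fractions (defined as
#'   0 when the denominator is 0).
#' @export
summarize_burden <- function(variants, manifest, wes_only = TRUE) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  if (wes_only) manifest <- manifest[manifest$wes, ]
  unknown <- setdiff(unique(variants$sample_id), manifest$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("variant records with unknown sample_id: ", paste(unknown, collapse = ", ")))
  }
  frac <- function(num, den) ifelse(den == 0, 0, num / den)
  variants %>%
    dplyr::inner_join(manifest[, c("sample_id", "group")], by = "sample_id") %>%
    dplyr::group_by(group = .data$group) %>%
    dplyr::summarise(
      n_total = dplyr::n(),
      n_coding = sum(.data$is_coding),
      n_deleterious = sum(.data$is_deleterious),
      .groups = "drop"
    ) %>%
    tidyr::complete(
      group = intersect(.groups, manifest$group),
      fill = list(n_total = 0L, n_coding = 0L, n_deleterious = 0L)
    ) %>%
    dplyr::mutate(
      group = factor(.data$group, levels = .groups)
    ) %>%
    dplyr::arrange(.data$group) %>%
    dplyr::mutate(
      group = as.character(.data$group),
      frac_coding_of_total = frac(.data$n_coding, .data$n_total),
      frac_deleterious_of_total = frac(.data$n_deleterious, .data$n_total),
      frac_deleterious_of_coding = frac(.data$n_deleterious, .data$n_coding)
    )
}

#' Gene-by-sample burden matrix with per-group distinct counts
#'
#' For every annotated gene, counts distinct variant keys per sample and,
#' at the group level, distinct keys pooled across the group's samples (so a
#' variant shared by all of a group's samples counts once at group level).
#' Records with `gene == "."` are excluded.
#'
#' @inheritParams summarize_burden
#' @return An object of class `gene_burden`: a list with
#'   \describe{
#'     \item{per_sample}{long tibble `gene`, `sample_id`, `group`, `n_distinct`}
#'     \item{per_group}{tibble `gene`, `group`, `n_distinct` (distinct keys
#'       across the group's samples)}
#'     \item{samples}{the manifest rows used}
#'   }
#' @export
gene_burden <- function(variants, manifest, wes_only = TRUE) {
  variants <- validate_variants(variants)
  manifest <- validate_manifest(manifest)
  if (wes_only) manifest <- manifest[manifest$wes, ]
  v <- variants %>%
    dplyr::filter(.data$gene != ".") %>%
    dplyr::inner_join(manifest[, c("sample_id", "group")], by = "sample_id") %>%
    dplyr::mutate(key = variant_key(.))
  per_sample <- v %>%
    dplyr::group_by(.data$gene, .data$sample_id, .data$group) %>%
    dplyr::summarise(n_distinct = dplyr::n_distinct(.data$key), .groups = "drop")
  per_group <- v %>%
    dplyr::distinct(.data$gene, .data$group, .data$key) %>%
    dplyr::count(.data$gene, .data$group, name = "n_distinct")
  structure(
    list(per_sample = per_sample, per_group = per_group, samples = manifest),
    class = "gene_burden"
  )
}

#' @export
print.gene_burden <- function(x, ...) {
  cat(
    "<gene_burden> ", dplyr::n_distinct(x$per_group$gene), " genes, ",
    nrow(x$samples), " samples (groups: ",
    paste(sort(unique(x$samples$group)), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.gene_burden <- function(x, ...) x$per_group

#' Wide gene-by-sample matrix view of a burden object
#'
#' @param x A `gene_burden` object.
#' @return A tibble with one row per gene, one count column per sample, and
#'   one `n_<group>` distinct-count column per group.
#' @export
burden_matrix <- function(x) {
  stopifnot(inherits(x, "gene_burden"))
  wide <- x$per_sample %>%
    dplyr::select("gene", "sample_id", "n_distinct") %>%
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "n_distinct", values_fill = 0L
    )
  grp <- x$per_group %>%
    tidyr::pivot_wider(
      names_from = "group", values_from = "n_distinct",
      values_fill = 0L, names_prefix = "n_"
    )
  dplyr::left_join(wide, grp, by = "gene")
}

#' Mutated gene sets per group
#'
#' A gene belongs to a group's set if at least one of the group's samples
#' carries at least one variant in it.
#'
#' @param burden A `gene_burden` object.
#' @return A list with `groups` (named list, group -> character vector of
#'   genes) and `union` (character vector, union over all groups).
#' @export
mutated_gene_sets <- function(burden) {
  stopifnot(inherits(burden, "gene_burden"))
  present <- sort(unique(burden$samples$group))
  groups <- lapply(
    setNames(present, present),
    function(g) sort(unique(burden$per_group$gene[burden$per_group$group == g]))
  )
  list(groups = groups, union = sort(unique(unlist(groups, use.names = FALSE))))
}

#' Flag hypermutated genes
#'
#' A gene is hypermutated within a group when its per-group distinct-variant
#' count strictly exceeds `threshold` ("more than `threshold` variants per
#' gene"); the default threshold is 50.
#'
#' @param burden A `gene_burden` object.
#' @param threshold Strict lower bound on the per-group distinct count.
#' @return Named list, group -> character vector of flagged genes.
#' @export
flag_hypermutated <- function(burden, threshold = 50L) {
  stopifnot(inherits(burden, "gene_burden"))
  if (threshold < 1) abort("hypermutation threshold must be >= 1")
  present <- sort(unique(burden$samples$group))
  hit <- burden$per_group[burden$per_group$n_distinct > threshold, ]
  lapply(
    setNames(present, present),
    function(g) sort(hit$gene[hit$group == g])
  )
}

#' Write burden outputs
#'
#' Writes `burden_summary.tsv` (per-group totals and fractions) and
#' `gene_burden.tsv` (wide matrix with per-group distinct counts and
#' hypermutation flags) under `dir`.
#'
#' @param summary Output of [summarize_burden()].
#' @param burden A `gene_burden` object.
#' @param dir Output directory (created if needed).
#' @param threshold Hypermutation threshold passed to [flag_hypermutated()].
#' @return The directory, invisibly.
#' @export
write_burden <- function(summary, burden, dir, threshold = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(summary, file.path(dir, "burden_summary.tsv"), progress = FALSE)
  mat <- burden_matrix(burden)
  flags <- flag_hypermutated(burden, threshold)
  for (g in names(flags)) {
    mat[[paste0("hypermutated_", g)]] <- mat$gene %in% flags[[g]]
  }
  readr::write_tsv(mat, file.path(dir, "gene_burden.tsv"), progress = FALSE)
  invisible(dir)
}

#' Bar chart of per-group burden totals
#'
#' @param x Output of [summarize_burden()].
#' @param ... Unused.
#' @return A ggplot object showing total, coding and deleterious counts per
#'   group.
#' @export
plot_burden_summary <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x[, c("group", "n_total", "n_coding", "n_deleterious")],
    cols = -"group", names_to = "class", values_to = "n"
  )
  long$class <- factor(
    long$class, levels = c("n_total", "n_coding", "n_deleterious"),
    labels = c("total", "coding", "deleterious")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "RFS group", y = "variant occurrences", fill = NULL) +
    ggplot2::theme_minimal()
}
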