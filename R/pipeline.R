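#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are coerced
#' to numeric or logical where possible. Keys mirror the arguments of
#' [run_pipeline()].
#'
#' @param path Configuration file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    val <- p[2]
    num <- suppressWarnings(as.numeric(val))
    out[[p[1]]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}

.default_pipeline_config <- function() {
  list(
    hyper_threshold = 50, min_variants = 4, alpha_fdr = 0.05,
    cnv_cutoff_tumor_normal = 1.0, cnv_cutoff_groups = 0.8,
    sd_band = 0.5, min_bins = 5, pseudocount = 0.5,
    test_method = "chi2", seed = 1
  )
}

#' Run the full cohort-contrast pipeline
#'
#' Orchestrates burden accounting, the S-vs-L contrast set algebra and
#' association tests, three-group differential expression with Venn
#' partitioning, copy-number calling (per-group versus normal and
#' group-versus-group), and the integrated per-gene report. Stage outputs
#' are written under `out_dir` together with `summary.json` and a `MANIFEST`
#' of completed stages.
#'
#' @param config Named list (or file parsed by [read_pipeline_config()])
#'   with input paths `variants`, `manifest`, `expression`, `coverage_dir`
#'   (per-sample TSVs plus `NORMAL.tsv`), `gene_model`, and optionally the
#'   thresholds `hyper_threshold` (50), `min_variants` (4), `alpha_fdr`
#'   (0.05), `cnv_cutoff_tumor_normal` (1.0), `cnv_cutoff_groups` (0.8),
#'   `sd_band` (0.5), `min_bins` (5), `pseudocount` (0.5), `test_method`
#'   (`"chi2"`), `union_size`, `seed`.
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  for (key in c("variants", "manifest", "expression")) {
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]])) {
      abort(paste0("pipeline config must point to an existing ", key, " file"))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stages_done <- character()
  note_stage <- function(s) {
    stages_done <<- c(stages_done, s)
    writeLines(stages_done, file.path(out_dir, "MANIFEST"))
  }
  summary <- list()

  variants <- read_variants(cfg$variants)
  manifest <- read_manifest(cfg$manifest)
  expr <- read_expression(cfg$expression)
  note_stage("io")

  # ---- burden ------------------------------------------------------------
  burden_sum <- summarize_burden(variants, manifest)
  burden <- gene_burden(variants, manifest)
  write_burden(burden_sum, burden, file.path(out_dir, "burden"),
               threshold = cfg$hyper_threshold)
  summary$burden <- burden_sum
  note_stage("burden")

  # ---- contrast ----------------------------------------------------------
  contrast <- contrast_report(
    variants, manifest,
    min_variants = cfg$min_variants, hyper_threshold = cfg$hyper_threshold,
    method = cfg$test_method, union_size = cfg$union_size
  )
  write_contrast_report(contrast, file.path(out_dir, "contrast"))
  summary$gene_counts <- as.list(glance(contrast))
  summary$tests <- contrast$tests
  note_stage("contrast")

  # ---- expression --------------------------------------------------------
  wts <- manifest[manifest$wts, ]
  n_per_group <- table(factor(wts$group, levels = c("S", "M", "L")))
  deg_dir <- file.path(out_dir, "expression")
  dir.create(deg_dir, showWarnings = FALSE)
  deg_sl <- differential_expression(expr, manifest, "S", "L", cfg$alpha_fdr)
  readr::write_tsv(deg_sl, file.path(deg_dir, "deg_S_vs_L.tsv"), progress = FALSE)
  summary$deg <- list(S_vs_L = sum(deg_sl$significant))
  venn <- NULL
  if (all(n_per_group >= 2)) {
    deg_sm <- differential_expression(expr, manifest, "S", "M", cfg$alpha_fdr)
    deg_ml <- differential_expression(expr, manifest, "M", "L", cfg$alpha_fdr)
    deg_m_rest <- differential_expression(expr, manifest, "M", NULL, cfg$alpha_fdr)
    readr::write_tsv(deg_sm, file.path(deg_dir, "deg_S_vs_M.tsv"), progress = FALSE)
    readr::write_tsv(deg_ml, file.path(deg_dir, "deg_M_vs_L.tsv"), progress = FALSE)
    readr::write_tsv(deg_m_rest, file.path(deg_dir, "deg_M_vs_rest.tsv"), progress = FALSE)
    venn <- venn_partition(deg_sl, deg_sm, deg_ml)
    readr::write_tsv(venn$membership, file.path(deg_dir, "venn_partition.tsv"), progress = FALSE)
    common <- common_degs(deg_m_rest, deg_sl)
    summary$deg <- c(summary$deg, list(
      S_vs_M = sum(deg_sm$significant),
      M_vs_L = sum(deg_ml$significant),
      M_vs_rest = sum(deg_m_rest$significant),
      venn_union = nrow(venn$membership),
      venn_regions = setNames(as.list(venn$regions$n), venn$regions$region),
      common_M_and_SL = length(common)
    ))
    summary$common_degs <- common
  }
  note_stage("expression")

  # ---- cnv ---------------------------------------------------------------
  cnv_states <- NULL
  if (!is.null(cfg$coverage_dir) && !is.null(cfg$gene_model)) {
    gm <- read_gene_model(cfg$gene_model)
    cov_files <- list.files(cfg$coverage_dir, pattern = "\\.tsv$", full.names = TRUE)
    covs <- purrr::map_dfr(cov_files, read_coverage)
    normal <- covs[covs$sample_id == "NORMAL", ]
    tumor <- covs[covs$sample_id != "NORMAL", ]
    cnv_dir <- file.path(out_dir, "cnv")
    seg_by_group <- list()
    for (g in intersect(c("S", "L"), unique(manifest$group))) {
      sg <- manifest$sample_id[manifest$group == g]
      trk <- log2_ratio_track(tumor[tumor$sample_id %in% sg, ], normal,
                              cfg$pseudocount)
      seg_by_group[[g]] <- call_segments(
        trk, cfg$cnv_cutoff_tumor_normal, cfg$sd_band, cfg$min_bins
      )
    }
    contrast_trk <- group_contrast_track(
      tumor[tumor$sample_id %in% manifest$sample_id[manifest$group == "S"], ],
      tumor[tumor$sample_id %in% manifest$sample_id[manifest$group == "L"], ],
      cfg$pseudocount
    )
    contrast_seg <- call_segments(
      contrast_trk, cfg$cnv_cutoff_groups, cfg$sd_band, cfg$min_bins
    )
    seg_genes <- annotate_segments(contrast_seg, gm)
    concord <- cnv_expression_concordance(seg_genes, expr, manifest)
    write_cnv(contrast_seg, seg_genes, cnv_dir, concordance = concord)
    cnv_states <- gene_cnv_states(seg_by_group, gm)
    summary$cnv <- list(
      tumor_normal = purrr::imap(
        seg_by_group,
        function(s, g) as.list(table(s$state[s$state != "neutral"]))
      ),
      group_contrast = as.list(table(contrast_seg$state[contrast_seg$state != "neutral"])),
      n_concordant = sum(concord$concordant, na.rm = TRUE),
      n_discordant = sum(!concord$concordant, na.rm = TRUE)
    )
    note_stage("cnv")
  }

  # ---- integrate ---------------------------------------------------------
  g <- contrast$groups
  key_genes <- sort(unique(c(
    contrast$recurrent_genes[[g[1]]]$gene,
    contrast$recurrent_genes[[g[2]]]$gene,
    unlist(contrast$hypermutated, use.names = FALSE),
    if (!is.null(summary$common_degs)) summary$common_degs
  )))
  if (length(key_genes) > 0) {
    report <- integrate_report(
      key_genes, contrast$burden, contrast$hypermutated, expr, manifest,
      cnv_states = cnv_states
    )
    readr::write_tsv(report, file.path(out_dir, "integrated_report.tsv"), progress = FALSE)
    summary$n_integrated_genes <- nrow(report)
  }
  note_stage("integrate")

  jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  note_stage("summary")
  invisible(summary)
}
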