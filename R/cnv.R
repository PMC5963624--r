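.check_binning <- function(cov) {
  bins <- cov %>%
    dplyr::distinct(.data$chrom, .data$start, .data$end) %>%
    dplyr::arrange(.data$chrom, .data$start)
  per_sample <- cov %>% dplyr::count(.data$sample_id)
  if (any(per_sample$n != nrow(bins))) {
    abort("all coverage tracks must share one binning")
  }
  bins
}

# Each track is normalized to a fixed library size (1e6) before sides are
# averaged, so rescaling any single track cancels exactly.
.side_norm <- function(cov, bins) {
  cov %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(norm = .data$read_count / sum(.data$read_count) * 1e6) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end) %>%
    dplyr::summarise(norm = mean(.data$norm), .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::pull("norm")
}

#' Windowed log2 coverage ratio between a test and a control side
#'
#' Each side may hold one coverage track or several (a group); every track is
#' first scaled to a common library size, group sides are then averaged
#' bin-wise, and the per-bin ratio is
#' `log2((test + pc) / (control + pc))` on the normalized scale. Both sides
#' must share the same binning.
#'
#' @param test,control Coverage tibbles (see [read_coverage()]); multiple
#'   `sample_id`s form a group side.
#' @param pseudocount Stabilizing pseudocount on the normalized scale
#'   (default 0.5; normalized bin values are around `1e6 / n_bins`, so the
#'   default is a light touch that only guards empty bins).
#' @return A `cnv_track` tibble: `chrom`, `start`, `end`, `log2_ratio`.
#' @export
log2_ratio_track <- function(test, control, pseudocount = 0.5) {
  test <- validate_coverage(test)
  control <- validate_coverage(control)
  bins_t <- .check_binning(test)
  bins_c <- .check_binning(control)
  if (!identical(bins_t, bins_c)) abort("test and control binning differ")
  t_norm <- .side_norm(test, bins_t)
  c_norm <- .side_norm(control, bins_c)
  out <- bins_t
  out$log2_ratio <- log2((t_norm + pseudocount) / (c_norm + pseudocount))
  class(out) <- c("cnv_track", class(out))
  out
}

#' Group-versus-group copy-number contrast track
#'
#' Convenience wrapper around [log2_ratio_track()] for two groups of tumor
#' tracks. Positive values mean higher copy number in the first group.
#'
#' @param tracks_g1,tracks_g2 Coverage tibbles holding the two groups'
#'   samples.
#' @inheritParams log2_ratio_track
#' @return A `cnv_track` tibble.
#' @export
group_contrast_track <- function(tracks_g1, tracks_g2, pseudocount = 0.5) {
  log2_ratio_track(tracks_g1, tracks_g2, pseudocount)
}

.segment_stats <- function(bins) {
  tibble(
    chrom = bins$chrom[1],
    start = min(bins$start),
    end = max(bins$end),
    mean_log2 = mean(bins$log2_ratio),
    sd_log2 = if (nrow(bins) > 1) stats::sd(bins$log2_ratio) else 0,
    n_bins = nrow(bins)
  )
}

#' Call amplified / deleted / neutral segments on a log2-ratio track
#'
#' Candidate runs are maximal stretches of consecutive bins whose
#' `|log2_ratio|` stays beyond the band edge `cutoff - sd_band`. A run of at
#' least `min_bins` bins is called amplified (or deleted) when its mean
#' log2 ratio lies beyond that edge and its within-run standard deviation is
#' at most `sd_band` (the stability filter); everything else is reported as
#' neutral, so segments tile the binned territory of every chromosome.
#'
#' @param track A `cnv_track`.
#' @param cutoff Central call threshold on `|log2_ratio|`; the call band is
#'   `cutoff - sd_band` onwards. Must be positive and exceed `sd_band`.
#' @param sd_band Half-width of the call band and ceiling on within-segment
#'   standard deviation (default 0.5).
#' @param min_bins Minimum run length for a non-neutral call (default 5).
#' @return A `cnv_segments` tibble: `chrom`, `start`, `end`, `state`,
#'   `mean_log2`, `sd_log2`, `n_bins`.
#' @export
call_segments <- function(track, cutoff, sd_band = 0.5, min_bins = 5L) {
  if (cutoff <= 0) abort("cutoff must be positive")
  enter <- cutoff - sd_band
  if (enter <= 0) abort("cutoff must exceed sd_band (empty call band)")
  track <- dplyr::arrange(as_tibble(track), .data$chrom, .data$start)
  out <- track %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map_dfr(function(ch) {
      dir <- ifelse(ch$log2_ratio >= enter, 1L, ifelse(ch$log2_ratio <= -enter, -1L, 0L))
      r <- rle(dir)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1L
      segs <- purrr::pmap_dfr(
        list(idx_start, idx_end, r$values),
        function(i0, i1, d) {
          bins <- ch[i0:i1, ]
          s <- .segment_stats(bins)
          called <- d != 0L &&
            s$n_bins >= min_bins &&
            abs(s$mean_log2) >= enter &&
            s$sd_log2 <= sd_band
          s$state <- if (!called) "neutral" else if (d > 0) "amplified" else "deleted"
          s
        }
      )
      # merge adjacent neutral stretches so neutral territory is maximal
      segs$run <- cumsum(c(1L, diff(segs$state == "neutral") != 0 | segs$state[-1] != "neutral"))
      segs %>%
        dplyr::group_by(.data$run) %>%
        dplyr::group_modify(function(g, key) {
          if (nrow(g) == 1) return(g[, setdiff(names(g), "run")])
          w <- g$n_bins
          tibble(
            chrom = g$chrom[1], start = min(g$start), end = max(g$end),
            mean_log2 = sum(g$mean_log2 * w) / sum(w),
            sd_log2 = NA_real_, n_bins = sum(w), state = "neutral"
          )
        }) %>%
        dplyr::ungroup() %>%
        dplyr::select(-"run")
    }) %>%
    dplyr::select("chrom", "start", "end", "state", "mean_log2", "sd_log2", "n_bins") %>%
    dplyr::arrange(.data$chrom, .data$start)
  class(out) <- c("cnv_segments", class(out))
  out
}

#' Annotate CNV segments with overlapping genes
#'
#' A gene is assigned to a segment when their half-open intervals overlap by
#' at least one base (a gene abutting a segment end is not an overlap).
#'
#' @param segments A `cnv_segments` tibble.
#' @param gene_model Gene model tibble (see [read_gene_model()]).
#' @param states Segment states to annotate (default amplified and deleted).
#' @return A tibble with one row per (segment, gene) overlap: the segment
#'   columns plus `gene`.
#' @export
annotate_segments <- function(segments, gene_model,
                              states = c("amplified", "deleted")) {
  gene_model <- validate_gene_model(gene_model)
  seg <- as_tibble(segments)[as_tibble(segments)$state %in% states, ]
  if (nrow(seg) == 0 || nrow(gene_model) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      state = character(), mean_log2 = double(), sd_log2 = double(),
      n_bins = integer(), gene = character()
    ))
  }
  purrr::map_dfr(unique(seg$chrom), function(ch) {
    s <- seg[seg$chrom == ch, ]
    g <- gene_model[gene_model$chrom == ch, ]
    if (nrow(g) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$start + 1L, s$end),
      IRanges::IRanges(g$start + 1L, g$end)
    )
    out <- s[S4Vectors::queryHits(hits), ]
    out$gene <- g$gene[S4Vectors::subjectHits(hits)]
    out
  })
}

#' Per-gene CNV state per group
#'
#' Collapses per-group segment calls to a per-gene state: a gene overlapping
#' an amplified (deleted) segment of a group's track is amplified (deleted)
#' in that group, otherwise neutral. When a gene overlaps both states, the
#' one with larger `|mean_log2|` wins.
#'
#' @param segments_by_group Named list, group -> `cnv_segments`.
#' @param gene_model Gene model tibble.
#' @return A tibble `gene`, `group`, `state` (non-neutral entries only).
#' @export
gene_cnv_states <- function(segments_by_group, gene_model) {
  purrr::imap_dfr(segments_by_group, function(seg, grp) {
    ann <- annotate_segments(seg, gene_model)
    if (nrow(ann) == 0) return(NULL)
    ann %>%
      dplyr::group_by(gene = .data$gene) %>%
      dplyr::slice_max(abs(.data$mean_log2), n = 1, with_ties = FALSE) %>%
      dplyr::ungroup() %>%
      dplyr::transmute(.data$gene, group = grp, state = .data$state)
  })
}

#' Concordance between copy-number state and expression
#'
#' For genes in contrast segments (positive log2 meaning higher copy in
#' `g1`), checks whether relative expression agrees: an amplified gene is
#' concordant when its mean FPKM is higher in `g1`; a deleted gene when it
#' is lower.
#'
#' @param segment_genes Output of [annotate_segments()] on a group-contrast
#'   track.
#' @param expr Expression matrix tibble.
#' @param manifest Cohort manifest.
#' @param g1,g2 The groups contrasted by the track (default S vs L).
#' @return A tibble: `gene`, `state`, `mean_log2`, `mean_fpkm_<g1>`,
#'   `mean_fpkm_<g2>`, `concordant`.
#' @export
cnv_expression_concordance <- function(segment_genes, expr, manifest,
                                       g1 = "S", g2 = "L") {
  manifest <- validate_manifest(manifest)
  expr <- validate_expression(expr)
  if (nrow(segment_genes) == 0) {
    out <- tibble(
      gene = character(), state = character(), mean_log2 = double(),
      m1 = double(), m2 = double(), concordant = logical()
    )
    names(out)[4:5] <- paste0("mean_fpkm_", c(g1, g2))
    return(out)
  }
  wts <- manifest[manifest$wts, ]
  mean_for <- function(g) {
    sg <- intersect(wts$sample_id[wts$group == g], names(expr))
    rowMeans(as.matrix(expr[, sg, drop = FALSE]))
  }
  m1 <- mean_for(g1)
  m2 <- mean_for(g2)
  out <- segment_genes %>%
    dplyr::distinct(.data$gene, .data$state, .data$mean_log2) %>%
    dplyr::mutate(
      m1 = m1[match(.data$gene, expr$gene)],
      m2 = m2[match(.data$gene, expr$gene)],
      concordant = ifelse(
        .data$state == "amplified", .data$m1 > .data$m2, .data$m1 < .data$m2
      )
    )
  names(out)[names(out) == "m1"] <- paste0("mean_fpkm_", g1)
  names(out)[names(out) == "m2"] <- paste0("mean_fpkm_", g2)
  out
}

#' Write CNV outputs
#'
#' Emits `segments.bed` (BED5; state in the name field, `mean_log2 * 1000`
#' rounded as the score), `cnv_genes.tsv` and `concordance.tsv`.
#'
#' @param segments A `cnv_segments` tibble.
#' @param segment_genes Output of [annotate_segments()].
#' @param concordance Output of [cnv_expression_concordance()] (optional).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cnv <- function(segments, segment_genes, dir, concordance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- as_tibble(segments) %>%
    dplyr::transmute(
      .data$chrom, .data$start, .data$end, name = .data$state,
      score = round(.data$mean_log2 * 1000)
    )
  readr::write_tsv(bed, file.path(dir, "segments.bed"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(segment_genes, file.path(dir, "cnv_genes.tsv"), progress = FALSE)
  if (!is.null(concordance)) {
    readr::write_tsv(concordance, file.path(dir, "concordance.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' @export
autoplot.cnv_track <- function(object, segments = NULL, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    seg <- as_tibble(segments)[as_tibble(segments)$state != "neutral", ]
    if (nrow(seg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(
          x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$mean_log2, yend = .data$mean_log2, colour = .data$state
        ),
        linewidth = 1.2, inherit.aes = FALSE
      ) +
        ggplot2::scale_colour_manual(
          values = c(amplified = "firebrick", deleted = "navy")
        )
    }
  }
  p
}
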