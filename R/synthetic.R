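# Expectation helpers for calibrating the background variant rate.
.E_min_pois <- function(lambda, cap) {
  j <- 0:300
  sum(pmin(j, cap) * dpois(j, lambda))
}

# Mean carriers per background variant: one anchored sample plus each of the
# other (n-1) samples with probability p, capped at n-1 carriers total.
.mu_carriers <- function(n, p) {
  1 + (n - 1) * p - p^(n - 1)
}

#' Configure a synthetic RFS cohort
#'
#' Builds the parameter set for [generate_cohort()]: cohort layout, synthetic
#' genome, per-group variant rates with planted structures (hypermutator
#' genes, recurrent group-private genes, group-exclusive universally shared
#' variant keys, cohort-universal keys), expression effects per Venn region,
#' and planted copy-number regions. All randomness is fixed by `seed`.
#'
#' @param seed Integer seed fixing every draw.
#' @param n_s,n_m,n_l Samples per RFS group.
#' @param wes_s,wes_l Exome-sequenced samples within S and L (M samples are
#'   transcriptome-only).
#' @param n_chrom,chrom_len,bin_size Synthetic genome layout (bases).
#' @param gene_len,gene_spacing Gene footprint and tiling pitch (bases).
#' @param n_genes Gene universe size (must fit the genome tiling).
#' @param n_shared_genes,n_s_only,n_l_only Sizes of the shared and
#'   group-private mutated-gene pools.
#' @param lambda_bg Named background rates (`S`, `L`): distinct variants per
#'   mutated gene are `1 + Poisson(lambda)`. Ignored when `target_totals`
#'   is supplied.
#' @param target_totals Optional list
#'   `list(S = c(total=, coding=, deleterious=), L = ...)`; when given, the
#'   background rates are calibrated by root finding so expected per-group
#'   occurrence totals hit `total`, and the coding/deleterious probabilities
#'   are the implied ratios.
#' @param p_coding,p_deleterious Per-variant coding probability and
#'   deleterious-given-coding probability (overridden by `target_totals`).
#' @param p_share Probability that each non-anchor group sample carries a
#'   background variant (carriers capped below the full group so that only
#'   planted keys can be universally shared).
#' @param hyper Tibble with columns `s_count`, `l_count`: one row per
#'   hypermutator gene, giving fixed per-group distinct counts (0 = absent
#'   from that group). `NULL` for none.
#' @param recurrent_s_k,recurrent_l_k Integer vectors of distinct counts for
#'   recurrent group-private genes (each must exceed the WES group size so
#'   cyclic carrier assignment covers every sample).
#' @param n_excl_shared_s,n_excl_shared_l Planted variant keys carried by
#'   every sample of one group and absent from the other.
#' @param n_universal Planted keys carried by every exome-sequenced sample.
#' @param baseline_mean,baseline_sd Per-gene baseline of `log2(FPKM+1)`.
#' @param noise_sd Within-group expression noise on the log2 scale (0 makes
#'   the planted Venn structure exactly recoverable).
#' @param effect Planted log2 expression effect size.
#' @param m_spread Deterministic within-group spread (log2 sd) given to the
#'   third group of a single-pair Venn region so the other two comparisons
#'   stay non-significant.
#' @param m_offset Log2 offset of the M group for three-pair ("triple")
#'   region genes, making them significant against the pooled rest.
#' @param venn Named integer vector of planted genes per Venn region:
#'   `sl_only`, `sm_only`, `ml_only`, `sl_sm`, `sl_ml`, `sm_ml`, `triple`.
#' @param depth Mean coverage reads per bin.
#' @param cnv_regions Tibble `chrom`, `start`, `end`, `fold`, `scope`
#'   (`"all"`, `"S"` or `"L"`) of planted copy-number regions.
#' @param n_concordant Number of S-vs-L DEGs placed inside the S-scope CNV
#'   region (copy-number/expression concordant by construction).
#' @param n_discordant Flat-expression genes inside that region (planted
#'   discordant).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_s = 6L, n_m = 3L, n_l = 4L,
                          wes_s = 4L, wes_l = 4L,
                          n_chrom = 3L, chrom_len = 1e6, bin_size = 5e4,
                          gene_len = 4000L, gene_spacing = 6000L,
                          n_genes = 450L,
                          n_shared_genes = 120L, n_s_only = 40L, n_l_only = 25L,
                          lambda_bg = c(S = 1.5, L = 1.0),
                          target_totals = NULL,
                          p_coding = 0.7, p_deleterious = 0.74,
                          p_share = 0.3,
                          hyper = tibble(s_count = c(70L, 55L), l_count = c(52L, 3L)),
                          recurrent_s_k = c(6L, 5L, 7L),
                          recurrent_l_k = c(5L, 6L),
                          n_excl_shared_s = 3L, n_excl_shared_l = 1L,
                          n_universal = 2L,
                          baseline_mean = 3, baseline_sd = 2,
                          noise_sd = 0, effect = 4,
                          m_spread = 4, m_offset = 16,
                          venn = c(sl_only = 8L, sm_only = 0L, ml_only = 0L,
                                   sl_sm = 0L, sl_ml = 0L, sm_ml = 4L,
                                   triple = 2L),
                          depth = 400,
                          cnv_regions = tibble(
                            chrom = c("chr1", "chr2", "chr3"),
                            start = c(2e5, 4e5, 4e5),
                            end = c(6e5, 7e5, 7e5),
                            fold = c(2, 0.5, 2),
                            scope = c("all", "all", "S")
                          ),
                          n_concordant = 2L, n_discordant = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param cfg A config list to validate.
#' @export
validate_cohort_config <- function(cfg) {
  capacity_per_chrom <- floor(cfg$chrom_len / cfg$gene_spacing)
  if (cfg$n_genes > cfg$n_chrom * capacity_per_chrom) {
    abort("n_genes exceeds genome gene capacity")
  }
  n_mut <- cfg$n_shared_genes + cfg$n_s_only + cfg$n_l_only
  if (n_mut > cfg$n_genes) abort("mutated gene pools exceed the gene universe")
  n_hyper <- if (is.null(cfg$hyper)) 0L else nrow(cfg$hyper)
  n_planted_shared <- n_hyper + cfg$n_excl_shared_s + cfg$n_excl_shared_l +
    cfg$n_universal
  if (n_planted_shared > cfg$n_shared_genes) {
    abort("planted shared structures exceed the shared gene pool")
  }
  if (length(cfg$recurrent_s_k) > cfg$n_s_only ||
      length(cfg$recurrent_l_k) > cfg$n_l_only) {
    abort("recurrent gene counts exceed the group-private gene pools")
  }
  if (any(cfg$recurrent_s_k < cfg$wes_s + 1L) ||
      any(cfg$recurrent_l_k < cfg$wes_l + 1L)) {
    abort("recurrent distinct counts must exceed the WES group size")
  }
  max_k <- max(c(1L, cfg$recurrent_s_k, cfg$recurrent_l_k,
                 if (!is.null(cfg$hyper)) c(cfg$hyper$s_count, cfg$hyper$l_count)))
  if (2L * max_k + 2L > cfg$gene_len) {
    abort("gene_len too small for the largest planted distinct-variant count")
  }
  if (cfg$wes_s > cfg$n_s || cfg$wes_l > cfg$n_l) {
    abort("WES sample counts exceed group sizes")
  }
  bad_venn <- setdiff(
    c("sl_only", "sm_only", "ml_only", "sl_sm", "sl_ml", "sm_ml", "triple"),
    names(cfg$venn)
  )
  if (length(bad_venn) > 0) abort("venn must name all 7 regions")
  if (sum(cfg$venn) + cfg$n_discordant > cfg$n_genes) {
    abort("planted expression genes exceed the gene universe")
  }
  if (!is.null(cfg$hyper) && nrow(cfg$hyper) > 0 &&
      any(cfg$hyper$s_count < 1L | cfg$hyper$l_count < 1L)) {
    abort("hypermutator genes are shared genes: both group counts must be >= 1")
  }
  if (cfg$n_concordant > cfg$venn[["sl_only"]]) {
    abort("n_concordant cannot exceed the sl_only Venn region")
  }
  structure(cfg, class = "cohort_config")
}

#' The paper-scale synthetic cohort preset
#'
#' A 13-sample cohort (6 S / 3 M / 4 L; exomes for 4 S + 4 L) over a
#' 3 x 30 Mb genome with 15000 genes, planted so that the set-valued
#' structures of the study design are exactly recoverable: mutated-gene sets
#' of 12714 (S) and 11126 (L) with 2914 S-private genes, 35 vs 9
#' hypermutated genes (top gene 105/75 distinct variants), 46 vs 5 recurrent
#' group-private genes, 17 vs 2 group-exclusive universally shared variants,
#' 5 cohort-universal variants, and a DEG Venn union of 158 genes (112 in
#' the S-vs-L-only region, 13 shared between the M-vs-rest and S-vs-L
#' screens). Occurrence burden totals are calibrated in expectation to
#' 76170/53319/39609 (S) and 45903/33050/24328 (L). Expression is noise-free
#' so recovery is exact; coverage is Poisson.
#'
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
paper_scale_config <- function(seed = 1L) {
  hyper <- dplyr::bind_rows(
    tibble(s_count = 105L, l_count = 75L),
    tibble(s_count = 51:84, l_count = 10:43),
    tibble(s_count = rep(30:37, length.out = 8L), l_count = 51:58)
  )
  cohort_config(
    seed = seed,
    n_s = 6L, n_m = 3L, n_l = 4L, wes_s = 4L, wes_l = 4L,
    n_chrom = 3L, chrom_len = 30e6, bin_size = 1e5,
    gene_len = 4000L, gene_spacing = 6000L, n_genes = 15000L,
    n_shared_genes = 9800L, n_s_only = 2914L, n_l_only = 1326L,
    target_totals = list(
      S = c(total = 76170, coding = 53319, deleterious = 39609),
      L = c(total = 45903, coding = 33050, deleterious = 24328)
    ),
    p_share = 0.3,
    hyper = hyper,
    recurrent_s_k = rep(5:8, length.out = 46L),
    recurrent_l_k = rep(5:6, length.out = 5L),
    n_excl_shared_s = 17L, n_excl_shared_l = 2L, n_universal = 5L,
    baseline_mean = 3, baseline_sd = 2, noise_sd = 0, effect = 4,
    m_spread = 4, m_offset = 16,
    venn = c(sl_only = 112L, sm_only = 0L, ml_only = 0L, sl_sm = 0L,
             sl_ml = 0L, sm_ml = 33L, triple = 13L),
    depth = 100,
    cnv_regions = tibble(
      chrom = c("chr1", "chr2", "chr3"),
      start = c(5e6, 10e6, 10e6),
      end = c(9e6, 13e6, 13e6),
      fold = c(2, 0.5, 2),
      scope = c("all", "all", "S")
    ),
    n_concordant = 20L, n_discordant = 3L
  )
}

.make_gene_model <- function(cfg) {
  i <- seq_len(cfg$n_genes) - 1L
  per_chrom <- floor(cfg$chrom_len / cfg$gene_spacing)
  tibble(
    gene = sprintf("G%05d", i + 1L),
    chrom = paste0("chr", i %/% per_chrom + 1L),
    start = as.integer((i %% per_chrom) * cfg$gene_spacing),
    end = as.integer((i %% per_chrom) * cfg$gene_spacing + cfg$gene_len)
  )
}

.make_manifest <- function(cfg) {
  rfs_s <- rep(c(2L, 3L, 4L, 5L), length.out = cfg$n_s)
  rfs_m <- rep(c(16L, 20L, 23L), length.out = cfg$n_m)
  rfs_l <- rep(c(26L, 30L, 41L, 60L), length.out = cfg$n_l)
  tibble(
    sample_id = c(
      sprintf("S%d", seq_len(cfg$n_s)),
      sprintf("M%d", seq_len(cfg$n_m)),
      sprintf("L%d", seq_len(cfg$n_l))
    ),
    group = rep(c("S", "M", "L"), c(cfg$n_s, cfg$n_m, cfg$n_l)),
    rfs_months = c(sort(rfs_s), sort(rfs_m), sort(rfs_l)),
    wes = c(
      seq_len(cfg$n_s) <= cfg$wes_s,
      rep(FALSE, cfg$n_m),
      seq_len(cfg$n_l) <= cfg$wes_l
    ),
    wts = TRUE
  )
}

.calibrate_lambda <- function(cfg, n_sh_bg, n_ex_bg, planted_occ, group) {
  tt <- cfg$target_totals[[group]]
  n_wes <- if (group == "S") cfg$wes_s else cfg$wes_l
  mu <- .mu_carriers(n_wes, cfg$p_share)
  f <- function(lambda) {
    n_sh_bg * (1 + lambda) * mu +
      n_ex_bg * (1 + .E_min_pois(lambda, n_wes - 1)) * mu +
      planted_occ - tt[["total"]]
  }
  if (n_sh_bg + n_ex_bg == 0) return(0)
  if (f(0) > 0) abort("planted occurrences already exceed the target total")
  uniroot(f, c(0, 60))$root
}

# Carrier matrix for D background variants over n samples: one anchored
# carrier plus Bernoulli(p) others, capped at n-1 carriers so no background
# variant is universally shared within its group.
.draw_carriers <- function(D, n, p) {
  if (D == 0) return(matrix(logical(0), 0, n))
  m <- matrix(runif(D * n) < p, D, n)
  anchor <- sample.int(n, D, replace = TRUE)
  m[cbind(seq_len(D), anchor)] <- TRUE
  full <- rowSums(m) == n
  if (any(full)) {
    off <- sample.int(n - 1, sum(full), replace = TRUE)
    drop_col <- (anchor[full] - 1L + off) %% n + 1L
    m[cbind(which(full), drop_col)] <- FALSE
  }
  m
}

.alleles_for <- function(consequence) {
  ref <- rep("A", length(consequence))
  alt <- rep("G", length(consequence))
  ref[consequence == "frameshift"] <- "AT"
  alt[consequence == "frameshift"] <- "A"
  ref[consequence == "inframe_indel"] <- "ATTTA"
  alt[consequence == "inframe_indel"] <- "A"
  list(ref = ref, alt = alt)
}

.draw_consequence <- function(is_coding, is_del) {
  n <- length(is_coding)
  out <- character(n)
  idx <- which(is_del)
  out[idx] <- sample(
    c("missense", "stop_gained", "frameshift", "splice"),
    length(idx), replace = TRUE, prob = c(0.7, 0.1, 0.15, 0.05)
  )
  idx <- which(is_coding & !is_del)
  out[idx] <- sample(
    c("missense", "synonymous", "inframe_indel"),
    length(idx), replace = TRUE, prob = c(0.5, 0.4, 0.1)
  )
  idx <- which(!is_coding)
  out[idx] <- sample(
    c("noncoding", "other"), length(idx), replace = TRUE, prob = c(0.9, 0.1)
  )
  out
}

# Expand distinct variants (one row each, with a carrier matrix) into
# per-sample occurrence records.
.expand_records <- function(distinct, carriers, samples) {
  idx <- which(carriers, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rec <- distinct[idx[, 1], ]
  rec$sample_id <- samples[idx[, 2]]
  rec
}

.group_variants <- function(cfg, gm, assign, group) {
  n_wes <- if (group == "S") cfg$wes_s else cfg$wes_l
  samples <- sprintf("%s%d", group, seq_len(n_wes))
  lambda <- assign$lambda[[group]]
  p_cod <- assign$p_coding[[group]]
  p_del <- assign$p_del[[group]]
  side <- if (group == "S") "s" else "l"
  # offsets: planted group-universal keys sit at offset 1 (shared across
  # groups for cohort-universal keys); S background/planted occupy even
  # offsets, L odd, so cross-group keys never collide by accident.
  off0 <- if (group == "S") 2L else 3L

  gene_rows <- list()
  # background over shared genes (planted-key hosts keep their background)
  sh_bg <- assign$shared_bg
  if (length(sh_bg) > 0) {
    gene_rows$shared <- tibble(
      gene = sh_bg, k = 1L + rpois(length(sh_bg), lambda), kind = "background"
    )
  }
  hosts <- c(assign$excl_shared$S, assign$excl_shared$L, assign$universal_genes)
  if (length(hosts) > 0) {
    gene_rows$hosts <- tibble(
      gene = hosts, k = 1L + rpois(length(hosts), lambda), kind = "background"
    )
  }
  # group-private background genes: distinct count capped at the group size
  # so only planted recurrent genes can pass the ">min_variants in every
  # sample" rule
  priv <- assign$private_bg[[group]]
  if (length(priv) > 0) {
    gene_rows$private <- tibble(
      gene = priv,
      k = 1L + pmin(rpois(length(priv), lambda), n_wes - 1L),
      kind = "background"
    )
  }
  hy <- assign$hyper
  if (!is.null(hy) && nrow(hy) > 0) {
    cnt <- hy[[paste0(side, "_count")]]
    keep <- cnt > 0
    if (any(keep)) {
      gene_rows$hyper <- tibble(gene = hy$gene[keep], k = cnt[keep], kind = "background")
    }
  }
  rec_k <- assign$recurrent_k[[group]]
  rec_genes <- assign$recurrent[[group]]
  if (length(rec_genes) > 0) {
    gene_rows$recurrent <- tibble(gene = rec_genes, k = rec_k, kind = "recurrent")
  }
  tab <- dplyr::bind_rows(gene_rows)

  build_distinct <- function(tab) {
    if (nrow(tab) == 0) {
      return(tibble(
        gene = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), kind = character()
      ))
    }
    g_idx <- match(tab$gene, gm$gene)
    gene_rep <- rep.int(seq_len(nrow(tab)), tab$k)
    ordinal <- sequence(tab$k)
    tibble(
      gene = tab$gene[gene_rep],
      chrom = gm$chrom[g_idx][gene_rep],
      pos = as.integer(gm$start[g_idx][gene_rep] + off0 + 2L * (ordinal - 1L)),
      kind = tab$kind[gene_rep]
    )
  }
  distinct <- build_distinct(tab)
  n_d <- nrow(distinct)
  is_cod <- runif(n_d) < p_cod
  is_del <- is_cod & runif(n_d) < p_del
  cons <- .draw_consequence(is_cod, is_del)
  al <- .alleles_for(cons)
  distinct$ref <- al$ref
  distinct$alt <- al$alt
  distinct$consequence <- cons
  distinct$is_coding <- is_cod
  distinct$is_deleterious <- is_del

  bg <- distinct$kind == "background"
  carriers <- matrix(FALSE, n_d, n_wes)
  carriers[bg, ] <- .draw_carriers(sum(bg), n_wes, cfg$p_share)
  # recurrent variants: one carrier each, cycling so every sample is covered
  rec_rows <- which(!bg)
  if (length(rec_rows) > 0) {
    rec_ord <- stats::ave(rec_rows, distinct$gene[rec_rows], FUN = seq_along)
    carriers[cbind(rec_rows, (rec_ord - 1L) %% n_wes + 1L)] <- TRUE
  }
  rec <- .expand_records(distinct[, setdiff(names(distinct), "kind")], carriers, samples)

  # planted keys: group-exclusive universally shared, and cohort-universal
  planted <- list()
  eg <- assign$excl_shared[[group]]
  if (length(eg) > 0) {
    g_idx <- match(eg, gm$gene)
    cons_p <- rep("missense", length(eg))
    if (length(eg) > 1) cons_p[2] <- "stop_gained"
    ref_p <- rep("A", length(eg))
    alt_p <- rep("G", length(eg))
    if (length(eg) > 2) { # one small deletion among the planted keys
      cons_p[3] <- "frameshift"
      ref_p[3] <- "AT"
      alt_p[3] <- "A"
    }
    planted$excl <- tibble(
      gene = eg, chrom = gm$chrom[g_idx], pos = as.integer(gm$start[g_idx] + 1L),
      ref = ref_p, alt = alt_p, consequence = cons_p,
      is_coding = TRUE, is_deleterious = cons_p != "missense"
    )
  }
  ug <- assign$universal_genes
  if (length(ug) > 0) {
    g_idx <- match(ug, gm$gene)
    cons_u <- rep("missense", length(ug))
    if (length(ug) > 1) cons_u[length(ug)] <- "synonymous"
    planted$univ <- tibble(
      gene = ug, chrom = gm$chrom[g_idx], pos = as.integer(gm$start[g_idx] + 1L),
      ref = "A", alt = "G", consequence = cons_u,
      is_coding = TRUE, is_deleterious = FALSE
    )
  }
  if (length(planted) > 0) {
    pl <- dplyr::bind_rows(planted)
    all_carr <- matrix(TRUE, nrow(pl), n_wes)
    rec <- dplyr::bind_rows(rec, .expand_records(pl, all_carr, samples))
  }

  n_r <- nrow(rec)
  rec$variant_class <- .class_from_alleles(rec$ref, rec$alt)
  rec$zygosity <- ifelse(runif(n_r) < 0.92, "heterozygous", "homozygous")
  rec$alt_allele_fraction <- round(
    ifelse(rec$zygosity == "heterozygous", runif(n_r, 0.09, 0.459), runif(n_r, 0.8, 1)),
    3
  )
  rec[, c("sample_id", "chrom", "pos", "ref", "alt", "gene", "variant_class",
          "zygosity", "consequence", "is_coding", "is_deleterious",
          "alt_allele_fraction")]
}

.spread_pattern <- function(n, sd_target) {
  v <- seq(-1, 1, length.out = n)
  v / stats::sd(v) * sd_target
}

.make_expression <- function(cfg, gm, manifest, deg_assign) {
  n_g <- nrow(gm)
  samples <- manifest$sample_id[manifest$wts]
  groups <- manifest$group[manifest$wts]
  baseline <- pmax(rnorm(n_g, cfg$baseline_mean, cfg$baseline_sd), 0)
  lx <- matrix(baseline, n_g, length(samples))
  if (cfg$noise_sd > 0) {
    lx <- lx + matrix(rnorm(n_g * length(samples), 0, cfg$noise_sd), n_g)
  }
  idx_of <- function(genes) match(genes, gm$gene)
  cols <- function(g) which(groups == g)
  add_const <- function(genes, grp, delta) {
    lx[idx_of(genes), cols(grp)] <<- lx[idx_of(genes), cols(grp)] + delta
  }
  add_spread <- function(genes, grp, center) {
    pat <- .spread_pattern(length(cols(grp)), cfg$m_spread)
    lx[idx_of(genes), cols(grp)] <<-
      lx[idx_of(genes), cols(grp)] +
      matrix(center + pat, length(genes), length(pat), byrow = TRUE)
  }
  d <- cfg$effect
  a <- deg_assign
  # single-pair regions: the two contrasted groups are flat-different, the
  # third receives a deterministic spread about the midpoint so both of its
  # comparisons stay non-significant
  if (length(a$sl_only)) {
    add_const(a$sl_only, "S", d)
    add_spread(a$sl_only, "M", d / 2)
  }
  if (length(a$sm_only)) {
    add_const(a$sm_only, "S", d)
    add_spread(a$sm_only, "L", d / 2)
  }
  if (length(a$ml_only)) {
    add_const(a$ml_only, "M", d)
    add_spread(a$ml_only, "S", d / 2)
  }
  # two-pair regions: one group shifted against the two others
  if (length(a$sl_sm)) add_const(a$sl_sm, "S", d)
  if (length(a$sl_ml)) add_const(a$sl_ml, "L", d)
  if (length(a$sm_ml)) add_const(a$sm_ml, "M", d)
  # triple region: all three means distinct, M far from the pooled rest
  if (length(a$triple)) {
    add_const(a$triple, "S", d)
    add_const(a$triple, "L", -d)
    add_const(a$triple, "M", cfg$m_offset)
  }
  fpkm <- round(pmax(2^lx - 1, 0), 4)
  out <- as_tibble(as.data.frame(fpkm))
  names(out) <- samples
  dplyr::bind_cols(tibble(gene = gm$gene), out)
}

.make_coverage <- function(cfg, manifest) {
  n_bins_chrom <- floor(cfg$chrom_len / cfg$bin_size)
  bins <- tibble(
    chrom = rep(paste0("chr", seq_len(cfg$n_chrom)), each = n_bins_chrom),
    start = as.integer(rep((seq_len(n_bins_chrom) - 1L) * cfg$bin_size, cfg$n_chrom)),
    end = as.integer(rep(seq_len(n_bins_chrom) * cfg$bin_size, cfg$n_chrom))
  )
  mult_for <- function(group) {
    mult <- rep(1, nrow(bins))
    for (i in seq_len(nrow(cfg$cnv_regions))) {
      r <- cfg$cnv_regions[i, ]
      if (r$scope == "all" || r$scope == group) {
        hit <- bins$chrom == r$chrom & bins$start >= r$start & bins$end <= r$end
        mult[hit] <- mult[hit] * r$fold
      }
    }
    mult
  }
  tumor <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    s <- manifest[i, ]
    out <- bins
    out$sample_id <- s$sample_id
    out$read_count <- rpois(nrow(bins), cfg$depth * mult_for(s$group))
    out
  })
  normal <- bins
  normal$sample_id <- "NORMAL"
  normal$read_count <- rpois(nrow(bins), cfg$depth)
  list(
    tumor = validate_coverage(tumor[, c("sample_id", "chrom", "start", "end", "read_count")]),
    normal = validate_coverage(normal[, c("sample_id", "chrom", "start", "end", "read_count")])
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces, in memory (and optionally on disk), every input the analysis
#' pipeline consumes: per-sample variant records for the exome-sequenced
#' samples, a manifest, a gene-by-sample FPKM matrix, windowed coverage for
#' every tumor sample plus one normal control, and a gene model — together
#' with the planted ground truth in the same shapes the pipeline reports.
#'
#' @param config A `cohort_config` (see [cohort_config()],
#'   [paper_scale_config()]).
#' @param dir Optional output directory; when given, all files are written
#'   in the dialects the package readers consume, plus `ground_truth.json`.
#' @return A list: `variants`, `manifest`, `expression`, `coverage`
#'   (`$tumor`, `$normal`), `gene_model`, `truth`, `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  cfg <- validate_cohort_config(config)
  withr::with_seed(cfg$seed, {
    gm <- .make_gene_model(cfg)
    manifest <- .make_manifest(cfg)

    # ---- gene role assignment -------------------------------------------
    region_s <- cfg$cnv_regions[cfg$cnv_regions$scope == "S", ]
    in_region_s <- rep(FALSE, nrow(gm))
    for (i in seq_len(nrow(region_s))) {
      in_region_s <- in_region_s |
        (gm$chrom == region_s$chrom[i] & gm$start < region_s$end[i] &
           gm$end > region_s$start[i])
    }
    region_genes <- gm$gene[in_region_s]
    need_region <- cfg$n_concordant + cfg$n_discordant
    if (length(region_genes) < need_region) {
      abort("S-scope CNV region holds fewer genes than n_concordant + n_discordant")
    }
    concordant <- head(region_genes, cfg$n_concordant)
    discordant <- head(setdiff(region_genes, concordant), cfg$n_discordant)

    pool <- setdiff(gm$gene, c(concordant, discordant))
    take <- function(n) {
      out <- sample(pool, n)
      pool <<- setdiff(pool, out)
      out
    }
    deg_assign <- list(
      sl_only = c(concordant, take(cfg$venn[["sl_only"]] - cfg$n_concordant)),
      sm_only = take(cfg$venn[["sm_only"]]),
      ml_only = take(cfg$venn[["ml_only"]]),
      sl_sm = take(cfg$venn[["sl_sm"]]),
      sl_ml = take(cfg$venn[["sl_ml"]]),
      sm_ml = take(cfg$venn[["sm_ml"]]),
      triple = take(cfg$venn[["triple"]])
    )

    # the showcase gene is S-private mutated, S-amplified and an S-vs-L DEG
    showcase <- if (length(concordant) > 0 && cfg$n_s_only > 0) concordant[1] else NA_character_
    forced <- if (is.na(showcase)) character() else showcase
    mut_pool <- sample(setdiff(gm$gene, forced))
    shared <- mut_pool[seq_len(cfg$n_shared_genes)]
    n_s_draw <- cfg$n_s_only - length(forced)
    s_only <- c(forced, mut_pool[cfg$n_shared_genes + seq_len(n_s_draw)])
    l_only <- mut_pool[cfg$n_shared_genes + n_s_draw + seq_len(cfg$n_l_only)]

    n_hyper <- if (is.null(cfg$hyper)) 0L else nrow(cfg$hyper)
    cursor <- 0L
    slice_shared <- function(n) {
      out <- shared[cursor + seq_len(n)]
      cursor <<- cursor + n
      out
    }
    hyper <- if (n_hyper > 0) {
      dplyr::bind_cols(tibble(gene = slice_shared(n_hyper)), cfg$hyper)
    } else {
      NULL
    }
    excl_shared <- list(
      S = slice_shared(cfg$n_excl_shared_s),
      L = slice_shared(cfg$n_excl_shared_l)
    )
    universal_genes <- slice_shared(cfg$n_universal)
    shared_bg <- if (cursor < length(shared)) {
      shared[(cursor + 1L):length(shared)]
    } else {
      character()
    }

    recurrent <- list(
      S = head(setdiff(s_only, forced), length(cfg$recurrent_s_k)),
      L = head(l_only, length(cfg$recurrent_l_k))
    )
    private_bg <- list(
      S = setdiff(s_only, recurrent$S),
      L = setdiff(l_only, recurrent$L)
    )

    # ---- per-group rates -------------------------------------------------
    derive_rates <- function(group) {
      n_wes <- if (group == "S") cfg$wes_s else cfg$wes_l
      side <- if (group == "S") "s" else "l"
      mu <- .mu_carriers(n_wes, cfg$p_share)
      hyper_cnt <- if (is.null(hyper)) 0 else sum(hyper[[paste0(side, "_count")]])
      rec_k <- if (group == "S") cfg$recurrent_s_k else cfg$recurrent_l_k
      planted_occ <- hyper_cnt * mu + sum(rec_k) +
        length(excl_shared[[group]]) * n_wes + length(universal_genes) * n_wes
      if (!is.null(cfg$target_totals)) {
        tt <- cfg$target_totals[[group]]
        lam <- .calibrate_lambda(
          cfg,
          n_sh_bg = length(shared_bg) + length(excl_shared$S) +
            length(excl_shared$L) + length(universal_genes),
          n_ex_bg = length(private_bg[[group]]),
          planted_occ = planted_occ, group = group
        )
        list(
          lambda = lam,
          p_coding = tt[["coding"]] / tt[["total"]],
          p_del = tt[["deleterious"]] / tt[["coding"]]
        )
      } else {
        list(lambda = cfg$lambda_bg[[group]], p_coding = cfg$p_coding,
             p_del = cfg$p_deleterious)
      }
    }
    rates <- list(S = derive_rates("S"), L = derive_rates("L"))
    assign <- list(
      shared_bg = shared_bg, hyper = hyper, excl_shared = excl_shared,
      universal_genes = universal_genes, recurrent = recurrent,
      private_bg = private_bg,
      recurrent_k = list(S = cfg$recurrent_s_k, L = cfg$recurrent_l_k),
      lambda = list(S = rates$S$lambda, L = rates$L$lambda),
      p_coding = list(S = rates$S$p_coding, L = rates$L$p_coding),
      p_del = list(S = rates$S$p_del, L = rates$L$p_del)
    )

    variants <- dplyr::bind_rows(
      .group_variants(cfg, gm, assign, "S"),
      .group_variants(cfg, gm, assign, "L")
    )
    variants <- validate_variants(variants)

    expression <- .make_expression(cfg, gm, manifest, deg_assign)
    coverage <- .make_coverage(cfg, manifest)

    key_at <- function(genes, ref = "A", alt = "G") {
      i <- match(genes, gm$gene)
      paste0(gm$chrom[i], ":", gm$start[i] + 1L, ":", ref, ">", alt)
    }
    excl_keys_for <- function(genes) {
      if (length(genes) == 0) return(character())
      k <- key_at(genes)
      if (length(genes) > 2) { # third planted key is the small deletion
        i <- match(genes[3], gm$gene)
        k[3] <- paste0(gm$chrom[i], ":", gm$start[i] + 1L, ":AT>A")
      }
      k
    }
    truth <- list(
      mutated_genes = list(S = sort(c(shared, s_only)), L = sort(c(shared, l_only))),
      exclusive_genes = list(S = sort(s_only), L = sort(l_only)),
      hypermutated = list(
        S = if (is.null(hyper)) character() else sort(hyper$gene[hyper$s_count > 50]),
        L = if (is.null(hyper)) character() else sort(hyper$gene[hyper$l_count > 50])
      ),
      hyper_counts = hyper,
      recurrent = list(
        S = tibble(gene = recurrent$S, n_distinct = cfg$recurrent_s_k),
        L = tibble(gene = recurrent$L, n_distinct = cfg$recurrent_l_k)
      ),
      exclusive_shared_keys = list(
        S = sort(excl_keys_for(excl_shared$S)),
        L = sort(excl_keys_for(excl_shared$L))
      ),
      universal_keys = sort(key_at(universal_genes)),
      deg = c(deg_assign, list(
        sl_significant = sort(c(deg_assign$sl_only, deg_assign$sl_sm,
                                deg_assign$sl_ml, deg_assign$triple)),
        m_rest_significant = sort(c(deg_assign$sm_ml, deg_assign$triple)),
        common_m_sl = sort(deg_assign$triple)
      )),
      cnv = list(
        regions = cfg$cnv_regions,
        concordant_genes = concordant,
        discordant_genes = discordant
      ),
      showcase_gene = showcase,
      lambda = assign$lambda
    )

    out <- list(
      variants = variants, manifest = manifest, expression = expression,
      coverage = coverage, gene_model = gm, truth = truth, config = cfg
    )
    if (!is.null(dir)) .write_cohort(out, dir)
    out
  })
}

.write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  cov_dir <- file.path(dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  for (s in unique(cohort$coverage$tumor$sample_id)) {
    write_coverage(
      cohort$coverage$tumor[cohort$coverage$tumor$sample_id == s, ],
      file.path(cov_dir, paste0(s, ".tsv"))
    )
  }
  write_coverage(cohort$coverage$normal, file.path(cov_dir, "NORMAL.tsv"))
  write_gene_model(cohort$gene_model, file.path(dir, "genes.bed"))
  truth <- cohort$truth
  truth$hyper_counts <- NULL
  jsonlite::write_json(
    truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
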