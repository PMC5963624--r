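# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, enumeration) so they never share code paths
# with the implementation they check.

oracle_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up q-values written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  running <- 1
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    q[o[i]] <- running
  }
  q
}

# A random mini-cohort: two groups of up to `max_n` samples over up to
# `max_keys` variant keys, each key present in each sample independently.
# Keys map deterministically to a handful of genes.
random_mini_cohort <- function(seed, max_n = 4, max_keys = 30, p_present = 0.4) {
  set.seed(seed)
  n_s <- sample(1:max_n, 1)
  n_l <- sample(1:max_n, 1)
  n_keys <- sample(5:max_keys, 1)
  samples <- c(sprintf("S%d", 1:n_s), sprintf("L%d", 1:n_l))
  manifest <- tibble::tibble(
    sample_id = samples,
    group = rep(c("S", "L"), c(n_s, n_l)),
    rfs_months = rep(c(3L, 30L), c(n_s, n_l)),
    wes = TRUE, wts = TRUE
  )
  genes <- sprintf("GENE%d", ((1:n_keys) - 1) %% 6 + 1)
  rows <- list()
  for (s in samples) {
    present <- which(runif(n_keys) < p_present)
    if (length(present) == 0) present <- sample(n_keys, 1)
    rows[[s]] <- tibble::tibble(
      sample_id = s, chrom = "chr1", pos = present * 10L,
      ref = "A", alt = "G", gene = genes[present],
      variant_class = "SNV", zygosity = "heterozygous",
      consequence = "missense", is_coding = TRUE, is_deleterious = FALSE,
      alt_allele_fraction = 0.4
    )
  }
  list(variants = dplyr::bind_rows(rows), manifest = manifest)
}

# Per-sample key sets computed by plain loops.
oracle_key_sets <- function(variants, samples) {
  out <- list()
  for (s in samples) {
    v <- variants[variants$sample_id == s, ]
    out[[s]] <- unique(paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt))
  }
  out
}

oracle_intersect_all <- function(sets) {
  out <- sets[[1]]
  for (s in sets[-1]) out <- out[out %in% s]
  sort(out)
}

# Brute-force per-(gene, sample) and per-(gene, group) distinct counts.
oracle_gene_counts <- function(variants, manifest) {
  key <- paste0(variants$chrom, ":", variants$pos, ":", variants$ref, ">", variants$alt)
  per_sample <- list()
  per_group <- list()
  for (g in unique(variants$gene)) {
    idx <- variants$gene == g
    for (s in unique(variants$sample_id[idx])) {
      per_sample[[paste(g, s)]] <- length(unique(key[idx & variants$sample_id == s]))
    }
    for (grp in unique(manifest$group)) {
      gs <- manifest$sample_id[manifest$group == grp]
      k <- unique(key[idx & variants$sample_id %in% gs])
      if (length(k) > 0) per_group[[paste(g, grp)]] <- length(k)
    }
  }
  list(per_sample = per_sample, per_group = per_group)
}

# All-pairs half-open interval overlap.
oracle_overlaps <- function(seg, genes) {
  hits <- list()
  for (i in seq_len(nrow(seg))) {
    for (j in seq_len(nrow(genes))) {
      if (seg$chrom[i] == genes$chrom[j] &&
          seg$start[i] < genes$end[j] && genes$start[j] < seg$end[i]) {
        hits[[length(hits) + 1]] <- c(i = i, gene = genes$gene[j])
      }
    }
  }
  hits
}

# Minimal single-variant row builder for hand fixtures.
variant_row <- function(sample_id, gene, pos, ref = "A", alt = "G",
                        chrom = "chr1", coding = TRUE, deleterious = FALSE,
                        class = NULL, consequence = "missense",
                        zygosity = "heterozygous") {
  if (is.null(class)) {
    class <- if (nchar(ref) == 1 && nchar(alt) == 1) {
      "SNV"
    } else if (nchar(ref) > nchar(alt)) "deletion" else "insertion"
  }
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = alt, gene = gene, variant_class = class, zygosity = zygosity,
    consequence = consequence, is_coding = coding,
    is_deleterious = deleterious, alt_allele_fraction = 0.3
  )
}

small_manifest <- function(n_s = 4, n_l = 4, n_m = 0) {
  tibble::tibble(
    sample_id = c(sprintf("S%d", seq_len(n_s)), sprintf("M%d", seq_len(n_m)),
                  sprintf("L%d", seq_len(n_l))),
    group = rep(c("S", "M", "L"), c(n_s, n_m, n_l)),
    rfs_months = rep(c(3L, 20L, 30L), c(n_s, n_m, n_l)),
    wes = rep(c(TRUE, FALSE, TRUE), c(n_s, n_m, n_l)),
    wts = TRUE
  )
}
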