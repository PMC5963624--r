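#' Variant identity keys
#'
#' Two variant records observed in different samples refer to the same
#' variant if and only if their `(chrom, pos, ref, alt)` tuples agree.
#' Identity is deliberately annotation-independent: the gene symbol, the
#' consequence and the carrying sample play no part.
#'
#' @param x A variant tibble (see [read_variants()]).
#' @return A character vector of `chrom:pos:ref>alt` keys, one per row.
#' @export
variant_key <- function(x) {
  if (nrow(x) == 0) return(character(0))
  paste0(x$chrom, ":", x$pos, ":", x$ref, ">", x$alt)
}

#' Validate a variant tibble
#'
#' Checks the invariants of the per-sample variant record: positive 1-based
#' positions, `ref != alt`, deleterious implies coding, and an allele-length
#' consistent `variant_class` (`SNV` iff both alleles are single bases).
#'
#' @param x A data frame of variant records.
#' @return `x` as a tibble, invisibly validated; errors describe the first
#'   violated invariant.
#' @export
validate_variants <- function(x) {
  x <- as_tibble(x)
  required <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "gene", "variant_class",
    "zygosity", "consequence", "is_coding", "is_deleterious"
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!"alt_allele_fraction" %in% names(x)) x$alt_allele_fraction <- NA_real_
  x$pos <- as.integer(x$pos)
  x$is_coding <- as.logical(x$is_coding)
  x$is_deleterious <- as.logical(x$is_deleterious)
  if (nrow(x) == 0) return(x)
  if (any(x$pos < 1L)) abort("variant positions must be >= 1 (1-based)")
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")
  if (any(x$is_deleterious & !x$is_coding)) {
    abort("deleterious variants must be coding (deleterious is a subset of coding)")
  }
  if (any(!x$variant_class %in% .variant_classes)) {
    abort(paste0("variant_class must be one of ", paste(.variant_classes, collapse = ", ")))
  }
  if (any(!x$zygosity %in% .zygosities)) {
    abort("zygosity must be heterozygous or homozygous")
  }
  is_snv <- nchar(x$ref) == 1L & nchar(x$alt) == 1L
  if (any(is_snv != (x$variant_class == "SNV"))) {
    abort("variant_class SNV must coincide with |ref| = |alt| = 1")
  }
  bad_cons <- !x$consequence %in% .consequences
  if (any(bad_cons)) {
    warn(paste0(
      "unknown consequence terms mapped to 'other': ",
      paste(unique(x$consequence[bad_cons]), collapse = ", ")
    ))
    x$consequence[bad_cons] <- "other"
  }
  aaf <- x$alt_allele_fraction
  if (any(!is.na(aaf) & (aaf < 0 | aaf > 1))) {
    abort("alt_allele_fraction must lie in [0, 1]")
  }
  x
}

.class_from_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(ref) > nchar(alt) ~ "deletion",
    nchar(ref) < nchar(alt) ~ "insertion",
    TRUE ~ NA_character_
  )
}

.parse_flag <- function(v) {
  !is.na(v) & v %in% c("1", "TRUE", "True", "true", "yes", "Y")
}

#' Read per-sample variant calls
#'
#' Reads either the package's tab-separated variant dialect (one header line,
#' exactly the variant-record fields as named columns) or a VCF 4.x file.
#' For VCF input, `annotation_spec` names the INFO keys that carry the gene
#' symbol, consequence term and the coding/deleterious flags; per-sample
#' genotype columns split a multi-sample file into per-sample records (a
#' record is emitted for every sample whose genotype carries the alternate
#' allele).
#'
#' Records with a missing gene annotation are kept with `gene = "."`;
#' gene-level operations exclude them. Unknown consequence terms are mapped
#' to `"other"` with a warning.
#'
#' @param path Path to the variant file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param annotation_spec Named list mapping the fields `gene`, `consequence`,
#'   `coding`, `deleterious` (and optionally `aaf`) to INFO keys. VCF only.
#' @param sample_id Sample identifier to use for a VCF without genotype
#'   columns.
#' @return A tibble of validated variant records.
#' @export
read_variants <- function(path,
                          format = c("tsv", "vcf"),
                          annotation_spec = list(
                            gene = "GENE", consequence = "CONSEQUENCE",
                            coding = "CODING", deleterious = "DELETERIOUS"
                          ),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(validate_variants(x))
  }
  .read_variants_vcf(path, annotation_spec, sample_id)
}

.read_variants_vcf <- function(path, spec, sample_id) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    abort(paste0("malformed VCF line ", body[which(nfield < 8L)[1]], " in ", path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(validate_variants(tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      variant_class = character(), zygosity = character(),
      consequence = character(), is_coding = logical(),
      is_deleterious = logical(), alt_allele_fraction = double()
    )))
  }
  gene <- vcfR::extract.info(vcf, element = spec$gene)
  consequence <- vcfR::extract.info(vcf, element = spec$consequence)
  coding <- .parse_flag(vcfR::extract.info(vcf, element = spec$coding))
  deleterious <- .parse_flag(vcfR::extract.info(vcf, element = spec$deleterious))
  aaf <- if (!is.null(spec$aaf)) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = spec$aaf)))
  } else {
    rep(NA_real_, nrow(fix))
  }
  base <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = ifelse(is.na(gene) | gene == "", ".", gene),
    consequence = ifelse(is.na(consequence), "other", consequence),
    is_coding = coding | deleterious,
    is_deleterious = deleterious,
    alt_allele_fraction = aaf
  )
  base$variant_class <- .class_from_alleles(base$ref, base$alt)
  if (anyNA(base$variant_class)) abort("unsupported allele pair (neither SNV, insertion nor deletion)")

  has_gt <- ncol(vcf@gt) > 1
  if (!has_gt) {
    if (is.null(sample_id)) abort("VCF has no genotype columns; supply sample_id")
    base$sample_id <- sample_id
    base$zygosity <- "heterozygous"
    return(validate_variants(base))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  per_sample <- purrr::map_dfr(colnames(gt), function(s) {
    g <- gt[, s]
    carrier <- !is.na(g) & grepl("1", g, fixed = TRUE)
    if (!any(carrier)) return(NULL)
    out <- base[carrier, , drop = FALSE]
    out$sample_id <- s
    out$zygosity <- ifelse(
      g[carrier] %in% c("1/1", "1|1"), "homozygous", "heterozygous"
    )
    out
  })
  validate_variants(per_sample)
}

#' Write variants in the package's TSV dialect
#'
#' @param x Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  x <- validate_variants(x)
  cols <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "gene", "variant_class",
    "zygosity", "consequence", "is_coding", "is_deleterious",
    "alt_allele_fraction"
  )
  readr::write_tsv(x[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write one sample's variants as a minimal VCF 4.2 file
#'
#' Annotations travel in the INFO column under the keys named by
#' `annotation_spec`; the single genotype column carries zygosity.
#'
#' @inheritParams write_variants
#' @param annotation_spec INFO key mapping as in [read_variants()].
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(x, path,
                               annotation_spec = list(
                                 gene = "GENE", consequence = "CONSEQUENCE",
                                 coding = "CODING", deleterious = "DELETERIOUS"
                               )) {
  x <- validate_variants(x)
  if (length(unique(x$sample_id)) > 1) abort("write_variants_vcf writes one sample per file")
  sid <- if (nrow(x) > 0) x$sample_id[1] else "SAMPLE"
  spec <- annotation_spec
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">', spec$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Consequence">', spec$consequence),
    sprintf('##INFO=<ID=%s,Number=1,Type=Integer,Description="Coding flag">', spec$coding),
    sprintf('##INFO=<ID=%s,Number=1,Type=Integer,Description="Deleterious flag">', spec$deleterious),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid), collapse = "\t")
  )
  info <- sprintf(
    "%s=%s;%s=%s;%s=%d;%s=%d",
    spec$gene, x$gene, spec$consequence, x$consequence,
    spec$coding, as.integer(x$is_coding),
    spec$deleterious, as.integer(x$is_deleterious)
  )
  gt <- ifelse(x$zygosity == "homozygous", "1/1", "0/1")
  rows <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", info, "GT", gt,
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' A manifest maps samples to recurrence-free survival (RFS) groups:
#' `S` (short), `M` (medium), `L` (long), with RFS in months. Optional
#' logical columns `wes` and `wts` mark which samples were exome- and
#' transcriptome-sequenced; they default to `TRUE`.
#'
#' @param path Path to a TSV with columns `sample_id`, `group`, `rfs_months`.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(x)
}

#' @rdname read_manifest
#' @param x A data frame to validate in place of a file.
#' @export
validate_manifest <- function(x) {
  x <- as_tibble(x)
  required <- c("sample_id", "group", "rfs_months")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in manifest")
  if (any(!x$group %in% .groups)) abort("manifest group must be one of S, M, L")
  x$rfs_months <- as.integer(x$rfs_months)
  if (any(is.na(x$rfs_months) | x$rfs_months <= 0L)) {
    abort("rfs_months must be a positive integer")
  }
  if (!"wes" %in% names(x)) x$wes <- TRUE
  if (!"wts" %in% names(x)) x$wts <- TRUE
  x$wes <- as.logical(x$wes)
  x$wts <- as.logical(x$wts)
  rng <- split(x$rfs_months, factor(x$group, levels = .groups))
  ok_order <- function(a, b) length(a) == 0 || length(b) == 0 || max(a) < min(b)
  if (!(ok_order(rng$S, rng$M) && ok_order(rng$M, rng$L) && ok_order(rng$S, rng$L))) {
    warn("RFS ranges of S, M, L groups overlap or are out of order")
  }
  x
}

#' @rdname read_manifest
#' @export
write_manifest <- function(x, path) {
  readr::write_tsv(validate_manifest(x), path, progress = FALSE)
  invisible(path)
}

#' Read a gene-by-sample FPKM expression matrix
#'
#' @param path TSV whose first column is `gene` and remaining columns are
#'   per-sample FPKM values (non-negative).
#' @return A tibble with a `gene` column and one numeric column per sample.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_expression(x)
}

#' @rdname read_expression
#' @param x A data frame to validate in place of a file.
#' @export
validate_expression <- function(x) {
  x <- as_tibble(x)
  if (names(x)[1] != "gene") abort("expression matrix must have 'gene' as its first column")
  if (anyDuplicated(x$gene)) abort("duplicate gene rows in expression matrix")
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (any(is.na(vals))) abort("expression matrix contains missing values")
  if (any(vals < 0)) abort("FPKM values must be non-negative")
  x
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(validate_expression(x), path, progress = FALSE)
  invisible(path)
}

#' Read windowed read-count coverage for one sample
#'
#' Bins use BED convention: 0-based inclusive start, exclusive end. Bins must
#' be sorted and non-overlapping within each chromosome.
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `read_count` and
#'   optionally `sample_id`.
#' @param sample_id Sample identifier, required when the file has no
#'   `sample_id` column.
#' @return A coverage tibble with columns `sample_id`, `chrom`, `start`,
#'   `end`, `read_count`.
#' @export
read_coverage <- function(path, sample_id = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x)) {
    if (is.null(sample_id)) abort("coverage file has no sample_id column; supply sample_id")
    x$sample_id <- sample_id
  }
  validate_coverage(x)
}

#' @rdname read_coverage
#' @param x A data frame to validate in place of a file.
#' @export
validate_coverage <- function(x) {
  x <- as_tibble(x)[, c("sample_id", "chrom", "start", "end", "read_count")]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$end <= x$start)) abort("coverage bins must have end > start")
  if (any(x$read_count < 0)) abort("read counts must be non-negative")
  x <- dplyr::arrange(x, .data$sample_id, .data$chrom, .data$start)
  overlap <- x %>%
    dplyr::group_by(.data$sample_id, .data$chrom) %>%
    dplyr::summarise(
      bad = any(.data$start[-1] < .data$end[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(overlap$bad, na.rm = TRUE)) abort("coverage bins overlap within a chromosome")
  x
}

#' @rdname read_coverage
#' @export
write_coverage <- function(x, path) {
  readr::write_tsv(validate_coverage(x), path, progress = FALSE)
  invisible(path)
}

#' Read a BED4 gene model
#'
#' One interval per gene (the longest transcript footprint), BED convention
#' (0-based half-open). BED files carry no header line.
#'
#' @param path BED4 file: chrom, start, end, gene.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_model <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene"),
    show_col_types = FALSE, progress = FALSE
  )
  validate_gene_model(x[, c("gene", "chrom", "start", "end")])
}

#' @rdname read_gene_model
#' @param x A data frame to validate in place of a file.
#' @export
validate_gene_model <- function(x) {
  x <- as_tibble(x)[, c("gene", "chrom", "start", "end")]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$end <= x$start)) abort("gene model intervals must have end > start")
  if (anyDuplicated(x$gene)) abort("gene model must have one interval per gene")
  x
}

#' @rdname read_gene_model
#' @export
write_gene_model <- function(x, path) {
  x <- validate_gene_model(x)
  readr::write_tsv(
    x[, c("chrom", "start", "end", "gene")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
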