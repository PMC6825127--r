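VARIANT_COLS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene",
  "tumor_vaf", "normal_vaf", "cadd_phred", "mutation_taster", "cravat_p"
)

#' Write one sample's variants as a minimal VCF 4.2
#'
#' Emits a single-sample VCF with the paired-VAF pipeline's payload in INFO
#' keys: `GENE`, `TVAF`, `NVAF` (fractions), `FUNC_SCORE` (CADD phred),
#' `MTASTER`, `CRAVAT_P`. Missing annotations are written as `.`-free
#' absent keys.
#'
#' @param variants Variant tibble for one sample (see [classify_zygosity()]
#'   for the expected columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  variants <- tibble::as_tibble(variants)
  if (length(unique(variants$sample_id)) > 1L) {
    abort("`write_vcf()` writes one sample per file.", class = "nogcss_validation_error")
  }
  fmt_num <- function(x) formatC(x, digits = 6, format = "g")
  info <- purrr::pmap_chr(variants, function(...) {
    v <- list(...)
    parts <- c(
      sprintf("GENE=%s", v$gene),
      sprintf("TVAF=%s", fmt_num(v$tumor_vaf)),
      sprintf("NVAF=%s", fmt_num(v$normal_vaf))
    )
    if (!is.null(v$cadd_phred) && !is.na(v$cadd_phred)) {
      parts <- c(parts, sprintf("FUNC_SCORE=%s", fmt_num(v$cadd_phred)))
    }
    if (!is.null(v$mutation_taster) && !is.na(v$mutation_taster)) {
      parts <- c(parts, sprintf("MTASTER=%s", v$mutation_taster))
    }
    if (!is.null(v$cravat_p) && !is.na(v$cravat_p)) {
      parts <- c(parts, sprintf("CRAVAT_P=%s", fmt_num(v$cravat_p)))
    }
    paste(parts, collapse = ";")
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=nogcss;sample=%s", variants$sample_id[1] %||% "NA"),
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=TVAF,Number=1,Type=Float,Description="Tumor variant allele frequency">',
    '##INFO=<ID=NVAF,Number=1,Type=Float,Description="Normal variant allele frequency">',
    '##INFO=<ID=FUNC_SCORE,Number=1,Type=Float,Description="CADD phred functional score">',
    '##INFO=<ID=MTASTER,Number=1,Type=String,Description="MutationTaster verdict">',
    '##INFO=<ID=CRAVAT_P,Number=1,Type=Float,Description="CRAVAT p-value">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"), collapse = "\t")
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
    variants$chrom, as.integer(variants$pos), variants$ref, variants$alt, info
  )
  writeLines(c(header, body), path)
  invisible(path)
}

info_field <- function(info, key, numeric = TRUE) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- stringr::str_match(info, pat)[, 2]
  if (numeric) suppressWarnings(as.numeric(m)) else m
}

#' Read a paired tumor/normal VCF into a variant tibble
#'
#' Supports two dialects: `"info"` reads the VAFs from INFO keys
#' `TVAF`/`NVAF` (with `GENE`, `FUNC_SCORE`, `MTASTER`, `CRAVAT_P`);
#' `"format"` reads per-sample `AF` from the FORMAT columns named by
#' `tumor_sample`/`normal_sample`. Multi-allelic records are split into one
#' record per alternate allele (comma-separated INFO values are split
#' positionally; scalar values are reused for every allele).
#'
#' @param path VCF file (uncompressed or bgzipped; anything `vcfR` reads).
#' @param sample_id Sample id to assign (default: file base name).
#' @param dialect `"info"` or `"format"`.
#' @param tumor_sample,normal_sample FORMAT column names for the
#'   `"format"` dialect.
#' @return Variant tibble with the standard columns.
#' @export
read_vcf_variants <- function(path, sample_id = NULL,
                              dialect = c("info", "format"),
                              tumor_sample = "TUMOR", normal_sample = "NORMAL") {
  dialect <- match.arg(dialect)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.", class = "nogcss_config_error")
  }
  sample_id <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCFs drop to a vector
  fix <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  info <- vcfR::getINFO(vcf)
  out <- tibble::tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_field(info, "GENE", numeric = FALSE)
  )
  if (dialect == "info") {
    out$tumor_vaf_raw <- info_field(info, "TVAF", numeric = FALSE)
    out$normal_vaf_raw <- info_field(info, "NVAF", numeric = FALSE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "AF", as.numeric = FALSE)
    if (!all(c(tumor_sample, normal_sample) %in% colnames(gt))) {
      abort(sprintf(
        "FORMAT columns '%s'/'%s' not found (saw: %s).",
        tumor_sample, normal_sample, toString(colnames(gt))
      ), class = "nogcss_validation_error")
    }
    out$tumor_vaf_raw <- gt[, tumor_sample]
    out$normal_vaf_raw <- gt[, normal_sample]
  }
  out$cadd_raw <- info_field(info, "FUNC_SCORE", numeric = FALSE)
  out$taster_raw <- info_field(info, "MTASTER", numeric = FALSE)
  out$cravat_raw <- info_field(info, "CRAVAT_P", numeric = FALSE)

  # split multi-allelic records: one row per ALT, positional for
  # comma-separated values, recycled for scalars
  nth_or_first <- function(x, i) {
    parts <- stringr::str_split(x %||% NA_character_, ",")[[1]]
    val <- if (length(parts) >= i) parts[i] else parts[1]
    if (identical(val, ".")) NA_character_ else val
  }
  out <- purrr::pmap_dfr(out, function(...) {
    r <- list(...)
    alts <- stringr::str_split(r$alt, ",")[[1]]
    purrr::map_dfr(seq_along(alts), function(i) {
      tibble::tibble(
        sample_id = r$sample_id, chrom = r$chrom, pos = r$pos, ref = r$ref,
        alt = alts[i],
        gene = r$gene,
        tumor_vaf = suppressWarnings(as.numeric(nth_or_first(r$tumor_vaf_raw, i))),
        normal_vaf = suppressWarnings(as.numeric(nth_or_first(r$normal_vaf_raw, i))),
        cadd_phred = suppressWarnings(as.numeric(nth_or_first(r$cadd_raw, i))),
        mutation_taster = nth_or_first(r$taster_raw, i),
        cravat_p = suppressWarnings(as.numeric(nth_or_first(r$cravat_raw, i)))
      )
    })
  })
  out
}

#' Read or write Varscan2-style variant TSVs
#'
#' The TSV carries one row per variant with the same columns the VCF INFO
#' dialect encodes; VAFs are fractions in \[0, 1\].
#'
#' @param variants Variant tibble.
#' @param path File path.
#' @return `read_variants_tsv()` returns the variant tibble;
#'   `write_variants_tsv()` returns `path` invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants[, intersect(VARIANT_COLS, names(variants))], path)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      tumor_vaf = readr::col_double(),
      normal_vaf = readr::col_double(),
      .default = readr::col_guess()
    )
  )
}

#' Read a weighted edge list
#'
#' @param path Two- or three-column TSV (`gene_a`, `gene_b`, optional
#'   `weight`), with or without a header line.
#' @return Edge tibble suitable for [normalize_network()].
#' @export
read_network_tsv <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("gene", tolower(first))
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE)
  if (!has_header) {
    names(df) <- c("gene_a", "gene_b", "weight")[seq_len(ncol(df))]
  }
  tibble::as_tibble(df)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readr::read_lines(path)
  parts <- stringr::str_split(lines, "\t")
  setNames(
    lapply(parts, function(p) p[-(1:2)]),
    vapply(parts, `[`, character(1), 1)
  )
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(genes, nm) {
    paste(c(nm, "synthetic", genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a genes-by-samples matrix TSV
#'
#' First column is the gene (row) name; remaining columns are samples.
#'
#' @param m Matrix with rownames.
#' @param path File path.
#' @param id Name of the first column.
#' @return `read_matrix_tsv()` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path, id = "gene") {
  df <- tibble::as_tibble(m, rownames = id)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id = "gene") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write every artifact of a synthetic cohort to a directory
#'
#' Serializes the cohort in the pipeline's interchange formats: the network
#' edge list, hallmark GMT, clinical TSV, expression and metagene matrices,
#' a combined Varscan2-style variant TSV, per-sample VCFs under `vcf/`, and
#' the leukocyte gene list.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param vcf Also write per-sample VCFs (default FALSE; the TSV is the
#'   compact default).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$network$edges, file.path(dir, "network.tsv"))
  write_gmt(cohort$hallmark_sets, file.path(dir, "hallmarks.gmt"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(cohort$metagenes, file.path(dir, "metagenes.tsv"), id = "metagene")
  write_variants_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  writeLines(cohort$leukocyte_genes, file.path(dir, "leukocyte_genes.txt"))
  if (vcf) {
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    for (id in unique(cohort$variants$sample_id)) {
      write_vcf(
        dplyr::filter(cohort$variants, .data$sample_id == id),
        file.path(vdir, paste0(id, ".vcf"))
      )
    }
  }
  invisible(dir)
}
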