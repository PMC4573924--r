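#' Classify a variant by its allele lengths
#'
#' Returns the variant class implied by the reference and alternate allele
#' lengths: `SNV` (1 vs 1), `MNV` (equal lengths > 1), `INS` (alt longer) or
#' `DEL` (ref longer, VCF-style anchored representation).
#'
#' @param ref Character vector of reference alleles (uppercase ACGT).
#' @param alt Character vector of alternate alleles (uppercase ACGT).
#' @return Character vector with elements in `c("SNV","MNV","INS","DEL")`.
#' @examples
#' variant_type(c("A", "AC", "ACTT", "A"), c("G", "GT", "A", "ATT"))
#' @export
variant_type <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == la & lr == 1L, "SNV",
    ifelse(lr == la, "MNV", ifelse(lr > la, "DEL", "INS")))
}

#' Construct and validate variant keys
#'
#' A variant key identifies one alternate allele at one genomic locus:
#' chromosome, 1-based position, reference and alternate allele, gene symbol
#' and variant class. All coordinates in the package are 1-based (hg19-style
#' positions as used in clinical hotspot reports); BED input is converted at
#' the boundary by [read_amplicons()].
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (integer, `>= 1`).
#' @param ref,alt Alleles (non-empty, uppercase ACGT; `ref != alt`).
#' @param gene HGNC gene symbols.
#' @param vtype Optional variant class; derived from allele lengths when `NULL`
#'   and checked for consistency when supplied.
#' @return A data.frame with columns `chrom, pos, ref, alt, gene, vtype`.
#' @examples
#' variant_key("chr7", 140453136, "T", "A", "BRAF")
#' @export
variant_key <- function(chrom, pos, ref, alt, gene, vtype = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt), length(gene))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  gene <- rep_len(as.character(gene), n)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant positions must be 1-based integers >= 1", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
    stop("ref and alt alleles must be non-empty ACGT strings", call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  derived <- variant_type(ref, alt)
  if (is.null(vtype)) {
    vtype <- derived
  } else {
    vtype <- rep_len(as.character(vtype), n)
    bad <- vtype != derived
    if (any(bad))
      stop("vtype inconsistent with allele lengths at: ",
        paste(variant_id(data.frame(chrom, pos, ref, alt))[bad], collapse = ", "),
        call. = FALSE)
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, vtype = vtype, stringsAsFactors = FALSE)
}

#' Canonical string id of a variant key
#'
#' `chrom:pos:ref:alt` string used for joining call sets, truth sets and
#' baselines.
#'
#' @param x A data.frame carrying `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of ids.
#' @export
variant_id <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# shared column order for call tables
.call_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "vtype",
  "observed_pct", "depth", "alt_depth", "quality", "strand_bias", "filters")

#' Construct and validate a variant call table
#'
#' A call table holds one row per observed alternate allele: the variant key
#' plus the observed allele frequency (percent, 0-100), total depth, optional
#' alternate-supporting depth, a phred-like call quality, and strand bias
#' expressed as the larger per-strand alternate-read proportion (range
#' 0.5-1.0). Frequencies are carried in percent end-to-end; VCF fractions are
#' converted on read.
#'
#' @param df A data.frame with at least `chrom, pos, ref, alt, gene,
#'   observed_pct, depth`; optional `sample_id, alt_depth, quality,
#'   strand_bias, filters, hgvs_c`.
#' @return The validated data.frame, classed `"vc_calls"`, with missing
#'   optional columns filled with `NA` and `filters` as `";"`-joined strings.
#' @examples
#' variant_calls(data.frame(chrom = "chr7", pos = 140453136, ref = "T",
#'   alt = "A", gene = "BRAF", observed_pct = 18.5, depth = 1200))
#' @export
variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "ref", "alt", "gene", "observed_pct", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("call table missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE)
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt, df$gene,
    if ("vtype" %in% names(df)) df$vtype else NULL)
  out <- key
  nr <- nrow(out)
  out$sample_id <- if ("sample_id" %in% names(df))
    as.character(df$sample_id) else rep(NA_character_, nr)
  out$observed_pct <- as.numeric(df$observed_pct)
  out$depth <- as.integer(df$depth)
  out$alt_depth <- if ("alt_depth" %in% names(df))
    as.integer(df$alt_depth) else rep(NA_integer_, nr)
  out$quality <- if ("quality" %in% names(df))
    as.numeric(df$quality) else rep(NA_real_, nr)
  out$strand_bias <- if ("strand_bias" %in% names(df))
    as.numeric(df$strand_bias) else rep(NA_real_, nr)
  out$filters <- if ("filters" %in% names(df))
    as.character(df$filters) else rep("", nr)
  out$filters[is.na(out$filters) | out$filters == "."] <- ""
  if ("hgvs_c" %in% names(df)) out$hgvs_c <- as.character(df$hgvs_c)

  if (any(out$observed_pct < 0 | out$observed_pct > 100, na.rm = TRUE))
    stop("observed_pct must lie in [0, 100]", call. = FALSE)
  if (any(out$depth < 0, na.rm = TRUE))
    stop("depth must be non-negative", call. = FALSE)
  both <- !is.na(out$alt_depth) & !is.na(out$depth)
  if (any(out$alt_depth[both] > out$depth[both]))
    stop("alt_depth exceeds depth", call. = FALSE)
  chk <- both & out$depth > 0
  if (any(abs(out$observed_pct[chk] - 100 * out$alt_depth[chk] / out$depth[chk]) > 0.05))
    stop("observed_pct inconsistent with alt_depth/depth (tolerance 0.05)",
      call. = FALSE)
  bad_sb <- !is.na(out$strand_bias) &
    (out$strand_bias < 0.5 | out$strand_bias > 1)
  if (any(bad_sb))
    stop("strand_bias must lie in [0.5, 1]", call. = FALSE)
  if (any(out$quality < 0, na.rm = TRUE))
    stop("quality must be non-negative", call. = FALSE)
  cols <- c(intersect(.call_cols, names(out)), setdiff(names(out), .call_cols))
  out <- out[, unique(cols)]
  rownames(out) <- NULL
  class(out) <- c("vc_calls", "data.frame")
  out
}

#' Per-run summary metrics
#'
#' @param run_id Run identifier.
#' @param mean_depth Mean per-base coverage.
#' @param q20_bases Count of bases with quality >= Q20.
#' @param reads_on_target_pct,uniformity_pct Percentages in `[0, 100]`.
#' @return A one-row data.frame classed `"run_metrics"`.
#' @export
run_metrics <- function(run_id, mean_depth, q20_bases = NA,
                        reads_on_target_pct = NA, uniformity_pct = NA) {
  pct <- c(reads_on_target_pct, uniformity_pct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("percent metrics must lie in [0, 100]", call. = FALSE)
  if (mean_depth < 0 || isTRUE(q20_bases < 0))
    stop("counts must be non-negative", call. = FALSE)
  out <- data.frame(run_id = as.character(run_id),
    mean_depth = as.numeric(mean_depth), q20_bases = as.numeric(q20_bases),
    reads_on_target_pct = as.numeric(reads_on_target_pct),
    uniformity_pct = as.numeric(uniformity_pct), stringsAsFactors = FALSE)
  class(out) <- c("run_metrics", "data.frame")
  out
}

#' @export
print.vc_calls <- function(x, ...) {
  cat("<variant calls> ", nrow(x), " call(s), ",
    length(unique(x$sample_id)), " sample(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
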