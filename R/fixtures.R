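#' Bundled assay-characterization tables
#'
#' The package ships the plain-text tables used throughout its examples and
#' validation workflow: per-line genotype profiles of the four characterized
#' cancer cell lines (colon HCT116, pancreatic MIA-PaCa-2, lung H1975,
#' melanoma SK-MEL-28) from fresh-frozen and FFPE preparations plus a normal
#' placental diluent, the equal four-line mixture specification, historical
#' run-metric summary statistics (mean/SD/z per metric), the QC-material
#' characterization (8 variants in 5 genes), reference single-gene assay
#' results for 55 clinical specimens with the corresponding panel calls, a
#' recurrent-artifact blacklist, germline MAF annotations, and a synthetic
#' amplicon BED.
#'
#' Published hotspot tables report positions and alternate alleles but not
#' reference alleles for most loci; where the reference base is not part of
#' the characterization, these tables carry a synthetic placeholder ref
#' (documented here, harmless for frequency arithmetic, which joins on the
#' full key consistently). The amplicon BED, the per-call depths/qualities of
#' the clinical panel calls, and three of the four MAF values are likewise
#' synthetic plumbing; the gene-level mutation statuses, frequencies and
#' summary statistics are the characterization content. The FFPE profile
#' records CDKN2A in H1975 at the genotype-level 100 percent (homozygous
#' variant) and as a homozygous deletion in MIA-PaCa-2.
#'
#' @param name File name under the package's `extdata/` directory.
#' @return `qc_fixture()` returns a file path; the loaders below return
#'   parsed objects.
#' @name fixtures
#' @export
qc_fixture <- function(name) {
  p <- system.file("extdata", name, package = "assayqc")
  if (p == "") stop("no bundled fixture named ", name, call. = FALSE)
  p
}

#' @rdname fixtures
#' @param type `"frozen"` (includes the `PLACENTA` diluent line) or
#'   `"ffpe"`.
#' @export
validation_profiles <- function(type = c("frozen", "ffpe")) {
  type <- match.arg(type)
  read_line_profiles(qc_fixture(paste0(type, "_line_profiles.tsv")))
}

#' Read a mixture specification from JSON
#'
#' Format: `{"components": [{"line": "HCT116", "fraction": 0.25}, ...]}`.
#'
#' @param path JSON file.
#' @return A [mixture_spec()].
#' @export
read_mixture_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  mixture_spec(j$components$line, j$components$fraction)
}

#' @rdname fixtures
#' @export
equal_mix <- function() read_mixture_json(qc_fixture("equal_mix.json"))

#' @rdname fixtures
#' @export
metric_summaries <- function() .read_tsv(qc_fixture("run_metric_summaries.tsv"))

#' Cutoff rules derived from the shipped metric summaries
#'
#' Applies [derive_cutoff()] to each row of [metric_summaries()]: a lower
#' coverage bound, a lower Q20-base-count bound, a lower (log10-scale)
#' quality bound and an upper strand-bias bound.
#'
#' @return A `"cutoff_rules"` collection.
#' @export
shipped_cutoff_rules <- function() {
  ms <- metric_summaries()
  cutoff_rules(lapply(seq_len(nrow(ms)), function(i)
    derive_cutoff(mean = ms$mean[i], sd = ms$sd[i], metric = ms$metric[i],
      side = ms$side[i], z = ms$z[i], confidence = ms$confidence[i],
      transform = ms$transform[i], rounding = ms$rounding[i],
      digits = if (is.na(ms$digits[i])) NA else ms$digits[i])))
}

#' @rdname fixtures
#' @export
qc_truth <- function() {
  df <- .read_tsv(qc_fixture("qc_material_truth.tsv"))
  df$vtype <- variant_type(df$ref, df$alt)
  df
}

#' @rdname fixtures
#' @export
clinical_reference <- function() {
  reference_results(.read_tsv(qc_fixture("clinical_reference.tsv")))
}

#' @rdname fixtures
#' @export
clinical_calls <- function() {
  df <- .read_tsv(qc_fixture("clinical_test_calls.tsv"))
  variant_calls(df)
}

#' @rdname fixtures
#' @export
artifact_blacklist <- function() .read_tsv(qc_fixture("artifact_blacklist.tsv"))

#' @rdname fixtures
#' @export
maf_annotations <- function() .read_tsv(qc_fixture("maf_annotations.tsv"))

#' @rdname fixtures
#' @export
panel_amplicons <- function() read_amplicons(qc_fixture("panel_amplicons.bed"))
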