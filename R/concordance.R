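# Concordance of panel calls against orthogonal single-gene assay results,
# and frequency correlation between paired call sets.

#' Validate reference single-gene assay results
#'
#' One row per sample per gene with `status` `"positive"` or `"negative"`
#' and, for positives, an optional coding-change string `hgvs_c`.
#'
#' @param df Data.frame with columns `sample_id, gene, status` and optional
#'   `hgvs_c`.
#' @return Validated data.frame classed `"reference_results"`.
#' @export
reference_results <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference table missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE)
  if (!all(df$status %in% c("positive", "negative")))
    stop("status must be 'positive' or 'negative'", call. = FALSE)
  if (!"hgvs_c" %in% names(df)) df$hgvs_c <- NA_character_
  df$hgvs_c[df$hgvs_c %in% ""] <- NA_character_
  if (any(df$status == "negative" & !is.na(df$hgvs_c)))
    stop("negative reference rows must not carry an hgvs_c", call. = FALSE)
  if (anyDuplicated(paste(df$sample_id, df$gene)))
    stop("one reference row per sample per gene required", call. = FALSE)
  class(df) <- c("reference_results", "data.frame")
  df
}

#' Score panel calls against reference assay results
#'
#' The scoring unit is the sample over the queried gene set: a sample is
#' reference-positive if any of its reference rows in `genes` is positive,
#' and test-positive if any of its calls in `genes` passes `policy`
#' (`mode = "hgvs_level"` additionally requires the call's `hgvs_c` to match
#' a positive reference `hgvs_c` for a true positive). Sensitivity is
#' `100 * TP / (TP + FN)` and specificity `100 * TN / (TN + FP)`, in
#' percent.
#'
#' @param calls A `"vc_calls"` table with `sample_id` (all samples pooled),
#'   or a list of per-sample tables named by sample id.
#' @param reference A [reference_results()] table.
#' @param genes Character vector of genes to score (non-empty).
#' @param samples Optional roster of sequenced samples; every reference
#'   sample must appear in it (an error lists missing ids). Defaults to the
#'   union of reference and call sample ids, i.e. a sample with no calls is
#'   a sequenced negative.
#' @param mode `"gene_level"` (default) or `"hgvs_level"`.
#' @param policy A [call_policy()] a call must pass to count as test
#'   positive.
#' @return A list classed `"concordance"`: `table` (per-sample labels),
#'   `counts` (TP/FP/TN/FN), `sensitivity_pct`, `specificity_pct`, `n`.
#' @export
score_concordance <- function(calls, reference, genes, samples = NULL,
                              mode = c("gene_level", "hgvs_level"),
                              policy = call_policy()) {
  mode <- match.arg(mode)
  if (!length(genes)) stop("gene set must be non-empty", call. = FALSE)
  reference <- reference_results(as.data.frame(reference))
  if (is.list(calls) && !is.data.frame(calls)) {
    for (nm in names(calls)) calls[[nm]]$sample_id <- nm
    calls <- do.call(rbind, lapply(calls, as.data.frame))
  }
  calls <- as.data.frame(calls)
  ref_samples <- unique(reference$sample_id)
  if (is.null(samples))
    samples <- union(ref_samples, unique(calls$sample_id))
  missing <- setdiff(ref_samples, samples)
  if (length(missing))
    stop("no test sample for reference id(s): ",
      paste(missing, collapse = ", "), call. = FALSE)

  ref <- reference[reference$gene %in% genes, , drop = FALSE]
  tst <- calls[calls$gene %in% genes & calls$sample_id %in% samples, ,
    drop = FALSE]
  if (nrow(tst)) tst <- tst[passes_policy(variant_calls(tst),
    policy), , drop = FALSE]

  per_sample <- lapply(ref_samples, function(s) {
    rs <- ref[ref$sample_id == s, , drop = FALSE]
    ref_pos <- any(rs$status == "positive")
    sc <- tst[tst$sample_id == s, , drop = FALSE]
    test_pos <- if (mode == "gene_level") nrow(sc) > 0 else {
      hg <- rs$hgvs_c[rs$status == "positive"]
      nrow(sc) > 0 && "hgvs_c" %in% names(sc) &&
        any(sc$hgvs_c %in% hg[!is.na(hg)])
    }
    label <- if (ref_pos && test_pos) "TP" else if (ref_pos) "FN"
      else if (test_pos) "FP" else "TN"
    data.frame(sample_id = s, reference = ifelse(ref_pos, "positive",
      "negative"), test = ifelse(test_pos, "positive", "negative"),
      label = label, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_sample)
  counts <- c(TP = sum(tab$label == "TP"), FP = sum(tab$label == "FP"),
    TN = sum(tab$label == "TN"), FN = sum(tab$label == "FN"))
  sens <- 100 * counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
  spec <- 100 * counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
  structure(list(table = tab, counts = counts,
    sensitivity_pct = sens, specificity_pct = spec, n = nrow(tab),
    genes = genes, mode = mode), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d samples over genes %s (%s)\n", x$n,
    paste(x$genes, collapse = "/"), x$mode))
  print(x$counts)
  cat(sprintf("sensitivity %.1f %%, specificity %.1f %%\n",
    x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Pearson correlation between two call sets' frequencies
#'
#' Pairs variants by key. With `join = "union_zero_fill"` (default) a variant
#' absent from one set contributes 0 percent there — appropriate for
#' replicate/paired comparisons where absence means not called; with
#' `"intersection"` only shared variants are used. Requires at least 3 paired
#' points and non-degenerate variance on both sides.
#'
#' @param set_a,set_b `"vc_calls"` tables (or data.frames with key columns
#'   and `observed_pct`).
#' @param join `"union_zero_fill"` or `"intersection"`.
#' @return Pearson r (scalar).
#' @export
correlate_frequencies <- function(set_a, set_b,
                                  join = c("union_zero_fill", "intersection")) {
  join <- match.arg(join)
  a <- stats::setNames(set_a$observed_pct, variant_id(set_a))
  b <- stats::setNames(set_b$observed_pct, variant_id(set_b))
  ids <- if (join == "intersection") intersect(names(a), names(b))
    else union(names(a), names(b))
  if (length(ids) < 3L)
    stop("need at least 3 paired points (found ", length(ids), ")",
      call. = FALSE)
  va <- ifelse(ids %in% names(a), a[ids], 0)
  vb <- ifelse(ids %in% names(b), b[ids], 0)
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("degenerate variance: correlation undefined", call. = FALSE)
  stats::cor(va, vb)
}
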