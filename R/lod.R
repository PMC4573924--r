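# Limit-of-detection estimation from replicate dilution series.

#' Call-acceptance policy
#'
#' Thresholds a call must meet to count as detected: minimum depth, minimum
#' frequency (percent), minimum phred-like quality and maximum strand bias
#' (larger per-strand alternate proportion). Defaults mirror the shipped
#' run-metric cutoffs: depth 200, quality 300 (raw scale), strand bias 0.79,
#' frequency 4 percent (the assay's limit of detection). All bounds are
#' inclusive. A missing field on a call is not assessed against its
#' threshold.
#'
#' @param min_depth,min_freq_pct,min_quality Non-negative thresholds.
#' @param max_strand_bias In `[0.5, 1]`.
#' @return A list classed `"call_policy"`.
#' @export
call_policy <- function(min_depth = 200, min_freq_pct = 4,
                        min_quality = 300, max_strand_bias = 0.79) {
  if (any(c(min_depth, min_freq_pct, min_quality) < 0))
    stop("policy thresholds must be non-negative", call. = FALSE)
  if (max_strand_bias < 0.5 || max_strand_bias > 1)
    stop("max_strand_bias must lie in [0.5, 1]", call. = FALSE)
  structure(list(min_depth = min_depth, min_freq_pct = min_freq_pct,
    min_quality = min_quality, max_strand_bias = max_strand_bias),
    class = "call_policy")
}

#' Which calls pass a policy
#'
#' @param calls A `"vc_calls"` table.
#' @param policy A [call_policy()].
#' @return Logical vector, one element per call.
#' @export
passes_policy <- function(calls, policy) {
  stopifnot(inherits(policy, "call_policy"))
  ok <- rep(TRUE, nrow(calls))
  chk <- function(v, f) ifelse(is.na(v), TRUE, f(v))
  ok <- ok & chk(calls$depth, function(v) v >= policy$min_depth)
  ok <- ok & chk(calls$observed_pct, function(v) v >= policy$min_freq_pct)
  ok <- ok & chk(calls$quality, function(v) v >= policy$min_quality)
  ok <- ok & chk(calls$strand_bias, function(v) v <= policy$max_strand_bias)
  ok
}

#' Build a detection-series table from a dilution series
#'
#' @param df A data.frame with columns `nominal_pct`, `n_detected`,
#'   `n_total`.
#' @return A data.frame classed `"detection_series"` with an added `rate`
#'   column.
#' @export
detection_series <- function(df) {
  stopifnot(all(c("nominal_pct", "n_detected", "n_total") %in% names(df)))
  df <- as.data.frame(df)
  df$n_detected <- as.integer(df$n_detected)
  df$n_total <- as.integer(df$n_total)
  if (any(df$n_total < 1) || any(df$n_detected < 0) ||
      any(df$n_detected > df$n_total))
    stop("need 0 <= n_detected <= n_total and n_total >= 1", call. = FALSE)
  if (any(df$nominal_pct <= 0))
    stop("nominal levels must be positive", call. = FALSE)
  df$rate <- df$n_detected / df$n_total
  df <- df[order(df$nominal_pct), ]
  rownames(df) <- NULL
  class(df) <- c("detection_series", "data.frame")
  df
}

#' Replicate detection rates across a dilution series
#'
#' A truth variant counts as detected in a replicate iff the replicate holds
#' a call with the same variant key that passes the policy. Rates are grouped
#' by the variant's nominal expected frequency at its level, rounded to
#' 0.1 percent; truth variants with expectation 0 are excluded (nothing to
#' detect). The result is invariant to replicate order and to duplicated
#' calls within a replicate.
#'
#' @param series A list of levels, each a list with elements `truth` (an
#'   `"expected_profile"`) and `replicates` (a list of `"vc_calls"` tables),
#'   as produced by [simulate_dilution_series()].
#' @param policy A [call_policy()].
#' @return A `"detection_series"` table.
#' @export
detection_rate <- function(series, policy = call_policy()) {
  det <- list()
  for (lv in series) {
    if (is.null(lv$truth) || is.null(lv$replicates))
      stop("each level needs 'truth' and 'replicates' (level label missing?)",
        call. = FALSE)
    truth <- lv$truth[lv$truth$expected_pct > 0, , drop = FALSE]
    if (nrow(truth) == 0L) next
    tid <- variant_id(truth)
    nominal <- round(truth$expected_pct, 1)
    hits <- matrix(0L, nrow = length(tid), ncol = length(lv$replicates))
    for (j in seq_along(lv$replicates)) {
      rep_calls <- lv$replicates[[j]]
      pass_ids <- unique(variant_id(rep_calls)[passes_policy(rep_calls, policy)])
      hits[, j] <- as.integer(tid %in% pass_ids)
    }
    det[[length(det) + 1L]] <- data.frame(nominal_pct = nominal,
      n_detected = rowSums(hits), n_total = ncol(hits))
  }
  if (!length(det))
    stop("empty detection series", call. = FALSE)
  all <- do.call(rbind, det)
  agg <- stats::aggregate(cbind(n_detected, n_total) ~ nominal_pct,
    data = all, FUN = sum)
  detection_series(agg)
}

#' Estimate the limit of detection
#'
#' Returns the smallest nominal level whose detection rate meets
#' `required_rate` *and* whose every higher level also meets it; the second
#' condition prevents a non-monotone series from yielding a spuriously low
#' LoD. With the default `required_rate = 1` this is the lowest frequency
#' detected in 100 percent of replicates.
#'
#' @param series A `"detection_series"` table.
#' @param required_rate Required detection rate in `(0, 1]` (default 1).
#' @return A list classed `"lod_estimate"` with elements `lod_pct` (`NA` if
#'   no level qualifies), `reached`, `required_rate` and `series`.
#' @export
estimate_lod <- function(series, required_rate = 1) {
  stopifnot(inherits(series, "detection_series"))
  if (nrow(series) == 0L) stop("empty detection series", call. = FALSE)
  if (!is.numeric(required_rate) || length(required_rate) != 1L ||
      is.na(required_rate) || required_rate <= 0 || required_rate > 1)
    stop("required_rate must lie in (0, 1]", call. = FALSE)
  s <- series[order(series$nominal_pct), ]
  ok <- s$rate >= required_rate
  # qualifying levels: ok here and at every higher level
  ok_above <- rev(cumprod(rev(ok))) > 0
  lod <- if (any(ok_above)) s$nominal_pct[which(ok_above)[1]] else NA_real_
  structure(list(lod_pct = lod, reached = !is.na(lod),
    required_rate = required_rate, series = s), class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  if (x$reached)
    cat(sprintf("Limit of detection: %.1f %% VAF (detection rate >= %.2f)\n",
      x$lod_pct, x$required_rate))
  else
    cat(sprintf("Limit of detection: not reached at rate >= %.2f\n",
      x$required_rate))
  print.data.frame(as.data.frame(x$series), row.names = FALSE, ...)
  invisible(x)
}

#' Linearity of observed versus expected frequencies
#'
#' Pearson correlation and ordinary least squares of observed on expected
#' frequency across shared loci, the standard check that a dilution series
#' tracks the equality line.
#'
#' @param expected An `"expected_profile"`.
#' @param observed A `"vc_calls"` table (or any data.frame with the key
#'   columns and `observed_pct`) of mean observed frequencies.
#' @return A list classed `"linearity_fit"`: `r`, `slope`, `intercept`, `n`.
#' @export
linearity <- function(expected, observed) {
  m <- merge(as.data.frame(expected)[, c("chrom", "pos", "ref", "alt",
      "expected_pct")],
    as.data.frame(observed)[, c("chrom", "pos", "ref", "alt", "observed_pct")],
    by = c("chrom", "pos", "ref", "alt"))
  if (nrow(m) < 3L)
    stop("need at least 3 shared loci (found ", nrow(m), ")", call. = FALSE)
  if (stats::var(m$expected_pct) == 0 || stats::var(m$observed_pct) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  fit <- stats::lm(observed_pct ~ expected_pct, data = m)
  structure(list(r = stats::cor(m$expected_pct, m$observed_pct),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]), n = nrow(m)),
    class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("observed ~ expected over %d loci: r = %.4f, slope = %.3f, intercept = %.3f\n",
    x$n, x$r, x$slope, x$intercept))
  invisible(x)
}
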