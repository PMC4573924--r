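# Run-acceptance cutoffs from historical metric distributions, and
# characterization of the QC material over baseline runs.

#' Shapiro-Wilk normality test
#'
#' Normality gate used before deriving z-score cutoffs from a historical
#' metric sample. Wraps the Royston approximation in [stats::shapiro.test()]
#' behind the package's validation contract (3 <= n <= 5000, non-degenerate
#' sample).
#'
#' @param values Numeric sample.
#' @return A list with elements `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (n = ", n, ")", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p = unname(t$p.value))
}

.roundings <- c("none", "integer", "signif", "decimals")

.apply_rounding <- function(x, rounding, digits) {
  switch(rounding,
    none = x,
    integer = round(x),
    signif = signif(x, digits),
    decimals = round(x, digits))
}

#' Derive a run-acceptance cutoff from a metric distribution
#'
#' Computes a one-sided acceptance bound `mean -/+ z * sd` on the (optionally
#' log10-transformed) scale of a historical metric sample. When raw `values`
#' are supplied the sample must pass the Shapiro-Wilk gate (`p >= alpha`) on
#' the chosen scale; with `transform = "auto"` the identity scale is tried
#' first and log10 second (recorded in the rule), failing with a "no usable
#' transform" error if neither is acceptably normal. When summary statistics
#' (`mean`, `sd`) are supplied directly the gate is skipped and the
#' arithmetic contract alone applies. A log10 rule back-transforms the bound
#' (`10^bound_raw`) before rounding.
#'
#' `z` may be given explicitly (conventions for published cutoffs vary), or
#' derived from `confidence`: `z_mode = "two_sided"` uses
#' `qnorm(1 - (1 - conf)/2)`, `"one_sided"` uses `qnorm(conf)`.
#'
#' @param values Historical metric values (one per run or call), or `NULL`
#'   when `mean`/`sd` are given.
#' @param mean,sd Summary statistics on the `transform` scale (used when
#'   `values` is `NULL`).
#' @param metric Metric name recorded in the rule.
#' @param side `"lower"` (value must be >= bound) or `"upper"` (<=).
#' @param z Explicit z value (positive); overrides `confidence`.
#' @param confidence Confidence level in percent (e.g. 95).
#' @param z_mode How to turn `confidence` into `z` when `z` is `NULL`.
#' @param transform `"identity"`, `"log10"` or `"auto"` (raw values only).
#' @param rounding Reporting policy for the back-transformed bound:
#'   `"none"`, `"integer"`, `"signif"` or `"decimals"`.
#' @param digits Digits for `"signif"`/`"decimals"` rounding.
#' @param alpha Normality-gate significance level (default 0.05).
#' @return A list classed `"cutoff_rule"`; see [write_cutoff_json()] for the
#'   serialized shape and [evaluate_run()] for its use.
#' @examples
#' # lower coverage bound: 1231 - 1.96 * 526 = 200.04 -> 200
#' derive_cutoff(mean = 1231, sd = 526, metric = "coverage", side = "lower",
#'   z = 1.96, confidence = 95, rounding = "integer")
#' @export
derive_cutoff <- function(values = NULL, mean = NULL, sd = NULL,
                          metric = "metric", side = c("lower", "upper"),
                          z = NULL, confidence = NULL,
                          z_mode = c("two_sided", "one_sided"),
                          transform = c("identity", "log10", "auto"),
                          rounding = .roundings, digits = NA, alpha = 0.05) {
  side <- match.arg(side)
  transform <- match.arg(transform)
  rounding <- match.arg(rounding)
  z_mode <- match.arg(z_mode)
  if (is.null(z)) {
    if (is.null(confidence))
      stop("supply either z or confidence", call. = FALSE)
    p <- confidence / 100
    z <- if (z_mode == "two_sided") stats::qnorm(1 - (1 - p) / 2)
      else stats::qnorm(p)
  }
  if (z <= 0) stop("z must be positive", call. = FALSE)

  if (!is.null(values)) {
    if (transform == "log10" && any(values <= 0))
      stop("log10 transform requires strictly positive values", call. = FALSE)
    pick <- transform
    if (transform == "identity" || transform == "auto") {
      p_id <- shapiro_wilk(values)$p
      if (p_id >= alpha) {
        pick <- "identity"
      } else if (transform == "auto") {
        if (any(values <= 0))
          stop("no usable transform: non-normal and not positive for log10",
            call. = FALSE)
        if (shapiro_wilk(log10(values))$p >= alpha) pick <- "log10"
        else stop("no usable transform: normality rejected on both scales",
          call. = FALSE)
      } else {
        stop("normality rejected (Shapiro-Wilk p < ", alpha, ")",
          call. = FALSE)
      }
    } else {
      if (shapiro_wilk(log10(values))$p < alpha)
        stop("normality rejected on log10 scale (Shapiro-Wilk p < ", alpha,
          ")", call. = FALSE)
    }
    transform <- pick
    v <- if (transform == "log10") log10(values) else values
    mean <- base::mean(v)
    sd <- stats::sd(v)
  } else {
    if (is.null(mean) || is.null(sd))
      stop("supply raw values or both mean and sd", call. = FALSE)
    if (transform == "auto")
      stop("transform = \"auto\" needs raw values; state the scale of the ",
        "summary statistics", call. = FALSE)
  }

  bound_raw <- if (side == "lower") mean - z * sd else mean + z * sd
  back <- if (transform == "log10") 10^bound_raw else bound_raw
  structure(list(metric = metric, transform = transform, side = side,
    confidence = if (is.null(confidence)) NA_real_ else confidence,
    z = z, mean = mean, sd = sd, bound_raw = bound_raw,
    bound_reported = .apply_rounding(back, rounding, digits),
    rounding = rounding, digits = as.integer(digits)),
    class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("<cutoff> %s: %s bound %s (= %s %s %.4g * %.4g%s)\n",
    x$metric, x$side, format(x$bound_reported),
    format(x$mean), if (x$side == "lower") "-" else "+", x$z, x$sd,
    if (x$transform == "log10") ", log10 scale" else ""))
  invisible(x)
}

#' Collect cutoff rules
#'
#' @param rules A list of `"cutoff_rule"` objects (or several rules as
#'   separate arguments).
#' @return A list classed `"cutoff_rules"`.
#' @export
cutoff_rules <- function(rules) {
  if (inherits(rules, "cutoff_rule")) rules <- list(rules)
  stopifnot(all(vapply(rules, inherits, logical(1), "cutoff_rule")))
  names(rules) <- vapply(rules, `[[`, character(1), "metric")
  structure(rules, class = "cutoff_rules")
}

#' @export
print.cutoff_rules <- function(x, ...) {
  cat("<cutoff rules> ", length(x), " rule(s)\n", sep = "")
  for (r in x) print(r)
  invisible(x)
}

#' Evaluate a run against cutoff rules
#'
#' A lower rule passes iff the metric value is `>=` the reported bound, an
#' upper rule iff `<=`; bounds are inclusive (a value equal to its cutoff
#' passes). A metric absent from the input yields an explicit `MISSING`
#' verdict and fails the run.
#'
#' @param metrics A named list/vector of metric values, or a one-row
#'   [run_metrics()] table.
#' @param rules A `"cutoff_rules"` collection.
#' @return A data.frame classed `"run_evaluation"` (metric, value, side,
#'   bound, verdict) with attribute `overall` (`"PASS"`/`"FAIL"`) also
#'   exposed by `$overall` via [attr()].
#' @export
evaluate_run <- function(metrics, rules) {
  stopifnot(inherits(rules, "cutoff_rules"))
  if (is.data.frame(metrics)) {
    stopifnot(nrow(metrics) == 1L)
    metrics <- as.list(metrics)
  }
  metrics <- unlist(metrics[!vapply(metrics, is.character, logical(1))])
  rows <- lapply(rules, function(r) {
    val <- if (r$metric %in% names(metrics)) metrics[[r$metric]] else NA_real_
    verdict <- if (is.na(val)) "MISSING"
      else if (r$side == "lower" && val >= r$bound_reported) "PASS"
      else if (r$side == "upper" && val <= r$bound_reported) "PASS"
      else "FAIL"
    data.frame(metric = r$metric, value = val, side = r$side,
      bound = r$bound_reported, verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- if (all(out$verdict == "PASS")) "PASS" else "FAIL"
  class(out) <- c("run_evaluation", "data.frame")
  out
}

#' @export
print.run_evaluation <- function(x, ...) {
  print.data.frame(as.data.frame(x), row.names = FALSE, ...)
  cat("overall:", attr(x, "overall"), "\n")
  invisible(x)
}

#' Characterize the QC material over baseline runs
#'
#' Computes per-variant mean, sample SD (n-1 denominator), CV and the
#' Levey-Jennings +/-2SD and +/-3SD control limits from repeated sequencing
#' of a quality-control material. A run missing a call for any truth variant
#' is rejected from the baseline (reported in the `rejected_runs` attribute);
#' at least `n_min` usable runs are required.
#'
#' @param runs A list of `"vc_calls"` tables, one per baseline run.
#' @param truth A data.frame of truth variant keys (`chrom, pos, ref, alt`,
#'   plus `gene` if available) expected in the material.
#' @param n_min Minimum usable baseline runs (default 10 consecutive runs).
#' @return A data.frame classed `"qc_baseline"`: key columns plus `mean_pct`,
#'   `sd_pct`, `cv_pct`, `lower_2sd`, `upper_2sd`, `lower_3sd`, `upper_3sd`;
#'   attributes `n_runs` and `rejected_runs`.
#' @export
characterize_baseline <- function(runs, truth, n_min = 10) {
  truth <- as.data.frame(truth)
  tid <- variant_id(truth)
  usable <- logical(length(runs))
  obs <- matrix(NA_real_, nrow = length(tid), ncol = length(runs))
  for (j in seq_along(runs)) {
    cid <- variant_id(runs[[j]])
    hit <- match(tid, cid)
    usable[j] <- !anyNA(hit)
    if (usable[j]) obs[, j] <- runs[[j]]$observed_pct[hit]
  }
  if (sum(usable) < n_min)
    stop("insufficient baseline: ", sum(usable), " usable run(s), need ",
      n_min, call. = FALSE)
  obs <- obs[, usable, drop = FALSE]
  out <- truth[, intersect(c("chrom", "pos", "ref", "alt", "gene", "vtype"),
    names(truth)), drop = FALSE]
  out$mean_pct <- rowMeans(obs)
  out$sd_pct <- apply(obs, 1, stats::sd)
  out$cv_pct <- 100 * out$sd_pct / out$mean_pct
  out$lower_2sd <- out$mean_pct - 2 * out$sd_pct
  out$upper_2sd <- out$mean_pct + 2 * out$sd_pct
  out$lower_3sd <- out$mean_pct - 3 * out$sd_pct
  out$upper_3sd <- out$mean_pct + 3 * out$sd_pct
  rownames(out) <- NULL
  attr(out, "n_runs") <- sum(usable)
  attr(out, "rejected_runs") <- which(!usable)
  class(out) <- c("qc_baseline", "data.frame")
  out
}

#' Build a baseline from stated means and SDs
#'
#' Constructs a `"qc_baseline"` directly from per-variant means and standard
#' deviations (e.g. analytically derived limits, or previously published
#' characterization values) instead of estimating them from runs.
#'
#' @param truth Data.frame with key columns plus `mean_pct` and `sd_pct`.
#' @param n_runs Number of runs the statistics represent (metadata).
#' @return A `"qc_baseline"` table.
#' @export
qc_baseline <- function(truth, n_runs = NA_integer_) {
  stopifnot(all(c("mean_pct", "sd_pct") %in% names(truth)))
  out <- as.data.frame(truth)
  out$cv_pct <- 100 * out$sd_pct / out$mean_pct
  out$lower_2sd <- out$mean_pct - 2 * out$sd_pct
  out$upper_2sd <- out$mean_pct + 2 * out$sd_pct
  out$lower_3sd <- out$mean_pct - 3 * out$sd_pct
  out$upper_3sd <- out$mean_pct + 3 * out$sd_pct
  attr(out, "n_runs") <- n_runs
  attr(out, "rejected_runs") <- integer()
  class(out) <- c("qc_baseline", "data.frame")
  out
}

#' @export
print.qc_baseline <- function(x, ...) {
  cat("<QC baseline> ", nrow(x), " variant(s) over ", attr(x, "n_runs"),
    " run(s)\n", sep = "")
  df <- as.data.frame(x)
  num <- c("mean_pct", "sd_pct", "cv_pct")
  df[num] <- lapply(df[num], round, 2)
  print.data.frame(df[, c(intersect(c("gene", "chrom", "pos", "ref", "alt"),
    names(df)), num)], row.names = FALSE, ...)
  invisible(x)
}
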