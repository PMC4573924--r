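# Levey-Jennings monitoring of the QC material against its baseline.

.lj_status_of <- function(dev) {
  ifelse(abs(dev) <= 2, "IN_CONTROL",
    ifelse(abs(dev) <= 3, "WARNING_2SD", "REJECT_3SD"))
}

#' Evaluate one run of the QC material against its baseline
#'
#' For every baseline variant, the signed deviation
#' `(observed - mean) / sd` is banded: `|dev| <= 2` is `IN_CONTROL`,
#' `2 < |dev| <= 3` is `WARNING_2SD` (1_2s warning), `|dev| > 3` is
#' `REJECT_3SD` (1_3s rejection). A baseline variant absent from the run is
#' `MISSING_VARIANT` — the QC material's expected variants must be
#' consistently called for a run to be accepted. The run verdict is
#' `"reject"` iff any variant is `REJECT_3SD` or `MISSING_VARIANT`. A zero
#' baseline SD with a discrepant observation yields an infinite deviation
#' and `REJECT_3SD`.
#'
#' @param calls A `"vc_calls"` table for the monitored run.
#' @param baseline A `"qc_baseline"` (see [characterize_baseline()]).
#' @return A data.frame classed `"lj_status"`: key columns, `observed_pct`,
#'   `mean_pct`, `sd_pct`, `deviation_sd`, `status`; attribute `verdict`
#'   (`"accept"`/`"reject"`).
#' @export
lj_evaluate <- function(calls, baseline) {
  stopifnot(inherits(baseline, "qc_baseline"))
  bid <- variant_id(baseline)
  hit <- match(bid, variant_id(calls))
  obs <- calls$observed_pct[hit]
  dev <- ifelse(baseline$sd_pct > 0,
    (obs - baseline$mean_pct) / baseline$sd_pct,
    ifelse(obs == baseline$mean_pct, 0, Inf * sign(obs - baseline$mean_pct)))
  status <- .lj_status_of(dev)
  status[is.na(hit)] <- "MISSING_VARIANT"
  dev[is.na(hit)] <- NA_real_
  out <- as.data.frame(baseline)[, intersect(c("chrom", "pos", "ref", "alt",
    "gene", "vtype", "mean_pct", "sd_pct"), names(baseline))]
  out$observed_pct <- obs
  out$deviation_sd <- dev
  out$status <- status
  rownames(out) <- NULL
  attr(out, "verdict") <- if (any(status %in% c("REJECT_3SD",
    "MISSING_VARIANT"))) "reject" else "accept"
  class(out) <- c("lj_status", "data.frame")
  out
}

#' @export
print.lj_status <- function(x, ...) {
  df <- as.data.frame(x)
  num <- c("mean_pct", "sd_pct", "observed_pct", "deviation_sd")
  df[num] <- lapply(df[num], round, 2)
  print.data.frame(df, row.names = FALSE, ...)
  cat("run verdict:", attr(x, "verdict"), "\n")
  invisible(x)
}

#' Levey-Jennings chart table over a run history
#'
#' Stacks per-run evaluations into one chart table (per run per variant:
#' observed, baseline mean, 2SD and 3SD limits, deviation, status) and
#' optionally applies Westgard multi-rules as advisory flags:
#' `2_2s` — two consecutive runs beyond the same 2SD limit for a variant;
#' `R_4s` — consecutive deviations spanning more than 4 SD.
#'
#' @param history A list of `"lj_status"` evaluations in run order, or a list
#'   of `"vc_calls"` tables if `baseline` is supplied.
#' @param baseline Optional `"qc_baseline"` used to evaluate raw call sets.
#' @param westgard Character subset of `c("2_2s", "R_4s")` to enable.
#' @param run_ids Optional run labels (default `run1, run2, ...`).
#' @return A data.frame classed `"lj_series"` with columns `run_index`,
#'   `run_id`, key columns, `observed_pct`, `mean_pct`, `sd_pct`,
#'   `lower_2sd`, `upper_2sd`, `lower_3sd`, `upper_3sd`, `deviation_sd`,
#'   `status`, `flag_2_2s`, `flag_R_4s`.
#' @export
lj_series <- function(history, baseline = NULL,
                      westgard = character(), run_ids = NULL) {
  if (!length(history)) stop("empty run history", call. = FALSE)
  bad <- setdiff(westgard, c("2_2s", "R_4s"))
  if (length(bad))
    stop("unknown Westgard rule(s): ", paste(bad, collapse = ", "),
      call. = FALSE)
  if (!is.null(baseline))
    history <- lapply(history, lj_evaluate, baseline = baseline)
  stopifnot(all(vapply(history, inherits, logical(1), "lj_status")))
  if (is.null(run_ids)) run_ids <- paste0("run", seq_along(history))
  rows <- lapply(seq_along(history), function(i) {
    df <- as.data.frame(history[[i]])
    df$lower_2sd <- df$mean_pct - 2 * df$sd_pct
    df$upper_2sd <- df$mean_pct + 2 * df$sd_pct
    df$lower_3sd <- df$mean_pct - 3 * df$sd_pct
    df$upper_3sd <- df$mean_pct + 3 * df$sd_pct
    cbind(run_index = i, run_id = run_ids[i], df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag_2_2s <- FALSE
  out$flag_R_4s <- FALSE
  vids <- variant_id(out)
  for (v in unique(vids)) {
    idx <- which(vids == v)
    idx <- idx[order(out$run_index[idx])]
    d <- out$deviation_sd[idx]
    if ("2_2s" %in% westgard && length(idx) > 1) {
      prev <- d[-length(d)]; cur <- d[-1]
      hit <- (prev > 2 & cur > 2) | (prev < -2 & cur < -2)
      out$flag_2_2s[idx[-1][which(hit)]] <- TRUE
    }
    if ("R_4s" %in% westgard && length(idx) > 1) {
      hit <- abs(diff(d)) > 4
      out$flag_R_4s[idx[-1][which(hit)]] <- TRUE
    }
  }
  rownames(out) <- NULL
  class(out) <- c("lj_series", "data.frame")
  out
}

#' Plot a Levey-Jennings control chart
#'
#' One panel per variant (or a selected variant): observed frequency per run
#' with the baseline mean (solid), 2SD limits (dashed) and 3SD limits
#' (solid outer lines); rejected points are highlighted.
#'
#' @param x An `"lj_series"` table.
#' @param variant Optional `chrom:pos:ref:alt` id to plot a single variant.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lj_series <- function(x, variant = NULL, ...) {
  vids <- variant_id(x)
  pick <- if (is.null(variant)) unique(vids)[1] else variant
  df <- x[vids == pick, ]
  if (!nrow(df)) stop("variant not in series: ", pick, call. = FALSE)
  ylim <- range(c(df$observed_pct, df$lower_3sd, df$upper_3sd), na.rm = TRUE)
  lab <- if ("gene" %in% names(df))
    paste0(df$gene[1], " ", df$chrom[1], ":", df$pos[1]) else pick
  graphics::plot(df$run_index, df$observed_pct, type = "b", pch = 16,
    xlab = "run", ylab = "VAF (%)", ylim = ylim,
    main = paste("Levey-Jennings:", lab), ...)
  graphics::abline(h = df$mean_pct[1], lty = 1)
  graphics::abline(h = c(df$lower_2sd[1], df$upper_2sd[1]), lty = 2)
  graphics::abline(h = c(df$lower_3sd[1], df$upper_3sd[1]), lty = 1,
    col = "red3")
  bad <- df$status == "REJECT_3SD"
  if (any(bad, na.rm = TRUE))
    graphics::points(df$run_index[bad], df$observed_pct[bad], pch = 4,
      col = "red3", cex = 1.4)
  invisible(x)
}
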