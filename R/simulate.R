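# Seeded simulator for cell-line profiles, sequencing runs, dilution series
# and drift scenarios. The read-count mechanism is binomial: at each locus a
# depth is drawn from the depth model and alternate reads follow
# Binomial(depth, VAF adjusted by the per-read error rate), so observed
# frequencies scatter around truth with SD 100*sqrt(p(1-p)/depth).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulator configuration
#'
#' Defaults emulate a hotspot amplicon assay on a benchtop semiconductor
#' sequencer. The `"frozen"` preset targets a mean per-locus coverage of
#' 2000 reads (fresh-frozen libraries), the `"ffpe"` preset 1300 reads plus
#' low-frequency C:G>T:A deamination artifacts at 1-3 percent VAF —
#' deliberately below a 4 percent detection policy. Depth spread (lognormal,
#' CV 0.3) and artifact rates are modelling choices, not measured values.
#' Per-call quality is lognormal (log10 mean 3.65, SD 0.45) and strand bias
#' Gaussian (mean 0.7, SD 0.04) truncated to `[0.5, 1]`, matching historical
#' run-metric summaries. All randomness flows from `seed`; helpers derive
#' per-run sub-seeds from it, so identical configs reproduce runs exactly.
#'
#' @param seed Integer seed (mandatory for any stochastic output).
#' @param preset `"frozen"` or `"ffpe"`.
#' @param depth_mean,depth_cv,depth_dist Depth model (lognormal or
#'   negative binomial with the same mean/CV).
#' @param base_error_rate Per-read error rate folded into the binomial
#'   success probability.
#' @param ffpe_ct_rate Probability an artifact appears at each susceptible
#'   site per run.
#' @param artifact_vaf_range Percent VAF interval for injected artifacts.
#' @param n_artifact_sites Number of susceptible C>T sites in the panel.
#' @param quality_log10_mean,quality_log10_sd,strand_bias_mean,strand_bias_sd
#'   Per-call metric model.
#' @param metrics_model Named list of `c(mean, sd)` pairs for run-level
#'   metrics.
#' @param n_replicates Replicates per dilution level.
#' @return A list classed `"simulator_config"`.
#' @export
simulator_config <- function(seed, preset = c("frozen", "ffpe"),
    depth_mean = NULL, depth_cv = 0.3,
    depth_dist = c("lognormal", "negative_binomial"),
    base_error_rate = 0, ffpe_ct_rate = NULL,
    artifact_vaf_range = c(1, 3), n_artifact_sites = 50,
    quality_log10_mean = 3.65, quality_log10_sd = 0.45,
    strand_bias_mean = 0.7, strand_bias_sd = 0.04,
    metrics_model = list(q20_bases = c(2.5e7, 2.4e6),
      reads_on_target_pct = c(95.13, 2.33),
      uniformity_pct = c(98.26, 0.68)),
    n_replicates = 10) {
  preset <- match.arg(preset)
  depth_dist <- match.arg(depth_dist)
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory", call. = FALSE)
  if (is.null(depth_mean))
    depth_mean <- if (preset == "frozen") 2000 else 1300
  if (is.null(ffpe_ct_rate))
    ffpe_ct_rate <- if (preset == "frozen") 0 else 0.02
  stopifnot(depth_mean > 0, depth_cv >= 0,
    base_error_rate >= 0, base_error_rate <= 1,
    ffpe_ct_rate >= 0, ffpe_ct_rate <= 1)
  structure(list(seed = as.integer(seed), preset = preset,
    depth_mean = depth_mean, depth_cv = depth_cv, depth_dist = depth_dist,
    base_error_rate = base_error_rate, ffpe_ct_rate = ffpe_ct_rate,
    artifact_vaf_range = artifact_vaf_range,
    n_artifact_sites = as.integer(n_artifact_sites),
    quality_log10_mean = quality_log10_mean,
    quality_log10_sd = quality_log10_sd,
    strand_bias_mean = strand_bias_mean, strand_bias_sd = strand_bias_sd,
    metrics_model = metrics_model, n_replicates = as.integer(n_replicates)),
    class = "simulator_config")
}

.draw_depth <- function(n, config) {
  m <- config$depth_mean; cv <- config$depth_cv
  if (cv == 0) return(rep(as.integer(round(m)), n))
  if (config$depth_dist == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(m) - sdlog^2 / 2
    as.integer(round(stats::rlnorm(n, meanlog, sdlog)))
  } else {
    size <- 1 / cv^2  # NB with mean m and CV ~ cv for large m
    as.integer(stats::rnbinom(n, size = size, mu = m))
  }
}

# fixed panel of deamination-susceptible sites, a pure function of the count
.artifact_sites <- function(n) {
  data.frame(chrom = paste0("chr", 1 + (seq_len(n) - 1) %% 22),
    pos = 5000000L + 137L * seq_len(n), ref = "C", alt = "T",
    gene = "FFPE_ARTIFACT", stringsAsFactors = FALSE)
}

#' Simulate one sequencing run of a known truth profile
#'
#' Draws a depth per truth locus, binomial alternate-read counts at the
#' expected VAF (adjusted by the base error rate), per-call quality and
#' strand bias, and run-level metrics. Every truth locus yields a call row;
#' a locus whose drawn depth is 0 is emitted as a zero-depth call with
#' filter `NO_DEPTH`. Under the FFPE preset, C:G>T:A artifact calls are
#' injected at susceptible sites with the configured probability and VAF
#' range.
#'
#' @param truth An `"expected_profile"`.
#' @param config A [simulator_config()].
#' @param seed Seed for this run (defaults to `config$seed`).
#' @param run_id Run label.
#' @return A list classed `"simulated_run"`: `calls` (`"vc_calls"`),
#'   `metrics` ([run_metrics()]), `truth`, `config`, `seed`.
#' @export
simulate_run <- function(truth, config, seed = config$seed,
                         run_id = "sim_run") {
  stopifnot(inherits(config, "simulator_config"))
  if (!nrow(truth)) stop("truth profile is empty", call. = FALSE)
  .with_seed(seed, {
    n <- nrow(truth)
    d <- .draw_depth(n, config)
    p <- truth$expected_pct / 100
    e <- config$base_error_rate
    p_eff <- p * (1 - e) + (1 - p) * e / 3
    a <- ifelse(d > 0, stats::rbinom(n, d, p_eff), 0L)
    obs <- ifelse(d > 0, 100 * a / d, 0)
    qual <- 10^stats::rnorm(n, config$quality_log10_mean,
      config$quality_log10_sd)
    sb <- pmin(1, pmax(0.5, stats::rnorm(n, config$strand_bias_mean,
      config$strand_bias_sd)))
    calls <- data.frame(sample_id = run_id, chrom = truth$chrom,
      pos = truth$pos, ref = truth$ref, alt = truth$alt, gene = truth$gene,
      observed_pct = obs, depth = d, alt_depth = as.integer(a),
      quality = qual, strand_bias = sb,
      filters = ifelse(d > 0, "", "NO_DEPTH"), stringsAsFactors = FALSE)
    if (config$ffpe_ct_rate > 0 && config$n_artifact_sites > 0) {
      sites <- .artifact_sites(config$n_artifact_sites)
      on <- stats::runif(nrow(sites)) < config$ffpe_ct_rate
      if (any(on)) {
        sites <- sites[on, , drop = FALSE]
        da <- .draw_depth(nrow(sites), config)
        vaf <- stats::runif(nrow(sites), config$artifact_vaf_range[1],
          config$artifact_vaf_range[2])
        aa <- ifelse(da > 0, stats::rbinom(nrow(sites), da, vaf / 100), 0L)
        art <- data.frame(sample_id = run_id, chrom = sites$chrom,
          pos = sites$pos, ref = sites$ref, alt = sites$alt,
          gene = sites$gene,
          observed_pct = ifelse(da > 0, 100 * aa / da, 0), depth = da,
          alt_depth = as.integer(aa),
          quality = 10^stats::rnorm(nrow(sites), config$quality_log10_mean,
            config$quality_log10_sd),
          strand_bias = pmin(1, pmax(0.5, stats::rnorm(nrow(sites),
            config$strand_bias_mean, config$strand_bias_sd))),
          filters = ifelse(da > 0, "", "NO_DEPTH"),
          stringsAsFactors = FALSE)
        art <- art[art$alt_depth > 0, , drop = FALSE]
        if (nrow(art)) calls <- rbind(calls, art)
      }
    }
    mm <- config$metrics_model
    metrics <- run_metrics(run_id, mean_depth = mean(d),
      q20_bases = max(0, stats::rnorm(1, mm$q20_bases[1], mm$q20_bases[2])),
      reads_on_target_pct = min(100, max(0, stats::rnorm(1,
        mm$reads_on_target_pct[1], mm$reads_on_target_pct[2]))),
      uniformity_pct = min(100, max(0, stats::rnorm(1,
        mm$uniformity_pct[1], mm$uniformity_pct[2]))))
    structure(list(calls = variant_calls(calls), metrics = metrics,
      truth = truth, config = config, seed = seed),
      class = "simulated_run")
  })
}

# reproducible sub-seeds for n runs
.sub_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate several runs of the same truth
#'
#' @inheritParams simulate_run
#' @param n Number of runs; each uses a sub-seed derived from `seed`.
#' @param run_prefix Run label prefix.
#' @return List of `"simulated_run"` objects.
#' @export
simulate_runs <- function(truth, config, n, seed = config$seed,
                          run_prefix = "run") {
  seeds <- .sub_seeds(seed, n)
  lapply(seq_len(n), function(i)
    simulate_run(truth, config, seed = seeds[i],
      run_id = paste0(run_prefix, i)))
}

#' Simulate synthetic cell-line profiles
#'
#' Generates `n_lines` characterized lines over `n_loci` collision-free
#' synthetic loci. Each line carries each locus with probability
#' `present_rate`; carried frequencies are sampled from `freq_spectrum`
#' (e.g. `c(50, 100)` for het/hom clonal variants, or any custom list), and
#' a fraction `hom_deletion_rate` of line-locus pairs is marked as a
#' homozygous deletion instead.
#'
#' @param seed Integer seed.
#' @param n_lines,n_loci Problem size (both >= 1).
#' @param freq_spectrum Numeric vector of percent frequencies to sample
#'   from.
#' @param present_rate Probability a line carries a given locus.
#' @param hom_deletion_rate Probability a carried locus is a homozygous
#'   deletion.
#' @return A `"line_profiles"` table.
#' @export
simulate_profiles <- function(seed, n_lines, n_loci,
                              freq_spectrum = c(50, 100),
                              present_rate = 0.4, hom_deletion_rate = 0) {
  stopifnot(n_lines >= 1, n_loci >= 1, length(freq_spectrum) >= 1)
  .with_seed(seed, {
    pos <- sort(sample.int(2e8L, n_loci))  # without collision
    loci <- data.frame(chrom = paste0("chr", 1 + (seq_len(n_loci) - 1) %% 22),
      pos = pos, ref = sample(c("A", "C", "G", "T"), n_loci, replace = TRUE),
      gene = sprintf("GENE%03d", seq_len(n_loci)), stringsAsFactors = FALSE)
    loci$alt <- vapply(loci$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    rows <- list()
    for (li in seq_len(n_lines)) {
      carry <- stats::runif(n_loci) < present_rate
      if (!any(carry)) carry[sample.int(n_loci, 1)] <- TRUE
      idx <- which(carry)
      del <- stats::runif(length(idx)) < hom_deletion_rate
      rows[[li]] <- data.frame(line = sprintf("LINE%02d", li),
        loci[idx, c("chrom", "pos", "ref", "alt", "gene")],
        freq_pct = ifelse(del, NA_real_, freq_spectrum[sample.int(
          length(freq_spectrum), length(idx), replace = TRUE)]),
        copy_state = ifelse(del, "hom_deletion", "normal"),
        stringsAsFactors = FALSE)
    }
    line_profiles(do.call(rbind, rows))
  })
}

#' Simulate a replicate dilution series
#'
#' Computes the truth per level through the mixture model (a level with
#' fraction `f` is the mixture expectation serially diluted by `f` into the
#' diluent; `f = 1` is the undiluted mixture), then simulates
#' `config$n_replicates` runs per level.
#'
#' @param profiles A `"line_profiles"` table.
#' @param mix A [mixture_spec()].
#' @param diluent A single-line `"line_profiles"` table, or `NULL` to skip
#'   dilution (all fractions must then be 1).
#' @param fractions Numeric vector of mix fractions in `(0, 1]`.
#' @param config A [simulator_config()].
#' @return A list classed `"dilution_series"`; one element per level with
#'   `fraction`, `truth` and `replicates`, directly consumable by
#'   [detection_rate()].
#' @export
simulate_dilution_series <- function(profiles, mix, diluent, fractions,
                                     config) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  base <- mixture_profile(profiles, mix)
  seeds <- .sub_seeds(config$seed, length(fractions))
  out <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    truth <- if (f == 1 || is.null(diluent)) base
      else serial_dilute(base, diluent, f)
    reps <- simulate_runs(truth, config, config$n_replicates,
      seed = seeds[i], run_prefix = sprintf("level%g_rep", f))
    list(fraction = f, truth = truth,
      replicates = lapply(reps, `[[`, "calls"))
  })
  class(out) <- c("dilution_series", class(out))
  out
}

#' Simulate a monitored run history with an injected mean shift
#'
#' Runs before `from_run` follow the baseline truth; from `from_run` onward
#' every variant's true mean is shifted by `shift_sd` times its binomial
#' sampling SD at the nominal depth (`100*sqrt(p(1-p)/depth_mean)`), the
#' canonical stress input for control-chart changepoint checks.
#'
#' @param baseline_truth An `"expected_profile"`.
#' @param shift_sd Shift size in per-variant SD units (can be 0 or
#'   negative).
#' @param from_run First shifted run index (`<= n_runs`).
#' @param n_runs Number of runs to simulate.
#' @param config A [simulator_config()].
#' @return List of `"simulated_run"` objects (empty when `n_runs = 0`).
#' @export
inject_drift <- function(baseline_truth, shift_sd, from_run, n_runs,
                         config) {
  if (n_runs > 0 && from_run > n_runs)
    stop("from_run must be <= n_runs", call. = FALSE)
  if (n_runs == 0) return(list())
  p <- baseline_truth$expected_pct / 100
  sd_pct <- 100 * sqrt(p * (1 - p) / config$depth_mean)
  shifted <- baseline_truth
  shifted$expected_pct <- pmin(100, pmax(0,
    baseline_truth$expected_pct + shift_sd * sd_pct))
  seeds <- .sub_seeds(config$seed, n_runs)
  lapply(seq_len(n_runs), function(i)
    simulate_run(if (i >= from_run) shifted else baseline_truth, config,
      seed = seeds[i], run_id = paste0("run", i)))
}
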