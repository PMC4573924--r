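# Readers/writers for the plain-text formats the pipeline touches.
# Frequencies are converted to percent at the boundary (VCF AF fractions);
# BED 0-based half-open coordinates are kept for amplicons, variant positions
# are 1-based throughout.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = c(".", "NA"),
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = "#")
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    v <- df[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant calls from VCF or TSV
#'
#' Reads one sample's calls into a [variant_calls()] table. The TSV dialect is
#' tab-delimited with a header row and `.` for missing values; required
#' columns are `chrom, pos, ref, alt, gene, observed_pct, depth`. The VCF
#' dialect accepts a VCF 4.2 subset whose records carry allele frequency
#' (`AF`, as a fraction) and depth (`DP`) in INFO; `AO` (alt reads), `GENE`
#' and `SBIAS` are used when present, `QUAL` becomes the call quality.
#' Multi-allelic records are split into one call per ALT allele.
#'
#' @param path File to read.
#' @param dialect `"auto"` (by file extension), `"tsv"` or `"vcf"`.
#' @param sample_id Sample label attached to each call; defaults to the file
#'   name without extension.
#' @return A `"vc_calls"` table (possibly empty, with a warning for an empty
#'   file).
#' @export
read_calls <- function(path, dialect = c("auto", "tsv", "vcf"),
                       sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  if (dialect == "tsv") .read_calls_tsv(path, sample_id)
  else .read_calls_vcf(path, sample_id)
}

.empty_calls <- function() {
  variant_calls(data.frame(chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    observed_pct = numeric(), depth = integer()))
}

.read_calls_tsv <- function(path, sample_id) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) {
    warning("no call records in ", path, call. = FALSE)
    return(.empty_calls())
  }
  need <- c("chrom", "pos", "ref", "alt", "gene", "observed_pct", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": TSV call dialect requires columns ",
      paste(miss, collapse = ", "), call. = FALSE)
  num <- function(v) suppressWarnings(as.numeric(v))
  bad <- which(is.na(num(df$pos)) | is.na(num(df$observed_pct)) |
    is.na(num(df$depth)))
  if (length(bad))
    stop(path, ": malformed record at data line ", bad[1], call. = FALSE)
  df$pos <- num(df$pos); df$observed_pct <- num(df$observed_pct)
  df$depth <- num(df$depth)
  if (!"sample_id" %in% names(df)) df$sample_id <- sample_id
  variant_calls(df)
}

.read_calls_vcf <- function(path, sample_id) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop(path, ": VCF parse error: ", conditionMessage(e),
      call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warning("no call records in ", path, call. = FALSE)
    return(.empty_calls())
  }
  info_get <- function(field) vcfR::extract.info(vcf, element = field)
  af <- info_get("AF"); dp <- info_get("DP")
  if (all(is.na(af)) || all(is.na(dp)))
    stop(path, ": VCF dialect requires AF and DP INFO fields", call. = FALSE)
  ao <- info_get("AO"); gene <- info_get("GENE"); sb <- info_get("SBIAS")
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]])
    aos <- if (!is.na(ao[i]))
      as.integer(strsplit(ao[i], ",", fixed = TRUE)[[1]]) else
      rep(NA_integer_, length(alts))
    if (length(afs) != length(alts) || anyNA(afs))
      stop(path, ": record ", i, " (", fix$CHROM[i], ":", fix$POS[i],
        ") has malformed AF", call. = FALSE)
    rows[[i]] <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      gene = if (!is.na(gene[i])) gene[i] else NA_character_,
      observed_pct = 100 * afs, depth = as.integer(dp[i]),
      alt_depth = rep_len(aos, length(alts)),
      quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      strand_bias = if (!is.na(sb[i])) as.numeric(sb[i]) else NA_real_,
      filters = ifelse(is.na(fix$FILTER[i]) | fix$FILTER[i] %in% c("PASS", "."),
        "", fix$FILTER[i]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$sample_id <- sample_id
  variant_calls(df)
}

#' Write variant calls to TSV
#'
#' Inverse of the TSV dialect of [read_calls()]: tab-delimited, header row,
#' `.` for missing values.
#'
#' @param calls A `"vc_calls"` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  .write_tsv(as.data.frame(calls), path)
}

#' Write variant calls to a VCF 4.2 subset
#'
#' One record per call with `AF` (fraction), `DP`, `AO`, `GENE` and `SBIAS`
#' INFO fields; `QUAL` carries the call quality. Readable by
#' [read_calls()] and by standard VCF tooling.
#'
#' @param calls A `"vc_calls"` table (one sample).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alt observation count\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SBIAS,Number=1,Type=Float,Description=\"Max per-strand alt proportion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AF=%s;DP=%d", format(calls$observed_pct / 100,
    digits = 12, scientific = FALSE, trim = TRUE), calls$depth)
  has_ao <- !is.na(calls$alt_depth)
  info[has_ao] <- paste0(info[has_ao], ";AO=", calls$alt_depth[has_ao])
  info <- paste0(info, ";GENE=", calls$gene)
  has_sb <- !is.na(calls$strand_bias)
  info[has_sb] <- paste0(info[has_sb], ";SBIAS=", calls$strand_bias[has_sb])
  qual <- ifelse(is.na(calls$quality), ".",
    format(calls$quality, digits = 12, trim = TRUE, scientific = FALSE))
  filt <- ifelse(is.na(calls$filters) | calls$filters == "", "PASS",
    calls$filters)
  body <- if (nrow(calls)) sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
    calls$chrom, calls$pos, calls$ref, calls$alt, qual, filt, info) else
    character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-line genotype profiles
#'
#' Reads a tab-delimited table of characterized cell-line (or diluent)
#' genotypes with columns `line, chrom, pos, ref, alt, gene, freq_pct,
#' copy_state`. `copy_state` is `normal` or `hom_deletion`; a homozygously
#' deleted locus contributes no DNA templates and must not carry a frequency.
#' Loci absent from a line's rows are taken as frequency 0 at normal copy
#' state, which is how mixture expectations treat wild-type components.
#'
#' @param path TSV file.
#' @return A data.frame classed `"line_profiles"`.
#' @seealso [mixture_profile()], [validation_profiles()]
#' @export
read_line_profiles <- function(path) {
  df <- .read_tsv(path)
  need <- c("line", "chrom", "pos", "ref", "alt", "gene", "freq_pct",
    "copy_state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": line profile table requires columns ",
      paste(miss, collapse = ", "), call. = FALSE)
  line_profiles(df)
}

#' @rdname read_line_profiles
#' @param df A data.frame with the columns listed above.
#' @export
line_profiles <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$copy_state[is.na(df$copy_state)] <- "normal"
  bad <- !df$copy_state %in% c("normal", "hom_deletion")
  if (any(bad))
    stop("unknown copy_state token(s): ",
      paste(unique(df$copy_state[bad]), collapse = ", "), call. = FALSE)
  del <- df$copy_state == "hom_deletion"
  if (any(del & !is.na(df$freq_pct)))
    stop("hom_deletion entries must not carry a frequency (no templates): ",
      paste(variant_id(df)[del & !is.na(df$freq_pct)], collapse = ", "),
      call. = FALSE)
  if (any(!del & (is.na(df$freq_pct) | df$freq_pct < 0 | df$freq_pct > 100)))
    stop("freq_pct must lie in [0, 100]", call. = FALSE)
  key <- paste(df$line, variant_id(df))
  if (anyDuplicated(key))
    stop("duplicate locus within a line: ",
      paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  kk <- variant_key(df$chrom, df$pos, df$ref, df$alt, df$gene,
    if ("vtype" %in% names(df)) df$vtype else NULL)
  out <- cbind(line = as.character(df$line), kk,
    freq_pct = as.numeric(df$freq_pct),
    copy_state = df$copy_state, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("line_profiles", "data.frame")
  out
}

#' Read amplicon target regions from BED
#'
#' BED input is 0-based half-open; that convention is preserved in the
#' returned table (`start`, `end`), and [read_amplicons()] /
#' [write_amplicons()] are exact inverses. Track and browser lines are
#' skipped; output is sorted within chromosome. Overlapping amplicons are
#' permitted and preserved.
#'
#' @param path BED file (3+ columns).
#' @return A data.frame classed `"amplicons"` with columns
#'   `chrom, start, end, name`.
#' @export
read_amplicons <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
    error = function(e) stop(path, ": BED validation error: ",
      conditionMessage(e), call. = FALSE))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("AMPL", seq_along(gr)), stringsAsFactors = FALSE)
  amplicons(df)
}

#' @rdname read_amplicons
#' @param df A data.frame with `chrom, start, end` (0-based half-open) and
#'   optional `name`.
#' @export
amplicons <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) df$name <- paste0("AMPL", seq_len(nrow(df)))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 0L) || any(df$start >= df$end))
    stop("amplicon intervals must satisfy 0 <= start < end", call. = FALSE)
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end", "name")]
  rownames(df) <- NULL
  class(df) <- c("amplicons", "data.frame")
  df
}

#' @rdname read_amplicons
#' @param amp An `"amplicons"` table.
#' @export
write_amplicons <- function(amp, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", amp$chrom, amp$start, amp$end,
    amp$name), path)
  invisible(path)
}

#' Write and read run-acceptance cutoff rules as JSON
#'
#' Serializes a [cutoff_rules()] collection to a JSON list of objects with a
#' stable key order (`metric, transform, side, confidence, z, mean, sd,
#' bound_raw, bound_reported, rounding, digits`), matching the JSON parameter
#' files consumed by variant-caller plugins. `read_cutoff_json()` is the
#' exact inverse.
#'
#' @param rules A `"cutoff_rules"` collection (see [derive_cutoff()]).
#' @param path JSON file path.
#' @return `write_cutoff_json()` returns `path` invisibly;
#'   `read_cutoff_json()` returns the rules.
#' @export
write_cutoff_json <- function(rules, path) {
  stopifnot(inherits(rules, "cutoff_rules"))
  lst <- lapply(rules, function(r)
    r[c("metric", "transform", "side", "confidence", "z", "mean", "sd",
        "bound_raw", "bound_reported", "rounding", "digits")])
  if (!dir.exists(dirname(path)))
    stop("cannot write ", path, ": directory does not exist", call. = FALSE)
  writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null", na = "null"), path)
  invisible(path)
}

#' @rdname write_cutoff_json
#' @export
read_cutoff_json <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(lst, function(r) {
    r$digits <- if (is.null(r$digits)) NA_integer_ else as.integer(r$digits)
    num <- c("confidence", "z", "mean", "sd", "bound_raw", "bound_reported")
    for (f in num) r[[f]] <- if (is.null(r[[f]])) NA_real_ else
      as.numeric(r[[f]])
    structure(r, class = "cutoff_rule")
  })
  cutoff_rules(rules)
}
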