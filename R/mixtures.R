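# Expected allele frequencies for DNA mixtures of characterized cell lines.
#
# Model: components are mixed by DNA mass fraction w_i. At a locus, component
# i contributes templates in proportion to w_i * c_i, where the copy weight
# c_i is 1 for a copy-neutral locus and 0 for a homozygous deletion (the line
# contributes no DNA there). If the component's variant allele frequency at
# the locus is f_i (percent), the expected mixture VAF is
#
#   E[f] = sum_i w_i * c_i * f_i / sum_i w_i * c_i .
#
# With all copy states normal this is the w-weighted mean of the f_i; with a
# single template-contributing component it collapses to that component's own
# frequency regardless of the weights.

#' Define a mixture of characterized DNA components
#'
#' @param lines Character vector of component (cell line) names; must be
#'   unique.
#' @param fractions DNA mass fractions in `(0, 1]`, summing to 1 (tolerance
#'   1e-9). Defaults to an equal split.
#' @return A data.frame classed `"mixture_spec"` with columns `line`,
#'   `fraction`.
#' @examples
#' mixture_spec(c("HCT116", "MIA-PaCa-2", "H1975", "SK-MEL-28"))
#' @export
mixture_spec <- function(lines, fractions = NULL) {
  lines <- as.character(lines)
  if (anyDuplicated(lines))
    stop("component names must be unique", call. = FALSE)
  if (is.null(fractions)) fractions <- rep(1 / length(lines), length(lines))
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(lines))
    stop("one fraction per component required", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  out <- data.frame(line = lines, fraction = fractions,
    stringsAsFactors = FALSE)
  class(out) <- c("mixture_spec", "data.frame")
  out
}

# per-component frequency and copy weight at each locus of the union
.mix_matrix <- function(profiles, lines) {
  miss <- setdiff(lines, unique(profiles$line))
  if (length(miss))
    stop("no profile for component(s): ", paste(miss, collapse = ", "),
      call. = FALSE)
  sub <- profiles[profiles$line %in% lines, , drop = FALSE]
  ids <- unique(variant_id(sub))
  keys <- sub[!duplicated(variant_id(sub)),
    c("chrom", "pos", "ref", "alt", "gene", "vtype")]
  rownames(keys) <- NULL
  f <- matrix(0, nrow = length(ids), ncol = length(lines),
    dimnames = list(ids, lines))
  cw <- matrix(1, nrow = length(ids), ncol = length(lines),
    dimnames = list(ids, lines))
  sid <- variant_id(sub)
  for (i in seq_len(nrow(sub))) {
    if (sub$copy_state[i] == "hom_deletion") {
      cw[sid[i], sub$line[i]] <- 0
    } else {
      f[sid[i], sub$line[i]] <- sub$freq_pct[i]
    }
  }
  list(keys = keys, f = f, cw = cw)
}

#' Expected VAF of one locus in a mixture
#'
#' Computes `sum(w * c * f) / sum(w * c)` for a single variant, where `w` are
#' the DNA mass fractions, `c` the copy weights (0 for a homozygous deletion,
#' 1 otherwise) and `f` the per-component frequencies (a component without a
#' profile row at the locus is wild type: `f = 0`, `c = 1`).
#'
#' @param profiles A `"line_profiles"` table covering every mixture component.
#' @param mix A [mixture_spec()].
#' @param key A one-row variant key ([variant_key()]) naming the locus.
#' @return Expected VAF in percent (full precision; see [round_pct()] for the
#'   1-decimal reporting convention).
#' @examples
#' pr <- line_profiles(data.frame(line = "A", chrom = "chr9", pos = 133738370,
#'   ref = "A", alt = "G", gene = "ABL1", freq_pct = 52.4,
#'   copy_state = "normal"))
#' mx <- mixture_spec(c("A", "B", "C", "D"))
#' expected_vaf(pr, mx, variant_key("chr9", 133738370, "A", "G", "ABL1"))
#' @export
expected_vaf <- function(profiles, mix, key) {
  stopifnot(inherits(mix, "mixture_spec"), nrow(key) == 1L)
  mm <- .mix_matrix(profiles, mix$line)
  id <- variant_id(key)
  if (!id %in% rownames(mm$f)) {
    # locus unseen in any component: wild type everywhere
    return(0)
  }
  w <- mix$fraction
  num <- sum(w * mm$cw[id, mix$line] * mm$f[id, mix$line])
  den <- sum(w * mm$cw[id, mix$line])
  if (den <= 0)
    stop("no template at locus ", id,
      ": every component is homozygously deleted", call. = FALSE)
  num / den
}

#' Expected VAF profile of a mixture
#'
#' Applies the mixture expectation to the union of loci across the named
#' components. Loci where every template-contributing component is wild type
#' are emitted with expectation 0 rather than dropped, so downstream
#' detection scoring sees the full locus set.
#'
#' @inheritParams expected_vaf
#' @return A data.frame classed `"expected_profile"` with the variant key
#'   columns plus `expected_pct` (full precision).
#' @export
mixture_profile <- function(profiles, mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  mm <- .mix_matrix(profiles, mix$line)
  w <- mix$fraction
  num <- as.vector(((mm$cw * mm$f)[, mix$line, drop = FALSE]) %*% w)
  den <- as.vector((mm$cw[, mix$line, drop = FALSE]) %*% w)
  if (any(den <= 0))
    stop("no template at locus ",
      paste(rownames(mm$f)[den <= 0], collapse = ", "),
      ": every component is homozygously deleted", call. = FALSE)
  out <- mm$keys
  out$expected_pct <- num / den
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  class(out) <- c("expected_profile", "data.frame")
  out
}

#' @rdname mixture_profile
#' @param df A data.frame with variant key columns and `expected_pct`.
#' @export
expected_profile <- function(df) {
  kk <- variant_key(df$chrom, df$pos, df$ref, df$alt, df$gene,
    if ("vtype" %in% names(df)) df$vtype else NULL)
  kk$expected_pct <- as.numeric(df$expected_pct)
  if (any(kk$expected_pct < 0 | kk$expected_pct > 100, na.rm = TRUE))
    stop("expected_pct must lie in [0, 100]", call. = FALSE)
  class(kk) <- c("expected_profile", "data.frame")
  kk
}

#' Serially dilute an expected profile into a diluent
#'
#' Models dilution of a DNA mixture into a characterized diluent (e.g. normal
#' placental DNA): the result equals a two-component mixture with the profile
#' at weight `mix_fraction` and the diluent at `1 - mix_fraction`. A "1:k"
#' dilution corresponds to `mix_fraction = 1/k`. Loci private to the diluent
#' (its germline variants) enter the union and are diluted toward the
#' diluent's frequency; homozygous deletions in the diluent remove its
#' template contribution at those loci.
#'
#' @param profile An `"expected_profile"` (the mix being diluted, treated as
#'   copy-neutral).
#' @param diluent A `"line_profiles"` table with a single line (the diluent).
#' @param mix_fraction Final mass fraction of the mix in `(0, 1]`.
#' @return An `"expected_profile"` over the union of loci.
#' @export
serial_dilute <- function(profile, diluent, mix_fraction) {
  if (!is.numeric(mix_fraction) || length(mix_fraction) != 1L ||
      is.na(mix_fraction) || mix_fraction <= 0 || mix_fraction > 1)
    stop("mix_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot(inherits(profile, "expected_profile"))
  dl <- unique(diluent$line)
  if (length(dl) != 1L)
    stop("diluent must be a single line profile", call. = FALSE)
  if (mix_fraction == 1) return(profile)
  # express the mix as a pseudo-line and reuse the mixture formula
  pseudo <- data.frame(line = ".mix", chrom = profile$chrom,
    pos = profile$pos, ref = profile$ref, alt = profile$alt,
    gene = profile$gene, vtype = profile$vtype,
    freq_pct = profile$expected_pct, copy_state = "normal",
    stringsAsFactors = FALSE)
  dil <- as.data.frame(diluent)[, names(pseudo)]
  combined <- line_profiles(rbind(pseudo, dil))
  mixture_profile(combined,
    mixture_spec(c(".mix", dl), c(mix_fraction, 1 - mix_fraction)))
}

#' Round percentages for reporting
#'
#' Expected and observed frequencies are computed at full precision and
#' reported to one decimal using round-half-to-even (base [round()]), the
#' package-wide reporting convention.
#'
#' @param x Numeric percentages.
#' @param digits Decimals to keep (default 1).
#' @return Rounded values.
#' @export
round_pct <- function(x, digits = 1L) round(x, digits)

#' @export
print.expected_profile <- function(x, ...) {
  cat("<expected VAF profile> ", nrow(x), " locus/loci\n", sep = "")
  df <- as.data.frame(x)
  df$expected_pct <- round_pct(df$expected_pct)
  print.data.frame(utils::head(df, 12), ...)
  if (nrow(df) > 12) cat("... and", nrow(df) - 12, "more rows\n")
  invisible(x)
}
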