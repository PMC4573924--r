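# Recurrent-artifact annotation: high-MAF germline SNPs, amplicon-edge
# errors and homopolymer-associated errors, plus blacklist application.

#' Flag recurrent artifact classes on calls
#'
#' Applies three independent predicates per call; a call may carry 0-3
#' classes, and omitting an annotation source disables only its class:
#'
#' * `HIGH_MAF_SNP` — the variant's global minor allele frequency (from
#'   `maf`) is `>= maf_threshold` (default 0.01, the common-SNP convention).
#' * `END_OF_AMPLICON` — the distance from the position to the nearest
#'   boundary of every overlapping amplicon is `<= edge_bp` (default 5);
#'   a position covered by no amplicon is annotated `OFF_TARGET` instead.
#' * `HOMOPOLYMER` — the position lies within or immediately adjacent to a
#'   reference run of one base of length `>= hp_len` (default 4), scanned in
#'   the supplied reference context.
#'
#' @param calls A `"vc_calls"` table.
#' @param contexts Optional data.frame with `chrom, pos, context`: reference
#'   bases centered on `pos` (odd length, e.g. +/-10).
#' @param amp Optional `"amplicons"` table.
#' @param maf Optional data.frame with `chrom, pos, ref, alt, maf` global
#'   minor allele frequencies.
#' @param maf_threshold,edge_bp,hp_len Rule parameters (see above).
#' @return A data.frame: one row per (call, class) with columns `chrom, pos,
#'   ref, alt, gene, class, evidence`; zero rows when nothing is flagged.
#' @export
flag_artifacts <- function(calls, contexts = NULL, amp = NULL, maf = NULL,
                           maf_threshold = 0.01, edge_bp = 5, hp_len = 4) {
  out <- list()
  add <- function(i, class, evidence) {
    out[[length(out) + 1L]] <<- data.frame(chrom = calls$chrom[i],
      pos = calls$pos[i], ref = calls$ref[i], alt = calls$alt[i],
      gene = calls$gene[i], class = class, evidence = evidence,
      stringsAsFactors = FALSE)
  }
  mid <- if (!is.null(maf)) variant_id(maf) else character()
  for (i in seq_len(nrow(calls))) {
    if (!is.null(maf)) {
      j <- match(variant_id(calls[i, ]), mid)
      if (!is.na(j) && maf$maf[j] >= maf_threshold)
        add(i, "HIGH_MAF_SNP", sprintf("MAF %.4f >= %.4f", maf$maf[j],
          maf_threshold))
    }
    if (!is.null(amp)) {
      cover <- amp$chrom == calls$chrom[i] & amp$start < calls$pos[i] &
        calls$pos[i] <= amp$end  # amplicon is 0-based half-open
      if (!any(cover)) {
        add(i, "OFF_TARGET", "position covered by no amplicon")
      } else {
        # distance to nearest boundary, per covering amplicon (1-based pos)
        dist <- pmin(calls$pos[i] - (amp$start[cover] + 1L),
          amp$end[cover] - calls$pos[i])
        if (all(dist <= edge_bp))
          add(i, "END_OF_AMPLICON", sprintf("<= %d bp from amplicon edge (min %d)",
            edge_bp, min(dist)))
      }
    }
    if (!is.null(contexts)) {
      k <- which(contexts$chrom == calls$chrom[i] &
        contexts$pos == calls$pos[i])
      if (length(k)) {
        run <- .hp_run_at_center(contexts$context[k[1]])
        if (run >= hp_len)
          add(i, "HOMOPOLYMER", sprintf("reference run length %d >= %d",
            run, hp_len))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      class = character(), evidence = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# longest single-base run touching (within or immediately adjacent to) the
# center position of an odd-length context string
.hp_run_at_center <- function(context) {
  bases <- strsplit(toupper(context), "")[[1]]
  n <- length(bases)
  center <- (n + 1L) %/% 2L
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # runs overlapping [center-1, center+1]
  touch <- starts <= center + 1L & ends >= center - 1L
  if (!any(touch)) return(0L)
  max(r$lengths[touch])
}

#' Apply a variant blacklist to calls
#'
#' Flags calls whose exact variant key (chrom, pos, ref, alt) appears in the
#' blacklist by appending `BLACKLIST:<class>` to their `filters`; a call
#' matching on position but with a different allele is not flagged. Flagged
#' calls retain all data; `reportable()` returns the view with flagged calls
#' removed, mirroring pipelines that exclude recurrent artifacts from the
#' final report.
#'
#' @param calls A `"vc_calls"` table.
#' @param blacklist Data.frame with `chrom, pos, ref, alt` and optional
#'   `class`.
#' @return `calls` with updated `filters`.
#' @export
apply_blacklist <- function(calls, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(calls)
  bl <- as.data.frame(blacklist)
  if (!"class" %in% names(bl)) bl$class <- "ARTIFACT"
  hit <- match(variant_id(calls), variant_id(bl))
  flag <- !is.na(hit)
  tag <- paste0("BLACKLIST:", bl$class[hit[flag]])
  calls$filters[flag] <- ifelse(calls$filters[flag] == "", tag,
    paste(calls$filters[flag], tag, sep = ";"))
  calls
}

#' @rdname apply_blacklist
#' @export
reportable <- function(calls) {
  calls[!grepl("BLACKLIST:", calls$filters), , drop = FALSE]
}
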