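# Classification of CGIs by position relative to transcripts and active
# promoters, and methylation-state calling from percent-methylation values.
#
# Rules (all windows 0-based half-open, built with interval arithmetic):
#  * promoter_associated: the CGI overlaps the 1 kbp region around the TSS of
#    a stranded transcript by at least 1 bp.
#  * intragenic: the CGI lies within a stranded transcript, at least 1 kbp
#    distant from the TSS (operationalised as full containment in the
#    transcript without overlapping the TSS window).
#  * distal_intragenic: the CGI overlaps the 1 kbp region immediately
#    downstream of the transcript end.
#  * end_associated: the CGI overlaps the 1 kbp region around either end of a
#    transcript whose strand is unknown.
# promoter_associated or end_associated combined with any other label makes
# the classification ambiguous; intragenic and distal_intragenic are
# compatible and collapse to the final class "intragenic_like".

TSS_WINDOW <- 1000L

transcript_tss_tes <- function(tr) {
  # TSS/TES as 0-based positions; NA when the strand is unknown
  tss <- ifelse(tr$strand == "+", tr$start,
                ifelse(tr$strand == "-", tr$end - 1L, NA_integer_))
  tes <- ifelse(tr$strand == "+", tr$end - 1L,
                ifelse(tr$strand == "-", tr$start, NA_integer_))
  cbind(tss = tss, tes = tes)
}

labels_for_cgi <- function(chrom, start, end, tr, w = TSS_WINDOW) {
  labels <- character(0)
  body_overlap_only <- FALSE
  same <- tr$chrom == chrom
  if (!any(same)) return(list(labels = labels, any_overlap = FALSE,
                              boundary_overlap = FALSE))
  tr <- tr[same, , drop = FALSE]
  pos <- transcript_tss_tes(tr)
  any_overlap <- FALSE
  for (i in seq_len(nrow(tr))) {
    got <- character(0)
    if (tr$strand[i] %in% c("+", "-")) {
      tss <- pos[i, "tss"]; tes <- pos[i, "tes"]
      tss_win <- c(tss - w, tss + w)                  # TSS +/- 1 kbp
      down_win <- if (tr$strand[i] == "+") c(tes + 1L, tes + 1L + w) else
        c(tes - w, tes)                               # 1 kbp downstream of TES
      if (max(start, tss_win[1]) < min(end, tss_win[2]))
        got <- c(got, "promoter_associated")
      if (start >= tr$start[i] && end <= tr$end[i] &&
          !(max(start, tss_win[1]) < min(end, tss_win[2])))
        got <- c(got, "intragenic")
      if (max(start, down_win[1]) < min(end, down_win[2]))
        got <- c(got, "distal_intragenic")
    } else {
      s_win <- c(tr$start[i] - w, tr$start[i] + w)
      e_win <- c(tr$end[i] - w, tr$end[i] + w)
      if (max(start, s_win[1]) < min(end, s_win[2]) ||
          max(start, e_win[1]) < min(end, e_win[2]))
        got <- c(got, "end_associated")
    }
    overlaps_body <- max(start, tr$start[i]) < min(end, tr$end[i])
    if (overlaps_body || length(got)) any_overlap <- TRUE
    if (overlaps_body && !length(got)) body_overlap_only <- TRUE
    labels <- c(labels, got)
  }
  list(labels = unique(labels), any_overlap = any_overlap,
       boundary_overlap = body_overlap_only)
}

final_class_of <- function(labels, any_overlap) {
  if (!length(labels))
    return("transcript_free")
  exclusive <- intersect(labels, c("promoter_associated", "end_associated"))
  if (length(exclusive) && length(labels) > 1L) return("ambiguous")
  if (identical(labels, "promoter_associated")) return("promoter_associated")
  if (identical(labels, "end_associated")) return("end_associated")
  "intragenic_like"  # subset of {intragenic, distal_intragenic}
}

#' Classify CGIs relative to transcripts
#'
#' Applies the four location rules (see the package vignette) to every CGI,
#' accumulating labels over all transcripts. A CGI whose labels mix
#' promoter_associated or end_associated with any other label is `ambiguous`;
#' `intragenic` and `distal_intragenic` collapse to `intragenic_like`; a CGI
#' overlapping no transcript at all is `transcript_free`. A CGI that overlaps
#' a transcript body without triggering any rule keeps its class from the
#' remaining labels and is flagged `boundary_overlap`.
#'
#' @param cgis data.frame with `chrom`, `start`, `end` and optionally `name`
#'   (0-based half-open, e.g. from [read_bed()]).
#' @param transcripts data.frame with `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"`, or `"*"` for unknown).
#' @return data.frame with `cgi_id`, `labels` (comma-joined), `final_class`,
#'   `boundary_overlap`.
#' @export
classify_cgis <- function(cgis, transcripts) {
  if (!all(c("chrom", "start", "end") %in% names(cgis)))
    stop("cgis must have chrom/start/end", call. = FALSE)
  if (nrow(transcripts) && !all(transcripts$strand %in% c("+", "-", "*")))
    stop("transcript strand must be '+', '-' or '*'", call. = FALSE)
  ids <- if ("name" %in% names(cgis)) cgis$name else
    paste0(cgis$chrom, ":", cgis$start, "-", cgis$end)
  out <- lapply(seq_len(nrow(cgis)), function(i) {
    lab <- labels_for_cgi(cgis$chrom[i], cgis$start[i], cgis$end[i], transcripts)
    data.frame(cgi_id = ids[i],
               labels = paste(sort(lab$labels), collapse = ","),
               final_class = final_class_of(lab$labels, lab$any_overlap),
               boundary_overlap = lab$boundary_overlap)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_intervals <- function(df) {
  # union of intervals, merging overlapping or abutting ones, per chromosome
  if (!nrow(df)) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    j <- nrow(out)
    if (df$chrom[i] == out$chrom[j] && df$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else out <- rbind(out, df[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Define active promoters from transcripts, unmethylated CGIs and H3K4me3
#'
#' The TSS +/- 1 kbp window of a stranded transcript is an active promoter if
#' it overlaps an unmethylated CGI and a region of H3K4me3 enrichment.
#' Overlapping or abutting promoter windows are merged.
#'
#' @param transcripts data.frame with `chrom`, `start`, `end`, `strand`
#'   (must be `"+"` or `"-"`).
#' @param unmeth_cgis data.frame of unmethylated CGI intervals.
#' @param h3k4me3 data.frame of H3K4me3-enriched intervals.
#' @return data.frame of merged promoter intervals (`chrom`, `start`, `end`).
#' @export
define_promoters <- function(transcripts, unmeth_cgis, h3k4me3) {
  tr <- transcripts[transcripts$strand %in% c("+", "-"), , drop = FALSE]
  if (!nrow(tr)) return(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)))
  pos <- transcript_tss_tes(tr)
  win <- data.frame(chrom = tr$chrom,
                    start = pmax(pos[, "tss"] - TSS_WINDOW, 0L),
                    end = pos[, "tss"] + TSS_WINDOW)
  hits_any <- function(w, set) {
    any(interval_overlaps(w$chrom, w$start, w$end, set$chrom, set$start, set$end))
  }
  keep <- vapply(seq_len(nrow(win)), function(i) {
    hits_any(win[i, ], unmeth_cgis) && hits_any(win[i, ], h3k4me3)
  }, logical(1))
  merge_intervals(win[keep, , drop = FALSE])
}

#' Call methylation state from percent methylation
#'
#' `no_call` when fewer than `min_cpgs` CpGs were assayed; otherwise
#' `unmethylated` below `low` percent, `methylated` above `high` percent,
#' `intermediate` in between. Defaults follow the usual RRBS thresholds
#' (<20% / >80% median per-CpG methylation, more than 5 assayed CpGs).
#'
#' @param percent percent methylation in `[0, 100]` (vectorised).
#' @param n_cpgs_assayed number of assayed CpGs per CGI.
#' @param low,high percent thresholds (defaults 20 and 80; `low < high`).
#' @param min_cpgs minimum assayed CpGs for a call (default 6).
#' @return character vector over `{unmethylated, methylated, intermediate,
#'   no_call}`.
#' @export
call_methylation_state <- function(percent, n_cpgs_assayed,
                                   low = 20, high = 80, min_cpgs = 6L) {
  stopifnot(low < high)
  if (any(percent < 0 | percent > 100, na.rm = TRUE))
    stop("percent methylation must be within [0, 100]", call. = FALSE)
  state <- ifelse(percent < low, "unmethylated",
                  ifelse(percent > high, "methylated", "intermediate"))
  state[n_cpgs_assayed < min_cpgs] <- "no_call"
  state
}

#' Cross-tabulate CGI class against methylation state
#'
#' Ambiguous CGIs are excluded. Percentages are per class (rows sum to 100).
#'
#' @param classified data.frame with `final_class` and `meth_state` columns.
#' @return list with `counts` (class x state table) and `percent`.
#' @export
class_state_crosstab <- function(classified) {
  keep <- classified[classified$final_class != "ambiguous", , drop = FALSE]
  if (!nrow(keep))
    return(list(counts = table(character(0), character(0)),
                percent = table(character(0), character(0))))
  counts <- table(class = keep$final_class, state = keep$meth_state)
  percent <- counts
  rs <- rowSums(counts)
  for (i in seq_len(nrow(counts)))
    percent[i, ] <- if (rs[i] > 0) 100 * counts[i, ] / rs[i] else 0
  list(counts = counts, percent = percent)
}
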