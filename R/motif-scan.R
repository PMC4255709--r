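# IUPAC motif occurrence scanning and presence/density/relative-density
# statistics, with a dinucleotide-shuffle control and a local-CpG-density
# control. Matching is done with Biostrings, with ambiguity codes interpreted
# in the pattern only, so an N in the subject sequence never matches any
# motif letter. Overlapping occurrences are all counted.

# overlapping match offsets (0-based) of one pattern on the forward residues;
# literal ACGT patterns take a perl lookahead fast path, degenerate IUPAC
# patterns go through Biostrings with ambiguities interpreted in the pattern
# only (subject N never matches either way)
match_offsets <- function(seq, pattern) {
  if (!grepl("[^ACGT]", pattern)) {
    m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(integer(0))
    return(as.integer(m) - 1L)
  }
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                   fixed = "subject")
  Biostrings::start(hits) - 1L
}

scan_one <- function(seq, motif, strands) {
  off_f <- match_offsets(seq, motif)
  out <- data.frame(offset = off_f, strand = rep("+", length(off_f)))
  if (strands == "both") {
    rc <- revcomp(motif)
    off_r <- if (motif == rc) integer(0) else  # palindromes: one hit per site
      match_offsets(seq, rc)
    out <- rbind(out, data.frame(offset = off_r,
                                 strand = rep("-", length(off_r))))
  }
  out[order(out$offset), , drop = FALSE]
}

#' Scan sequences for IUPAC motif occurrences
#'
#' @param seqs named character vector of DNA sequences.
#' @param motif IUPAC pattern (e.g. `"TGCCGC"`, `"MCGCGCS"`).
#' @param strands `"both"` (default; forward pattern plus its reverse
#'   complement, both reported in forward coordinates) or `"forward"`.
#' @return data.frame with `seq_id`, `offset` (0-based), `strand`.
#' @export
scan_motif <- function(seqs, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  motif <- assert_iupac(motif)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  res <- lapply(names(seqs), function(id) {
    occ <- scan_one(seqs[[id]], motif, strands)
    if (nrow(occ)) cbind(seq_id = id, occ) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0))
  rownames(res) <- NULL
  res
}

#' Per-sequence motif occurrence counts
#'
#' @inheritParams scan_motif
#' @return data.frame with `seq_id`, `length`, `count` (both strands).
#' @export
per_sequence_counts <- function(seqs, motif, strands = "both") {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  occ <- scan_motif(seqs, motif, strands)
  counts <- table(factor(occ$seq_id, levels = names(seqs)))
  data.frame(seq_id = names(seqs), length = nchar(seqs),
             count = as.integer(counts), row.names = NULL)
}

#' Percentage of sequences containing a motif
#'
#' @inheritParams scan_motif
#' @return percentage (0-100) of sequences with at least one occurrence on
#'   either strand.
#' @export
presence_fraction <- function(seqs, motif) {
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  100 * mean(per_sequence_counts(seqs, motif)$count > 0)
}

#' Motif density statistics for a category of sequences
#'
#' Density is pooled: `1000 * total occurrences / total bp` (not the mean of
#' per-sequence densities). `relative_density = density / background_density`
#' when a background is supplied, either directly as occurrences per kbp or as
#' a background sequence set scanned with the same motif.
#'
#' @inheritParams scan_motif
#' @param background_density background occurrences per 1 kbp (optional).
#' @param background_seqs background sequence set from which to compute the
#'   background density (optional, overrides `background_density`).
#' @param category label stored in the result.
#' @return one-row data.frame: `category`, `n_seqs`, `presence_fraction`,
#'   `density`, `relative_density` (NA when no background, flagged NA when
#'   the background density is zero).
#' @export
motif_stats <- function(seqs, motif, background_density = NULL,
                        background_seqs = NULL, category = "all") {
  if (sum(nchar(seqs)) == 0) stop("total sequence length is zero", call. = FALSE)
  counts <- per_sequence_counts(seqs, motif)
  dens <- 1000 * sum(counts$count) / sum(counts$length)
  if (!is.null(background_seqs)) {
    bg <- per_sequence_counts(background_seqs, motif)
    background_density <- 1000 * sum(bg$count) / sum(bg$length)
  }
  rel <- NA_real_
  if (!is.null(background_density)) {
    if (background_density == 0) {
      warning("background density is zero; relative density undefined")
    } else rel <- dens / background_density
  }
  data.frame(category = category, n_seqs = length(seqs),
             presence_fraction = 100 * mean(counts$count > 0),
             density = dens, relative_density = rel)
}

#' Reduction in motif occurrences under dinucleotide-preserving shuffling
#'
#' Each sequence is shuffled (preserving its dinucleotide multiset) and the
#' motif re-scanned. If occurrences only reflect global dinucleotide (CpG)
#' composition, shuffling leaves them unchanged; a large reduction means the
#' occurrences are not explained by composition. One shuffle per sequence by
#' default; `replicates > 1` averages the shuffled totals over R shuffles.
#'
#' @inheritParams scan_motif
#' @param seed integer master seed.
#' @param replicates shuffles per sequence to average over (default 1).
#' @return list: `occurrence_reduction_pct` (100 x (1 - shuffled/original)),
#'   `density_change_pct` (change in mean per-sequence density),
#'   `zero_before`/`zero_after` (sequences without any occurrence), `defined`.
#' @export
shuffle_reduction <- function(seqs, motif, seed, replicates = 1L) {
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  orig <- per_sequence_counts(seqs, motif)
  shuf_counts <- matrix(0, nrow = length(seqs), ncol = replicates)
  for (r in seq_len(replicates)) {
    shuffled <- vapply(seq_along(seqs), function(i) {
      dinuc_shuffle(seqs[[i]], derive_seed(seed, i), stream = r)
    }, character(1))
    names(shuffled) <- names(seqs)
    shuf_counts[, r] <- per_sequence_counts(shuffled, motif)$count
  }
  shuf_mean <- rowMeans(shuf_counts)
  total_orig <- sum(orig$count)
  dens_orig <- mean(1000 * orig$count / orig$length)
  dens_shuf <- mean(1000 * shuf_mean / orig$length)
  list(
    occurrence_reduction_pct = if (total_orig == 0) NA_real_ else
      100 * (1 - sum(shuf_mean) / total_orig),
    density_change_pct = if (dens_orig == 0) NA_real_ else
      100 * (dens_shuf - dens_orig) / dens_orig,
    zero_before = sum(orig$count == 0),
    zero_after = sum(shuf_counts[, 1] == 0),
    defined = total_orig > 0
  )
}

window_cpg_bins <- function(seqs, occ, counts_len, window) {
  # CpG count of the window centred on each occurrence, clipped to the sequence
  vapply(seq_len(nrow(occ)), function(i) {
    s <- seqs[[occ$seq_id[i]]]
    centre <- occ$offset[i] + counts_len %/% 2L
    lo <- max(centre - window %/% 2L, 0L)
    hi <- min(lo + window, nchar(s))
    length(cpg_positions(substr(s, lo + 1L, hi)))
  }, numeric(1))
}

#' Fraction of motif occurrences attributable to local CpG density
#'
#' Occurrences are binned by the CpG count of the window centred on them, for
#' the real sequences and for dinucleotide-preserving shuffled counterparts.
#' The explained fraction is the overlap of the two binned distributions:
#' `100 * sum_bin min(real_bin, shuffled_bin) / sum_bin real_bin`. If
#' occurrences merely track locally CpG-dense stretches, the shuffled
#' counterparts reproduce them bin-for-bin and the explained fraction is
#' near 100%.
#'
#' @inheritParams shuffle_reduction
#' @param window window size in bp (default 100; must be >= motif length).
#' @return list: `explained_pct`, `real_bins`, `shuffled_bins`, `defined`.
#' @export
local_density_control <- function(seqs, motif, window = 100L, seed) {
  motif <- assert_iupac(motif)
  if (window < nchar(motif)) stop("window must be >= motif length", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  occ_real <- scan_motif(seqs, motif)
  shuffled <- vapply(seq_along(seqs), function(i) {
    dinuc_shuffle(seqs[[i]], derive_seed(seed, i))
  }, character(1))
  names(shuffled) <- names(seqs)
  occ_shuf <- scan_motif(shuffled, motif)
  if (nrow(occ_real) == 0L)
    return(list(explained_pct = NA_real_, real_bins = table(integer(0)),
                shuffled_bins = table(integer(0)), defined = FALSE))
  bins_real <- window_cpg_bins(seqs, occ_real, nchar(motif), window)
  bins_shuf <- if (nrow(occ_shuf)) window_cpg_bins(shuffled, occ_shuf,
                                                   nchar(motif), window) else numeric(0)
  lev <- 0:max(c(bins_real, bins_shuf, 0))
  tr <- table(factor(bins_real, levels = lev))
  ts <- table(factor(bins_shuf, levels = lev))
  list(explained_pct = 100 * sum(pmin(tr, ts)) / sum(tr),
       real_bins = tr, shuffled_bins = ts, defined = TRUE)
}
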