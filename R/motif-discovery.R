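# Simplified discriminative ab initio motif search and the
# "characteristic motif" extreme-outlier criterion.
#
# Deliberately simpler than a full regular-expression beam search: candidate
# motifs are the exact words of length k_min..k_max present in at least one
# positive sequence (either strand), each scored by a one-sided Fisher test
# on the 2x2 presence table (positives vs negatives) and an E-value equal to
# p times the number of candidates evaluated (the multiple-testing analogue
# of the E-value of occurrence-based searches). Downstream inference only
# uses ranks and order-of-magnitude gaps between E-values, which this
# presence-based statistic supports.

canonical_word <- function(words) {
  rc <- vapply(words, revcomp, character(1))
  ifelse(words <= rc, words, rc)
}

# canonical k-mer set present in one sequence (either strand). The k-mers of
# the reverse complement, read back-to-front, are the reverse complements of
# the forward k-mers, so one reverse-complement call per sequence suffices.
seq_kmer_presence <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1), k:n)
  rcs <- revcomp(seq)
  rc_aligned <- substring(rcs, 1:(n - k + 1), k:n)[(n - k + 1):1]
  canon <- ifelse(fwd <= rc_aligned, fwd, rc_aligned)
  unique(canon[!grepl("N", fwd, fixed = TRUE)])
}

presence_counts <- function(seqs, k) {
  tab <- table(unlist(lapply(seqs, seq_kmer_presence, k = k)))
  stats::setNames(as.integer(tab), names(tab))
}

#' One-sided Fisher presence test
#'
#' Exact one-sided (enrichment) p-value for the 2x2 table
#' `[[a, b], [c, d]]` = `[[pos_present, pos_absent], [neg_present,
#' neg_absent]]`: the upper tail of the hypergeometric distribution of `a`
#' given the margins. The odds ratio is the cross-product `(a d)/(b c)`,
#' infinite when `b c = 0`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with `p` and `odds_ratio`.
#' @export
fisher_presence_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (a + b + c + d == 0) stop("all-zero contingency table", call. = FALSE)
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p = p, odds_ratio = or)
}

generalize_word <- function(word, pos_seqs, neg_seqs, n_candidates) {
  # greedy single-position IUPAC degeneration of the top word, kept only while
  # the E-value improves
  score <- function(pat) {
    pp <- sum(per_sequence_counts(pos_seqs, pat)$count > 0)
    np <- sum(per_sequence_counts(neg_seqs, pat)$count > 0)
    p <- fisher_presence_test(pp, length(pos_seqs) - pp,
                              np, length(neg_seqs) - np)$p
    list(p = p, E = p * n_candidates, pos_present = pp, neg_present = np)
  }
  best <- list(pattern = word, fit = score(word))
  two_codes <- c("R", "Y", "S", "W", "K", "M")
  repeat {
    improved <- FALSE
    chars <- strsplit(best$pattern, "")[[1]]
    for (i in seq_along(chars)) {
      if (!chars[i] %in% DNA_BASES) next
      for (code in two_codes) {
        if (!chars[i] %in% IUPAC_SETS[[code]]) next
        cand <- chars; cand[i] <- code
        cand <- paste(cand, collapse = "")
        fit <- score(cand)
        if (fit$E < best$fit$E) {
          best <- list(pattern = cand, fit = fit)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

#' Discriminative exact-word motif search
#'
#' Enumerates every word of length `k_min..k_max` present in at least one
#' positive sequence (word and reverse complement collapsed to one canonical
#' candidate), scores each by [fisher_presence_test()] on presence in
#' positives versus negatives, and reports candidates with
#' `E = p * n_candidates` below `e_threshold`, ranked by E then
#' lexicographically.
#'
#' @param pos_seqs,neg_seqs named character vectors of DNA sequences.
#' @param k_min,k_max word lengths searched (3 <= k_min <= k_max <= 10).
#' @param e_threshold report motifs with E below this (default 0.05).
#' @param generalize if `TRUE`, greedily degenerate the top word one IUPAC
#'   position at a time while the E-value improves (off by default).
#' @return object of class `discovery_report`: `results` (data.frame with
#'   `motif`, `pos_present`, `pos_total`, `neg_present`, `neg_total`, `p`,
#'   `E`, `rank`), `n_candidates`, `characteristic` (filled by
#'   [characteristic_motif()]), `generalized` (optional).
#' @export
discriminative_search <- function(pos_seqs, neg_seqs, k_min = 4L, k_max = 8L,
                                  e_threshold = 0.05, generalize = FALSE) {
  stopifnot(length(pos_seqs) > 0, length(neg_seqs) > 0,
            k_min >= 3L, k_max >= k_min, k_max <= 10L)
  pos_n <- length(pos_seqs); neg_n <- length(neg_seqs)
  rows <- list()
  n_candidates <- 0L
  for (k in k_min:k_max) {
    pos_counts <- presence_counts(pos_seqs, k)
    if (!length(pos_counts)) next
    neg_counts <- presence_counts(neg_seqs, k)
    n_candidates <- n_candidates + length(pos_counts)
    np <- ifelse(names(pos_counts) %in% names(neg_counts),
                 neg_counts[names(pos_counts)], 0L)
    p <- stats::phyper(pos_counts - 1, pos_counts + np,
                       (pos_n - pos_counts) + (neg_n - np),
                       pos_n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      motif = names(pos_counts), pos_present = as.integer(pos_counts),
      pos_total = pos_n, neg_present = as.integer(np), neg_total = neg_n,
      p = as.numeric(p), row.names = NULL)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), pos_present = integer(0),
               pos_total = integer(0), neg_present = integer(0),
               neg_total = integer(0), p = numeric(0))
  res$rc <- vapply(res$motif, revcomp, character(1))
  res$E <- res$p * n_candidates
  res <- res[order(res$E, res$motif), , drop = FALSE]
  res <- res[res$E < e_threshold, , drop = FALSE]
  if (nrow(res)) res$rank <- seq_len(nrow(res))
  else res$rank <- integer(0)
  rownames(res) <- NULL
  report <- structure(list(results = res, n_candidates = n_candidates,
                           e_threshold = e_threshold, characteristic = NULL),
                      class = "discovery_report")
  if (generalize && nrow(res))
    report$generalized <- generalize_word(res$motif[1], pos_seqs, neg_seqs,
                                          n_candidates)
  report$characteristic <- characteristic_motif(report)
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("Discriminative motif search:", x$n_candidates, "candidate words,",
      nrow(x$results), "reported at E <", x$e_threshold, "\n")
  if (nrow(x$results)) print(utils::head(x$results, 10))
  if (!is.null(x$characteristic))
    cat("characteristic motif:", x$characteristic$motif,
        sprintf("(E = %.3g)\n", x$characteristic$E))
  else cat("characteristic motif: none\n")
  invisible(x)
}

is_distinct_motif <- function(candidate, top) {
  # distinct = not a substring/superstring of the top motif or of its RC
  top_rc <- revcomp(top)
  !(grepl(candidate, top, fixed = TRUE) || grepl(top, candidate, fixed = TRUE) ||
      grepl(candidate, top_rc, fixed = TRUE) || grepl(top_rc, candidate, fixed = TRUE))
}

#' Characteristic-motif criterion
#'
#' The top-ranked motif is *characteristic* of the positive set iff it is
#' significant (`E < e_threshold`) and an extreme outlier: the next most
#' significant *distinct* motif (not a substring or superstring of the top
#' motif or of its reverse complement) has an E-value at least `gap_orders`
#' orders of magnitude larger. With no second distinct motif the gap is
#' infinite and the (significant) top motif is characteristic by convention.
#'
#' @param report a `discovery_report`.
#' @param e_threshold significance threshold on E (default 0.05).
#' @param gap_orders required gap in log10(E) (default 5).
#' @return one-row data.frame for the characteristic motif (with
#'   `gap_orders` achieved), or `NULL` if none qualifies.
#' @export
characteristic_motif <- function(report, e_threshold = 0.05, gap_orders = 5) {
  res <- report$results
  if (!nrow(res)) return(NULL)
  top <- res[1, , drop = FALSE]
  if (!(top$E < e_threshold)) return(NULL)
  distinct <- which(vapply(res$motif[-1], is_distinct_motif, logical(1),
                           top = top$motif)) + 1L
  gap <- if (length(distinct)) log10(res$E[distinct[1]]) - log10(top$E) else Inf
  if (is.na(gap)) gap <- Inf  # top E numerically zero
  if (gap >= gap_orders) {
    top$gap_orders <- gap
    top
  } else NULL
}
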