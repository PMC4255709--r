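# Dinucleotide-frequency-invariant shuffling and generic empirical-null
# machinery for per-sequence statistics.

#' Dinucleotide-preserving sequence shuffle
#'
#' Produces a permutation of `seq` with exactly the same multiset of
#' overlapping dinucleotides (hence the same length, mononucleotide counts and
#' first/last residue), sampled uniformly over the valid Eulerian arrangements
#' by the Altschul-Erickson construction (random last-edge arborescence plus
#' random ordering of the remaining edges). A naive swap-based shuffle does
#' not sample this set uniformly and is deliberately not offered.
#'
#' @param seq a single DNA sequence (character scalar).
#' @param seed integer seed; the same `(seq, seed, stream)` always yields the
#'   same output.
#' @param stream RNG stream index, used to draw several independent shuffles
#'   from one master seed.
#' @return shuffled sequence (character scalar).
#' @export
dinuc_shuffle <- function(seq, seed, stream = 0L) {
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  cpp_dinuc_shuffle(seq, as.integer(seed), as.integer(stream))
}

#' Empirical null distribution of a per-sequence statistic
#'
#' Applies `statistic` to `n_perm` dinucleotide-preserving shuffles of `seq`.
#' Shuffle `i` uses RNG stream `i` of `seed`, so the same
#' `(seq, statistic, n_perm, seed)` always yields the identical distribution,
#' and the compiled fast path for spacing statistics draws the very same
#' shuffles.
#'
#' @param seq a single DNA sequence.
#' @param statistic function mapping a sequence to a single number; must be
#'   deterministic.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer master seed.
#' @param statistic_name label stored in the result.
#' @return an object of class `null_distribution` with elements `values`,
#'   `n_perm`, `seed`, `statistic_name`.
#' @export
empirical_null <- function(seq, statistic, n_perm, seed,
                           statistic_name = deparse(substitute(statistic))) {
  stopifnot(is.function(statistic), n_perm >= 1)
  values <- vapply(seq_len(n_perm), function(i) {
    sh <- dinuc_shuffle(seq, seed, stream = i)
    v <- tryCatch(statistic(sh), error = function(e)
      stop("statistic failed at permutation ", i, ": ", conditionMessage(e),
           call. = FALSE))
    as.numeric(v)
  }, numeric(1))
  structure(list(values = values, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), statistic_name = statistic_name),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Empirical null of '", x$statistic_name, "': ", x$n_perm,
      " permutations (seed ", x$seed, ")\n", sep = "")
  print(summary(x$values))
  invisible(x)
}

#' Upper-tail empirical p-value
#'
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`: the add-one formula keeps
#' p strictly positive, and ties between the observation and null values count
#' towards the tail ("as many or more by chance"). One-sided upper tail, the
#' orientation of an enrichment test.
#'
#' @param observed observed value of the statistic.
#' @param null a `null_distribution`, or a numeric vector of null values.
#' @return empirical p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null) {
  values <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(values) == 0L) stop("null distribution is empty", call. = FALSE)
  (1 + sum(values >= observed)) / (length(values) + 1)
}

#' Count the 16 dinucleotides of a sequence
#'
#' Overlapping dinucleotide counts over `{A,C,G,T}` (pairs touching `N` are
#' tallied separately under their literal letters). Mainly used to verify
#' shuffle invariance.
#'
#' @param seq a single DNA sequence.
#' @return named integer vector of counts for every observed dinucleotide.
#' @export
dinuc_counts <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(integer(0))
  ch <- strsplit(seq, "")[[1]]
  di <- paste0(ch[-n], ch[-1])
  table_ <- table(di)
  stats::setNames(as.integer(table_), names(table_))
}
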