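# CpG-pair spacing statistics: per-distance observed counts, permutation
# expectations, obs/exp profiles, range-enrichment tests and category
# summaries. The de novo methyltransferase complex Dnmt3a/Dnmt3l can methylate
# two CpGs 8-10 bp apart simultaneously, so the default tested range is
# 8-10 bp with 12-14 bp as a non-harmonic control range.

#' 0-based start offsets of all CpG dinucleotides
#'
#' @param seq a single DNA sequence.
#' @return integer vector of offsets `i` with `substr(seq, i+1, i+2) == "CG"`.
#' @export
cpg_positions <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Counts of CpG pairs per distance
#'
#' All unordered pairs are counted (not only adjacent CpGs), where distance is
#' the difference of the two start offsets. In a sequence of length L the
#' largest realisable distance is L - 2.
#'
#' @param positions sorted ascending integer offsets (from [cpg_positions()]).
#' @param max_d largest distance tallied.
#' @return named integer vector of counts for distances `0..max_d`.
#' @export
pair_distance_counts <- function(positions, max_d) {
  counts <- cpp_pair_counts(as.integer(positions), as.integer(max_d))
  stats::setNames(counts, 0:max_d)
}

#' Observed/expected CpG spacing profile of one sequence
#'
#' `expected[D]` is the mean CpG-pair count at distance D over `n_perm`
#' dinucleotide-preserving shuffles; `obs_exp[D] = observed[D] / expected[D]`,
#' reported as `NA` where the expectation is zero (and excluded from category
#' averages).
#'
#' @param seq a single DNA sequence (length >= 2).
#' @param n_perm number of permutations (default 1000).
#' @param max_d largest distance profiled (default 200, the plotting range;
#'   use 1000 for p-value work).
#' @param seed integer master seed.
#' @param seq_id identifier stored in the profile.
#' @return an object of class `spacing_profile` with fields `seq_id`, `L`,
#'   `observed`, `expected`, `obs_exp`, `n_perm`, `seed`.
#' @export
obs_exp_profile <- function(seq, n_perm = 1000L, max_d = 200L, seed,
                            seq_id = "seq") {
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  max_d <- as.integer(min(max_d, max(nchar(seq) - 2L, 0L)))
  observed <- pair_distance_counts(cpg_positions(seq), max_d)
  null <- cpp_spacing_null(seq, max_d, as.integer(n_perm), as.integer(seed))
  expected <- colMeans(null)
  names(expected) <- names(observed)
  obs_exp <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(list(seq_id = seq_id, L = nchar(seq), observed = observed,
                 expected = expected, obs_exp = obs_exp,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "spacing_profile")
}

#' @export
print.spacing_profile <- function(x, ...) {
  cat("CpG spacing profile of '", x$seq_id, "' (L=", x$L, ", ", x$n_perm,
      " permutations)\n", sep = "")
  ok <- !is.na(x$obs_exp)
  if (any(ok)) {
    top <- order(x$obs_exp, decreasing = TRUE)[1:min(5, sum(ok))]
    cat("top obs/exp distances:",
        paste0(names(x$obs_exp)[top], " (", round(x$obs_exp[top], 2), ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Range-enrichment permutation test for CpG spacing
#'
#' Statistic: total CpG-pair count over distances `d_lo..d_hi`, compared
#' against the same statistic on `n_perm` dinucleotide-preserving shuffles
#' (upper-tail add-one empirical p). A sequence too short to realise the
#' range (`L < d_lo + 2`) yields `p = NA` with `defined = FALSE`.
#'
#' @param seq a single DNA sequence.
#' @param d_lo,d_hi distance range in bp (defaults 8 and 10).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer master seed.
#' @return list with `statistic`, `p`, `defined`, `d_lo`, `d_hi`, `n_perm`,
#'   `seed`.
#' @export
range_enrichment_test <- function(seq, d_lo = 8L, d_hi = 10L,
                                  n_perm = 1000L, seed) {
  stopifnot(d_lo >= 0L, d_hi >= d_lo)
  if (nchar(seq) < d_lo + 2L)
    return(list(statistic = NA_real_, p = NA_real_, defined = FALSE,
                d_lo = d_lo, d_hi = d_hi, n_perm = as.integer(n_perm),
                seed = as.integer(seed)))
  observed <- sum(pair_distance_counts(cpg_positions(seq), d_hi)[(d_lo:d_hi) + 1L])
  null <- cpp_spacing_null(seq, as.integer(d_hi), as.integer(n_perm),
                           as.integer(seed))
  stat_null <- rowSums(null[, (d_lo:d_hi) + 1L, drop = FALSE])
  list(statistic = as.numeric(observed), p = empirical_p(observed, stat_null),
       defined = TRUE, d_lo = d_lo, d_hi = d_hi,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Average obs/exp profile over a category of sequences
#'
#' At each distance D, the mean of `obs_exp[D]` over exactly those profiles
#' whose sequence can realise the distance (`L - 2 >= D`) and whose
#' permutation expectation at D is positive. The number of contributing
#' sequences is reported per distance.
#'
#' @param profiles list of `spacing_profile` objects.
#' @param max_d largest distance summarised.
#' @return data.frame with `distance`, `mean_obs_exp`, `n_contributing`.
#' @export
category_average_profile <- function(profiles, max_d = 200L) {
  if (length(profiles) == 0L) stop("no profiles supplied", call. = FALSE)
  dists <- 0:max_d
  acc <- matrix(NA_real_, nrow = length(profiles), ncol = length(dists))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    usable <- dists <= (p$L - 2L) & dists <= (length(p$obs_exp) - 1L)
    vals <- rep(NA_real_, length(dists))
    vals[usable] <- p$obs_exp[dists[usable] + 1L]
    acc[i, ] <- vals
  }
  data.frame(distance = dists,
             mean_obs_exp = colMeans(acc, na.rm = TRUE),
             n_contributing = colSums(!is.na(acc)))
}

#' Cumulative distribution of empirical p-values
#'
#' For each threshold X, the fraction of p-values strictly below X; the
#' fraction at X = 0.05 (the significance threshold) is attached as attribute
#' `frac_at_0.05`.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @param thresholds evaluation points (default a fine grid plus 0.05).
#' @return data.frame `threshold`, `frac_below`, with attribute
#'   `frac_at_0.05`.
#' @export
p_value_ecdf <- function(pvals, thresholds = sort(unique(c(seq(0, 1, by = 0.01), 0.05)))) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  frac <- vapply(thresholds, function(x) mean(pvals < x), numeric(1))
  structure(data.frame(threshold = thresholds, frac_below = frac),
            frac_at_0.05 = mean(pvals < 0.05))
}

#' Fraction of p-values below a significance threshold
#'
#' @param pvals numeric vector of p-values.
#' @param alpha threshold (default 0.05).
#' @return fraction of `pvals` strictly below `alpha`.
#' @export
fraction_significant <- function(pvals, alpha = 0.05) mean(pvals < alpha)
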