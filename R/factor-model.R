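# Multi-factor logistic analysis of binary CGI methylation state: deviance
# reductions of single factors, added-value likelihood-ratio tests, the
# pairwise interaction network with Bonferroni correction, stratified odds
# ratios, phi correlations, and the G-skew R-loop-potential factor.
#
# Model fitting is maximum likelihood by IRLS via stats::glm; all reported
# tests are likelihood-ratio (deviance-difference) tests, not Wald tests.

#' G-skew R-loop formation potential
#'
#' Orients the CGI sequence to the sense (RNA-like) strand of the overlapping
#' transcript and returns 1 iff it contains strictly more G than C residues
#' (ties give 0). For a minus-strand transcript the sense strand is the
#' reverse complement, so G and C counts swap. `N` counts as neither.
#'
#' @param seq CGI sequence as given (forward genomic strand).
#' @param transcript_strand `"+"`, `"-"`, or `"*"` (unknown).
#' @return 0/1, or `NA` (with a warning) when the strand is unknown.
#' @export
gskew_rloop_potential <- function(seq, transcript_strand) {
  if (!transcript_strand %in% c("+", "-")) {
    warning("transcript strand unknown; R-loop potential undefined")
    return(NA_integer_)
  }
  g <- lengths(regmatches(seq, gregexpr("G", seq, fixed = TRUE)))
  c_ <- lengths(regmatches(seq, gregexpr("C", seq, fixed = TRUE)))
  if (transcript_strand == "-") { tmp <- g; g <- c_; c_ <- tmp }
  as.integer(g > c_)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic fit (IRLS, `stats::glm`). Errors on rank
#' deficiency, naming the collinear terms; flags (quasi-)complete separation
#' when fitted probabilities are numerically 0/1.
#'
#' @param table data.frame containing the outcome and predictors.
#' @param formula model formula, e.g. `M ~ PA + Motif`.
#' @return object of class `logit_fit`: `coefficients` (matrix with
#'   estimates and Wald SEs), `deviance`, `null_deviance`, `df_residual`,
#'   `converged`, `separation`, `n`, and the underlying `glm`.
#' @export
fit_logistic <- function(table, formula) {
  fit <- stats::glm(formula, family = stats::binomial(), data = table,
                    control = list(epsilon = 1e-8, maxit = 100))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    any(abs(coef(fit)) > 10)
  sm <- summary(fit)
  structure(list(coefficients = sm$coefficients,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 df_residual = fit$df.residual,
                 converged = fit$converged,
                 separation = separation,
                 n = length(fit$y),
                 glm = fit),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, "): deviance", round(x$deviance, 2),
      "| null", round(x$null_deviance, 2),
      if (x$separation) "| WARNING: separation detected" else "", "\n")
  print(round(x$coefficients[, 1:2, drop = FALSE], 4))
  invisible(x)
}

#' Predicted probabilities from a fitted or literal logistic model
#'
#' @param coefs named coefficient vector (names matching model-matrix
#'   columns, `(Intercept)` included; interactions as `A:B`).
#' @param newdata data.frame of predictor values.
#' @return vector of predicted probabilities.
#' @export
predict_logistic <- function(coefs, newdata) {
  terms <- setdiff(names(coefs), "(Intercept)")
  f <- stats::as.formula(paste(
    "~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
  mm <- stats::model.matrix(f, newdata)
  unname(stats::plogis(drop(mm[, names(coefs), drop = FALSE] %*% coefs)))
}

#' Deviance reduction of a single factor
#'
#' `null_deviance - deviance` of the one-factor logistic model, with the
#' 1-df chi-square p-value of the likelihood-ratio test against the
#' intercept-only model.
#'
#' @param table data.frame with the outcome and the factor.
#' @param factor name of the predictor column.
#' @param outcome name of the binary outcome column (default `"M"`).
#' @return list with `reduction`, `p`, `fit`.
#' @export
deviance_reduction <- function(table, factor, outcome = "M") {
  fit <- fit_logistic(table, stats::as.formula(paste(outcome, "~", factor)))
  red <- fit$null_deviance - fit$deviance
  list(reduction = red, p = stats::pchisq(red, df = 1, lower.tail = FALSE),
       fit = fit)
}

#' Rank factors by single-factor deviance reduction
#'
#' @param table data.frame with the outcome and factors.
#' @param factors character vector of factor column names.
#' @param outcome binary outcome column (default `"M"`).
#' @return data.frame `factor`, `reduction`, `p`, `rank` (1 = most
#'   predictive), sorted by decreasing reduction.
#' @export
deviance_ranking <- function(table, factors, outcome = "M") {
  rows <- lapply(factors, function(f) {
    dr <- deviance_reduction(table, f, outcome)
    data.frame(factor = f, reduction = dr$reduction, p = dr$p)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$reduction), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Added predictive value of one factor over another
#'
#' Likelihood-ratio test (1 df) of `outcome ~ base` versus
#' `outcome ~ base + added`.
#'
#' @param table data.frame with the outcome and both factors.
#' @param base_factor,added_factor predictor column names.
#' @param outcome binary outcome column (default `"M"`).
#' @return list with `reduction` (deviance drop) and `p`.
#' @export
added_value_test <- function(table, base_factor, added_factor, outcome = "M") {
  f0 <- fit_logistic(table, stats::as.formula(paste(outcome, "~", base_factor)))
  # fitted directly so that an added factor aliased with the base (e.g. a
  # duplicate column) yields reduction 0 rather than a rank-deficiency error
  g1 <- stats::glm(stats::as.formula(
    paste(outcome, "~", base_factor, "+", added_factor)),
    family = stats::binomial(), data = table,
    control = list(epsilon = 1e-8, maxit = 100))
  red <- f0$deviance - g1$deviance
  red <- max(red, 0)
  list(reduction = red, p = stats::pchisq(red, df = 1, lower.tail = FALSE))
}

#' Pairwise interaction network of binary factors
#'
#' For every unordered pair, a likelihood-ratio test (1 df) of the
#' main-effects model against the model with the interaction term added.
#' Bonferroni correction uses m = number of pairs tested in the run. Pairs
#' whose interaction model separates or fails to converge are flagged
#' non-estimable (`p = NA`).
#'
#' @param table data.frame with the outcome and factors.
#' @param factors character vector of >= 2 factor names.
#' @param alpha family-wise significance level (default 0.05).
#' @param outcome binary outcome column (default `"M"`).
#' @return data.frame `factor1`, `factor2`, `effect_size` (interaction
#'   deviance reduction), `p`, `p_bonferroni`, `significant`, `estimable`;
#'   attribute `m` = number of pairs.
#' @export
interaction_network <- function(table, factors, alpha = 0.05, outcome = "M") {
  stopifnot(length(factors) >= 2L)
  pairs <- utils::combn(factors, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    f1 <- pairs[1, j]; f2 <- pairs[2, j]
    main <- fit_logistic(table, stats::as.formula(
      paste(outcome, "~", f1, "+", f2)))
    int <- tryCatch(fit_logistic(table, stats::as.formula(
      paste(outcome, "~", f1, "*", f2))), error = function(e) NULL)
    if (is.null(int) || !int$converged || int$separation)
      return(data.frame(factor1 = f1, factor2 = f2, effect_size = NA_real_,
                        p = NA_real_, estimable = FALSE))
    red <- max(main$deviance - int$deviance, 0)
    data.frame(factor1 = f1, factor2 = f2, effect_size = red,
               p = stats::pchisq(red, df = 1, lower.tail = FALSE),
               estimable = TRUE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(res$p * m, 1)
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
  res <- res[, c("factor1", "factor2", "effect_size", "p", "p_bonferroni",
                 "significant", "estimable")]
  attr(res, "m") <- m
  res
}

#' Stratified odds ratios of an exposure on methylation state
#'
#' Within each stratum, the 2x2 table of exposure against outcome is
#' summarised by (i) the odds ratio oriented so that OR > 1 means the
#' exposure protects against methylation (odds of methylation without the
#' exposure over odds with it), with the risk orientation also reported,
#' (ii) the percentage-point reduction in the methylated fraction, and
#' (iii) Fisher's exact p.
#'
#' @param table data.frame with binary outcome, exposure and stratum columns.
#' @param exposure exposure column name.
#' @param stratum_var stratum column name.
#' @param outcome binary outcome column (default `"M"`).
#' @return data.frame per stratum: `stratum`, `or_protective`, `or_risk`,
#'   `meth_reduction_pp`, `p_fisher`, `n`, `degenerate`.
#' @export
stratified_or <- function(table, exposure, stratum_var, outcome = "M") {
  strata <- sort(unique(table[[stratum_var]]))
  rows <- lapply(strata, function(s) {
    d <- table[table[[stratum_var]] == s, , drop = FALSE]
    m <- d[[outcome]]; e <- d[[exposure]]
    a <- sum(m == 1 & e == 0); b <- sum(m == 0 & e == 0)
    c_ <- sum(m == 1 & e == 1); d_ <- sum(m == 0 & e == 1)
    degenerate <- (a + b) == 0 || (c_ + d_) == 0 || (a + c_) == 0 || (b + d_) == 0
    orp <- if (b * c_ == 0) {
      if (a * d_ == 0) NaN else Inf
    } else (a * d_) / (b * c_)
    pp <- if ((a + b) > 0 && (c_ + d_) > 0)
      100 * (a / (a + b) - c_ / (c_ + d_)) else NA_real_
    pf <- if (!degenerate)
      stats::fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))$p.value
    else NA_real_
    data.frame(stratum = s, or_protective = orp, or_risk = 1 / orp,
               meth_reduction_pp = pp, p_fisher = pf, n = nrow(d),
               degenerate = degenerate)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pairwise correlations among binary factors and the outcome
#'
#' Pearson correlation on the 0/1 columns (the phi coefficient). Constant
#' columns yield `NA` for their pairs, with a warning.
#'
#' @param table data.frame of binary columns.
#' @param columns columns to correlate (default all numeric columns).
#' @return correlation matrix.
#' @export
factor_correlations <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(columns) < 2L) stop("need >= 2 columns", call. = FALSE)
  x <- as.matrix(table[, columns, drop = FALSE])
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning("constant column(s): ", paste(columns[const], collapse = ", "),
            "; correlations undefined")
  suppressWarnings(stats::cor(x))
}
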