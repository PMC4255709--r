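# Seed-deterministic synthetic-data generators with ground truth: CGI-like
# Markov-chain sequences with optional embedded motifs, periodically spaced
# CpGs, logistic factor tables, and transcript/CGI genomic layouts. The
# first-order Markov background makes dinucleotide-preserving shuffles
# non-trivial (an i.i.d. background would make every shuffle statistically
# equivalent to the original by construction).

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# transition matrix with P(G|C) = x and all other rows/entries proportional
# to the base composition
markov_matrix <- function(gc, x) {
  p <- base_probs(gc)
  P <- matrix(rep(p, each = 4), nrow = 4, dimnames = list(names(p), names(p)))
  other <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
  P["C", ] <- c(other["A"], other["C"], 0, other["T"]) * (1 - x)
  P["C", "G"] <- x
  P
}

stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(P))
}

# calibrate P(G|C) so that the stationary per-bp CpG rate hits the target
calibrate_cpg <- function(gc, cpg_per_kbp) {
  target <- cpg_per_kbp / 1000
  rate <- function(x) {
    P <- markov_matrix(gc, x)
    pi_ <- stationary_dist(P)
    pi_["C"] * x
  }
  if (target >= rate(0.999))
    stop("CpG density ", cpg_per_kbp, "/kbp infeasible at GC fraction ", gc,
         call. = FALSE)
  stats::uniroot(function(x) rate(x) - target, c(1e-4, 0.999), tol = 1e-9)$root
}

markov_seq <- function(L, P, pi_) {
  cum <- t(apply(P, 1, cumsum))
  cpp_markov_seq(as.integer(L), cum, cumsum(pi_),
                 paste(rownames(P), collapse = ""))
}

instantiate_iupac <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

embed_motif_once <- function(seq, motif, k, mode, window = 100L) {
  # place k non-overlapping instances; re-draw placements (max 100 attempts)
  # if splicing changed the occurrence count off-target (junction artefacts)
  L <- nchar(seq)
  w <- nchar(motif)
  if (L < (w + 1) * k) stop("sequence too short to embed ", k, " x ", motif,
                            call. = FALSE)
  bg_occ <- scan_motif(c(s = seq), motif)
  for (attempt in 1:100) {
    cand <- 0:(L - w)
    weights <- NULL
    if (mode == "cpg-dense") {
      cpos <- cpg_positions(seq)
      weights <- vapply(cand, function(s0) {
        1 + sum(cpos >= s0 - window %/% 2 & cpos < s0 + window %/% 2)
      }, numeric(1))
    }
    starts <- integer(0)
    avail <- rep(TRUE, length(cand))
    ok <- TRUE
    for (j in seq_len(k)) {
      sel <- which(avail)
      if (!length(sel)) { ok <- FALSE; break }
      s0 <- if (is.null(weights)) sample(sel, 1L) else
        sample(sel, 1L, prob = weights[sel])
      s0 <- cand[s0]
      starts <- c(starts, s0)
      avail[cand >= s0 - w + 1 & cand <= s0 + w - 1] <- FALSE
    }
    if (!ok) next
    out <- seq
    for (s0 in starts)
      substr(out, s0 + 1L, s0 + w) <- instantiate_iupac(motif)
    # every embedded window must carry exactly one occurrence and the
    # off-window occurrence count must be unchanged relative to background
    occ <- scan_motif(c(s = out), motif)
    in_win <- vapply(occ$offset, function(o) {
      any(o >= starts - w + 1 & o <= starts + w - 1)
    }, logical(1))
    bg_out <- sum(!vapply(bg_occ$offset, function(o) {
      any(o >= starts - w + 1 & o <= starts + w - 1)
    }, logical(1)))
    if (sum(in_win) == k && sum(!in_win) == bg_out)
      return(list(seq = out, n_embedded = k))
  }
  warning("motif embedding kept a junction artefact after 100 attempts")
  list(seq = out, n_embedded = k)
}

#' Generate CGI-like sequences from a calibrated Markov chain
#'
#' First-order Markov background with `P(G|C)` calibrated so the stationary
#' CpG rate matches `cpg_per_kbp`, optionally with IUPAC motifs embedded at
#' known per-sequence counts. The returned truth table records per-sequence
#' embedded-motif counts.
#'
#' @param n number of sequences.
#' @param length_range `c(min, max)` bp; lengths drawn uniformly (a scalar
#'   gives constant length).
#' @param cpg_per_kbp target CpG density (default 80/kbp, a CpG-island-like
#'   density at the default GC).
#' @param gc GC fraction (default 0.6).
#' @param motifs optional list of embedding specs, each
#'   `list(pattern=, count=, mode=, in_fraction=)` with `mode` one of
#'   `"uniform"`, `"cpg-dense"`, `"independent"` (alias of uniform) and
#'   `in_fraction` the fraction of sequences receiving embeddings (default 1).
#' @param seed integer seed (mandatory).
#' @return list with `seqs` (named character vector) and `truth`
#'   (data.frame: `seq_id`, `length`, one `embedded_<pattern>` column per
#'   motif, `periodic = FALSE`).
#' @export
sim_cgi_seqs <- function(n, length_range = c(1000, 1000), cpg_per_kbp = 80,
                         gc = 0.6, motifs = NULL, seed) {
  if (length(length_range) == 1L) length_range <- rep(length_range, 2)
  x <- calibrate_cpg(gc, cpg_per_kbp)
  P <- markov_matrix(gc, x)
  pi_ <- stationary_dist(P)
  with_local_seed(seed, {
    lens <- as.integer(round(stats::runif(n, length_range[1], length_range[2])))
    seqs <- vapply(lens, markov_seq, character(1), P = P, pi_ = pi_)
    names(seqs) <- sprintf("sim%04d", seq_len(n))
    truth <- data.frame(seq_id = names(seqs), length = lens,
                        periodic = FALSE)
    for (m in motifs) {
      frac <- if (is.null(m$in_fraction)) 1 else m$in_fraction
      mode <- if (is.null(m$mode)) "uniform" else m$mode
      if (mode == "independent") mode <- "uniform"
      count <- if (!is.null(m$count)) m$count else NULL
      chosen <- sort(sample(n, round(frac * n)))
      emb <- integer(n)
      for (i in chosen) {
        k <- if (!is.null(count)) count else
          max(1L, as.integer(round(m$rate_per_kbp * lens[i] / 1000)))
        res <- embed_motif_once(seqs[[i]], m$pattern, k, mode)
        seqs[[i]] <- res$seq
        emb[i] <- res$n_embedded
      }
      truth[[paste0("embedded_", m$pattern)]] <- emb
    }
    list(seqs = seqs, truth = truth)
  })
}

cpg_free_filler <- function(L, gc) {
  # CpG-free sequence: draw i.i.d., then resample any G that follows a C
  # from {A,C,T} until no CG remains
  p <- base_probs(gc)
  p_noG <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
  ch <- sample(names(p), L, replace = TRUE, prob = p)
  repeat {
    idx <- which(ch[-L] == "C" & ch[-1] == "G") + 1L
    if (!length(idx)) break
    ch[idx] <- sample(names(p_noG), length(idx), replace = TRUE, prob = p_noG)
  }
  paste(ch, collapse = "")
}

#' Generate sequences with periodically spaced CpGs
#'
#' CpGs are placed at successive offsets `period +/- jitter` starting from a
#' small random phase, in CpG-free filler sequence, so all CpG pairs arise
#' from the deliberate placement. With `periodic = FALSE` the same number of
#' CpGs is placed uniformly at random (minimum gap 2 bp) -- the matched
#' non-periodic control.
#'
#' @param n number of sequences.
#' @param length sequence length in bp (default 500).
#' @param period spacing period in bp (default 9, the Dnmt3a/Dnmt3l-relevant
#'   spacing; must be >= 2).
#' @param jitter uniform jitter on each spacing, in bp (default 1).
#' @param periodic if `FALSE`, generate the matched random-spacing control.
#' @param gc GC fraction of the filler (default 0.5).
#' @param seed integer seed.
#' @return list with `seqs` and `truth` (`seq_id`, `length`, `n_cpg`,
#'   `periodic`).
#' @export
sim_periodic_seqs <- function(n, length = 500L, period = 9L, jitter = 1L,
                              periodic = TRUE, gc = 0.5, seed) {
  if (period < 2L) stop("period must be >= 2", call. = FALSE)
  if (period - jitter < 2L) stop("period - jitter must be >= 2 (CpGs overlap)",
                                 call. = FALSE)
  with_local_seed(seed, {
    seqs <- character(n)
    n_cpg <- integer(n)
    for (i in seq_len(n)) {
      if (periodic) {
        pos <- sample.int(min(period, length - 2L), 1L) - 1L
        positions <- integer(0)
        while (pos <= length - 2L) {
          positions <- c(positions, pos)
          pos <- pos + period + sample((-jitter):jitter, 1L)
        }
      } else {
        k <- max(1L, (length - 2L) %/% period)
        repeat {  # uniform placement with min gap 2
          positions <- sort(sample(0:(length - 2L), k))
          if (all(diff(positions) >= 2L)) break
        }
      }
      filler <- cpg_free_filler(length, gc)
      s <- filler
      for (p0 in positions) substr(s, p0 + 1L, p0 + 2L) <- "CG"
      seqs[i] <- s
      n_cpg[i] <- length(positions)
    }
    names(seqs) <- sprintf("%s%04d", if (periodic) "per" else "ctl", seq_len(n))
    list(seqs = seqs,
         truth = data.frame(seq_id = names(seqs), length = length,
                            n_cpg = n_cpg, periodic = periodic))
  })
}

phi_to_rho <- function(phi, p1, p2) {
  a <- stats::qnorm(p1); b <- stats::qnorm(p2)
  p11 <- function(rho) {
    if (abs(rho) < 1e-12) return(p1 * p2)
    f <- function(z) stats::dnorm(z) *
      stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
    stats::integrate(f, -8, a, rel.tol = 1e-10)$value
  }
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  g <- function(rho) (p11(rho) - p1 * p2) / denom - phi
  lo <- g(-0.9999); hi <- g(0.9999)
  if (lo > 0 || hi < 0)
    stop("target phi ", phi, " infeasible for prevalences ", p1, ", ", p2,
         call. = FALSE)
  stats::uniroot(g, c(-0.9999, 0.9999), tol = 1e-8)$root
}

#' Simulate a factor table from a known logistic model
#'
#' Binary factors are drawn at the stated prevalences (optionally one pair
#' correlated to a target phi coefficient via a Gaussian copula), continuous
#' predictors uniformly over stated ranges, and the binary outcome `M` from
#' the logistic model defined by `coef` (names follow model-matrix
#' conventions, interactions as `"A:B"`; must include `"(Intercept)"`).
#'
#' @param n rows.
#' @param coef named coefficient vector of the generating model.
#' @param prevalence named vector of binary-factor prevalences.
#' @param continuous named list of `c(min, max)` uniform ranges.
#' @param copula optional `list(pair = c("A","B"), phi = r)`.
#' @param seed integer seed.
#' @return list with `table` (data.frame incl. outcome `M`) and `truth`
#'   (the generating coefficients).
#' @export
sim_factor_table <- function(n, coef, prevalence = NULL, continuous = NULL,
                             copula = NULL, seed) {
  if (!"(Intercept)" %in% names(coef))
    stop("coef must include '(Intercept)'", call. = FALSE)
  with_local_seed(seed, {
    tab <- data.frame(row.names = seq_len(n))
    if (!is.null(copula)) {
      pr <- prevalence[copula$pair]
      rho <- phi_to_rho(copula$phi, pr[1], pr[2])
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      tab[[copula$pair[1]]] <- as.integer(z1 < stats::qnorm(pr[1]))
      tab[[copula$pair[2]]] <- as.integer(z2 < stats::qnorm(pr[2]))
    }
    for (f in names(prevalence))
      if (is.null(tab[[f]]))
        tab[[f]] <- stats::rbinom(n, 1, prevalence[[f]])
    for (f in names(continuous))
      tab[[f]] <- stats::runif(n, continuous[[f]][1], continuous[[f]][2])
    p <- predict_logistic(coef, tab)
    tab$M <- stats::rbinom(n, 1, p)
    list(table = tab, truth = coef)
  })
}

#' Simulate a transcript/CGI genomic layout with known classes
#'
#' Plants transcripts (some strand-unknown) and CGIs realising every
#' classification outcome: promoter_associated, intragenic, distal
#' intragenic, end_associated, ambiguous (promoter window of one transcript
#' and intragenic in another) and transcript_free. Positions are jittered
#' per seed; intended classes are returned as truth.
#'
#' @param n_per_class CGIs planted per class (default 2).
#' @param seed integer seed.
#' @return list with `cgis`, `transcripts` (interval data.frames) and
#'   `truth` (`cgi_id`, `class`).
#' @export
sim_layout <- function(n_per_class = 2L, seed) {
  classes <- c("promoter_associated", "intragenic", "distal_intragenic",
               "end_associated", "ambiguous", "transcript_free")
  with_local_seed(seed, {
    tr <- list(); cg <- list(); truth <- list()
    block <- 0L
    for (cl in classes) {
      for (r in seq_len(n_per_class)) {
        b <- block * 50000L
        block <- block + 1L
        j <- sample(0:100, 1L)  # positional jitter
        id <- sprintf("cgi_%s_%d", cl, r)
        if (cl == "promoter_associated") {
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 10000L,
                                              end = b + 20000L, strand = "+")
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 10100L + j,
                                              end = b + 10400L + j, name = id)
        } else if (cl == "intragenic") {
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 10000L,
                                              end = b + 20000L, strand = "+")
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 13000L + j,
                                              end = b + 13400L + j, name = id)
        } else if (cl == "distal_intragenic") {
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 10000L,
                                              end = b + 20000L, strand = "+")
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 20100L + j,
                                              end = b + 20500L + j, name = id)
        } else if (cl == "end_associated") {
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 10000L,
                                              end = b + 20000L, strand = "*")
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 9700L + j,
                                              end = b + 10100L + j, name = id)
        } else if (cl == "ambiguous") {
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 10000L,
                                              end = b + 20000L, strand = "+")
          tr[[length(tr) + 1L]] <- data.frame(chrom = "chrS", start = b + 8000L,
                                              end = b + 30000L, strand = "+")
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 9900L + j,
                                              end = b + 10200L + j, name = id)
        } else {  # transcript_free
          cg[[length(cg) + 1L]] <- data.frame(chrom = "chrS",
                                              start = b + 10000L + j,
                                              end = b + 10300L + j, name = id)
        }
        final <- switch(cl, intragenic = "intragenic_like",
                        distal_intragenic = "intragenic_like", cl)
        truth[[length(truth) + 1L]] <- data.frame(cgi_id = id, class = final)
      }
    }
    list(cgis = do.call(rbind, cg), transcripts = do.call(rbind, tr),
         truth = do.call(rbind, truth))
  })
}
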