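# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct combinatorial
# sums, regex scanning and grid-search likelihood maximisation.

# All distinct sequences with the same multiset of overlapping dinucleotides
# as `seq` (same endpoints follow automatically): exhaustive DFS over the
# edge multigraph. Feasible for length <= ~12.
enum_dinuc_arrangements <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 2) return(seq)
  verts <- unique(ch)
  M <- matrix(0L, length(verts), length(verts), dimnames = list(verts, verts))
  for (i in 1:(n - 1)) M[ch[i], ch[i + 1]] <- M[ch[i], ch[i + 1]] + 1L
  out <- character(0)
  rec <- function(cur, path, M, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- paste(path, collapse = "")
      return(invisible())
    }
    for (v in verts) {
      if (M[cur, v] > 0L) {
        M[cur, v] <- M[cur, v] - 1L
        rec(v, c(path, v), M, left - 1L)
        M[cur, v] <- M[cur, v] + 1L
      }
    }
  }
  rec(ch[1], ch[1], M, n - 1L)
  unique(out)
}

# Upper-tail Fisher p by direct summation of hypergeometric terms.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  m <- a + c
  n2 <- b + d
  N <- a + b + c + d
  js <- max(0, r1 - n2):min(r1, m)
  probs <- choose(m, js) * choose(n2, r1 - js) / choose(N, r1)
  sum(probs[js >= a])
}

# IUPAC motif occurrence count (both strands) via perl regex with lookahead
# (overlapping matches), independent of Biostrings.
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

count_occurrences_oracle <- function(seq, motif, both = TRUE) {
  to_re <- function(p) paste0("(?=", paste(vapply(
    strsplit(p, "")[[1]],
    function(ch) paste0("[", paste(iupac_sets_oracle[[ch]], collapse = ""), "]"),
    character(1)), collapse = ""), ")")
  cnt <- function(p) {
    m <- gregexpr(to_re(p), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  n <- cnt(motif)
  rc <- revcomp_oracle(motif)
  if (both && rc != motif) n <- n + cnt(rc)
  n
}

# Grid-search maximiser of the Bernoulli log-likelihood for a
# single-predictor logistic model, refined over 4 rounds.
grid_logistic_oracle <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  width <- 10
  for (round in 1:6) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 8
  }
  centre
}

# Random DNA sequence (i.i.d.) for fuzzing.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
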