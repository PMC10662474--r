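# In-code fixtures and independent oracles shared across test files.

onehot20 <- function(aa) {
  p <- numeric(20)
  p[match(aa, AA_ALPHABET)] <- 1
  p
}

# short records trip the working-range warning by design; silence it here
toy_record <- function(id, sequence, ...) {
  suppressWarnings(protein_record(id, sequence, ...))
}

# hand-built feature profile with one-hot residues and self-paired sites;
# two sites with equal (aa, ss, acc) score 2 + omega1 + omega2 against each
# other, fully differing sites score 0
toy_profile <- function(aa, ss, acc, id = "toy") {
  L <- length(aa)
  m <- matrix(0, L, 640L)
  for (i in seq_len(L)) {
    p <- onehot20(aa[i])
    m[i, 1:400] <- build_pair_block(p, p)
    m[i, 401:640] <- build_structure_block(acc[i], acc[i], ss[i], p)
  }
  structure(m, class = c("feature_profile", "matrix", "array"),
            id = id, ss = ss, acc = acc)
}

random_toy_profile <- function(L, id = "rnd") {
  toy_profile(sample(AA_ALPHABET[1:6], L, replace = TRUE),
              sample(SS_ALPHABET, L, replace = TRUE),
              sample(ACC_ALPHABET, L, replace = TRUE), id = id)
}

# Independent affine-gap oracle: exhaustive enumeration of every global
# alignment (monotone path), scoring a gap run of length k as d + (k-1)e.
# Enumerates adjacent opposite-gap alignments too, unlike the DP.
brute_force_align_score <- function(S, d, e) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i == n && j == m) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, score + S[i + 1, j + 1], "M")
    if (i < n) rec(i + 1, j, score + if (identical(last, "X")) e else d, "X")
    if (j < m) rec(i, j + 1, score + if (identical(last, "Y")) e else d, "Y")
  }
  rec(0L, 0L, 0, "start")
  best
}

# random symmetric labelled distance matrix
random_distance_matrix <- function(n, ids = sprintf("t%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2, 0.05, 2)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
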