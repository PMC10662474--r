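# Profile scoring, affine-gap global alignment, distance mapping

test_that("site pair scores follow the dot-product-plus-bonus closed forms", {
  p <- alignment_params(omega1 = 1.5, omega2 = 1.5)
  A <- toy_profile("A", "H", "B")
  expect_equal(pair_score(A, 1, A, 1, p), 2 + 1.5 + 1.5)

  B <- toy_profile("C", "E", "E")   # orthogonal residues, differing labels
  expect_equal(pair_score(A, 1, B, 1, p), 0)

  # uniform-probability sites, same labels, omega = 1:
  # 400*0.0025^2 + 20*0.05^2 = 0.0525, plus both bonuses
  pu <- alignment_params(omega1 = 1, omega2 = 1)
  m <- matrix(c(build_pair_block(rep(0.05, 20), rep(0.05, 20)),
                build_structure_block("B", "B", "H", rep(0.05, 20))), 1, 640,
              byrow = TRUE)
  U <- structure(m, class = c("feature_profile", "matrix", "array"),
                 id = "u", ss = "H", acc = "B")
  got <- pair_score(U, 1, U, 1, pu)
  # brute-force dot product as the oracle
  expect_equal(got, sum(m[1, ]^2) + 2)
  expect_equal(got, 2.0525, tolerance = 1e-12)

  expect_error(pair_score(A, 2, B, 1, p), "out of range")
})

test_that("self-alignment is the full diagonal with the self-score", {
  set.seed(3)
  P <- random_toy_profile(6)
  p <- alignment_params()
  aln <- global_align(P, P, p)
  expect_equal(aln$aligned_pairs[, "i"], 1:6, ignore_attr = TRUE)
  expect_equal(aln$aligned_pairs[, "j"], 1:6, ignore_attr = TRUE)
  expect_equal(aln$score,
               sum(vapply(1:6, function(i) pair_score(P, i, P, i, p), 0)))
})

test_that("a 1-vs-2 alignment opens exactly one gap", {
  p <- alignment_params(gap_open = -1, gap_extend = -0.2)
  A <- toy_profile("A", "H", "B", id = "A")
  # B1 fully differs from A1 (score 0); B2 equals A1 (score 5)
  B <- toy_profile(c("C", "A"), c("E", "H"), c("E", "B"), id = "B")
  aln <- global_align(A, B, p)
  expect_equal(aln$score, 5 - 1)
  expect_equal(aln$aligned_pairs, cbind(i = 1L, j = 2L), ignore_attr = TRUE)
  expect_equal(sum(aln$gaps$length[aln$gaps$op != "match"]), 1)
})

test_that("DP score equals exhaustive enumeration for all short profile pairs", {
  set.seed(17)
  p <- alignment_params()
  profiles <- c(
    lapply(1:4, function(L) random_toy_profile(L)),
    lapply(1:4, function(L) random_toy_profile(sample(1:4, 1)))
  )
  for (a in seq_along(profiles)) {
    for (b in seq_along(profiles)) {
      S <- protsd:::profile_score_matrix(profiles[[a]], profiles[[b]], p)
      dp <- global_align(profiles[[a]], profiles[[b]], p,
                         keep_alignment = FALSE)$score
      oracle <- brute_force_align_score(S, p$gap_open, p$gap_extend)
      expect_equal(dp, oracle, tolerance = 1e-10)
    }
  }
})

test_that("aligned pairs are strictly increasing in both coordinates", {
  set.seed(23)
  for (k in 1:10) {
    A <- random_toy_profile(sample(3:8, 1))
    B <- random_toy_profile(sample(3:8, 1))
    aln <- global_align(A, B)
    if (nrow(aln$aligned_pairs) > 1L) {
      expect_true(all(diff(aln$aligned_pairs[, "i"]) > 0))
      expect_true(all(diff(aln$aligned_pairs[, "j"]) > 0))
    }
  }
})

test_that("the score-to-distance map hits its closed-form spot values", {
  expect_equal(score_to_distance(1), 0)
  expect_equal(score_to_distance(0.25), 0.5)
  expect_equal(score_to_distance(1e-4), 49.5)
  expect_equal(score_to_distance(0), 49.5)        # clamped at eps
  expect_equal(score_to_distance(2), 0)           # clamped at 1
})

test_that("profile distance is symmetric, zero on identical profiles, bounded", {
  set.seed(29)
  A <- random_toy_profile(7, id = "A")
  B <- random_toy_profile(9, id = "B")
  p <- alignment_params()
  dab <- sd_distance(A, B, p)
  dba <- sd_distance(B, A, p)
  expect_equal(dab$distance, dba$distance, tolerance = 1e-12)
  expect_equal(dab$distance,
               (1 / sqrt(dab$normalized_score) - 1) / 2, tolerance = 1e-12)
  expect_gte(dab$distance, 0)
  expect_lte(dab$distance, 49.5)
  expect_equal(sd_distance(A, A, p)$distance, 0)
})

test_that("distance matrices are symmetric with zero diagonal and permute consistently", {
  sim <- make_superfamily(synthetic_config(
    seed = 41, n_superfamilies = 1, families_per_sf = 2,
    proteins_per_family = 3, length_range = c(50L, 60L)))
  recs <- sim$records
  dm <- distance_matrix(recs)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, nrow(dm)))
  expect_equal(nrow(attr(dm, "pairs")), choose(length(recs), 2))

  perm <- c(4, 1, 6, 2, 5, 3)
  dm2 <- distance_matrix(recs[perm])
  expect_equal(dm2, dm[rownames(dm2), colnames(dm2)], ignore_attr = TRUE)

  # identical records are at distance zero
  twins <- list(recs[[1]],
                toy_record("copy", recs[[1]]$sequence,
                           aa_probs = recs[[1]]$aa_probs,
                           ss = recs[[1]]$ss, acc = recs[[1]]$acc))
  expect_equal(unname(distance_matrix(twins)), matrix(0, 2, 2),
               ignore_attr = TRUE)

  expect_error(distance_matrix(list(recs[[1]], recs[[1]])), "duplicate")
})

test_that("distance trends upward with the number of substitutions", {
  set.seed(53)
  base_aas <- sample(AA_ALPHABET, 80, replace = TRUE)
  base <- toy_record("anc", paste(base_aas, collapse = ""))
  prof0 <- build_profile(base)
  p <- alignment_params()
  mean_dist <- vapply(c(4, 20, 48), function(k) {
    mean(vapply(1:5, function(rep) {
      aas <- base_aas
      idx <- sample(80, k)
      aas[idx] <- vapply(aas[idx],
                         function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
      sd_distance(prof0, build_profile(
        toy_record("mut", paste(aas, collapse = ""))), p,
        keep_alignment = FALSE)$distance
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dist) > 0))
})
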