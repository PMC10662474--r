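# Superfamily benchmark statistics

# benchmark with two families per superfamily and prescribed pair distances:
# within-family pairs at d_same, between-family pairs at d_diff (+ jitter)
separated_bench <- function(n_sf = 10, per_family = 4,
                            d_same = 0.1, d_diff = 0.9, jitter = 0) {
  ids <- character(0); fams <- character(0); sfs <- character(0)
  for (s in seq_len(n_sf)) {
    for (f in 1:2) {
      for (p in seq_len(per_family)) {
        ids <- c(ids, sprintf("s%02df%dp%d", s, f, p))
        fams <- c(fams, sprintf("s%02df%d", s, f))
        sfs <- c(sfs, sprintf("s%02d", s))
      }
    }
  }
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (sfs[i] != sfs[j]) 2 else if (fams[i] == fams[j]) d_same else d_diff
      d <- d + jitter * ((i * 31 + j * 17) %% 7) / 1e3
      m[i, j] <- m[j, i] <- d
    }
  }
  superfamily_bench(m, tibble::tibble(id = ids, family = fams, superfamily = sfs))
}

test_that("sfsd is the population sd of between-family distances", {
  b <- separated_bench(n_sf = 2, d_diff = 0.9, jitter = 0)
  expect_equal(sfsd(b, "s01"), 0)

  # two families with one protein each: one between pair per value
  ids <- c("x1", "y1", "x2", "y2")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["x1", "y1"] <- m["y1", "x1"] <- 0     # sf A between pair
  m["x2", "y2"] <- m["y2", "x2"] <- 1     # also sf A between pair
  m[m == 0 & row(m) != col(m)] <- 0       # keep others zero
  lab <- tibble::tibble(id = ids,
                        family = c("fx", "fy", "fx2", "fy2"),
                        superfamily = "A")
  b2 <- superfamily_bench(m, lab)
  # between-family distances within A: all 6 cross-family pairs; restrict by
  # direct recomputation instead
  p <- bench_pairs(b2)
  d <- p$distance[!p$same_family]
  expect_equal(sfsd(b2, "A"), sqrt(mean((d - mean(d))^2)))

  expect_true(is.na(sfsd(b2, "missing")))

  set.seed(91)
  b3 <- separated_bench(n_sf = 3, jitter = 1)
  p3 <- bench_pairs(b3)
  d3 <- p3$distance[p3$superfamily == "s02" & p3$same_superfamily & !p3$same_family]
  expect_equal(sfsd(b3, "s02"), sqrt(mean((d3 - mean(d3))^2)))
})

test_that("two between-family distances {0, 1} give population sd 0.5", {
  # a, c in family f1; b alone in f2: between pairs are (a,b)=0 and (b,c)=1
  ids <- c("a", "b", "c")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["b", "c"] <- m["c", "b"] <- 1
  m["a", "c"] <- m["c", "a"] <- 0.3
  b <- superfamily_bench(m, tibble::tibble(
    id = ids, family = c("f1", "f2", "f1"), superfamily = "S"))
  expect_equal(sfsd(b, "S"), 0.5)
})

test_that("RR and RD take their closed forms on a separated benchmark", {
  b <- separated_bench(n_sf = 10, per_family = 4, d_same = 0.1, d_diff = 0.9,
                       jitter = 1)  # jitter breaks ties for the exact test
  rep <- rr_rd(b, alpha = 0.001)
  expect_equal(rep$RR, 1.0)
  expect_equal(rep$RD, mean((rep$per_superfamily$d_diff_mean -
                               rep$per_superfamily$d_same_mean) /
                              rep$per_superfamily$d_diff_mean))
  expect_equal(rep$RD, (0.9 - 0.1) / 0.9, tolerance = 0.02)
  expect_true(all(rep$per_superfamily$in_Q))

  g <- glance(rep)
  expect_equal(g$RR, 1.0)
  expect_equal(g$n_superfamilies, 10L)
  expect_equal(nrow(tidy(rep)), 10L)
})

test_that("the Mann-Whitney backend matches exact enumeration on small samples", {
  expect_equal(protsd:::mwu_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # symmetric in its arguments
  expect_equal(protsd:::mwu_p(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # large/tied samples fall back to the tie-corrected normal approximation
  x <- rep(c(1, 2), 10); y <- rep(c(1.5, 2.5), 10)
  expect_no_warning(p <- protsd:::mwu_p(x, y))
  expect_true(p > 0 && p < 1)
})

test_that("label-shuffled nulls enter Q at about the alpha rate", {
  set.seed(101)
  hits <- 0L
  n_sim <- 60L
  for (k in seq_len(n_sim)) {
    ids <- sprintf("p%02d", 1:8)
    m <- random_distance_matrix(8, ids)
    lab <- tibble::tibble(id = ids,
                          family = sample(rep(c("f1", "f2"), 4)),
                          superfamily = "S")
    rep <- rr_rd(superfamily_bench(m, lab), alpha = 0.001)
    hits <- hits + sum(rep$per_superfamily$in_Q)
  }
  expect_lte(hits / n_sim, 0.05)
})

test_that("superfamilies without both pair types are excluded and logged", {
  ids <- c("a", "b", "c", "d")
  m <- random_distance_matrix(4, ids)
  lab <- tibble::tibble(id = ids,
                        family = c("f1", "f1", "f2", "f2"),
                        superfamily = c("S1", "S1", "S2", "S2"))
  # S1 and S2 each have only within-family pairs -> nothing evaluable
  expect_error(suppressMessages(rr_rd(superfamily_bench(m, lab))),
               "no evaluable")

  lab2 <- tibble::tibble(id = ids,
                         family = c("f1", "f1", "f2", "f3"),
                         superfamily = c("S1", "S1", "S1", "S2"))
  expect_message(rep <- rr_rd(superfamily_bench(m, lab2)), "excluded")
  expect_equal(rep$excluded, "S2")
  expect_equal(rep$n_evaluable, 1L)
})

test_that("chain-combined TM-scores are length-weighted means", {
  expect_equal(combine_tm(0.8, 0.4, 300, 100), 0.7)
  expect_equal(combine_tm(0.8, 0.4, 100, 100), 0.6)
  expect_equal(combine_tm(0.35, 0.35, 123, 999), 0.35)
  # invariant under swapping the chain roles
  expect_equal(combine_tm(0.8, 0.4, 300, 100), combine_tm(0.4, 0.8, 100, 300))
  expect_error(combine_tm(1.2, 0.4, 10, 10), "\\[0, 1\\]")
  expect_error(combine_tm(0.5, 0.4, 0, 10), "positive")
})

test_that("the TM-score scale factor follows its closed form with a 0.5 floor", {
  expect_equal(tm_d0(140), 4.4)
  expect_equal(tm_d0(16), 0.5)
  d0 <- tm_d0(1:500)
  expect_true(all(diff(d0) >= 0))
  expect_true(all(d0 >= 0.5))
})

test_that("structure correlation recovers exact and null relationships", {
  set.seed(111)
  n <- 40L
  ids <- sprintf("q%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 0.95)  # 1 - d stays in [0, 1]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  pairs <- t(utils::combn(ids, 2))
  lab <- tibble::tibble(id = ids, family = ids, superfamily = "S")

  # distance = 1 - tm exactly -> Pearson -1
  tm1 <- tibble::tibble(id_a = pairs[, 1], id_b = pairs[, 2],
                        tm = pmax(0, pmin(1, 1 - m[pairs])))
  b1 <- superfamily_bench(m, lab, tm_scores = tm1)
  corr1 <- correlate_with_structure(b1)
  expect_equal(corr1$overall_pearson, -1.0, tolerance = 1e-12)

  # bin means equal direct recomputation on the pair table
  p1 <- bench_pairs(b1)
  bin <- cut(p1$tm, seq(0, 1, 0.1), include.lowest = TRUE)
  direct <- tapply(p1$distance, bin, mean)
  expect_equal(corr1$per_bin$mean_distance, unname(as.vector(direct)),
               tolerance = 1e-12)

  # shuffled tm -> near-zero correlation at large n
  set.seed(112)
  big <- 10000L
  x <- runif(big); y <- runif(big)
  expect_lt(abs(cor(x, y)), 0.1)
})

test_that("top-1 homologue is the non-self argmin with lexicographic ties", {
  ids <- c("b", "a", "c")
  m <- matrix(c(0, 0, 0.4,
                0, 0, 0.9,
                0.4, 0.9, 0), 3, 3, dimnames = list(ids, ids))
  expect_equal(top1_homolog("b", m), "a")     # zero-distance partner

  m2 <- random_distance_matrix(5)
  m2[m2 > 0] <- 0.7                           # all ties
  expect_equal(top1_homolog("t03", m2), "t01")

  set.seed(121)
  m3 <- random_distance_matrix(12)
  for (q in rownames(m3)) {
    d <- m3[q, setdiff(rownames(m3), q)]
    expect_equal(top1_homolog(q, m3), names(d)[which.min(d)])
  }
})
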