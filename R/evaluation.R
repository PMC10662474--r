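#' Superfamily benchmark container
#'
#' Couples a distance matrix with family/superfamily membership labels
#' (and optionally pairwise structural TM-scores) for the recognition-rate
#' and relative-distance statistics.
#'
#' @param dm Labelled symmetric distance matrix.
#' @param labels Data frame with columns `id`, `family`, `superfamily`
#'   covering every id in `dm`.
#' @param tm_scores Optional data frame with columns `id_a`, `id_b`, `tm`
#'   (combined TM-score in `[0, 1]`, see [combine_tm()]).
#' @return A `superfamily_bench` object.
#' @export
superfamily_bench <- function(dm, labels, tm_scores = NULL) {
  dm <- validate_distance_matrix(dm)
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("id", "family", "superfamily") %in% names(labels)))
  missing <- setdiff(rownames(dm), labels$id)
  if (length(missing)) {
    stop("ids without family/superfamily labels: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(tm_scores)) {
    tm_scores <- tibble::as_tibble(tm_scores)
    stopifnot(all(c("id_a", "id_b", "tm") %in% names(tm_scores)))
    if (any(tm_scores$tm < 0 | tm_scores$tm > 1)) {
      stop("TM-scores must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(dm = dm, labels = labels, tm_scores = tm_scores),
            class = "superfamily_bench")
}

#' @export
print.superfamily_bench <- function(x, ...) {
  cat("<superfamily_bench> ", nrow(x$dm), " proteins, ",
      dplyr::n_distinct(x$labels$family), " families, ",
      dplyr::n_distinct(x$labels$superfamily), " superfamilies",
      if (!is.null(x$tm_scores)) ", with TM-scores", "\n", sep = "")
  invisible(x)
}

#' All unordered labelled pairs of a benchmark
#'
#' One row per unordered id pair in the distance matrix, annotated with
#' family/superfamily membership and, when available, the TM-score.
#'
#' @param bench A [superfamily_bench()].
#' @return Tibble with columns id_a, id_b, distance, same_superfamily,
#'   same_family, superfamily (of id_a), and tm when present.
#' @export
bench_pairs <- function(bench) {
  dm <- bench$dm
  ids <- rownames(dm)
  idx <- utils::combn(length(ids), 2L)
  lab <- bench$labels[match(ids, bench$labels$id), ]
  out <- tibble::tibble(
    id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
    distance = dm[cbind(idx[1L, ], idx[2L, ])],
    superfamily = lab$superfamily[idx[1L, ]],
    same_superfamily = lab$superfamily[idx[1L, ]] == lab$superfamily[idx[2L, ]],
    same_family = lab$family[idx[1L, ]] == lab$family[idx[2L, ]]
  )
  if (!is.null(bench$tm_scores)) {
    tm <- bench$tm_scores
    k1 <- paste(tm$id_a, tm$id_b, sep = "\r")
    k2 <- paste(tm$id_b, tm$id_a, sep = "\r")
    key <- paste(out$id_a, out$id_b, sep = "\r")
    hit <- match(key, k1)
    hit2 <- match(key, k2)
    out$tm <- ifelse(is.na(hit), tm$tm[hit2], tm$tm[hit])
  }
  out
}

#' Superfamily standard deviation of between-family distances
#'
#' Population-form standard deviation of all pairwise distances between
#' proteins of the same superfamily but different families; detects
#' heterogeneity of the distant evolutionary relationships within a
#' superfamily.
#'
#' @param bench A [superfamily_bench()].
#' @param sf Superfamily label.
#' @return Scalar; `NA` when the superfamily has no between-family pair.
#' @export
sfsd <- function(bench, sf) {
  p <- bench_pairs(bench)
  d <- p$distance[p$superfamily == sf & p$same_superfamily & !p$same_family]
  if (!length(d)) return(NA_real_)
  sqrt(mean((d - mean(d))^2))
}

# Two-sided Mann-Whitney U p-value: exact enumeration when both samples
# have at most 8 observations and no ties, otherwise the tie-corrected
# normal approximation (no continuity correction).
mwu_p <- function(x, y) {
  exact <- length(x) <= 8L && length(y) <= 8L && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE)$p.value
  )
}

#' Recognition rate and relative distance over a superfamily benchmark
#'
#' For each superfamily with at least one within-family and one
#' between-family pair, a two-sided Mann-Whitney U test compares the
#' within-family against the between-family pair-distance samples. Q is
#' the set of superfamilies with p below `alpha`; the recognition rate RR
#' is `#Q / #evaluable superfamilies` and the relative distance RD is the
#' mean over Q of `(d_diff - d_same) / d_diff`, where `d_same` / `d_diff`
#' are the per-superfamily mean within- and between-family distances.
#' Superfamilies without both pair types are excluded and listed in the
#' report.
#'
#' @param bench A [superfamily_bench()].
#' @param alpha Significance level for Q membership (default 0.001).
#' @return An `rrrd_report` with fields `per_superfamily` (tibble),
#'   `RR`, `RD`, `alpha`, `n_evaluable`, `excluded`.
#' @export
rr_rd <- function(bench, alpha = 0.001) {
  p <- bench_pairs(bench)
  p <- p[p$same_superfamily, ]
  sfs <- sort(unique(bench$labels$superfamily))

  rows <- lapply(sfs, function(sf) {
    d_same <- p$distance[p$superfamily == sf & p$same_family]
    d_diff <- p$distance[p$superfamily == sf & !p$same_family]
    if (!length(d_same) || !length(d_diff)) return(NULL)
    pv <- mwu_p(d_same, d_diff)
    tibble::tibble(
      superfamily = sf,
      n_within = length(d_same), n_between = length(d_diff),
      p_value = pv,
      sfsd = sqrt(mean((d_diff - mean(d_diff))^2)),
      d_same_mean = mean(d_same), d_diff_mean = mean(d_diff),
      in_Q = pv < alpha
    )
  })
  per <- dplyr::bind_rows(rows)
  excluded <- setdiff(sfs, if (nrow(per)) per$superfamily else character(0))
  if (length(excluded)) {
    message(length(excluded), " superfamily(ies) excluded ",
            "(need both within- and between-family pairs): ",
            paste(head(excluded, 5), collapse = ", "))
  }
  if (!nrow(per)) stop("no evaluable superfamilies", call. = FALSE)

  q <- per[per$in_Q, ]
  rd_terms <- (q$d_diff_mean - q$d_same_mean) / q$d_diff_mean
  if (any(!is.finite(rd_terms))) {
    warning("superfamily with zero between-family mean excluded from RD",
            call. = FALSE)
    rd_terms <- rd_terms[is.finite(rd_terms)]
  }
  structure(list(
    per_superfamily = per,
    RR = nrow(q) / nrow(per),
    RD = if (length(rd_terms)) mean(rd_terms) else NA_real_,
    alpha = alpha,
    n_evaluable = nrow(per),
    excluded = excluded
  ), class = "rrrd_report")
}

#' @export
print.rrrd_report <- function(x, ...) {
  cat(sprintf(
    "<rrrd_report> %d superfamilies evaluated (alpha = %g)\n  RR = %.4f (%d in Q)\n  RD = %.4f\n",
    x$n_evaluable, x$alpha, x$RR, sum(x$per_superfamily$in_Q), x$RD))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-superfamily rows of an RR/RD report
#' @param x An `rrrd_report`.
#' @param ... Unused.
#' @return Tibble, one row per evaluated superfamily.
#' @export
tidy.rrrd_report <- function(x, ...) x$per_superfamily

#' One-row summary of an RR/RD report
#' @param x An `rrrd_report`.
#' @param ... Unused.
#' @return One-row tibble with RR, RD, counts and alpha.
#' @export
glance.rrrd_report <- function(x, ...) {
  tibble::tibble(RR = x$RR, RD = x$RD, n_superfamilies = x$n_evaluable,
                 n_in_Q = sum(x$per_superfamily$in_Q),
                 n_excluded = length(x$excluded), alpha = x$alpha)
}

#' Chain-combined TM-score
#'
#' A TM-score depends on which chain normalizes it; the combined score
#' weights the two normalizations by the chain lengths,
#' `(n_i * tm_i + n_j * tm_j) / (n_i + n_j)`, so the result does not
#' depend on the chain order.
#'
#' @param tm_i,tm_j TM-scores normalized by chains i and j, in `[0, 1]`.
#' @param n_i,n_j Chain lengths (positive integers).
#' @return Combined TM-score(s) in `[0, 1]`. Vectorized.
#' @export
combine_tm <- function(tm_i, tm_j, n_i, n_j) {
  if (any(tm_i < 0 | tm_i > 1 | tm_j < 0 | tm_j > 1)) {
    stop("TM-scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_i <= 0 | n_j <= 0)) stop("chain lengths must be positive", call. = FALSE)
  (n_i * tm_i + n_j * tm_j) / (n_i + n_j)
}

#' TM-score length-normalization scale factor
#'
#' `d0(n) = 1.24 * (n - 15)^(1/3) - 1.8`, clamped below at 0.5 (the raw
#' expression goes negative for short chains; 0.5 is the customary floor).
#'
#' @param n Chain length(s), `n >= 1`.
#' @return Scale factor(s) in Angstroms. Vectorized.
#' @export
tm_d0 <- function(n) {
  stopifnot(all(n >= 1))
  x <- n - 15
  raw <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' Correlation between evolutionary distance and structural similarity
#'
#' Pools all pairs carrying a TM-score, computes the overall Pearson
#' correlation between distance and TM-score, and bins pairs into
#' equal-width TM-score bins on `[0, 1]` with the per-bin mean and
#' standard deviation of the distance.
#'
#' @param bench A [superfamily_bench()] with `tm_scores`.
#' @param n_bins Number of equal-width TM bins (default 10).
#' @return A `structure_correlation`: list with `overall_pearson` and
#'   `per_bin` tibble (bin bounds, n, mean and sd of distance; empty bins
#'   have `NA`).
#' @export
correlate_with_structure <- function(bench, n_bins = 10L) {
  if (is.null(bench$tm_scores)) stop("benchmark has no TM-scores", call. = FALSE)
  p <- bench_pairs(bench)
  p <- p[!is.na(p$tm), ]
  if (nrow(p) < 2L) stop("need at least 2 pairs with TM-scores", call. = FALSE)

  r <- if (sd(p$distance) == 0 || sd(p$tm) == 0) {
    message("constant distances or TM-scores; correlation undefined")
    NA_real_
  } else {
    cor(p$distance, p$tm, method = "pearson")
  }

  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin_of <- cut(p$tm, breaks = breaks, include.lowest = TRUE)
  bin_mean <- vapply(levels(bin_of), function(l) {
    d <- p$distance[bin_of == l]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  bin_sd <- vapply(levels(bin_of), function(l) {
    d <- p$distance[bin_of == l]
    if (length(d) > 1L) sd(d) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  per_bin <- tibble::tibble(
    bin = seq_len(n_bins),
    tm_lo = breaks[-length(breaks)],
    tm_hi = breaks[-1],
    n = as.integer(tabulate(bin_of, nbins = n_bins)),
    mean_distance = bin_mean,
    sd_distance = bin_sd
  )
  structure(list(overall_pearson = r, per_bin = per_bin, n_pairs = nrow(p)),
            class = "structure_correlation")
}

#' @export
print.structure_correlation <- function(x, ...) {
  cat(sprintf("<structure_correlation> %d pairs, overall Pearson r = %.4f\n",
              x$n_pairs, x$overall_pearson))
  invisible(x)
}

#' @rdname tidy.rrrd_report
#' @export
tidy.structure_correlation <- function(x, ...) x$per_bin

#' Closest non-self protein by distance
#'
#' The Top-1 remote homologue of a query: the non-self id minimizing the
#' distance, ties broken lexicographically.
#'
#' @param query_id Query id (must be in `dm`).
#' @param dm Labelled distance matrix with at least 2 taxa.
#' @return Single id.
#' @export
top1_homolog <- function(query_id, dm) {
  ids <- rownames(dm)
  stopifnot(length(ids) >= 2L, query_id %in% ids)
  d <- dm[query_id, setdiff(ids, query_id)]
  cand <- sort(names(d)[d == min(d)])
  cand[[1]]
}
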