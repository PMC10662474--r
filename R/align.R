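#' Alignment parameters
#'
#' Scoring and gap parameters of the feature-profile aligner. The
#' secondary-structure and accessibility match weights were characterized
#' over the range 1.0-2.0; defaults take the midpoint 1.5. Gap costs are
#' affine: a gap of length k costs `gap_open + (k-1)*gap_extend`.
#' Defaults `-1.0` / `-0.2` make one gap opening cost roughly half a
#' typical good site match (site scores live in `[0, 2 + omega1 + omega2]`).
#'
#' @param omega1 Secondary-structure match weight (default 1.5).
#' @param omega2 Accessibility match weight (default 1.5).
#' @param gap_open Gap opening penalty d, non-positive (default -1).
#' @param gap_extend Gap extension penalty e, non-positive with
#'   `|e| <= |d|` (default -0.2).
#' @param eps Lower clamp of the normalized score before the distance
#'   mapping; caps the distance at `(1/sqrt(eps) - 1)/2` (49.5 at 1e-4).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(omega1 = 1.5, omega2 = 1.5,
                             gap_open = -1.0, gap_extend = -0.2,
                             eps = 1e-4) {
  stopifnot(is.numeric(omega1), is.numeric(omega2),
            is.numeric(gap_open), is.numeric(gap_extend),
            eps > 0, eps <= 1)
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be non-positive", call. = FALSE)
  }
  if (abs(gap_extend) > abs(gap_open)) {
    stop("|gap_extend| must not exceed |gap_open|", call. = FALSE)
  }
  if (omega1 < 1 || omega1 > 2 || omega2 < 1 || omega2 > 2) {
    warning("omega weights outside the characterized 1.0-2.0 range",
            call. = FALSE)
  }
  structure(list(omega1 = omega1, omega2 = omega2,
                 gap_open = gap_open, gap_extend = gap_extend, eps = eps),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf(
    "<alignment_params> omega1=%g omega2=%g gap_open=%g gap_extend=%g eps=%g\n",
    x$omega1, x$omega2, x$gap_open, x$gap_extend, x$eps))
  invisible(x)
}

#' Score one pair of profile sites
#'
#' The site score is the dot product of the two 640-dimensional feature
#' vectors, plus `omega1` if the secondary-structure labels agree and
#' `omega2` if the accessibility labels agree. Bounded in
#' `[0, 2 + omega1 + omega2]` by the block-sum invariants.
#'
#' @param profA,profB [build_profile()] objects.
#' @param i,j 1-based site indices into `profA` / `profB`.
#' @param params [alignment_params()].
#' @return Scalar score.
#' @export
pair_score <- function(profA, i, profB, j, params = alignment_params()) {
  if (i < 1L || i > nrow(profA) || j < 1L || j > nrow(profB)) {
    stop("site index out of range", call. = FALSE)
  }
  sum(unclass(profA)[i, ] * unclass(profB)[j, ]) +
    params$omega1 * (attr(profA, "ss")[i] == attr(profB, "ss")[j]) +
    params$omega2 * (attr(profA, "acc")[i] == attr(profB, "acc")[j])
}

# All-vs-all site score matrix between two profiles (BLAS + indicator outer
# products); row i / column j equals pair_score(profA, i, profB, j, params).
profile_score_matrix <- function(profA, profB, params) {
  unclass(profA) %*% t(unclass(profB)) +
    params$omega1 * outer(attr(profA, "ss"), attr(profB, "ss"), "==") +
    params$omega2 * outer(attr(profA, "acc"), attr(profB, "acc"), "==")
}

# Gapless self-score: sum of diagonal site scores; upper-bounds any global
# alignment score against another profile of the same kind.
self_score <- function(prof, params) {
  sum(unclass(prof)^2) + nrow(prof) * (params$omega1 + params$omega2)
}

#' Global affine-gap alignment of two feature profiles
#'
#' Needleman-Wunsch/Gotoh three-matrix dynamic programming over the
#' site-score matrix, with affine gap penalty `d + (k-1)e` and end gaps
#' penalized like internal gaps. The optimal score is the maximum of the
#' three state matrices at the terminal cell; traceback tie-breaks are
#' fixed (match state preferred over gap-in-A over gap-in-B; gap opening
#' preferred over extension) so results are reproducible.
#'
#' @inheritParams pair_score
#' @param keep_alignment If `FALSE`, skip the traceback and return only
#'   the score (faster for all-vs-all matrices).
#' @return An `sd_alignment` list: `score`, `aligned_pairs` (k x 2 matrix
#'   of matched 1-based site indices), `gaps` (run-length tibble of the
#'   alignment operations), `params`.
#' @export
global_align <- function(profA, profB, params = alignment_params(),
                         keep_alignment = TRUE) {
  if (nrow(profA) == 0L || nrow(profB) == 0L) {
    stop("cannot align an empty profile", call. = FALSE)
  }
  S <- profile_score_matrix(profA, profB, params)
  res <- gotoh_align_cpp(S, params$gap_open, params$gap_extend,
                         keep_alignment)
  out <- list(score = res$score, params = params,
              ids = c(attr(profA, "id"), attr(profB, "id")))
  if (keep_alignment) {
    out$aligned_pairs <- res$pairs
    colnames(out$aligned_pairs) <- c("i", "j")
    r <- rle(strsplit(res$ops, "", fixed = TRUE)[[1]])
    out$gaps <- tibble::tibble(
      op = c(M = "match", X = "gap_in_B", Y = "gap_in_A")[r$values],
      length = r$lengths
    )
  }
  class(out) <- "sd_alignment"
  out
}

#' @export
print.sd_alignment <- function(x, ...) {
  cat("<sd_alignment> ", paste(x$ids, collapse = " vs "),
      sprintf(": score %.4f", x$score), sep = "")
  if (!is.null(x$distance)) {
    cat(sprintf(", normalized %.4f, distance %.4f",
                x$normalized_score, x$distance))
  }
  cat("\n")
  invisible(x)
}

#' Map a normalized alignment score to an evolutionary distance
#'
#' The normalized score S in (0, 1] measures closeness; the distance is
#' `D = (1/sqrt(S) - 1) / 2`, so S = 1 gives D = 0 and the clamp floor
#' `eps` caps D at `(1/sqrt(eps) - 1)/2`.
#'
#' @param s Normalized score(s).
#' @param eps Lower clamp (default 1e-4, capping D at 49.5).
#' @return Distance(s), non-negative.
#' @export
score_to_distance <- function(s, eps = 1e-4) {
  s <- pmin(pmax(s, eps), 1)
  (1 / sqrt(s) - 1) / 2
}

#' Evolutionary distance between two feature profiles
#'
#' Runs the global alignment, normalizes the raw score by the geometric
#' mean of the two gapless self-scores (which upper-bound any global
#' alignment score, so the normalized score lies in (0, 1] up to the
#' clamp), and maps it to a distance with [score_to_distance()].
#'
#' @inheritParams global_align
#' @return An `sd_alignment` with additional fields `self_scores`,
#'   `normalized_score`, `distance`.
#' @export
sd_distance <- function(profA, profB, params = alignment_params(),
                        keep_alignment = TRUE) {
  saa <- self_score(profA, params)
  sbb <- self_score(profB, params)
  if (saa <= 0 || sbb <= 0) {
    stop("degenerate profile: non-positive self-score", call. = FALSE)
  }
  aln <- global_align(profA, profB, params, keep_alignment)
  aln$self_scores <- c(saa, sbb)
  aln$normalized_score <- min(max(aln$score / sqrt(saa * sbb), params$eps), 1)
  aln$distance <- score_to_distance(aln$normalized_score, params$eps)
  aln
}

#' All-vs-all distance matrix and pair table
#'
#' Computes the profile distance for every unordered pair of records
#' (N(N-1)/2 alignments; each pair is aligned once, so the matrix is
#' symmetric by construction with a zero diagonal).
#'
#' `sd_pair_table()` returns the per-pair report as a tibble;
#' `distance_matrix()` returns the labelled symmetric matrix (the pair
#' table is attached as attribute `"pairs"`).
#'
#' @param records List of [protein_record()] objects with unique ids.
#' @param params [alignment_params()].
#' @return For `distance_matrix()`: N x N labelled numeric matrix. For
#'   `sd_pair_table()`: tibble with columns id_a, id_b, raw_score,
#'   self_score_a, self_score_b, normalized_score, distance.
#' @export
distance_matrix <- function(records, params = alignment_params()) {
  pt <- sd_pair_table(records, params)
  ids <- vapply(records, `[[`, character(1), "id")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(pt$id_a, pt$id_b)] <- pt$distance
  m[cbind(pt$id_b, pt$id_a)] <- pt$distance
  attr(m, "pairs") <- pt
  attr(m, "params") <- params
  m
}

#' @rdname distance_matrix
#' @export
sd_pair_table <- function(records, params = alignment_params()) {
  if (length(records) < 2L) stop("need at least 2 records", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  profs <- lapply(records, build_profile)
  idx <- utils::combn(length(ids), 2L)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    a <- idx[1L, k]; b <- idx[2L, k]
    r <- sd_distance(profs[[a]], profs[[b]], params, keep_alignment = FALSE)
    tibble::tibble(id_a = ids[a], id_b = ids[b], raw_score = r$score,
                   self_score_a = r$self_scores[1],
                   self_score_b = r$self_scores[2],
                   normalized_score = r$normalized_score,
                   distance = r$distance)
  })
  dplyr::bind_rows(rows)
}
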