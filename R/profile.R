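#' Adjacent-site pair-probability block (400 dimensions)
#'
#' Outer product of the amino-acid probability vectors of a site and its
#' right neighbour, flattened row-major over (residue at i, residue at
#' i+1): entry (a, b) sits at flat index `(a-1)*20 + b`. Encodes the joint
#' occurrence probability of a specific residue pair at adjacent sites.
#'
#' @param p_i,p_next Probability vectors of length 20 (each summing to 1
#'   within 1e-4).
#' @return Numeric vector of length 400 summing to 1.
#' @export
build_pair_block <- function(p_i, p_next) {
  check_prob_vector(p_i)
  check_prob_vector(p_next)
  as.vector(t(outer(p_i, p_next)))
}

#' Structure-intersection block (4 x 3 x 20 = 240 dimensions)
#'
#' Crosses the joint accessibility state of the adjacent pair (BB, BE, EB,
#' EE), the secondary-structure state of the site (H, E, C) and the site's
#' amino-acid probability vector. Exactly one 20-long slice is nonzero and
#' equals `p_i`; flat index of (acc-pair ap, ss s, residue a) is
#' `((ap-1)*3 + (s-1))*20 + a`.
#'
#' @param acc_i,acc_next Accessibility labels in B/E.
#' @param ss_i Secondary-structure label in H/E/C.
#' @param p_i Length-20 probability vector of the site.
#' @return Numeric vector of length 240 summing to 1.
#' @export
build_structure_block <- function(acc_i, acc_next, ss_i, p_i) {
  check_prob_vector(p_i)
  ai <- match(acc_i, ACC_ALPHABET)
  an <- match(acc_next, ACC_ALPHABET)
  si <- match(ss_i, SS_ALPHABET)
  if (anyNA(c(ai, an, si))) {
    stop("invalid structure label (acc in {B,E}, ss in {H,E,C}); got acc_i='",
         acc_i, "', acc_next='", acc_next, "', ss_i='", ss_i, "'", call. = FALSE)
  }
  ap <- (ai - 1L) * 2L + an            # 1..4 over BB, BE, EB, EE
  v <- numeric(240L)
  off <- ((ap - 1L) * 3L + (si - 1L)) * 20L
  v[(off + 1L):(off + 20L)] <- p_i
  v
}

check_prob_vector <- function(p, tol = 1e-4) {
  if (length(p) != 20L) stop("probability vector must have 20 components", call. = FALSE)
  if (any(p < 0)) stop("negative probability component", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("probability vector sums to ", format(sum(p)), ", not 1", call. = FALSE)
  }
  invisible(p)
}

#' Build the 640-dimensional per-site feature profile of a record
#'
#' Each site i is represented by the concatenation of its 400-dimensional
#' adjacent-pair probability block and its 240-dimensional
#' structure-intersection block, both built from site i and its right
#' neighbour i+1. The terminal site pairs with itself so the profile has
#' one site per residue and alignment coordinates map 1:1 to residues.
#' Every per-site vector therefore sums to 2 (each block sums to 1).
#'
#' @param rec A [protein_record()] of length at least 2.
#' @return A `feature_profile`: numeric L x 640 matrix with attributes
#'   `id`, `ss`, `acc` (per-site label vectors).
#' @export
build_profile <- function(rec) {
  stopifnot(inherits(rec, "protein_record"))
  L <- nchar(rec$sequence)
  if (L < 2L) stop("feature profile needs at least 2 sites (no adjacent pair)",
                   call. = FALSE)
  p <- rec$aa_probs
  ss_v <- strsplit(rec$ss, "", fixed = TRUE)[[1]]
  acc_v <- strsplit(rec$acc, "", fixed = TRUE)[[1]]
  nxt <- c(seq_len(L - 1L) + 1L, L)    # terminal site pairs with itself

  ai <- match(acc_v, ACC_ALPHABET)
  an <- ai[nxt]
  si <- match(ss_v, SS_ALPHABET)
  ap <- (ai - 1L) * 2L + an

  m <- matrix(0, L, 640L)
  for (i in seq_len(L)) {
    m[i, 1:400] <- as.vector(t(outer(p[i, ], p[nxt[i], ])))
    off <- 400L + ((ap[i] - 1L) * 3L + (si[i] - 1L)) * 20L
    m[i, (off + 1L):(off + 20L)] <- p[i, ]
  }
  structure(m, class = c("feature_profile", "matrix", "array"),
            id = rec$id, ss = ss_v, acc = acc_v)
}

#' @export
print.feature_profile <- function(x, ...) {
  cat("<feature_profile> ", attr(x, "id"), ": ", nrow(x),
      " sites x ", ncol(x), " dims\n", sep = "")
  invisible(x)
}

#' Dump a feature profile as plain text (one site per line, 640 floats)
#'
#' Debugging aid; not used by the pipeline.
#'
#' @param prof A `feature_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_text <- function(prof, path) {
  writeLines(apply(unclass(prof), 1L, function(r)
    paste(formatC(r, format = "g", digits = 8), collapse = " ")), path)
  invisible(path)
}
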