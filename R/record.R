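#' Protein record: sequence plus per-site raw features
#'
#' Bundles a protein sequence with its raw per-site features: 20
#' amino-acid occurrence probabilities (one row per residue, PSSM-derived),
#' a three-state secondary-structure label and a two-state solvent
#' accessibility label. These 20 + 1 + 2 = 23 raw feature dimensions per
#' site are the input to [build_profile()].
#'
#' @param id Single identifier string.
#' @param sequence Amino-acid sequence (string over the 20-letter alphabet).
#' @param aa_probs Numeric L x 20 matrix of per-site occurrence
#'   probabilities; rows are renormalized to sum to 1. Columns follow
#'   [AA_ALPHABET]. Defaults to one-hot rows on the observed residues.
#' @param ss Length-L string over H/E/C (default all "C").
#' @param acc Length-L string over B/E (default all "E").
#'
#' @return An object of class `protein_record`.
#' @examples
#' rec <- protein_record("p1", "ACDG")
#' dim(raw_features(rec))  # 4 x 23
#' @export
protein_record <- function(id, sequence,
                           aa_probs = NULL,
                           ss = NULL,
                           acc = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(letters)
  if (L == 0L) stop("empty sequence for record '", id, "'", call. = FALSE)
  idx <- aa_index(letters)

  if (is.null(aa_probs)) {
    aa_probs <- matrix(0, L, 20L)
    aa_probs[cbind(seq_len(L), idx)] <- 1
  }
  aa_probs <- as.matrix(aa_probs)
  if (nrow(aa_probs) != L || ncol(aa_probs) != 20L) {
    stop("aa_probs must be ", L, " x 20 for record '", id, "', got ",
         nrow(aa_probs), " x ", ncol(aa_probs), call. = FALSE)
  }
  if (any(aa_probs < 0)) stop("negative aa_probs for record '", id, "'", call. = FALSE)
  rs <- rowSums(aa_probs)
  if (any(rs <= 0)) stop("all-zero aa_probs row for record '", id, "'", call. = FALSE)
  aa_probs <- aa_probs / rs
  colnames(aa_probs) <- AA_ALPHABET

  ss <- if (is.null(ss)) strrep("C", L) else toupper(as.character(ss))
  acc <- if (is.null(acc)) strrep("E", L) else toupper(as.character(acc))
  ss_v <- strsplit(ss, "", fixed = TRUE)[[1]]
  acc_v <- strsplit(acc, "", fixed = TRUE)[[1]]
  if (length(ss_v) != L || length(acc_v) != L) {
    stop("sequence, ss and acc lengths disagree for record '", id, "' (",
         L, ", ", length(ss_v), ", ", length(acc_v), ")", call. = FALSE)
  }
  if (!all(ss_v %in% SS_ALPHABET)) {
    stop("invalid secondary-structure symbol(s) for record '", id, "': ",
         paste(unique(setdiff(ss_v, SS_ALPHABET)), collapse = ", "), call. = FALSE)
  }
  if (!all(acc_v %in% ACC_ALPHABET)) {
    stop("invalid accessibility symbol(s) for record '", id, "': ",
         paste(unique(setdiff(acc_v, ACC_ALPHABET)), collapse = ", "), call. = FALSE)
  }
  if (L < 50L || L > 500L) {
    warning("record '", id, "' has length ", L,
            "; the method was characterized on proteins of 50-500 residues",
            call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, aa_probs = aa_probs,
         ss = ss, acc = acc),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " residues\n", sep = "")
  cat("  seq: ", abbreviate_seq(x$sequence), "\n", sep = "")
  cat("  ss : ", abbreviate_seq(x$ss), "\n", sep = "")
  cat("  acc: ", abbreviate_seq(x$acc), "\n", sep = "")
  invisible(x)
}

abbreviate_seq <- function(s, n = 60L) {
  if (nchar(s) <= n) s else paste0(substr(s, 1L, n - 3L), "...")
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Raw 23-dimensional per-site feature matrix
#'
#' Exposes the raw feature representation of one site: the 20 amino-acid
#' occurrence probabilities, the secondary-structure state encoded as a
#' single integer dimension (H=1, E=2, C=3), and the two-state solvent
#' accessibility as a pair of indicator dimensions (buried, exposed).
#'
#' @param rec A [protein_record()].
#' @return Numeric L x 23 matrix.
#' @export
raw_features <- function(rec) {
  stopifnot(inherits(rec, "protein_record"))
  ss_v <- strsplit(rec$ss, "", fixed = TRUE)[[1]]
  acc_v <- strsplit(rec$acc, "", fixed = TRUE)[[1]]
  m <- cbind(
    rec$aa_probs,
    ss = match(ss_v, SS_ALPHABET),
    acc_B = as.numeric(acc_v == "B"),
    acc_E = as.numeric(acc_v == "E")
  )
  rownames(m) <- NULL
  m
}
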