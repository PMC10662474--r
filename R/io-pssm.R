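#' Read a PSI-BLAST ASCII PSSM into per-site probability rows
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue carrying the position, the residue letter, 20 log-odds integers,
#' 20 weighted observed percentages and two trailing per-site statistics.
#' The 20 percentage columns are taken as the amino-acid occurrence
#' probabilities: divided by 100 and renormalized row-wise. A row whose 20
#' percentages are all zero (PSI-BLAST emits these for positions with no
#' weighted observations) falls back to a one-hot vector on the observed
#' residue, keeping every row a valid probability vector.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence The protein sequence the PSSM belongs to; residue
#'   letters in the file must match it positionally.
#' @return Numeric L x 20 probability matrix, columns in [AA_ALPHABET]
#'   order, each row summing to 1.
#' @export
read_pssm <- function(path, sequence) {
  lines <- readLines(path, warn = FALSE)
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(letters)

  probs <- matrix(NA_real_, 0L, 20L)
  res_letters <- character(0)
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[k]]), "\\s+")[[1]]
    if (length(toks) < 2L) next
    if (!grepl("^[0-9]+$", toks[[1]])) next
    if (!grepl("^[A-Za-z]$", toks[[2]])) next
    # data row: pos, residue, 20 log-odds, 20 percentages, 2 statistics
    if (length(toks) != 44L) {
      stop("malformed PSSM row at line ", k, " of '", path, "': expected 44 ",
           "columns, found ", length(toks), call. = FALSE)
    }
    pct <- suppressWarnings(as.numeric(toks[23:42]))
    if (anyNA(pct)) {
      stop("non-numeric percentage column at line ", k, " of '", path, "'",
           call. = FALSE)
    }
    probs <- rbind(probs, pct)
    res_letters <- c(res_letters, toupper(toks[[2]]))
  }

  if (nrow(probs) != L) {
    stop("PSSM '", path, "' has ", nrow(probs), " rows but sequence has ",
         L, " residues", call. = FALSE)
  }
  if (!all(res_letters == letters)) {
    bad <- which(res_letters != letters)[1]
    stop("PSSM '", path, "' residue mismatch at position ", bad, ": file has '",
         res_letters[bad], "', sequence has '", letters[bad], "'", call. = FALSE)
  }

  probs <- probs / 100
  zero <- rowSums(probs) == 0
  if (any(zero)) {
    idx <- aa_index(letters[zero])
    probs[zero, ] <- 0
    probs[cbind(which(zero), idx)] <- 1
  }
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(NULL, AA_ALPHABET)
  probs
}

#' Write per-site probabilities as a PSI-BLAST-style ASCII PSSM
#'
#' Emits the `-out_ascii_pssm` layout that [read_pssm()] parses. Log-odds
#' columns are written as zeros (they are not consumed); percentage columns
#' are `round(100 * p)` per site. Used by the synthetic fixture generator
#' so the full file-based pipeline can run without PSI-BLAST.
#'
#' @param probs Numeric L x 20 probability matrix.
#' @param sequence Matching protein sequence.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(probs, sequence, path) {
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  stopifnot(nrow(probs) == length(letters), ncol(probs) == 20L)
  pct <- round(100 * probs / rowSums(probs))
  hdr <- paste(rep(sprintf("%3s", AA_ALPHABET), 2L), collapse = " ")
  rows <- vapply(seq_along(letters), function(i) {
    paste0(sprintf("%5d %s ", i, letters[i]),
           paste(sprintf("%3d", rep(0L, 20L)), collapse = " "), " ",
           paste(sprintf("%3d", pct[i, ]), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapless real matches to pseudocounts"),
    paste0("        ", hdr),
    rows,
    ""
  ), path)
  invisible(path)
}
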