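#' Validate a labelled distance matrix
#'
#' Distance matrices are plain numeric matrices with identical row and
#' column names (the taxon ids), zero diagonal and symmetry within
#' tolerance; this is the container consumed by [bionj_tree()] and the
#' benchmark statistics.
#'
#' @param m Numeric square matrix with dimnames.
#' @param tol Allowed asymmetry.
#' @return The matrix, symmetrized exactly (averaged with its transpose).
#' @export
validate_distance_matrix <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix is not square", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m))) {
    stop("distance matrix must carry row and column names", call. = FALSE)
  }
  if (!identical(ids, colnames(m))) {
    stop("row and column names disagree", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate ids in distance matrix", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite entries in distance matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop("distance matrix asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  if (any(abs(diag(m)) > tol)) stop("nonzero diagonal", call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write / read a square PHYLIP distance matrix
#'
#' Relaxed square PHYLIP layout: first line the taxon count, then one
#' whitespace-delimited row per taxon starting with its name. Names up to
#' 50 characters are kept verbatim (no 10-character truncation), since
#' SCOP-style identifiers exceed the strict limit; names must not contain
#' whitespace. Values are written with 10 significant digits so a
#' write/read round-trip is the identity within 1e-9.
#'
#' @param m Validated distance matrix (see [validate_distance_matrix()]).
#' @param path File path.
#' @return `write_phylip` returns `path` invisibly; `read_phylip` returns
#'   the labelled matrix.
#' @export
write_phylip <- function(m, path) {
  m <- validate_distance_matrix(m)
  ids <- rownames(m)
  if (any(grepl("\\s", ids))) stop("taxon ids must not contain whitespace", call. = FALSE)
  if (any(nchar(ids) > 50L)) stop("taxon ids longer than 50 characters", call. = FALSE)
  w <- max(nchar(ids)) + 2L
  rows <- vapply(seq_along(ids), function(i) {
    paste0(formatC(ids[i], width = -w),
           paste(formatC(m[i, ], format = "g", digits = 10), collapse = " "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 1L) stop("'", path, "': bad taxon count line", call. = FALSE)
  if (length(lines) < n + 1L) {
    stop("'", path, "': expected ", n, " taxon rows, found ",
         length(lines) - 1L, call. = FALSE)
  }
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    if (length(toks) != n + 1L) {
      stop("'", path, "' row ", i, ": expected name + ", n, " values, found ",
           length(toks) - 1L, " values", call. = FALSE)
    }
    ids[i] <- toks[[1]]
    m[i, ] <- as.numeric(toks[-1])
  }
  if (anyDuplicated(ids)) stop("'", path, "': duplicate taxon ids", call. = FALSE)
  dimnames(m) <- list(ids, ids)
  validate_distance_matrix(m)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector of uppercase sequences keyed by the first token of
#' each FASTA header.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids in '", path, "'", call. = FALSE)
  }
  seqs
}

#' Assemble protein records from FASTA + per-id PSSM and structure files
#'
#' File discovery is by naming convention: for each sequence id the PSSM is
#' `<pssm_dir>/<id>.pssm` and the structure table `<struct_dir>/<id>.ss.tsv`.
#'
#' @param fasta FASTA path.
#' @param pssm_dir Directory of per-id ASCII PSSM files.
#' @param struct_dir Directory of per-id structure tables.
#' @return List of [protein_record()] objects.
#' @export
read_protein_set <- function(fasta, pssm_dir, struct_dir) {
  seqs <- read_protein_fasta(fasta)
  pssm_paths <- file.path(pssm_dir, paste0(names(seqs), ".pssm"))
  ss_paths <- file.path(struct_dir, paste0(names(seqs), ".ss.tsv"))
  missing <- c(pssm_paths[!file.exists(pssm_paths)],
               ss_paths[!file.exists(ss_paths)])
  if (length(missing)) {
    stop("missing per-id input files:\n  ",
         paste(missing, collapse = "\n  "), call. = FALSE)
  }
  lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    probs <- read_pssm(pssm_paths[i], seqs[[i]])
    loc <- read_local_structure(ss_paths[i], seqs[[i]])
    protein_record(id, seqs[[i]], aa_probs = probs, ss = loc$ss, acc = loc$acc)
  })
}
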