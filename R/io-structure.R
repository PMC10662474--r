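#' Read per-residue secondary structure and accessibility predictions
#'
#' Reads a per-residue table with (at least) columns for position, residue,
#' three-state secondary structure (H/E/C) and relative accessible surface
#' area. Column names are matched case-insensitively against common
#' spellings (`pos`/`idx`/`#`, `aa`/`res`, `ss`, `rasa`/`asa`); a headerless
#' four-column table is read as (pos, aa, ss, rasa). rASA values may be
#' fractions or percentages: if any value exceeds 1.5 the column is treated
#' as percent and divided by 100. Residues with rASA strictly below 20% are
#' labelled B (buried), otherwise E (exposed).
#'
#' @param path Path to the table (whitespace- or tab-delimited).
#' @param sequence Protein sequence the predictions belong to; residues
#'   must match positionally.
#' @return List with `ss` and `acc`, both length-L strings.
#' @export
read_local_structure <- function(path, sequence) {
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(letters)

  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("[A-Za-z]{2}", first) || grepl("#", first, fixed = TRUE)
  df <- utils::read.table(path, header = has_header, comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(trimws(sub("^#\\s*", "", names(df))))
  find_col <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  if (has_header) {
    i_aa <- find_col(c("aa", "res", "residue"))
    i_ss <- find_col(c("ss", "sec", "ss3"))
    i_ra <- find_col(c("rasa", "asa", "rsa", "acc"))
    if (anyNA(c(i_aa, i_ss, i_ra))) {
      stop("'", path, "': could not locate aa/ss/rasa columns in header (",
           paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
  } else {
    if (ncol(df) < 4L) {
      stop("'", path, "': headerless structure table needs 4 columns ",
           "(pos, aa, ss, rasa)", call. = FALSE)
    }
    i_aa <- 2L; i_ss <- 3L; i_ra <- 4L
  }

  aa <- toupper(as.character(df[[i_aa]]))
  ss <- toupper(as.character(df[[i_ss]]))
  rasa <- suppressWarnings(as.numeric(df[[i_ra]]))

  if (nrow(df) != L) {
    stop("'", path, "' has ", nrow(df), " rows but sequence has ", L,
         " residues", call. = FALSE)
  }
  if (!all(aa == letters)) {
    bad <- which(aa != letters)[1]
    stop("'", path, "' residue mismatch at position ", bad, ": file has '",
         aa[bad], "', sequence has '", letters[bad], "'", call. = FALSE)
  }
  if (!all(ss %in% SS_ALPHABET)) {
    stop("'", path, "': unknown secondary-structure symbol(s): ",
         paste(unique(setdiff(ss, SS_ALPHABET)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(rasa)) stop("'", path, "': non-numeric rASA values", call. = FALSE)

  # unit auto-detection: percentages if anything exceeds 1.5
  if (any(rasa > 1.5)) rasa <- rasa / 100
  acc <- ifelse(rasa < RASA_BURIED_THRESHOLD, "B", "E")

  list(ss = paste(ss, collapse = ""), acc = paste(acc, collapse = ""))
}

#' Write a minimal per-residue structure table
#'
#' Four tab-separated columns (pos, aa, ss, rasa) with a header; the
#' format read back by [read_local_structure()].
#'
#' @param ss Length-L secondary-structure string (H/E/C).
#' @param rasa Numeric vector of rASA fractions in `[0, 1]`.
#' @param sequence Matching protein sequence.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_local_structure <- function(ss, rasa, sequence, path) {
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ss_v <- strsplit(ss, "", fixed = TRUE)[[1]]
  stopifnot(length(ss_v) == length(letters), length(rasa) == length(letters))
  df <- data.frame(pos = seq_along(letters), aa = letters, ss = ss_v,
                   rasa = sprintf("%.4f", rasa))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
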