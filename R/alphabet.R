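#' Amino-acid, secondary-structure and accessibility alphabets
#'
#' Column order of PSSM-derived probability vectors follows the PSI-BLAST
#' ASCII PSSM column order. Secondary structure is three-state
#' (H = helix, E = strand, C = coil); solvent accessibility is two-state
#' (B = buried, rASA < 20%; E = exposed).
#'
#' @format Character vectors.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname alphabets
#' @export
SS_ALPHABET <- c("H", "E", "C")

#' @rdname alphabets
#' @export
ACC_ALPHABET <- c("B", "E")

# rASA below this fraction => buried (strict less-than)
RASA_BURIED_THRESHOLD <- 0.20

aa_index <- function(aa) {
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}
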