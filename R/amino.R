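#' Standard amino-acid integer coding
#'
#' The package labels amino-acid types with integers 1--20 assigned
#' alphabetically by three-letter code (ALA = 1, ..., VAL = 20); 0 denotes
#' an absent C-alpha or a non-standard residue. The mapping is exposed so
#' downstream consumers of amino-type masks can decode them.
#'
#' @return `amino_codes()` returns a named integer vector mapping
#'   three-letter residue codes to 1--20.
#' @examples
#' amino_codes()[["GLY"]]  # 8
#' @export
amino_codes <- function() {
  stats::setNames(seq_along(.AA3), .AA3)
}

.AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' @rdname amino_codes
#' @param code integer vector of amino codes in 0--20.
#' @return `amino_three_letter()` / `amino_one_letter()` return character
#'   vectors; code 0 maps to `"UNK"` / `"X"`.
#' @export
amino_three_letter <- function(code) {
  stopifnot(all(code >= 0 & code <= 20))
  out <- rep("UNK", length(code))
  out[code > 0] <- .AA3[code[code > 0]]
  out
}

#' @rdname amino_codes
#' @export
amino_one_letter <- function(code) {
  stopifnot(all(code >= 0 & code <= 20))
  out <- rep("X", length(code))
  out[code > 0] <- .AA1[code[code > 0]]
  out
}

#' @rdname amino_codes
#' @param letters character vector of one-letter residue codes.
#' @return `amino_from_one_letter()` returns integer codes (0 for unknown
#'   letters).
#' @export
amino_from_one_letter <- function(letters) {
  idx <- match(toupper(letters), .AA1)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Background amino-acid frequencies
#'
#' Default background distribution used for HMM emissions and for drawing
#' synthetic sequences. Uniform 1/20 unless overridden with a user table
#' (e.g. frequencies estimated from a sequence database).
#'
#' @param freqs optional numeric vector of length 20 (any positive scale;
#'   it is renormalized). Names, if present, must match the three-letter
#'   codes of [amino_codes()].
#' @return numeric vector of length 20 summing to 1, named by three-letter
#'   code.
#' @export
background_frequencies <- function(freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- rep(1 / 20, 20)
  }
  if (length(freqs) != 20 || any(!is.finite(freqs)) || any(freqs < 0) ||
      sum(freqs) <= 0) {
    stop("`freqs` must be 20 nonnegative finite values with positive sum")
  }
  if (!is.null(names(freqs))) {
    if (!setequal(names(freqs), .AA3)) {
      stop("names of `freqs` must be the 20 standard three-letter codes")
    }
    freqs <- freqs[.AA3]
  }
  stats::setNames(as.numeric(freqs) / sum(freqs), .AA3)
}
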