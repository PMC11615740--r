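#' The canonical amino-acid alphabet
#'
#' All L x 20 matrices in this package (one-hot encodings, likelihood
#' matrices, column-frequency tables) order their columns by the fixed
#' alphabetical one-letter code `"ACDEFGHIKLMNPQRSTVWY"`. The gap symbol
#' `"-"` is not part of this alphabet; where a 21-state encoding is needed
#' (Hamming distances, mutual information) the gap is appended as state 21.
#'
#' @return Character vector of the 20 canonical one-letter codes, in the
#'   fixed column order.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# gap symbol used throughout after canonicalization
.gap <- "-"

# fast lookup table: raw byte -> index 1..20, NA otherwise
.aa_lookup <- local({
  tab <- rep(NA_integer_, 256)
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (k in seq_along(alpha)) tab[utf8ToInt(alpha[k])] <- k
  tab
})

#' Map amino-acid letters to canonical column indices
#'
#' `aa_index()` returns, for each canonical residue letter, its 1-based
#' column index in the fixed alphabet [aa_alphabet()]; `aa_from_index()` is
#' the inverse. The mapping is a bijection on the 20 canonical letters.
#'
#' @param residue Character vector of single uppercase amino-acid letters.
#' @param index Integer vector with values in `1:20`.
#' @return `aa_index()`: integer vector in `1:20`; `aa_from_index()`:
#'   character vector of residue letters.
#' @examples
#' aa_index("A")        # 1
#' aa_index("Y")        # 20
#' aa_from_index(1:3)   # "A" "C" "D"
#' @export
aa_index <- function(residue) {
  idx <- .aa_lookup[utf8ToInt(paste0(residue, collapse = ""))]
  if (anyNA(idx)) {
    bad <- residue[is.na(idx)][1L]
    stop("not a canonical amino-acid letter: '", bad, "'", call. = FALSE)
  }
  idx
}

#' @rdname aa_index
#' @export
aa_from_index <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > 20L)) {
    stop("index must be in 1..20", call. = FALSE)
  }
  aa_alphabet()[index]
}

# split a sequence string into a character vector of single letters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# encode a sequence string as integers: 1..20 canonical, 21 gap
# (used by Hamming distance and mutual information, where the gap is a
# 21st symbol)
.encode21 <- function(s) {
  v <- .aa_lookup[utf8ToInt(s)]
  v[is.na(v)] <- 21L
  v
}
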