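#' Select the highest-probability contact pairs
#'
#' Ranks the unordered off-diagonal position pairs of a contact map by
#' probability, descending, and returns the top `n_pairs`. Each pair is
#' reported once with `i < j`; ties are broken by `(i, j)` ascending. No
#' minimum sequence-separation filter is applied (sequence-adjacent pairs
#' are legitimate design sites).
#'
#' @param cmap A symmetric `L x L` contact map (values in `[0, 1]`).
#' @param n_pairs Number of pairs to keep, default `1000`. If more pairs are
#'   requested than exist, all `L(L-1)/2` pairs are returned.
#' @return A data frame with columns `i`, `j` (1-based positions, `i < j`)
#'   and `probability`, sorted by probability descending.
#' @export
select_top_pairs <- function(cmap, n_pairs = 1000L) {
  if (!is.matrix(cmap) || nrow(cmap) != ncol(cmap)) {
    stop("cmap must be a square matrix", call. = FALSE)
  }
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) {
    stop("n_pairs must be a positive integer", call. = FALSE)
  }
  L <- nrow(cmap)
  ut <- which(upper.tri(cmap), arr.ind = TRUE)
  p <- cmap[ut]
  ord <- order(-p, ut[, 1L], ut[, 2L])
  ord <- ord[seq_len(min(n_pairs, length(ord)))]
  data.frame(i = ut[ord, 1L], j = ut[ord, 2L], probability = p[ord],
             row.names = NULL)
}

#' Enumerate saturation double mutations at a contact pair
#'
#' All `20 x 20` residue combinations at positions `(i, j)` of the query
#' except the double-wild-type combination: exactly 399 candidates per pair.
#' Same-residue substitutions at one of the two positions are included, so
#' candidates of the shape `H287H/Q288Y` — wild type retained at one
#' position — are part of every scan. Order is deterministic: the residue at
#' `i`, then the residue at `j`, each in alphabet order.
#'
#' Labels use 1-based positions in slash notation,
#' `"<wt_i><i><aa_i>/<wt_j><j><aa_j>"`, e.g. `"F237R/S240G"`.
#'
#' @param query Gap-free query sequence string.
#' @param i,j 1-based positions with `i < j`.
#' @return A data frame with columns `i`, `j`, `wt_i`, `wt_j`, `aa_i`,
#'   `aa_j`, `label`; 399 rows. `NULL` (with a warning) if a wild-type
#'   residue at `i` or `j` is not canonical, so a scan can skip the pair and
#'   continue.
#' @export
enumerate_double_mutants <- function(query, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  L <- nchar(query)
  if (is.na(i) || is.na(j) || i < 1L || j > L || i >= j) {
    stop("need 1 <= i < j <= ", L, call. = FALSE)
  }
  wt_i <- substr(query, i, i)
  wt_j <- substr(query, j, j)
  alpha <- aa_alphabet()
  if (!(wt_i %in% alpha) || !(wt_j %in% alpha)) {
    warning("wild-type residue at pair (", i, ", ", j,
            ") is not canonical; pair skipped", call. = FALSE)
    return(NULL)
  }
  grid <- expand.grid(aa_j = alpha, aa_i = alpha,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder columns so aa_i is
  # the outer (slower) index: alphabet order in aa_i, then aa_j
  grid <- grid[, c("aa_i", "aa_j")]
  keep <- !(grid$aa_i == wt_i & grid$aa_j == wt_j)
  grid <- grid[keep, , drop = FALSE]
  data.frame(
    i = i, j = j, wt_i = wt_i, wt_j = wt_j,
    aa_i = grid$aa_i, aa_j = grid$aa_j,
    label = paste0(wt_i, i, grid$aa_i, "/", wt_j, j, grid$aa_j),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Apply a double mutation to the query sequence
#'
#' @param query Gap-free query sequence string.
#' @param i,j 1-based positions.
#' @param aa_i,aa_j Replacement residues (canonical letters; a residue equal
#'   to the wild type leaves that position unchanged).
#' @return The mutated sequence string; same length as `query`.
#' @examples
#' apply_mutant("FS", 1, 2, "A", "G")  # "AG"
#' @export
apply_mutant <- function(query, i, j, aa_i, aa_j) {
  L <- nchar(query)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || i > L || j < 1L || j > L) {
    stop("mutation position out of range", call. = FALSE)
  }
  stopifnot(aa_i %in% aa_alphabet(), aa_j %in% aa_alphabet())
  substr(query, i, i) <- aa_i
  substr(query, j, j) <- aa_j
  query
}
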