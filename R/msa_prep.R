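#' Gap ratio of an aligned sequence
#'
#' Fraction of alignment columns occupied by the gap symbol `"-"`.
#'
#' @param seq A single aligned sequence string (canonicalized).
#' @return A fraction in `[0, 1]`.
#' @examples
#' gap_ratio("A-C-")  # 0.5
#' @export
gap_ratio <- function(seq) {
  L <- nchar(seq)
  if (length(seq) != 1L || is.na(L) || L == 0L) {
    stop("seq must be a single non-empty sequence string", call. = FALSE)
  }
  (L - nchar(gsub("-", "", seq, fixed = TRUE))) / L
}

#' Remove high-gap sequences from an alignment
#'
#' Drops every non-query record whose gap ratio strictly exceeds
#' `max_gap_ratio`; a record exactly at the threshold is kept. The query is
#' always retained (the pipeline cannot proceed without it), input order is
#' preserved, and the operation is idempotent.
#'
#' @param x An [msa] object.
#' @param max_gap_ratio Maximum tolerated gap fraction, default `0.15`.
#' @return A filtered [msa]. If everything but the query is removed, a
#'   query-only alignment is returned with a warning.
#' @export
filter_by_gap <- function(x, max_gap_ratio = 0.15) {
  stopifnot(inherits(x, "msa"))
  if (!is.numeric(max_gap_ratio) || max_gap_ratio < 0 || max_gap_ratio > 1) {
    stop("max_gap_ratio must be in [0, 1]", call. = FALSE)
  }
  ratios <- vapply(x$seqs, gap_ratio, 0, USE.NAMES = FALSE)
  keep <- ratios <= max_gap_ratio
  keep[x$query] <- TRUE
  if (sum(keep) == 1L && x$depth > 1L) {
    warning("gap filtering removed every non-query sequence",
            call. = FALSE)
  }
  msa(x$ids[keep], x$seqs[keep], query = match(x$query, which(keep)))
}

#' Hamming distance between two aligned sequences
#'
#' Counts columns where the symbols differ. The gap is treated as a 21st
#' symbol: it mismatches every amino acid and matches another gap.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return Non-negative integer count of differing columns.
#' @examples
#' hamming_distance("A-C", "AAC")  # 1
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  sum(.encode21(a) != .encode21(b))
}

#' Greedy diversity-maximizing subsampling of an alignment
#'
#' Deterministic greedy max-min selection of a fixed-size sequence context:
#' the selection starts with the query; each step adds the record that
#' maximizes the minimum Hamming distance ([hamming_distance()]) to the
#' already-selected set, until `context_size` records are chosen or the pool
#' is exhausted. Ties are broken by original record order, so the result is
#' reproducible without a random seed.
#'
#' @param x An [msa] object.
#' @param context_size Number of records to select, default `64`.
#' @return An [msa] with the query first and the remaining records in
#'   selection order.
#' @export
subsample_diverse <- function(x, context_size = 64L) {
  stopifnot(inherits(x, "msa"))
  context_size <- as.integer(context_size)
  if (is.na(context_size) || context_size < 1L) {
    stop("context_size must be a positive integer", call. = FALSE)
  }
  n <- x$depth
  codes <- .msa_codes(x)
  selected <- x$query
  remaining <- setdiff(seq_len(n), x$query)
  # min distance of every remaining record to the selected set
  mind <- rep(Inf, n)
  last <- x$query
  while (length(selected) < min(context_size, n)) {
    d <- rowSums(codes[remaining, , drop = FALSE] !=
                 rep(codes[last, ], each = length(remaining)))
    mind[remaining] <- pmin(mind[remaining], d)
    pick <- remaining[which.max(mind[remaining])]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    last <- pick
    if (length(remaining) == 0L) break
  }
  msa(x$ids[selected], x$seqs[selected], query = 1L)
}
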