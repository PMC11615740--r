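#' Simulate an alignment with planted inter-column couplings
#'
#' Generates a synthetic protein multiple sequence alignment in which
#' selected column pairs co-vary, so that contact estimation, pair
#' selection, and scoring can be exercised end to end with known ground
#' truth and no external database.
#'
#' Sampling model: each planted pair `(i, j)` is assigned a two-state
#' coupled table `{(A1, B1), (A2, B2)}` with `A1 != A2` and `B1 != B2`,
#' the two states equiprobable (so at coupling 1 and no gaps the mutual
#' information of the pair is exactly `log(2)`). The query is drawn
#' gap-free from the background composition with every planted pair set to
#' its primary state `(A1, B1)`. Each homolog draws uncoupled columns
#' independently from the background; at each planted pair it draws, with
#' probability `coupling`, one of the two coupled states, and otherwise two
#' independent background residues. Gaps then overwrite homolog symbols
#' independently with probability `gap_rate`. Output is fully reproducible
#' from `seed`.
#'
#' @param length Number of alignment columns `L`.
#' @param depth Number of sequences including the query.
#' @param pairs Data frame with columns `i`, `j` (1-based, `i < j`) and
#'   `coupling` in `[0, 1]`; positions must be disjoint across pairs.
#'   `NULL` for no planted signal.
#' @param background Length-20 vector of residue probabilities in alphabet
#'   order; default uniform. Normalized internally.
#' @param gap_rate Per-cell gap probability in `[0, 1)` applied to
#'   homologs, default `0`.
#' @param seed Integer seed; required for reproducible output.
#' @return A list with elements `msa` (an [msa], query first) and `truth`
#'   (data frame `i`, `j`, `coupling`, `a1`, `b1`, `a2`, `b2` recording the
#'   planted states).
#' @examples
#' sim <- simulate_msa(20, 64, data.frame(i = 3, j = 11, coupling = 0.9),
#'                     seed = 1)
#' sim$truth
#' @export
simulate_msa <- function(length, depth, pairs = NULL,
                         background = rep(1 / 20, 20),
                         gap_rate = 0, seed = NULL) {
  L <- as.integer(length)
  depth <- as.integer(depth)
  if (is.na(L) || L < 1L || is.na(depth) || depth < 1L) {
    stop("length and depth must be positive integers", call. = FALSE)
  }
  if (!is.numeric(background) || base::length(background) != 20L ||
      any(background < 0) || sum(background) <= 0) {
    stop("background must be 20 non-negative probabilities", call. = FALSE)
  }
  background <- background / sum(background)
  if (!is.numeric(gap_rate) || gap_rate < 0 || gap_rate >= 1) {
    stop("gap_rate must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("i", "j", "coupling") %in% names(pairs)))
    if (any(pairs$i >= pairs$j) || any(pairs$i < 1L) || any(pairs$j > L)) {
      stop("planted pairs must satisfy 1 <= i < j <= L", call. = FALSE)
    }
    pos <- c(pairs$i, pairs$j)
    if (anyDuplicated(pos)) {
      stop("planted pairs must occupy disjoint positions", call. = FALSE)
    }
    if (any(pairs$coupling < 0) || any(pairs$coupling > 1)) {
      stop("coupling must be in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  alpha <- aa_alphabet()
  npairs <- if (is.null(pairs)) 0L else nrow(pairs)
  # per-pair two-state coupled tables, equal marginals
  truth <- if (npairs > 0L) {
    a <- t(vapply(seq_len(npairs), function(k) sample(20L, 2L), integer(2)))
    b <- t(vapply(seq_len(npairs), function(k) sample(20L, 2L), integer(2)))
    data.frame(i = as.integer(pairs$i), j = as.integer(pairs$j),
               coupling = pairs$coupling,
               a1 = alpha[a[, 1L]], b1 = alpha[b[, 1L]],
               a2 = alpha[a[, 2L]], b2 = alpha[b[, 2L]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(), j = integer(), coupling = numeric(),
               a1 = character(), b1 = character(),
               a2 = character(), b2 = character())
  }
  # background sampling for the full matrix, then overwrite planted pairs
  mat <- matrix(sample(alpha, depth * L, replace = TRUE, prob = background),
                nrow = depth, ncol = L)
  if (npairs > 0L) {
    for (k in seq_len(npairs)) {
      i <- truth$i[k]; j <- truth$j[k]; cpl <- truth$coupling[k]
      coupled <- stats::runif(depth) < cpl
      state2 <- sample(c(FALSE, TRUE), depth, replace = TRUE)
      mat[coupled & !state2, i] <- truth$a1[k]
      mat[coupled & !state2, j] <- truth$b1[k]
      mat[coupled & state2, i] <- truth$a2[k]
      mat[coupled & state2, j] <- truth$b2[k]
      # uncoupled rows keep their independent background draws
    }
    # query: primary coupled state at every planted pair
    mat[1L, truth$i] <- truth$a1
    mat[1L, truth$j] <- truth$b1
  }
  if (gap_rate > 0 && depth > 1L) {
    hom <- 2:depth
    gaps <- matrix(stats::runif(base::length(hom) * L) < gap_rate,
                   nrow = base::length(hom))
    sub <- mat[hom, , drop = FALSE]
    sub[gaps] <- "-"
    mat[hom, ] <- sub
  }
  seqs <- apply(mat, 1L, paste0, collapse = "")
  ids <- c("query", sprintf("synth_%04d", seq_len(depth - 1L) + 0L))
  ids <- ids[seq_len(depth)]
  list(msa = msa(ids, seqs, query = 1L), truth = truth)
}

#' Precision and recall of planted-pair recovery
#'
#' Compares the top `k` selected position pairs against the planted truth.
#' Pairs are matched as unordered position pairs.
#'
#' @param selected Data frame with columns `i`, `j` (e.g. from
#'   [select_top_pairs()]), ranked best first.
#' @param truth Truth data frame from [simulate_msa()] (columns `i`, `j`).
#' @param k Number of top selected pairs to evaluate.
#' @return A list with `precision` (= hits / k) and `recall`
#'   (= hits / number of planted pairs), both in `[0, 1]`.
#' @export
recovery_metrics <- function(selected, truth, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (nrow(truth) == 0L) stop("truth contains no planted pairs",
                              call. = FALSE)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  top <- utils::head(selected, k)
  hits <- sum(key(top$i, top$j) %in% key(truth$i, truth$j))
  list(precision = hits / k, recall = hits / nrow(truth))
}
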