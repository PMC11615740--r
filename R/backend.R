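#' Per-column amino-acid frequencies with Laplace smoothing
#'
#' For column `i` and amino acid `a`,
#' `p(i, a) = (count(i, a) + pseudocount) / (n_i + 20 * pseudocount)`,
#' where `n_i` is the number of non-gap symbols in column `i`. Gaps
#' contribute to neither numerator nor denominator. A column consisting
#' entirely of gaps falls back to the uniform row `1/20` with a warning.
#'
#' @param x An [msa] object.
#' @param pseudocount Positive smoothing constant, default `1` (Laplace).
#' @return An `L x 20` matrix of probabilities; every row sums to 1.
#'   Columns are ordered by [aa_alphabet()].
#' @export
column_frequencies <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "msa"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  codes <- .msa_codes(x)
  counts <- matrix(0L, nrow = x$L, ncol = 20L,
                   dimnames = list(NULL, aa_alphabet()))
  for (i in seq_len(x$L)) {
    counts[i, ] <- tabulate(codes[, i][codes[, i] <= 20L], nbins = 20L)
  }
  n <- rowSums(counts)
  if (any(n == 0L)) {
    warning("column(s) ", paste(which(n == 0L), collapse = ", "),
            " contain only gaps; using uniform frequencies", call. = FALSE)
  }
  p <- (counts + pseudocount) / (n + 20 * pseudocount)
  p
}

#' Baseline per-position likelihood matrix
#'
#' The default implementation of the scoring contract's likelihood method:
#' the natural log of the smoothed column frequencies of the context
#' alignment. It does not depend on `variant_sequence` (a deliberate,
#' documented property of this backend; a sequence-conditioned backend such
#' as an alignment-conditioned language model may differ). Every row is a
#' normalized log-probability vector: `logsumexp(row) = 0`.
#'
#' @param variant_sequence A gap-free sequence string of the context's
#'   length (checked; unused beyond validation).
#' @param context An [msa] providing the evolutionary context.
#' @param pseudocount Positive smoothing constant, default `1`.
#' @return An `L x 20` matrix of log-probabilities (class
#'   `likelihood_matrix`), columns ordered by [aa_alphabet()].
#' @export
baseline_likelihoods <- function(variant_sequence, context, pseudocount = 1) {
  stopifnot(inherits(context, "msa"))
  if (nchar(variant_sequence) != context$L) {
    stop("variant sequence length (", nchar(variant_sequence),
         ") does not match alignment length (", context$L, ")",
         call. = FALSE)
  }
  m <- log(column_frequencies(context, pseudocount))
  structure(m, class = c("likelihood_matrix", class(m)))
}

#' Mutual information between alignment columns
#'
#' Empirical mutual information
#' `MI(i, j) = sum_ab p(a, b) * log(p(a, b) / (p(a) p(b)))`
#' over the symbol pairs observed in columns `i` and `j`, with the gap
#' treated as a 21st symbol and no pseudocount. The diagonal is set to 0.
#' Used as the default covariation signal behind the contact-map estimate.
#'
#' @param x An [msa] with depth >= 2 and at least 2 columns.
#' @return A symmetric `L x L` matrix of non-negative values with zero
#'   diagonal.
#' @export
mutual_information <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (x$depth < 2L) stop("mutual information needs depth >= 2",
                         call. = FALSE)
  if (x$L < 2L) stop("mutual information needs at least 2 columns",
                     call. = FALSE)
  codes <- .msa_codes(x)
  n <- x$depth
  L <- x$L
  # per-column marginal counts over the 21 states
  marg <- lapply(seq_len(L), function(i) tabulate(codes[, i], nbins = 21L))
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ci <- codes[, i]
    pi_ <- marg[[i]] / n
    for (j in (i + 1L):L) {
      joint <- tabulate((ci - 1L) * 21L + codes[, j], nbins = 21L * 21L) / n
      pj <- marg[[j]] / n
      pij <- joint[joint > 0]
      idx <- which(joint > 0)
      a <- ((idx - 1L) %/% 21L) + 1L
      b <- ((idx - 1L) %% 21L) + 1L
      val <- sum(pij * log(pij / (pi_[a] * pj[b])))
      mi[i, j] <- mi[j, i] <- max(val, 0)
    }
  }
  mi
}

#' Average-product correction and contact-map normalization
#'
#' Applies the standard background correction for covariation-based contact
#' estimates, `corrected(i, j) = raw(i, j) - rowmean(i) * rowmean(j) /
#' grandmean`, with row and grand means taken over off-diagonal entries,
#' then min-max rescales the off-diagonal entries into `[0, 1]` so the
#' result satisfies the contact-map range invariant (rescaling preserves the
#' ranking, which is the only property pair selection consumes). A constant
#' input (or zero grand mean) yields the all-zero map with a warning where
#' degenerate.
#'
#' @param raw A symmetric `L x L` matrix with zero diagonal.
#' @return A `contact_map`: symmetric `L x L` matrix in `[0, 1]`, zero
#'   diagonal.
#' @export
apc_correct <- function(raw) {
  if (!is.matrix(raw) || nrow(raw) != ncol(raw)) {
    stop("raw must be a square matrix", call. = FALSE)
  }
  L <- nrow(raw)
  if (max(abs(raw - t(raw))) > 1e-8) {
    stop("raw matrix must be symmetric", call. = FALSE)
  }
  diag(raw) <- 0
  off <- row(raw) != col(raw)
  if (L < 2L) return(.contact_map(matrix(0, L, L)))
  rowmean <- rowSums(raw) / (L - 1L)  # diagonal is zero
  grandmean <- sum(raw[off]) / (L * (L - 1L))
  if (grandmean == 0) {
    warning("zero grand mean; returning all-zero contact map",
            call. = FALSE)
    return(.contact_map(matrix(0, L, L)))
  }
  corr <- raw - outer(rowmean, rowmean) / grandmean
  diag(corr) <- 0
  lo <- min(corr[off]); hi <- max(corr[off])
  if (hi - lo == 0) {
    corr[] <- 0
  } else {
    corr <- (corr - lo) / (hi - lo)
  }
  diag(corr) <- 0
  corr <- (corr + t(corr)) / 2
  .contact_map(corr)
}

.contact_map <- function(m) {
  structure(m, class = c("contact_map", class(m)))
}

#' The bundled deterministic scoring backend
#'
#' A scoring backend bundles the two model-facing estimates the pipeline
#' needs: a contact map given an alignment, and a per-position likelihood
#' matrix given a (possibly mutated) sequence and its alignment context.
#' The baseline backend is dependency-free and fully deterministic: contact
#' maps are mutual information ([mutual_information()]) with average-product
#' correction ([apc_correct()]); likelihoods are smoothed log column
#' frequencies ([baseline_likelihoods()]), independent of the variant
#' sequence.
#'
#' External backends (e.g. an alignment-conditioned protein language model)
#' plug in by supplying the same contract: a list with fields `name`
#' (character), `deterministic` (flag), `sequence_dependent` (flag:
#' whether `likelihoods` depends on its first argument), and functions
#' `contact_map(msa)` and `likelihoods(variant_sequence, context)`.
#'
#' @param pseudocount Positive smoothing constant for the likelihoods,
#'   default `1`.
#' @return A list implementing the scoring-backend contract, class
#'   `scoring_backend`.
#' @examples
#' b <- baseline_backend()
#' b$name
#' @export
baseline_backend <- function(pseudocount = 1) {
  structure(
    list(
      name = "baseline",
      deterministic = TRUE,
      sequence_dependent = FALSE,
      contact_map = function(msa) apc_correct(mutual_information(msa)),
      likelihoods = function(variant_sequence, context) {
        baseline_likelihoods(variant_sequence, context, pseudocount)
      }
    ),
    class = "scoring_backend"
  )
}
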