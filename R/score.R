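#' One-hot encoding of a protein sequence
#'
#' Encodes a gap-free sequence as an `L x 20` indicator matrix: row `i`
#' carries a single 1 in the column of the residue at position `i`
#' (columns ordered by [aa_alphabet()]).
#'
#' @param sequence Gap-free, canonical sequence string.
#' @return An `L x 20` matrix of 0/1 with exactly one 1 per row.
#' @export
one_hot <- function(sequence) {
  v <- .aa_lookup[utf8ToInt(sequence)]
  if (anyNA(v)) {
    pos <- which(is.na(v))[1L]
    stop("non-canonical symbol '", substr(sequence, pos, pos),
         "' at position ", pos, call. = FALSE)
  }
  L <- length(v)
  oh <- matrix(0L, nrow = L, ncol = 20L,
               dimnames = list(NULL, aa_alphabet()))
  oh[cbind(seq_len(L), v)] <- 1L
  oh
}

#' Hamiltonian score of a sequence under a likelihood matrix
#'
#' The negative log-likelihood score
#' `H(s) = -sum_i sum_j oh[i, j] * M[i, j]`, where `oh` is the one-hot
#' encoding of the sequence and `M` holds per-position log-probabilities.
#' Because the one-hot matrix selects one entry per row, this is
#' `-sum_i M[i, aa_index(s[i])]`. Lower values indicate a sequence the
#' evolutionary context considers more likely, interpreted here as more
#' thermostable.
#'
#' @param sequence Gap-free, canonical sequence string of length `L`.
#' @param m An `L x 20` matrix of log-probabilities (e.g. from
#'   [baseline_likelihoods()]).
#' @return A single non-negative number (given log-probabilities <= 0).
#' @examples
#' m <- matrix(log(1 / 20), nrow = 3, ncol = 20)
#' hamiltonian("MKV", m)  # 3 * log(20)
#' @export
hamiltonian <- function(sequence, m) {
  if (!is.matrix(m) || ncol(m) != 20L) {
    stop("m must be an L x 20 matrix", call. = FALSE)
  }
  v <- .aa_lookup[utf8ToInt(sequence)]
  if (anyNA(v)) {
    stop("sequence contains gap or non-canonical symbols", call. = FALSE)
  }
  if (length(v) != nrow(m)) {
    stop("sequence length (", length(v), ") does not match matrix rows (",
         nrow(m), ")", call. = FALSE)
  }
  -sum(m[cbind(seq_along(v), v)])
}

#' Score double mutants with a backend's Hamiltonian
#'
#' For each candidate, applies the mutation to the query
#' ([apply_mutant()]), obtains the likelihood matrix from the backend for
#' the mutated sequence in its alignment context, and computes the
#' Hamiltonian plus its difference from the wild-type Hamiltonian (the
#' wild-type reference uses the likelihood matrix of the unmutated query,
#' so the delta is meaningful for sequence-dependent backends too).
#'
#' With a variant-independent backend (`sequence_dependent = FALSE`, as the
#' baseline), the likelihood matrix is computed once and the per-mutant
#' Hamiltonian follows from the exact two-position decomposition
#' `H(mut) = H(wt) - (M[i, aa_i] - M[i, wt_i]) - (M[j, aa_j] - M[j, wt_j])`.
#'
#' @param query Gap-free query sequence string.
#' @param mutants Data frame of candidates as produced by
#'   [enumerate_double_mutants()] (columns `i`, `j`, `wt_i`, `wt_j`,
#'   `aa_i`, `aa_j`, `label`).
#' @param context The [msa] context handed to the backend.
#' @param backend A scoring backend, default [baseline_backend()].
#' @return The `mutants` data frame with columns `hamiltonian` and
#'   `delta_vs_wildtype` appended, plus attributes `wt_hamiltonian` and
#'   `backend`.
#' @export
score_variants <- function(query, mutants, context,
                           backend = baseline_backend()) {
  stopifnot(inherits(context, "msa"), is.data.frame(mutants))
  if (nchar(query) != context$L) {
    stop("query length does not match alignment length", call. = FALSE)
  }
  m_wt <- backend$likelihoods(query, context)
  h_wt <- hamiltonian(query, m_wt)
  n <- nrow(mutants)
  if (isTRUE(backend$sequence_dependent)) {
    h <- numeric(n)
    failed <- logical(n)
    for (k in seq_len(n)) {
      mut_seq <- apply_mutant(query, mutants$i[k], mutants$j[k],
                              mutants$aa_i[k], mutants$aa_j[k])
      h[k] <- tryCatch(
        hamiltonian(mut_seq, backend$likelihoods(mut_seq, context)),
        error = function(e) {
          failed[k] <<- TRUE
          NA_real_
        }
      )
    }
    if (any(failed)) {
      warning(sum(failed), " of ", n, " mutants failed backend scoring",
              call. = FALSE)
    }
  } else {
    qi <- .aa_lookup[utf8ToInt(query)]
    d_i <- m_wt[cbind(mutants$i, aa_index(mutants$aa_i))] -
           m_wt[cbind(mutants$i, qi[mutants$i])]
    d_j <- m_wt[cbind(mutants$j, aa_index(mutants$aa_j))] -
           m_wt[cbind(mutants$j, qi[mutants$j])]
    h <- h_wt - d_i - d_j
  }
  out <- mutants
  out$hamiltonian <- h
  out$delta_vs_wildtype <- h - h_wt
  attr(out, "wt_hamiltonian") <- h_wt
  attr(out, "backend") <- backend$name
  out
}

#' Rank scored variants by Hamiltonian
#'
#' Sorts ascending by Hamiltonian (lowest predicted-most-stable first);
#' ties are broken by `(i, j, aa_i, aa_j)` ascending so the ranking is a
#' deterministic total order. Ranks `1..K` are assigned and the first
#' `top_k` rows returned.
#'
#' @param scored Data frame from [score_variants()].
#' @param top_k Number of top variants to keep, default `20`.
#' @return The top rows of `scored`, sorted, with a `rank` column prepended.
#' @export
rank_variants <- function(scored, top_k = 20L) {
  stopifnot(is.data.frame(scored), nrow(scored) >= 1L)
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) {
    stop("top_k must be a positive integer", call. = FALSE)
  }
  ord <- order(scored$hamiltonian, scored$i, scored$j,
               match(scored$aa_i, aa_alphabet()),
               match(scored$aa_j, aa_alphabet()))
  out <- scored[ord[seq_len(min(top_k, length(ord)))], , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "wt_hamiltonian") <- attr(scored, "wt_hamiltonian")
  attr(out, "backend") <- attr(scored, "backend")
  out
}

#' Contact-map change between wild type and mutant contexts
#'
#' Elementwise difference `mut - wt` between two contact maps of equal
#' length; positive entries mark pairs whose contact signal intensified in
#' the mutant context. Antisymmetric under argument swap.
#'
#' @param cmap_wt,cmap_mut `L x L` contact maps.
#' @return An `L x L` matrix of differences.
#' @export
contact_delta <- function(cmap_wt, cmap_mut) {
  if (!identical(dim(cmap_wt), dim(cmap_mut))) {
    stop("contact maps must have identical dimensions", call. = FALSE)
  }
  unclass(cmap_mut) - unclass(cmap_wt)
}

#' Read a single pair's signal off a contact map
#'
#' @param cmap An `L x L` contact map.
#' @param i,j 1-based positions, `i != j`.
#' @return The scalar `cmap[i, j]`.
#' @export
extract_pair_signal <- function(cmap, i, j) {
  L <- nrow(cmap)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > L || j > L || i == j) {
    stop("need distinct positions in 1..", L, call. = FALSE)
  }
  cmap[i, j]
}

#' Write a ranked-variant report
#'
#' Emits a tab-separated table (columns: `rank`, `label`, `pos_i`, `pos_j`,
#' `wt_i`, `wt_j`, `mut_i`, `mut_j`, `contact_probability`, `hamiltonian`,
#' `delta_vs_wildtype`; positions 1-based; numbers formatted with 6 decimal
#' places) preceded by a `#`-prefixed provenance block recording the
#' parameters, backend and wild-type Hamiltonian of the run. Re-reading
#' with [read_report()] reproduces every value at full printed precision.
#'
#' @param report A `zsh` object from [zsh_scan()], or a ranked data frame
#'   from [rank_variants()] with a `probability` column.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "zsh")) {
    variants <- report$variants
    meta <- c(
      sprintf("backend = %s", report$backend),
      sprintf("wt_hamiltonian = %.6f", report$wt_hamiltonian),
      sprintf("%s = %s", names(report$config),
              vapply(report$config, format, ""))
    )
  } else {
    variants <- report
    meta <- c(
      sprintf("backend = %s", attr(report, "backend") %||% "unknown"),
      sprintf("wt_hamiltonian = %.6f",
              attr(report, "wt_hamiltonian") %||% NA_real_)
    )
  }
  header <- c("rank", "label", "pos_i", "pos_j", "wt_i", "wt_j",
              "mut_i", "mut_j", "contact_probability", "hamiltonian",
              "delta_vs_wildtype")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(variants) > 0L) {
    prob <- variants$probability %||% rep(NA_real_, nrow(variants))
    rows <- paste(
      variants$rank, variants$label, variants$i, variants$j,
      variants$wt_i, variants$wt_j, variants$aa_i, variants$aa_j,
      sprintf("%.6f", prob),
      sprintf("%.6f", variants$hamiltonian),
      sprintf("%.6f", variants$delta_vs_wildtype),
      sep = "\t"
    )
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read back a ranked-variant report
#'
#' @param path A file written by [write_report()].
#' @return A data frame of the table rows; the provenance block is attached
#'   as attribute `provenance` (character vector).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  meta <- sub("^# ", "", grep("^#", lines, value = TRUE))
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- meta
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
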