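# Independent brute-force oracles and simple fixture builders. Everything
# here is deliberately written as plain loops, separate from the package's
# vectorized implementations.

ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random alignment built directly (not via simulate_msa): query gap-free,
# homologs with independent per-cell gap probability
random_msa <- function(L, depth, seed, gap_rate = 0) {
  set.seed(seed)
  rows <- character(depth)
  rows[1] <- paste0(sample(ALPHA, L, replace = TRUE), collapse = "")
  if (depth > 1) {
    for (r in 2:depth) {
      chars <- sample(ALPHA, L, replace = TRUE)
      if (gap_rate > 0) chars[runif(L) < gap_rate] <- "-"
      rows[r] <- paste0(chars, collapse = "")
    }
  }
  msa(paste0("s", seq_len(depth)), rows, query = 1)
}

# literal double sum of Eq-style Hamiltonian: -sum_i sum_j oh[i,j] * m[i,j]
oracle_hamiltonian <- function(sequence, m) {
  chars <- strsplit(sequence, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    for (j in 1:20) {
      oh_ij <- if (ALPHA[j] == chars[i]) 1 else 0
      total <- total + oh_ij * m[i, j]
    }
  }
  unname(-total)
}

# per-column residue tally with Laplace smoothing, symbol by symbol
oracle_column_freq <- function(x, pseudocount = 1) {
  chars <- do.call(rbind, strsplit(x$seqs, ""))
  p <- matrix(0, x$L, 20)
  for (i in seq_len(x$L)) {
    counts <- numeric(20)
    n <- 0
    for (r in seq_len(x$depth)) {
      a <- match(chars[r, i], ALPHA)
      if (!is.na(a)) {
        counts[a] <- counts[a] + 1
        n <- n + 1
      }
    }
    p[i, ] <- (counts + pseudocount) / (n + 20 * pseudocount)
  }
  p
}

# mutual information by direct joint-count tally, gap as 21st symbol
oracle_mi <- function(x) {
  chars <- do.call(rbind, strsplit(x$seqs, ""))
  code <- function(a) { k <- match(a, ALPHA); ifelse(is.na(k), 21L, k) }
  codes <- apply(chars, c(1, 2), code)
  n <- x$depth
  mi <- matrix(0, x$L, x$L)
  for (i in seq_len(x$L - 1)) {
    for (j in (i + 1):x$L) {
      joint <- matrix(0, 21, 21)
      for (r in seq_len(n)) {
        joint[codes[r, i], codes[r, j]] <- joint[codes[r, i], codes[r, j]] + 1
      }
      joint <- joint / n
      pi_ <- rowSums(joint)
      pj <- colSums(joint)
      val <- 0
      for (a in 1:21) for (b in 1:21) {
        if (joint[a, b] > 0) {
          val <- val + joint[a, b] * log(joint[a, b] / (pi_[a] * pj[b]))
        }
      }
      mi[i, j] <- mi[j, i] <- val
    }
  }
  mi
}

# two-pass average-product correction + min-max rescale
oracle_apc <- function(raw) {
  L <- nrow(raw)
  rowmean <- numeric(L)
  for (i in seq_len(L)) {
    s <- 0
    for (j in seq_len(L)) if (j != i) s <- s + raw[i, j]
    rowmean[i] <- s / (L - 1)
  }
  gs <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j) gs <- gs + raw[i, j]
  grandmean <- gs / (L * (L - 1))
  corr <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i != j) corr[i, j] <- raw[i, j] - rowmean[i] * rowmean[j] / grandmean
  }
  off <- corr[row(corr) != col(corr)]
  lo <- min(off); hi <- max(off)
  if (hi - lo == 0) return(matrix(0, L, L))
  out <- (corr - lo) / (hi - lo)
  diag(out) <- 0
  out
}

# full sort of the upper triangle with the documented tie-break
oracle_top_pairs <- function(cmap, n) {
  L <- nrow(cmap)
  rows <- list()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      rows[[length(rows) + 1]] <- data.frame(i = i, j = j, probability = cmap[i, j])
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$probability, df$i, df$j), ]
  rownames(df) <- NULL
  utils::head(df, n)
}

# brute-force greedy max-min diversity selection seeded with the query
oracle_greedy <- function(x, k) {
  chars <- do.call(rbind, strsplit(x$seqs, ""))
  n <- x$depth
  dist <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    dist[a, b] <- sum(chars[a, ] != chars[b, ])
  }
  selected <- x$query
  remaining <- setdiff(seq_len(n), x$query)
  while (length(selected) < min(k, n) && length(remaining) > 0) {
    best <- NA; bestd <- -1
    for (r in remaining) {
      d <- min(dist[r, selected])
      if (d > bestd) { bestd <- d; best <- r }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# random symmetric matrix with zero diagonal
random_sym <- function(L, seed) {
  set.seed(seed)
  m <- matrix(runif(L * L), L, L)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random likelihood matrix: normalized log-probabilities
random_likelihoods <- function(L, seed) {
  set.seed(seed)
  m <- matrix(rexp(L * 20), L, 20)
  m <- m / rowSums(m)
  log(m)
}

random_protein <- function(L, seed) {
  set.seed(seed)
  paste0(sample(ALPHA, L, replace = TRUE), collapse = "")
}
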