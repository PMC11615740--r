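# Hamiltonian scoring, ranking, contact deltas, and report round trips

test_that("one-hot encoding places a single 1 per row at the residue column", {
  oh <- one_hot("A")
  expect_identical(dim(oh), c(1L, 20L))
  expect_identical(unname(oh[1, ]), c(1L, rep(0L, 19)))
  oh2 <- one_hot("AC")
  expect_equal(unname(rowSums(oh2)), c(1, 1))
  expect_identical(sum(oh2), 2L)
  # decode oracle: argmax per row reconstructs the sequence
  s <- random_protein(30, seed = 11)
  oh30 <- one_hot(s)
  expect_identical(paste0(ALPHA[apply(oh30, 1, which.max)], collapse = ""), s)
  expect_error(one_hot("A-C"), "position 2")
})

test_that("hamiltonian matches closed forms", {
  m3 <- matrix(log(1 / 20), 3, 20)
  expect_equal(hamiltonian("MKV", m3), 3 * log(20), tolerance = 1e-12)
  m1 <- matrix(log(0.5), 1, 20)
  expect_equal(hamiltonian("A", m1), log(2), tolerance = 1e-12)
  expect_error(hamiltonian("MK", m3), "length")
  expect_error(hamiltonian("M-V", m3), "non-canonical")
})

test_that("hamiltonian equals the literal one-hot double-sum oracle", {
  for (seed in 1:25) {
    L <- sample(5:50, 1)
    m <- random_likelihoods(L, seed)
    s <- random_protein(L, seed + 1000)
    expect_equal(hamiltonian(s, m), oracle_hamiltonian(s, m),
                 tolerance = 1e-9)
  }
})

test_that("hamiltonian is additive over positions", {
  for (seed in 1:5) {
    L <- 24
    m <- random_likelihoods(L, seed)
    s <- random_protein(L, seed + 500)
    cut <- sample(2:(L - 1), 1)
    h_split <- hamiltonian(substr(s, 1, cut), m[1:cut, , drop = FALSE]) +
      hamiltonian(substr(s, cut + 1, L), m[(cut + 1):L, , drop = FALSE])
    expect_equal(hamiltonian(s, m), h_split, tolerance = 1e-12)
  }
})

test_that("baseline deltas obey the exact two-position decomposition", {
  m <- random_msa(L = 15, depth = 32, seed = 21, gap_rate = 0.05)
  q <- query_sequence(m)
  mm <- enumerate_double_mutants(q, 3, 10)
  scored <- score_variants(q, mm, m)
  lk <- baseline_likelihoods(q, m)
  h_wt <- hamiltonian(q, lk)
  expect_equal(attr(scored, "wt_hamiltonian"), h_wt, tolerance = 1e-12)
  for (k in seq_len(nrow(scored))) {
    d <- -(lk[3, aa_index(scored$aa_i[k])] - lk[3, aa_index(scored$wt_i[k])]) -
      (lk[10, aa_index(scored$aa_j[k])] - lk[10, aa_index(scored$wt_j[k])])
    expect_equal(scored$delta_vs_wildtype[k], unname(d), tolerance = 1e-12)
  }
  # a self-substitution at one position depends only on the other position
  selfs <- scored[scored$aa_i == scored$wt_i, ]
  d_only_j <- -(lk[10, aa_index(selfs$aa_j)] - lk[10, aa_index(selfs$wt_j)])
  expect_equal(selfs$delta_vs_wildtype, unname(d_only_j), tolerance = 1e-12)
})

test_that("scored hamiltonians equal per-mutant recomputation by the oracle", {
  m <- random_msa(L = 12, depth = 24, seed = 31, gap_rate = 0.02)
  q <- query_sequence(m)
  mm <- rbind(enumerate_double_mutants(q, 1, 5),
              enumerate_double_mutants(q, 2, 8),
              enumerate_double_mutants(q, 4, 11))
  scored <- score_variants(q, mm, m)
  expect_identical(nrow(scored), 3L * 399L)
  lk <- baseline_likelihoods(q, m)
  for (k in sample(nrow(scored), 40)) {
    mut_seq <- apply_mutant(q, scored$i[k], scored$j[k],
                            scored$aa_i[k], scored$aa_j[k])
    expect_equal(scored$hamiltonian[k], oracle_hamiltonian(mut_seq, lk),
                 tolerance = 1e-9)
  }
  # scoring twice is bit-identical
  expect_identical(scored$hamiltonian, score_variants(q, mm, m)$hamiltonian)
})

test_that("a sequence-dependent backend is scored per mutant", {
  m <- random_msa(L = 8, depth = 16, seed = 41)
  q <- query_sequence(m)
  # toy backend whose likelihoods lean toward the variant's own residues
  dep <- structure(list(
    name = "toy-dependent", deterministic = TRUE, sequence_dependent = TRUE,
    contact_map = function(msa) apc_correct(mutual_information(msa)),
    likelihoods = function(variant_sequence, context) {
      p <- column_frequencies(context) + 0.5 * one_hot(variant_sequence)
      log(p / rowSums(p))
    }), class = "scoring_backend")
  mm <- enumerate_double_mutants(q, 2, 6)
  scored <- score_variants(q, mm, m, dep)
  for (k in sample(nrow(mm), 10)) {
    mut_seq <- apply_mutant(q, mm$i[k], mm$j[k], mm$aa_i[k], mm$aa_j[k])
    expect_equal(scored$hamiltonian[k],
                 hamiltonian(mut_seq, dep$likelihoods(mut_seq, m)),
                 tolerance = 1e-12)
  }
})

test_that("ranking sorts ascending with a deterministic tie policy", {
  base <- data.frame(
    i = c(1L, 1L, 1L), j = c(2L, 2L, 2L),
    wt_i = "A", wt_j = "C", aa_i = c("C", "D", "E"), aa_j = "A",
    label = c("x", "y", "z"), hamiltonian = c(3, 1, 2),
    delta_vs_wildtype = c(1, -1, 0)
  )
  top2 <- rank_variants(base, 2)
  expect_identical(top2$label, c("y", "z"))
  expect_identical(top2$rank, 1:2)
  # all-equal scores fall back to the positional tie-break
  tie <- base; tie$hamiltonian <- 5
  expect_identical(rank_variants(tie, 3)$label, c("x", "y", "z"))
  # permutation invariance: shuffled input gives the identical ranking
  m <- random_msa(L = 10, depth = 16, seed = 51)
  q <- query_sequence(m)
  scored <- score_variants(q, enumerate_double_mutants(q, 2, 7), m)
  set.seed(1)
  shuffled <- scored[sample(nrow(scored)), ]
  r1 <- rank_variants(scored, 20)
  r2 <- rank_variants(shuffled, 20)
  rownames(r2) <- rownames(r1)
  expect_equal(r1, r2, ignore_attr = TRUE)
  expect_error(rank_variants(scored, 0), "positive")
})

test_that("contact deltas subtract elementwise and expose pair signals", {
  a <- random_sym(6, 1); b <- random_sym(6, 2)
  expect_true(all(contact_delta(a, a) == 0))
  d <- contact_delta(a, b)
  expect_equal(d, -contact_delta(b, a))
  expect_equal(d[2, 5], b[2, 5] - a[2, 5])
  expect_equal(extract_pair_signal(a, 2, 5), a[2, 5])
  expect_error(extract_pair_signal(a, 2, 2), "distinct")
  expect_error(contact_delta(a, random_sym(7, 3)), "dimensions")
})

test_that("reports round-trip through their tab-separated form", {
  m <- random_msa(L = 10, depth = 20, seed = 61)
  fit <- zsh_scan(m, top_pairs = 2, top_variants = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(fit, path)
  back <- read_report(path)
  expect_identical(nrow(back), 10L)
  expect_identical(back$rank, fit$variants$rank)
  expect_identical(back$label, fit$variants$label)
  expect_equal(back$hamiltonian, round(fit$variants$hamiltonian, 6))
  expect_true(all(grepl("^[A-Y]\\d+[A-Y]/[A-Y]\\d+[A-Y]$", back$label)))
  expect_true(any(grepl("^backend = ", attr(back, "provenance"))))
  # an empty variant table writes a header-only report
  empty <- fit; empty$variants <- fit$variants[0, ]
  write_report(empty, path)
  expect_identical(nrow(read_report(path)), 0L)
})
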