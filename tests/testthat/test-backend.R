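# the deterministic statistics backend: column frequencies, likelihood
# matrices, mutual information, and the average-product correction

test_that("column frequencies match closed forms and a brute-force tally", {
  m8 <- msa(paste0("s", 1:8), rep("A", 8))
  p <- column_frequencies(m8, pseudocount = 1)
  expect_equal(unname(p[1, "A"]), 9 / 28)
  expect_equal(unname(p[1, "C"]), 1 / 28)
  # all-gap column falls back to uniform with a warning (such a column can
  # only arise in contexts without the gap-free query; build one directly)
  mg <- structure(list(ids = c("h1", "h2"), seqs = c("A-", "C-"),
                       query = 1L, L = 2L, depth = 2L), class = "msa")
  expect_warning(pg <- column_frequencies(mg), "only gaps")
  expect_equal(unname(pg[2, ]), rep(0.05, 20))
  # random alignments: row-by-row equality with the symbol-wise tally
  for (seed in 1:5) {
    m <- random_msa(L = 10, depth = 16, seed = seed, gap_rate = 0.1)
    expect_equal(unname(column_frequencies(m, 1)), oracle_column_freq(m, 1),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(column_frequencies(m, 0.5))), rep(1, m$L))
  }
  expect_error(column_frequencies(m8, pseudocount = 0), "> 0")
})

test_that("baseline likelihood rows are normalized log-probabilities", {
  # uniform-composition context: every entry is log(1/20)
  u <- msa(paste0("s", 1:20), vapply(1:20, function(k)
    paste0(rep(aa_alphabet()[k], 4), collapse = ""), ""))
  mlik <- baseline_likelihoods(query_sequence(u), u)
  expect_equal(unname(mlik), matrix(log(1 / 20), 4, 20), tolerance = 1e-12)
  # normalization holds on arbitrary alignments
  for (seed in 1:10) {
    m <- random_msa(L = 8, depth = 12, seed = seed, gap_rate = 0.1)
    lk <- baseline_likelihoods(query_sequence(m), m)
    expect_true(all(lk <= 0))
    expect_equal(unname(rowSums(exp(lk))), rep(1, m$L), tolerance = 1e-12)
  }
  expect_error(baseline_likelihoods("MK", random_msa(8, 4, 1)), "length")
})

test_that("mutual information reproduces analytic coupling limits", {
  # perfect two-state coupling: MI = log 2
  coupled <- msa(paste0("s", 1:4), c("AA", "AA", "CC", "CC"))
  mi <- mutual_information(coupled)
  expect_equal(mi[1, 2], log(2), tolerance = 1e-12)
  # exact independence construction: MI = 0
  indep <- msa(paste0("s", 1:4), c("AA", "AC", "CA", "CC"))
  expect_equal(mutual_information(indep)[1, 2], 0, tolerance = 1e-12)
  expect_error(mutual_information(msa("q", "AC")), "depth")
})

test_that("mutual information equals the direct joint-count tally", {
  for (seed in 1:4) {
    m <- random_msa(L = 6, depth = 64, seed = seed, gap_rate = 0.05)
    mi <- mutual_information(m)
    expect_equal(mi, oracle_mi(m), tolerance = 1e-10)
    expect_equal(mi, t(mi))
    expect_true(all(diag(mi) == 0))
    expect_true(all(mi >= 0))
  }
})

test_that("APC cancels constant matrices and preserves the extreme entry", {
  L <- 6
  const <- matrix(0.3, L, L); diag(const) <- 0
  expect_true(all(apc_correct(const) == 0))
  # single dominant entry attains the maximum value 1 after rescaling
  m <- matrix(0.01, L, L); diag(m) <- 0
  m[2, 5] <- m[5, 2] <- 5
  cm <- apc_correct(m)
  expect_equal(cm[2, 5], 1)
  expect_equal(max(cm), 1)
  expect_error(apc_correct(matrix(1:9, 3)), "symmetric")
  # zero grand mean degenerates to the all-zero map with a warning
  z <- matrix(0, 4, 4)
  expect_warning(cz <- apc_correct(z), "zero grand mean")
  expect_true(all(cz == 0))
})

test_that("APC equals an independently coded two-pass recomputation", {
  for (seed in 1:6) {
    raw <- random_sym(8, seed)
    expect_equal(unclass(apc_correct(raw)), oracle_apc(raw),
                 tolerance = 1e-12)
  }
})

test_that("contact maps satisfy their invariants on random alignments", {
  b <- baseline_backend()
  for (seed in 1:8) {
    m <- random_msa(L = 12, depth = 32, seed = seed, gap_rate = 0.05)
    cm <- b$contact_map(m)
    expect_equal(unclass(cm), unclass(t(cm)))
    expect_true(all(diag(cm) == 0))
    expect_true(all(is.finite(cm)))
    expect_true(all(cm >= 0 & cm <= 1))
  }
})

test_that("the baseline backend is bit-deterministic", {
  m <- random_msa(L = 10, depth = 24, seed = 42, gap_rate = 0.1)
  b <- baseline_backend()
  expect_true(b$deterministic)
  expect_false(b$sequence_dependent)
  expect_identical(b$contact_map(m), b$contact_map(m))
  q <- query_sequence(m)
  expect_identical(b$likelihoods(q, m), b$likelihoods(q, m))
})
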