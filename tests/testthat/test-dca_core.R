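test_that("compute_weights matches the brute-force identity oracle", {
  # full redundancy collapses to one effective sequence
  dup <- toy_msa(rep("ACDEF", 5), ids = paste0("s", 1:5))
  w <- compute_weights(dup)
  expect_equal(w$m, rep(5L, 5))
  expect_equal(w$Meff, 1)

  # hand case: pairwise identities 0.75 / 0 / 0 at threshold 0.8
  x <- toy_msa(c("AAAA", "AAAT", "CCCC"))
  w2 <- compute_weights(x, 0.8)
  expect_equal(w2$m, c(1L, 1L, 1L))
  expect_equal(w2$Meff, 3)

  # single sequence
  expect_equal(compute_weights(toy_msa("ACD"))$Meff, 1)

  # random alignments, gaps included, against the oracle
  set.seed(21)
  for (rep in 1:5) {
    strings <- vapply(1:12, function(i)
      paste(sample(c("A", "C", "D", "-"), 8, replace = TRUE), collapse = ""),
      "")
    x <- toy_msa(strings, ids = paste0("r", 1:12))
    for (thr in c(0.5, 0.8)) {
      got <- compute_weights(x, thr)
      want <- oracle_weights(strings, thr)
      expect_equal(got$m, want$m)
      expect_equal(got$Meff, want$Meff)
    }
  }
})

test_that("compute_frequencies implements the pseudocount formulas", {
  # one sequence "AC", lambda = Meff = 1, q = 21 -> f_1(A) = (1/21 + 1)/2
  x <- toy_msa("AC")
  f <- compute_frequencies(x, compute_weights(x))  # Meff = 1, lambda = Meff
  expect_equal(f$fi["A", 1], (1 / 21 + 1) / 2)
  expect_equal(f$fi["C", 1], (1 / 21) / 2)
  # pair block: f_12(A,C) = (1/441 + 1)/2
  q <- f$q
  expect_equal(f$fij[match("A", f$alphabet), q + match("C", f$alphabet)],
               (1 / q^2 + 1) / 2)

  # lambda = 0 with equal weights reduces to empirical column frequencies
  y <- toy_msa(c("AA", "AC", "CC", "AC"))
  f0 <- compute_frequencies(y, lambda = 0)
  expect_equal(unname(f0$fi["A", ]), c(3 / 4, 1 / 4))

  # normalisation invariants on random models (tolerance 1e-10)
  f1 <- random_freq_model(L = 5, q = 4, M = 80, seed = 9)
  expect_lt(max(abs(colSums(f1$fi) - 1)), 1e-10)
  idx <- function(k) (k - 1) * f1$q + seq_len(f1$q)
  for (i in 1:4) for (j in (i + 1):5) {
    blk <- f1$fij[idx(i), idx(j)]
    expect_lt(abs(sum(blk) - 1), 1e-10)
    # f_ij(A,B) = f_ji(B,A)
    expect_equal(blk, t(f1$fij[idx(j), idx(i)]))
  }
  expect_true(all(f1$fij[idx(1), idx(2)] > 0))
  # diagonal closure f_ii(A,B) = delta_AB f_i(A)
  expect_equal(f1$fij[idx(2), idx(2)], diag(f1$fi[, 2]),
               ignore_attr = TRUE)
})

test_that("mean_field_couplings inverts the reduced covariance", {
  # factorised pair frequencies -> zero cross-column couplings
  f <- random_freq_model(L = 3, q = 3, M = 100, seed = 2)
  idx <- function(k) (k - 1) * f$q + seq_len(f$q)
  for (i in 1:2) for (j in (i + 1):3) {
    f$fij[idx(i), idx(j)] <- outer(f$fi[, i], f$fi[, j])
    f$fij[idx(j), idx(i)] <- outer(f$fi[, j], f$fi[, i])
  }
  e <- mean_field_couplings(f)
  expect_lt(max(abs(e$e[idx(1), idx(2)])), 1e-10)
  expect_equal(e$reduced_dim, 3 * 2)

  # 2-column, 2-letter toy against the closed-form 2x2 inverse
  p1 <- 0.6; p2 <- 0.3; p11 <- 0.25
  fm <- structure(list(
    fi = matrix(c(p1, 1 - p1, p2, 1 - p2), nrow = 2,
                dimnames = list(c("A", "C"), NULL)),
    fij = {
      m <- matrix(0, 4, 4)
      blk <- matrix(c(p11, p2 - p11, p1 - p11, 1 - p1 - p2 + p11), 2, 2)
      m[1:2, 3:4] <- blk; m[3:4, 1:2] <- t(blk)
      m[1:2, 1:2] <- diag(c(p1, 1 - p1)); m[3:4, 3:4] <- diag(c(p2, 1 - p2))
      m
    },
    q = 2L, L = 2L, lambda = 0, Meff = 1, alphabet = c("A", "C"),
    col_labels = NULL, partition = NULL), class = "freq_model")
  e2 <- mean_field_couplings(fm)
  v1 <- p1 * (1 - p1); v2 <- p2 * (1 - p2); cov <- p11 - p1 * p2
  det <- v1 * v2 - cov^2
  expect_equal(e2$e[1, 3], cov / det)            # -(C^-1)_12
  expect_equal(e2$e[1, 1], 0)                    # e_ii = 0 by construction
  # symmetry on a random valid model
  e3 <- mean_field_couplings(random_freq_model(L = 4, q = 3, seed = 5))
  expect_equal(e3$e, t(e3$e))
})

test_that("direct_information matches the independent field-search oracle", {
  # e = 0 -> P = f_i f_j -> DI = 0
  f <- random_freq_model(L = 3, q = 3, M = 50, seed = 3)
  e0 <- structure(list(e = matrix(0, 9, 9), q = 3L, L = 3L,
                       reduced_dim = 6L, col_labels = NULL,
                       partition = NULL), class = "coupling_model")
  di0 <- direct_information(e0, f)
  expect_lt(max(di0$di, na.rm = TRUE), 1e-12)

  # strongly coupled 2-letter toy: fixed point vs Nelder-Mead oracle
  x <- toy_msa(c("AA", "AA", "CC", "CC", "AC"), alphabet = c("A", "C"))
  ps <- dca(x, lambda = 0.5, tol = 1e-10, max_iter = 2000)
  f2 <- attr(ps, "freqs")
  cpl <- mean_field_couplings(f2)
  W <- exp(cpl$e[1:2, 3:4])
  want <- oracle_di_pair(W, f2$fi[, 1], f2$fi[, 2])
  expect_equal(ps$di[1, 2], want, tolerance = 1e-5)

  # DI symmetric and non-negative on random valid inputs
  f3 <- random_freq_model(L = 5, q = 4, M = 120, seed = 13)
  di <- direct_information(mean_field_couplings(f3), f3)
  expect_true(all(di$di >= 0, na.rm = TRUE))
  expect_equal(di$di, t(di$di))
})

test_that("rank_pairs enforces separation, ordering and tie-breaks", {
  L <- 20
  m <- matrix(0, L, L)
  m[10, 14] <- m[14, 10] <- 5   # |i-j| = 4 -> excluded at default
  m[10, 15] <- m[15, 10] <- 4   # |i-j| = 5 -> retained
  m[1, 7] <- m[7, 1] <- 4       # tie with (10,15): lexicographic order
  rp <- rank_pairs(m)
  expect_false(any(rp$i == 10 & rp$j == 14))
  expect_equal(rp$i[1:2], c(1, 10))
  expect_equal(rp$j[1:2], c(7, 15))
  expect_true(all(diff(rp$score) <= 0))
  expect_equal(nrow(rank_pairs(m, top_k = 3)), 3L)

  # the 25% helper reproduces 44 pairs for a 178-column domain
  expect_identical(top_fraction_k(178), 44L)
})

test_that("permuting sequence order changes neither Meff nor DI", {
  set.seed(31)
  x <- sample_potts_msa(potts_spec(L = 8, q_sim = 4, planted_pairs = 1L,
                                   N = 150, seed = 77))
  perm <- sample(n_seq(x))
  y <- msa(x$seqs[perm, , drop = FALSE], ids = x$ids[perm],
           alphabet = x$alphabet)
  expect_equal(compute_weights(y)$Meff, compute_weights(x)$Meff)
  expect_equal(dca(y)$di, dca(x)$di, tolerance = 1e-12)
})

test_that("pair tables are written with residue numbering when mapped", {
  x <- toy_msa(c("ACDEFG", "ACDEFG", "CCDEFG"), column_map = 11:16)
  ps <- dca(x)
  rp <- rank_pairs(ps, min_separation = 4)
  path <- tempfile(fileext = ".tsv")
  write_pairs(rp, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# i\tj")
  expect_equal(strsplit(lines[2], "\t")[[1]][3:4], c("11", "16"))
})
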