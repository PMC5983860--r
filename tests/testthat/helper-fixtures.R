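# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

toy_msa <- function(strings, ids = NULL, species = NULL,
                    alphabet = aa_alphabet(), column_map = NULL) {
  msa(strings, ids = ids, species = species, column_map = column_map,
      alphabet = alphabet)
}

write_fasta_fixture <- function(strings, path = tempfile(fileext = ".fasta"),
                                ids = paste0("s", seq_along(strings))) {
  writeLines(as.vector(rbind(paste0(">", ids), strings)), path)
  path
}

# brute-force pairwise identity oracle (gaps compared as symbols)
oracle_weights <- function(strings, threshold) {
  chars <- strsplit(strings, "")
  M <- length(strings)
  m <- integer(M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      id <- mean(chars[[a]] == chars[[b]])
      if (id >= threshold) m[a] <- m[a] + 1L
    }
  }
  list(m = m, Meff = sum(1 / m))
}

# brute-force per-site max over qualifying pairs
oracle_site_max <- function(pairs, n_sites) {
  out <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    sc <- pairs$score[pairs$i == s | pairs$j == s]
    out[s] <- if (length(sc) > 0) max(sc) else 0
  }
  out
}

# independent DI oracle for one pair: fields found by direct numerical
# optimisation of the marginal-matching residual (Nelder-Mead on logits),
# nothing shared with the C++ fixed-point path
oracle_di_pair <- function(W, fi, fj) {
  q <- length(fi)
  obj <- function(par) {
    mu1 <- exp(c(par[seq_len(q - 1)], 0)); mu1 <- mu1 / sum(mu1)
    mu2 <- exp(c(par[q:(2 * q - 2)], 0)); mu2 <- mu2 / sum(mu2)
    P <- W * outer(mu1, mu2)
    P <- P / sum(P)
    sum((rowSums(P) - fi)^2) + sum((colSums(P) - fj)^2)
  }
  fit <- optim(rep(0, 2 * (q - 1)), obj,
               control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, obj, control = list(maxit = 5000, reltol = 1e-14))
  mu1 <- exp(c(fit$par[seq_len(q - 1)], 0)); mu1 <- mu1 / sum(mu1)
  mu2 <- exp(c(fit$par[q:(2 * q - 2)], 0)); mu2 <- mu2 / sum(mu2)
  P <- W * outer(mu1, mu2); P <- P / sum(P)
  sum(P * log(P / outer(fi, fj)))
}

# exhaustive hypergeometric tail by direct enumeration over all tables
# with the observed margins, probabilities from factorials
oracle_fisher_depletion <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- r1 + r2
  x_obs <- tab[1, 2]  # high-DCA / unflagged cell
  lprob <- function(x) {
    a <- r1 - x; b <- x; c <- c2 - x; d <- c1 - (r1 - x)
    if (min(a, b, c, d) < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) -
      lfactorial(d)
  }
  sum(exp(vapply(0:x_obs, lprob, numeric(1))))
}

# a valid small frequency model built directly from an explicit weighted
# alignment (used where tests need random but consistent frequencies)
random_freq_model <- function(L = 4, q = 3, M = 60, lambda = NULL,
                              seed = 1) {
  set.seed(seed)
  alphabet <- aa_alphabet(q, gap = FALSE)
  x <- msa(matrix(sample(alphabet, M * L, replace = TRUE), M, L),
           alphabet = alphabet)
  compute_frequencies(x, compute_weights(x), lambda = lambda)
}
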