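uniform_pi <- function() {
  sense <- standard_genetic_code()$sense_codons
  stats::setNames(rep(1 / length(sense), length(sense)), sense)
}

test_that("codon frequency estimation is F61-style with pseudocounts", {
  code <- standard_genetic_code()
  one_each <- paste(code$sense_codons, collapse = "")
  pi <- estimate_codon_frequencies(one_each)
  expect_equal(unname(pi), rep(1 / 61, 61))
  expect_equal(sum(pi), 1)
  # pseudocount-only: empty counts give the uniform distribution
  pi0 <- estimate_codon_frequencies(stats::setNames(numeric(0), character(0)))
  expect_equal(unname(pi0), rep(1 / 61, 61))
  # pooling two sequences equals counting their concatenation
  s1 <- "ATGAAA"; s2 <- "ATGCCG"
  expect_equal(estimate_codon_frequencies(c(s1, s2)),
               estimate_codon_frequencies(paste0(s1, s2)))
  expect_error(estimate_codon_frequencies(c(TAA = 5, ATG = 2)), "stop")
})

test_that("rate matrix construction satisfies its structural invariants", {
  cls <- table1_classification()
  set.seed(11)
  for (k in 1:8) {
    pi <- estimate_codon_frequencies(
      stats::setNames(runif(61, 0, 10), standard_genetic_code()$sense_codons))
    params <- list(kappa = runif(1, 0.5, 5), gamma = runif(1, 0.05, 2),
                   lam = runif(1, 0.05, 3))
    Q <- build_rate_matrix(params, pi, cls)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    piv <- attr(Q, "pi")
    expect_lt(max(abs(piv * Q - t(piv * Q))), 1e-14)
    # normalisation: one expected substitution per codon per unit time
    expect_equal(-sum(piv * diag(Q)), 1, tolerance = 1e-12)
    # sparsity: no rate between codons differing at 2+ positions
    sense <- rownames(Q)
    idx <- cbind(sample(61, 40, TRUE), sample(61, 40, TRUE))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ndiff <- sum(strsplit(sense[i], "")[[1]] != strsplit(sense[j], "")[[1]])
      if (ndiff >= 2) expect_identical(Q[i, j], 0)
    }
  }
})

test_that("parameter identities collapse the rate matrix as expected", {
  pi <- uniform_pi()
  # gamma = lambda = 1: every single-nt change has rate pi_j (x kappa for
  # transitions), synonymous or not
  Q1 <- build_rate_matrix(list(kappa = 3, gamma = 1, lam = 1), pi)
  off <- Q1[Q1 > 0]
  scale <- sort(unique(round(off / min(off), 6)))
  expect_equal(scale, c(1, 3))
  # lambda = 0 zeroes every NC change, e.g. GTT (V) -> GCT (A)
  Q0 <- build_rate_matrix(list(kappa = 2, gamma = 0.5, lam = 0), pi)
  expect_identical(Q0["GTT", "GCT"], 0)
  expect_gt(Q0["CTT", "ATT"], 0)  # L -> I conservative, stays positive
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  pi <- uniform_pi()
  Q <- build_rate_matrix(list(kappa = 2, gamma = 0.4, lam = 0.6), pi)
  P0 <- transition_matrix(Q, 0)
  expect_equal(P0, diag(61), ignore_attr = TRUE, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:4) {
    t1 <- runif(1, 0.05, 0.8); t2 <- runif(1, 0.05, 0.8)
    P1 <- transition_matrix(Q, t1)
    P2 <- transition_matrix(Q, t2)
    P12 <- transition_matrix(Q, t1 + t2)
    expect_lt(max(abs(P1 %*% P2 - P12)), 1e-8)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
    expect_true(all(P1 >= 0))
  }
})

test_that("pairwise likelihood limits and symmetries hold", {
  pi <- uniform_pi()
  code <- standard_genetic_code()
  # single column, identical codon i: as t -> 0, ll -> log pi_i
  n <- matrix(0L, 61, 61, dimnames = list(code$sense_codons, code$sense_codons))
  n["ATG", "ATG"] <- 1L
  ll <- pair_log_likelihood(n, list(t = 1e-9, kappa = 2, gamma = 0.3,
                                    lam = 0.5), pi)
  expect_equal(ll, log(pi[["ATG"]]), tolerance = 1e-6)
  # reversibility: swapping the sequences leaves the likelihood unchanged
  aln <- simulate_codon_pair(150, t = 0.4, kappa = 2, gamma = 0.4,
                             lam = 0.6, seed = 21)
  nm <- codon_pair_counts(aln)
  params <- list(t = 0.37, kappa = 1.8, gamma = 0.5, lam = 0.4)
  expect_equal(pair_log_likelihood(nm, params, pi),
               pair_log_likelihood(t(nm), params, pi), tolerance = 1e-9)
})

test_that("likelihood peaks near the generating parameters on large data", {
  pi <- uniform_pi()
  aln <- simulate_codon_pair(3000, t = 0.3, kappa = 2, gamma = 0.3,
                             lam = 0.5, seed = 8)
  n <- codon_pair_counts(aln)
  true_params <- list(t = 0.3, kappa = 2, gamma = 0.3, lam = 0.5)
  ll_true <- pair_log_likelihood(n, true_params, pi)
  for (p in names(true_params)) {
    for (f in c(0.8, 1.2)) {
      perturbed <- true_params
      perturbed[[p]] <- perturbed[[p]] * f
      expect_gte(ll_true, pair_log_likelihood(n, perturbed, pi))
    }
  }
})

test_that("ML fit recovers parameters and flags degenerate inputs", {
  aln <- simulate_codon_pair(800, t = 0.3, kappa = 2, gamma = 0.3,
                             lam = 0.5, seed = 17)
  fit <- fit_ml(aln, n_starts = 2)
  expect_true(fit$converged)
  expect_equal(fit$params$t, 0.3, tolerance = 0.25)
  expect_equal(fit$params$kappa, 2, tolerance = 0.4)
  expect_equal(fit$params$gamma, 0.3, tolerance = 0.4)
  expect_gt(fit$params$lam, 0)
  expect_named(tidy(fit), c("term", "estimate"))
  # identical sequences: divergence time collapses to the lower bound
  ident <- codon_pair_alignment(rep(c("ATG", "AAA", "CTG"), 10),
                                rep(c("ATG", "AAA", "CTG"), 10))
  fit0 <- fit_ml(ident, n_starts = 1)
  expect_true("t_at_lower_bound" %in% fit0$notes)
})

test_that("the extended model nests the standard omega model", {
  aln <- simulate_codon_pair(400, t = 0.3, kappa = 2, gamma = 0.4,
                             lam = 0.7, seed = 23)
  ext <- fit_ml(aln, n_starts = 2)
  std <- fit_standard_omega(aln, n_starts = 2)
  expect_gte(ext$loglik, std$loglik - 1e-6)
  expect_true("omega" %in% names(std$params))
  # at low divergence the ML omega tracks the count-model omega
  cnt <- estimate_rates_count(aln)
  expect_equal(std$params$omega, cnt$omega, tolerance = 0.35)
})

test_that("purely synonymous divergence pins omega at its lower bound", {
  # third-position synonymous changes only (Leu CTx box)
  a <- rep(c("CTT", "GGT", "CCT"), 15)
  b <- rep(c("CTC", "GGC", "CCC"), 15)
  fit <- fit_standard_omega(codon_pair_alignment(a, b), n_starts = 1)
  expect_true(fit$params$omega < 1e-3 ||
                "omega_at_lower_bound" %in% fit$notes)
})
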