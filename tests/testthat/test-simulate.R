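test_that("codon pair simulation honours its degenerate limits", {
  a0 <- simulate_codon_pair(40, t = 0, kappa = 2, gamma = 0.3, lam = 0.5,
                            seed = 2)
  expect_identical(a0$codons_a, a0$codons_b)
  # lambda = 0: the NC instantaneous rate is zero, so at modest divergence
  # no NC amino-acid difference appears (endpoint NC pairs can only arise
  # through two hits in one codon, probability O(t^2) per codon)
  cls <- table1_classification()
  a1 <- simulate_codon_pair(300, t = 0.15, kappa = 2, gamma = 0.5, lam = 0,
                            seed = 3)
  aaA <- translate_codons(a1$codons_a)
  aaB <- translate_codons(a1$codons_b)
  n_nc <- 0
  for (i in which(aaA != aaB)) {
    lab <- tryCatch(classify_pair(aaA[i], aaB[i], cls),
                    error = function(e) "multi")
    if (lab == "NC") n_nc <- n_nc + 1
  }
  expect_equal(n_nc, 0)
  # and the zero NC rate shows up structurally in the generator's matrix
  pi <- stats::setNames(rep(1 / 61, 61), standard_genetic_code()$sense_codons)
  Q0 <- build_rate_matrix(list(kappa = 2, gamma = 0.5, lam = 0), pi)
  expect_identical(Q0["GTT", "GCT"], 0)  # V -> A, non-conservative
})

test_that("simulation is deterministic given the seed", {
  x <- simulate_codon_pair(60, t = 0.3, kappa = 2, gamma = 0.3, lam = 0.5,
                           seed = 11)
  y <- simulate_codon_pair(60, t = 0.3, kappa = 2, gamma = 0.3, lam = 0.5,
                           seed = 11)
  z <- simulate_codon_pair(60, t = 0.3, kappa = 2, gamma = 0.3, lam = 0.5,
                           seed = 12)
  expect_identical(x$codons_a, y$codons_a)
  expect_identical(x$codons_b, y$codons_b)
  expect_false(identical(x$codons_b, z$codons_b))
  d1 <- synthetic_ddg_table(c(AV = 0.4), n_per_pair = 50, seed = 5)
  d2 <- synthetic_ddg_table(c(AV = 0.4), n_per_pair = 50, seed = 5)
  expect_identical(d1, d2)
  n1 <- synthetic_network_pair(n_nodes = 60, extra_nonortholog_edges = 5,
                               seed = 9)
  n2 <- synthetic_network_pair(n_nodes = 60, extra_nonortholog_edges = 5,
                               seed = 9)
  expect_identical(n1, n2)
})

test_that("ancestor-split and single-branch modes agree under reversibility", {
  args <- list(length = 4000, t = 0.4, kappa = 2, gamma = 0.4, lam = 0.6)
  p_diff <- function(mode, seed) {
    a <- do.call(simulate_codon_pair, c(args, list(seed = seed, mode = mode)))
    mean(a$codons_a != a$codons_b)
  }
  ps <- p_diff("ancestor_split", 31)
  pb <- p_diff("single_branch", 32)
  # proportions of differing columns agree within binomial sampling error
  se <- sqrt(ps * (1 - ps) / args$length + pb * (1 - pb) / args$length)
  expect_lt(abs(ps - pb), 4 * se)
})

test_that("long simulations stay at the stationary codon distribution", {
  aln <- simulate_codon_pair(6000, t = 2, kappa = 2, gamma = 0.5, lam = 0.5,
                             seed = 13)
  counts <- table(factor(aln$codons_b,
                         levels = standard_genetic_code()$sense_codons))
  p <- stats::chisq.test(counts, p = rep(1 / 61, 61))$p.value
  expect_gt(p, 1e-4)
})

test_that("synthetic ddG tables encode the planted fractions", {
  all0 <- synthetic_ddg_table(c(AV = 0, IL = 0), n_per_pair = 30, seed = 1)
  cls0 <- derive_classification(all0)
  expect_length(cls0$nc_pairs, 0)
  # n_per_pair = 1: per-pair fractions can only be 0 or 1
  one <- synthetic_ddg_table(c(AV = 0.6, IL = 0.3), n_per_pair = 1, seed = 2)
  frac <- tapply(one$ddg < -2, pmin(one$aa_wt, one$aa_mut), mean)
  expect_true(all(frac %in% c(0, 1)))
  # both directions are represented
  big <- synthetic_ddg_table(c(AV = 0.5), n_per_pair = 100, seed = 3)
  expect_setequal(unique(big$aa_wt), c("A", "V"))
})

test_that("planted classifications round-trip through the ddG generator", {
  cls <- table1_classification()
  planted <- stats::setNames(
    ifelse(c(cls$c_pairs, cls$nc_pairs) %in% cls$nc_pairs, 0.5, 0.05),
    c(cls$c_pairs, cls$nc_pairs)
  )
  recs <- synthetic_ddg_table(planted, n_per_pair = 200, seed = 7)
  derived <- derive_classification(recs)
  expect_identical(derived$nc_pairs, cls$nc_pairs)
  expect_identical(derived$c_pairs, cls$c_pairs)
  expect_length(derived$uncovered, 0)
})

test_that("network pair generator plants recoverable re-wired nodes", {
  net <- synthetic_network_pair(n_nodes = 100, edge_density = 0.03,
                                ortholog_fraction = 0.8,
                                n_planted_rewired = 5,
                                extra_nonortholog_edges = 10, seed = 4)
  expect_length(net$planted, 5)
  expect_true(all(net$planted %in% net$ortholog_map$node_sp1))
  # fully orthologous world with no extra edges: all re-wiring scores 0
  full <- synthetic_network_pair(n_nodes = 60, edge_density = 0.05,
                                 ortholog_fraction = 1,
                                 n_planted_rewired = 0,
                                 extra_nonortholog_edges = 0, seed = 6)
  m <- compute_metrics(full$edges_a, full$ortholog_map)
  expect_true(all(m$nonortholog_neighbors == 0))
  expect_error(
    synthetic_network_pair(n_nodes = 50, ortholog_fraction = 0.9,
                           n_planted_rewired = 2,
                           extra_nonortholog_edges = 40, seed = 1),
    "exceeds"
  )
})

test_that("recovery experiments aggregate replicates deterministically", {
  s1 <- parameter_recovery_experiment(
    list(t = 0.3, kappa = 2, gamma = 0.5, lam = 0.5),
    length = 200, n_reps = 2, seed = 5, estimator = "count"
  )
  s2 <- parameter_recovery_experiment(
    list(t = 0.3, kappa = 2, gamma = 0.5, lam = 0.5),
    length = 200, n_reps = 2, seed = 5, estimator = "count"
  )
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  est <- attr(s1, "estimates")
  expect_equal(nrow(est), 2)
  # the two replicates use distinct seeds, hence distinct data
  expect_false(identical(est$omega[1], est$omega[2]))
})
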