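test_that("codon site opportunities match hand-enumerated examples", {
  # TTT: 9 single-nt mutants, 1 synonymous (TTC), nonsynonymous partners
  # I,L,V (pos 1), Y,S,C (pos 2), L,L (pos 3); V, S, C changes are NC
  s1 <- codon_site_opportunities("TTT")
  expect_equal(s1$s_sites, 1 / 3)
  expect_equal(s1$n_sites, 8 / 3)
  expect_equal(s1$c_sites, 5 / 3)
  expect_equal(s1$nc_sites, 1)
  # TGG: stop mutants TAG, TGA drop out of the denominators entirely
  s2 <- codon_site_opportunities("TGG")
  expect_equal(s2$s_sites, 0)
  expect_equal(s2$n_sites, 3)
  expect_equal(s2$c_sites, 8 / 3)
  expect_equal(s2$nc_sites, 1 / 3)
  expect_error(codon_site_opportunities("TAA"), "sense")
})

test_that("site-count identities hold for every sense codon", {
  code <- standard_genetic_code()
  for (cd in code$sense_codons) {
    s <- codon_site_opportunities(cd)
    expect_equal(s$s_sites + s$n_sites, 3, tolerance = 1e-9)
    expect_equal(s$c_sites + s$nc_sites, s$n_sites, tolerance = 1e-9)
  }
})

test_that("pair site counts average the two sequences", {
  a1 <- codon_pair_alignment("TTT", "TTT")
  expect_equal(pair_site_counts(a1), codon_site_opportunities("TTT"))
  a2 <- codon_pair_alignment("TTT", "TGG")
  expected <- (as.numeric(codon_site_opportunities("TTT")) +
                 as.numeric(codon_site_opportunities("TGG"))) / 2
  expect_equal(as.numeric(pair_site_counts(a2)), expected)
  # additivity over concatenated codons
  a3 <- codon_pair_alignment(rep("TTT", 7), rep("TTT", 7))
  expect_equal(as.numeric(pair_site_counts(a3)),
               7 * as.numeric(codon_site_opportunities("TTT")))
})

test_that("pathway difference counts match hand-enumerated examples", {
  expect_equal(as.numeric(pathway_difference_counts("GCT", "GCC")),
               c(1, 0, 0, 0))
  # F -> L, conservative
  expect_equal(as.numeric(pathway_difference_counts("TTT", "TTA")),
               c(0, 1, 1, 0))
  # two pathways: TTT->GTT (F->V, NC) ->GTA (syn) and
  #               TTT->TTA (F->L, C) ->GTA (L->V, C)
  expect_equal(as.numeric(pathway_difference_counts("TTT", "GTA")),
               c(0.5, 1.5, 1.0, 0.5))
  expect_equal(as.numeric(pathway_difference_counts("AAA", "AAA")),
               c(0, 0, 0, 0))
  expect_error(pathway_difference_counts("TAA", "AAA"), "sense")
})

test_that("pathway averaging agrees with recursive enumeration on random codon pairs", {
  cls <- table1_classification()
  code <- standard_genetic_code()
  label_of <- oracle_label_fun(cls)
  set.seed(7)
  pairs <- cbind(sample(code$sense_codons, 150, replace = TRUE),
                 sample(code$sense_codons, 150, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    got <- as.numeric(pathway_difference_counts(pairs[k, 1], pairs[k, 2]))
    want <- unname(oracle_pathway_counts(pairs[k, 1], pairs[k, 2], label_of))
    expect_equal(got, want, tolerance = 1e-12)
    # conservation: sd + nd = number of differing positions unless every
    # pathway is stop-blocked
    ndiff <- sum(strsplit(pairs[k, 1], "")[[1]] != strsplit(pairs[k, 2], "")[[1]])
    if (got[1] + got[2] > 0) {
      expect_true(got[1] + got[2] <= ndiff + 1e-9)
    }
    expect_equal(got[3] + got[4], got[2], tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction has the closed form and its domain", {
  expect_equal(jukes_cantor_correct(0), 0)
  expect_equal(jukes_cantor_correct(0.3), -0.75 * log(0.6))
  expect_equal(jukes_cantor_correct(0.3), 0.383119, tolerance = 1e-6)
  expect_error(jukes_cantor_correct(0.75), "saturation")
  expect_error(jukes_cantor_correct(0.8, class_label = "NC"), "NC")
})

test_that("identical sequences give zero rates with undefined ratios", {
  aln <- codon_pair_alignment(c("ATG", "AAA", "CTG"), c("ATG", "AAA", "CTG"))
  r <- estimate_rates_count(aln)
  expect_equal(c(r$dS, r$dN, r$dC, r$dNC), rep(0, 4))
  expect_true(is.na(r$omega) && is.na(r$lambda))
  expect_match(r$flags, "omega_undefined")
  expect_match(r$flags, "lambda_undefined")
})

test_that("single-codon worked example composes sites, pathways and correction", {
  # TTT | TTA: averaged sites of TTT (1/3, 8/3, 5/3, 1) and
  # TTA (2/3, 7/3, 4/3, 1) -> (1/2, 5/2, 3/2, 1); one conservative difference
  aln <- codon_pair_alignment("TTT", "TTA")
  r <- estimate_rates_count(aln)
  expect_equal(c(r$s_sites, r$n_sites, r$c_sites, r$nc_sites),
               c(1 / 2, 5 / 2, 3 / 2, 1))
  expect_equal(c(r$sd, r$nd, r$cd, r$ncd), c(0, 1, 1, 0))
  expect_equal(r$dN, jukes_cantor_correct(1 / (5 / 2)))
  expect_equal(r$dC, jukes_cantor_correct(1 / (3 / 2)))
  expect_equal(r$dS, 0)
  expect_equal(r$dNC, 0)
  expect_true(is.na(r$omega))  # dS = 0
  expect_equal(r$lambda, 0)
})

test_that("collapsing the classification makes dC equal dN and removes dNC", {
  flat <- all_conservative_classification()
  aln <- simulate_codon_pair(200, t = 0.4, kappa = 2, gamma = 0.5,
                             lam = 0.7, seed = 5)
  r <- estimate_rates_count(aln, cls = flat)
  expect_equal(r$dC, r$dN, tolerance = 1e-12)
  expect_equal(r$c_sites, r$n_sites, tolerance = 1e-12)
  expect_true(is.na(r$dNC))  # zero NC sites -> flagged
  expect_match(r$flags, "no_NC_sites")
})

test_that("count omega agrees with the independent NG86 oracle", {
  set.seed(13)
  for (k in 1:6) {
    aln <- simulate_codon_pair(80, t = runif(1, 0.1, 0.5),
                               kappa = runif(1, 1, 3),
                               gamma = runif(1, 0.2, 1),
                               lam = runif(1, 0.3, 1.5),
                               seed = 1000 + k)
    r <- estimate_rates_count(aln)
    o <- oracle_ng86_omega(aln$codons_a, aln$codons_b)
    expect_equal(r$omega, o$omega, tolerance = 1e-6)
    expect_equal(r$dS, o$dS, tolerance = 1e-9)
    expect_equal(r$dN, o$dN, tolerance = 1e-9)
  }
})
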