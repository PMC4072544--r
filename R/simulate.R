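# Synthetic-data generators with known ground truth: codon pair alignments
# evolved under the extended model, predicted-stability (ddG) record tables,
# and paired interaction networks with planted re-wired nodes. Every
# generator is deterministic given its seed.

#' Simulate an orthologous codon pair under the extended model
#'
#' Draws ancestor codons i.i.d. from `pi` and evolves two independent
#' lineages for t/2 each (`mode = "ancestor_split"`), or evolves a single
#' lineage for t and pairs it with the ancestor (`mode = "single_branch"`).
#' Lineage evolution samples endpoint states exactly from the transition
#' matrix (the pairwise likelihood only sees endpoints, so no within-branch
#' trajectory is needed). Under reversibility both modes produce the same
#' pair distribution.
#'
#' @param length number of codons (>= 1).
#' @param t,kappa,gamma,lam model parameters: divergence time (expected
#'   substitutions per codon), transition multiplier, nonsynonymous
#'   (conservative) multiplier, non-conservative multiplier on top of gamma.
#' @param pi equilibrium codon frequencies; default uniform over the 61
#'   sense codons.
#' @param seed integer seed (mandatory: the generator must be reproducible).
#' @param mode `"ancestor_split"` or `"single_branch"`.
#' @param cls a `substitution_classification`.
#' @param code a [standard_genetic_code()] object.
#' @param id pair identifier; defaults to one derived from the seed.
#' @return A gap-free [codon_pair_alignment()].
#' @examples
#' aln <- simulate_codon_pair(50, t = 0.3, kappa = 2, gamma = 0.3,
#'                            lam = 0.5, seed = 42)
#' sum(aln$valid_mask)
#' @export
simulate_codon_pair <- function(length, t, kappa, gamma, lam, pi = NULL,
                                seed, mode = c("ancestor_split", "single_branch"),
                                cls = table1_classification(),
                                code = standard_genetic_code(), id = NULL) {
  mode <- match.arg(mode)
  stopifnot(length >= 1)
  if (missing(seed)) abort("seed is mandatory for simulation")
  sense <- code$sense_codons
  if (is.null(pi)) pi <- setNames(rep(1 / length(sense), length(sense)), sense)
  Q <- build_rate_matrix(list(kappa = kappa, gamma = gamma, lam = lam),
                         pi, cls, code)
  pi <- attr(Q, "pi")

  draw_descendants <- function(anc_idx, P) {
    out <- integer(length(anc_idx))
    for (s in unique(anc_idx)) {
      sel <- anc_idx == s
      out[sel] <- sample.int(length(sense), sum(sel), replace = TRUE,
                             prob = P[s, ])
    }
    out
  }

  withr::with_seed(seed, {
    anc <- sample.int(length(sense), length, replace = TRUE, prob = pi)
    if (mode == "ancestor_split") {
      P_half <- transition_matrix(Q, t / 2)
      ia <- draw_descendants(anc, P_half)
      ib <- draw_descendants(anc, P_half)
    } else {
      P_full <- transition_matrix(Q, t)
      ia <- anc
      ib <- draw_descendants(anc, P_full)
    }
    codon_pair_alignment(sense[ia], sense[ib],
                         id = id %||% sprintf("sim_seed%d", seed),
                         code = code)
  })
}

# deterministic per-replicate seeds derived from a master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates codon pairs at known parameters and re-estimates
#' them, summarising per-parameter bias, root-mean-square error and median
#' relative error. Estimator failures are counted and reported, never fatal.
#'
#' @param true_params named list with `t`, `kappa`, `gamma`, `lam`.
#' @param length codons per simulated pair.
#' @param n_reps number of replicates (>= 2).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param estimator `"ml"` (full fit; recovers all four parameters) or
#'   `"count"` (pathway-counting estimator; recovers `lam` as dNC/dC plus
#'   `omega`, `dC`, `dNC`).
#' @param cls,code,pi as in [simulate_codon_pair()].
#' @param n_starts passed to [fit_ml()].
#' @return A tibble with one row per recovered parameter: `parameter`,
#'   `true`, `mean_estimate`, `bias`, `rmse`, `median_rel_error`,
#'   `n_ok`, `n_failed`. The per-replicate estimates are attached as
#'   `attr(, "estimates")` and the object carries class `ncr_recovery`
#'   for [autoplot()].
#' @export
parameter_recovery_experiment <- function(true_params, length = 500,
                                          n_reps = 100, seed = 1,
                                          estimator = c("ml", "count"),
                                          cls = table1_classification(),
                                          code = standard_genetic_code(),
                                          pi = NULL, n_starts = 2) {
  estimator <- match.arg(estimator)
  stopifnot(n_reps >= 2)
  seeds <- derive_seeds(seed, n_reps)
  est_rows <- purrr::map(seq_len(n_reps), function(r) {
    aln <- simulate_codon_pair(length, t = true_params$t,
                               kappa = true_params$kappa,
                               gamma = true_params$gamma,
                               lam = true_params$lam, pi = pi,
                               seed = seeds[r], cls = cls, code = code)
    tryCatch({
      if (estimator == "ml") {
        fit <- fit_ml(aln, cls, code, n_starts = n_starts)
        tibble(rep = r, t = fit$params$t, kappa = fit$params$kappa,
               gamma = fit$params$gamma, lam = fit$params$lam,
               loglik = fit$loglik, failed = FALSE)
      } else {
        cnt <- estimate_rates_count(aln, code, cls)
        tibble(rep = r, lam = cnt$lambda, omega = cnt$omega,
               dC = cnt$dC, dNC = cnt$dNC, failed = FALSE)
      }
    }, error = function(e) tibble(rep = r, failed = TRUE))
  })
  est <- dplyr::bind_rows(est_rows)
  ok <- dplyr::filter(est, !.data$failed)
  recovered <- intersect(names(ok), names(true_params))
  summary <- purrr::map_dfr(recovered, function(p) {
    x <- ok[[p]]
    x <- x[is.finite(x)]
    truth <- true_params[[p]]
    tibble(
      parameter = p, true = truth,
      mean_estimate = mean(x),
      bias = mean(x) - truth,
      rmse = sqrt(mean((x - truth)^2)),
      median_rel_error = stats::median(abs(x - truth) / truth),
      n_ok = base::length(x),
      n_failed = n_reps - nrow(ok)
    )
  })
  attr(summary, "estimates") <- est
  class(summary) <- c("ncr_recovery", class(summary))
  summary
}

#' Generate a synthetic table of predicted stability changes
#'
#' Emulates a predictor's per-mutation ddG output with planted per-pair
#' destabilizing fractions: for each amino-acid pair, a deterministic share
#' `round(fraction * n_per_pair)` of records is placed strictly below
#' -2 kcal/mol and the rest strictly above, with Gaussian jitter on the
#' magnitudes; records are split across both mutation directions.
#'
#' @param planted_fractions named numeric vector of destabilizing fractions
#'   in \[0, 1\], names are unordered pair keys (e.g. `"AV"`), or a data
#'   frame with columns `aa1`, `aa2`, `fraction`.
#' @param n_per_pair records per pair (default 200).
#' @param noise_sd kcal/mol jitter SD (default 0.5).
#' @param seed integer seed.
#' @return A tibble of records: `protein_id`, `position`, `aa_wt`,
#'   `aa_mut`, `ddg`.
#' @examples
#' tab <- synthetic_ddg_table(c(AV = 0.5, IL = 0.05), n_per_pair = 20,
#'                            seed = 1)
#' @export
synthetic_ddg_table <- function(planted_fractions, n_per_pair = 200,
                                noise_sd = 0.5, seed) {
  if (missing(seed)) abort("seed is mandatory for simulation")
  if (is.data.frame(planted_fractions)) {
    planted_fractions <- setNames(planted_fractions$fraction,
                                  pair_key(planted_fractions$aa1,
                                           planted_fractions$aa2))
  }
  if (any(planted_fractions < 0 | planted_fractions > 1)) {
    abort("planted fractions must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(names(planted_fractions), function(key) {
      a <- substr(key, 1, 1); b <- substr(key, 2, 2)
      n_destab <- round(planted_fractions[[key]] * n_per_pair)
      destab <- c(rep(TRUE, n_destab), rep(FALSE, n_per_pair - n_destab))
      # margin 0.2 keeps every record strictly on its planted side of -2
      ddg <- ifelse(destab,
                    -2 - 0.2 - abs(rnorm(n_per_pair, 0, noise_sd)),
                    -2 + 0.2 + abs(rnorm(n_per_pair, 0, noise_sd)))
      forward <- seq_len(n_per_pair) %% 2 == 0
      tibble(
        protein_id = sprintf("synthetic_%s", key),
        position = sample.int(500, n_per_pair, replace = TRUE),
        aa_wt = ifelse(forward, a, b),
        aa_mut = ifelse(forward, b, a),
        ddg = ddg
      )
    })
  })
}

#' Generate a pair of interaction networks with planted re-wired nodes
#'
#' Builds two random (Erdos-Renyi) graphs that share an orthologous core of
#' nodes, then plants re-wired nodes: selected orthologous nodes receive
#' `extra_nonortholog_edges` additional edges to species-specific
#' (non-orthologous) nodes in both networks. Ground-truth planted labels are
#' returned for recovery experiments.
#'
#' @param n_nodes nodes per species network (default 200).
#' @param edge_density Erdos-Renyi edge probability (default 0.02).
#' @param ortholog_fraction fraction of nodes with an ortholog in the other
#'   species (default 0.8).
#' @param n_planted_rewired number of planted re-wired ortholog nodes
#'   (default 10).
#' @param extra_nonortholog_edges extra species-specific edges per planted
#'   node (default 15).
#' @param seed integer seed.
#' @return A list with `edges_a`, `edges_b` (tibbles `node_a`, `node_b`),
#'   `ortholog_map` (tibble `node_sp1`, `node_sp2`) and `planted`
#'   (species-1 names of the planted nodes).
#' @export
synthetic_network_pair <- function(n_nodes = 200, edge_density = 0.02,
                                   ortholog_fraction = 0.8,
                                   n_planted_rewired = 10,
                                   extra_nonortholog_edges = 15, seed) {
  if (missing(seed)) abort("seed is mandatory for simulation")
  n_orth <- round(ortholog_fraction * n_nodes)
  n_spec <- n_nodes - n_orth
  if (n_planted_rewired > n_orth) {
    abort("more planted re-wired nodes than orthologous nodes")
  }
  if (n_planted_rewired > 0 && extra_nonortholog_edges > n_spec) {
    abort("extra_nonortholog_edges exceeds available species-specific nodes")
  }
  withr::with_seed(seed, {
    mk_species <- function(sp) {
      orth <- sprintf("o%03d_%s", seq_len(n_orth), sp)
      spec <- if (n_spec > 0) sprintf("s%s%03d", sp, seq_len(n_spec)) else character(0)
      nodes <- c(orth, spec)
      g <- igraph::sample_gnp(n_nodes, edge_density)
      el <- igraph::as_edgelist(g)
      edges <- tibble(node_a = nodes[el[, 1]], node_b = nodes[el[, 2]])
      list(nodes = nodes, orth = orth, spec = spec, edges = edges)
    }
    a <- mk_species("a")
    b <- mk_species("b")
    planted_idx <- if (n_planted_rewired > 0) {
      sort(sample.int(n_orth, n_planted_rewired))
    } else integer(0)
    add_planted <- function(sp) {
      if (length(planted_idx) == 0 || extra_nonortholog_edges == 0) {
        return(tibble(node_a = character(0), node_b = character(0)))
      }
      purrr::map_dfr(planted_idx, function(i) {
        targets <- sample(sp$spec, extra_nonortholog_edges)
        tibble(node_a = sp$orth[i], node_b = targets)
      })
    }
    edges_a <- dplyr::distinct(dplyr::bind_rows(a$edges, add_planted(a)))
    edges_b <- dplyr::distinct(dplyr::bind_rows(b$edges, add_planted(b)))
    list(
      edges_a = edges_a,
      edges_b = edges_b,
      ortholog_map = tibble(node_sp1 = a$orth, node_sp2 = b$orth),
      planted = a$orth[planted_idx]
    )
  })
}
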