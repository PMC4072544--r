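# Extended pairwise maximum-likelihood codon model.
#
# A reversible 61-state Markov model of codon substitution in the
# Goldman-Yang style. For codons i, j differing at exactly one nucleotide,
# the instantaneous rate is the target codon frequency pi_j multiplied by
#   kappa   if the nucleotide change is a transition,
#   gamma   if the codon change is nonsynonymous (conservative), and
#   gamma * lambda if the nonsynonymous change is non-conservative,
# with multipliers composing (an NC transition gets kappa * gamma * lambda).
# Codons differing at two or more positions have instantaneous rate 0.
# Setting lambda = 1 collapses the model to the standard omega-style
# parameterisation, so the conservative multiplier gamma then plays the
# role of omega = dN/dS.

#' Estimate equilibrium codon frequencies (F61-style)
#'
#' Frequencies proportional to pooled sense-codon counts plus a pseudocount
#' per sense codon, mirroring the F61 convention of using the average codon
#' composition of the sequences (or genomes) compared. The pseudocount
#' guarantees strictly positive frequencies.
#'
#' @param x either a character vector of coding sequences (concatenated
#'   codons; gap codons ignored) or a named numeric vector / two-column data
#'   frame of codon counts or frequencies (e.g. a genome codon table).
#' @param pseudocount added to each sense codon's count (default 0.5).
#' @param code a [standard_genetic_code()] object.
#' @return A named numeric vector over the 61 sense codons summing to 1.
#' @examples
#' pi <- estimate_codon_frequencies(c("ATGAAA", "ATGAAG"))
#' sum(pi)
#' @export
estimate_codon_frequencies <- function(x, pseudocount = 0.5,
                                       code = standard_genetic_code()) {
  counts <- setNames(numeric(length(code$sense_codons)), code$sense_codons)
  if (is.data.frame(x)) {
    x <- setNames(as.numeric(x[[2]]), toupper(as.character(x[[1]])))
  }
  if (is.character(x)) {
    codons <- unlist(lapply(toupper(x), split_codons))
    codons <- codons[codons %in% code$sense_codons]
    tab <- table(codons)
    counts[names(tab)] <- as.numeric(tab)
  } else if (is.numeric(x)) {
    if (is.null(names(x))) abort("codon table must be named by codon")
    names(x) <- toupper(names(x))
    if (any(names(x) %in% code$stop_codons & x > 0)) {
      abort("codon table assigns mass to stop codons")
    }
    keep <- names(x) %in% code$sense_codons
    counts[names(x)[keep]] <- counts[names(x)[keep]] + as.numeric(x[keep])
  } else {
    abort("x must be sequences or a codon count table")
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

# Precomputed neighbor structure of the 61-codon state space under a
# classification: index pairs of single-nt neighbors with their multipliers.
codon_model_structure <- function(code, cls) {
  key <- paste0("struct_", digest_keys(cls))
  cached <- get0(key, envir = .ncrates_cache)
  if (!is.null(cached)) return(cached)
  sense <- code$sense_codons
  n <- length(sense)
  ii <- jj <- integer(0)
  ts <- syn <- nc <- logical(0)
  for (i in seq_len(n)) {
    ci <- sense[i]
    muts <- single_nt_mutants(ci)
    for (m in muts) {
      j <- match(m, sense)
      if (is.na(j)) next
      pos <- which(strsplit(ci, "")[[1]] != strsplit(m, "")[[1]])
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, is_transition(substr(ci, pos, pos), substr(m, pos, pos)))
      ai <- code$codon_to_aa[[ci]]; aj <- code$codon_to_aa[[m]]
      s <- ai == aj
      syn <- c(syn, s)
      nc <- c(nc, if (s) FALSE else classify_pair(ai, aj, cls) == "NC")
    }
  }
  out <- list(i = ii, j = jj, transition = ts, synonymous = syn,
              nonconservative = nc, n = n, sense = sense)
  assign(key, out, envir = .ncrates_cache)
  out
}

#' Build the extended codon rate matrix
#'
#' @param params named numeric vector or list with `t` ignored here and
#'   `kappa`, `gamma`, `lam` (all > 0).
#' @param pi named frequency vector over the 61 sense codons (sums to 1).
#' @param cls a `substitution_classification` covering all neighbor pairs.
#' @param code a [standard_genetic_code()] object.
#' @return A 61 x 61 rate matrix `Q` (rows/cols named by codon) with rows
#'   summing to 0, satisfying detailed balance `pi_i q_ij = pi_j q_ji`, and
#'   scaled so the expected number of substitutions per codon per unit time,
#'   `-sum(pi_i q_ii)`, equals 1. The frequency vector is attached as
#'   `attr(Q, "pi")`.
#' @examples
#' pi <- rep(1 / 61, 61)
#' names(pi) <- standard_genetic_code()$sense_codons
#' Q <- build_rate_matrix(list(kappa = 2, gamma = 0.3, lam = 0.5), pi)
#' max(abs(rowSums(Q)))
#' @export
build_rate_matrix <- function(params, pi, cls = table1_classification(),
                              code = standard_genetic_code()) {
  params <- as.list(params)
  kappa <- params$kappa
  gamma <- params$gamma
  lam <- params$lam
  if (is.null(kappa) || is.null(gamma) || is.null(lam)) {
    abort("params must provide kappa, gamma and lam")
  }
  if (any(c(kappa, gamma, lam) < 0)) abort("rate multipliers must be >= 0")
  st <- codon_model_structure(code, cls)
  pi <- pi[st$sense]
  if (anyNA(pi)) abort("pi must be named by the 61 sense codons")
  Q <- matrix(0, st$n, st$n, dimnames = list(st$sense, st$sense))
  mult <- ifelse(st$transition, kappa, 1) *
    ifelse(st$synonymous, 1, gamma) *
    ifelse(st$nonconservative, lam, 1)
  Q[cbind(st$i, st$j)] <- unname(pi[st$j]) * mult
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  attr(Q, "pi") <- pi
  Q
}

#' Transition probability matrix P = exp(Qt)
#'
#' For the reversible rate matrices built by [build_rate_matrix()] the
#' exponential is computed through the symmetrized eigendecomposition
#' (numerically robust and fast); otherwise a scaling-and-squaring Pade
#' exponential is used. Entries are clipped at 0 from below.
#'
#' @param Q rate matrix (with `attr(Q, "pi")` for the symmetric path).
#' @param t time (expected substitutions per codon), >= 0.
#' @return A stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) abort("t must be >= 0")
  if (any(!is.finite(Q))) abort("non-finite rate matrix")
  pi <- attr(Q, "pi")
  if (!is.null(pi)) {
    dec <- eigen_reversible(Q, pi)
    P <- dec$inv_sqrt_pi * (dec$vectors %*%
      (exp(dec$values * t) * t(dec$vectors))) %*% diag(dec$sqrt_pi)
    dimnames(P) <- dimnames(Q)
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q) * t))
  }
  P[P < 0] <- 0
  P
}

# symmetrized eigendecomposition of a reversible Q: B = D^1/2 Q D^-1/2
eigen_reversible <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- sq * t(t(unclass(Q)) / sq)  # B_ij = sqrt(pi_i) q_ij / sqrt(pi_j)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, sqrt_pi = sq,
       inv_sqrt_pi = 1 / sq)
}

#' Codon pair counts of an alignment
#'
#' @param aln a [codon_pair_alignment()].
#' @param code a [standard_genetic_code()] object.
#' @return 61 x 61 integer matrix `n`; `n[i, j]` counts valid columns with
#'   codon i in sequence a and codon j in sequence b.
#' @export
codon_pair_counts <- function(aln, code = standard_genetic_code()) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  sense <- code$sense_codons
  a <- factor(aln$codons_a[aln$valid_mask], levels = sense)
  b <- factor(aln$codons_b[aln$valid_mask], levels = sense)
  unclass(table(a, b))
}

#' Pairwise log-likelihood of codon pair counts
#'
#' The two sequences are separated by total time `t` under the reversible
#' model (equivalent to two branches of t/2 from an unobserved ancestor), so
#' the likelihood of observing codons (i, j) in a column is
#' `pi_i * P_ij(t)` and the alignment log-likelihood is
#' `sum_ij n_ij log(pi_i P_ij(t))`.
#'
#' @param n 61 x 61 pair count matrix from [codon_pair_counts()].
#' @param params list/vector with `t`, `kappa`, `gamma`, `lam`.
#' @param pi frequency vector over the sense codons.
#' @param cls a `substitution_classification`.
#' @param code a [standard_genetic_code()] object.
#' @return The log-likelihood (`-Inf` if an observed pair has probability
#'   0).
#' @export
pair_log_likelihood <- function(n, params, pi,
                                cls = table1_classification(),
                                code = standard_genetic_code()) {
  params <- as.list(params)
  t <- params$t
  if (is.null(t)) abort("params must provide t")
  Q <- build_rate_matrix(params, pi, cls, code)
  P <- transition_matrix(Q, t)
  pi <- attr(Q, "pi")
  nz <- which(n > 0, arr.ind = TRUE)
  probs <- pi[nz[, 1]] * P[nz]
  if (any(probs <= 0)) return(-Inf)
  sum(n[nz] * log(probs))
}

# deterministic multiplicative jitter factors for multi-start optimisation
# (log-scale offsets; row k seeds start k+1)
START_JITTER <- matrix(c(
   0.7, -0.7,  0.7, -0.7,
  -0.7,  0.7, -0.7,  0.7,
   1.0,  0.0, -1.0,  0.0,
   0.0, -1.0,  0.0,  1.0,
  -1.0,  1.0,  1.0, -1.0,
   0.5,  0.5, -0.5, -0.5,
  -0.5, -0.5,  0.5,  0.5,
   1.2, -0.3,  0.3, -1.2,
  -0.3,  1.2, -1.2,  0.3
), ncol = 4, byrow = TRUE)

new_ml_fit <- function(params, loglik, converged, n_starts, pi, notes,
                       kind = "extended") {
  structure(
    list(params = params, loglik = loglik, converged = converged,
         n_starts = n_starts, pi = pi, notes = notes, kind = kind),
    class = "ml_fit"
  )
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit>", x$kind, "pairwise codon model\n")
  print(round(unlist(x$params), 4))
  cat("loglik:", format(x$loglik), " converged:", x$converged,
      if (length(x$notes)) paste0(" [", paste(x$notes, collapse = "; "), "]"),
      "\n")
  invisible(x)
}

#' @export
tidy.ml_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(unlist(x$params)))
}

#' @export
glance.ml_fit <- function(x, ...) {
  out <- as_tibble(as.list(unlist(x$params)))
  out$loglik <- x$loglik
  out$converged <- x$converged
  out$n_starts <- x$n_starts
  out$flags <- paste(x$notes, collapse = ";")
  out
}

ml_optimise <- function(n, pi, cls, code, free, fixed, start, n_starts, tol) {
  negll <- function(theta) {
    p <- as.list(exp(pmin(pmax(theta, log(1e-8)), log(1e8))))
    names(p) <- free
    p <- c(p, fixed)
    ll <- pair_log_likelihood(n, p, pi, cls, code)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  n_fail <- 0
  for (k in seq_len(n_starts)) {
    th0 <- log(unlist(start))
    if (k > 1) {
      jit <- START_JITTER[((k - 2) %% nrow(START_JITTER)) + 1L,
                          seq_along(free)]
      th0 <- th0 + jit
    }
    opt <- tryCatch(
      optim(th0, negll, method = "Nelder-Mead",
            control = list(reltol = tol, maxit = 5000)),
      error = function(e) NULL
    )
    if (is.null(opt)) { n_fail <- n_fail + 1; next }
    if (is.null(best) || opt$value < best$value - 1e-10 ||
        (abs(opt$value - best$value) <= 1e-10 &&
         exp(opt$par[1]) < exp(best$par[1]))) {
      best <- opt
    }
  }
  if (is.null(best)) {
    abort(paste0("maximum-likelihood optimisation failed in all ", n_starts,
                 " starts (", n_fail, " errors)"))
  }
  est <- exp(pmin(pmax(best$par, log(1e-8)), log(1e8)))
  names(est) <- free
  list(estimate = est, loglik = -best$value,
       converged = best$convergence == 0)
}

boundary_notes <- function(est) {
  notes <- character(0)
  if (!is.null(est[["t"]]) && est[["t"]] < 1e-6) {
    notes <- c(notes, "t_at_lower_bound")
  }
  for (nm in setdiff(names(est), "t")) {
    if (est[[nm]] < 1e-4) notes <- c(notes, paste0(nm, "_at_lower_bound"))
    if (est[[nm]] > 1e4) notes <- c(notes, paste0(nm, "_at_upper_bound"))
  }
  notes
}

# count-model seeded starting values, with safe defaults when degenerate
count_seeded_start <- function(aln, code, cls) {
  start <- list(t = 0.2, kappa = 2, gamma = 0.3, lam = 0.5)
  cnt <- tryCatch(estimate_rates_count(aln, code, cls), error = function(e) NULL)
  if (is.null(cnt)) return(start)
  n_codons <- sum(aln$valid_mask)
  ok <- function(x) !is.na(x) && is.finite(x) && x > 0
  if (ok(cnt$dS) && ok(cnt$dN) && n_codons > 0) {
    t0 <- (cnt$dS * cnt$s_sites + cnt$dN * cnt$n_sites) / n_codons
    if (ok(t0)) start$t <- min(max(t0, 1e-3), 20)
  }
  if (ok(cnt$dC) && ok(cnt$dS)) {
    start$gamma <- min(max(cnt$dC / cnt$dS, 1e-3), 100)
  }
  if (ok(cnt$lambda)) start$lam <- min(max(cnt$lambda, 1e-3), 100)
  start
}

#' Fit the extended pairwise codon model by maximum likelihood
#'
#' Maximizes the pairwise log-likelihood over (t, kappa, gamma, lambda)
#' with a derivative-free simplex search on log-transformed parameters.
#' The first start is seeded from the count-model estimates; further starts
#' apply fixed log-scale jitters. Estimates pinned at the internal bounds
#' (t below 1e-6, multipliers outside [1e-4, 1e4]) are flagged in `notes`.
#'
#' @param aln a curated [codon_pair_alignment()] with at least one valid
#'   column.
#' @param cls a `substitution_classification`.
#' @param code a [standard_genetic_code()] object.
#' @param pi_mode `"from_pair"` (F61-style frequencies pooled from the two
#'   sequences with pseudocount 0.5) or `"supplied"` (pass `pi`).
#' @param pi frequency vector when `pi_mode = "supplied"`.
#' @param n_starts number of optimisation starts (default 3).
#' @param tol relative convergence tolerance (default 1e-8).
#' @return An `ml_fit` with `params` (t, kappa, gamma, lam), `loglik`,
#'   `converged`, `n_starts`, `pi` and boundary `notes`. Use [tidy()] /
#'   [glance()] for tabular access.
#' @examples
#' aln <- simulate_codon_pair(length = 120, t = 0.3, kappa = 2,
#'                            gamma = 0.4, lam = 0.5, seed = 1)
#' fit <- fit_ml(aln, n_starts = 1)
#' tidy(fit)
#' @export
fit_ml <- function(aln, cls = table1_classification(),
                   code = standard_genetic_code(),
                   pi_mode = c("from_pair", "supplied"), pi = NULL,
                   n_starts = 3, tol = 1e-8) {
  pi_mode <- match.arg(pi_mode)
  stopifnot(inherits(aln, "codon_pair_alignment"))
  if (!any(aln$valid_mask)) abort("alignment has no valid codon columns")
  if (pi_mode == "from_pair") {
    seqs <- c(paste(aln$codons_a[aln$valid_mask], collapse = ""),
              paste(aln$codons_b[aln$valid_mask], collapse = ""))
    pi <- estimate_codon_frequencies(seqs, code = code)
  } else if (is.null(pi)) {
    abort("pi_mode='supplied' requires pi")
  }
  n <- codon_pair_counts(aln, code)
  start <- count_seeded_start(aln, code, cls)
  res <- ml_optimise(n, pi, cls, code,
                     free = c("t", "kappa", "gamma", "lam"),
                     fixed = list(), start = start, n_starts = n_starts,
                     tol = tol)
  new_ml_fit(as.list(res$estimate), res$loglik, res$converged, n_starts, pi,
             boundary_notes(res$estimate), kind = "extended")
}

#' Fit the standard omega model (lambda fixed at 1)
#'
#' Fits the same machinery with the C/NC distinction collapsed (lambda fixed
#' to 1), so the nonsynonymous multiplier plays the role of
#' omega = dN/dS; the estimate is reported as `omega`.
#'
#' @inheritParams fit_ml
#' @return An `ml_fit` with `params` (t, kappa, omega).
#' @export
fit_standard_omega <- function(aln, cls = table1_classification(),
                               code = standard_genetic_code(),
                               pi_mode = c("from_pair", "supplied"),
                               pi = NULL, n_starts = 3, tol = 1e-8) {
  pi_mode <- match.arg(pi_mode)
  stopifnot(inherits(aln, "codon_pair_alignment"))
  if (!any(aln$valid_mask)) abort("alignment has no valid codon columns")
  if (pi_mode == "from_pair") {
    seqs <- c(paste(aln$codons_a[aln$valid_mask], collapse = ""),
              paste(aln$codons_b[aln$valid_mask], collapse = ""))
    pi <- estimate_codon_frequencies(seqs, code = code)
  } else if (is.null(pi)) {
    abort("pi_mode='supplied' requires pi")
  }
  n <- codon_pair_counts(aln, code)
  start0 <- count_seeded_start(aln, code, cls)
  res <- ml_optimise(n, pi, cls, code,
                     free = c("t", "kappa", "gamma"),
                     fixed = list(lam = 1),
                     start = start0[c("t", "kappa", "gamma")],
                     n_starts = n_starts, tol = tol)
  est <- res$estimate
  params <- list(t = est[["t"]], kappa = est[["kappa"]],
                 omega = est[["gamma"]])
  notes <- boundary_notes(setNames(unlist(params), names(params)))
  new_ml_fit(params, res$loglik, res$converged, n_starts, pi, notes,
             kind = "standard_omega")
}
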