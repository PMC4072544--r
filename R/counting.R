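# Extended Nei-Gojobori-style count estimator.
#
# Classical NG86 partitions nucleotide sites and observed differences into
# synonymous and nonsynonymous classes; here the nonsynonymous class is
# further split into conservative (C) and non-conservative (NC) amino-acid
# changes, giving the four rates dS, dN, dC, dNC, the classical ratio
# omega = dN/dS and the stability-partitioning ratio lambda = dNC/dC.

#' Site opportunities of a single codon
#'
#' For each of the three codon positions, considers the single-nucleotide
#' mutants that are sense codons and computes the fraction that are
#' synonymous; synonymous sites are the sum of these fractions and
#' nonsynonymous sites the complement (stop mutants are excluded from both
#' numerator and denominator, so `s_sites + n_sites = 3` for every codon).
#' The nonsynonymous fraction at each position is partitioned into
#' conservative and non-conservative parts by classifying each mutant
#' amino-acid pair.
#'
#' @param codon a sense codon string, e.g. `"TTT"`.
#' @param code a [standard_genetic_code()] object.
#' @param cls a `substitution_classification` covering all neighbor pairs.
#' @return A one-row tibble with columns `s_sites`, `n_sites`, `c_sites`,
#'   `nc_sites`.
#' @examples
#' codon_site_opportunities("TTT")
#' @export
codon_site_opportunities <- function(codon, code = standard_genetic_code(),
                                     cls = table1_classification()) {
  aa <- code$codon_to_aa[[codon]]
  if (is.na(aa) || aa == "*") abort(paste0("not a sense codon: ", codon))
  s <- n <- cc <- nc <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    muts <- vapply(DNA_BASES[DNA_BASES != ref], function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, character(1))
    aas <- code$codon_to_aa[muts]
    sense <- aas != "*"
    n_sense <- sum(sense)
    if (n_sense == 0) next  # cannot occur in the standard code
    syn <- sense & aas == aa
    nonsyn_aas <- aas[sense & aas != aa]
    s <- s + sum(syn) / n_sense
    n <- n + length(nonsyn_aas) / n_sense
    if (length(nonsyn_aas) > 0) {
      lab <- classify_pair(rep(aa, length(nonsyn_aas)), nonsyn_aas, cls)
      cc <- cc + sum(lab == "C") / n_sense
      nc <- nc + sum(lab == "NC") / n_sense
    }
  }
  tibble(s_sites = s, n_sites = n, c_sites = cc, nc_sites = nc)
}

# memoised per-codon site opportunities for all 61 sense codons
all_codon_site_opportunities <- function(code, cls) {
  key <- paste0("sites_", cls$source, "_", digest_keys(cls))
  cached <- get0(key, envir = .ncrates_cache)
  if (!is.null(cached)) return(cached)
  tab <- purrr::map_dfr(code$sense_codons, function(cd) {
    codon_site_opportunities(cd, code, cls)
  })
  tab <- as.matrix(tab)
  rownames(tab) <- code$sense_codons
  assign(key, tab, envir = .ncrates_cache)
  tab
}

.ncrates_cache <- new.env(parent = emptyenv())

digest_keys <- function(cls) {
  # cheap stable fingerprint of the NC set (cache key only)
  paste0(length(cls$c_pairs), "_", length(cls$nc_pairs), "_",
         paste(substr(cls$nc_pairs, 1, 2), collapse = ""))
}

#' Site counts of a codon pair alignment
#'
#' Sums per-codon site opportunities over valid columns for each sequence
#' separately, then averages the two totals component-wise (the standard
#' two-sequence convention of pathway-counting estimators).
#'
#' @param aln a [codon_pair_alignment()].
#' @inheritParams codon_site_opportunities
#' @return One-row tibble with `s_sites`, `n_sites`, `c_sites`, `nc_sites`.
#' @export
pair_site_counts <- function(aln, code = standard_genetic_code(),
                             cls = table1_classification()) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  if (!any(aln$valid_mask)) abort("alignment has no valid codon columns")
  per_codon <- all_codon_site_opportunities(code, cls)
  a <- aln$codons_a[aln$valid_mask]
  b <- aln$codons_b[aln$valid_mask]
  tot <- (colSums(per_codon[a, , drop = FALSE]) +
          colSums(per_codon[b, , drop = FALSE])) / 2
  tibble(s_sites = tot[["s_sites"]], n_sites = tot[["n_sites"]],
         c_sites = tot[["c_sites"]], nc_sites = tot[["nc_sites"]])
}

# label one single-nucleotide codon step: "syn", "C" or "NC"
step_label <- function(from, to, code, cls) {
  aa1 <- code$codon_to_aa[[from]]
  aa2 <- code$codon_to_aa[[to]]
  if (aa1 == aa2) "syn" else classify_pair(aa1, aa2, cls)
}

#' Pathway-averaged difference counts between two codons
#'
#' Codons differing at several positions can have evolved through different
#' orders of the single changes; each order is a mutational pathway (1, 2 or
#' 6 pathways for 1, 2 or 3 differing positions). Every step of a pathway is
#' labeled synonymous, conservative or non-conservative, pathways that
#' traverse a stop codon are discarded, and the per-class step counts are
#' averaged over the retained pathways. In the degenerate case where every
#' pathway traverses a stop codon, all pathways are kept and only their
#' stop-free steps contribute.
#'
#' @param codon_a,codon_b sense codons.
#' @inheritParams codon_site_opportunities
#' @return One-row tibble with `sd`, `nd`, `cd`, `ncd` (fractional counts).
#' @examples
#' pathway_difference_counts("TTT", "GTA")
#' @export
pathway_difference_counts <- function(codon_a, codon_b,
                                      code = standard_genetic_code(),
                                      cls = table1_classification()) {
  for (cd in c(codon_a, codon_b)) {
    aa <- code$codon_to_aa[[cd]]
    if (is.na(aa) || aa == "*") abort(paste0("not a sense codon: ", cd))
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  zero <- tibble(sd = 0, nd = 0, cd = 0, ncd = 0)
  if (length(diff_pos) == 0) return(zero)

  orderings <- permutations_of(diff_pos)
  per_path <- lapply(orderings, function(ord) {
    cur <- codon_a
    steps <- character(length(ord))
    blocked <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[k], ord[k]) <- substr(codon_b, ord[k], ord[k])
      from_stop <- code$codon_to_aa[[cur]] == "*"
      to_stop <- code$codon_to_aa[[nxt]] == "*"
      if (from_stop || to_stop) {
        blocked <- TRUE
        steps[k] <- "stop"
      } else {
        steps[k] <- step_label(cur, nxt, code, cls)
      }
      cur <- nxt
    }
    list(blocked = blocked, steps = steps)
  })

  blocked <- vapply(per_path, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) per_path else per_path[!blocked]
  tally <- function(lab) {
    mean(vapply(use, function(p) sum(p$steps == lab), numeric(1)))
  }
  sd_ <- tally("syn"); cd_ <- tally("C"); ncd_ <- tally("NC")
  tibble(sd = sd_, nd = cd_ + ncd_, cd = cd_, ncd = ncd_)
}

# all orderings of a vector (n <= 3 in practice)
permutations_of <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differences per site into an expected
#' number of substitutions per site, `d = -(3/4) * log(1 - (4/3) * p)`.
#'
#' @param p proportion(s) of observed differences per site, in `[0, 3/4)`.
#' @param class_label optional label naming the substitution class, used in
#'   the saturation error message.
#' @return Corrected distance(s).
#' @examples
#' jukes_cantor_correct(0.3)
#' @export
jukes_cantor_correct <- function(p, class_label = NULL) {
  if (any(p < 0)) abort("negative proportion of differences")
  if (any(p >= 0.75)) {
    lab <- if (is.null(class_label)) "" else paste0(" [class ", class_label, "]")
    abort(paste0("saturation: proportion of differences >= 3/4", lab),
          class = "ncrates_saturation")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Count-model rate estimates for a codon pair alignment
#'
#' The extended pathway-counting estimator: observed differences are
#' partitioned into synonymous, conservative and non-conservative classes by
#' pathway averaging, divided by the corresponding site counts, and each
#' proportion is Jukes-Cantor corrected independently. Rate ratios
#' `omega = dN/dS` and `lambda = dNC/dC` are flagged undefined when their
#' denominator is 0.
#'
#' @param aln a [codon_pair_alignment()].
#' @inheritParams codon_site_opportunities
#' @param id identifier copied to the output row (defaults to the
#'   alignment's id).
#' @return A one-row tibble: `id`, site counts (`s_sites`, `n_sites`,
#'   `c_sites`, `nc_sites`), difference counts (`sd`, `nd`, `cd`, `ncd`),
#'   rates (`dS`, `dN`, `dC`, `dNC`), ratios (`omega`, `lambda`) and a
#'   `flags` string (`;`-separated).
#' @examples
#' aln <- codon_pair_alignment(c("TTT", "GCT"), c("TTA", "GCC"))
#' estimate_rates_count(aln)
#' @export
estimate_rates_count <- function(aln, code = standard_genetic_code(),
                                 cls = table1_classification(),
                                 id = NULL) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  id <- id %||% aln$id
  sites <- pair_site_counts(aln, code, cls)

  a <- aln$codons_a[aln$valid_mask]
  b <- aln$codons_b[aln$valid_mask]
  differ <- a != b
  if (any(differ)) {
    diffs <- purrr::map2_dfr(a[differ], b[differ], pathway_difference_counts,
                             code = code, cls = cls) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum))
  } else {
    diffs <- tibble(sd = 0, nd = 0, cd = 0, ncd = 0)
  }

  flags <- character(0)
  rate <- function(d, s, lab) {
    if (s <= 0) {
      flags <<- c(flags, paste0("no_", lab, "_sites"))
      return(NA_real_)
    }
    jukes_cantor_correct(d / s, class_label = lab)
  }
  dS <- rate(diffs$sd, sites$s_sites, "S")
  dN <- rate(diffs$nd, sites$n_sites, "N")
  dC <- rate(diffs$cd, sites$c_sites, "C")
  dNC <- rate(diffs$ncd, sites$nc_sites, "NC")

  ratio <- function(num, den, lab) {
    if (is.na(num) || is.na(den) || den == 0) {
      flags <<- c(flags, paste0(lab, "_undefined"))
      return(NA_real_)
    }
    num / den
  }
  omega <- ratio(dN, dS, "omega")
  lam <- ratio(dNC, dC, "lambda")

  tibble(
    id = id,
    s_sites = sites$s_sites, n_sites = sites$n_sites,
    c_sites = sites$c_sites, nc_sites = sites$nc_sites,
    sd = diffs$sd, nd = diffs$nd, cd = diffs$cd, ncd = diffs$ncd,
    dS = dS, dN = dN, dC = dC, dNC = dNC,
    omega = omega, lambda = lam,
    flags = paste(flags, collapse = ";")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
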