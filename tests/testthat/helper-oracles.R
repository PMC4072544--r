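# Independent oracles, deliberately implemented with different algorithms
# and data structures than the package internals.

oracle_code <- local({
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
})

# classification lookup table driven off the tidied classification,
# not classify_pair()
oracle_label_fun <- function(cls) {
  tab <- tidy(cls)
  labels <- setNames(tab$label, paste0(tab$aa1, tab$aa2))
  function(a, b) {
    lab <- labels[paste0(min(a, b), max(a, b))]
    unname(lab)
  }
}

# Exhaustive pathway enumeration by recursion over remaining positions.
# Returns c(sd, nd, cd, ncd) averaged over retained (stop-free) pathways,
# falling back to all pathways with stop-adjacent steps dropped.
oracle_pathway_counts <- function(codon_a, codon_b, label_of) {
  enumerate <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(pos) == 0) {
      return(list(list(steps = character(0), blocked = FALSE)))
    }
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      this_step <- if (oracle_code[[cur]] == "*" || oracle_code[[nxt]] == "*") {
        "stop"
      } else if (oracle_code[[cur]] == oracle_code[[nxt]]) {
        "syn"
      } else {
        label_of(oracle_code[[cur]], oracle_code[[nxt]])
      }
      for (tail_path in enumerate(nxt, target)) {
        out[[length(out) + 1L]] <- list(
          steps = c(this_step, tail_path$steps),
          blocked = this_step == "stop" || tail_path$blocked
        )
      }
    }
    out
  }
  paths <- enumerate(codon_a, codon_b)
  keep <- Filter(function(p) !p$blocked, paths)
  if (length(keep) == 0) keep <- paths
  avg <- function(lab) {
    mean(vapply(keep, function(p) sum(p$steps == lab), numeric(1)))
  }
  c(sd = avg("syn"), nd = avg("C") + avg("NC"), cd = avg("C"), ncd = avg("NC"))
}

# Textbook NG86 dN/dS on a pair of gap-free aligned codon vectors, written
# without the package's classification machinery: synonymous/nonsynonymous
# only, sense-mutant site denominators, pathway averaging with stop-free
# pathways, Jukes-Cantor correction.
oracle_ng86_omega <- function(codons_a, codons_b) {
  syn_sites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      n_syn <- 0L; n_sense <- 0L
      for (b in setdiff(c("A", "C", "G", "T"), ref)) {
        mut <- codon
        substr(mut, pos, pos) <- b
        if (oracle_code[[mut]] == "*") next
        n_sense <- n_sense + 1L
        if (oracle_code[[mut]] == oracle_code[[codon]]) n_syn <- n_syn + 1L
      }
      if (n_sense > 0) s <- s + n_syn / n_sense
    }
    s
  }
  S <- (sum(vapply(codons_a, syn_sites, numeric(1))) +
        sum(vapply(codons_b, syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S

  lab <- function(a, b) "C"  # every nonsynonymous step in one class
  sd <- nd <- 0
  for (k in seq_along(codons_a)) {
    if (codons_a[k] == codons_b[k]) next
    cnt <- oracle_pathway_counts(codons_a[k], codons_b[k], lab)
    sd <- sd + cnt[["sd"]]
    nd <- nd + cnt[["nd"]]
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  dN <- jc(nd / N)
  dS <- jc(sd / S)
  list(dN = dN, dS = dS, omega = dN / dS)
}

# Brandes-free betweenness: BFS shortest-path counting per source pair.
oracle_betweenness <- function(adj) {
  nodes <- names(adj)
  btw <- setNames(numeric(length(nodes)), nodes)
  for (si in seq_along(nodes)) {
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      s <- nodes[si]; t <- nodes[ti]
      # BFS from s recording distances and path counts
      dist <- setNames(rep(Inf, length(nodes)), nodes)
      sigma <- setNames(rep(0, length(nodes)), nodes)
      dist[s] <- 0; sigma[s] <- 1
      frontier <- s
      while (length(frontier) > 0) {
        nxt <- character(0)
        for (v in frontier) {
          for (w in adj[[v]]) {
            if (is.infinite(dist[w])) {
              dist[w] <- dist[v] + 1
              nxt <- c(nxt, w)
            }
            if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
          }
        }
        frontier <- unique(nxt)
      }
      if (is.infinite(dist[t])) next
      # fraction of s-t shortest paths through each interior node v:
      # sigma_s(v) * sigma_t(v) / sigma_s(t) for nodes with
      # d_s(v) + d_t(v) = d_s(t)
      dist_t <- setNames(rep(Inf, length(nodes)), nodes)
      sigma_t <- setNames(rep(0, length(nodes)), nodes)
      dist_t[t] <- 0; sigma_t[t] <- 1
      frontier <- t
      while (length(frontier) > 0) {
        nxt <- character(0)
        for (v in frontier) {
          for (w in adj[[v]]) {
            if (is.infinite(dist_t[w])) {
              dist_t[w] <- dist_t[v] + 1
              nxt <- c(nxt, w)
            }
            if (dist_t[w] == dist_t[v] + 1) sigma_t[w] <- sigma_t[w] + sigma_t[v]
          }
        }
        frontier <- unique(nxt)
      }
      interior <- setdiff(nodes, c(s, t))
      for (v in interior) {
        if (dist[v] + dist_t[v] == dist[t]) {
          btw[v] <- btw[v] + sigma[v] * sigma_t[v] / sigma[t]
        }
      }
    }
  }
  btw
}
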