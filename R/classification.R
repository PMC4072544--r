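# Conservative / non-conservative classification of amino-acid substitutions.
#
# A substitution is called non-conservative (NC) when mutations between the
# two residues are frequently predicted to be highly destabilizing
# (ddG < -2 kcal/mol in at least 20% of sampled sequence contexts), and
# conservative (C) otherwise. Only amino-acid pairs that are direct
# single-nucleotide neighbors in the genetic code are in the domain of the
# classification: these are the only pairs that can interconvert through a
# single point mutation, which is what the codon models act on.

new_substitution_classification <- function(nc_keys, c_keys, source,
                                            summary = NULL, uncovered = character(0)) {
  nc_keys <- sort(unique(nc_keys))
  c_keys <- sort(unique(c_keys))
  if (length(intersect(nc_keys, c_keys)) > 0) {
    abort(paste0(
      "inconsistent classification: pair(s) labeled both C and NC: ",
      paste(intersect(nc_keys, c_keys), collapse = ", ")
    ))
  }
  structure(
    list(nc_pairs = nc_keys, c_pairs = c_keys, source = source,
         summary = summary, uncovered = sort(unique(uncovered))),
    class = "substitution_classification"
  )
}

#' @export
print.substitution_classification <- function(x, ...) {
  cat("<substitution_classification> source:", x$source, "\n",
      " ", length(x$c_pairs), "conservative pairs,",
      length(x$nc_pairs), "non-conservative pairs\n")
  if (length(x$uncovered) > 0) {
    cat("  ", length(x$uncovered), "neighbor pairs without records (uncovered)\n")
  }
  invisible(x)
}

#' @export
tidy.substitution_classification <- function(x, ...) {
  keys <- c(x$c_pairs, x$nc_pairs)
  tibble(
    aa1 = substr(keys, 1, 1),
    aa2 = substr(keys, 2, 2),
    label = rep(c("C", "NC"), c(length(x$c_pairs), length(x$nc_pairs)))
  ) |>
    dplyr::arrange(.data$aa1, .data$aa2)
}

# Stability-based C/NC assignment for the 75 single-nucleotide-neighbor
# amino-acid pairs. For each residue, the partners it can reach by one
# point mutation, split by how often mutations between the two residues are
# predicted highly destabilizing (>= 20% of occurrences -> NC).
CANONICAL_C <- list(
  A = c("D", "E", "G", "S", "T"),
  C = c("G", "R", "S", "W", "Y"),
  D = c("A", "E", "G", "H", "N", "V", "Y"),
  E = c("A", "D", "G", "K", "Q", "V"),
  F = c("I", "L", "Y"),
  G = c("A", "C", "D", "E", "R"),
  H = c("D", "L", "N", "P", "Q", "R", "Y"),
  I = c("F", "L", "M", "N", "V"),
  K = c("E", "M", "N", "Q", "R", "T"),
  L = c("F", "H", "I", "M", "P", "Q", "R", "V", "W"),
  M = c("I", "K", "L", "R", "T", "V"),
  N = c("D", "H", "I", "K", "S", "T", "Y"),
  P = c("H", "L", "Q", "R", "S"),
  Q = c("E", "H", "K", "L", "P", "R"),
  R = c("C", "G", "H", "K", "L", "M", "P", "Q", "T", "W"),
  S = c("A", "C", "N", "P", "T", "W", "Y"),
  T = c("A", "K", "M", "N", "R", "S"),
  V = c("D", "E", "I", "L", "M"),
  W = c("C", "L", "R", "S"),
  Y = c("C", "D", "F", "H", "N", "S")
)

CANONICAL_NC <- list(
  A = c("P", "V"),
  C = "F",
  F = c("C", "S", "V"),
  G = c("S", "V", "W"),
  I = c("K", "R", "S", "T"),
  K = "I",
  L = "S",
  P = c("A", "T"),
  R = c("I", "S"),
  S = c("F", "G", "I", "L", "R"),
  T = c("I", "P"),
  V = c("A", "F", "G"),
  W = "G"
)

#' The canonical stability-based C/NC classification
#'
#' Returns the canonical classification of the 75 single-nucleotide-neighbor
#' amino-acid pairs into conservative (C) and non-conservative (NC)
#' substitutions, derived from large-scale predicted folding free-energy
#' changes across the yeast cytosolic proteome (pairs whose mutations are
#' highly destabilizing, ddG < -2 kcal/mol, in at least 20% of occurrences
#' are NC). 60 pairs are conservative and 15 non-conservative; no NC pair
#' has a positive BLOSUM62 score.
#'
#' @return A `substitution_classification` object with fields `nc_pairs`,
#'   `c_pairs` (canonical two-letter pair keys) and `source = "table1"`.
#' @examples
#' cls <- table1_classification()
#' classify_pair("V", "A", cls)
#' tidy(cls)
#' @export
table1_classification <- function() {
  expand_keys <- function(lst) {
    unlist(lapply(names(lst), function(a) pair_key(a, lst[[a]])))
  }
  new_substitution_classification(
    nc_keys = expand_keys(CANONICAL_NC),
    c_keys = expand_keys(CANONICAL_C),
    source = "table1"
  )
}

#' Classify an amino-acid substitution as conservative or non-conservative
#'
#' Direction-independent lookup: `classify_pair("V", "A", cls)` and
#' `classify_pair("A", "V", cls)` give the same label.
#'
#' @param aa_from,aa_to one-letter residues (vectors are recycled pairwise).
#' @param cls a `substitution_classification`, e.g.
#'   [table1_classification()].
#' @return character vector of labels, `"C"` or `"NC"`.
#' @export
classify_pair <- function(aa_from, aa_to, cls = table1_classification()) {
  if (any(aa_from == aa_to)) {
    abort("not a substitution: identical residues supplied")
  }
  keys <- pair_key(aa_from, aa_to)
  out <- character(length(keys))
  out[keys %in% cls$c_pairs] <- "C"
  out[keys %in% cls$nc_pairs] <- "NC"
  if (any(out == "")) {
    bad <- unique(keys[out == ""])
    abort(paste0(
      "not classifiable (multi-nucleotide amino-acid pair or uncovered): ",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

#' Derive a C/NC classification from predicted stability changes
#'
#' Pools predicted folding free-energy changes (ddG, kcal/mol; negative
#' destabilizes) bidirectionally per unordered amino-acid pair, computes the
#' fraction of records that are highly destabilizing (`ddg < ddg_cutoff`,
#' strict), and labels a pair non-conservative when that fraction reaches
#' `fraction_cutoff` (pairs destabilizing in less than the cutoff fraction of
#' occurrences are conservative). Only single-nucleotide-neighbor pairs are
#' classified; neighbor pairs without any record are reported in the
#' `uncovered` field, never silently defaulted.
#'
#' @param records data frame with columns `aa_wt`, `aa_mut`, `ddg`
#'   (additional columns such as `protein_id`, `position` are ignored).
#' @param ddg_cutoff highly-destabilizing threshold in kcal/mol; a record
#'   counts as highly destabilizing when `ddg < ddg_cutoff` (default -2).
#' @param fraction_cutoff proportion of highly destabilizing occurrences at
#'   or above which a pair is NC (default 0.20).
#' @param code a [standard_genetic_code()] object.
#' @return A `substitution_classification` whose `summary` field is a tibble
#'   with one row per covered pair (`aa1`, `aa2`, `n_total`,
#'   `n_destabilizing`, `fraction`, `label`).
#' @examples
#' recs <- tibble::tibble(
#'   aa_wt = c("V", "A", "L"), aa_mut = c("A", "V", "I"),
#'   ddg = c(-3.5, -0.1, 0.2)
#' )
#' cls <- derive_classification(recs)
#' cls$nc_pairs
#' @export
derive_classification <- function(records, ddg_cutoff = -2.0,
                                  fraction_cutoff = 0.20,
                                  code = standard_genetic_code()) {
  records <- as_tibble(records)
  stopifnot(all(c("aa_wt", "aa_mut", "ddg") %in% names(records)))
  if (any(records$aa_wt == records$aa_mut)) {
    abort("records contain identity mutations (aa_wt == aa_mut)")
  }
  nbr <- single_nt_neighbor_pairs(code)
  nbr_keys <- pair_key(nbr$aa1, nbr$aa2)

  summary <- records |>
    dplyr::mutate(key = pair_key(.data$aa_wt, .data$aa_mut)) |>
    dplyr::filter(.data$key %in% nbr_keys) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_destabilizing = sum(.data$ddg < ddg_cutoff),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = .data$n_destabilizing / .data$n_total,
      label = ifelse(.data$fraction < fraction_cutoff, "C", "NC"),
      aa1 = substr(.data$key, 1, 1),
      aa2 = substr(.data$key, 2, 2)
    ) |>
    dplyr::select("aa1", "aa2", "n_total", "n_destabilizing",
                  "fraction", "label")

  covered_keys <- pair_key(summary$aa1, summary$aa2)
  new_substitution_classification(
    nc_keys = covered_keys[summary$label == "NC"],
    c_keys = covered_keys[summary$label == "C"],
    source = sprintf("derived(frac=%g, ddg=%g)", fraction_cutoff, ddg_cutoff),
    summary = summary,
    uncovered = setdiff(nbr_keys, covered_keys)
  )
}

#' Count non-conservative pairs with a positive BLOSUM62 score
#'
#' Consistency check of a C/NC classification against the BLOSUM62
#' substitution matrix: residue pairs that exchange frequently in homologous
#' proteins (positive score) should not be labeled as likely destabilizing.
#' For the canonical classification the count is 0.
#'
#' @param cls a `substitution_classification`.
#' @return Integer count of NC pairs scoring > 0 in BLOSUM62.
#' @examples
#' blosum62_positive_nc_count(table1_classification())
#' @export
blosum62_positive_nc_count <- function(cls) {
  if (length(cls$nc_pairs) == 0) return(0L)
  scores <- blosum62_score(substr(cls$nc_pairs, 1, 1),
                           substr(cls$nc_pairs, 2, 2))
  sum(scores > 0L)
}

#' Write / read a classification as TSV
#'
#' Serializes a classification as tab-separated columns `aa1`, `aa2`,
#' `label`, one unordered pair per line, residues lexicographically ordered
#' within a pair.
#'
#' @param cls a `substitution_classification`.
#' @param path file path.
#' @return `write_classification()` returns `cls` invisibly;
#'   `read_classification()` returns a `substitution_classification`.
#' @export
write_classification <- function(cls, path) {
  readr::write_tsv(tidy(cls), path)
  invisible(cls)
}

#' @rdname write_classification
#' @param source provenance string stored on the object read back.
#' @export
read_classification <- function(path, source = paste0("file:", basename(path))) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  stopifnot(all(c("aa1", "aa2", "label") %in% names(tab)))
  keys <- pair_key(tab$aa1, tab$aa2)
  new_substitution_classification(
    nc_keys = keys[tab$label == "NC"],
    c_keys = keys[tab$label == "C"],
    source = source
  )
}

#' Collapse a classification so every nonsynonymous change is conservative
#'
#' Used to reduce the extended model to the standard one (all amino-acid
#' changes in one class); with this classification the non-conservative rate
#' is structurally zero and the conservative rate equals dN.
#'
#' @param code a [standard_genetic_code()] object.
#' @return A `substitution_classification` with empty `nc_pairs`.
#' @export
all_conservative_classification <- function(code = standard_genetic_code()) {
  nbr <- single_nt_neighbor_pairs(code)
  new_substitution_classification(
    nc_keys = character(0),
    c_keys = pair_key(nbr$aa1, nbr$aa2),
    source = "all_conservative"
  )
}
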