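# Sequence / alignment I/O, back-translation and curation filters.

#' Construct a codon pair alignment
#'
#' Two gap-aligned codon sequences with per-column validity flags. A column
#' is valid when both codons are sense codons: gap codons (`"---"`), codons
#' containing ambiguous bases and stop codons are excluded from all
#' downstream counting and likelihood computation.
#'
#' @param codons_a,codons_b character vectors of aligned codons (each `"---"`
#'   or 3 bases), equal length.
#' @param id pair identifier.
#' @param code a [standard_genetic_code()] object.
#' @return An object of class `codon_pair_alignment` with fields `id`,
#'   `codons_a`, `codons_b`, `valid_mask`.
#' @examples
#' codon_pair_alignment(c("ATG", "AAA"), c("ATG", "AAG"))
#' @export
codon_pair_alignment <- function(codons_a, codons_b, id = "pair",
                                 code = standard_genetic_code()) {
  codons_a <- toupper(codons_a)
  codons_b <- toupper(codons_b)
  if (length(codons_a) != length(codons_b)) {
    abort("aligned codon sequences differ in length")
  }
  bad <- nchar(codons_a) != 3L | nchar(codons_b) != 3L
  if (any(bad)) abort("every aligned column must hold a 3-character codon or '---'")
  is_sense <- function(x) x %in% code$sense_codons
  valid <- is_sense(codons_a) & is_sense(codons_b)
  structure(
    list(id = id, codons_a = codons_a, codons_b = codons_b,
         valid_mask = valid),
    class = "codon_pair_alignment"
  )
}

#' @export
print.codon_pair_alignment <- function(x, ...) {
  cat("<codon_pair_alignment>", x$id, "-", length(x$codons_a), "columns,",
      sum(x$valid_mask), "valid\n")
  invisible(x)
}

#' @export
tidy.codon_pair_alignment <- function(x, ...) {
  tibble(column = seq_along(x$codons_a), codon_a = x$codons_a,
         codon_b = x$codons_b, valid = x$valid_mask)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Read and validate coding sequences from FASTA
#'
#' Sequences are uppercased and validated: length must be divisible by 3,
#' no internal stop codons are allowed, and a trailing stop codon is
#' stripped. Codons containing IUPAC-ambiguous bases are retained but
#' flagged.
#'
#' @param path FASTA file of CDS records.
#' @param code a [standard_genetic_code()] object.
#' @return A tibble with columns `id`, `seq` (codon-trimmed sequence),
#'   `n_codons`, `n_ambiguous_codons`.
#' @export
read_cds <- function(path, code = standard_genetic_code()) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(paste0("no records in ", path))
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  purrr::map2_dfr(ids, seqs, function(id, s) {
    if (nchar(s) == 0) abort(paste0("empty record: ", id))
    if (nchar(s) %% 3 != 0) {
      abort(paste0("length of record '", id, "' (", nchar(s),
                   ") is not divisible by 3"))
    }
    codons <- split_codons(s)
    aas <- translate_codons(codons, code)
    n <- length(codons)
    if (any(aas[-n] == "*")) {
      abort(paste0("internal stop codon in record '", id, "' at codon ",
                   which(aas[-n] == "*")[1]))
    }
    if (aas[n] == "*") codons <- codons[-n]
    tibble(
      id = id,
      seq = paste(codons, collapse = ""),
      n_codons = length(codons),
      n_ambiguous_codons = sum(!grepl("^[ACGT]{3}$", codons))
    )
  })
}

#' Read a pre-aligned two-record codon FASTA
#'
#' @param path FASTA with exactly two aligned records (gaps as `-`).
#' @param id pair identifier; defaults to the two record names joined.
#' @param code a [standard_genetic_code()] object.
#' @return A [codon_pair_alignment()].
#' @export
read_codon_pair_fasta <- function(path, id = NULL,
                                  code = standard_genetic_code()) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2) {
    abort(paste0("expected exactly 2 aligned records in ", path,
                 ", found ", length(recs)))
  }
  seqs <- toupper(as.character(recs))
  if (nchar(seqs[1]) != nchar(seqs[2]) || nchar(seqs[1]) %% 3 != 0) {
    abort("aligned records must have equal lengths divisible by 3")
  }
  ids <- sub("\\s.*$", "", names(recs))
  codon_pair_alignment(split_codons(seqs[1]), split_codons(seqs[2]),
                       id = id %||% paste(ids, collapse = "|"), code = code)
}

#' Write a codon pair alignment as FASTA
#'
#' @param aln a [codon_pair_alignment()].
#' @param path output FASTA path.
#' @param names record names (length 2).
#' @return `aln`, invisibly.
#' @export
write_codon_pair_fasta <- function(aln, path, names = c("seq_a", "seq_b")) {
  x <- Biostrings::BStringSet(c(paste(aln$codons_a, collapse = ""),
                                paste(aln$codons_b, collapse = "")))
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
  invisible(aln)
}

#' Back-translate an aligned protein pair onto its coding sequences
#'
#' Expands each aligned residue column to its source codon; residue gaps
#' become gap codons `"---"`. Every residue is cross-checked against the
#' translation of its codon and a mismatch is a hard error (a mismatch means
#' the protein alignment does not belong to the supplied CDS).
#'
#' @param protein_a,protein_b aligned residue strings (gaps as `-`), equal
#'   length.
#' @param cds_a,cds_b ungapped coding sequences (trailing stop already
#'   stripped, as from [read_cds()]).
#' @param id pair identifier.
#' @param code a [standard_genetic_code()] object.
#' @return A [codon_pair_alignment()].
#' @examples
#' backtranslate("M-K", "MQK", "ATGAAA", "ATGCAAAAG")
#' @export
backtranslate <- function(protein_a, protein_b, cds_a, cds_b, id = "pair",
                          code = standard_genetic_code()) {
  pa <- strsplit(toupper(protein_a), "")[[1]]
  pb <- strsplit(toupper(protein_b), "")[[1]]
  if (length(pa) != length(pb)) abort("protein alignment rows differ in length")
  expand <- function(prot, cds, which) {
    codons <- split_codons(toupper(cds))
    if (sum(prot != "-") != length(codons)) {
      abort(paste0("sequence ", which, ": ", sum(prot != "-"),
                   " aligned residues but ", length(codons), " codons"))
    }
    out <- rep("---", length(prot))
    out[prot != "-"] <- codons
    aas <- translate_codons(out[prot != "-"], code)
    res <- prot[prot != "-"]
    mismatch <- aas != res & aas != "X" & res != "X"
    if (any(mismatch)) {
      i <- which(mismatch)[1]
      abort(paste0("translation mismatch in sequence ", which,
                   " at residue ", i, ": protein says ", res[i],
                   " but codon ", out[prot != "-"][i], " encodes ", aas[i]))
    }
    out
  }
  codon_pair_alignment(expand(pa, cds_a, "a"), expand(pb, cds_b, "b"),
                       id = id, code = code)
}

#' Curation report for a codon pair alignment
#'
#' Applies the data-curation filters used before rate estimation: the gap
#' rule fails when more than `max_gap_fraction` of alignment columns contain
#' a gap in either sequence (a fraction of exactly 1/3 passes), the optional
#' length rule requires at least `min_codons` valid codon columns, and the
#' optional NC rule requires at least `min_nc_subs` estimated
#' non-conservative substitutions (supply the estimate via
#' `nc_substitutions`).
#'
#' @param aln a [codon_pair_alignment()].
#' @param max_gap_fraction maximum tolerated gap fraction (default 1/3).
#' @param min_codons optional minimum number of valid codon columns.
#' @param min_nc_subs optional minimum number of NC substitutions.
#' @param nc_substitutions estimated NC substitution count for the pair
#'   (e.g. `ncd` from [estimate_rates_count()] or `dNC * nc_sites` from an
#'   ML fit); required when `min_nc_subs` is set.
#' @return One-row tibble: `id`, `gap_fraction`, `n_valid_codons`,
#'   `nc_substitution_count`, per-rule pass flags and overall `passed`.
#' @export
curate <- function(aln, max_gap_fraction = 1 / 3, min_codons = NULL,
                   min_nc_subs = NULL, nc_substitutions = NULL) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  n_col <- length(aln$codons_a)
  gapped <- aln$codons_a == "---" | aln$codons_b == "---"
  gap_fraction <- sum(gapped) / n_col
  gap_ok <- gap_fraction <= max_gap_fraction  # strictly more than the cutoff fails
  len_ok <- if (is.null(min_codons)) NA else sum(aln$valid_mask) >= min_codons
  nc_ok <- if (is.null(min_nc_subs)) {
    NA
  } else {
    if (is.null(nc_substitutions)) {
      abort("min_nc_subs set but nc_substitutions not supplied")
    }
    nc_substitutions >= min_nc_subs
  }
  tibble(
    id = aln$id,
    gap_fraction = gap_fraction,
    n_valid_codons = sum(aln$valid_mask),
    nc_substitution_count = nc_substitutions %||% NA_real_,
    gap_rule_passed = gap_ok,
    length_rule_passed = len_ok,
    nc_rule_passed = nc_ok,
    passed = gap_ok && !isFALSE(len_ok) && !isFALSE(nc_ok)
  )
}

#' Batch rate estimation over a manifest of ortholog pairs
#'
#' Runs curation and rate estimation for every pair in a manifest. Each row
#' must carry a `pair_id` and either a `pair_fasta` column (pre-aligned
#' two-record codon FASTA) or columns `cds_a`, `cds_b`, `protein_aln`
#' (unaligned CDS FASTAs plus an aligned two-record protein FASTA that is
#' back-translated). Pairs failing curation or erroring during estimation
#' are skipped with a reason, never aborting the batch.
#'
#' @param manifest data frame or TSV path with the columns above.
#' @param cls a `substitution_classification`.
#' @param method `"count"`, `"ml"` or `"both"`.
#' @param code a [standard_genetic_code()] object.
#' @param max_gap_fraction,min_codons curation settings (see [curate()]).
#' @param ... passed to [fit_ml()] (e.g. `n_starts`).
#' @return A tibble of per-pair results, one row per pair that passed; the
#'   skipped pairs are attached as `attr(, "skipped")`, a tibble with
#'   `pair_id` and `reason`.
#' @export
batch_estimate <- function(manifest, cls = table1_classification(),
                           method = c("both", "count", "ml"),
                           code = standard_genetic_code(),
                           max_gap_fraction = 1 / 3, min_codons = NULL, ...) {
  method <- match.arg(method)
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  manifest <- as_tibble(manifest)
  if (!"pair_id" %in% names(manifest)) abort("manifest lacks a pair_id column")

  results <- list()
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      aln <- if ("pair_fasta" %in% names(manifest) && !is.na(row$pair_fasta)) {
        read_codon_pair_fasta(row$pair_fasta, id = row$pair_id, code = code)
      } else {
        prot <- Biostrings::readBStringSet(row$protein_aln)
        if (length(prot) != 2) abort("protein alignment must hold 2 records")
        backtranslate(as.character(prot[[1]]), as.character(prot[[2]]),
                      read_cds(row$cds_a, code)$seq[1],
                      read_cds(row$cds_b, code)$seq[1],
                      id = row$pair_id, code = code)
      }
      rep_ <- curate(aln, max_gap_fraction = max_gap_fraction,
                     min_codons = min_codons)
      if (!rep_$passed) abort(paste0("failed curation (gap_fraction=",
                                     signif(rep_$gap_fraction, 3), ")"))
      out <- tibble(pair_id = row$pair_id)
      if (method %in% c("count", "both")) {
        cnt <- estimate_rates_count(aln, code, cls, id = row$pair_id)
        out <- dplyr::bind_cols(out, dplyr::rename_with(
          dplyr::select(cnt, -"id"), ~ paste0("count_", .x)))
      }
      if (method %in% c("ml", "both")) {
        fit <- fit_ml(aln, cls, code, ...)
        out <- dplyr::bind_cols(out, dplyr::rename_with(
          glance(fit), ~ paste0("ml_", .x)))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble(pair_id = row$pair_id, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "skipped") <- if (length(skipped)) {
    dplyr::bind_rows(skipped)
  } else {
    tibble(pair_id = character(0), reason = character(0))
  }
  if (nrow(attr(out, "skipped")) > 0) {
    warn(paste0(nrow(attr(out, "skipped")), " pair(s) skipped; see attr(, 'skipped')"))
  }
  out
}
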