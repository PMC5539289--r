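# Post-hoc annotation: expression-based filtering of candidate TFs, and a
# somatic-hypermutation (SHM) hotspot-motif enrichment test. The hotspot
# motif pair DGYW/WRCH (IUPAC: D = A/G/T, Y = C/T, W = A/T, R = A/G,
# H = A/C/T) is the AID target motif of germinal-center B cells; WRCH is
# the reverse complement of DGYW.

#' Filter and categorize TFs by tumor expression
#'
#' Each TF symbol is matched (case-insensitively) to a gene row of the
#' expression table; heterodimer names like `"AHR::ARNT"` use the minimum
#' of the components' medians. TFs whose median tumor RPKM falls below
#' `threshold` are marked `"filtered"` (to be removed from ranking and
#' significance outputs); surviving TFs are categorized by quartile of the
#' median RPKM: `"+"` = top quartile, `"-"` = bottom quartile, `"."` =
#' in-between.
#'
#' @param tf_names Character vector of TF names (one per PWM or unique).
#' @param expr [expression_table()].
#' @param threshold RPKM noise floor (default 0.03).
#' @param aliases Optional named character vector mapping TF symbols to
#'   expression-table gene ids.
#' @return Tibble with `tf_name`, `median_rpkm`, `category` (one row per
#'   unique input name). Unmapped TFs get `median_rpkm = NA` and category
#'   `"filtered"`, with a warning.
#' @export
filter_tfs_by_expression <- function(tf_names, expr, threshold = 0.03,
                                     aliases = NULL) {
  if (nrow(expr$values) == 0L) stop("empty expression table")
  tf_names <- unique(tf_names)
  genes <- rownames(expr$values)
  lookup_gene <- function(sym) {
    if (!is.null(aliases) && sym %in% names(aliases)) sym <- aliases[[sym]]
    hit <- which(toupper(genes) == toupper(sym))
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }
  tumor <- expr$groups == "tumor"
  med <- vapply(tf_names, function(nm) {
    parts <- strsplit(nm, "::", fixed = TRUE)[[1]]
    idx <- vapply(parts, lookup_gene, integer(1))
    if (any(is.na(idx))) return(NA_real_)
    min(vapply(idx, function(i) median(expr$values[i, tumor]), numeric(1)))
  }, numeric(1))
  if (any(is.na(med))) {
    warning("TF(s) not found in expression table (marked 'filtered'): ",
            paste(head(tf_names[is.na(med)], 5L), collapse = ", "))
  }
  out <- tibble::tibble(tf_name = tf_names, median_rpkm = unname(med))
  survives <- !is.na(out$median_rpkm) & out$median_rpkm >= threshold
  category <- rep("filtered", nrow(out))
  if (any(survives)) {
    r <- rank(out$median_rpkm[survives], ties.method = "average")
    n <- sum(survives)
    category[survives] <- dplyr::case_when(
      r / n <= 0.25 ~ "-",
      r / n > 0.75 ~ "+",
      .default = "."
    )
  }
  out$category <- category
  out
}

#' Positions covered by SHM hotspot motifs
#'
#' Finds every occurrence of DGYW or WRCH (the strand-symmetric AID
#' hotspot pair) on the given sequence and returns the union of the
#' 1-based positions inside any match. Because WRCH is the reverse
#' complement of DGYW, scanning both patterns on the forward strand covers
#' both strands.
#'
#' @param sequence DNA string.
#' @return Sorted integer vector of 1-based covered positions.
#' @export
#' @examples
#' find_hotspot_positions("AGCT")  # WRCH match: positions 1:4
find_hotspot_positions <- function(sequence) {
  subject <- Biostrings::DNAString(toupper(sequence))
  hits <- lapply(c("DGYW", "WRCH"), function(pat) {
    m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (length(m) == 0L) return(integer())
    unlist(lapply(seq_along(m), function(i) {
      seq.int(IRanges::start(m)[i], IRanges::end(m)[i])
    }))
  })
  sort(unique(unlist(hits)))
}

#' SHM hotspot-motif enrichment test for a mutation block
#'
#' Tests whether the block's mutations fall inside SHM hotspot motifs more
#' (or less) often than expected by chance. The null rate `p0` is the
#' fraction of reference-block positions covered by a DGYW/WRCH
#' occurrence; the observed in-hotspot mutation count is compared with an
#' exact two-sided binomial test.
#'
#' @param block_seq Reference DNA sequence of the block.
#' @param mutation_offsets 1-based offsets of the mutations within
#'   `block_seq` (>= 1 mutation).
#' @param block_id Optional label carried into the result.
#' @return One-row tibble with `block_id`, `n_mutations`, `n_in_hotspot`,
#'   `p0`, `binom_p`.
#' @export
shm_enrichment_test <- function(block_seq, mutation_offsets,
                                block_id = NA_character_) {
  stopifnot(length(mutation_offsets) >= 1)
  L <- nchar(block_seq)
  if (any(mutation_offsets < 1 | mutation_offsets > L)) {
    stop("mutation offsets outside the block sequence")
  }
  hot <- find_hotspot_positions(block_seq)
  p0 <- length(hot) / L
  k <- sum(mutation_offsets %in% hot)
  n <- length(mutation_offsets)
  p <- if (p0 <= 0 || p0 >= 1) {
    warning("degenerate hotspot fraction p0 = ", p0, "; p set to 1")
    1
  } else {
    binom_test_2sided(k, n, p0)
  }
  tibble::tibble(block_id = block_id, n_mutations = n, n_in_hotspot = k,
                 p0 = p0, binom_p = p)
}
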