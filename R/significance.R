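# Step 2 of the pipeline: compare patient delta-dbA values per TF against
# delta-dbA of randomly generated background mutation blocks, with a
# rank-sum test, Bonferroni correction over the PWMs tested, and a
# triplicate-robustness rule.

#' Generate random background mutation blocks
#'
#' Background blocks are drawn from the 1000-bp regions immediately
#' upstream of annotated TSSs (the universe), excluding the regions of the
#' gene carrying the tested block. Each selected region contributes one
#' block: a window of `block_length` bp placed uniformly inside the
#' region, carrying `n_mutations` random single-base substitutions at
#' distinct positions.
#'
#' @param tss TSS tibble from [read_tss()] defining the universe.
#' @param genome `DNAStringSet`.
#' @param block_length Length of each background block in bp (use the
#'   scored length of the tested patient sequences).
#' @param n_mutations Substitutions per background block (>= 1).
#' @param excluded_gene Gene id(s) whose upstream regions are excluded.
#' @param count Number of background blocks; `NULL` means one per eligible
#'   region (about 20k for a human annotation).
#' @param seed Optional RNG seed.
#' @param upstream Width of the upstream universe regions (default 1000).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `ref_seq`,
#'   `alt_seq`; the seed is attached as attribute `"seed"`.
#' @export
generate_background_blocks <- function(tss, genome, block_length,
                                       n_mutations, excluded_gene = NULL,
                                       count = NULL, seed = NULL,
                                       upstream = 1000) {
  if (n_mutations < 1) stop("n_mutations must be >= 1")
  regions <- dplyr::distinct(dplyr::transmute(tss,
    gene_id = .data$gene_id,
    chrom = .data$chrom,
    start = pmax(1L, .data$tss - as.integer(upstream)),
    end = pmax(1L, .data$tss - 1L)
  ))
  if (!is.null(excluded_gene)) {
    regions <- dplyr::filter(regions, !(.data$gene_id %in% excluded_gene))
  }
  lens <- vapply(unique(regions$chrom),
                 function(ch) length(genome_chrom(genome, ch)), integer(1))
  regions$end <- pmin(regions$end,
                      lens[match(regions$chrom, unique(regions$chrom))])
  wide_enough <- (regions$end - regions$start + 1L) >= block_length
  if (any(!wide_enough)) {
    message("generate_background_blocks: skipped ", sum(!wide_enough),
            " region(s) shorter than the block length")
  }
  regions <- regions[wide_enough, , drop = FALSE]
  if (nrow(regions) == 0L) stop("no eligible background regions")
  if (is.null(count)) count <- nrow(regions)
  with_seed_if(seed, {
    # One block per region when possible; with a small universe (fewer
    # regions than requested blocks) regions are re-drawn, each time with
    # a fresh placement and fresh mutations.
    pick <- if (count == nrow(regions)) {
      seq_len(nrow(regions))
    } else {
      sample.int(nrow(regions), count, replace = count > nrow(regions))
    }
    rows <- purrr::map(pick, function(i) {
      reg <- regions[i, ]
      slack <- (reg$end - reg$start + 1L) - block_length
      bstart <- reg$start + if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
      bend <- bstart + block_length - 1L
      ref_seq <- get_sequence(genome, reg$chrom, bstart, bend)
      mut_pos <- sample.int(block_length, n_mutations)
      alt <- strsplit(ref_seq, "")[[1]]
      for (p in mut_pos) {
        choices <- setdiff(DNA_BASES, alt[p])
        alt[p] <- choices[sample.int(length(choices), 1L)]
      }
      tibble::tibble(gene_id = reg$gene_id, chrom = reg$chrom,
                     start = bstart, end = bend, ref_seq = ref_seq,
                     alt_seq = paste(alt, collapse = ""))
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "seed") <- seed
    out
  })
}

#' Per-patient empirical tail probability against the background
#'
#' The expected probability that random background mutations affect the TF
#' as strongly as the patient's mutations: for positive shifts,
#' `p = (1 + #\{bg >= patient\}) / (1 + n_bg)`; for negative shifts the
#' inequality is reversed.
#'
#' @param patient_ddba One patient's delta-dbA value.
#' @param background_ddbas Background delta-dbA values (>= 20).
#' @param direction `"positive"` or `"negative"`.
#' @return Tail probability in (0, 1].
#' @export
per_patient_tail_probability <- function(patient_ddba, background_ddbas,
                                         direction = c("positive",
                                                       "negative")) {
  direction <- match.arg(direction)
  stopifnot(length(background_ddbas) >= 20)
  n_ge <- if (direction == "positive") {
    sum(background_ddbas >= patient_ddba)
  } else {
    sum(background_ddbas <= patient_ddba)
  }
  (1 + n_ge) / (1 + length(background_ddbas))
}

#' Rank-sum test of patient vs background delta-dbA
#'
#' Two-sided Wilcoxon rank-sum ([wilcoxon_rank_sum()]) comparing the
#' per-patient delta-dbA values of a block against the background
#' distribution; direction is the sign of the median difference.
#'
#' @param patient_ddbas One delta-dbA per patient carrying the block
#'   (>= 2 values).
#' @param background_ddbas Background delta-dbA values.
#' @param exact See [wilcoxon_rank_sum()].
#' @return List with `statistic`, `p_value`, `direction`.
#' @export
wilcoxon_block_test <- function(patient_ddbas, background_ddbas,
                                exact = NULL) {
  if (length(patient_ddbas) < 2L) {
    stop("need >= 2 patient delta-dbA values (got ", length(patient_ddbas),
         ")")
  }
  w <- wilcoxon_rank_sum(patient_ddbas, background_ddbas, exact = exact)
  list(statistic = w$statistic, p_value = w$p_value,
       direction = w$direction)
}

#' Bonferroni correction
#'
#' @param p Raw p-value(s).
#' @param m Number of hypotheses (PWMs tested).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Consolidate replicate significance records
#'
#' The background-resampling test is repeated (three times by default)
#' with fresh backgrounds; a (TF, block) pair is reported significant only
#' when every replicate is significant at `alpha` after Bonferroni
#' correction. The reported p-values are the medians across replicates;
#' direction is the majority call and per-patient probabilities are taken
#' from the replicate with the median corrected p.
#'
#' @param records Replicate-level tibble with columns `tf_name`, `pwm_id`,
#'   `block_id`, `replicate`, `direction`, `wilcoxon_p`, `bonferroni_p`
#'   and (optionally) a `per_patient` list-column.
#' @param replicates Required replicate count (default 3).
#' @param alpha Per-replicate significance level on the corrected p
#'   (default 0.05).
#' @return One row per (TF, block) with `n_replicates_significant` and
#'   `significant`.
#' @export
triplicate_consensus <- function(records, replicates = 3, alpha = 0.05) {
  counts <- dplyr::count(records, .data$pwm_id, .data$block_id)
  if (any(counts$n < replicates)) {
    stop("some (TF, block) pairs have fewer than ", replicates,
         " replicates; pass `replicates` explicitly to override")
  }
  has_pp <- "per_patient" %in% names(records)
  dplyr::group_modify(
    dplyr::group_by(records, .data$tf_name, .data$pwm_id, .data$block_id),
    function(df, key) {
      med_p <- median(df$bonferroni_p)
      pick <- which.min(abs(df$bonferroni_p - med_p))
      dir_tab <- table(df$direction)
      direction <- if (length(dir_tab) == 1L) {
        names(dir_tab)
      } else if (max(dir_tab) > min(dir_tab)) {
        names(dir_tab)[which.max(dir_tab)]
      } else {
        df$direction[pick]
      }
      tibble::tibble(
        direction = direction,
        wilcoxon_p = median(df$wilcoxon_p),
        bonferroni_p = med_p,
        n_replicates_significant = sum(df$bonferroni_p < alpha),
        significant = all(df$bonferroni_p < alpha),
        per_patient = if (has_pp) df$per_patient[pick] else list(NULL)
      )
    }
  ) |> dplyr::ungroup()
}

#' Test mutation blocks for significantly affected TFs
#'
#' Runs the full background-comparison stage for each block: builds the
#' patient-specific sequences, generates `replicates` independent sets of
#' background mutation blocks matched in length and mutation count
#' (excluding the tested gene's upstream regions), scores patient and
#' background delta-dbA for every PWM, and applies the rank-sum test with
#' Bonferroni correction over the PWMs tested, consolidated across
#' replicates by [triplicate_consensus()].
#'
#' @param blocks Gated block tibble (e.g. `tidy()` of [mussd()] joined
#'   back with its `snvs` list-column, or `mussd_result$blocks`).
#' @param genome `DNAStringSet`.
#' @param tss TSS tibble (background universe).
#' @param pwms PWM collection; apply [filter_tfs_by_expression()] first if
#'   an expression filter is wanted.
#' @param params [affinity_params()].
#' @param n_background Background blocks per replicate (default 500;
#'   `NULL` = one per eligible upstream region, the full
#'   count).
#' @param replicates Number of background replicates (default 3).
#' @param alpha Significance level on the Bonferroni-corrected p (default
#'   0.05).
#' @param flank Flank added to patient block sequences (default 30).
#' @param seed RNG seed; replicate seeds are derived deterministically.
#' @param threads Worker processes for the per-block computations (forked
#'   via `parallel::mclapply`); results are identical to a serial run
#'   because every (block, replicate) has its own derived seed.
#' @return An object of class `significance_result` with the consolidated
#'   table (`$records`), the replicate-level table (`$replicates`) and the
#'   run parameters.
#' @export
test_blocks <- function(blocks, genome, tss, pwms,
                        params = affinity_params(), n_background = 500,
                        replicates = 3, alpha = 0.05, flank = 30,
                        seed = 1, threads = 1) {
  stopifnot(nrow(blocks) > 0, nrow(pwms) > 0)
  ems <- energy_matrices(pwms)
  m <- nrow(ems)
  seeds <- with_seed_if(seed, matrix(
    sample.int(.Machine$integer.max - 1L, nrow(blocks) * replicates),
    nrow = nrow(blocks)
  ))
  one_block <- function(b) {
    blk <- blocks[b, ]
    units <- build_patient_sequences(blk, genome, flank = flank)
    if (nrow(units) < 2L) {
      stop("block ", blk$block_id, " has fewer than 2 patients")
    }
    per_patient_counts <- vapply(split(blk$snvs[[1]]$patient_id,
                                       blk$snvs[[1]]$patient_id),
                                 length, integer(1))
    n_mut <- max(1L, as.integer(round(median(per_patient_counts))))
    block_len <- nchar(units$ref_seq[1])
    excluded <- if ("gene_id" %in% names(blk)) blk$gene_id else NULL
    purrr::map(seq_len(replicates), function(r) {
      bg <- generate_background_blocks(
        tss, genome, block_length = block_len, n_mutations = n_mut,
        excluded_gene = excluded, count = n_background,
        seed = seeds[b, r]
      )
      purrr::map(seq_len(m), function(i) {
        en <- ems$energies[[i]]
        pat <- as.numeric(.ddba_batch_cpp(units$ref_seq, units$alt_seq, en,
                                          params$mu_grid, params$beta,
                                          params$both_strands))
        bgd <- as.numeric(.ddba_batch_cpp(bg$ref_seq, bg$alt_seq, en,
                                          params$mu_grid, params$beta,
                                          params$both_strands))
        w <- wilcoxon_block_test(pat, bgd)
        pp <- vapply(pat, per_patient_tail_probability, numeric(1),
                     background_ddbas = bgd, direction = w$direction)
        tibble::tibble(
          tf_name = ems$tf_name[i], pwm_id = ems$pwm_id[i],
          block_id = blk$block_id, replicate = r,
          direction = w$direction, statistic = w$statistic,
          wilcoxon_p = w$p_value,
          bonferroni_p = bonferroni(w$p_value, m),
          per_patient = list(setNames(pp, units$patient_id))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }
  rep_rows <- if (threads > 1) {
    parallel::mclapply(seq_len(nrow(blocks)), one_block,
                       mc.cores = threads)
  } else {
    purrr::map(seq_len(nrow(blocks)), one_block)
  }
  rep_tbl <- dplyr::bind_rows(rep_rows)
  consolidated <- triplicate_consensus(rep_tbl, replicates = replicates,
                                       alpha = alpha)
  structure(list(records = consolidated, replicates = rep_tbl,
                 params = list(n_background = n_background,
                               replicates = replicates, alpha = alpha,
                               flank = flank, m = m, seed = seed)),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("<significance_result> ", nrow(x$records), " (TF, block) pairs, ",
      sum(x$records$significant), " significant at Bonferroni alpha = ",
      x$params$alpha, " (m = ", x$params$m, " PWMs, ",
      x$params$replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' Tidy a significance result
#'
#' @param x A `significance_result` from [test_blocks()].
#' @param ... Unused.
#' @return Consolidated per-(TF, block) tibble.
#' @export
tidy.significance_result <- function(x, ...) {
  x$records
}

#' @rdname tidy.significance_result
#' @export
glance.significance_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$records),
    n_significant = sum(x$records$significant),
    n_blocks = dplyr::n_distinct(x$records$block_id),
    m_pwms = x$params$m,
    n_background = x$params$n_background %||% NA_integer_,
    replicates = x$params$replicates,
    alpha = x$params$alpha
  )
}
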