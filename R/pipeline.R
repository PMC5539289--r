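# One-shot orchestration: mutation-block discovery -> delta-dbA scoring
# and ranking -> background significance testing -> annotation, with all
# stage tables written to a result directory plus a reproducibility
# manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Numeric
#' defaults are the operating point of the method: 30-bp block merging,
#' +/-1000-bp promoters, KS gate at 0.05, RPKM noise floor 0.03,
#' direct-binding filter 0.1, top-20% magnitude filter, top-15 ranks,
#' triplicate background testing.
#'
#' @param genome,tss,pwms,expression,sample_groups,vcfs Input paths or
#'   pre-loaded objects (`vcfs` may be a named vector of paths or an SNV
#'   tibble; `expression` may be a path plus `sample_groups`, or an
#'   [expression_table()]).
#' @param half_width Promoter half-width in bp.
#' @param max_gap Block-merging gap in bp.
#' @param ks_alpha Expression-gate significance level.
#' @param rpkm_threshold TF expression noise floor.
#' @param p_direct_cutoff Direct-binding p-value filter for ranking.
#' @param magnitude_quantile Keep TFs at or above this |delta-dbA|
#'   quantile per unit.
#' @param top_k Ranking list length per direction.
#' @param mu_grid Chemical potential grid.
#' @param flank Patient-block sequence flank in bp.
#' @param n_background Background blocks per replicate.
#' @param n_shuffles Shuffles for the direct-binding p-value.
#' @param replicates Background replicates.
#' @param expression_filter Apply the TF expression filter.
#' @param rank_snv Also run the per-SNV 61-bp ranking stage.
#' @param threads Worker processes for block-level scoring.
#' @param seed RNG seed for the whole run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome = NULL, tss = NULL, pwms = NULL,
                       expression = NULL, sample_groups = NULL,
                       vcfs = NULL, half_width = 1000, max_gap = 30,
                       ks_alpha = 0.05, rpkm_threshold = 0.03,
                       p_direct_cutoff = 0.1, magnitude_quantile = 0.8,
                       top_k = 15, mu_grid = c(-2, 0, 2, 4), flank = 30,
                       n_background = 500, n_shuffles = 100,
                       replicates = 3, expression_filter = TRUE,
                       rank_snv = FALSE, threads = 1, seed = 1) {
  structure(list(
    genome = genome, tss = tss, pwms = pwms, expression = expression,
    sample_groups = sample_groups, vcfs = vcfs, half_width = half_width,
    max_gap = max_gap, ks_alpha = ks_alpha,
    rpkm_threshold = rpkm_threshold, p_direct_cutoff = p_direct_cutoff,
    magnitude_quantile = magnitude_quantile, top_k = top_k,
    mu_grid = mu_grid, flank = flank, n_background = n_background,
    n_shuffles = n_shuffles, replicates = replicates,
    expression_filter = expression_filter, rank_snv = rank_snv,
    threads = threads, seed = seed
  ), class = "run_config")
}

load_inputs <- function(config) {
  genome <- if (is.character(config$genome)) {
    read_genome(config$genome)
  } else config$genome
  tss <- if (is.character(config$tss)) read_tss(config$tss) else config$tss
  pwms <- if (is.character(config$pwms)) {
    read_pwms(config$pwms)
  } else config$pwms
  snvs <- if (is.character(config$vcfs)) {
    read_snvs(config$vcfs)
  } else config$vcfs
  expr <- if (is.character(config$expression)) {
    groups <- config$sample_groups
    if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
      g <- readr::read_tsv(groups, show_col_types = FALSE, progress = FALSE)
      groups <- setNames(g$group, g$sample)
    }
    read_expression(config$expression, groups)
  } else config$expression
  list(genome = genome, tss = tss, pwms = pwms, snvs = snvs, expr = expr)
}

#' Run the full pipeline
#'
#' Executes block discovery, per-unit delta-dbA scoring and ranking,
#' background significance testing and annotation, writing `blocks.tsv`,
#' `blocks.bed`, `block_sequences.fa`, `rankings.tsv`,
#' `significance.tsv`, `shm.tsv`, `tf_expression.tsv` (and
#' `snv_rankings.tsv` when `rank_snv` is set) plus `manifest.json` to
#' `out_dir`. Deterministic for a fixed seed; block-level scoring is
#' independent across blocks and may be parallelized with `threads`
#' without changing results.
#'
#' @param config A [run_config()].
#' @param out_dir Result directory (created if needed).
#' @return Invisibly, a list with the stage results (`mussd`, `rankings`,
#'   `significance`, `shm`, `tf_expression`, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_inputs(config)
  params <- affinity_params(mu_grid = config$mu_grid)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ms <- stage("mussd", {
    check_snv_reference(inputs$snvs, inputs$genome)
    mussd(inputs$snvs, inputs$tss,
          expr = if (config$expression_filter) inputs$expr else NULL,
          max_gap = config$max_gap, half_width = config$half_width,
          alpha = config$ks_alpha)
  })
  blocks <- ms$blocks
  readr::write_tsv(tidy(ms), file.path(out_dir, "blocks.tsv"),
                   progress = FALSE)
  if (nrow(blocks) > 0) {
    write_blocks_bed(dplyr::distinct(blocks, .data$block_id,
                                     .keep_all = TRUE),
                     file.path(out_dir, "blocks.bed"))
  }
  if (nrow(blocks) == 0) {
    warning("no recurrent promoter blocks survive the gates; stopping")
    manifest <- write_manifest(config, out_dir)
    return(invisible(list(mussd = ms, rankings = NULL,
                          significance = NULL, shm = NULL,
                          manifest = manifest)))
  }
  blocks_unique <- dplyr::distinct(blocks, .data$block_id, .keep_all = TRUE)

  units <- stage("block_sequences", {
    build_patient_sequences(blocks_unique, inputs$genome,
                            flank = config$flank)
  })
  seq_fa <- Biostrings::DNAStringSet(c(
    setNames(units$ref_seq, paste0(units$unit_id, "|ref")),
    setNames(units$alt_seq, paste0(units$unit_id, "|alt"))
  ))
  Biostrings::writeXStringSet(seq_fa, file.path(out_dir,
                                                "block_sequences.fa"))

  tf_annot <- NULL
  pwms_use <- inputs$pwms
  if (config$expression_filter && !is.null(inputs$expr)) {
    tf_annot <- stage("tf_expression", {
      filter_tfs_by_expression(inputs$pwms$tf_name, inputs$expr,
                               threshold = config$rpkm_threshold)
    })
    keep_tfs <- tf_annot$tf_name[tf_annot$category != "filtered"]
    pwms_use <- dplyr::filter(inputs$pwms, .data$tf_name %in% keep_tfs)
    readr::write_tsv(tf_annot, file.path(out_dir, "tf_expression.tsv"),
                     progress = FALSE)
  } else if (!config$expression_filter) {
    tf_annot <- tibble::tibble(tf_name = unique(inputs$pwms$tf_name),
                               median_rpkm = NA_real_, category = ".")
    readr::write_tsv(tf_annot, file.path(out_dir, "tf_expression.tsv"),
                     progress = FALSE)
  }
  if (nrow(pwms_use) == 0) stop("all PWMs removed by the expression filter")

  rankings <- stage("block_ranking", {
    scored <- score_units(units, pwms_use, params,
                          n_shuffles = config$n_shuffles,
                          seed = config$seed)
    dplyr::bind_rows(lapply(split(scored, scored$unit_id), rank_tfs,
                            k = config$top_k,
                            p_direct_cutoff = config$p_direct_cutoff,
                            magnitude_quantile = config$magnitude_quantile))
  })
  readr::write_tsv(rankings, file.path(out_dir, "rankings.tsv"),
                   progress = FALSE)

  snv_rankings <- NULL
  if (config$rank_snv) {
    snv_rankings <- stage("snv_ranking", {
      block_snvs <- dplyr::bind_rows(blocks_unique$snvs)
      wins <- snv_window_sequences(block_snvs, inputs$genome, half = 30)
      scored <- score_units(wins, pwms_use, params,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed + 1L)
      dplyr::bind_rows(lapply(split(scored, scored$unit_id), rank_tfs,
                              k = config$top_k,
                              p_direct_cutoff = config$p_direct_cutoff,
                              magnitude_quantile = config$magnitude_quantile))
    })
    readr::write_tsv(snv_rankings, file.path(out_dir, "snv_rankings.tsv"),
                     progress = FALSE)
  }

  sig <- stage("significance", {
    test_blocks(blocks, inputs$genome, inputs$tss, pwms_use,
                params = params, n_background = config$n_background,
                replicates = config$replicates, flank = config$flank,
                seed = config$seed, threads = config$threads)
  })
  readr::write_tsv(significance_table(sig),
                   file.path(out_dir, "significance.tsv"), progress = FALSE)

  shm <- stage("shm", {
    purrr::map(seq_len(nrow(blocks_unique)), function(i) {
      blk <- blocks_unique[i, ]
      seqs <- get_sequence(inputs$genome, blk$chrom, blk$start, blk$end)
      shm_enrichment_test(seqs, blk$snvs[[1]]$pos - blk$start + 1L,
                          block_id = blk$block_id)
    }) |> dplyr::bind_rows()
  })
  readr::write_tsv(shm, file.path(out_dir, "shm.tsv"), progress = FALSE)

  manifest <- write_manifest(config, out_dir)
  invisible(list(mussd = ms, units = units, rankings = rankings,
                 snv_rankings = snv_rankings, significance = sig,
                 shm = shm, tf_expression = tf_annot,
                 manifest = manifest, out_dir = out_dir))
}

# Flatten the consolidated significance records to a wide TSV with one
# per-patient probability column per patient.
significance_table <- function(sig) {
  rec <- sig$records
  pp <- purrr::map(rec$per_patient, function(x) {
    if (is.null(x)) {
      tibble::tibble(.rows = 1)
    } else {
      tibble::as_tibble(as.list(setNames(x, paste0("p_", names(x)))))
    }
  })
  dplyr::bind_cols(dplyr::select(rec, -"per_patient"),
                   dplyr::bind_rows(pp))
}

write_manifest <- function(config, out_dir) {
  cfg <- config[setdiff(names(config),
                        c("genome", "tss", "pwms", "expression",
                          "sample_groups", "vcfs"))]
  inputs <- config[c("genome", "tss", "pwms", "expression", "vcfs")]
  inputs <- lapply(inputs, function(x) {
    if (is.character(x)) unname(x) else class(x)[1]
  })
  manifest <- list(
    package = "regblock",
    version = as.character(utils::packageVersion("regblock")),
    r_version = as.character(getRversion()),
    config = cfg,
    inputs = inputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
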