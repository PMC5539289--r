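# ggplot2 displays for the main result types.

#' Heat-map of per-patient background tail probabilities
#'
#' One tile per (TF PWM, patient), colored by -log10 of the expected
#' probability that random background mutations affect the TF as strongly
#' as the patient's mutations; orange for positive (gained binding) and
#' blue for negative (disrupted binding) shifts, faceted by block.
#'
#' @param sig A `significance_result` from [test_blocks()].
#' @param significant_only Show only TFs passing the triplicate consensus
#'   (default `TRUE`).
#' @param tf_categories Optional annotation from
#'   [filter_tfs_by_expression()]; categories are appended to row labels
#'   in square brackets.
#' @return A ggplot object.
#' @export
plot_significance_heatmap <- function(sig, significant_only = TRUE,
                                      tf_categories = NULL) {
  rec <- sig$records
  if (significant_only) rec <- dplyr::filter(rec, .data$significant)
  if (nrow(rec) == 0) {
    stop("nothing to plot: no ",
         if (significant_only) "significant " else "", "records")
  }
  long <- tidyr::unnest_longer(
    dplyr::mutate(rec, per_patient = purrr::map(.data$per_patient,
                                                ~ tibble::enframe(.x))),
    "per_patient"
  )
  long <- tidyr::unpack(long, "per_patient")
  long <- dplyr::rename(long, patient = "name", tail_p = "value")
  if (!is.null(tf_categories)) {
    long <- dplyr::left_join(long, tf_categories, by = "tf_name")
    long$row_label <- paste0(long$tf_name, " [", long$category, "] (",
                             long$pwm_id, ")")
  } else {
    long$row_label <- paste0(long$tf_name, " (", long$pwm_id, ")")
  }
  long <- dplyr::mutate(long,
    signed_score = -log10(.data$tail_p) *
      ifelse(.data$direction == "positive", 1, -1))
  lim <- max(abs(long$signed_score))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient,
                                     y = .data$row_label,
                                     fill = .data$signed_score)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#e08214",
      limits = c(-lim, lim),
      name = expression("signed" ~ -log[10] ~ "tail prob.")
    ) +
    ggplot2::facet_wrap(~block_id, scales = "free") +
    ggplot2::labs(x = "patient", y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.significance_result <- function(object, ...) {
  plot_significance_heatmap(object, ...)
}

#' Plot the nucleotide substitution spectrum
#'
#' @param stats Tibble from [nucleotide_change_stats()].
#' @return A ggplot object.
#' @export
plot_substitution_spectrum <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$category,
                                      y = .data$fraction,
                                      fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "substitution (pyrimidine-referenced)",
                  y = "fraction of SNVs") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Overview of mutation blocks along the genome
#'
#' SNV positions per patient with the kept block spans underneath; one
#' facet per chromosome.
#'
#' @param object A `mussd_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mussd_result <- function(object, ...) {
  blocks <- dplyr::distinct(object$blocks, .data$block_id, .keep_all = TRUE)
  if (nrow(blocks) == 0) stop("no blocks to plot")
  snvs <- dplyr::bind_rows(blocks$snvs)
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = blocks,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf),
                       fill = "indianred", alpha = 0.2) +
    ggplot2::geom_point(data = snvs,
                        ggplot2::aes(x = .data$pos,
                                     y = .data$patient_id),
                        shape = 124, size = 3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "patient") +
    ggplot2::theme_minimal(base_size = 10)
}
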