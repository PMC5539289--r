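# Step 1 of the pipeline: cluster somatic SNVs into recurrent mutation
# blocks, assign blocks to promoters, gate target genes by tumor-vs-normal
# differential expression, and build patient-specific block sequences.

block_id_of <- function(chrom, start, end) {
  paste0(chrom, ":", start, "-", end)
}

#' Cluster SNVs into mutation blocks
#'
#' Single-linkage clustering per chromosome: SNVs are sorted by position
#' and a new block starts whenever the gap to the previous SNV is at least
#' `max_gap` (strictly smaller gaps merge). SNVs at the same position from
#' different patients always share a block. This sorted sweep is exactly
#' the transitive closure of the pairwise "closer than `max_gap`" relation.
#'
#' @param snvs SNV tibble from [read_snvs()]/[snv_table()].
#' @param max_gap Merge threshold in bp (default 30); positions merge when
#'   their distance is `< max_gap`.
#' @return Block tibble with `block_id`, `chrom`, `start`, `end`,
#'   `n_snvs`, `n_patients` and a list-column `snvs` holding the member
#'   records.
#' @export
cluster_snvs <- function(snvs, max_gap = 30) {
  stopifnot(max_gap >= 1)
  if (nrow(snvs) == 0L) {
    return(tibble::tibble(block_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_snvs = integer(), n_patients = integer(),
                          snvs = list()))
  }
  snvs <- dplyr::arrange(snvs, .data$chrom, .data$pos, .data$patient_id)
  clustered <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(snvs, .data$chrom),
    cluster = cumsum(c(TRUE, diff(.data$pos) >= max_gap))
  ))
  out <- dplyr::summarise(
    dplyr::group_by(clustered, .data$chrom, .data$cluster),
    start = min(.data$pos), end = max(.data$pos),
    n_snvs = dplyr::n(),
    n_patients = dplyr::n_distinct(.data$patient_id),
    snvs = list(dplyr::pick("pos", "ref_base", "alt_base", "patient_id")),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
    block_id = block_id_of(.data$chrom, .data$start, .data$end),
    snvs = purrr::map2(.data$snvs, .data$chrom,
                       function(s, ch) dplyr::mutate(s, chrom = ch,
                                                     .before = 1L))
  )
  dplyr::select(out, "block_id", "chrom", "start", "end", "n_snvs",
                "n_patients", "snvs")
}

#' Keep recurrent mutation blocks
#'
#' A block is recurrent when it holds at least two SNVs coming from at
#' least two distinct patients.
#'
#' @param blocks Block tibble from [cluster_snvs()].
#' @return Filtered block tibble.
#' @export
filter_recurrent <- function(blocks) {
  dplyr::filter(blocks, .data$n_snvs >= 2L, .data$n_patients >= 2L)
}

#' Assign mutation blocks to gene promoters
#'
#' A block is assigned to gene `g` when any member SNV lies inside any
#' promoter window of `g` (every TSS of a gene yields its own window).
#' Blocks overlapping no promoter are dropped; a block inside overlapping
#' promoters of several genes is duplicated, once per gene.
#'
#' @param blocks Block tibble.
#' @param tss TSS tibble from [read_tss()].
#' @param half_width Promoter half-width in bp (default 1000).
#' @return Block tibble with added `gene_id` and `gene_name` columns.
#' @export
assign_to_promoters <- function(blocks, tss, half_width = 1000) {
  win <- promoter_windows(tss, half_width)
  win <- dplyr::mutate(win, nchrom = norm_chrom(.data$chrom))
  hits <- purrr::map(seq_len(nrow(blocks)), function(i) {
    pos <- blocks$snvs[[i]]$pos
    w <- dplyr::filter(win, .data$nchrom == norm_chrom(blocks$chrom[i]))
    if (nrow(w) == 0L) return(NULL)
    in_any <- vapply(seq_len(nrow(w)), function(j) {
      any(pos >= w$start[j] & pos <= w$end[j])
    }, logical(1))
    genes <- dplyr::distinct(w[in_any, c("gene_id", "gene_name")])
    if (nrow(genes) == 0L) return(NULL)
    dplyr::bind_cols(blocks[rep(i, nrow(genes)), ], genes)
  })
  dplyr::bind_rows(hits)
}

#' Gate blocks by tumor-vs-normal differential expression
#'
#' For every block's assigned gene, the tumor and normal expression values
#' are compared with a two-sample Kolmogorov-Smirnov test
#' ([ks_test_2sample()]); a block is kept when `p < alpha`.
#'
#' @param blocks Block tibble with `gene_id` (from
#'   [assign_to_promoters()]).
#' @param expr [expression_table()].
#' @param alpha Significance level (default 0.05).
#' @return `blocks` with added `de_pvalue` and `keep` columns (no rows are
#'   dropped here; the caller filters on `keep`).
#' @export
ks_gate <- function(blocks, expr, alpha = 0.05) {
  if (sum(expr$groups == "tumor") < 2L || sum(expr$groups == "normal") < 2L) {
    stop("ks_gate needs >= 2 tumor and >= 2 normal samples")
  }
  pv <- vapply(blocks$gene_id, function(g) {
    ks_test_2sample(expr_values(expr, g, "tumor"),
                    expr_values(expr, g, "normal"))$p_value
  }, numeric(1))
  dplyr::mutate(blocks, de_pvalue = unname(pv), keep = .data$de_pvalue < alpha)
}

#' Build patient-specific block sequences
#'
#' For every (block, patient) pair with at least one member SNV, extracts
#' the reference sequence spanning the block plus a flank on each side and
#' substitutes ALL of that patient's block SNVs into the alternative
#' sequence. The flank lets motif windows straddle block edges.
#'
#' @param blocks Block tibble (one or more rows).
#' @param genome `DNAStringSet` from [read_genome()].
#' @param flank Flank width in bp (default 30), clipped at chromosome
#'   bounds.
#' @return Tibble with `unit_id`, `block_id`, `patient_id`, `win_start`,
#'   `win_end`, `ref_seq`, `alt_seq`.
#' @export
build_patient_sequences <- function(blocks, genome, flank = 30) {
  stopifnot(flank >= 0)
  rows <- purrr::map(seq_len(nrow(blocks)), function(i) {
    blk <- blocks[i, ]
    chr_len <- length(genome_chrom(genome, blk$chrom))
    win_start <- max(1L, blk$start - as.integer(flank))
    win_end <- min(chr_len, blk$end + as.integer(flank))
    ref_seq <- get_sequence(genome, blk$chrom, win_start, win_end)
    member <- blk$snvs[[1]]
    off <- member$pos - win_start + 1L
    ref_at <- substring(ref_seq, off, off)
    if (any(ref_at != member$ref_base)) {
      bad <- which(ref_at != member$ref_base)
      stop("genome/ref mismatch in block ", blk$block_id, " at position(s) ",
           paste(member$pos[bad], collapse = ", "))
    }
    purrr::map(split(seq_len(nrow(member)), member$patient_id),
               function(idx) {
      alt <- strsplit(ref_seq, "")[[1]]
      alt[off[idx]] <- member$alt_base[idx]
      tibble::tibble(
        unit_id = paste0(blk$block_id, "|", member$patient_id[idx[1]]),
        block_id = blk$block_id,
        patient_id = member$patient_id[idx[1]],
        win_start = win_start, win_end = win_end,
        ref_seq = ref_seq,
        alt_seq = paste(alt, collapse = "")
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Reference/alternative windows centered on single SNVs
#'
#' Builds the fixed-width sequence pair around each SNV (61 bp at the
#' default half-width of 30); windows running off a chromosome end are
#' clipped with a warning, keeping the SNV at its original offset.
#'
#' @param snvs SNV tibble.
#' @param genome `DNAStringSet`.
#' @param half Half-window in bp (default 30).
#' @return Tibble with `unit_id`, `patient_id`, `chrom`, `pos`,
#'   `center_offset` (1-based offset of the SNV in the window), `ref_seq`,
#'   `alt_seq`.
#' @export
snv_window_sequences <- function(snvs, genome, half = 30) {
  stopifnot(half >= 0)
  rows <- purrr::map(seq_len(nrow(snvs)), function(i) {
    s <- snvs[i, ]
    chr_len <- length(genome_chrom(genome, s$chrom))
    win_start <- s$pos - as.integer(half)
    win_end <- s$pos + as.integer(half)
    if (win_start < 1L || win_end > chr_len) {
      warning("window for ", s$chrom, ":", s$pos,
              " clipped at chromosome bounds")
      win_start <- max(1L, win_start)
      win_end <- min(chr_len, win_end)
    }
    ref_seq <- get_sequence(genome, s$chrom, win_start, win_end)
    off <- s$pos - win_start + 1L
    if (substring(ref_seq, off, off) != s$ref_base) {
      stop("genome/ref mismatch at ", s$chrom, ":", s$pos)
    }
    alt <- strsplit(ref_seq, "")[[1]]
    alt[off] <- s$alt_base
    tibble::tibble(
      unit_id = paste0(s$chrom, ":", s$pos, ":", s$ref_base, ">",
                       s$alt_base, "|", s$patient_id),
      patient_id = s$patient_id,
      chrom = s$chrom, pos = s$pos, center_offset = off,
      ref_seq = ref_seq, alt_seq = paste(alt, collapse = "")
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full mutation-block discovery stage
#'
#' Convenience wrapper chaining [cluster_snvs()], [filter_recurrent()],
#' [assign_to_promoters()] and (when an expression table is given)
#' [ks_gate()], in that order.
#'
#' @param snvs SNV tibble.
#' @param tss TSS tibble.
#' @param expr Optional [expression_table()]; when `NULL` the expression
#'   gate is skipped and all assigned blocks are kept.
#' @param max_gap Clustering gap in bp (default 30).
#' @param half_width Promoter half-width in bp (default 1000).
#' @param alpha KS-gate significance level (default 0.05).
#' @return An object of class `mussd_result`: list with `blocks` (the
#'   gated block tibble), `all_blocks` (before promoter assignment) and the
#'   parameters used.
#' @export
mussd <- function(snvs, tss, expr = NULL, max_gap = 30, half_width = 1000,
                  alpha = 0.05) {
  clustered <- cluster_snvs(snvs, max_gap = max_gap)
  recurrent <- filter_recurrent(clustered)
  assigned <- assign_to_promoters(recurrent, tss, half_width = half_width)
  if (!is.null(expr) && nrow(assigned) > 0L) {
    gated <- ks_gate(assigned, expr, alpha = alpha)
    blocks <- dplyr::filter(gated, .data$keep)
  } else {
    gated <- assigned
    blocks <- assigned
  }
  structure(list(blocks = blocks, assigned = gated, all_blocks = clustered,
                 params = list(max_gap = max_gap, half_width = half_width,
                               alpha = alpha)),
            class = "mussd_result")
}

#' @export
print.mussd_result <- function(x, ...) {
  cat("<mussd_result> ", nrow(x$all_blocks), " raw blocks -> ",
      nrow(x$blocks), " recurrent promoter blocks",
      if (!is.null(x$params$alpha)) paste0(" (KS gate alpha = ",
                                           x$params$alpha, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname mussd
#' @param x A `mussd_result`.
#' @param ... Unused.
#' @export
tidy.mussd_result <- function(x, ...) {
  dplyr::select(x$blocks, -dplyr::any_of("snvs"))
}

#' @rdname mussd
#' @export
glance.mussd_result <- function(x, ...) {
  tibble::tibble(
    n_blocks_raw = nrow(x$all_blocks),
    n_blocks_kept = nrow(x$blocks),
    n_snvs_kept = sum(x$blocks$n_snvs),
    n_patients = if (nrow(x$blocks) > 0) {
      dplyr::n_distinct(dplyr::bind_rows(x$blocks$snvs)$patient_id)
    } else 0L,
    max_gap = x$params$max_gap,
    half_width = x$params$half_width,
    alpha = x$params$alpha
  )
}
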