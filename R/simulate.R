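# Synthetic-cohort simulator: a miniature multi-patient study (genome,
# TSS annotation, per-patient somatic SNVs, PWM collection, tumor/normal
# expression) with planted regulatory mutation blocks, so that every
# pipeline stage can be exercised end-to-end without external data.

#' Parameters of a synthetic cohort scenario
#'
#' The defaults emulate the structure of a small lymphoma cohort: a dozen
#' tumor-normal paired patients, a few dozen genes with symmetric 1-kb
#' promoters, two "driver" genes whose promoters carry a planted mutation
#' block in which patient SNVs disrupt occurrences of a known binding
#' motif, and tumor expression of the driver genes shifted against the
#' normals.
#'
#' @param n_patients Number of tumor patients (default 12).
#' @param n_genes Number of genes on the synthetic chromosome (default
#'   50).
#' @param n_drivers Number of driver genes with planted blocks (default
#'   2).
#' @param chrom_length Chromosome length in bp (default 200000).
#' @param block_width Width of each planted block in bp (default 60); it
#'   holds three occurrences of the planted motif's consensus.
#' @param snvs_per_patient_in_block Planted SNVs per affected patient per
#'   block (default 2); halved (minimum 1) when `weak_effect` is set.
#' @param block_prob Probability that a patient carries planted SNVs in a
#'   given driver block (default 0.7).
#' @param background_snv_rate Genome-wide per-bp SNV probability per
#'   patient (default 1e-5).
#' @param expression_effect Multiplicative tumor shift of driver-gene
#'   expression (default 4).
#' @param expr_sigma Log-normal sigma of expression noise (default 0.5).
#' @param n_normals Number of normal control samples (default 4).
#' @param n_decoy_pwms Decoy PWMs accompanying the planted one (default
#'   50).
#' @param weak_effect Halve the planted disruptions for power testing.
#' @param seed RNG seed (default 1).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_patients = 12, n_genes = 50,
                               n_drivers = 2, chrom_length = 200000,
                               block_width = 60,
                               snvs_per_patient_in_block = 2,
                               block_prob = 0.7,
                               background_snv_rate = 1e-5,
                               expression_effect = 4, expr_sigma = 0.5,
                               n_normals = 4, n_decoy_pwms = 50,
                               weak_effect = FALSE, seed = 1) {
  stopifnot(n_patients >= 2, n_genes >= n_drivers, n_drivers >= 1,
            block_width >= 20, n_normals >= 2)
  structure(list(
    n_patients = n_patients, n_genes = n_genes, n_drivers = n_drivers,
    chrom_length = chrom_length, block_width = block_width,
    snvs_per_patient_in_block = if (weak_effect) {
      max(1L, snvs_per_patient_in_block %/% 2L)
    } else snvs_per_patient_in_block,
    block_prob = block_prob, background_snv_rate = background_snv_rate,
    expression_effect = expression_effect, expr_sigma = expr_sigma,
    n_normals = n_normals, n_decoy_pwms = n_decoy_pwms, seed = seed
  ), class = "synthetic_scenario")
}

# The planted motif: an 8-bp matrix with 0.85 on the consensus base and
# unequal off-consensus probabilities so every position has a unique worst
# base. The worst base cycles through the non-consensus alphabet across
# positions, so that consensus->worst disruptions are compositionally
# balanced rather than enriching one nucleotide. Consensus: TGACTCAG.
planted_pwm <- function() {
  consensus <- c("T", "G", "A", "C", "T", "C", "A", "G")
  probs <- matrix(0, nrow = length(consensus), ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(consensus)) {
    others <- setdiff(DNA_BASES, consensus[i])
    worst <- others[(i - 1L) %% 3L + 1L]
    probs[i, consensus[i]] <- 0.85
    probs[i, setdiff(others, worst)] <- c(0.07, 0.05)
    probs[i, worst] <- 0.03
  }
  pwm("PLANTED_TF", "PLANTED.1", probs)
}

# Maximum aligned consensus identity between two consensus strings over
# all offsets and both strands.
consensus_identity <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  for (cand in list(b, rev(unname(comp[b])))) {
    la <- length(a)
    lb <- length(cand)
    for (sh in seq(-(lb - 1L), la - 1L)) {
      ia <- max(1L, 1L + sh):min(la, lb + sh)
      best <- max(best, sum(a[ia] == cand[ia - sh]))
    }
  }
  best
}

# Decoy PWMs: informative consensus-style matrices (peak probability
# 0.6-0.9, lengths 6-10) with a random consensus screened against the
# planted motif — a motif sharing most of the planted consensus would be
# genuinely affected by the planted mutations and is no decoy.
random_decoy_pwms <- function(n, planted_consensus, min_len = 6,
                              max_len = 10, max_identity = 4) {
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    L <- sample(min_len:max_len, 1L)
    cons <- sample(DNA_BASES, L, replace = TRUE)
    if (consensus_identity(planted_consensus, cons) > max_identity) next
    i <- i + 1L
    peak <- runif(1, 0.6, 0.9)
    probs <- t(vapply(seq_len(L), function(j) {
      rest <- stats::rgamma(3, shape = 1)
      rest <- rest / sum(rest) * (1 - peak)
      p <- numeric(4)
      p[match(cons[j], DNA_BASES)] <- peak
      p[p == 0] <- rest
      p
    }, numeric(4)))
    out[[i]] <- pwm(sprintf("DECOY_TF_%02d", i), sprintf("DECOY.%02d", i),
                    probs)
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic cohort
#'
#' Builds the full in-memory study bundle for a [synthetic_scenario()]
#' and, when `dir` is given, writes it to disk in the exact formats the
#' package readers consume (FASTA genome, TSS TSV, one VCF per patient,
#' JASPAR PWM file, expression TSV with a sample-group TSV, and a truth
#' table of planted blocks).
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Optional output directory (created if missing).
#' @return List with `genome`, `tss`, `snvs`, `pwms`, `expr`, `truth`
#'   (planted-block tibble) and, when written, `paths`.
#' @export
generate_scenario <- function(scenario, dir = NULL) {
  p <- scenario
  motif <- planted_pwm()
  probs <- motif$probs[[1]]
  L <- nrow(probs)
  consensus <- DNA_BASES[apply(probs, 1, which.max)]
  worst <- DNA_BASES[apply(probs, 1, which.min)]
  if (L > p$block_width) stop("planted motif longer than the block")

  with_seed_if(p$seed, {
    chrom <- "chrS"
    genome_chars <- sample(DNA_BASES, p$chrom_length, replace = TRUE)

    spacing <- p$chrom_length %/% (p$n_genes + 1L)
    if (spacing < 2200) stop("chromosome too short for the gene count")
    tss_pos <- as.integer(seq_len(p$n_genes) * spacing)
    tss <- tibble::tibble(
      gene_id = sprintf("G%03d", seq_len(p$n_genes)),
      gene_name = sprintf("GENE%03d", seq_len(p$n_genes)),
      chrom = chrom, tss = tss_pos,
      strand = rep_len(c("+", "-"), p$n_genes)
    )
    drivers <- sort(sample.int(p$n_genes, p$n_drivers))

    # Plant three consensus occurrences inside a block downstream of each
    # driver TSS (still within the +/-1 kb promoter window).
    occ_rel <- round((p$block_width - L) * c(0.05, 0.5, 0.95))
    truth <- purrr::map(drivers, function(g) {
      bstart <- tss$tss[g] + 100L
      occ_starts <- bstart + as.integer(occ_rel)
      for (s in occ_starts) {
        genome_chars[s:(s + L - 1L)] <<- consensus
      }
      tibble::tibble(gene_id = tss$gene_id[g], chrom = chrom,
                     block_start = bstart,
                     block_end = bstart + p$block_width - 1L,
                     occ_starts = list(occ_starts),
                     pwm_id = motif$pwm_id, expected_sign = "negative")
    }) |> dplyr::bind_rows()

    patients <- sprintf("P%02d", seq_len(p$n_patients))
    snv_rows <- purrr::map(patients, function(pid) {
      n_bg <- rbinom(1, p$chrom_length, p$background_snv_rate)
      in_block <- function(pos) {
        any(pos >= truth$block_start & pos <= truth$block_end)
      }
      bg_pos <- sample.int(p$chrom_length, n_bg)
      bg_pos <- bg_pos[!vapply(bg_pos, in_block, logical(1))]
      bg <- if (length(bg_pos) > 0) {
        tibble::tibble(
          chrom = chrom, pos = sort(bg_pos),
          ref_base = genome_chars[sort(bg_pos)],
          alt_base = vapply(genome_chars[sort(bg_pos)], function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
          }, character(1)),
          patient_id = pid
        )
      } else NULL
      planted <- purrr::map(seq_len(nrow(truth)), function(b) {
        if (runif(1) > p$block_prob) return(NULL)
        slots <- unlist(purrr::map(truth$occ_starts[[b]],
                                   function(s) s:(s + L - 1L)))
        hit <- sort(sample(slots, p$snvs_per_patient_in_block))
        motif_pos <- vapply(hit, function(h) {
          occ <- max(truth$occ_starts[[b]][truth$occ_starts[[b]] <= h])
          h - occ + 1L
        }, integer(1))
        tibble::tibble(
          chrom = chrom, pos = hit,
          ref_base = consensus[motif_pos],
          alt_base = worst[motif_pos],
          patient_id = pid
        )
      }) |> dplyr::bind_rows()
      dplyr::bind_rows(bg, planted)
    })
    snvs <- dplyr::bind_rows(snv_rows)
    if (nrow(snvs) == 0L) {
      snvs <- snv_table(character(), integer(), character(), character(),
                        character())
    }
    snvs <- dplyr::arrange(snvs, .data$chrom, .data$pos, .data$patient_id)
    snvs <- dplyr::distinct(snvs, .data$patient_id, .data$pos,
                            .keep_all = TRUE)

    pwms <- dplyr::bind_rows(motif,
                             random_decoy_pwms(p$n_decoy_pwms, consensus))

    # Expression: log-normal noise around per-gene means; driver genes
    # shifted multiplicatively in tumors. TF genes are appended so the
    # expression filter can be exercised, including a few straddling the
    # noise floor.
    samples <- c(patients, sprintf("N%02d", seq_len(p$n_normals)))
    groups <- setNames(rep(c("tumor", "normal"),
                           c(p$n_patients, p$n_normals)), samples)
    gene_means <- rlnorm(p$n_genes, meanlog = log(5), sdlog = 1)
    vals <- vapply(seq_along(samples), function(j) {
      mu <- gene_means
      if (groups[j] == "tumor") {
        mu[drivers] <- mu[drivers] * p$expression_effect
      }
      rlnorm(p$n_genes, meanlog = log(mu), sdlog = p$expr_sigma)
    }, numeric(p$n_genes))
    tf_means <- c(10, rep(5, p$n_decoy_pwms))
    n_straddle <- min(3L, p$n_decoy_pwms)
    tf_means[1 + seq_len(n_straddle)] <- c(0.01, 0.02, 0.05)[seq_len(n_straddle)]
    tf_vals <- vapply(seq_along(samples), function(j) {
      rlnorm(length(tf_means), meanlog = log(tf_means), sdlog = p$expr_sigma)
    }, numeric(length(tf_means)))
    values <- rbind(vals, tf_vals)
    rownames(values) <- c(tss$gene_id, unique(pwms$tf_name))
    colnames(values) <- samples
    expr <- expression_table(values, groups)

    bundle <- list(genome = Biostrings::DNAStringSet(
                     setNames(paste(genome_chars, collapse = ""), chrom)),
                   tss = tss, snvs = snvs, pwms = pwms, expr = expr,
                   truth = truth, scenario = p)
  })

  if (!is.null(dir)) {
    bundle$paths <- write_scenario(bundle, dir)
  }
  bundle
}

# Write the bundle in the formats the package readers consume.
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    tss = file.path(dir, "tss.tsv"),
    pwms = file.path(dir, "pwms.jaspar"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "sample_groups.tsv"),
    truth = file.path(dir, "truth.tsv"),
    vcf_dir = file.path(dir, "vcf")
  )
  Biostrings::writeXStringSet(bundle$genome, paths$genome)
  readr::write_tsv(bundle$tss, paths$tss, progress = FALSE)
  write_pwms(bundle$pwms, paths$pwms)
  expr_tbl <- tibble::as_tibble(bundle$expr$values, rownames = "gene_id")
  readr::write_tsv(expr_tbl, paths$expression, progress = FALSE)
  readr::write_tsv(tibble::tibble(sample = names(bundle$expr$groups),
                                  group = unname(bundle$expr$groups)),
                   paths$groups, progress = FALSE)
  readr::write_tsv(dplyr::select(bundle$truth, -"occ_starts"), paths$truth,
                   progress = FALSE)
  dir.create(paths$vcf_dir, showWarnings = FALSE)
  chrom_len <- Biostrings::width(bundle$genome)[1]
  vcfs <- purrr::map(split(bundle$snvs, bundle$snvs$patient_id),
                     function(df) {
    path <- file.path(paths$vcf_dir, paste0(df$patient_id[1], ".vcf"))
    header <- c("##fileformat=VCFv4.2",
                paste0("##contig=<ID=", names(bundle$genome)[1],
                       ",length=", chrom_len, ">"),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", df$chrom, df$pos,
                    df$ref_base, df$alt_base)
    readr::write_lines(c(header, body), path)
    path
  })
  paths$vcfs <- setNames(unlist(vcfs), names(vcfs))
  paths
}

#' Nucleotide substitution spectrum
#'
#' Collapses SNVs to the six pyrimidine-referenced substitution categories
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-referenced changes are mapped to
#' their reverse complements.
#'
#' @param snvs SNV tibble.
#' @return Tibble with `category`, `count`, `fraction` (all six categories
#'   always present; fractions sum to 1 for non-empty input).
#' @export
#' @examples
#' nucleotide_change_stats(snv_table("1", 1, "G", "A", "P1"))
nucleotide_change_stats <- function(snvs) {
  categories <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (nrow(snvs) > 0) {
    ref <- snvs$ref_base
    alt <- snvs$alt_base
    flip <- ref %in% c("A", "G")
    ref[flip] <- comp[ref[flip]]
    alt[flip] <- comp[alt[flip]]
    tab <- table(factor(paste0(ref, ">", alt), levels = categories))
  } else {
    tab <- table(factor(character(), levels = categories))
  }
  counts <- as.integer(tab)
  tibble::tibble(
    category = categories, count = counts,
    fraction = if (sum(counts) > 0) counts / sum(counts) else rep(0, 6)
  )
}
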