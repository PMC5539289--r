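# Biophysical PWM-occupancy scoring.
#
# A PWM is converted to a mismatch-energy matrix (consensus base = 0,
# larger = weaker). A site of energy E is occupied with Fermi-Dirac
# probability P = 1/(1 + exp(beta * (E - mu))) at chemical potential mu.
# The binding affinity of a sequence, dbA, is the log of the total
# occupancy summed over every motif-length window on both strands, so
# multiple nearby sites contribute. The differential binding affinity
# delta-dbA of a (reference, alternative) sequence pair is dbA(alt) -
# dbA(ref), averaged over a grid of chemical potentials to model unknown
# nuclear TF abundance: positive = gained binding, negative = disrupted.

#' Affinity model parameters
#'
#' @param mu_grid Chemical potential grid (dimensionless, on the same
#'   ln-probability scale as the energies). Delta-dbA is averaged over the
#'   grid.
#' @param beta Inverse temperature; fixed at 1 by default.
#' @param both_strands Scan the reverse complement as well as the forward
#'   strand.
#' @return A list of class `affinity_params`.
#' @export
affinity_params <- function(mu_grid = c(-2, 0, 2, 4), beta = 1,
                            both_strands = TRUE) {
  stopifnot(length(mu_grid) >= 1, is.numeric(mu_grid), beta > 0)
  structure(list(mu_grid = as.numeric(mu_grid), beta = as.numeric(beta),
                 both_strands = isTRUE(both_strands)),
            class = "affinity_params")
}

#' Convert PWM probabilities to binding energies
#'
#' Per position i and base b, `E[i,b] = ln(max_b' p[i,b']) - ln(p[i,b])`,
#' so the consensus base has energy 0 and every entry is non-negative.
#'
#' @param probs L x 4 probability matrix (columns A,C,G,T, rows summing
#'   to 1), e.g. one element of the `probs` column from [read_pwms()].
#' @return L x 4 energy matrix.
#' @export
#' @examples
#' pwm_to_energy(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
pwm_to_energy <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs <= 0)) stop("zero probability in PWM; apply a pseudocount first")
  e <- log(apply(probs, 1, max)) - log(probs)
  colnames(e) <- DNA_BASES
  e
}

# Add an `energies` list-column to a PWM collection.
energy_matrices <- function(pwms) {
  dplyr::mutate(pwms, energies = purrr::map(.data$probs, pwm_to_energy))
}

#' Fermi-Dirac occupancy of a single site
#'
#' @param seq_window DNA string of exactly the motif length.
#' @param energies L x 4 energy matrix from [pwm_to_energy()].
#' @param mu Chemical potential.
#' @param beta Inverse temperature.
#' @return Occupancy in (0, 1).
#' @export
site_occupancy <- function(seq_window, energies, mu, beta = 1) {
  bases <- strsplit(toupper(seq_window), "")[[1]]
  if (length(bases) != nrow(energies)) {
    stop("window length ", length(bases), " != motif length ", nrow(energies))
  }
  idx <- match(bases, DNA_BASES)
  if (any(is.na(idx))) stop("window contains non-ACGT characters")
  e <- sum(energies[cbind(seq_len(nrow(energies)), idx)])
  1 / (1 + exp(beta * (e - mu)))
}

#' Sequence-level binding affinity (dbA)
#'
#' `dbA = ln(sum over all motif windows on both strands of the site
#' occupancy)`. Windows containing non-ACGT characters are skipped.
#'
#' @param sequence DNA string, at least as long as the motif.
#' @param energies L x 4 energy matrix.
#' @param mu Chemical potential(s); the result is vectorized over `mu`.
#' @param beta Inverse temperature.
#' @param both_strands Include the reverse-complement scan.
#' @param tf Optional TF label used in error messages.
#' @return Numeric vector of dbA values, one per `mu`.
#' @export
dba <- function(sequence, energies, mu, beta = 1, both_strands = TRUE,
                tf = NULL) {
  L <- nrow(energies)
  if (nchar(sequence) < L) {
    stop("sequence (", nchar(sequence), " bp) shorter than motif (", L,
         " bp)", if (!is.null(tf)) paste0(" for TF '", tf, "'"))
  }
  as.numeric(.dba_cpp(toupper(sequence), energies, as.numeric(mu), beta,
                      both_strands))
}

#' Differential binding affinity (delta-dbA) of a sequence pair
#'
#' Computes `dbA(alt) - dbA(ref)` at every chemical potential in the grid
#' and averages. Identical sequences give exactly zero.
#'
#' @param ref_seq,alt_seq Equal-length DNA strings.
#' @param energies L x 4 energy matrix.
#' @param params [affinity_params()].
#' @return A single delta-dbA value; positive means increased binding on
#'   the alternative sequence.
#' @export
delta_dba <- function(ref_seq, alt_seq, energies,
                      params = affinity_params()) {
  if (nchar(ref_seq) != nchar(alt_seq)) {
    stop("ref (", nchar(ref_seq), " bp) and alt (", nchar(alt_seq),
         " bp) sequences differ in length")
  }
  as.numeric(.ddba_batch_cpp(toupper(ref_seq), toupper(alt_seq), energies,
                             params$mu_grid, params$beta,
                             params$both_strands))
}

#' Z-score delta-dbA values across scored units, per TF
#'
#' Each PWM's raw delta-dbA values are centered and scaled to zero mean and
#' unit standard deviation across all scored units (single SNVs or
#' patient-blocks) so magnitudes are comparable between TFs. The population
#' (1/n) standard deviation is used; a single unit or zero spread yields
#' zeros.
#'
#' @param results Tibble with at least `pwm_id` and `ddba_raw`.
#' @return `results` with an added/overwritten `ddba_norm` column.
#' @export
normalize_deltas <- function(results) {
  if (any(!is.finite(results$ddba_raw))) {
    stop("non-finite ddba_raw values cannot be normalized")
  }
  single <- dplyr::count(results, .data$pwm_id)
  if (any(single$n == 1L)) {
    warning("PWM(s) with a single scored unit get ddba_norm = 0")
  }
  dplyr::mutate(
    dplyr::group_by(results, .data$pwm_id),
    ddba_norm = {
      mu <- mean(.data$ddba_raw)
      s <- sqrt(mean((.data$ddba_raw - mu)^2))
      if (length(.data$ddba_raw) < 2L || s == 0) {
        rep(0, length(.data$ddba_raw))
      } else {
        (.data$ddba_raw - mu) / s
      }
    }
  ) |> dplyr::ungroup()
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Generates random permutations of a DNA string that exactly preserve its
#' dinucleotide (and hence mononucleotide) composition, via a random
#' Eulerian path on the dinucleotide transition multigraph
#' (Altschul-Erickson construction). Used as the background model for the
#' direct-binding p-value; preserving dinucleotides keeps CpG composition.
#'
#' @param sequence DNA string (length > 3 for a non-trivial shuffle).
#' @param n Number of shuffles.
#' @param seed Optional RNG seed (global RNG state is preserved).
#' @return Character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 1, seed = NULL) {
  with_seed_if(seed, {
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) <= 3L || length(unique(chars)) < 2L) {
      return(rep(sequence, n))
    }
    vapply(seq_len(n), function(i) shuffle_once(chars), character(1))
  })
}

shuffle_once <- function(chars) {
  L <- length(chars)
  first <- chars[1]
  last <- chars[L]
  edges <- split(chars[-1], chars[-L])  # outgoing edge multisets
  verts <- names(edges)
  inner <- setdiff(verts, last)
  # Choose a "last exit" edge for every vertex except the final one such
  # that following last-exits always reaches the final vertex (a random
  # arborescence; rejection sampling is cheap with <= 4 vertices).
  repeat {
    last_edge <- vapply(inner, function(v) {
      out <- edges[[v]]
      out[sample.int(length(out), 1L)]
    }, character(1))
    ok <- all(vapply(inner, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || !(v %in% inner)) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
  }
  # Permute the remaining edges, appending each vertex's last-exit edge.
  lists <- lapply(verts, function(v) {
    out <- edges[[v]]
    if (v %in% inner) {
      drop <- match(last_edge[[v]], out)
      rest <- out[-drop]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      out[sample.int(length(out))]
    }
  })
  names(lists) <- verts
  # Walk the Eulerian path.
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(L)
  out[1] <- first
  cur <- first
  for (i in 2:L) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Empirical p-value for direct TF binding
#'
#' Tests whether the reference sequence binds the TF more strongly than
#' dinucleotide-preserving shuffles of itself:
#' `p = (1 + #\{dbA(shuffle) >= dbA(ref)\}) / (1 + n_generated)`. With
#' `early_stop = TRUE`, generation halts once `ceil(0.2 * n_background)`
#' shuffles have exceeded the observed dbA, at which point the p-value is
#' already guaranteed to exceed the 0.1 filtering cutoff.
#'
#' @param ref_seq Reference DNA string.
#' @param energies L x 4 energy matrix.
#' @param params [affinity_params()].
#' @param n_background Number of shuffles (>= 20).
#' @param seed Optional RNG seed.
#' @param early_stop Allow early termination for clearly non-binding TFs.
#' @param shuffles Optional pre-generated shuffle set (recycled across TFs
#'   by the pipeline); overrides `n_background`/`seed`/`early_stop`.
#' @return p-value in (0, 1].
#' @export
direct_binding_pvalue <- function(ref_seq, energies,
                                  params = affinity_params(),
                                  n_background = 100, seed = NULL,
                                  early_stop = TRUE, shuffles = NULL) {
  obs <- mean(dba(ref_seq, energies, params$mu_grid, params$beta,
                  params$both_strands))
  if (!is.null(shuffles)) {
    bg <- .dba_batch_cpp(shuffles, energies, params$mu_grid, params$beta,
                         params$both_strands)
    return((1 + sum(bg >= obs)) / (1 + length(bg)))
  }
  stopifnot(n_background >= 20)
  stop_at <- ceiling(0.2 * n_background)
  with_seed_if(seed, {
    n_exceed <- 0L
    n_gen <- 0L
    batch <- 25L
    while (n_gen < n_background) {
      m <- min(batch, n_background - n_gen)
      sh <- dinucleotide_shuffle(ref_seq, n = m)
      bg <- .dba_batch_cpp(sh, energies, params$mu_grid, params$beta,
                           params$both_strands)
      n_exceed <- n_exceed + sum(bg >= obs)
      n_gen <- n_gen + m
      if (early_stop && n_exceed >= stop_at) break
    }
    (1 + n_exceed) / (1 + n_gen)
  })
}

#' Rank TFs affected by one scored unit
#'
#' Applies the reporting filters: TFs without a plausible site on the
#' reference sequence (direct-binding p-value at or above
#' `p_direct_cutoff`) are discarded; TFs whose normalized |delta-dbA| falls
#' below the `magnitude_quantile` quantile within this unit are discarded;
#' the survivors are split by sign, ordered by decreasing |delta-dbA|
#' (ties broken by `pwm_id`), and truncated to the top `k` per direction.
#'
#' @param results Tibble for one unit with `pwm_id`, `ddba_norm`,
#'   `p_direct` (plus any carry-along columns).
#' @param k Maximum list length per direction (default 15).
#' @param p_direct_cutoff Direct-binding filter (default 0.1, strict `<`).
#' @param magnitude_quantile Magnitude filter quantile (default 0.8, i.e.
#'   keep the top 20 percent).
#' @return Filtered tibble with added `direction` and `rank` columns.
#' @export
rank_tfs <- function(results, k = 15, p_direct_cutoff = 0.1,
                     magnitude_quantile = 0.8) {
  res <- dplyr::filter(results, .data$p_direct < p_direct_cutoff)
  if (nrow(res) == 0L) {
    return(dplyr::mutate(res, direction = character(), rank = integer()))
  }
  thr <- quantile(abs(res$ddba_norm), magnitude_quantile, names = FALSE)
  res <- dplyr::filter(res, abs(.data$ddba_norm) >= thr)
  res <- dplyr::mutate(res, direction = ifelse(.data$ddba_norm >= 0,
                                               "positive", "negative"))
  res <- dplyr::arrange(res, .data$direction,
                        dplyr::desc(abs(.data$ddba_norm)), .data$pwm_id)
  res <- dplyr::mutate(dplyr::group_by(res, .data$direction),
                       rank = dplyr::row_number())
  dplyr::ungroup(dplyr::filter(res, .data$rank <= k))
}

#' Score delta-dbA for a set of sequence units against a PWM collection
#'
#' The workhorse joining the mutation-block stage to the statistics stage:
#' every (unit, PWM) pair gets a raw delta-dbA; values are then z-scored
#' per PWM across units, and (optionally) a direct-binding p-value is
#' attached using one shared shuffle set per unit.
#'
#' @param units Tibble with `unit_id`, `patient_id`, `ref_seq`, `alt_seq`.
#' @param pwms PWM collection from [read_pwms()].
#' @param params [affinity_params()].
#' @param n_shuffles Shuffle count for the direct-binding p-value; set to 0
#'   to skip the p-value (column filled with `NA`).
#' @param seed Optional RNG seed for the shuffle sets.
#' @return Tibble with `unit_id`, `patient_id`, `tf_name`, `pwm_id`,
#'   `ddba_raw`, `ddba_norm`, `p_direct`.
#' @export
score_units <- function(units, pwms, params = affinity_params(),
                        n_shuffles = 100, seed = NULL) {
  stopifnot(nrow(units) > 0, nrow(pwms) > 0)
  ems <- energy_matrices(pwms)
  shuffle_sets <- if (n_shuffles > 0) {
    with_seed_if(seed, lapply(units$ref_seq, dinucleotide_shuffle,
                              n = n_shuffles))
  } else {
    NULL
  }
  res <- purrr::map(seq_len(nrow(ems)), function(i) {
    en <- ems$energies[[i]]
    raw <- .ddba_batch_cpp(toupper(units$ref_seq), toupper(units$alt_seq),
                           en, params$mu_grid, params$beta,
                           params$both_strands)
    pd <- if (is.null(shuffle_sets)) {
      rep(NA_real_, nrow(units))
    } else {
      vapply(seq_len(nrow(units)), function(j) {
        direct_binding_pvalue(units$ref_seq[j], en, params,
                              shuffles = shuffle_sets[[j]])
      }, numeric(1))
    }
    tibble::tibble(
      unit_id = units$unit_id,
      patient_id = units$patient_id,
      tf_name = ems$tf_name[i],
      pwm_id = ems$pwm_id[i],
      ddba_raw = as.numeric(raw),
      p_direct = pd
    )
  })
  res <- dplyr::bind_rows(res)
  if (length(unique(units$unit_id)) >= 2L) {
    res <- normalize_deltas(res)
  } else {
    res$ddba_norm <- 0
  }
  dplyr::select(res, "unit_id", "patient_id", "tf_name", "pwm_id",
                "ddba_raw", "ddba_norm", "p_direct")
}
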