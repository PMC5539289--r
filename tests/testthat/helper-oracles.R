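# Independent brute-force oracles used to validate the fast paths, plus
# tiny fixture builders. Everything here is deliberately naive and
# string-based so it shares no code with the implementation under test.

RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(seq) {
  paste(rev(unname(RC_MAP[strsplit(seq, "")[[1]]])), collapse = "")
}

# dbA by direct enumeration of every window on both strands.
oracle_dba <- function(seq, probs, mu, beta = 1, both_strands = TRUE) {
  L <- nrow(probs)
  emax <- log(apply(probs, 1, max))
  window_energy <- function(win) {
    chars <- strsplit(win, "")[[1]]
    if (any(!chars %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(emax - log(probs[cbind(seq_len(L),
                               match(chars, c("A", "C", "G", "T")))]))
  }
  strands <- if (both_strands) c(seq, oracle_revcomp(seq)) else seq
  total <- 0
  for (s in strands) {
    for (w in seq_len(nchar(s) - L + 1)) {
      e <- window_energy(substring(s, w, w + L - 1))
      if (!is.na(e)) total <- total + 1 / (1 + exp(beta * (e - mu)))
    }
  }
  log(total)
}

oracle_delta_dba <- function(ref, alt, probs, mu_grid, beta = 1) {
  mean(vapply(mu_grid, function(m) {
    oracle_dba(alt, probs, m, beta) - oracle_dba(ref, probs, m, beta)
  }, numeric(1)))
}

# Transitive closure of the pairwise "closer than max_gap" relation.
oracle_cluster <- function(pos, max_gap) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(pos[i] - pos[j]) < max_gap && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # Canonical form: sorted list of sorted member position sets.
  unname(lapply(split(pos, grp), sort))[order(vapply(split(pos, grp), min,
                                                     numeric(1)))]
}

# Exact two-sided rank-sum p by enumerating all rank assignments.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  u_obs <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exhaustive two-sided binomial p (minimum-likelihood rule).
oracle_binom <- function(k, n, p0) {
  probs <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                  numeric(1))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# KS statistic as the sup of |ECDF1 - ECDF2| over all sample points.
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

# A tiny deterministic genome with known content.
make_test_genome <- function(seqs = c(chr1 = paste(rep("ACGT", 250),
                                                   collapse = ""))) {
  Biostrings::DNAStringSet(seqs)
}

# A maximally informative test PWM with consensus ACGT.
make_test_pwm <- function(peak = 0.85, id = "TEST.1", tf = "TESTTF") {
  cons <- c("A", "C", "G", "T")
  probs <- matrix((1 - peak) / 3, 4, 4, dimnames = list(NULL, cons))
  for (i in 1:4) probs[i, cons[i]] <- peak
  pwm(tf, id, probs)
}

write_test_vcf <- function(path, chrom, pos, ref, alt,
                           extra_lines = character()) {
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", chrom[1], ",length=100000>"),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos, ref, alt)
  writeLines(c(header, body, extra_lines), path)
  path
}

# Exact Mann-Whitney U null pmf by lattice-path counting (independent of
# stats::pwilcox): f(i, j, u) = ways to interleave i "x" and j "y"
# observations with U = u.
oracle_u_pmf <- function(n1, n2) {
  umax <- n1 * n2
  zero <- rep(0, umax + 1)
  N <- lapply(0:n1, function(i) lapply(0:n2, function(j) NULL))
  base <- c(1, rep(0, umax))
  for (j in 0:n2) N[[1]][[j + 1]] <- base
  for (i in seq_len(n1)) {
    N[[i + 1]][[1]] <- base
    for (j in seq_len(n2)) {
      a <- N[[i]][[j + 1]]  # append an x after j ys: U gains j
      shifted <- c(rep(0, j), a[seq_len(umax + 1 - j)])
      N[[i + 1]][[j + 1]] <- shifted + N[[i + 1]][[j]]  # or append a y
    }
  }
  N[[n1 + 1]][[n2 + 1]] / choose(n1 + n2, n1)
}

oracle_u_two_sided_p <- function(u, n1, n2) {
  pmf <- oracle_u_pmf(n1, n2)
  mu <- n1 * n2 / 2
  sum(pmf[abs(seq_along(pmf) - 1 - mu) >= abs(u - mu) - 1e-9])
}

# A featureless genome + evenly spaced TSS annotation, for background
# universe tests.
make_small_universe <- function(n_genes = 30, chrom_length = 60000,
                                seed = 1) {
  withr::with_seed(seed, {
    genome <- Biostrings::DNAStringSet(setNames(
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = ""), "chrU"))
    tss <- tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      gene_name = sprintf("g%02d", seq_len(n_genes)),
      chrom = "chrU",
      tss = as.integer(seq_len(n_genes) * (chrom_length %/% (n_genes + 1))),
      strand = "+"
    )
    list(genome = genome, tss = tss)
  })
}
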