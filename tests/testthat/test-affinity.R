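test_that("pwm_to_energy gives zero-energy consensus and positive mismatches", {
  row <- matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4)
  e <- pwm_to_energy(row)
  expect_equal(unname(e[1, ]), c(0, log(7), log(7), log(7)))
  # uniform row has no preference
  expect_equal(unname(pwm_to_energy(matrix(0.25, 1, 4))[1, ]), rep(0, 4))
  # row minima are always zero
  p <- make_test_pwm()$probs[[1]]
  e <- pwm_to_energy(p)
  expect_equal(unname(apply(e, 1, min)), rep(0, 4))
  expect_true(all(e >= 0) && all(is.finite(e)))
  expect_error(pwm_to_energy(matrix(c(0, 0.5, 0.25, 0.25), 1, 4)),
               "pseudocount")
})

test_that("site occupancy hits its analytic values and monotonicities", {
  en <- pwm_to_energy(make_test_pwm()$probs[[1]])
  # E(consensus) = 0; at mu = 0 occupancy is exactly 1/2
  expect_equal(site_occupancy("ACGT", en, mu = 0), 0.5)
  # consensus at mu = ln 3: 1/(1 + e^-ln3) = 3/4
  expect_equal(site_occupancy("ACGT", en, mu = log(3)), 0.75)
  # E - mu = +20 pushes occupancy below 1e-8
  expect_lt(site_occupancy("ACGT", en, mu = -20), 1e-8)
  # strictly decreasing in E at fixed mu, strictly increasing in mu
  occ_cons <- site_occupancy("ACGT", en, mu = 1)
  occ_mis <- site_occupancy("TCGT", en, mu = 1)
  expect_lt(occ_mis, occ_cons)
  expect_lt(site_occupancy("ACGT", en, mu = 0.5), occ_cons)
  expect_true(occ_cons > 0 && occ_cons < 1)
})

test_that("dba matches the brute-force enumeration oracle", {
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(4:6, 1)
    probs <- matrix(stats::rgamma(4 * L, 1) + 0.05, ncol = 4)
    probs <- probs / rowSums(probs)
    en <- pwm_to_energy(probs)
    seq <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1),
                        replace = TRUE), collapse = "")
    for (mu in c(-2, 0, 3)) {
      expect_equal(dba(seq, en, mu), oracle_dba(seq, probs, mu),
                   tolerance = 1e-9)
    }
  }
})

test_that("single consensus window at mu = 0 scores ln(0.5 + rc term)", {
  probs <- make_test_pwm()$probs[[1]]
  en <- pwm_to_energy(probs)
  got <- dba("ACGT", en, mu = 0)
  occ_fwd <- 0.5
  e_rc <- sum(log(apply(probs, 1, max)) -
              log(probs[cbind(1:4, match(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))]))
  # reverse complement of ACGT is ACGT (palindrome): both strands identical
  expect_equal(got, log(occ_fwd + occ_fwd))
})

test_that("embedded consensus beats a scrambled embedding", {
  set.seed(7)
  en <- pwm_to_energy(make_test_pwm()$probs[[1]])
  flank <- paste(sample(c("A", "C"), 57, replace = TRUE), collapse = "")
  with_motif <- paste0(substr(flank, 1, 28), "ACGT", substr(flank, 29, 57))
  scrambled <- paste0(substr(flank, 1, 28), "AAGC", substr(flank, 29, 57))
  expect_gt(dba(with_motif, en, mu = 0), dba(scrambled, en, mu = 0))
})

test_that("dba is invariant under reverse complement and errors on short input", {
  set.seed(11)
  probs <- matrix(stats::rgamma(4 * 5, 1) + 0.05, ncol = 4)
  probs <- probs / rowSums(probs)
  en <- pwm_to_energy(probs)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    expect_equal(dba(s, en, mu = 1), dba(revcomp(s), en, mu = 1),
                 tolerance = 1e-12)
  }
  expect_error(dba("ACG", en, mu = 0, tf = "SHORTY"), "SHORTY")
})

test_that("delta_dba is antisymmetric, zero on identity, negative on disruption", {
  set.seed(13)
  en <- pwm_to_energy(make_test_pwm()$probs[[1]])
  params <- affinity_params()
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    a <- paste(sample(bases, 20, replace = TRUE), collapse = "")
    b <- paste(sample(bases, 20, replace = TRUE), collapse = "")
    expect_identical(delta_dba(a, a, en, params), 0)
    expect_equal(delta_dba(a, b, en, params), -delta_dba(b, a, en, params),
                 tolerance = 1e-12)
  }
  # destroying the consensus base at an informative position
  ref <- "TTTTTACGTTTTTT"
  alt <- sub("ACGT", "TCGT", ref)
  expect_lt(delta_dba(ref, alt, en, params), 0)
  # cross-check against the enumeration oracle
  expect_equal(delta_dba(ref, alt, en, params),
               oracle_delta_dba(ref, alt, make_test_pwm()$probs[[1]],
                                params$mu_grid),
               tolerance = 1e-9)
  expect_error(delta_dba("ACGT", "ACGTA", en), "length")
})

test_that("windows containing N are skipped, matching the oracle", {
  probs <- make_test_pwm()$probs[[1]]
  en <- pwm_to_energy(probs)
  s <- "ACGTNACGTACGT"
  expect_equal(dba(s, en, mu = 0), oracle_dba(s, probs, 0), tolerance = 1e-9)
})

test_that("normalization z-scores per TF with population sd", {
  res <- tibble::tibble(pwm_id = c("m1", "m1"), ddba_raw = c(1, 3))
  out <- normalize_deltas(res)
  expect_equal(out$ddba_norm, c(-1, 1))
  # all-equal raw values give zeros
  res <- tibble::tibble(pwm_id = "m1", ddba_raw = rep(2, 5))
  expect_equal(normalize_deltas(res)$ddba_norm, rep(0, 5))
  # output mean 0 / sd 1 whenever there is spread
  set.seed(3)
  res <- tibble::tibble(pwm_id = rep(c("a", "b"), each = 10),
                        ddba_raw = rnorm(20))
  out <- dplyr::group_by(normalize_deltas(res), pwm_id)
  sds <- dplyr::summarise(out, m = mean(ddba_norm),
                          s = sqrt(mean(ddba_norm^2)))
  expect_equal(sds$m, c(0, 0), tolerance = 1e-12)
  expect_equal(sds$s, c(1, 1), tolerance = 1e-12)
  # single unit -> zero with warning
  expect_warning(out <- normalize_deltas(
    tibble::tibble(pwm_id = "m1", ddba_raw = 5)), "single")
  expect_equal(out$ddba_norm, 0)
})

test_that("dinucleotide shuffles preserve composition and transitions", {
  dinuc_counts <- function(s) {
    table(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
  }
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                      replace = TRUE), collapse = "")
    sh <- dinucleotide_shuffle(s, n = 3)
    for (x in sh) {
      expect_equal(nchar(x), nchar(s))
      expect_equal(sort(dinuc_counts(x)), sort(dinuc_counts(s)))
      expect_equal(substring(x, 1, 1), substring(s, 1, 1))
    }
  }
  # seeded determinism
  expect_identical(dinucleotide_shuffle("ACGTACGGTT", n = 5, seed = 9),
                   dinucleotide_shuffle("ACGTACGGTT", n = 5, seed = 9))
})

test_that("direct-binding p-value separates planted sites from the null", {
  en <- pwm_to_energy(make_test_pwm(peak = 0.9)$probs[[1]])
  params <- affinity_params()
  set.seed(21)
  # sequence with 3 exact consensus occurrences scores p <= 0.05
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  seq3 <- paste0(flank(10), "ACGT", flank(10), "ACGT", flank(10), "ACGT",
                 flank(10))
  p <- direct_binding_pvalue(seq3, en, params, n_background = 200,
                             seed = 1, early_stop = FALSE)
  expect_lte(p, 0.05)
  # a shuffle-null sequence is uninformative: median p around 0.5
  ps <- vapply(1:20, function(i) {
    s0 <- dinucleotide_shuffle(seq3, seed = 1000 + i)
    direct_binding_pvalue(s0, en, params, n_background = 49,
                          seed = 2000 + i, early_stop = TRUE)
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})

test_that("early stopping never changes the filtering decision", {
  en <- pwm_to_energy(make_test_pwm()$probs[[1]])
  params <- affinity_params()
  set.seed(33)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
             collapse = "")
  p_full <- direct_binding_pvalue(s, en, params, n_background = 100,
                                  seed = 5, early_stop = FALSE)
  p_stop <- direct_binding_pvalue(s, en, params, n_background = 100,
                                  seed = 5, early_stop = TRUE)
  expect_true(p_full > 0 && p_full <= 1 && p_stop > 0 && p_stop <= 1)
  # early stop may only fire when the p-value already exceeds the cutoff
  if (p_stop != p_full) expect_gt(p_stop, 0.1)
  if (p_full < 0.1) expect_equal(p_stop, p_full)
})

test_that("rank_tfs applies the direct-binding, magnitude and top-k filters", {
  # all p_direct at 0.5: everything filtered
  res <- tibble::tibble(pwm_id = paste0("m", 1:10), tf_name = "t",
                        ddba_norm = rnorm(10), p_direct = 0.5)
  expect_equal(nrow(rank_tfs(res)), 0L)
  # one TF surviving
  res$p_direct[1] <- 0.01
  res$ddba_norm[1] <- 2
  out <- rank_tfs(res)
  expect_equal(out$pwm_id, "m1")
  expect_equal(out$direction, "positive")
  # 100 TFs passing p_direct with distinct magnitudes -> exactly 20 survive
  res <- tibble::tibble(pwm_id = sprintf("m%03d", 1:100), tf_name = "t",
                        ddba_norm = seq(0.01, 1, length.out = 100) *
                          rep(c(1, -1), 50),
                        p_direct = 0.01)
  out <- rank_tfs(res, k = 15)
  expect_equal(nrow(out), 20L)
  expect_true(all(abs(out$ddba_norm) >= sort(abs(res$ddba_norm))[81] - 1e-12))
  expect_true(all(out$rank <= 15))
  # ranks ordered by decreasing magnitude within direction
  pos <- dplyr::filter(out, direction == "positive")
  expect_true(all(diff(abs(pos$ddba_norm)) <= 0))
})

test_that("score_units produces normalized per-(unit, PWM) records", {
  genome <- make_test_genome()
  pwms <- dplyr::bind_rows(make_test_pwm(id = "A.1", tf = "TFA"),
                           make_test_pwm(peak = 0.7, id = "B.1",
                                         tf = "TFB"))
  units <- tibble::tibble(
    unit_id = c("u1", "u2"), patient_id = c("P1", "P2"),
    ref_seq = c("ACGTACGTACGTACGT", "TTTTACGTACGTTTTT"),
    alt_seq = c("ACGTACTTACGTACGT", "TTTTACGAACGTTTTT")
  )
  scored <- score_units(units, pwms, n_shuffles = 25, seed = 2)
  expect_equal(nrow(scored), 4L)
  expect_true(all(scored$p_direct > 0 & scored$p_direct <= 1))
  expect_equal(sort(unique(scored$pwm_id)), c("A.1", "B.1"))
  # deterministic given the seed
  again <- score_units(units, pwms, n_shuffles = 25, seed = 2)
  expect_identical(scored, again)
})
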