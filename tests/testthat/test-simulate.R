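test_that("scenario bundle is internally consistent and reader-compatible", {
  sc <- synthetic_scenario(n_patients = 6, n_genes = 12, n_drivers = 2,
                           chrom_length = 48000, n_decoy_pwms = 8,
                           seed = 4)
  d <- withr::local_tempdir()
  b <- generate_scenario(sc, dir = d)
  # truth lists exactly the planted blocks
  expect_equal(nrow(b$truth), 2L)
  expect_true(all(b$truth$expected_sign == "negative"))
  # SNVs are reference-consistent with the genome
  expect_silent(check_snv_reference(b$snvs, b$genome))
  # planted SNVs fall inside the planted blocks and disrupt the consensus
  cons <- strsplit("TGACTCAG", "")[[1]]
  for (i in seq_len(nrow(b$truth))) {
    inside <- dplyr::filter(b$snvs, pos >= b$truth$block_start[i],
                            pos <= b$truth$block_end[i])
    expect_gt(nrow(inside), 0)
    expect_true(all(inside$ref_base %in% cons))
  }
  # the three planted consensus occurrences really are in the genome
  occ <- b$truth$occ_starts[[1]]
  expect_equal(length(occ), 3L)
  for (s in occ) {
    expect_equal(get_sequence(b$genome, "chrS", s, s + 7L), "TGACTCAG")
  }
  # on-disk round trip through the package readers
  expect_equal(nrow(read_tss(b$paths$tss)), 12L)
  pw <- read_pwms(b$paths$pwms)
  expect_equal(nrow(pw), 9L)
  expect_equal(pw$probs[[1]], b$pwms$probs[[1]], tolerance = 1e-5)
  snvs_rt <- read_snvs(b$paths$vcfs)
  expect_equal(nrow(snvs_rt), nrow(b$snvs))
  expect_equal(snvs_rt$pos, b$snvs$pos)
  ex <- read_expression(b$paths$expression, b$paths$groups)
  expect_equal(dim(ex$values), dim(b$expr$values))
  g <- read_genome(b$paths$genome)
  expect_equal(as.character(g[[1]]), as.character(b$genome[[1]]))
  # deterministic regeneration
  b2 <- generate_scenario(sc)
  expect_identical(b2$snvs, b$snvs)
  expect_identical(b2$truth$block_start, b$truth$block_start)
})

test_that("decoy motifs are screened against the planted consensus", {
  b <- generate_scenario(synthetic_scenario(n_patients = 4, n_genes = 10,
                                            chrom_length = 40000,
                                            n_decoy_pwms = 20, seed = 8))
  cons <- strsplit("TGACTCAG", "")[[1]]
  for (i in which(b$pwms$pwm_id != "PLANTED.1")) {
    decoy_cons <- c("A", "C", "G", "T")[apply(b$pwms$probs[[i]], 1,
                                              which.max)]
    expect_lte(regblock:::consensus_identity(cons, decoy_cons), 4L)
  }
})

test_that("no planted SNVs means no recurrent driver blocks beyond chance", {
  b <- generate_scenario(synthetic_scenario(n_patients = 6, n_genes = 12,
                                            chrom_length = 48000,
                                            snvs_per_patient_in_block = 0,
                                            block_prob = 0, seed = 10))
  ms <- mussd(b$snvs, b$tss, expr = NULL)
  in_truth <- vapply(seq_len(nrow(ms$blocks)), function(i) {
    any(ms$blocks$start[i] <= b$truth$block_end &
        ms$blocks$end[i] >= b$truth$block_start)
  }, logical(1))
  expect_equal(sum(in_truth), 0L)
})

test_that("null expression gives ~alpha-level KS gate keep rate", {
  # driver shift of 1 = no differential expression anywhere
  keep <- vapply(1:12, function(s) {
    b <- generate_scenario(synthetic_scenario(n_patients = 12, n_genes = 40,
                                              chrom_length = 160000,
                                              expression_effect = 1,
                                              background_snv_rate = 0,
                                              block_prob = 0, seed = s))
    pv <- vapply(b$tss$gene_id, function(g) {
      ks_test_2sample(regblock:::expr_values(b$expr, g, "tumor"),
                      regblock:::expr_values(b$expr, g, "normal"))$p_value
    }, numeric(1))
    mean(pv < 0.05)
  }, numeric(1))
  # small-sample KS (12 vs 4) is discrete; the keep rate should be near
  # the nominal level and certainly bounded well below 2 alpha
  expect_lt(mean(keep), 0.1)
})

test_that("substitution spectrum collapses purine changes correctly", {
  expect_equal(
    dplyr::filter(nucleotide_change_stats(
      snv_table("1", 1, "G", "A", "P")), count > 0)$category, "C>T")
  two <- nucleotide_change_stats(snv_table("1", c(1, 5), c("C", "G"),
                                           c("T", "A"), "P"))
  expect_equal(two$fraction[two$category == "C>T"], 1)
  # empty input: all-zero counts over the six categories
  empty <- nucleotide_change_stats(b <- snv_table(character(), integer(),
                                                  character(), character(),
                                                  character()))
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 6L)
  # large-sample fractions converge to the generation probabilities
  set.seed(19)
  ref <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1), "")
  st <- nucleotide_change_stats(snv_table("1", seq_along(ref), ref, alt,
                                          "P"))
  expect_equal(st$fraction, rep(1 / 6, 6), tolerance = 0.12)
})
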