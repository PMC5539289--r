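test_that("clustering follows the strict gap rule", {
  snvs <- snv_table("1", c(100L, 120L, 160L), "C", "T",
                    c("P1", "P2", "P3"))
  blocks <- cluster_snvs(snvs, max_gap = 30)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$start, c(100L, 160L))
  expect_equal(blocks$end, c(120L, 160L))
  # boundary semantics: 29-bp gap merges, 30-bp gap splits
  b29 <- cluster_snvs(snv_table("1", c(100L, 129L), "C", "T",
                                c("P1", "P2")), 30)
  expect_equal(nrow(b29), 1L)
  b30 <- cluster_snvs(snv_table("1", c(100L, 130L), "C", "T",
                                c("P1", "P2")), 30)
  expect_equal(nrow(b30), 2L)
  # singleton
  expect_equal(nrow(cluster_snvs(snv_table("1", 100L, "C", "T", "P1"), 30)),
               1L)
})

test_that("clustering matches the transitive-closure oracle on random instances", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    gap <- sample(c(5L, 30L, 50L), 1)
    pos <- sort(sample.int(500, n))
    snvs <- snv_table("1", pos, "C", "T",
                      sample(paste0("P", 1:4), n, replace = TRUE))
    got <- cluster_snvs(snvs, max_gap = gap)
    got_sets <- lapply(got$snvs, function(s) sort(s$pos))
    expect_identical(got_sets, oracle_cluster(pos, gap))
  }
})

test_that("block set is invariant to input order and byte-deterministic", {
  set.seed(23)
  pos <- sample.int(2000, 40)
  snvs <- snv_table("1", pos, "C", "T",
                    sample(paste0("P", 1:5), 40, replace = TRUE))
  a <- cluster_snvs(snvs, 30)
  b <- cluster_snvs(snvs[sample.int(nrow(snvs)), ], 30)
  expect_identical(a, b)
  expect_identical(a, cluster_snvs(snvs, 30))
})

test_that("recurrence filter needs two SNVs from two patients", {
  one_patient <- cluster_snvs(snv_table("1", c(10L, 20L, 25L), "C", "T",
                                        "P1"), 30)
  expect_equal(nrow(filter_recurrent(one_patient)), 0L)
  two <- cluster_snvs(snv_table("1", c(10L, 20L), "C", "T",
                                c("P1", "P2")), 30)
  expect_equal(nrow(filter_recurrent(two)), 1L)
  empty <- cluster_snvs(snv_table(character(), integer(), character(),
                                  character(), character()), 30)
  expect_equal(nrow(filter_recurrent(empty)), 0L)
})

test_that("blocks are assigned to promoters, with duplication on overlap", {
  tss <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        gene_name = c("g1", "g2", "g3"),
                        chrom = "1", tss = c(5000L, 5500L, 50000L),
                        strand = "+")
  blocks <- cluster_snvs(snv_table("1", c(4990L, 5010L), "C", "T",
                                   c("P1", "P2")), 30)
  hit <- assign_to_promoters(blocks, tss, 1000)
  expect_equal(sort(hit$gene_id), c("g1", "g2"))  # overlapping promoters
  # block far downstream of the only promoter is dropped
  far <- cluster_snvs(snv_table("1", c(7000L, 7010L), "C", "T",
                                c("P1", "P2")), 30)
  expect_equal(nrow(assign_to_promoters(far,
                                        tss[tss$gene_id == "g1", ], 1000)),
               0L)
})

test_that("expression gate keeps only differentially expressed targets", {
  vals <- rbind(
    g1 = c(10, 11, 12, 13, 0, 0.1, 0.2, 0.3),  # disjoint: D = 1
    g2 = c(1, 2, 3, 4, 1, 2, 3, 4)             # identical: D = 0
  )
  colnames(vals) <- c(paste0("t", 1:4), paste0("n", 1:4))
  expr <- expression_table(vals, setNames(rep(c("tumor", "normal"),
                                              each = 4), colnames(vals)))
  blocks <- tibble::tibble(block_id = c("b1", "b2"), gene_id = c("g1", "g2"))
  gated <- ks_gate(blocks, expr, alpha = 0.05)
  expect_true(gated$keep[1])
  expect_false(gated$keep[2])
  expect_equal(gated$de_pvalue[2], 1)
  expect_error(ks_gate(tibble::tibble(block_id = "b", gene_id = "nope"),
                       expr), "absent")
  small <- expression_table(vals[, c(1, 5), drop = FALSE],
                            c(t1 = "tumor", n1 = "normal"))
  expect_error(ks_gate(blocks, small), ">= 2")
})

test_that("patient block sequences substitute exactly each patient's SNVs", {
  genome <- make_test_genome()  # ACGT repeated; pos 41 = A, pos 44 = T
  snvs <- snv_table("chr1", c(41L, 44L, 48L), c("A", "T", "T"),
                    c("G", "A", "C"), c("P1", "P1", "P2"))
  blocks <- filter_recurrent(cluster_snvs(snvs, 30))
  seqs <- build_patient_sequences(blocks, genome, flank = 5)
  expect_equal(nrow(seqs), 2L)
  p1 <- seqs[seqs$patient_id == "P1", ]
  p2 <- seqs[seqs$patient_id == "P2", ]
  expect_equal(nchar(p1$ref_seq), (48L + 5L) - (41L - 5L) + 1L)
  diff_at <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(diff_at(p1$ref_seq, p1$alt_seq), c(6L, 9L))
  expect_equal(diff_at(p2$ref_seq, p2$alt_seq), 13L)
  # genome mismatch is an error naming the position
  bad <- blocks
  bad$snvs[[1]]$ref_base[1] <- "C"
  expect_error(build_patient_sequences(bad, genome, flank = 5), "41")
})

test_that("SNV windows are centered, clipped and substituted at the center", {
  genome <- make_test_genome()
  snvs <- snv_table("chr1", 100L, "T", "A", "P1")
  w <- snv_window_sequences(snvs, genome, half = 30)
  expect_equal(nchar(w$ref_seq), 61L)
  expect_equal(w$center_offset, 31L)
  expect_equal(substring(w$alt_seq, 31, 31), "A")
  expect_equal(substring(w$ref_seq, 31, 31), "T")
  # half = 0 degenerates to the single base pair
  w0 <- snv_window_sequences(snvs, genome, half = 0)
  expect_equal(w0$ref_seq, "T")
  expect_equal(w0$alt_seq, "A")
  # clipping near the chromosome start keeps the center consistent
  near <- snv_table("chr1", 10L, "C", "G", "P1")
  expect_warning(wc <- snv_window_sequences(near, genome, half = 30),
                 "clipped")
  expect_equal(nchar(wc$ref_seq), 40L)
  expect_equal(wc$center_offset, 10L)
})

test_that("mussd chains the stages in order and summarizes", {
  set.seed(31)
  b <- generate_scenario(synthetic_scenario(n_patients = 6, n_genes = 10,
                                            n_drivers = 1,
                                            chrom_length = 40000,
                                            seed = 5))
  ms <- mussd(b$snvs, b$tss, expr = b$expr)
  expect_s3_class(ms, "mussd_result")
  expect_true(all(ms$blocks$n_patients >= 2))
  expect_true(all(ms$blocks$de_pvalue < 0.05))
  td <- tidy(ms)
  expect_false("snvs" %in% names(td))
  g <- glance(ms)
  expect_equal(g$n_blocks_kept, nrow(ms$blocks))
  expect_equal(g$alpha, 0.05)
})
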