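test_that("simulated plastome has the planted quadripartite layout", {
  sim <- small_sim(seed = 1)
  expect_equal(nchar(sim$sequence), 4600)
  p <- sim$partition
  expect_equal(p$label, c("LSC", "IR1", "SSC", "IR2"))
  expect_equal(p$start, c(1L, 3001L, 3401L, 4201L))
  expect_equal(p$end, c(3000L, 3400L, 4200L, 4600L))
  ir1 <- substr(sim$sequence, 3001, 3400)
  ir2 <- substr(sim$sequence, 4201, 4600)
  expect_identical(ir2, revcomp(ir1))
})

test_that("plastome simulation is deterministic and GC lands on target", {
  expect_identical(small_sim(seed = 7)$sequence, small_sim(seed = 7)$sequence)
  expect_false(identical(small_sim(seed = 7)$sequence,
                         small_sim(seed = 8)$sequence))
  # binomial concentration: at 50 kb sd(GC) ~ 0.002, so +/-0.02 is ~10 sd
  big <- simulate_plastome(plastome_spec(50000, 5000, 1000,
                                         gc_content = 0.3, seed = 3))
  gc <- plastidkit:::gc_fraction(big$sequence)
  expect_lt(abs(gc - 0.3), 0.02)
})

test_that("plastome spec rejects invalid parameters", {
  expect_error(plastome_spec(800, 3000, 400), class = "plastidkit_param_error")
  expect_error(plastome_spec(3000, 800, 0), class = "plastidkit_param_error")
  expect_error(plastome_spec(3000, 800, 400, gc_content = 1.2),
               class = "plastidkit_param_error")
})

test_that("isoform construction flips exactly the SSC and is an involution", {
  sim <- small_sim(seed = 2)
  iso <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  expect_identical(build_isoform(sim$sequence, sim$partition, "canonical"),
                   sim$sequence)
  expect_identical(build_isoform(iso, sim$partition, "noncanonical"),
                   sim$sequence)
  expect_equal(nchar(iso), nchar(sim$sequence))
  diffs <- which(strsplit(sim$sequence, "")[[1]] != strsplit(iso, "")[[1]])
  expect_true(all(diffs >= 3401 & diffs <= 4200))
  expect_identical(substr(iso, 3401, 4200),
                   revcomp(substr(sim$sequence, 3401, 4200)))
})

test_that("read simulation respects mixture, truth and determinism", {
  sim <- small_sim(seed = 3)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  p0 <- read_sim_params(n_reads = 40, length_mean = 1000, length_sd = 300,
                        mixture_ratio = 0, seed = 5)
  rs0 <- simulate_reads(isoA, isoB, p0)
  expect_true(all(rs0$truth$isoform == "canonical"))

  # error-free reads are exact substrings of the doubled source on the
  # recorded strand
  p1 <- read_sim_params(n_reads = 30, length_mean = 1000, length_sd = 300,
                        mixture_ratio = 0.5, seed = 6)
  rs1 <- simulate_reads(isoA, isoB, p1)
  doubled <- list(canonical = paste0(isoA, isoA),
                  noncanonical = paste0(isoB, isoB))
  for (i in seq_len(nrow(rs1$reads))) {
    tr <- rs1$truth[i, ]
    query <- if (tr$strand == "+") rs1$reads$sequence[i] else
      revcomp(rs1$reads$sequence[i])
    expect_identical(substr(doubled[[tr$isoform]], tr$start,
                            tr$start + tr$length - 1), query)
  }
  expect_equal(nrow(rs1$truth), 30)
  expect_false(anyDuplicated(rs1$truth$read_id) > 0)

  rs1b <- simulate_reads(isoA, isoB, p1)
  expect_identical(rs1$reads, rs1b$reads)

  empty <- simulate_reads(isoA, isoB, read_sim_params(n_reads = 0, seed = 1))
  expect_equal(nrow(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("read error process perturbs at roughly the requested rates", {
  sim <- small_sim(seed = 4)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  rs <- simulate_reads(isoA, isoA,
                       read_sim_params(n_reads = 40, length_mean = 2000,
                                       length_sd = 200, mismatch_rate = 0.05,
                                       ins_rate = 0.02, del_rate = 0.02,
                                       mixture_ratio = 0, seed = 9))
  # length changes reflect indel rates: E[len_out/len_in] = 1 + ins - del
  ratio <- sum(nchar(rs$reads$sequence)) / sum(rs$truth$length)
  expect_lt(abs(ratio - 1), 0.01)
})

test_that("population evolution on a zero-length tree is the identity", {
  anc <- random_ancestor(500, seed = 11)
  tr <- balanced_tree_12(0)
  pop <- simulate_population(anc, tr, seed = 1)
  expect_true(all(pop$leaves == anc))
  expect_equal(nrow(pop$variant_truth), 0)
  expect_equal(nchar(pop$alignment[[1]]), 500)
})

test_that("low-rate substitutions: SNV columns equal distinct mutated sites", {
  anc <- random_ancestor(1000, seed = 12)
  tr <- ape::read.tree(text = "((A:0.001,B:0.001):0.001,(C:0.001,D:0.001):0.001);")
  pop <- simulate_population(anc, tr, seed = 13)
  # site-collision accounting: with no repeated hits on a site, planted
  # sites and variable columns must agree exactly
  expect_equal(anyDuplicated(pop$events$key), 0)
  snv_cols <- classify_columns(pop$alignment)$variants$column
  truth_cols <- match(pop$variant_truth$key, pop$column_keys)
  expect_setequal(snv_cols, truth_cols)
  expect_gt(length(snv_cols), 0)
})

test_that("population simulation is seed-reproducible and validates input", {
  anc <- random_ancestor(300, seed = 14)
  tr <- balanced_tree_12(0.01)
  p1 <- simulate_population(anc, tr, indel_rate = 0.1, seed = 5)
  p2 <- simulate_population(anc, tr, indel_rate = 0.1, seed = 5)
  expect_identical(unclass(p1$alignment), unclass(p2$alignment))
  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(simulate_population(anc, bad, seed = 1),
               class = "plastidkit_param_error")
})

test_that("indel events in the true alignment are recoverable", {
  anc <- random_ancestor(800, seed = 15)
  tr <- balanced_tree_12(0.01)
  pop <- simulate_population(anc, tr, subst_rate_scale = 0.2,
                             indel_rate = 0.5, seed = 16)
  scan <- classify_columns(pop$alignment)
  expect_gt(nrow(scan$indels), 0)
  # exact coordinate accounting: alignment width is the ancestor length
  # plus every inserted base (deletions keep their columns as gaps)
  n_ins <- sum(pop$events$length[pop$events$type == "ins"])
  expect_equal(nchar(pop$alignment[[1]]), 800 + n_ins)
  # ancestral columns carry integer keys, inserted columns fractional ones
  expect_equal(sum(pop$column_keys == floor(pop$column_keys)), 800)
})

test_that("FASTQ round trip preserves reads", {
  sim <- small_sim(seed = 5)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  rs <- simulate_reads(isoA, isoA,
                       read_sim_params(n_reads = 5, length_mean = 500,
                                       length_sd = 100, mixture_ratio = 0,
                                       seed = 2))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rs$reads, fq)
  back <- read_reads_fastq(fq)
  expect_equal(back$read_id, rs$reads$read_id)
  expect_equal(back$sequence, rs$reads$sequence)
})
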