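test_that("segment mapping reports single-region and multi-region hits", {
  sim <- small_sim(seed = 1)
  idx <- segment_index(sim$sequence, sim$partition)

  # wholly inside LSC, forward strand
  r1 <- substr(sim$sequence, 500, 1500)
  h1 <- map_read_segments(r1, idx)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$label, "LSC")
  expect_equal(h1$strand, "+")
  expect_equal(h1$ref_start, 500L)
  expect_equal(h1$ref_end, 1500L)
  expect_equal(h1$identity, 1)

  # crossing LSC -> IR1 -> SSC on the canonical molecule
  r2 <- substr(sim$sequence, 2500, 3900)
  h2 <- map_read_segments(r2, idx)
  expect_equal(h2$label, c("LSC", "IR1", "SSC"))
  expect_true(all(h2$strand == "+"))
  expect_true(all(diff(h2$read_start) > 0))

  # empty / too-short read
  expect_equal(nrow(map_read_segments("", idx)), 0)
  expect_equal(nrow(map_read_segments("ACGTACGT", idx)), 0)
})

test_that("span classification follows the anchor and orientation rules", {
  part <- layout_partition(3000L, 400L, 800L)
  mk <- function(label, rs, re, fs, fe, strand) {
    tibble::tibble(label = label, read_start = rs, read_end = re,
                   ref_start = fs, ref_end = fe, strand = strand,
                   identity = 1)
  }
  both_plus <- dplyr::bind_rows(
    mk("LSC", 1, 600, 2401, 3000, "+"),
    mk("IR1", 601, 1000, 3001, 3400, "+"),
    mk("SSC", 1001, 1600, 3401, 4000, "+")
  )
  expect_equal(classify_spanning_read(both_plus, part, anchor_min = 500)$call,
               "canonical")

  flipped <- both_plus
  flipped$strand[3] <- "-"
  expect_equal(classify_spanning_read(flipped, part, anchor_min = 500)$call,
               "noncanonical")

  thin <- dplyr::bind_rows(
    mk("LSC", 1, 600, 2401, 3000, "+"),
    mk("IR1", 601, 1000, 3001, 3400, "+"),
    mk("SSC", 1001, 1100, 3401, 3500, "+")
  )
  expect_equal(classify_spanning_read(thin, part, anchor_min = 500)$call,
               "unclassified")

  # both-minus anchors are still collinear, hence canonical
  minus <- dplyr::bind_rows(
    mk("SSC", 1, 600, 3401, 4000, "-"),
    mk("IR1", 601, 1000, 3001, 3400, "-"),
    mk("LSC", 1001, 1600, 2401, 3000, "-")
  )
  expect_equal(classify_spanning_read(minus, part, anchor_min = 500)$call,
               "canonical")

  # no IR coverage: not a spanning read at all
  sc_only <- mk("LSC", 1, 900, 1001, 1900, "+")
  expect_true(is.na(classify_spanning_read(sc_only, part, 500)$call))
})

test_that("error-free phasing classifies every truth-spanning read correctly", {
  sim <- simulate_plastome(plastome_spec(5000, 3000, 1000,
                                         gc_content = 0.38, seed = 7))
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  rs <- simulate_reads(isoA, isoB,
                       read_sim_params(n_reads = 120, length_mean = 3500,
                                       length_sd = 800, mixture_ratio = 0.5,
                                       seed = 11))
  ph <- phase_reads(rs$reads, sim$sequence, sim$partition, anchor_min = 500)
  expect_equal(ph$n_canonical + ph$n_noncanonical + ph$n_unclassified,
               ph$n_spanning)
  j <- dplyr::left_join(rs$truth, ph$calls, by = "read_id")
  span <- spanning_truth(rs$truth, sim$partition, anchor_min = 500)
  expect_gt(sum(span), 10)
  expect_true(all(j$call[span] %in% c("canonical", "noncanonical")))
  expect_true(all(j$call[span] == j$isoform[span]))
  # no classified read contradicts its truth label even off the truth set
  cls <- j[!is.na(j$call) & j$call %in% c("canonical", "noncanonical"), ]
  expect_true(all(cls$call == cls$isoform))
})

test_that("mixture 0 yields no noncanonical calls and read sets are disjoint", {
  sim <- small_sim(seed = 3)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  rs <- simulate_reads(isoA, isoB,
                       read_sim_params(n_reads = 60, length_mean = 1800,
                                       length_sd = 300, mixture_ratio = 0,
                                       seed = 4))
  out <- withr::local_tempdir()
  ph <- phase_reads(rs$reads, sim$sequence, sim$partition, anchor_min = 300,
                    out_dir = out)
  expect_equal(ph$n_noncanonical, 0)
  ids <- lapply(c("canonical", "noncanonical", "unclassified"), function(nm) {
    f <- file.path(out, paste0(nm, ".fastq"))
    if (file.size(f) == 0) character(0) else read_reads_fastq(f)$read_id
  })
  expect_equal(length(unlist(ids)), length(unique(unlist(ids))))
})

test_that("reads shorter than the IR produce no spanning calls", {
  sim <- small_sim(seed = 5)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  rs <- simulate_reads(isoA, isoB,
                       read_sim_params(n_reads = 30, length_mean = 250,
                                       length_sd = 20, mixture_ratio = 0.5,
                                       seed = 6))
  ph <- phase_reads(rs$reads, sim$sequence, sim$partition, anchor_min = 300)
  expect_equal(ph$n_spanning, 0)
  expect_true(is.na(ph$ratio_noncanonical))
})

test_that("phasing stays accurate with a 5% total error rate", {
  sim <- simulate_plastome(plastome_spec(5000, 3000, 1000,
                                         gc_content = 0.38, seed = 7))
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  rs <- simulate_reads(isoA, isoB,
                       read_sim_params(n_reads = 60, length_mean = 3500,
                                       length_sd = 800,
                                       mismatch_rate = 0.03, ins_rate = 0.01,
                                       del_rate = 0.01, mixture_ratio = 0.5,
                                       seed = 12))
  ph <- phase_reads(rs$reads, sim$sequence, sim$partition, anchor_min = 500)
  j <- dplyr::left_join(rs$truth, ph$calls, by = "read_id")
  cls <- j[!is.na(j$call) & j$call %in% c("canonical", "noncanonical"), ]
  expect_gt(nrow(cls), 10)
  expect_gte(mean(cls$call == cls$isoform), 0.99)
})

test_that("ratio estimation matches the exact binomial oracle", {
  est <- estimate_ratio(9, 11)
  expect_equal(est$ratio_noncanonical, 0.55)
  # closed form: two-sided exact binomial at n = 20 is 1 - P(X = 10)
  expect_equal(est$p_equal, 1 - choose(20, 10) / 2^20, tolerance = 1e-12)
  expect_equal(round(est$p_equal, 4), 0.8238)

  est2 <- estimate_ratio(0, 7)
  expect_equal(est2$ratio_noncanonical, 1)
  expect_equal(est2$p_equal, 2 * (1 / 2)^7, tolerance = 1e-12)

  est3 <- estimate_ratio(5, 5)
  expect_equal(est3$ratio_noncanonical, 0.5)
  expect_equal(est3$p_equal, 1)

  expect_error(estimate_ratio(0, 0), class = "plastidkit_param_error")
})

test_that("Wilson interval matches the score-test inversion", {
  for (case in list(c(11, 20), c(3, 50), c(49, 50), c(0, 10))) {
    x <- case[1]; n <- case[2]
    got <- estimate_ratio(n - x, x)
    want <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(c(got$ci_lo, got$ci_hi), as.numeric(want), tolerance = 1e-9)
  }
})

test_that("collapsed mapping doubles relative IR depth", {
  sim <- small_sim(seed = 13)
  isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
  isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
  col <- collapse_reference(sim$sequence, sim$partition)
  rs <- simulate_reads(isoA, isoB,
                       read_sim_params(n_reads = 700, length_mean = 700,
                                       length_sd = 120, mixture_ratio = 0.5,
                                       seed = 14))
  dr <- region_depth_ratio(rs$reads, col$sequence, col$partition)
  expect_gte(min(dr$depth$mean_depth), 20)
  expect_gt(dr$ir_sc_ratio, 1.7)
  expect_lt(dr$ir_sc_ratio, 2.3)
})
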