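test_that("toy alignment yields the hand-computed SNV and indel event", {
  sc <- classify_columns(toy_alignment())
  expect_equal(sc$variants$column, 3L)
  expect_equal(unlist(sc$variants[1, c("s1", "s2", "s3")], use.names = FALSE),
               c("G", "A", "G"))
  expect_equal(nrow(sc$indels), 1)
  expect_equal(sc$indels$start, 7L)
  expect_equal(sc$indels$end, 7L)
  expect_equal(sc$indels$pattern, "110")
  expect_equal(sc$n_indel_columns, 1L)
})

test_that("invariant alignments produce no variants", {
  al <- new_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  sc <- classify_columns(al)
  expect_equal(nrow(sc$variants), 0)
  expect_equal(nrow(sc$indels), 0)
})

test_that("N is missing data: N-only variation is not an SNV", {
  al <- new_alignment(c(a = "ANGT", b = "ACGT", c = "ACGA"))
  sc <- classify_columns(al)
  expect_equal(sc$variants$column, 4L)  # column 2 varies only by N
})

test_that("column scan agrees with the brute-force oracle on random alignments", {
  set.seed(314)
  for (rep in 1:100) {
    al <- random_alignment(n_seq = sample(3:10, 1),
                           n_col = sample(20:200, 1))
    mmc <- sample(1:2, 1)
    got <- classify_columns(al, min_minor_count = mmc)
    want <- brute_force_columns(al, min_minor_count = mmc)
    expect_equal(got$variants$column, want$snv)
    expect_equal(got$n_indel_columns, length(want$indel_cols))
    expect_equal(nrow(got$indels), want$n_events)
  }
})

test_that("SNV calls are invariant under sequence reordering and renaming", {
  set.seed(99)
  al <- random_alignment(6, 120)
  perm <- sample(seq_along(al))
  al2 <- new_alignment(setNames(unclass(al)[perm],
                                paste0("x", seq_along(al))))
  expect_equal(classify_columns(al)$variants$column,
               classify_columns(al2)$variants$column)
})

test_that("planted substitutions are recovered from evolved populations", {
  anc <- random_ancestor(1500, seed = 21)
  tr <- balanced_tree_12(0.005)
  pop <- simulate_population(anc, tr, seed = 22)
  got <- classify_columns(pop$alignment)$variants$column
  planted <- match(pop$variant_truth$key, pop$column_keys)
  # every variable column is planted; planted sites may coincide/revert
  expect_true(all(got %in% planted))
  expect_gte(length(got) / length(planted), 0.95)
})

test_that("coordinate map and liftover honour reference gaps", {
  al <- toy_alignment()
  cmap <- build_coordinate_map(al, "s1")
  expect_equal(liftover(cmap, 1), 1L)
  expect_equal(liftover(cmap, 7), NA_integer_)
  expect_equal(liftover(cmap, 8), 7L)
  expect_equal(liftover(cmap, 9), 8L)
  expect_equal(liftover(cmap, liftover(cmap, 3), "ref_to_aln"), 3L)
  # round trip on every non-gap column
  non_gap <- cmap$column[!is.na(cmap$ref_pos)]
  expect_equal(liftover(cmap, liftover(cmap, non_gap), "ref_to_aln"), non_gap)
  expect_error(build_coordinate_map(al, "nope"),
               class = "plastidkit_param_error")
  expect_error(liftover(cmap, 10), class = "plastidkit_param_error")
})

test_that("liftover round trip holds on random gapped alignments", {
  set.seed(27)
  for (rep in 1:20) {
    al <- random_alignment(4, 80, gap_prob = 0.2)
    cmap <- build_coordinate_map(al, names(al)[1])
    non_gap <- cmap$column[!is.na(cmap$ref_pos)]
    if (length(non_gap) == 0) next
    expect_equal(liftover(cmap, liftover(cmap, non_gap), "ref_to_aln"),
                 non_gap)
  }
})

test_that("marker intersection follows set arithmetic", {
  snvs <- tibble::tibble(column = c(10L, 20L, 30L, 40L))
  cmap <- build_coordinate_map(
    new_alignment(c(r = strrep("A", 50), o = strrep("C", 50))), "r"
  )
  mi <- intersect_markers(snvs, cmap, c(20, 30, 50), c(30, 40))
  expect_equal(mi$shared_with_a, c(20L, 30L))
  expect_equal(mi$shared_with_b, c(30L, 40L))
  expect_equal(mi$high_confidence, 30L)
  expect_true(all(mi$high_confidence %in% mi$shared_with_a))
  expect_true(all(mi$high_confidence %in% mi$shared_with_b))

  empty <- intersect_markers(snvs, cmap, integer(0), integer(0))
  expect_equal(empty$n_shared_a, 0)
  expect_equal(empty$n_high_confidence, 0)

  all_mi <- intersect_markers(snvs, cmap, c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(all_mi$high_confidence, c(10L, 20L, 30L, 40L))
})

test_that("marker lists parse from TSV and reject malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos", "10", "25", "3"), f)
  expect_equal(read_marker_positions(f), c(10L, 25L, 3L))
  writeLines(c("10", "abc", "3"), f)
  expect_error(read_marker_positions(f), "line 2",
               class = "plastidkit_format_error")
})

test_that("alignment reader validates input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt-acgt", ">b", "ACGTTACGT"), f)
  al <- read_alignment(f)
  expect_equal(unname(unclass(al)[1]), "ACGT-ACGT")  # upper-cased
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f), class = "plastidkit_format_error")
  writeLines(character(0), f)
  expect_error(read_alignment(f), class = "plastidkit_format_error")
})

test_that("variant writer emits consistent TSV and VCF", {
  al <- toy_alignment()
  sc <- classify_columns(al)
  cmap <- build_coordinate_map(al, "s1")
  ref <- gsub("-", "", unclass(al)[["s1"]], fixed = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  rows <- write_variants(sc, cmap, ref, tsv, vcf)
  expect_equal(rows$ref_pos, 3L)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(f[2], "3")
  expect_equal(f[4], "G")
  expect_equal(f[5], "A")

  # empty variant table -> header-only VCF
  al0 <- new_alignment(c(a = "ACGT", b = "ACGT"))
  sc0 <- classify_columns(al0)
  write_variants(sc0, build_coordinate_map(al0, "a"), "ACGT", tsv, vcf)
  expect_true(all(startsWith(readLines(vcf), "#")))

  # REF mismatch triggers a consistency error
  expect_error(write_variants(sc, cmap, gsub("G", "T", ref), tsv, vcf),
               class = "plastidkit_consistency_error")
})

test_that("multi-allelic columns list alternates comma-separated", {
  al <- new_alignment(c(r = "AAG", x = "ACG", y = "ATG", z = "AGG"))
  sc <- classify_columns(al)
  cmap <- build_coordinate_map(al, "r")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(sc, cmap, "AAG", NULL, vcf)
  body <- readLines(vcf)
  body <- body[!startsWith(body, "#")]
  f <- strsplit(body, "\t")[[1]]
  expect_equal(f[4], "A")
  expect_setequal(strsplit(f[5], ",")[[1]], c("C", "T", "G"))
})
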