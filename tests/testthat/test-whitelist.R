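test_that("whitelist TSV round-trips and invariants are enforced", {
  wl <- random_whitelist(96L, 10L, min_dist = 3L, "bc1", seed = 7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_whitelist(wl, path)
  back <- load_whitelist(path, "bc1")
  expect_identical(back$sequences, wl$sequences)
  expect_identical(back$well_labels, wl$well_labels)
  expect_length(back$sequences, 96L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ACGTA", "ACGTN"), bad)
  expect_error(load_whitelist(bad, "bc1"), "non-ACGT.*ACGTN")
  writeLines(c("ACGTA", "ACG"), bad)
  expect_error(load_whitelist(bad, "bc1"), "mixed lengths")
  writeLines(c("ACGTA", "TTTTT", "ACGTA"), bad)
  expect_error(load_whitelist(bad, "bc1"), "duplicated.*ACGTA")
})

test_that("hamming counts mismatches and rejects unequal lengths", {
  expect_identical(hamming("ACGT", "ACGT"), 0L)
  expect_identical(hamming("ACGT", "ACGA"), 1L)
  expect_identical(hamming("AAAA", "TTTT"), 4L)
  expect_identical(hamming(c("AA", "AT"), "AA"), c(0L, 1L))
  expect_error(hamming("ACG", "ACGT"), "equal-length")
})

test_that("correction index resolves the worked single-mismatch cases", {
  wl <- chseq:::new_whitelist(c("AAAA", "TTTT"), "bc1")
  idx <- build_correction_index(wl, 1L)
  res <- correct_barcodes(idx, c("AAAT", "AAAA", "GGGG"))
  expect_identical(res$status, c("matched", "matched", "no_match"))
  expect_identical(res$entry[1:2], c(1L, 1L))
  expect_identical(res$mismatches[1:2], c(1L, 0L))

  amb <- chseq:::new_whitelist(c("AAAA", "AAAT"), "bc1")
  idx2 <- build_correction_index(amb, 1L)
  res2 <- correct_barcodes(idx2, c("AAAC", "AAAA", "AAAT"))
  expect_identical(res2$status[1], "ambiguous")
  # exact entries still self-correct even though each is within 1 of the other
  expect_identical(res2$status[2:3], c("matched", "matched"))
  expect_identical(res2$entry[2:3], c(1L, 2L))

  expect_error(build_correction_index(wl, 2L), "unsupported")
})

test_that("index lookup agrees with brute-force nearest-whitelist search", {
  wl <- random_whitelist(20L, 8L, min_dist = 1L, "bc1", seed = 11L)
  idx <- build_correction_index(wl, 1L)
  set.seed(99)
  queries <- chseq:::random_dna(3000L, 8L)
  got <- correct_barcodes(idx, queries)
  for (i in seq_along(queries)) {
    want <- bf_correct(wl$sequences, queries[i], 1L)
    expect_identical(got$status[i], want$status)
    if (want$status == "matched") expect_identical(got$entry[i], want$entry)
  }
})

test_that("1-mismatch corruptions of min-distance-3 whitelists always restore", {
  wl <- random_whitelist(40L, 10L, min_dist = 3L, "bc1", seed = 5L)
  idx <- build_correction_index(wl, 1L)
  set.seed(1)
  for (rep in 1:500) {
    e <- sample.int(40L, 1L)
    s <- wl$sequences[e]
    p <- sample.int(10L, 1L)
    alt <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))
    substr(s, p, p) <- sample(alt, 1L)
    res <- correct_barcodes(idx, s)
    expect_identical(res$entry, e)
    expect_identical(res$mismatches, 1L)
  }
})

test_that("validate_scheme reports min distances and warns on weak lists", {
  sch <- tiny_scheme(min_dist = 3L)
  rep <- validate_scheme(sch)
  expect_identical(rep$round_id, c("bc1", "bc2", "i5", "i7"))
  expect_true(all(rep$min_distance >= 3L))
  expect_true(all(rep$correction_guaranteed))

  weak <- ch_scheme(
    bc1 = chseq:::new_whitelist(c("AAAAAAAAAA", "AAAAAAAATT"), "bc1"),
    bc2 = random_whitelist(4L, 10L, 3L, "bc2", seed = 2L),
    i5 = random_whitelist(2L, 8L, 3L, "i5", seed = 3L),
    i7 = random_whitelist(2L, 8L, 3L, "i7", seed = 4L))
  expect_warning(rep2 <- validate_scheme(weak), "bc1.*not guaranteed")
  expect_identical(rep2$min_distance[rep2$round_id == "bc1"], 2L)

  single <- ch_scheme(
    bc1 = chseq:::new_whitelist("AAAAAAAAAA", "bc1"),
    bc2 = random_whitelist(4L, 10L, 3L, "bc2", seed = 2L),
    i5 = random_whitelist(2L, 8L, 3L, "i5", seed = 3L),
    i7 = random_whitelist(2L, 8L, 3L, "i7", seed = 4L))
  rep3 <- validate_scheme(single)
  expect_true(is.na(rep3$min_distance[rep3$round_id == "bc1"]))
})
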