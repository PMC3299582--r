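test_that("variant tokens parse and validate against the packaged rCRS", {
  v <- parse_variant("C16223T")
  expect_equal(v$pos, 16223)
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "T")
  v2 <- parse_variant("A16235G")
  expect_equal(unlist(v2[c("ref", "alt")]), c(ref = "A", alt = "G"))
  expect_error(parse_variant("C99999T"),
               class = "hvsadmix_position_outside_window")
  expect_error(parse_variant("nonsense"), class = "hvsadmix_malformed_token")
  # rCRS has T at 16311, so a token claiming C there must be rejected
  expect_error(parse_variant("C16311A"), class = "hvsadmix_ref_mismatch")
  # deletion and insertion dialects
  expect_equal(parse_variant("A16166d")$type, "deletion")
  expect_equal(parse_variant("16193.1C")$type, "insertion")
})

test_that("sequences call variants against rCRS, ignoring poly-C length changes", {
  w <- hvs_window()
  expect_length(haplotype_from_sequence(rcrs_segment(w), w), 0L)
  s <- rcrs_segment(w)
  substr(s, 16223 - w$start + 1, 16223 - w$start + 1) <- "T"
  h <- haplotype_from_sequence(s, w)
  expect_equal(haplotype_string(h), "C16223T")
  # a gap inside 16184-16193 (the aligned trace of a poly-C length change)
  s2 <- rcrs_segment(w)
  substr(s2, 16190 - w$start + 1, 16190 - w$start + 1) <- "-"
  expect_length(haplotype_from_sequence(s2, w), 0L)
  # but a substitution inside the tract is kept (e.g. the common 16189 change)
  s3 <- rcrs_segment(w)
  substr(s3, 16189 - w$start + 1, 16189 - w$start + 1) <- "C"
  expect_equal(haplotype_string(haplotype_from_sequence(s3, w)), "T16189C")
  expect_error(haplotype_from_sequence("ACGT", w),
               class = "hvsadmix_length_mismatch")
  sx <- rcrs_segment(w); substr(sx, 5, 5) <- "X"
  expect_error(haplotype_from_sequence(sx, w), class = "hvsadmix_bad_character")
})

test_that("mismatch distance counts per-position state differences", {
  expect_equal(mismatch_distance(haplotype("C16223T"), haplotype("C16223T")), 0)
  # the two haplotype profiles printed for U6a and H2a2b1 differ at 9 positions
  u6a <- haplotype("T16172C C16184T A16219G C16234T C16278T T16311C")
  h2 <- haplotype("A16235G C16291T A16293G")
  expect_equal(mismatch_distance(u6a, h2), 9)
  # same position, different derived state: one mismatch, not two
  expect_equal(mismatch_distance(haplotype("C16223T"), haplotype("C16223A")), 1)
})

test_that("mismatch distance agrees with a symmetric-difference oracle and is a metric", {
  set.seed(11)
  for (rep in 1:30) {
    h1 <- random_haplotype(sample(0:8, 1))
    h2 <- random_haplotype(sample(0:8, 1))
    h3 <- random_haplotype(sample(0:8, 1))
    d12 <- mismatch_distance(h1, h2)
    expect_identical(d12, oracle_mismatch(h1, h2))
    expect_identical(d12, mismatch_distance(h2, h1))
    expect_lte(mismatch_distance(h1, h3), d12 + mismatch_distance(h2, h3))
    expect_identical(mismatch_distance(h1, h1), 0L)
  }
})

test_that("serialisation round-trips and excluded-tract indels never score", {
  set.seed(12)
  for (rep in 1:10) {
    h <- random_haplotype(sample(1:6, 1))
    h2 <- haplotype(haplotype_string(h), id = attr(h, "id"))
    expect_identical(unclass(h)[order(names(h))], unclass(h2)[order(names(h2))])
  }
  # an insertion inside the excluded tract is dropped at parse time
  h_ins <- haplotype("C16223T 16193.1C")
  expect_equal(haplotype_string(h_ins), "C16223T")
  expect_equal(mismatch_distance(h_ins, haplotype("C16223T")), 0)
  # but indels outside the tract are retained and count one each
  h_del <- haplotype("C16223T A16166d")
  expect_equal(mismatch_distance(h_del, haplotype("C16223T")), 1)
})

test_that("population tables read and write in both formats", {
  tsv <- file.path(tempdir(), "pops.tsv")
  writeLines(c("sample_id\tpopulation\tvariants",
               "s1\tPopA\tC16223T C16278T",
               "s2\tPopA\t",
               "s3\tPopB\tC16223T"), tsv)
  pops <- read_population_table(tsv, "variant-tsv")
  expect_named(pops, c("PopA", "PopB"))
  expect_equal(pops$PopA$n, 2L)
  expect_equal(pops$PopB$n, 1L)
  expect_length(pops$PopA$haplotypes[[2]], 0L)

  out <- file.path(tempdir(), "roundtrip.tsv")
  write_population_tsv(pops, out)
  pops2 <- read_population_table(out, "variant-tsv")
  expect_equal(vapply(pops2$PopA$haplotypes, haplotype_string, character(1)),
               vapply(pops$PopA$haplotypes, haplotype_string, character(1)))

  fa <- file.path(tempdir(), "pops.fasta")
  write_population_fasta(pops, fa)
  pops3 <- read_population_table(fa, "fasta")
  expect_equal(haplotype_string(pops3$PopA$haplotypes[[1]]),
               "C16223T C16278T")
  expect_length(pops3$PopA$haplotypes[[2]], 0L)

  # malformed token errors name the offending row
  bad <- file.path(tempdir(), "bad.tsv")
  writeLines(c("sample_id\tpopulation\tvariants",
               "s1\tPopA\tC16223T",
               "s2\tPopA\tC16223X"), bad)
  expect_error(read_population_table(bad, "variant-tsv"), "row 2",
               class = "hvsadmix_io_error")
  dup <- file.path(tempdir(), "dup.tsv")
  writeLines(c("sample_id\tpopulation\tvariants",
               "s1\tPopA\tC16223T",
               "s1\tPopB\t"), dup)
  expect_error(read_population_table(dup, "variant-tsv"),
               class = "hvsadmix_io_error")
})
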