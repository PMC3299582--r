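mt <- default_motif_table()
sc <- default_category_scheme()

test_that("motif matching assigns the expected haplogroups", {
  # exact motif match wins without a tie
  l1b <- haplotype(haplotype_string(mt$motif[[match("L1b", mt$label)]]))
  a <- assign_haplogroup(l1b, mt)
  expect_equal(a$label, "L1b")
  expect_false(a$tie)
  # rCRS-identical haplotype maps to the root label
  expect_equal(assign_haplogroup(haplotype(), mt)$label, "rCRS")
  # the L2a1 profile seen at high frequency in Caribbean samples
  a2 <- assign_haplogroup(haplotype("C16223T C16278T C16294T A16309G G16319A"), mt)
  expect_equal(a2$label, "L2a1")
  expect_error(assign_haplogroup(haplotype(), mt[0, ]),
               class = "hvsadmix_empty_motifs")
})

test_that("private variants never change the assignment", {
  set.seed(21)
  free <- setdiff(seq(16024, 16365),
                  unique(unlist(lapply(mt$motif, function(m)
                    floor(as.numeric(names(m)))))))
  for (lab in c("L1b", "L2a1", "L3e", "U6a", "A2")) {
    base <- mt$motif[[match(lab, mt$label)]]
    h <- haplotype(haplotype_string(base))
    expect_equal(assign_haplogroup(h, mt)$label, lab)
    for (rep in 1:5) {
      p <- sample(free, 1)
      tok <- paste0(rcrs_base(p), p,
                    sample(setdiff(c("A", "C", "G", "T"), rcrs_base(p)), 1))
      h2 <- haplotype(paste(haplotype_string(h), tok))
      expect_equal(assign_haplogroup(h2, mt)$label, lab)
    }
  }
})

test_that("labels collapse into macro-categories by longest prefix", {
  expect_equal(collapse_to_category("U6a", sc), "U6")
  expect_equal(collapse_to_category("A2", sc), "non-L/U6")
  expect_equal(collapse_to_category("L3h", sc), "Other L3")
  expect_equal(collapse_to_category("L2a1", sc), "L2a")
  expect_equal(collapse_to_category("L2d", sc), "Other L0'1'2")
  expect_equal(collapse_to_category("H2a2b1", sc), "non-L/U6")
})

test_that("profile counts conserve the sample size", {
  pop <- population_sample("Mix", list(
    haplotype("C16223T C16278T C16294T", id = "1"),     # L2a
    haplotype("C16223T C16327T", id = "2"),             # L3e
    haplotype("T16126C C16187T T16189C C16223T C16264T C16270T C16278T T16311C",
              id = "3"),                                # L1b
    haplotype("C16111T C16223T C16290T G16319A T16362C", id = "4")))  # A2
  prof <- profile_counts(pop, mt, sc)
  expect_equal(sum(prof$counts) + prof$unclassified, 4L)
  expect_equal(unname(prof$counts[["non-L/U6"]]), 1L)
  expect_equal(unname(prof$counts[["L2a"]] + prof$counts[["L3e"]] +
                        prof$counts[["L1b"]]), 3L)
  # empty sample: all-zero profile
  prof0 <- profile_counts(population_sample("Empty", list()), mt, sc)
  expect_equal(prof0$n, 0L)
  expect_true(all(prof0$counts == 0L))
})

test_that("assignment recovers the generating haplogroup without mutation, and sampled profiles match expectation", {
  cfg <- generator_config(seed = 31, source_sizes = c(150L, 150L, 150L),
                          mutation_mean = 0, founder_extra = 0L)
  src <- generate_sources(cfg)
  for (s in names(src$samples)) {
    prof <- profile_counts(src$samples[[s]], mt, sc)
    truth <- src$truth$lineages[src$truth$lineages$source == s, ]
    got <- prof$assignments$haplogroup
    expect_equal(mean(got == truth$haplogroup), 1.0)
  }
  # large multinomial draw: observed category counts within sampling error
  cfg2 <- generator_config(
    profiles = list(S = c(L2a1 = 0.6, L1b = 0.4)),
    source_sizes = 10000L, mixing = 1, seed = 32, mutation_mean = 1)
  src2 <- generate_sources(cfg2)
  prof2 <- profile_counts(src2$samples$S, mt, sc)
  obs <- prof2$counts[c("L2a", "L1b")]
  chi <- stats::chisq.test(obs, p = c(0.6, 0.4))
  expect_gt(chi$p.value, 0.01)
})
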