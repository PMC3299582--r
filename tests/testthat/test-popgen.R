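test_that("diversity summary matches brute-force pair enumeration and frozen constants", {
  # three haplotypes with pairwise distances {1, 2, 1}
  pop3 <- population_sample("T3", list(haplotype("C16223T", id = "1"),
                                       haplotype("C16223T C16278T", id = "2"),
                                       haplotype("", id = "3")))
  expect_equal(diversity_summary(pop3)$theta_pi, 4 / 3)

  pop <- toy_population()
  ds <- diversity_summary(pop)
  expect_equal(ds$n, 5L)
  expect_equal(ds$k, 4L)
  expect_equal(ds$S, 3L)
  # mean pairwise differences, with its independently computed value and
  # the Tajima-1989 D evaluated by hand from (n, S, theta_pi)
  expect_equal(ds$theta_pi, 1.4)
  expect_equal(ds$theta_pi_sd, 1.1910779431534557, tolerance = 1e-12)
  expect_equal(ds$tajima_d, -0.1747488474246183, tolerance = 1e-12)
  expect_true(ds$tajima_d_p >= 0 && ds$tajima_d_p <= 1)

  # all-identical sample: k = 1, S = 0, D undefined (not zero)
  same <- population_sample("Same", lapply(1:4, function(i)
    haplotype("C16223T", id = paste0("s", i))))
  d2 <- diversity_summary(same)
  expect_equal(c(d2$k, d2$S), c(1L, 0L))
  expect_equal(d2$theta_pi, 0)
  expect_false(d2$d_defined)
  expect_true(is.na(d2$tajima_d))
  expect_error(diversity_summary(population_sample("one",
                                                   list(haplotype()))),
               class = "hvsadmix_too_small")
})

test_that("theta_pi equals brute-force pairwise enumeration on random samples", {
  set.seed(51)
  for (rep in 1:5) {
    haps <- lapply(1:12, function(i) random_haplotype(sample(0:5, 1),
                                                      id = paste0("r", i)))
    pop <- population_sample("R", haps)
    # oracle: enumerate all pairs directly
    tot <- 0; np <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      tot <- tot + oracle_mismatch(haps[[i]], haps[[j]]); np <- np + 1
    }
    expect_equal(diversity_summary(pop)$theta_pi, tot / np)
    # first moment of the mismatch distribution equals theta_pi
    x <- mismatch_distribution(pop)
    expect_equal(sum(as.numeric(names(x)) * x), tot / np)
    expect_equal(sum(x), 1)
  }
})

test_that("mismatch distribution handles degenerate shapes", {
  same <- population_sample("Same", lapply(1:3, function(i)
    haplotype("C16223T", id = paste0("s", i))))
  expect_equal(unname(mismatch_distribution(same)), 1)
  two <- population_sample("Two", list(haplotype("C16223T C16278T T16311C",
                                                 id = "a"),
                                       haplotype("", id = "b")))
  x <- mismatch_distribution(two)
  expect_equal(unname(x[["3"]]), 1)
})

test_that("raggedness follows Harpending's formula and rewards smoothness", {
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  expect_equal(raggedness(c(1.0)), 1.0)
  expect_error(raggedness(numeric()), class = "hvsadmix_degenerate")
  # over all permutations of a 5-class mass vector, the minimal raggedness
  # is attained by a unimodal arrangement and every non-unimodal
  # arrangement is strictly rougher than the best unimodal one
  masses <- c(0.05, 0.1, 0.2, 0.3, 0.35)
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(permute(v[-i]), function(p) c(v[i], p))))
  }
  ps <- permute(masses)
  rs <- vapply(ps, raggedness, numeric(1))
  unimodal <- vapply(ps, function(x) {
    d <- diff(x); up <- which(d > 0); dn <- which(d < 0)
    length(up) == 0 || length(dn) == 0 || max(up) < min(dn)
  }, logical(1))
  expect_true(unimodal[which.min(rs)])
  expect_lt(min(rs[unimodal]), min(rs[!unimodal]))
})

test_that("sudden-expansion fit recovers generating parameters", {
  # perfect-fit limit: data equal to the model expectation
  tau <- 4; th0 <- 0.5; th1 <- 300
  f <- expected_mismatch(0:30, tau, th0, th1)
  x <- f / sum(f)
  fit <- fit_sudden_expansion(x, n = 200, n_boot = 0)
  expect_lt(fit$ssd, 1e-6)
  # tau recovery within 20% on model-simulated histograms
  set.seed(52)
  taus <- numeric(20)
  for (r in 1:20) {
    cnt <- stats::rmultinom(1, 200 * 199 / 2, x)[, 1]
    xb <- cnt / sum(cnt)
    taus[r] <- fit_sudden_expansion(xb, n = 200, n_boot = 0)$tau
  }
  expect_lt(abs(mean(taus) - tau) / tau, 0.2)
  # degenerate distribution flagged
  expect_true(fit_sudden_expansion(c(1), n = 10, n_boot = 0)$degenerate)
})

test_that("SSD bootstrap p-values are valid and seed-reproducible", {
  pop <- toy_population()
  x <- mismatch_distribution(pop)
  f1 <- fit_sudden_expansion(x, pop$n, n_boot = 60, seed = 7)
  f2 <- fit_sudden_expansion(x, pop$n, n_boot = 60, seed = 7)
  expect_true(f1$ssd_p >= 0 && f1$ssd_p <= 1)
  expect_true(f1$raggedness_p >= 0 && f1$raggedness_p <= 1)
  expect_identical(f1$ssd_p, f2$ssd_p)
  expect_identical(f1$raggedness_p, f2$raggedness_p)
  expect_error(fit_sudden_expansion(x, pop$n, n_boot = 10),
               class = "hvsadmix_bad_config")
})

test_that("exact test matches enumeration facts and the hypergeometric oracle", {
  # 2x2 table of all ones: the three tables with these margins have
  # probabilities 1/6, 4/6, 1/6 and every one is as extreme as observed
  expect_equal(exact_differentiation_test(matrix(c(1, 1, 1, 1), 2))$p, 1.0)
  # dropping an all-zero column leaves the p-value unchanged
  tab <- matrix(c(5, 2, 1, 6, 3, 3), 2, 3)
  tab0 <- cbind(tab, c(0, 0))
  expect_equal(exact_differentiation_test(tab0)$p,
               exact_differentiation_test(tab)$p)
  # enumeration agrees with the network-algorithm implementation in
  # stats::fisher.test on random small tables
  set.seed(53)
  for (r in 1:5) {
    t2 <- matrix(stats::rpois(12, 2.5), 3, 4)
    t2 <- t2[rowSums(t2) > 0, colSums(t2) > 0, drop = FALSE]
    if (nrow(t2) < 2 || ncol(t2) < 2) next
    expect_equal(exact_differentiation_test(t2, method = "enumerate")$p,
                 stats::fisher.test(t2, workspace = 2e7)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(exact_differentiation_test(matrix(c(2, 3), 1, 2)),
               class = "hvsadmix_degenerate")
})

test_that("Markov-chain p agrees with full enumeration within Monte Carlo error", {
  set.seed(54)
  for (r in 1:4) {
    tab <- matrix(stats::rpois(12, 2) + 1, 3, 4)
    pe <- exact_differentiation_test(tab, method = "enumerate")$p
    ch <- exact_differentiation_test(tab, method = "chain", seed = 100 + r)
    expect_lt(abs(ch$p - pe), 3 * max(ch$se, 0.005))
  }
})

test_that("pairwise differentiation tests cover all population pairs", {
  profs <- list(haplogroup_profile("P1", c(a = 20L, b = 5L, c = 2L)),
                haplogroup_profile("P2", c(a = 4L, b = 18L, c = 5L)),
                haplogroup_profile("P3", c(a = 10L, b = 10L, c = 7L)))
  dt <- differentiation_tests(profs, seed = 60)
  expect_true(all(!is.na(dt$pairwise[upper.tri(dt$pairwise)])))
  expect_equal(dt$pairwise, t(dt$pairwise))
  expect_lt(dt$pairwise["P1", "P2"], 0.01)   # strongly differentiated pair
  expect_true(dt$overall$p >= 0 && dt$overall$p <= 1)
})
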