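test_that("single-source admixture is exactly 1", {
  p <- haplogroup_profile("A", c(x = 10L, y = 5L))
  h <- haplogroup_profile("H", c(x = 3L, y = 2L))
  fit <- fit_admixture_mcmc(h, list(p), mcmc_config(seed = 1))
  expect_identical(fit$mean, 1)
  expect_identical(fit$sd, 0)
})

test_that("a hybrid identical to one disjoint source is attributed to it", {
  pr <- disjoint_profiles()
  h <- haplogroup_profile("H", c(L2a = 140L, L1b = 60L, L3e = 0L, L3f = 0L))
  fit <- fit_admixture_mcmc(h, list(pr$a, pr$b),
                            mcmc_config(seed = 2, chain_length = 20000L,
                                        burn_in = 5000L))
  expect_gte(fit$mean[fit$source == "A"], 0.95)
  expect_equal(sum(fit$mean), 1, tolerance = 1e-9)
})

test_that("posterior means track a grid-search maximum-likelihood oracle", {
  pr <- disjoint_profiles(n_a = 500L, n_b = 500L)
  pa <- pr$a$counts / pr$a$n
  pb <- pr$b$counts / pr$b$n
  truth <- 0.7
  set.seed(3)
  y <- stats::rmultinom(1, 1000, truth * pa + (1 - truth) * pb)[, 1]
  # independent oracle: likelihood maximised over a 0.001 lattice on m
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, function(m) {
    q <- m * pa + (1 - m) * pb
    sum(y[y > 0] * log(q[y > 0]))
  }, numeric(1))
  m_ml <- grid[which.max(ll)]
  hyb <- haplogroup_profile("H", y)
  fit <- fit_admixture_mcmc(hyb, list(pr$a, pr$b), mcmc_config(seed = 4))
  m_hat <- fit$mean[fit$source == "A"]
  expect_lt(abs(m_hat - truth), 0.05)
  expect_lt(abs(m_hat - m_ml), 0.03)
  expect_equal(sum(fit$mean), 1, tolerance = 1e-9)
  expect_true(attr(fit, "converged"))
})

test_that("permuting source order permutes the estimates identically", {
  pr <- disjoint_profiles()
  h <- haplogroup_profile("H", c(L2a = 70L, L1b = 30L, L3e = 60L, L3f = 40L))
  f1 <- fit_admixture_mcmc(h, list(pr$a, pr$b), mcmc_config(seed = 5))
  f2 <- fit_admixture_mcmc(h, list(pr$b, pr$a), mcmc_config(seed = 5))
  expect_equal(f1$mean[match(c("A", "B"), f1$source)],
               f2$mean[match(c("A", "B"), f2$source)], tolerance = 0.02)
  expect_error(fit_admixture_mcmc(
    haplogroup_profile("H", c(u = 1L)), list(pr$a), mcmc_config(seed = 1)),
    class = "hvsadmix_category_mismatch")
})

test_that("sharing matrix counts matching source lineages per tolerance", {
  hA <- haplotype("C16223T C16278T", id = "a1")
  hA2 <- haplotype("C16223T C16278T", id = "a2")
  hG <- haplotype("C16223T C16327T", id = "a3")
  srcA <- population_sample("A", list(hA, hA2, hG))
  srcB <- population_sample("B", list(haplotype("C16223T C16278T", id = "b1")))
  hyb <- population_sample("H", list(haplotype("C16223T C16278T", id = "h1")))
  S0 <- build_sharing_matrix(hyb, list(srcA, srcB), m = 0)
  expect_equal(unname(S0[1, ]), c(2 / 3, 1))
  # nested match sets: entries non-decreasing in m
  S1 <- build_sharing_matrix(hyb, list(srcA, srcB), m = 1)
  S2 <- build_sharing_matrix(hyb, list(srcA, srcB), m = 2)
  expect_true(all(S1 >= S0) && all(S2 >= S1))
  expect_error(build_sharing_matrix(hyb, list(population_sample("E", list()))),
               class = "hvsadmix_empty_source")
})

test_that("ancestry proportions normalise rows and average them", {
  mk_sharing <- function(S, counts) {
    # build an hvs_sharing object from a plain matrix for unit testing
    structure(S, class = c("hvs_sharing", "matrix"), m = 0L,
              source_n = vapply(counts, sum, integer(1)),
              hyb_type = seq_len(nrow(S)),
              match_sets = lapply(seq_len(ncol(S)), function(c)
                matrix(TRUE, nrow(S), length(counts[[c]]))),
              src_counts = counts)
  }
  S <- matrix(c(0.2, 0.0, 0.1, 0.3), 2, 2,
              dimnames = list(NULL, c("A", "B")))
  obj <- mk_sharing(S, list(c(2L, 3L), c(1L, 4L)))
  ap <- ancestry_proportions(obj, n_boot = 50, seed = 6)
  expect_equal(ap$mean, c(mean(c(2 / 3, 0)), mean(c(1 / 3, 1))))
  expect_equal(sum(ap$mean), 1, tolerance = 1e-9)
  # degenerate matrix errors
  Z <- matrix(0, 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(ancestry_proportions(mk_sharing(Z, list(1L, 1L)),
                                    n_boot = 10, seed = 1),
               class = "hvsadmix_degenerate")
})

test_that("sharing estimator on synthetic admixture ranks sources by truth and brackets the point estimate", {
  cfg <- generator_config(seed = 41, source_sizes = c(200L, 200L, 200L),
                          hybrid_size = 400L)
  src <- generate_sources(cfg)
  hyb <- generate_admixed(src$samples, cfg$mixing, 400L, seed = 42)
  S <- build_sharing_matrix(hyb$sample, unname(src$samples), m = 0)
  ap <- ancestry_proportions(S, n_boot = 300, seed = 43)
  expect_equal(order(-ap$mean), order(-cfg$mixing))
  expect_true(all(ap$lower <= ap$mean + 1e-9 & ap$mean <= ap$upper + 1e-9))
  expect_equal(attr(ap, "method"), "sharing-m0")
  # every hybrid lineage is an exact copy of some source lineage
  expect_identical(attr(ap, "unmatched"), 0L)
})

test_that("census separates non-sub-Saharan lineages from the admixture pool", {
  pop <- population_sample("H", list(
    haplotype("C16223T C16278T C16294T", id = "1"),            # L2a
    haplotype("C16069T T16126C", id = "2"),                     # J -> non-L/U6
    haplotype("C16223T C16327T", id = "3")))                    # L3e
  cs <- census_and_filter(pop)
  expect_equal(cs$n_excluded, 1L)
  expect_equal(cs$filtered$n, 2L)
  expect_equal(cs$pct_african, 100 * 2 / 3)
})
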