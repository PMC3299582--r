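# Arlequin-style diversity and demography statistics on HVS-I samples:
# haplotype diversity summaries, the mismatch distribution with the
# Rogers-Harpending sudden-expansion fit (SSD, raggedness, parametric
# bootstrap), and the Raymond-Rousset exact test of differentiation.

#' Diversity summary of a population sample
#'
#' Computes n, the number of distinct haplotypes k, the number of
#' segregating sites S, the mean number of pairwise differences
#' theta_pi with its total-variance SD (Tajima 1983), and Tajima's D
#' with a two-sided p-value from the beta approximation (Tajima 1989).
#' When S = 0, D is undefined and reported as NA with `d_defined = FALSE`
#' rather than 0.
#'
#' @param sample an `hvs_population` with at least 2 lineages.
#' @return Object of class `hvs_diversity`: list with `label`, `n`, `k`,
#'   `S`, `theta_pi`, `theta_pi_sd`, `tajima_d`, `tajima_d_p`,
#'   `d_defined`, `signif` (`""`, `"*"` p < 0.05, `"**"` p < 0.01).
#' @export
diversity_summary <- function(sample) {
  n <- sample$n
  if (n < 2L) .hvs_error("diversity summary requires n >= 2", "hvsadmix_too_small")
  u <- .unique_haplotypes(sample$haplotypes)
  k <- length(u$haps)
  # segregating sites: position keys with >= 2 states across the sample
  keys <- unique(unlist(lapply(u$haps, names)))
  S <- 0L
  for (key in keys) {
    states <- character()
    carriers <- 0L
    for (i in seq_along(u$haps)) {
      st <- u$haps[[i]][key]
      if (!is.na(st)) { states <- c(states, unname(st)); carriers <- carriers + u$counts[i] }
    }
    if (carriers < n) states <- c(states, ".")   # some lineage carries rCRS
    if (length(unique(states)) >= 2L) S <- S + 1L
  }
  d <- .hap_distance_matrix(u$haps)
  cnt <- u$counts
  npairs <- n * (n - 1) / 2
  tot <- 0
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    tot <- tot + cnt[i] * cnt[j] * d[i, j]
  theta_pi <- tot / npairs
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  theta_pi_sd <- sqrt(b1 * theta_pi + b2 * theta_pi^2)
  td <- .tajima_d(n, S, theta_pi)
  structure(list(label = sample$label, n = n, k = k, S = S,
                 theta_pi = theta_pi, theta_pi_sd = theta_pi_sd,
                 tajima_d = td$D, tajima_d_p = td$p,
                 d_defined = td$defined,
                 signif = if (!td$defined || is.na(td$p)) "" else
                   if (td$p < 0.01) "**" else if (td$p < 0.05) "*" else ""),
            class = "hvs_diversity")
}

# Tajima's D and its beta-approximation p-value (Tajima 1989).
.tajima_d <- function(n, S, theta_pi) {
  if (S == 0L) return(list(D = NA_real_, p = NA_real_, defined = FALSE))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  u <- (D - Dmin) / (Dmax - Dmin)
  Fu <- stats::pbeta(min(max(u, 0), 1), beta, alpha)
  p <- min(1, 2 * min(Fu, 1 - Fu))
  list(D = D, p = p, defined = TRUE)
}

#' @export
print.hvs_diversity <- function(x, ...) {
  cat(sprintf("%s: n=%d k=%d S=%d theta_pi=%.2f +/- %.2f D=%s%s\n",
              x$label, x$n, x$k, x$S, x$theta_pi, x$theta_pi_sd,
              if (x$d_defined) sprintf("%.2f", x$tajima_d) else "undefined",
              x$signif))
  invisible(x)
}

#' Mismatch distribution of a sample
#'
#' @param sample an `hvs_population` with at least 2 lineages.
#' @return Named numeric vector; element `i + 1` (name `i`) is the
#'   fraction of lineage pairs at mismatch distance `i`, for
#'   `i = 0 ... max observed`. Sums to 1.
#' @export
mismatch_distribution <- function(sample) {
  n <- sample$n
  if (n < 2L) .hvs_error("mismatch distribution requires n >= 2",
                         "hvsadmix_too_small")
  u <- .unique_haplotypes(sample$haplotypes)
  d <- .hap_distance_matrix(u$haps)
  cnt <- u$counts
  k <- length(cnt)
  dmax <- if (k >= 2L) max(d) else 0L
  counts <- numeric(dmax + 1L)
  counts[1L] <- sum(cnt * (cnt - 1) / 2)       # within-type pairs, distance 0
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    counts[d[i, j] + 1L] <- counts[d[i, j] + 1L] + cnt[i] * cnt[j]
  x <- counts / sum(counts)
  names(x) <- 0:dmax
  x
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` with `x_{d+1} = 0`.
#'
#' @param x mismatch relative-frequency vector over classes `0...d`.
#' @return Non-negative raggedness value.
#' @examples
#' raggedness(c(0.5, 0.5)) # 0.25
#' @export
raggedness <- function(x) {
  if (!length(x)) .hvs_error("empty mismatch vector", "hvsadmix_degenerate")
  sum(diff(c(unname(x), 0))^2)
}

#' Rogers-Harpending sudden-expansion expectation
#'
#' Expected mismatch relative frequencies under a stepwise expansion from
#' population-mutation parameter `theta0` to `theta1` at `tau` mutational
#' time units in the past.
#'
#' @param j integer vector of mismatch classes.
#' @param tau,theta0,theta1 model parameters (all >= 0).
#' @return Numeric vector of expected class probabilities.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  fhat <- function(i, th) th^i / (1 + th)^(i + 1)
  jmax <- max(j)
  # cumulative convolution term, computed for 0..jmax then indexed
  out <- numeric(jmax + 1L)
  damp <- exp(-tau * (theta1 + 1) / max(theta1, 1e-12))
  for (jj in 0:jmax) {
    i <- 0:jj
    out[jj + 1L] <- fhat(jj, theta1) +
      damp * sum(tau^i / factorial(i) * (fhat(jj - i, theta0) - fhat(jj - i, theta1)))
  }
  pmax(out[j + 1L], 0)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) minimising
#' `SSD = sum_i (x_i - F_i)^2` against the Rogers-Harpending expectation,
#' by bounded optimisation from multiple random restarts. The SSD and
#' raggedness p-values come from a parametric bootstrap: replicate
#' mismatch histograms are drawn as multinomials of `n(n-1)/2` pairs from
#' the fitted expectation, each replicate refitted, and the observed SSD
#' (raggedness) compared with the replicate distribution.
#'
#' @param x observed mismatch relative frequencies (classes `0...d`).
#' @param n sample size (number of lineages) behind `x`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory when `n_boot > 0`).
#' @param n_restarts random restarts for the optimiser (default 10).
#' @return Object of class `hvs_mismatch_fit`: list with `x`, `tau`,
#'   `theta0`, `theta1`, `ssd`, `ssd_p`, `raggedness`, `raggedness_p`,
#'   `n_boot`, `seed`, `converged`, `degenerate`.
#' @export
fit_sudden_expansion <- function(x, n, n_boot = 1000L, seed = NULL,
                                 n_restarts = 10L) {
  x <- unname(x)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-8)
    .hvs_error("x must be a relative-frequency vector summing to 1",
               "hvsadmix_bad_distribution")
  if (sum(x > 0) < 2L) {
    return(structure(list(x = x, tau = NA_real_, theta0 = NA_real_,
                          theta1 = NA_real_, ssd = NA_real_, ssd_p = NA_real_,
                          raggedness = raggedness(x), raggedness_p = NA_real_,
                          n_boot = 0L, seed = seed, converged = FALSE,
                          degenerate = TRUE),
                     class = "hvs_mismatch_fit"))
  }
  if (n_boot > 0L && is.null(seed))
    .hvs_error("bootstrap requires a seed", "hvsadmix_bad_config")
  old <- .hvs_set_seed(if (is.null(seed)) 0L else as.integer(seed))
  on.exit(.hvs_restore_seed(old), add = TRUE)
  fit <- .fit_rh(x, n_restarts = n_restarts)
  rag <- raggedness(x)
  ssd_p <- rag_p <- NA_real_
  if (n_boot > 0L) {
    npairs <- n * (n - 1) / 2
    Fext <- .rh_extended(fit$par, length(x) - 1L)
    ssd_b <- rag_b <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      cnts <- stats::rmultinom(1L, npairs, Fext)[, 1L]
      dmax_b <- max(which(cnts > 0)) - 1L
      xb <- cnts[seq_len(dmax_b + 1L)] / npairs
      fb <- .fit_rh(xb, n_restarts = 3L)
      ssd_b[b] <- fb$value
      rag_b[b] <- raggedness(xb)
    }
    ssd_p <- mean(ssd_b >= fit$value)
    rag_p <- mean(rag_b >= rag)
  }
  structure(list(x = x, tau = fit$par[1], theta0 = fit$par[2],
                 theta1 = fit$par[3], ssd = fit$value, ssd_p = ssd_p,
                 raggedness = rag, raggedness_p = rag_p,
                 n_boot = as.integer(n_boot), seed = seed,
                 converged = fit$converged, degenerate = FALSE),
            class = "hvs_mismatch_fit")
}

# Bounded least-squares fit from multiple restarts. Returns par, value.
.fit_rh <- function(x, n_restarts = 10L) {
  j <- seq_along(x) - 1L
  obj <- function(par) {
    f <- expected_mismatch(j, par[1], par[2], par[3])
    sum((x - f)^2)
  }
  mean_d <- sum(j * x)
  lower <- c(0, 0, 1e-3); upper <- c(100, 50, 5000)
  best <- NULL
  starts <- list(c(max(mean_d, 0.1), 0.1, max(10 * mean_d, 10)))
  for (r in seq_len(max(n_restarts - 1L, 0L))) {
    starts <- c(starts, list(c(stats::runif(1, 0.1, 2 * mean_d + 1),
                               stats::runif(1, 0, 3),
                               stats::runif(1, 1, 1000))))
  }
  for (s in starts) {
    ft <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                lower = lower, upper = upper),
                   error = function(e) NULL)
    if (!is.null(ft) && (is.null(best) || ft$value < best$value)) best <- ft
  }
  if (is.null(best))
    .hvs_error("sudden-expansion optimiser failed from every restart",
               "hvsadmix_optim_failure")
  list(par = best$par, value = best$value, converged = best$convergence == 0)
}

# Fitted expectation extended past the observed classes and normalised,
# so bootstrap replicates can realise larger distances.
.rh_extended <- function(par, dmax) {
  D <- dmax
  repeat {
    f <- expected_mismatch(0:D, par[1], par[2], par[3])
    if (sum(f) >= 0.9999 || D >= 300L) break
    D <- D + 10L
  }
  f / sum(f)
}

#' @export
print.hvs_mismatch_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Sudden-expansion fit: degenerate mismatch distribution (single class)\n")
  } else {
    cat(sprintf("Sudden-expansion fit: tau=%.3f theta0=%.3f theta1=%.3f\n",
                x$tau, x$theta0, x$theta1))
    cat(sprintf("  SSD=%.5f (p=%s)  raggedness=%.5f (p=%s)\n", x$ssd,
                format(x$ssd_p, digits = 3), x$raggedness,
                format(x$raggedness_p, digits = 3)))
  }
  invisible(x)
}

# log hypergeometric probability of a contingency table with fixed margins
.log_table_prob <- function(t) {
  sum(lgamma(rowSums(t) + 1)) + sum(lgamma(colSums(t) + 1)) -
    lgamma(sum(t) + 1) - sum(lgamma(t + 1))
}

# enumerate all tables with the margins of `t`, calling fn(table)
# returns FALSE if the enumeration exceeded `limit` tables
.enumerate_tables <- function(rs, cs, fn, limit = 1e6) {
  R <- length(rs); C <- length(cs)
  count <- 0L
  tab <- matrix(0L, R, C)
  rec <- function(i, cs_left) {
    if (count > limit) return(FALSE)
    if (i == R) {
      tab[R, ] <<- cs_left
      count <<- count + 1L
      fn(tab)
      return(TRUE)
    }
    # enumerate row i with total rs[i], bounded by remaining column totals
    row <- integer(C)
    fill <- function(j, left) {
      if (count > limit) return(FALSE)
      if (j == C) {
        if (left > cs_left[C]) return(TRUE)
        row[C] <<- left
        tab[i, ] <<- row
        return(rec(i + 1L, cs_left - row))
      }
      for (v in 0:min(left, cs_left[j])) {
        row[j] <<- v
        if (!fill(j + 1L, left - v)) return(FALSE)
      }
      TRUE
    }
    fill(1L, rs[i])
  }
  rec(1L, cs)
}

#' Exact test of population differentiation
#'
#' Raymond-Rousset probability test: the p-value is the total
#' hypergeometric probability of all contingency tables with the observed
#' margins whose probability does not exceed that of the observed table.
#' Computed by full enumeration when the table universe is small enough,
#' otherwise by a Metropolis Markov chain over tables with fixed margins
#' (2x2 subtable moves), with a batch-means Monte Carlo standard error.
#'
#' @param tab matrix of counts (rows = populations, columns = categories).
#' @param method `"auto"` (default), `"enumerate"` or `"chain"`.
#' @param chain_length sampling steps of the Markov chain (default 100000).
#' @param dememorization discarded initial steps (default 10000).
#' @param batches batches for the chain standard error (default 20).
#' @param seed integer seed (required for the chain).
#' @param max_enumeration table-universe cap for enumeration (default 1e6).
#' @return List of class `hvs_exact_test`: `p`, `se` (NA for
#'   enumeration), `method`, `n_tables` (enumeration only).
#' @examples
#' exact_differentiation_test(matrix(c(1, 1, 1, 1), 2))$p # 1
#' @export
exact_differentiation_test <- function(tab, method = c("auto", "enumerate", "chain"),
                                       chain_length = 100000L,
                                       dememorization = 10000L,
                                       batches = 20L, seed = NULL,
                                       max_enumeration = 1e6) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab)))
    .hvs_error("contingency table must hold non-negative integers",
               "hvsadmix_bad_table")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    .hvs_error("degenerate table: need >= 2 rows and columns with positive margins",
               "hvsadmix_degenerate")
  mode(tab) <- "integer"
  lp_obs <- .log_table_prob(tab) + 1e-7        # tolerance for ties
  rs <- rowSums(tab); cs <- colSums(tab)
  # cheap upper bound on the number of tables with these margins, to avoid
  # starting an enumeration that cannot finish under max_enumeration
  lbound <- min(sum(lchoose(rs + ncol(tab) - 1, ncol(tab) - 1)),
                sum(lchoose(cs + nrow(tab) - 1, nrow(tab) - 1)))
  if (method == "auto" && lbound > log(max_enumeration)) method <- "chain"
  if (method != "chain") {
    acc <- new.env(); acc$p <- 0; acc$nt <- 0L
    complete <- .enumerate_tables(rs, cs, function(t) {
      lp <- .log_table_prob(t)
      acc$nt <- acc$nt + 1L
      if (lp <= lp_obs) acc$p <- acc$p + exp(lp)
    }, limit = max_enumeration)
    if (complete)
      return(structure(list(p = min(acc$p, 1), se = NA_real_,
                            method = "enumeration", n_tables = acc$nt),
                       class = "hvs_exact_test"))
    if (method == "enumerate")
      .hvs_error("table universe exceeds max_enumeration", "hvsadmix_too_large")
  }
  if (is.null(seed)) .hvs_error("Markov-chain exact test requires a seed",
                                "hvsadmix_bad_config")
  old <- .hvs_set_seed(as.integer(seed)); on.exit(.hvs_restore_seed(old), add = TRUE)
  R <- nrow(tab); C <- ncol(tab)
  t <- tab
  lp <- .log_table_prob(t)
  total <- chain_length + dememorization
  hits <- logical(chain_length)
  # pre-draw the move stream
  i1 <- sample.int(R, total, replace = TRUE)
  i2 <- sample.int(R - 1L, total, replace = TRUE); i2 <- i2 + (i2 >= i1)
  j1 <- sample.int(C, total, replace = TRUE)
  j2 <- sample.int(C - 1L, total, replace = TRUE); j2 <- j2 + (j2 >= j1)
  dir <- sample(c(-1L, 1L), total, replace = TRUE)
  u <- stats::runif(total)
  for (s in seq_len(total)) {
    a <- t[i1[s], j1[s]]; b <- t[i1[s], j2[s]]
    cc <- t[i2[s], j1[s]]; dd <- t[i2[s], j2[s]]
    if (dir[s] > 0L) {
      # a--, b++, cc++, dd--
      if (a > 0L && dd > 0L) {
        ratio <- (a * dd) / ((b + 1) * (cc + 1))
        if (u[s] < ratio) {
          t[i1[s], j1[s]] <- a - 1L; t[i1[s], j2[s]] <- b + 1L
          t[i2[s], j1[s]] <- cc + 1L; t[i2[s], j2[s]] <- dd - 1L
          lp <- lp + log(ratio)
        }
      }
    } else {
      if (b > 0L && cc > 0L) {
        ratio <- (b * cc) / ((a + 1) * (dd + 1))
        if (u[s] < ratio) {
          t[i1[s], j1[s]] <- a + 1L; t[i1[s], j2[s]] <- b - 1L
          t[i2[s], j1[s]] <- cc - 1L; t[i2[s], j2[s]] <- dd + 1L
          lp <- lp + log(ratio)
        }
      }
    }
    if (s > dememorization) hits[s - dememorization] <- lp <= lp_obs
  }
  p <- mean(hits)
  bsize <- chain_length %/% batches
  bm <- vapply(seq_len(batches), function(b)
    mean(hits[((b - 1L) * bsize + 1L):(b * bsize)]), numeric(1))
  se <- stats::sd(bm) / sqrt(batches)
  structure(list(p = p, se = se, method = "chain",
                 chain_length = chain_length, seed = as.integer(seed)),
            class = "hvs_exact_test")
}

#' @export
print.hvs_exact_test <- function(x, ...) {
  cat(sprintf("Exact test of differentiation: p = %.4g (%s%s)\n", x$p,
              x$method,
              if (!is.na(x$se)) sprintf(", MC se %.2g", x$se) else ""))
  invisible(x)
}

#' Pairwise exact tests between population profiles
#'
#' @param profiles list of `hvs_profile`.
#' @param ... passed to [exact_differentiation_test()].
#' @return List with `pairwise` (symmetric matrix of p-values) and
#'   `overall` (single test on the full population-by-category table).
#' @export
differentiation_tests <- function(profiles, ...) {
  labs <- vapply(profiles, `[[`, character(1), "label")
  cats <- names(profiles[[1]]$counts)
  tabfull <- t(vapply(profiles, function(p) as.numeric(p$counts[cats]),
                      numeric(length(cats))))
  rownames(tabfull) <- labs
  P <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    P[i, j] <- P[j, i] <- exact_differentiation_test(tabfull[c(i, j), ], ...)$p
  }
  list(pairwise = P, overall = exact_differentiation_test(tabfull, ...))
}

#' Diversity table across samples
#'
#' @param samples list of `hvs_population`.
#' @param fit_expansion also fit the sudden-expansion model per sample
#'   (adds RI and SSD columns).
#' @param n_boot,seed bootstrap settings for the expansion fit.
#' @return data.frame with one row per sample (columns n, k, S, theta_pi,
#'   theta_pi_sd, D, D_p, signif, and optionally RI, SSD).
#' @export
diversity_table <- function(samples, fit_expansion = TRUE, n_boot = 0L,
                            seed = NULL) {
  rows <- lapply(samples, function(s) {
    ds <- diversity_summary(s)
    row <- data.frame(sample = ds$label, n = ds$n, k = ds$k, S = ds$S,
                      theta_pi = ds$theta_pi, theta_pi_sd = ds$theta_pi_sd,
                      D = ds$tajima_d, D_p = ds$tajima_d_p,
                      signif = ds$signif, stringsAsFactors = FALSE)
    if (fit_expansion) {
      mf <- fit_sudden_expansion(mismatch_distribution(s), s$n,
                                 n_boot = n_boot, seed = seed)
      row$RI <- mf$raggedness
      row$SSD <- mf$ssd
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
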