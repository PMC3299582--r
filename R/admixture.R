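# Two maternal-ancestry estimators for a hybrid population given candidate
# source populations:
#  * fit_admixture_mcmc(): multinomial mixture on haplogroup-category
#    profiles, hybrid counts y ~ Multinomial(N, q) with q = sum_c m_c p_c,
#    Dirichlet uncertainty on source frequencies p_c, flat Dirichlet prior
#    on the mixing vector m, sampled by Metropolis-within-Gibbs.
#  * build_sharing_matrix() + ancestry_proportions(): haplotype-sharing
#    estimator, per-lineage source weights from the frequency of matching
#    haplotypes (within a mismatch tolerance) in each source.

#' MCMC configuration for the profile admixture sampler
#'
#' @param chain_length total iterations (default 50000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param proposal_sd standard deviation of the Gaussian random walk on
#'   the log-ratio (softmax) scale of the mixing vector (default 0.3).
#' @param prior_m Dirichlet concentration of the prior on the mixing
#'   vector (default 1, flat on the simplex).
#' @param prior_p Dirichlet concentration added to source category counts
#'   for the source-frequency prior (default 1).
#' @param seed integer seed; mandatory so runs are reproducible.
#' @return A list of class `hvs_mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 50000L, burn_in = 10000L, thin = 10L,
                        proposal_sd = 0.3, prior_m = 1, prior_p = 1, seed) {
  if (missing(seed)) .hvs_error("mcmc_config requires an explicit seed",
                                "hvsadmix_bad_config")
  if (burn_in < 0 || chain_length <= burn_in)
    .hvs_error("need chain_length > burn_in >= 0", "hvsadmix_bad_config")
  if (proposal_sd <= 0 || prior_m <= 0 || prior_p <= 0)
    .hvs_error("concentrations and proposal_sd must be > 0", "hvsadmix_bad_config")
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_sd = proposal_sd, prior_m = prior_m,
                 prior_p = prior_p, seed = as.integer(seed)),
            class = "hvs_mcmc_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Admixture proportions from haplogroup profiles by MCMC
#'
#' Fits the multinomial mixture model: hybrid category counts
#' `y ~ Multinomial(N, q)` with `q = sum_c m_c p_c`, where each source
#' frequency vector `p_c` carries a `Dirichlet(x_c + prior_p)` prior from
#' its observed counts `x_c`, and the mixing vector `m` a flat Dirichlet
#' prior. `m` moves by a Gaussian random walk on the softmax scale
#' (Jacobian-corrected); each `p_c` by an independence proposal from its
#' prior, accepted on the likelihood ratio.
#'
#' @param hybrid an `hvs_profile` for the admixed population.
#' @param sources list of `hvs_profile`, one per candidate source; all
#'   profiles must share one category set.
#' @param cfg an [mcmc_config()].
#' @return Object of class `hvs_admixture`: a data.frame with columns
#'   `source`, `n`, `mean`, `sd`, `lower`, `upper` (central 95% posterior
#'   interval). Attributes: `method = "profile-mcmc"`, `samples` (kept
#'   draws), `converged` (split-chain agreement), `accept_rate`.
#' @examples
#' a <- haplogroup_profile("A", c(x = 90L, y = 10L))
#' b <- haplogroup_profile("B", c(x = 10L, y = 90L))
#' h <- haplogroup_profile("H", c(x = 50L, y = 50L))
#' fit_admixture_mcmc(h, list(a, b), mcmc_config(seed = 1))
#' @export
fit_admixture_mcmc <- function(hybrid, sources, cfg) {
  stopifnot(inherits(cfg, "hvs_mcmc_config"))
  cats <- names(hybrid$counts)
  for (s in sources)
    if (!identical(names(s$counts), cats))
      .hvs_error(sprintf("category mismatch between '%s' and hybrid profile",
                         s$label), "hvsadmix_category_mismatch")
  y <- as.numeric(hybrid$counts)
  if (sum(y) == 0) .hvs_error("zero-count hybrid profile", "hvsadmix_bad_profile")
  C <- length(sources)
  labels <- vapply(sources, `[[`, character(1), "label")
  n_src <- vapply(sources, `[[`, integer(1), "n")
  if (C == 0) .hvs_error("need at least one source", "hvsadmix_bad_profile")
  if (C == 1L) {
    out <- data.frame(source = labels, n = n_src, mean = 1, sd = 0,
                      lower = 1, upper = 1, stringsAsFactors = FALSE)
    return(structure(out, class = c("hvs_admixture", "data.frame"),
                     method = "profile-mcmc", samples = matrix(1, 1, 1,
                       dimnames = list(NULL, labels)),
                     converged = TRUE, accept_rate = NA_real_,
                     seed = cfg$seed))
  }
  X <- vapply(sources, function(s) as.numeric(s$counts), numeric(length(cats)))
  alpha_p <- X + cfg$prior_p                    # K x C prior concentrations
  old <- .hvs_set_seed(cfg$seed); on.exit(.hvs_restore_seed(old), add = TRUE)

  P <- apply(alpha_p, 2L, function(a) a / sum(a))  # init at prior means
  z <- rep(0, C - 1L)
  m <- .softmax(c(z, 0))
  loglik <- function(m, P) {
    q <- as.vector(P %*% m)
    if (any(q[y > 0] <= 0)) return(-Inf)
    sum(y[y > 0] * log(q[y > 0]))
  }
  logtarget_m <- function(z, P) {
    m <- .softmax(c(z, 0))
    # flat Dirichlet prior (prior_m) + softmax Jacobian sum(log m)
    loglik(m, P) + (cfg$prior_m - 1) * sum(log(m)) + sum(log(m))
  }
  lt <- logtarget_m(z, P)
  ll <- loglik(m, P)
  n_keep <- (cfg$chain_length - cfg$burn_in) %/% cfg$thin
  kept <- matrix(NA_real_, n_keep, C, dimnames = list(NULL, labels))
  ki <- 0L; acc_m <- 0L
  for (it in seq_len(cfg$chain_length)) {
    # mixing-vector update
    z_new <- z + stats::rnorm(C - 1L, 0, cfg$proposal_sd)
    lt_new <- logtarget_m(z_new, P)
    if (is.finite(lt_new) && log(stats::runif(1)) < lt_new - lt) {
      z <- z_new; lt <- lt_new
      m <- .softmax(c(z, 0)); ll <- loglik(m, P)
      acc_m <- acc_m + 1L
    }
    # source-frequency updates (independence proposals from the prior)
    for (cix in seq_len(C)) {
      p_new <- P
      p_new[, cix] <- .rdirichlet1(alpha_p[, cix])
      ll_new <- loglik(m, p_new)
      if (is.finite(ll_new) && log(stats::runif(1)) < ll_new - ll) {
        P <- p_new; ll <- ll_new
        lt <- logtarget_m(z, P)
      }
    }
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      ki <- ki + 1L
      kept[ki, ] <- m
    }
  }
  kept <- kept[seq_len(ki), , drop = FALSE]
  half <- nrow(kept) %/% 2L
  split_gap <- max(abs(colMeans(kept[seq_len(half), , drop = FALSE]) -
                       colMeans(kept[half + seq_len(half), , drop = FALSE])))
  converged <- split_gap <= 0.05
  if (!converged)
    warning(sprintf("profile-MCMC split-chain means differ by %.3f; chain may not have converged", split_gap))
  out <- data.frame(source = labels, n = n_src,
                    mean = colMeans(kept),
                    sd = apply(kept, 2L, stats::sd),
                    lower = apply(kept, 2L, stats::quantile, 0.025),
                    upper = apply(kept, 2L, stats::quantile, 0.975),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("hvs_admixture", "data.frame"),
            method = "profile-mcmc", samples = kept, converged = converged,
            split_gap = split_gap,
            accept_rate = acc_m / cfg$chain_length, seed = cfg$seed)
}

# Seed handling: isolate package RNG use from the caller's stream.
.hvs_set_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.hvs_restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Haplotype-sharing matrix
#'
#' Entry (i, c) is the frequency, in source c, of haplotypes within
#' `m` mismatches of hybrid lineage i:
#' `S[i, c] = #{source-c lineages at distance <= m} / N_c`.
#'
#' @param hybrid an `hvs_population`.
#' @param sources list of `hvs_population`.
#' @param m mismatch tolerance, 0, 1 or 2 (larger values allowed).
#' @return Matrix of class `hvs_sharing` (rows = hybrid lineages, columns
#'   = sources) with attributes `m`, `source_n`, and the match structure
#'   used by [ancestry_proportions()] for posterior simulation.
#' @export
build_sharing_matrix <- function(hybrid, sources, m = 0L) {
  if (!length(sources)) .hvs_error("need at least one source", "hvsadmix_bad_profile")
  for (s in sources) if (s$n == 0L)
    .hvs_error(sprintf("empty source population '%s'", s$label),
               "hvsadmix_empty_source")
  m <- as.integer(m)
  hu <- .unique_haplotypes(hybrid$haplotypes)
  hyb_type <- match(hu$key, hu$ukey)          # lineage -> unique type index
  C <- length(sources)
  labels <- vapply(sources, `[[`, character(1), "label")
  S <- matrix(0, hybrid$n, C, dimnames = list(NULL, labels))
  match_sets <- vector("list", C)
  src_counts <- vector("list", C)
  for (cix in seq_len(C)) {
    su <- .unique_haplotypes(sources[[cix]]$haplotypes)
    kH <- length(hu$haps); kS <- length(su$haps)
    M <- matrix(FALSE, kH, kS)
    for (i in seq_len(kH)) for (j in seq_len(kS))
      M[i, j] <- mismatch_distance(hu$haps[[i]], su$haps[[j]]) <= m
    freq <- su$counts / sources[[cix]]$n
    S[, cix] <- as.vector(M %*% freq)[hyb_type]
    match_sets[[cix]] <- M
    src_counts[[cix]] <- su$counts
  }
  structure(S, class = c("hvs_sharing", "matrix"), m = m,
            source_n = vapply(sources, `[[`, integer(1), "n"),
            hyb_type = hyb_type, match_sets = match_sets,
            src_counts = src_counts)
}

#' Ancestry proportions from a sharing matrix
#'
#' Each hybrid lineage contributes source weights
#' `w[i, c] = S[i, c] / sum_c' S[i, c']`; lineages matching no source
#' (all-zero rows) are excluded and counted. The point estimate is the
#' mean weight over included lineages. The 95% interval comes from
#' posterior simulation: source haplotype frequencies are redrawn from
#' `Dirichlet(counts + 1)` and hybrid lineages bootstrap-resampled, the
#' estimator recomputed, and 2.5/97.5 percentiles taken.
#'
#' @param S an `hvs_sharing` matrix from [build_sharing_matrix()].
#' @param n_boot posterior-simulation replicates (default 2000).
#' @param seed integer seed (mandatory).
#' @return Object of class `hvs_admixture`: data.frame with `source`,
#'   `n`, `mean`, `lower`, `upper`; attributes `method`
#'   (`"sharing-m<m>"`), `unmatched` (excluded lineage count), `seed`.
#' @export
ancestry_proportions <- function(S, n_boot = 2000L, seed) {
  if (missing(seed)) .hvs_error("ancestry_proportions requires a seed",
                                "hvsadmix_bad_config")
  stopifnot(inherits(S, "hvs_sharing"))
  rs <- rowSums(S)
  include <- rs > 0
  if (!any(include)) .hvs_error("all-zero sharing matrix", "hvsadmix_degenerate")
  W <- S[include, , drop = FALSE] / rs[include]
  point <- colMeans(W)
  hyb_type <- attr(S, "hyb_type")
  match_sets <- attr(S, "match_sets")
  src_counts <- attr(S, "src_counts")
  C <- ncol(S); n <- nrow(S)
  old <- .hvs_set_seed(as.integer(seed)); on.exit(.hvs_restore_seed(old), add = TRUE)
  boot <- matrix(NA_real_, n_boot, C)
  for (b in seq_len(n_boot)) {
    Sb <- matrix(0, n, C)
    for (cix in seq_len(C)) {
      fb <- .rdirichlet1(src_counts[[cix]] + 1)
      Sb[, cix] <- as.vector(match_sets[[cix]] %*% fb)[hyb_type]
    }
    idx <- sample.int(n, n, replace = TRUE)
    Sb <- Sb[idx, , drop = FALSE]
    rb <- rowSums(Sb)
    keep <- rb > 0
    if (!any(keep)) next
    boot[b, ] <- colMeans(Sb[keep, , drop = FALSE] / rb[keep])
  }
  ok <- stats::complete.cases(boot)
  out <- data.frame(source = colnames(S), n = attr(S, "source_n"),
                    mean = point,
                    lower = apply(boot[ok, , drop = FALSE], 2L,
                                  stats::quantile, 0.025),
                    upper = apply(boot[ok, , drop = FALSE], 2L,
                                  stats::quantile, 0.975),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("hvs_admixture", "data.frame"),
            method = paste0("sharing-m", attr(S, "m")),
            unmatched = sum(!include), n_boot = n_boot, seed = as.integer(seed))
}

#' Census of sub-Saharan vs other lineages, and admixture-stage filter
#'
#' Splits a hybrid sample by macro-category: lineages in the scheme's
#' default bucket (non-L/U6) are excluded from admixture analyses (they
#' cannot descend from the sub-Saharan source pool) but retained in the
#' census percentages.
#'
#' @param sample an `hvs_population`.
#' @param motifs an `hvs_motif_table`.
#' @param scheme an `hvs_category_scheme`.
#' @return List with `filtered` (an `hvs_population` of included
#'   lineages), `n`, `n_excluded`, `pct_african`, `pct_other`, and the
#'   census `profile`.
#' @export
census_and_filter <- function(sample, motifs = default_motif_table(),
                              scheme = default_category_scheme()) {
  prof <- profile_counts(sample, motifs, scheme)
  other <- attr(scheme, "default")
  excl <- !is.na(prof$assignments$category) & prof$assignments$category == other
  excl[is.na(prof$assignments$category)] <- TRUE   # unclassified excluded too
  filtered <- population_sample(sample$label, sample$haplotypes[!excl])
  list(filtered = filtered, n = sample$n, n_excluded = sum(excl),
       pct_african = 100 * (1 - sum(excl) / sample$n),
       pct_other = 100 * sum(excl) / sample$n,
       profile = prof)
}

#' @export
print.hvs_admixture <- function(x, ...) {
  cat(sprintf("Admixture estimate (%s)\n", attr(x, "method")))
  print.data.frame(x, digits = 4)
  if (!is.null(attr(x, "unmatched")) && attr(x, "unmatched") > 0)
    cat(sprintf("unmatched hybrid lineages excluded: %d\n", attr(x, "unmatched")))
  invisible(x)
}
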