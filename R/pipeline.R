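# Config-driven orchestration: regional aggregation of source populations,
# exclusion iterations (all, without Sahelian groups, without Pygmy
# groups, without both), and the full analysis battery per iteration:
# haplogroup profiles, both admixture estimators, diversity/demography
# table, pairwise exact tests, and the historical comparison.

#' Aggregate population samples into regions
#'
#' @param samples named list of `hvs_population`.
#' @param regions named character vector or list mapping population label
#'   to region name; populations absent from the map are kept under their
#'   own label.
#' @return Named list of `hvs_population`, one per region.
#' @export
aggregate_regions <- function(samples, regions = NULL) {
  if (is.null(regions) || !length(regions)) return(samples)
  regions <- unlist(regions)
  out <- list()
  for (s in samples) {
    reg <- if (s$label %in% names(regions)) regions[[s$label]] else s$label
    if (is.null(out[[reg]])) {
      out[[reg]] <- population_sample(reg, s$haplotypes)
    } else {
      out[[reg]] <- population_sample(reg, c(out[[reg]]$haplotypes,
                                             s$haplotypes))
    }
  }
  out
}

#' Resolve exclusion sets from a pipeline config
#'
#' Exclusions may be given as label lists, or (for the Sahel) as a
#' bounding box applied to population coordinates:
#' latitude 11.25-18.75 N, longitude 16.875 W - 35.625 E.
#'
#' @param exclusions list with optional `sahelian` (character vector),
#'   `pygmies` (character vector), and `coordinates` (named list of
#'   `c(lat, lon)` per population, used with `sahelian_box: true`).
#' @param labels all population labels.
#' @return List with character vectors `sahelian` and `pygmies`.
#' @export
resolve_exclusions <- function(exclusions, labels) {
  sah <- as.character(unlist(exclusions$sahelian %||% character()))
  if (isTRUE(exclusions$sahelian_box) && !is.null(exclusions$coordinates)) {
    co <- exclusions$coordinates
    inbox <- vapply(names(co), function(l) {
      lat <- co[[l]][[1]]; lon <- co[[l]][[2]]
      lat >= 11.25 && lat <= 18.75 && lon >= -16.875 && lon <= 35.625
    }, logical(1))
    sah <- union(sah, names(co)[inbox])
  }
  list(sahelian = intersect(sah, labels),
       pygmies = intersect(as.character(unlist(exclusions$pygmies %||%
                                                 character())), labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipeline_iterations <- function(excl) {
  its <- list(all = character())
  if (length(excl$sahelian)) its$wo_sahelian <- excl$sahelian
  if (length(excl$pygmies)) its$wo_pygmies <- excl$pygmies
  if (length(excl$sahelian) && length(excl$pygmies))
    its$wo_sahelian_pygmies <- union(excl$sahelian, excl$pygmies)
  its
}

#' Run the full analysis pipeline from a config
#'
#' The config (YAML file or equivalent list) declares the inputs (either
#' file paths or a synthetic-generation block), the hybrid population,
#' region aggregation, exclusion sets, seeds and estimator settings. Per
#' exclusion iteration the pipeline writes haplogroup profiles, both
#' admixture tables, the diversity table, the pairwise exact-test matrix
#' and (when region labels match the packaged record) the historical
#' comparison, plus a JSON summary with seeds and a config hash. All
#' randomness flows from the single master seed, split per stage, so
#' reruns are byte-identical.
#'
#' @param config path to a YAML config, or a list with the same
#'   structure.
#' @param output_dir directory for output tables (default
#'   `config$output_dir`, or none if `NULL`: results only returned).
#' @return List of class `hvs_pipeline_report`: per-iteration results
#'   (`profiles`, `census`, `mcmc`, `sharing`, `diversity`,
#'   `exact_tests`, `historical`) plus `config_hash`, `seed`,
#'   `session`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  } else cfg_path <- NULL
  seed <- config$seed
  if (is.null(seed)) .hvs_error("pipeline config must set a seed",
                                "hvsadmix_bad_config")
  seed <- as.integer(seed)
  output_dir <- output_dir %||% config$output_dir
  window <- do.call(hvs_window, config$window %||% list())
  motifs <- if (is.null(config$motifs)) default_motif_table(window)
            else read_motif_table(config$motifs, window)
  scheme <- if (is.null(config$categories)) default_category_scheme()
            else read_category_scheme(config$categories)

  # ---- inputs -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input$synthetic)) {
    sy <- config$input$synthetic
    gc_args <- sy[intersect(names(sy),
                            c("profiles", "source_sizes", "hybrid_size",
                              "mixing", "founders_per_haplogroup",
                              "founder_extra", "mutation_mean",
                              "hybrid_mutation_mean"))]
    gc_args$profiles <- lapply(gc_args$profiles, unlist)
    if (!length(gc_args$profiles)) gc_args$profiles <- NULL
    gcfg <- do.call(generator_config,
                    c(gc_args, list(seed = seed, motifs = motifs,
                                    window = window)))
    src <- generate_sources(gcfg)
    hyb <- generate_admixed(src$samples, gcfg$mixing, gcfg$hybrid_size,
                            seed = seed + 1L,
                            mutation_mean = gcfg$hybrid_mutation_mean,
                            motifs = motifs, window = window)
    sources <- src$samples
    hybrid <- hyb$sample
    truth <- list(sources = src$truth, hybrid = hyb$truth)
  } else if (!is.null(config$input$path)) {
    all_samples <- read_population_table(config$input$path,
                                         config$input$format %||% "variant-tsv",
                                         window = window)
    hyb_lab <- config$hybrid_label %||% "Hybrid"
    if (!hyb_lab %in% names(all_samples))
      .hvs_error(sprintf("hybrid population '%s' not found in input", hyb_lab),
                 "hvsadmix_bad_config")
    hybrid <- all_samples[[hyb_lab]]
    sources <- all_samples[names(all_samples) != hyb_lab]
  } else .hvs_error("config must declare input$synthetic or input$path",
                    "hvsadmix_bad_config")

  # ---- hybrid census & admixture-stage filter ---------------------------
  census <- census_and_filter(hybrid, motifs, scheme)
  hybrid_f <- census$filtered

  excl <- resolve_exclusions(config$exclusions %||% list(), names(sources))
  iterations <- .pipeline_iterations(excl)
  sharing_m <- unlist(config$sharing_m %||% c(0L, 1L, 2L))
  mcmc_cfg <- do.call(mcmc_config,
                      c(config$mcmc %||% list(), list(seed = seed + 2L)))
  n_boot <- config$n_boot %||% 2000L
  et_cfg <- config$exact_test %||% list()

  report <- list()
  for (it in names(iterations)) {
    drop <- iterations[[it]]
    src_it <- aggregate_regions(sources[setdiff(names(sources), drop)],
                                config$regions)
    profs <- lapply(src_it, profile_counts, motifs = motifs, scheme = scheme)
    hyb_prof <- profile_counts(hybrid_f, motifs, scheme)
    mcmc_fit <- fit_admixture_mcmc(hyb_prof, unname(profs), mcmc_cfg)
    sharing <- list()
    for (m in sharing_m) {
      S <- build_sharing_matrix(hybrid_f, unname(src_it), m = m)
      sharing[[paste0("m", m)]] <-
        ancestry_proportions(S, n_boot = n_boot, seed = seed + 3L + m)
    }
    div <- diversity_table(c(list(hybrid_f), unname(src_it)),
                           fit_expansion = TRUE,
                           n_boot = config$expansion_boot %||% 0L,
                           seed = seed + 7L)
    et <- differentiation_tests(unname(profs),
                                chain_length = et_cfg$chain_length %||% 100000L,
                                dememorization = et_cfg$dememorization %||% 10000L,
                                seed = seed + 8L)
    hist_cmp <- tryCatch({
      fr <- regional_fractions(load_disembarkation_table())
      est <- stats::setNames(mcmc_fit$mean, mcmc_fit$source)
      if (length(intersect(names(est), names(fr)))) compare_estimates(est, fr)
      else NULL
    }, hvsadmix_error = function(e) NULL)
    res <- list(profiles = profile_table(c(profs, list(hyb_prof))),
                census = census[c("n", "n_excluded", "pct_african",
                                  "pct_other")],
                mcmc = mcmc_fit, sharing = sharing, diversity = div,
                exact_tests = et, historical = hist_cmp)
    if (!is.null(truth)) {
      truth_m <- truth$hybrid$mixing
      if (it == "all" && is.null(config$regions))
        res$recovery <- data.frame(
          source = mcmc_fit$source,
          truth = as.numeric(truth_m[mcmc_fit$source]),
          mcmc_mean = mcmc_fit$mean,
          abs_error = abs(mcmc_fit$mean -
                            as.numeric(truth_m[mcmc_fit$source])),
          stringsAsFactors = FALSE)
    }
    report[[it]] <- res
  }

  cfg_hash <- .config_hash(config)
  out <- structure(list(iterations = report, census = census,
                        truth = truth, seed = seed,
                        config_hash = cfg_hash,
                        session = list(package = "hvsadmix",
                                       version = as.character(
                                         utils::packageVersion("hvsadmix")),
                                       r = R.version.string)),
                   class = "hvs_pipeline_report")
  if (!is.null(output_dir)) .write_report(out, output_dir)
  invisible(out)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (it in names(report$iterations)) {
    d <- file.path(output_dir, it)
    dir.create(d, showWarnings = FALSE)
    r <- report$iterations[[it]]
    .write_tsv(r$profiles, file.path(d, "haplogroup_profiles.tsv"))
    .write_tsv(as.data.frame(r$mcmc), file.path(d, "admixture_mcmc.tsv"))
    sh <- do.call(rbind, lapply(names(r$sharing), function(mn) {
      x <- as.data.frame(r$sharing[[mn]])
      x$tolerance <- mn
      x
    }))
    .write_tsv(sh, file.path(d, "ancestry_sharing.tsv"))
    .write_tsv(r$diversity, file.path(d, "diversity.tsv"))
    pw <- as.data.frame(r$exact_tests$pairwise)
    pw <- cbind(population = rownames(pw), pw)
    .write_tsv(pw, file.path(d, "exact_test_pairwise.tsv"))
    if (!is.null(r$historical))
      .write_tsv(r$historical$table, file.path(d, "historical_comparison.tsv"))
  }
  summary <- list(seed = report$seed, config_hash = report$config_hash,
                  census = report$census[c("n", "n_excluded", "pct_african",
                                           "pct_other")],
                  session = report$session,
                  iterations = names(report$iterations))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.hvs_pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("hybrid census: %.1f%% sub-Saharan, %d lineage(s) excluded from admixture\n",
              x$census$pct_african, x$census$n_excluded))
  for (it in names(x$iterations)) {
    m <- x$iterations[[it]]$mcmc
    cat(sprintf("  [%s] profile-MCMC: %s\n", it,
                paste(sprintf("%s=%.3f", m$source, m$mean), collapse = " ")))
  }
  invisible(x)
}
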