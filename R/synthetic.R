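# Synthetic source and hybrid populations with known truth. Generation is
# star-like: each haplogroup contributes a few founder haplotypes (motif
# plus fixed founder-private variants); lineages copy a founder and add
# Poisson-many private substitutions at positions used by no motif, so the
# generating haplogroup is always recoverable and haplotype sharing
# between sources flows only through shared founders.

#' Configuration for the synthetic-population generator
#'
#' @param profiles named list: source label -> named probability vector
#'   over haplogroup labels (must exist in `motifs`). The default is
#'   three sources with well-separated profiles that share one low-weight
#'   haplogroup, emulating regional pools with distinct haplogroup
#'   compositions and partially shared haplotype stock.
#' @param source_sizes integer vector of lineages per source
#'   (default 500 each).
#' @param hybrid_size lineages in the admixed population (default 1000).
#' @param mixing true mixing vector over sources (default
#'   `c(0.5, 0.3, 0.2)` for the default profiles).
#' @param founders_per_haplogroup founder haplotypes per haplogroup
#'   (default 3).
#' @param founder_extra fixed founder-private variants added to the motif
#'   (default 2).
#' @param mutation_mean Poisson mean of private substitutions per lineage
#'   (default 2.5, giving HVS-I-like pairwise diversity).
#' @param hybrid_mutation_mean Poisson mean of additional mutations on
#'   hybrid lineages (default 0: hybrids copy source haplotypes exactly,
#'   so exact-match sharing is non-degenerate by construction).
#' @param seed integer seed (mandatory).
#' @param motifs an `hvs_motif_table`.
#' @param window an [hvs_window()].
#' @return List of class `hvs_generator_config`.
#' @export
generator_config <- function(profiles = NULL,
                             source_sizes = NULL,
                             hybrid_size = 1000L,
                             mixing = NULL,
                             founders_per_haplogroup = 3L,
                             founder_extra = 2L,
                             mutation_mean = 2.5,
                             hybrid_mutation_mean = 0,
                             seed,
                             motifs = default_motif_table(),
                             window = hvs_window()) {
  if (missing(seed)) .hvs_error("generator_config requires a seed",
                                "hvsadmix_bad_config")
  if (is.null(profiles)) {
    profiles <- list(
      SourceA = c(L2a1 = 0.4, L1b = 0.3, L2b = 0.2, L3e = 0.1),
      SourceB = c(L3e = 0.4, L3f = 0.3, L3b = 0.2, L2a1 = 0.1),
      SourceC = c(L0a = 0.4, U6a = 0.3, L1c = 0.2, L3e = 0.1))
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    .hvs_error("profiles must be a named list of sources", "hvsadmix_bad_config")
  for (p in profiles) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      .hvs_error("each source profile must be a probability vector",
                 "hvsadmix_bad_config")
    if (anyDuplicated(names(p)))
      .hvs_error("duplicate haplogroup labels in a source profile",
                 "hvsadmix_bad_config")
    miss <- setdiff(names(p), motifs$label)
    if (length(miss))
      .hvs_error(paste0("profile haplogroup(s) not in motif table: ",
                        paste(miss, collapse = ", ")), "hvsadmix_bad_config")
  }
  if (is.null(source_sizes)) source_sizes <- rep(500L, length(profiles))
  if (is.null(mixing)) {
    mixing <- if (length(profiles) == 3L) c(0.5, 0.3, 0.2)
              else rep(1 / length(profiles), length(profiles))
  }
  if (length(mixing) != length(profiles) || abs(sum(mixing) - 1) > 1e-8 ||
      any(mixing < 0))
    .hvs_error("mixing must be a probability vector over the sources",
               "hvsadmix_bad_config")
  if (any(source_sizes <= 0) || hybrid_size <= 0)
    .hvs_error("population sizes must be positive", "hvsadmix_bad_config")
  if (mutation_mean < 0 || hybrid_mutation_mean < 0)
    .hvs_error("mutation means must be >= 0", "hvsadmix_bad_config")
  structure(list(profiles = profiles,
                 source_sizes = as.integer(source_sizes),
                 hybrid_size = as.integer(hybrid_size),
                 mixing = mixing,
                 founders_per_haplogroup = as.integer(founders_per_haplogroup),
                 founder_extra = as.integer(founder_extra),
                 mutation_mean = mutation_mean,
                 hybrid_mutation_mean = hybrid_mutation_mean,
                 seed = as.integer(seed), motifs = motifs, window = window),
            class = "hvs_generator_config")
}

# positions free for private variation: inside the window, outside the
# excluded tract, and used by no motif in the table
.free_positions <- function(motifs, window) {
  motif_pos <- unique(unlist(lapply(motifs$motif, function(m)
    as.integer(floor(as.numeric(names(m)))))))
  setdiff(seq.int(window$start, window$end),
          c(motif_pos, window$excluded))
}

.mutate_haplotype <- function(h, k, free_pos, window) {
  if (k == 0L) return(h)
  taken <- as.integer(floor(as.numeric(names(h))))
  avail <- setdiff(free_pos, taken)
  pos <- avail[sample.int(length(avail), min(k, length(avail)))]
  bases <- c("A", "C", "G", "T")
  alt <- vapply(rcrs_base(pos), function(r)
    bases[-match(r, bases)][sample.int(3L, 1L)], character(1))
  all_pos <- c(as.numeric(names(h)), pos)
  all_alt <- c(unname(unclass(h)), alt)
  o <- order(all_pos)
  structure(stats::setNames(all_alt[o], .variant_key(all_pos[o])),
            id = attr(h, "id"), window = window, class = "hvs_haplotype")
}

#' Generate synthetic source populations
#'
#' @param cfg a [generator_config()].
#' @return List with `samples` (list of `hvs_population`, one per source)
#'   and `truth`: the generating profiles, the founder pool, and a
#'   per-lineage data.frame (`id`, `source`, `haplogroup`, `founder`).
#' @export
generate_sources <- function(cfg) {
  stopifnot(inherits(cfg, "hvs_generator_config"))
  old <- .hvs_set_seed(cfg$seed); on.exit(.hvs_restore_seed(old), add = TRUE)
  window <- cfg$window
  free_pos <- .free_positions(cfg$motifs, window)
  hgs <- unique(unlist(lapply(cfg$profiles, names)))
  founders <- list()
  for (hg in hgs) {
    motif <- cfg$motifs$motif[[match(hg, cfg$motifs$label)]]
    founders[[hg]] <- lapply(seq_len(cfg$founders_per_haplogroup), function(f) {
      h <- haplotype(if (length(motif)) haplotype_string(motif) else character(),
                     id = sprintf("%s_f%d", hg, f), window = window)
      .mutate_haplotype(h, cfg$founder_extra, free_pos, window)
    })
  }
  samples <- list()
  truth_rows <- list()
  for (s in seq_along(cfg$profiles)) {
    lab <- names(cfg$profiles)[s]
    prof <- cfg$profiles[[s]]
    nc <- cfg$source_sizes[s]
    hg_draw <- sample(names(prof), nc, replace = TRUE, prob = prof)
    haps <- vector("list", nc)
    f_idx <- integer(nc)
    for (i in seq_len(nc)) {
      f_idx[i] <- sample.int(cfg$founders_per_haplogroup, 1L)
      base <- founders[[hg_draw[i]]][[f_idx[i]]]
      h <- structure(base, id = sprintf("%s_%04d", lab, i),
                     window = window, class = "hvs_haplotype")
      haps[[i]] <- .mutate_haplotype(h, stats::rpois(1L, cfg$mutation_mean),
                                     free_pos, window)
    }
    samples[[lab]] <- population_sample(lab, haps)
    truth_rows[[lab]] <- data.frame(
      id = vapply(haps, function(h) attr(h, "id"), character(1)),
      source = lab, haplogroup = hg_draw, founder = f_idx,
      stringsAsFactors = FALSE)
  }
  list(samples = samples,
       truth = list(profiles = cfg$profiles,
                    founders = founders,
                    lineages = do.call(rbind, c(truth_rows,
                                                make.row.names = FALSE)),
                    seed = cfg$seed))
}

#' Generate an admixed population from sources
#'
#' Each hybrid lineage picks a source with probabilities `mixing` and
#' copies a uniformly chosen lineage from it (optionally adding
#' Poisson-many further private substitutions).
#'
#' @param sources list of `hvs_population` (e.g. from
#'   [generate_sources()]).
#' @param mixing probability vector over sources (true m).
#' @param n hybrid sample size.
#' @param seed integer seed.
#' @param label hybrid population label.
#' @param mutation_mean Poisson mean of post-admixture mutations
#'   (default 0: exact copies).
#' @param motifs,window used to locate motif-free positions when
#'   `mutation_mean > 0`.
#' @return List with `sample` (an `hvs_population`) and `truth`
#'   (per-lineage data.frame `id`, `source`, `origin_id`, plus `mixing`).
#' @export
generate_admixed <- function(sources, mixing, n, seed, label = "Hybrid",
                             mutation_mean = 0,
                             motifs = default_motif_table(),
                             window = hvs_window()) {
  if (length(mixing) != length(sources) || abs(sum(mixing) - 1) > 1e-8 ||
      any(mixing < 0))
    .hvs_error("mixing must be a probability vector over the sources",
               "hvsadmix_bad_config")
  old <- .hvs_set_seed(as.integer(seed)); on.exit(.hvs_restore_seed(old), add = TRUE)
  labs <- vapply(sources, `[[`, character(1), "label")
  free_pos <- if (mutation_mean > 0) .free_positions(motifs, window) else NULL
  src_draw <- sample.int(length(sources), n, replace = TRUE, prob = mixing)
  haps <- vector("list", n)
  origin <- character(n)
  for (i in seq_len(n)) {
    s <- sources[[src_draw[i]]]
    j <- sample.int(s$n, 1L)
    origin[i] <- as.character(attr(s$haplotypes[[j]], "id"))
    h <- structure(s$haplotypes[[j]], id = sprintf("%s_%04d", label, i),
                   window = window, class = "hvs_haplotype")
    if (mutation_mean > 0)
      h <- .mutate_haplotype(h, stats::rpois(1L, mutation_mean), free_pos,
                             window)
    haps[[i]] <- h
  }
  list(sample = population_sample(label, haps),
       truth = list(mixing = stats::setNames(mixing, labs),
                    lineages = data.frame(
                      id = vapply(haps, function(h) attr(h, "id"), character(1)),
                      source = labs[src_draw], origin_id = origin,
                      stringsAsFactors = FALSE),
                    seed = as.integer(seed)))
}

#' Write generator truth to a JSON sidecar
#'
#' @param truth a truth list from [generate_sources()] or
#'   [generate_admixed()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$founders <- NULL   # haplotype objects are not JSON-portable
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
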