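# Motif-based haplogroup assignment. The packaged motif table is a small
# curated HVS-I motif set for the macro-clades used in admixture work
# (L0-L5, U6, and representative non-L clades); it is a configuration
# artifact, deliberately coarse, and users supply richer tables (e.g.
# Phylotree-derived) for finer resolution.

#' Read a haplogroup motif table
#'
#' TSV with columns `label`, `parent`, `motif` (space-separated variant
#' tokens; empty for the reference/root node). Parent links must form a
#' tree rooted at a single node with an empty parent.
#'
#' @param path TSV file; defaults to the packaged curated table.
#' @param window an [hvs_window()].
#' @return Object of class `hvs_motif_table`: a data.frame with columns
#'   `label`, `parent`, `motif` (list of `hvs_haplotype`-like named
#'   vectors), `depth`.
#' @export
read_motif_table <- function(path = system.file("extdata", "motifs_hvs1.tsv",
                                                package = "hvsadmix"),
                             window = hvs_window()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  need <- c("label", "parent", "motif")
  if (!all(need %in% names(tab)))
    .hvs_error("motif table must have columns label, parent, motif",
               "hvsadmix_io_error")
  if (anyDuplicated(tab$label))
    .hvs_error("duplicate haplogroup labels in motif table",
               "hvsadmix_io_error")
  root <- tab$label[!nzchar(tab$parent)]
  if (length(root) != 1L)
    .hvs_error("motif table must have exactly one root (empty parent)",
               "hvsadmix_io_error")
  depth <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]; d <- 0L; seen <- character()
    while (nzchar(tab$parent[match(lab, tab$label)])) {
      seen <- c(seen, lab)
      lab <- tab$parent[match(lab, tab$label)]
      if (is.na(lab) || lab %in% seen)
        .hvs_error(sprintf("parent links of '%s' do not reach the root",
                           tab$label[i]), "hvsadmix_io_error")
      d <- d + 1L
    }
    depth[i] <- d
  }
  motifs <- lapply(tab$motif, function(m) haplotype(m, window = window))
  out <- data.frame(label = tab$label, parent = tab$parent,
                    depth = depth, stringsAsFactors = FALSE)
  out$motif <- motifs
  structure(out, class = c("hvs_motif_table", "data.frame"), root = root)
}

#' Default packaged motif table
#' @inheritParams read_motif_table
#' @return An `hvs_motif_table`.
#' @export
default_motif_table <- function(window = hvs_window()) {
  read_motif_table(window = window)
}

#' Assign a haplotype to a haplogroup by motif matching
#'
#' Each haplogroup is scored as (motif variants carried by the haplotype)
#' minus `penalty` times (motif variants absent from it); extra private
#' variants are never penalised, so adding a variant at a position absent
#' from every motif cannot change the assignment. The highest-scoring
#' label wins; ties are broken by deeper tree node, then lexicographically,
#' and flagged. Labels scoring below `threshold` are not eligible; if none
#' is eligible the haplotype is `"unclassified"`.
#'
#' @param h an `hvs_haplotype`.
#' @param motifs an `hvs_motif_table`.
#' @param penalty penalty per missing motif variant (default 1).
#' @param threshold minimum eligible score (default 0; the empty-motif
#'   root always scores 0, so an rCRS-identical haplotype maps to the
#'   root label).
#' @return List with `label`, `score`, `runner_up`, `tie` (logical).
#' @export
assign_haplogroup <- function(h, motifs, penalty = 1, threshold = 0) {
  if (!nrow(motifs)) .hvs_error("empty motif table", "hvsadmix_empty_motifs")
  score <- numeric(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    m <- motifs$motif[[i]]
    if (!length(m)) { score[i] <- 0; next }
    st <- h[names(m)]
    matched <- sum(!is.na(st) & st == m)
    score[i] <- matched - penalty * (length(m) - matched)
  }
  ok <- score >= threshold
  if (!any(ok))
    return(list(label = "unclassified", score = NA_real_,
                runner_up = NA_character_, tie = FALSE))
  ord <- order(-score, -motifs$depth, motifs$label)
  ord <- ord[ok[ord]]
  best <- ord[1]
  tie <- sum(score[ok] == score[best]) > 1L
  list(label = motifs$label[best], score = score[best],
       runner_up = if (length(ord) > 1L) motifs$label[ord[2]] else NA_character_,
       tie = tie)
}

#' Read a category scheme
#'
#' YAML with a `prefixes` map (haplogroup-label prefix to category) and a
#' `default` bucket for anything unmatched (the non-L/U6 paragroup in the
#' packaged scheme). Collapse uses longest-prefix match.
#'
#' @param path YAML file; defaults to the packaged scheme.
#' @return Object of class `hvs_category_scheme`: named character vector
#'   (prefix -> category) with attributes `default` and `categories`.
#' @export
read_category_scheme <- function(path = system.file("extdata",
                                                    "categories_default.yaml",
                                                    package = "hvsadmix")) {
  y <- yaml::read_yaml(path)
  map <- unlist(y$prefixes)
  structure(map, default = y$default,
            categories = unique(c(unname(map), y$default)),
            class = "hvs_category_scheme")
}

#' Default packaged category scheme
#' @return An `hvs_category_scheme`.
#' @export
default_category_scheme <- function() read_category_scheme()

#' Collapse a haplogroup label into a macro-category
#'
#' @param label haplogroup label (e.g. `"L2a1"`).
#' @param scheme an `hvs_category_scheme`.
#' @return Category name; the scheme default (non-L/U6 in the packaged
#'   scheme) when no prefix matches.
#' @examples
#' collapse_to_category("U6a", default_category_scheme()) # "U6"
#' @export
collapse_to_category <- function(label, scheme = default_category_scheme()) {
  pref <- names(scheme)
  hit <- pref[startsWith(label, pref)]
  if (!length(hit)) return(attr(scheme, "default"))
  unname(scheme[[hit[which.max(nchar(hit))]]])
}

#' Haplogroup-category profile of a population sample
#'
#' Assigns every lineage, collapses to categories, and tabulates counts.
#' Unclassified lineages (possible only with user motif tables lacking a
#' root) are counted separately so that
#' `sum(counts) + unclassified == n` always holds.
#'
#' @param sample an `hvs_population`.
#' @param motifs an `hvs_motif_table`.
#' @param scheme an `hvs_category_scheme`.
#' @param penalty,threshold passed to [assign_haplogroup()].
#' @return Object of class `hvs_profile`: list with `label`, `counts`
#'   (named integer over all scheme categories), `n`, `unclassified`,
#'   and per-lineage `assignments` data.frame.
#' @export
profile_counts <- function(sample, motifs = default_motif_table(),
                           scheme = default_category_scheme(),
                           penalty = 1, threshold = 0) {
  cats <- attr(scheme, "categories")
  # identical variant sets get identical assignments: classify unique types
  u <- .unique_haplotypes(sample$haplotypes)
  asg_u <- lapply(seq_along(u$haps), function(i) {
    h <- u$haps[[i]]
    tryCatch(assign_haplogroup(h, motifs, penalty, threshold),
             hvsadmix_error = function(e)
               .hvs_error(sprintf("sample '%s': %s", attr(h, "id"),
                                  conditionMessage(e)), class(e)[1]))
  })
  asg <- asg_u[match(u$key, u$ukey)]
  lab <- vapply(asg, `[[`, character(1), "label")
  cat_of <- ifelse(lab == "unclassified", NA_character_,
                   vapply(lab, collapse_to_category, character(1),
                          scheme = scheme))
  counts <- stats::setNames(integer(length(cats)), cats)
  tb <- table(factor(cat_of[!is.na(cat_of)], levels = cats))
  counts[names(tb)] <- as.integer(tb)
  haplogroup_profile(sample$label, counts, scheme = scheme,
                     unclassified = sum(is.na(cat_of)),
                     assignments = data.frame(
                       id = vapply(sample$haplotypes,
                                   function(h) as.character(attr(h, "id")),
                                   character(1)),
                       haplogroup = lab,
                       category = cat_of,
                       score = vapply(asg, `[[`, numeric(1), "score"),
                       tie = vapply(asg, `[[`, logical(1), "tie"),
                       stringsAsFactors = FALSE))
}

#' Construct a haplogroup-category profile directly from counts
#'
#' @param label population label.
#' @param counts named non-negative integer vector of category counts.
#' @param scheme optional `hvs_category_scheme` the categories belong to.
#' @param unclassified count of unclassified lineages (default 0).
#' @param assignments optional per-lineage assignment table.
#' @return An `hvs_profile` with `n = sum(counts) + unclassified`.
#' @export
haplogroup_profile <- function(label, counts, scheme = NULL,
                               unclassified = 0L, assignments = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    .hvs_error("profile counts must be named by category", "hvsadmix_bad_profile")
  if (any(counts < 0)) .hvs_error("negative category count", "hvsadmix_bad_profile")
  structure(list(label = label,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n = sum(as.integer(counts)) + as.integer(unclassified),
                 unclassified = as.integer(unclassified),
                 assignments = assignments),
            class = "hvs_profile")
}

#' @export
print.hvs_profile <- function(x, ...) {
  cat(sprintf("<haplogroup profile %s> n = %d", x$label, x$n))
  if (x$unclassified) cat(sprintf(" (%d unclassified)", x$unclassified))
  cat("\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Tabulate several profiles as a population-by-category table
#'
#' @param profiles list of `hvs_profile`.
#' @param freq if `TRUE`, report relative frequencies instead of counts.
#' @return data.frame with one row per population.
#' @export
profile_table <- function(profiles, freq = FALSE) {
  cats <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  m <- t(vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(cats)), cats)
    v[names(p$counts)] <- p$counts
    if (freq && sum(v) > 0) v <- v / sum(v)
    v
  }, numeric(length(cats))))
  data.frame(population = vapply(profiles, `[[`, character(1), "label"),
             n = vapply(profiles, `[[`, integer(1), "n"),
             m, check.names = FALSE, stringsAsFactors = FALSE)
}
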