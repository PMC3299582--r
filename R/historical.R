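# Historical disembarkation records for Jamaica (1651-1810), by decade and
# coastal region of embarkation, packaged for comparison of genetic
# ancestry estimates with the documentary record of the slave trade.

#' Load the packaged disembarkation table
#'
#' Imputed numbers of enslaved people disembarked in Jamaica per decade
#' (1651-1810) and embarkation region (Senegambia, Sierra Leone, Gold
#' Coast, Bight of Benin, Bight of Biafra, West-central Africa, Southeast
#' Africa). Row and column margins are validated against the packaged
#' totals at load time; any mismatch is an error.
#'
#' @return Object of class `hvs_disembarkation`: a data.frame of decade
#'   rows by region columns (integer persons) with attributes
#'   `region_totals` and `grand_total`.
#' @examples
#' sum(load_disembarkation_table()) # 701389
#' @export
load_disembarkation_table <- function() {
  path <- system.file("extdata", "disembarkation_jamaica.tsv",
                      package = "hvsadmix")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  totals <- tab[tab$decade == "Total", , drop = FALSE]
  body <- tab[tab$decade != "Total", , drop = FALSE]
  rownames(body) <- body$decade
  body$decade <- NULL
  regions <- setdiff(colnames(body), "Total")
  row_tot <- body$Total
  body$Total <- NULL
  m <- as.data.frame(lapply(body, as.integer), check.names = FALSE,
                     row.names = rownames(body))
  if (any(rowSums(m) != row_tot))
    .hvs_error("packaged table corrupt: row totals do not match",
               "hvsadmix_checksum")
  reg_tot <- unlist(totals[regions])
  if (any(colSums(m) != reg_tot))
    .hvs_error("packaged table corrupt: column totals do not match",
               "hvsadmix_checksum")
  if (sum(m) != totals$Total || sum(reg_tot) != totals$Total)
    .hvs_error("packaged table corrupt: grand total does not match",
               "hvsadmix_checksum")
  structure(m, class = c("hvs_disembarkation", "data.frame"),
            region_totals = stats::setNames(as.integer(reg_tot), regions),
            grand_total = as.integer(totals$Total))
}

#' Regional disembarkation fractions
#'
#' @param table an `hvs_disembarkation` table.
#' @param from,to decade range bounds (years; a decade is included when
#'   its start year lies in `[from, to]`). Defaults to the full span.
#' @return Named numeric vector of per-region fractions summing to 1.
#' @examples
#' regional_fractions(load_disembarkation_table())[["Gold Coast"]]
#' @export
regional_fractions <- function(table, from = 1651, to = 1810) {
  starts <- as.integer(sub("-.*", "", rownames(table)))
  keep <- starts >= from & starts <= to
  if (!any(keep)) .hvs_error("empty decade range", "hvsadmix_degenerate")
  tot <- colSums(table[keep, , drop = FALSE])
  tot / sum(tot)
}

#' Compare genetic ancestry estimates with historical fractions
#'
#' @param ancestry named numeric vector of per-region ancestry estimates
#'   (e.g. the `mean` column of an `hvs_admixture` named by `source`), or
#'   an `hvs_admixture` object.
#' @param fractions named numeric vector of historical fractions, as from
#'   [regional_fractions()].
#' @return List of class `hvs_divergence`: `table` (region, estimate,
#'   fraction, difference), `tv_distance` (total-variation distance over
#'   shared regions after renormalising both vectors to them),
#'   `rank_concordance` (Spearman correlation of ranks), `unmatched`
#'   (regions present on one side only, e.g. East Africa, which the
#'   historical record does not list as an Atlantic embarkation region).
#' @examples
#' compare_estimates(c(A = 0.5, B = 0.5), c(A = 0.9, B = 0.1))$tv_distance # 0.4
#' @export
compare_estimates <- function(ancestry, fractions) {
  if (inherits(ancestry, "hvs_admixture"))
    ancestry <- stats::setNames(ancestry$mean, ancestry$source)
  shared <- intersect(names(ancestry), names(fractions))
  if (!length(shared))
    .hvs_error("no shared region labels between estimate and record",
               "hvsadmix_label_mismatch")
  a <- ancestry[shared] / sum(ancestry[shared])
  f <- fractions[shared] / sum(fractions[shared])
  tv <- sum(abs(a - f)) / 2
  rc <- if (length(shared) >= 3L)
    stats::cor(rank(a), rank(f), method = "spearman") else NA_real_
  structure(list(
    table = data.frame(region = shared, estimate = unname(a),
                       fraction = unname(f),
                       difference = unname(a - f),
                       stringsAsFactors = FALSE),
    tv_distance = tv, rank_concordance = rc,
    unmatched = list(estimate_only = setdiff(names(ancestry), shared),
                     record_only = setdiff(names(fractions), shared))),
    class = "hvs_divergence")
}

#' @export
print.hvs_divergence <- function(x, ...) {
  print(x$table, digits = 3)
  cat(sprintf("total-variation distance %.3f; rank concordance %s\n",
              x$tv_distance, format(x$rank_concordance, digits = 3)))
  if (length(x$unmatched$estimate_only))
    cat("estimate regions without historical column:",
        paste(x$unmatched$estimate_only, collapse = ", "), "\n")
  invisible(x)
}
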