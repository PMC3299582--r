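# Haplotypes are stored as named character vectors: names are position keys
# ("16223" for substitutions/deletions, "16193.1" for insertions), values are
# the observed state ("T", "d" for a deletion, or an inserted base). The
# reference state is implicit: a position absent from the vector carries the
# rCRS base. Sample id and window travel as attributes.

.hvs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hvsadmix_error")))
}

#' Parse a variant token in rCRS notation
#'
#' Tokens follow the HVS-I literature dialect:
#' * substitution: `C16223T` (rCRS base, position, observed base);
#' * deletion: `C16166d`;
#' * insertion: `16193.1C` (position, insertion index, inserted base).
#'
#' The rCRS base in a substitution/deletion token is checked against the
#' packaged reference; a mismatch is an error of class
#' `hvsadmix_ref_mismatch`. Malformed tokens raise
#' `hvsadmix_malformed_token`; positions outside the window raise
#' `hvsadmix_position_outside_window`.
#'
#' @param token a single variant token.
#' @param window an [hvs_window()].
#' @return A list of class `hvs_variant` with fields `pos` (numeric;
#'   fractional for insertions), `ref`, `alt`, `type`
#'   (`"substitution"`, `"deletion"` or `"insertion"`).
#' @examples
#' parse_variant("C16223T")
#' @export
parse_variant <- function(token, window = hvs_window()) {
  if (length(token) != 1L || !is.character(token) || is.na(token))
    .hvs_error("variant token must be a single string", "hvsadmix_malformed_token")
  token <- toupper(trimws(token))
  if (grepl("^[ACGT][0-9]+[ACGT]$", token)) {
    ref <- substr(token, 1L, 1L)
    pos <- as.integer(substr(token, 2L, nchar(token) - 1L))
    alt <- substr(token, nchar(token), nchar(token))
    type <- "substitution"
  } else if (grepl("^[ACGT]?[0-9]+D$", token)) {
    has_ref <- grepl("^[ACGT]", token)
    ref <- if (has_ref) substr(token, 1L, 1L) else NA_character_
    pos <- as.integer(gsub("[^0-9]", "", token))
    alt <- "d"
    type <- "deletion"
  } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", token)) {
    pos <- as.numeric(sub("[ACGT]$", "", token))
    ref <- "-"
    alt <- substr(token, nchar(token), nchar(token))
    type <- "insertion"
  } else {
    .hvs_error(sprintf("malformed variant token '%s'", token),
               "hvsadmix_malformed_token")
  }
  base_pos <- as.integer(floor(pos))
  if (base_pos < window$start || base_pos > window$end)
    .hvs_error(sprintf("position %d outside analysis window %d-%d",
                       base_pos, window$start, window$end),
               "hvsadmix_position_outside_window")
  if (type != "insertion") {
    rbase <- rcrs_base(base_pos)
    if (is.na(ref)) ref <- rbase
    if (ref != rbase)
      .hvs_error(sprintf("token '%s' states rCRS base %s at %d but rCRS has %s",
                         token, ref, base_pos, rbase),
                 "hvsadmix_ref_mismatch")
    if (type == "substitution" && alt == ref)
      .hvs_error(sprintf("token '%s' is not a variant: alt equals rCRS base",
                         token), "hvsadmix_malformed_token")
  }
  structure(list(pos = pos, ref = ref, alt = alt, type = type),
            class = "hvs_variant")
}

#' Format a variant back into token notation
#' @param v an `hvs_variant`.
#' @return Character token such as `"C16223T"`.
#' @export
variant_token <- function(v) {
  switch(v$type,
         substitution = paste0(v$ref, format(v$pos, scientific = FALSE), v$alt),
         deletion     = paste0(v$ref, format(v$pos, scientific = FALSE), "d"),
         insertion    = paste0(format(v$pos, nsmall = 1, scientific = FALSE), v$alt))
}

.variant_key <- function(pos) {
  # "16223" for integral positions, "16193.1" for insertion positions
  ifelse(pos == floor(pos), format(as.integer(pos), scientific = FALSE),
         format(pos, nsmall = 1, scientific = FALSE))
}

#' Build a haplotype from variant tokens
#'
#' Insertions and deletions inside the window's excluded poly-C tract are
#' dropped (length polymorphism there is not scored); substitutions in the
#' tract are kept. At most one variant may remain per position.
#'
#' @param tokens character vector of variant tokens (or a single
#'   space-separated string); may be empty for an rCRS-identical lineage.
#' @param id sample identifier.
#' @param window an [hvs_window()].
#' @return Named character vector of class `hvs_haplotype` (possibly
#'   length 0) with attributes `id` and `window`.
#' @examples
#' haplotype("C16223T C16278T", id = "JM001")
#' @export
haplotype <- function(tokens = character(), id = NA_character_,
                      window = hvs_window()) {
  tokens <- tokens[!is.na(tokens)]
  tokens <- unlist(strsplit(trimws(toupper(tokens)), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  # fast path for plain substitutions (the overwhelming case); indels and
  # malformed tokens take the general parser
  is_sub <- grepl("^[ACGT][0-9]+[ACGT]$", tokens)
  pos <- numeric(length(tokens)); alt <- character(length(tokens))
  if (any(is_sub)) {
    tk <- tokens[is_sub]
    p <- as.integer(substr(tk, 2L, nchar(tk) - 1L))
    a <- substr(tk, nchar(tk), nchar(tk))
    r <- substr(tk, 1L, 1L)
    bad <- p < window$start | p > window$end
    if (any(bad))
      .hvs_error(sprintf("position %d outside analysis window %d-%d",
                         p[bad][1], window$start, window$end),
                 "hvsadmix_position_outside_window")
    mism <- r != rcrs_base(p)
    if (any(mism))
      .hvs_error(sprintf("token '%s' states rCRS base %s at %d but rCRS has %s",
                         tk[mism][1], r[mism][1], p[mism][1],
                         rcrs_base(p[mism][1])),
                 "hvsadmix_ref_mismatch")
    if (any(a == r))
      .hvs_error(sprintf("token '%s' is not a variant: alt equals rCRS base",
                         tk[a == r][1]), "hvsadmix_malformed_token")
    pos[is_sub] <- p; alt[is_sub] <- a
  }
  if (any(!is_sub)) {
    vars <- lapply(tokens[!is_sub], parse_variant, window = window)
    keep_v <- vapply(vars, function(v) !(floor(v$pos) %in% window$excluded),
                     logical(1))
    pos[!is_sub] <- vapply(vars, `[[`, numeric(1), "pos")
    alt[!is_sub] <- vapply(vars, `[[`, character(1), "alt")
    keep <- is_sub; keep[!is_sub] <- keep_v
    pos <- pos[keep]; alt <- alt[keep]
  }
  if (anyDuplicated(pos))
    .hvs_error(sprintf("duplicate variant position(s) %s in haplotype '%s'",
                       paste(unique(pos[duplicated(pos)]), collapse = ", "), id),
               "hvsadmix_duplicate_position")
  o <- order(pos)
  structure(stats::setNames(alt[o], .variant_key(pos[o])),
            id = id, window = window, class = "hvs_haplotype")
}

#' @export
print.hvs_haplotype <- function(x, ...) {
  cat(sprintf("<haplotype %s> %s\n", attr(x, "id"),
              if (length(x)) haplotype_string(x) else "(rCRS)"))
  invisible(x)
}

#' Serialize a haplotype to space-separated variant tokens
#' @param h an `hvs_haplotype`.
#' @return Single string; empty string for an rCRS-identical haplotype.
#' @export
haplotype_string <- function(h) {
  if (!length(h)) return("")
  keys <- names(h)
  pos <- as.numeric(keys)
  toks <- character(length(h))
  for (i in seq_along(h)) {
    if (pos[i] == floor(pos[i])) {
      ref <- rcrs_base(pos[i])
      toks[i] <- if (h[[i]] == "d") paste0(ref, keys[i], "d")
                 else paste0(ref, keys[i], h[[i]])
    } else {
      toks[i] <- paste0(keys[i], h[[i]])
    }
  }
  paste(toks, collapse = " ")
}

#' Call a haplotype from an aligned sequence
#'
#' The sequence must be aligned to the window (same length, `-` for a
#' deleted base). Differences from rCRS are recorded as variants; IUPAC
#' ambiguity codes and `N` are treated as no-calls; deletions inside the
#' excluded poly-C tract are ignored so that length polymorphism there
#' never contributes.
#'
#' @param seq a single nucleotide string aligned to `window`.
#' @param window an [hvs_window()].
#' @param id sample identifier.
#' @return An `hvs_haplotype`.
#' @examples
#' haplotype_from_sequence(rcrs_segment(), id = "ref") # empty variant set
#' @export
haplotype_from_sequence <- function(seq, window = hvs_window(),
                                    id = NA_character_) {
  seq <- toupper(gsub("\\s", "", seq))
  width <- window$end - window$start + 1L
  if (nchar(seq) != width)
    .hvs_error(sprintf("aligned sequence length %d does not match window length %d",
                       nchar(seq), width), "hvsadmix_length_mismatch")
  chars <- strsplit(seq, "")[[1]]
  ok <- chars %in% c("A", "C", "G", "T", "-", "N", "R", "Y", "S", "W", "K",
                     "M", "B", "D", "H", "V", ".")
  if (!all(ok))
    .hvs_error(sprintf("non-IUPAC character(s): %s",
                       paste(unique(chars[!ok]), collapse = " ")),
               "hvsadmix_bad_character")
  ref <- strsplit(rcrs_segment(window), "")[[1]]
  pos <- seq.int(window$start, window$end)
  tokens <- character()
  for (i in seq_len(width)) {
    s <- chars[i]
    if (s == ref[i] || s %in% c("N", ".", "R", "Y", "S", "W", "K", "M",
                                "B", "D", "H", "V")) next
    if (s == "-") {
      if (pos[i] %in% window$excluded) next
      tokens <- c(tokens, paste0(ref[i], pos[i], "d"))
    } else {
      tokens <- c(tokens, paste0(ref[i], pos[i], s))
    }
  }
  haplotype(tokens, id = id, window = window)
}

#' Number of mismatches between two haplotypes
#'
#' The distance is the number of positions at which the two lineages carry
#' different states; two different variants at the same position count one
#' mismatch, not two. It is a metric on variant sets.
#'
#' @param h1,h2 `hvs_haplotype` objects on the same window.
#' @return Non-negative integer.
#' @examples
#' mismatch_distance(haplotype("C16223T"), haplotype("C16223A")) # 1
#' @export
mismatch_distance <- function(h1, h2) {
  if (!length(h1) && !length(h2)) return(0L)
  keys <- union(names(h1), names(h2))
  s1 <- h1[keys]; s2 <- h2[keys]
  s1[is.na(s1)] <- "."; s2[is.na(s2)] <- "."
  sum(s1 != s2)
}

# Canonical key for collapsing identical haplotypes.
.hap_key <- function(h) paste(names(h), unname(h), sep = ">", collapse = " ")

# Collapse a list of haplotypes into unique types with counts.
# Returns list(haps = list of representative haplotypes, counts = integer).
.unique_haplotypes <- function(haps) {
  keys <- vapply(haps, .hap_key, character(1))
  idx <- !duplicated(keys)
  list(haps = haps[idx], counts = as.integer(table(factor(keys, levels = keys[idx]))),
       key = keys, ukey = keys[idx])
}

# Pairwise mismatch distances between unique haplotypes (k x k matrix).
.hap_distance_matrix <- function(haps) {
  k <- length(haps)
  d <- matrix(0L, k, k)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      d[i, j] <- d[j, i] <- mismatch_distance(haps[[i]], haps[[j]])
    }
  }
  d
}

#' Construct a population sample
#'
#' @param label population / region name (non-empty).
#' @param haplotypes list of `hvs_haplotype`.
#' @return Object of class `hvs_population` with fields `label`,
#'   `haplotypes`, and lineage count `n`.
#' @export
population_sample <- function(label, haplotypes) {
  if (!is.character(label) || !nzchar(label))
    .hvs_error("population label must be non-empty", "hvsadmix_bad_label")
  structure(list(label = label, haplotypes = haplotypes,
                 n = length(haplotypes)),
            class = "hvs_population")
}

#' @export
print.hvs_population <- function(x, ...) {
  cat(sprintf("<population %s> n = %d lineages\n", x$label, x$n))
  invisible(x)
}

#' Read population samples from a variant table or FASTA
#'
#' Variant tables are TSV with columns `sample_id`, `population`,
#' `variants` (space-separated tokens; empty for rCRS-identical). FASTA
#' records use headers `id|population` and must be aligned to the window.
#'
#' @param path file path.
#' @param format `"variant-tsv"` or `"fasta"`.
#' @param window an [hvs_window()].
#' @return Named list of [population_sample()] objects, one per population,
#'   in order of first appearance.
#' @export
read_population_table <- function(path, format = c("variant-tsv", "fasta"),
                                  window = hvs_window()) {
  format <- match.arg(format)
  if (!file.exists(path)) .hvs_error(paste0("no such file: ", path),
                                     "hvsadmix_io_error")
  if (format == "variant-tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("sample_id", "population", "variants")
    if (!all(need %in% names(tab)))
      .hvs_error(paste0("variant table must have columns ",
                        paste(need, collapse = ", ")), "hvsadmix_io_error")
    ids <- tab$sample_id
    pops <- tab$population
    haps <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      haps[[i]] <- tryCatch(
        haplotype(tab$variants[i], id = ids[i], window = window),
        hvsadmix_error = function(e)
          .hvs_error(sprintf("row %d (sample '%s'): %s", i, ids[i],
                             conditionMessage(e)), "hvsadmix_io_error"))
    }
  } else {
    dna <- ape::read.FASTA(path)
    hdr <- names(dna)
    parts <- strsplit(hdr, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      .hvs_error("FASTA headers must be 'id|population'", "hvsadmix_io_error")
    ids <- vapply(parts, `[`, character(1), 1L)
    pops <- vapply(parts, `[`, character(1), 2L)
    seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
    haps <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      haps[[i]] <- haplotype_from_sequence(seqs[i], window = window, id = ids[i])
    }
  }
  if (anyDuplicated(ids))
    .hvs_error(sprintf("duplicate sample id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "hvsadmix_io_error")
  out <- list()
  for (lab in unique(pops)) {
    out[[lab]] <- population_sample(lab, haps[pops == lab])
  }
  out
}

#' Write population samples to a variant-list TSV
#' @param samples list of `hvs_population`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = vapply(s$haplotypes,
                                  function(h) as.character(attr(h, "id")),
                                  character(1)),
               population = s$label,
               variants = vapply(s$haplotypes, haplotype_string, character(1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write population samples as aligned FASTA
#'
#' Sequences are the rCRS window with each haplotype's substitutions
#' applied and deletions shown as `-`; insertions cannot be represented in
#' the fixed window and raise an error.
#'
#' @param samples list of `hvs_population`.
#' @param path output file.
#' @param window an [hvs_window()].
#' @return `path`, invisibly.
#' @export
write_population_fasta <- function(samples, path, window = hvs_window()) {
  ref <- strsplit(rcrs_segment(window), "")[[1]]
  seqs <- list(); nm <- character()
  for (s in samples) {
    for (h in s$haplotypes) {
      x <- ref
      for (k in seq_along(h)) {
        p <- as.numeric(names(h)[k])
        if (p != floor(p))
          .hvs_error("insertions cannot be written to aligned FASTA",
                     "hvsadmix_io_error")
        x[as.integer(p) - window$start + 1L] <-
          if (h[[k]] == "d") "-" else h[[k]]
      }
      nm <- c(nm, paste0(attr(h, "id"), "|", s$label))
      seqs <- c(seqs, list(tolower(x)))
    }
  }
  names(seqs) <- nm
  ape::write.FASTA(ape::as.DNAbin(seqs), path)
  invisible(path)
}
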