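# Shared builders for small in-code fixtures.

toy_population <- function(label = "Toy",
                           variant_strings = list("C16223T C16278T",
                                                  "C16223T",
                                                  "C16223T C16278T T16311C",
                                                  "",
                                                  "C16223T C16278T")) {
  haps <- lapply(seq_along(variant_strings), function(i)
    haplotype(variant_strings[[i]], id = sprintf("%s%02d", label, i)))
  population_sample(label, haps)
}

# random haplotype over motif-free positions, for property tests
random_haplotype <- function(n_var, id = "r", window = hvs_window()) {
  pos <- sample(setdiff(seq(window$start, window$end), window$excluded), n_var)
  toks <- vapply(pos, function(p) {
    ref <- rcrs_base(p)
    paste0(ref, p, sample(setdiff(c("A", "C", "G", "T"), ref), 1))
  }, character(1))
  haplotype(toks, id = id, window = window)
}

# independent mismatch oracle: plain symmetric difference over position
# states, written without reference to the package internals
oracle_mismatch <- function(h1, h2) {
  st <- function(h) {
    out <- list()
    if (length(h)) for (i in seq_along(h)) out[[names(h)[i]]] <- h[[i]]
    out
  }
  s1 <- st(h1); s2 <- st(h2)
  keys <- union(names(s1), names(s2))
  n <- 0L
  for (k in keys) {
    a <- if (is.null(s1[[k]])) "ref" else s1[[k]]
    b <- if (is.null(s2[[k]])) "ref" else s2[[k]]
    if (a != b) n <- n + 1L
  }
  n
}

# two-source profiles with disjoint category support
disjoint_profiles <- function(n_a = 200L, n_b = 200L) {
  list(a = haplogroup_profile("A", c(L2a = round(0.7 * n_a),
                                     L1b = n_a - round(0.7 * n_a),
                                     L3e = 0L, L3f = 0L)),
       b = haplogroup_profile("B", c(L2a = 0L, L1b = 0L,
                                     L3e = round(0.6 * n_b),
                                     L3f = n_b - round(0.6 * n_b))))
}
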