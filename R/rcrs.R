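# Packaged rCRS (NC_012920.1) segment spanning the HVS-I analysis window.
# Stored as one string; position 16024 is the first character.
.RCRS_HVS1_START <- 16024L
.RCRS_HVS1 <- paste0(
  "TTCTTTCATGGGGAAGCAGATTTGGGTACCACCCAAGTATTGACTCACCC", # 16024-16073
  "ATCAACAACCGCTATGTATTTCGTACATTACTGCCAGCCACCATGAATAT", # 16074-16123
  "TGTACGGTACCATAAATACTTGACCACCTGTAGTACATAAAAACCCAATC", # 16124-16173
  "CACATCAAAACCCCCTCCCCATGCTTACAAGCAAGTACAGCAATCAACCC", # 16174-16223
  "TCAACTATCACACATCAACTGCAACTCCAAAGCCACCCCTCACCCACTAG", # 16224-16273
  "GATACCAACAAACCTACCCACCCTTAACAGTACATAGTACATAAAGCCAT", # 16274-16323
  "TTACCGTACATAGCACATTACAGTCAAATCCCTTCTCGTCCC"          # 16324-16365
)

#' HVS-I analysis window
#'
#' Describes the rCRS coordinate window on which haplotypes are expressed,
#' together with the poly-cytosine tract whose length polymorphism is
#' ignored (insertions/deletions there are dropped; substitutions such as
#' C16184T or T16189C are kept).
#'
#' @param start,end 1-based inclusive rCRS coordinates. The default window
#'   16024-16365 covers the positions conventionally reported for HVS-I.
#' @param excluded_start,excluded_end the tract excluded for length
#'   polymorphism (default 16184-16193).
#' @return An object of class `hvs_window` with fields `start`, `end`,
#'   `excluded` (integer vector of positions).
#' @examples
#' hvs_window()
#' @export
hvs_window <- function(start = 16024L, end = 16365L,
                       excluded_start = 16184L, excluded_end = 16193L) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start < end)) stop("window start must be < end")
  if (start < .RCRS_HVS1_START || end > .RCRS_HVS1_START + nchar(.RCRS_HVS1) - 1L)
    stop("window must lie within the packaged rCRS segment (",
         .RCRS_HVS1_START, "-", .RCRS_HVS1_START + nchar(.RCRS_HVS1) - 1L, ")")
  excluded <- seq.int(as.integer(excluded_start), as.integer(excluded_end))
  if (any(excluded < start) || any(excluded > end))
    stop("excluded interval must lie within [start, end]")
  structure(list(start = start, end = end, excluded = excluded),
            class = "hvs_window")
}

#' rCRS reference base(s)
#'
#' @param pos integer rCRS position(s) within the packaged segment.
#' @return Character vector of upper-case reference bases.
#' @examples
#' rcrs_base(16223) # "C"
#' @export
rcrs_base <- function(pos) {
  pos <- as.integer(pos)
  off <- pos - .RCRS_HVS1_START + 1L
  if (any(is.na(off)) || any(off < 1L) || any(off > nchar(.RCRS_HVS1)))
    stop("position outside the packaged rCRS segment")
  vapply(off, function(i) substr(.RCRS_HVS1, i, i), character(1))
}

#' rCRS HVS-I segment for a window
#'
#' @param window an [hvs_window()].
#' @return Single string, one character per window position.
#' @export
rcrs_segment <- function(window = hvs_window()) {
  substr(.RCRS_HVS1, window$start - .RCRS_HVS1_START + 1L,
         window$end - .RCRS_HVS1_START + 1L)
}

#' @export
print.hvs_window <- function(x, ...) {
  cat(sprintf("HVS-I window %d-%d (rCRS), length-polymorphism tract %d-%d excluded\n",
              x$start, x$end, min(x$excluded), max(x$excluded)))
  invisible(x)
}
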