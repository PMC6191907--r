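#' Fragments per kilobase per million mapped fragments
#'
#' fpkm = count x 10^9 / (length x total_mapped). Counts are fragments
#' (read pairs; single-end reads count as one fragment) and are assumed to
#' come from uniquely placed alignments with at most 1% mismatches.
#'
#' @param count fragment count(s) for the gene(s).
#' @param length_nt gene length(s) in nt (> 0).
#' @param total_mapped library size: total counted fragments (> 0).
#' @return FPKM value(s), non-negative.
#' @export
fpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("gene lengths must be positive")
  if (length(total_mapped) != 1L || total_mapped <= 0) {
    stop("'total_mapped' must be a single positive library size")
  }
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e9 / (length_nt * total_mapped)
}

#' FPKM table from a per-gene fragment count table
#'
#' The library size is the sum of counted fragments across all annotated
#' genes (recorded as attribute \code{total_mapped}).
#'
#' @param counts data.frame with columns \code{gene_id}, \code{length},
#'   \code{count}, e.g. from [sim_count_table()].
#' @return the input with an added \code{fpkm} column.
#' @export
fpkm_table <- function(counts) {
  stopifnot(all(c("gene_id", "length", "count") %in% names(counts)))
  total <- sum(counts$count)
  counts$fpkm <- fpkm(counts$count, counts$length, total)
  attr(counts, "total_mapped") <- total
  counts
}
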