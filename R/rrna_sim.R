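#' Plan of excluded (fragmentation) intervals for a simulated rRNA locus
#'
#' @param locus_id locus identifier.
#' @param reference_length locus length in nt.
#' @param excluded_intervals two-column matrix or data.frame of 1-based
#'   inclusive \code{start}, \code{end} intervals from which no read may be
#'   sampled (the planted fragmentation regions); may be \code{NULL}.
#' @return list of class \code{"gap_plan"}.
#' @export
gap_plan <- function(locus_id, reference_length, excluded_intervals = NULL) {
  stopifnot(reference_length >= 1)
  if (!is.null(excluded_intervals)) {
    iv <- as.matrix(as.data.frame(excluded_intervals)[, 1:2])
    colnames(iv) <- c("start", "end")
    iv <- iv[order(iv[, "start"]), , drop = FALSE]
    if (any(iv[, "start"] > iv[, "end"])) stop("interval start > end")
    if (any(iv < 1) || any(iv > reference_length)) {
      stop("intervals must lie within [1, reference_length]")
    }
    if (nrow(iv) > 1 &&
        any(iv[-1, "start"] <= iv[-nrow(iv), "end"])) {
      stop("intervals must not overlap")
    }
  } else {
    iv <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  }
  structure(list(locus_id = locus_id,
                 reference_length = as.integer(reference_length),
                 excluded_intervals = iv),
            class = "gap_plan")
}

#' Simulate reads from an rRNA locus with planted coverage gaps
#'
#' A random reference sequence is generated (or a supplied one used) and
#' \code{n_reads} reads of fixed length are sampled uniformly from the start
#' positions whose full span avoids every excluded interval, so the planted
#' intervals have exactly zero true coverage. Sequencing errors are opt-in
#' uniform substitutions at rate \code{per_base_error} (default 0, keeping
#' mapping exact).
#'
#' @param plan a [gap_plan()].
#' @param reference optional reference sequence (single character string of
#'   A/C/G/T, length matching the plan); randomly generated when NULL.
#' @param read_length read length in nt (<= reference length).
#' @param n_reads number of reads to sample.
#' @param per_base_error substitution probability per base.
#' @param seed optional integer seed.
#' @return list with \code{reads} (data.frame \code{read_id}, \code{start},
#'   \code{sequence}), \code{truth_coverage} (integer vector, exact per-base
#'   coverage of the placements), \code{reference} (character string) and
#'   \code{plan}.
#' @export
sim_rrna_reads <- function(plan, reference = NULL, read_length = 100,
                           n_reads = 1000, per_base_error = 0, seed = NULL) {
  stopifnot(inherits(plan, "gap_plan"),
            read_length >= 1, read_length <= plan$reference_length,
            n_reads >= 1, per_base_error >= 0, per_base_error < 1)
  if (!is.null(seed)) set.seed(seed)
  L <- plan$reference_length
  bases <- c("A", "C", "G", "T")
  if (is.null(reference)) {
    reference <- paste(sample(bases, L, replace = TRUE), collapse = "")
  } else if (nchar(reference) != L) {
    stop("'reference' length does not match the plan")
  }

  # valid start positions: [s, s + read_length - 1] misses every interval
  valid <- rep(TRUE, L - read_length + 1L)
  iv <- plan$excluded_intervals
  for (k in seq_len(nrow(iv))) {
    lo <- max(1L, iv[k, "start"] - read_length + 1L)
    hi <- min(length(valid), iv[k, "end"])
    if (lo <= hi) valid[lo:hi] <- FALSE
  }
  starts_pool <- which(valid)
  if (length(starts_pool) == 0L) {
    stop("excluded intervals leave no valid read start position")
  }
  starts <- starts_pool[sample.int(length(starts_pool), n_reads,
                                   replace = TRUE)]
  seqs <- substring(reference, starts, starts + read_length - 1L)

  if (per_base_error > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    seqs <- vapply(chars, function(s) {
      hit <- stats::runif(length(s)) < per_base_error
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
  }

  cov <- integer(L)
  tab <- tabulate(starts, nbins = L)
  # coverage at p = number of starts in (p - read_length, p]
  cs <- cumsum(tab)
  lagged <- c(rep(0L, read_length), cs[seq_len(L - read_length)])
  cov <- cs - lagged

  list(reads = data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
                          start = starts, sequence = seqs,
                          stringsAsFactors = FALSE),
       truth_coverage = as.integer(cov),
       reference = reference,
       plan = plan)
}

#' Write reads as FASTQ with a constant quality
#'
#' @param reads data.frame with \code{read_id} and \code{sequence}.
#' @param path output file.
#' @param quality_char single Phred quality character applied to every base.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence,
                           "+",
                           vapply(nchar(reads$sequence), function(n)
                             strrep(quality_char, n), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read sequences from FASTQ as a character vector
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}
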