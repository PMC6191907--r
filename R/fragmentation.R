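#' Full-length, high-identity read placement by exhaustive scan
#'
#' Each read (and its reverse complement) is scanned over every offset of
#' every reference; a placement is acceptable when the read matches over its
#' complete length with at most \code{floor(max_mismatch_frac * read
#' length)} mismatches (no indels), i.e. an identity of at least 99% at the
#' default. Among the acceptable placements with the fewest mismatches one
#' is chosen uniformly at random with the seeded generator, so reads mapping
#' equally well to near-identical rRNA gene copies are assigned once,
#' reproducibly. Unplaceable reads are reported with \code{mapped = FALSE}.
#'
#' @param reads character vector of read sequences (names used as read ids),
#'   or a data.frame with \code{read_id} and \code{sequence} columns, or a
#'   FASTQ file path.
#' @param references named character vector of reference sequences, a
#'   \code{DNAStringSet}, or a FASTA file path.
#' @param max_mismatch_frac maximum mismatch fraction per read (default
#'   0.01).
#' @param seed optional integer seed for the tie-break.
#' @return data.frame with one row per read: \code{read_id}, \code{locus},
#'   \code{start}, \code{end}, \code{strand}, \code{mismatches},
#'   \code{mapped}; attribute \code{n_unmapped}.
#' @export
map_reads <- function(reads, references, max_mismatch_frac = 0.01,
                      seed = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$sequence, reads$read_id)
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  }
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    references <- Biostrings::readDNAStringSet(references)
  }
  refs <- Biostrings::DNAStringSet(references)
  if (is.null(names(refs))) {
    names(refs) <- sprintf("locus_%d", seq_along(refs))
  }
  if (!is.null(seed)) set.seed(seed)

  res <- vector("list", length(reads))
  n_unmapped <- 0L
  for (i in seq_along(reads)) {
    pat <- Biostrings::DNAString(reads[[i]])
    k <- floor(max_mismatch_frac * length(pat))
    hits <- list()
    for (j in seq_along(refs)) {
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(p, refs[[j]], max.mismatch = k,
                                      with.indels = FALSE)
        if (length(m) > 0L) {
          st <- Biostrings::start(m)
          mm <- Biostrings::neditStartingAt(p, refs[[j]], starting.at = st,
                                            with.indels = FALSE)
          keep <- mm <= k   # guard against fuzzy edge hits
          if (any(keep)) {
            hits[[length(hits) + 1L]] <- data.frame(
              locus = names(refs)[j], start = st[keep],
              end = st[keep] + length(pat) - 1L, strand = strand,
              mismatches = mm[keep], stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(hits) == 0L) {
      n_unmapped <- n_unmapped + 1L
      res[[i]] <- data.frame(locus = NA_character_, start = NA_integer_,
                             end = NA_integer_, strand = NA_character_,
                             mismatches = NA_integer_,
                             stringsAsFactors = FALSE)
    } else {
      h <- do.call(rbind, hits)
      best <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
      res[[i]] <- best[sample.int(nrow(best), 1L), , drop = FALSE]
    }
  }
  out <- do.call(rbind, res)
  out <- cbind(read_id = names(reads), out, stringsAsFactors = FALSE)
  out$mapped <- !is.na(out$locus)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-base coverage tracks from read placements
#'
#' @param placements data.frame from [map_reads()] (unmapped rows ignored).
#' @param reference_lengths named integer vector of locus lengths.
#' @return named list of integer depth vectors, one per locus.
#' @export
coverage_from_placements <- function(placements, reference_lengths) {
  stopifnot(!is.null(names(reference_lengths)))
  out <- lapply(names(reference_lengths), function(locus) {
    L <- reference_lengths[[locus]]
    p <- placements[placements$mapped & placements$locus == locus, ,
                    drop = FALSE]
    cov <- integer(L)
    for (r in seq_len(nrow(p))) {
      span <- p$start[r]:min(p$end[r], L)
      cov[span] <- cov[span] + 1L
    }
    cov
  })
  stats::setNames(out, names(reference_lengths))
}

#' Call low-coverage (fragmentation) regions of one locus
#'
#' The locus mean coverage is taken over the entire track, low positions
#' included. Regions are the maximal runs of positions whose depth is
#' strictly below \code{fraction} times that mean (a position at exactly the
#' threshold is never called); coordinates are 1-based inclusive. A track
#' with zero coverage everywhere yields a single whole-locus region flagged
#' \code{degenerate}.
#'
#' @param depths integer vector of per-base depths (1-based positions).
#' @param fraction threshold as a fraction of the locus mean (default 0.05).
#' @param locus_id optional identifier copied into the output.
#' @return data.frame with columns \code{locus_id}, \code{start},
#'   \code{end}, \code{length}, \code{mean_fraction} (region mean depth over
#'   locus mean depth), \code{degenerate}.
#' @export
call_low_coverage_regions <- function(depths, fraction = 0.05,
                                      locus_id = NA_character_) {
  stopifnot(length(depths) >= 1, all(depths >= 0), fraction > 0)
  cbar <- mean(depths)
  empty <- data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_fraction = numeric(0), degenerate = logical(0))
  if (cbar == 0) {
    return(data.frame(locus_id = locus_id, start = 1L,
                      end = length(depths), length = length(depths),
                      mean_fraction = NaN, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  low <- depths < fraction * cbar
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  data.frame(
    locus_id = locus_id,
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    mean_fraction = vapply(seq_along(starts), function(k)
      mean(depths[starts[k]:ends[k]]) / cbar, numeric(1)),
    degenerate = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Group equivalent fragmentation regions across rRNA gene copies
#'
#' Regions from different loci are considered equivalent when both their
#' start and end coordinates differ by at most \code{tolerance} nucleotides
#' (transitively closed). Groups present in every locus are labelled
#' \code{"shared"}, all others \code{"unique"}.
#'
#' @param regions data.frame of called regions from several loci
#'   (columns \code{locus_id}, \code{start}, \code{end}), e.g. the row-bind
#'   of per-locus [call_low_coverage_regions()] output.
#' @param tolerance maximum coordinate difference in nt (default 2).
#' @return the input with added columns \code{group} (integer id) and
#'   \code{status} (\code{"shared"} or \code{"unique"}); attribute
#'   \code{n_loci}.
#' @export
compare_regions <- function(regions, tolerance = 2) {
  loci <- unique(regions$locus_id)
  if (length(loci) < 2L) stop("need regions from at least two loci")
  n <- nrow(regions)
  # union-find over pairwise equivalence
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(regions$start[i] - regions$start[j]) <= tolerance &&
            abs(regions$end[i] - regions$end[j]) <= tolerance) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  regions$group <- match(roots, unique(roots))
  present <- tapply(regions$locus_id, regions$group,
                    function(l) length(unique(l)))
  regions$status <- ifelse(present[regions$group] == length(loci),
                           "shared", "unique")
  attr(regions, "n_loci") <- length(loci)
  regions
}
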