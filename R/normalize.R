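#' Spot quality filter
#'
#' A spot passes when its flag is non-negative and the signal-to-noise ratio
#' (foreground median over background median) is at least 3 in at least one
#' channel. A zero background with positive foreground counts as passing
#' that channel; a zero background with zero foreground does not.
#'
#' @param spots spot data.frame (columns \code{flags}, \code{f635_median},
#'   \code{b635_median}, \code{f532_median}, \code{b532_median}).
#' @param min_sn signal-to-noise threshold (default 3, inclusive).
#' @return logical vector, one entry per spot.
#' @export
passes_quality <- function(spots, min_sn = 3) {
  sn <- function(f, b) ifelse(b > 0, f / b, ifelse(f > 0, Inf, 0))
  spots$flags >= 0 &
    (sn(spots$f635_median, spots$b635_median) >= min_sn |
       sn(spots$f532_median, spots$b532_median) >= min_sn)
}

#' Per-hybridization spike-in normalization factor
#'
#' The factor f = 2^(-mean(log2 r_i)) over the quality-passing 1:1 control
#' spots, so that after multiplying every spot's ratio of medians by f the
#' mean log2 ratio of those controls is exactly zero.
#'
#' @param hyb a hybridization list (see [read_gpr()]).
#' @param spike_ids identifiers of the 1:1 control spots.
#' @param min_sn signal-to-noise threshold of the quality filter.
#' @return the normalization factor, a positive scalar.
#' @export
normalization_factor <- function(hyb, spike_ids = spike_control_ids(),
                                 min_sn = 3) {
  spots <- hyb$spots
  ctrl <- spots$gene_id %in% spike_ids & passes_quality(spots, min_sn) &
    !is.na(spots$ratio_of_medians) & spots$ratio_of_medians > 0
  if (!any(ctrl)) {
    stop("hybridization '", hyb$array_id,
         "' rejected: no quality-passing 1:1 control spots")
  }
  2^(-mean(log2(spots$ratio_of_medians[ctrl])))
}

#' Normalize and orient the log2 ratios of one hybridization
#'
#' Quality-passing spots with a positive ratio of medians are normalized
#' with the supplied factor and log2-transformed. Arrays whose stored
#' Cy5/Cy3 ratio corresponds to t0/tx (dye orientation \code{"t0_in_cy5"})
#' are sign-flipped so every output is log2(level_tx / level_t0). Spots with
#' a missing or non-positive ratio are dropped; the number dropped is
#' attached as attribute \code{n_dropped}.
#'
#' @param hyb hybridization list with a \code{dye_orientation} field.
#' @param factor normalization factor from [normalization_factor()].
#' @param min_sn signal-to-noise threshold of the quality filter.
#' @return data.frame with columns \code{gene_id}, \code{log2_ratio}.
#' @export
normalize_log2_ratios <- function(hyb, factor, min_sn = 3) {
  stopifnot(factor > 0)
  orientation <- hyb$dye_orientation
  if (is.null(orientation) ||
      !orientation %in% c("t0_in_cy3", "t0_in_cy5")) {
    stop("hybridization '", hyb$array_id, "' has no valid dye_orientation")
  }
  spots <- hyb$spots
  ok <- passes_quality(spots, min_sn)
  usable <- ok & !is.na(spots$ratio_of_medians) & spots$ratio_of_medians > 0
  lr <- log2(spots$ratio_of_medians[usable] * factor)
  # stored ratio is Cy5/Cy3: with t0 in Cy5 that is t0/tx, so flip the sign
  if (orientation == "t0_in_cy5") lr <- -lr
  out <- data.frame(gene_id = spots$gene_id[usable], log2_ratio = lr,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(ok) - sum(usable)
  out
}

#' Average replicate log2 ratios per gene and timepoint
#'
#' @param long data.frame with columns \code{gene_id}, \code{timepoint},
#'   \code{log2_ratio}, one row per passing spot measurement.
#' @return object of class \code{"decay_profiles"}: a list with
#'   \code{log2_ratio} (genes x timepoints matrix of means, \code{NA} where
#'   no replicate passed), \code{n_replicates} (matching count matrix) and
#'   \code{timepoints}.
#' @export
average_replicates <- function(long) {
  stopifnot(all(c("gene_id", "timepoint", "log2_ratio") %in% names(long)))
  tps <- sort(unique(long$timepoint))
  genes <- sort(unique(long$gene_id))
  gi <- match(long$gene_id, genes)
  ti <- match(long$timepoint, tps)
  idx <- (ti - 1L) * length(genes) + gi
  sums <- numeric(length(genes) * length(tps))
  ns <- integer(length(genes) * length(tps))
  add <- tapply(long$log2_ratio, idx, sum)
  cnt <- tapply(long$log2_ratio, idx, length)
  at <- as.integer(names(add))
  sums[at] <- add
  ns[at] <- cnt
  m <- matrix(ifelse(ns > 0, sums / ns, NA_real_),
              nrow = length(genes), ncol = length(tps),
              dimnames = list(genes, tps))
  n <- matrix(ns, nrow = length(genes), ncol = length(tps),
              dimnames = list(genes, tps))
  structure(list(log2_ratio = m, n_replicates = n, timepoints = tps),
            class = "decay_profiles")
}

#' @export
print.decay_profiles <- function(x, ...) {
  cat("Decay profiles:", nrow(x$log2_ratio), "genes,",
      length(x$timepoints), "timepoints (",
      paste(x$timepoints, collapse = ", "), "min )\n")
  invisible(x)
}

#' Build per-gene decay profiles from a hybridization set
#'
#' Runs the full normalization stage: per-array spike-in factor, quality
#' filtering, log2 transform and dye-orientation handling, then averaging of
#' replicates per gene per timepoint. Arrays with no passing control spot
#' are dropped with a warning. Spike-in control spots are excluded from the
#' gene profiles.
#'
#' @param hybs list of hybridizations.
#' @param spike_ids identifiers of the 1:1 control spots.
#' @param min_sn signal-to-noise threshold of the quality filter.
#' @return object of class \code{"decay_profiles"} (see
#'   [average_replicates()]).
#' @export
build_decay_profiles <- function(hybs, spike_ids = spike_control_ids(),
                                 min_sn = 3) {
  pieces <- list()
  for (hyb in hybs) {
    f <- tryCatch(normalization_factor(hyb, spike_ids, min_sn),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(f)) next
    lr <- normalize_log2_ratios(hyb, f, min_sn)
    lr <- lr[!lr$gene_id %in% spike_ids, , drop = FALSE]
    lr$timepoint <- hyb$timepoint
    pieces[[length(pieces) + 1L]] <- lr
  }
  if (length(pieces) == 0L) stop("no usable hybridizations")
  average_replicates(do.call(rbind, pieces))
}
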