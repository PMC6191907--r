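#' Ordinary least squares fit of log2 ratio against time
#'
#' Free-intercept OLS from the sum-of-squares definitions. R-squared is
#' 1 - SSres/SStot and is undefined (\code{NA}) when the responses are
#' constant (SStot = 0).
#'
#' @param times timepoints in minutes, distinct, length >= 3.
#' @param log2_ratios responses, same length.
#' @return list with \code{slope} (per minute, log2 scale),
#'   \code{intercept}, \code{r_squared}, \code{n}.
#' @export
ols_fit <- function(times, log2_ratios) {
  n <- length(times)
  if (n < 3L) stop("need at least 3 points for a decay fit")
  if (length(log2_ratios) != n) stop("'times' and 'log2_ratios' differ in length")
  if (anyDuplicated(times)) stop("'times' must be distinct")
  xbar <- mean(times)
  ybar <- mean(log2_ratios)
  dx <- times - xbar
  dy <- log2_ratios - ybar
  sxx <- sum(dx * dx)
  sxy <- sum(dx * dy)
  syy <- sum(dy * dy)
  slope <- sxy / sxx
  ss_res <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - ss_res / syy else NA_real_
  list(slope = slope, intercept = ybar - slope * xbar,
       r_squared = r2, n = n)
}

#' Convert a log2 decay slope to a half-life
#'
#' With y(t) = log2(level_t / level_0) = -t/h, the slope of the fitted line
#' is -1/h, so h = -1/slope. Non-negative slopes (no detectable decay) are
#' censored and returned as \code{NA}.
#'
#' @param slope fitted slope, per minute on the log2 scale.
#' @return half-life in minutes, or \code{NA} when censored.
#' @export
half_life_from_slope <- function(slope) {
  ifelse(slope < 0, -1 / slope, NA_real_)
}

#' Estimate one gene's half-life with the R-squared gate and 3-point fallback
#'
#' The full window (all available timepoints, normally 2, 5, 10 and 15 min)
#' is fitted first; the estimate is accepted when R-squared exceeds the gate
#' and the slope is negative. Otherwise the last timepoint is dropped and
#' the first three sampling times are refitted under the same gate. Genes
#' with no acceptable fit are \code{"censored"} when the final slope is
#' non-negative (no decay signal) and \code{"unresolved"} otherwise; an
#' undefined R-squared (constant responses) never passes the gate.
#'
#' @param times available timepoints in minutes.
#' @param log2_ratios averaged log2 ratios at those timepoints.
#' @param gate R-squared threshold, exceeded strictly (default 0.7).
#' @param fallback_times the reduced window (default 2, 5 and 10 min); all
#'   of these must be present or the gene is unresolved.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n_points}, \code{half_life}, \code{status} (one of
#'   \code{"ok_4pt"}, \code{"ok_3pt"}, \code{"censored"},
#'   \code{"unresolved"}).
#' @export
estimate_half_life <- function(times, log2_ratios, gate = 0.7,
                               fallback_times = c(2, 5, 10)) {
  keep <- is.finite(log2_ratios)
  times <- times[keep]
  y <- log2_ratios[keep]
  unresolved <- list(slope = NA_real_, intercept = NA_real_,
                     r_squared = NA_real_, n_points = NA_integer_,
                     half_life = NA_real_, status = "unresolved")
  if (length(times) < 3L || !all(fallback_times %in% times)) {
    return(unresolved)
  }

  accept <- function(fit, status) {
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, n_points = fit$n,
         half_life = -1 / fit$slope, status = status)
  }
  passes <- function(fit) {
    !is.na(fit$r_squared) && fit$r_squared > gate && fit$slope < 0
  }

  full <- ols_fit(times, y)
  if (passes(full)) {
    return(accept(full, if (full$n >= 4L) "ok_4pt" else "ok_3pt"))
  }
  sub <- times %in% fallback_times
  short <- ols_fit(times[sub], y[sub])
  if (passes(short)) {
    out <- accept(short, "ok_3pt")
    return(out)
  }
  status <- if (short$slope >= 0) "censored" else "unresolved"
  list(slope = short$slope, intercept = short$intercept,
       r_squared = short$r_squared, n_points = short$n,
       half_life = NA_real_, status = status)
}

#' Fit per-gene mRNA half-lives from decay profiles
#'
#' The model for each gene is exponential decay after transcription arrest:
#' the averaged log2 ratio y(t) = log2(level_t / level_0) is fitted as a
#' straight line in t and the half-life is -1/slope. Fits are gated on
#' R-squared > \code{gate}, with a fallback refit on the first three
#' sampling times when the full window fails (see [estimate_half_life()]).
#'
#' @param profiles a \code{"decay_profiles"} object from
#'   [build_decay_profiles()], or a numeric matrix of averaged log2 ratios
#'   with genes in rows and timepoints (minutes) as column names.
#' @param gate R-squared threshold, exceeded strictly.
#' @param fallback_times reduced fitting window, minutes.
#' @return object of class \code{"halflife_fit"} with components
#'   \code{estimates} (data.frame: \code{gene_id}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_points},
#'   \code{half_life}, \code{status}), \code{gate}, \code{timepoints},
#'   \code{profiles} and \code{call}.
#' @seealso [summary.halflife_fit()], [operon_half_lives()]
#' @export
#' @examples
#' truth <- sim_decay_truth(20, seed = 1)
#' hybs <- sim_hybridizations(truth, noise_sd_log2 = 0, bad_spot_prob = 0,
#'                            array_scale_sd_log2 = 0, seed = 2)
#' fit <- fit_half_lives(build_decay_profiles(hybs))
#' fit
fit_half_lives <- function(profiles, gate = 0.7, fallback_times = c(2, 5, 10)) {
  m <- if (inherits(profiles, "decay_profiles")) profiles$log2_ratio
       else as.matrix(profiles)
  if (is.null(colnames(m))) {
    stop("profile matrix must have timepoints (minutes) as column names")
  }
  tps <- as.numeric(colnames(m))
  ests <- lapply(seq_len(nrow(m)), function(i) {
    estimate_half_life(tps, m[i, ], gate = gate,
                       fallback_times = fallback_times)
  })
  estimates <- data.frame(
    gene_id = rownames(m),
    slope = vapply(ests, `[[`, numeric(1), "slope"),
    intercept = vapply(ests, `[[`, numeric(1), "intercept"),
    r_squared = vapply(ests, `[[`, numeric(1), "r_squared"),
    n_points = vapply(ests, function(e) as.integer(e$n_points), integer(1)),
    half_life = vapply(ests, `[[`, numeric(1), "half_life"),
    status = vapply(ests, `[[`, character(1), "status"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(estimates = estimates, gate = gate, timepoints = tps,
                 profiles = m, call = match.call()),
            class = "halflife_fit")
}

.ok_status <- c("ok_4pt", "ok_3pt")

#' @export
print.halflife_fit <- function(x, ...) {
  st <- table(factor(x$estimates$status,
                     levels = c(.ok_status, "censored", "unresolved")))
  cat("mRNA half-life fit (R-squared gate >", format(x$gate), ")\n")
  cat("  genes:", nrow(x$estimates), "\n")
  cat(sprintf("  full-window fits: %d, fallback 3-point fits: %d\n",
              st[["ok_4pt"]], st[["ok_3pt"]]))
  cat(sprintf("  censored: %d, unresolved: %d\n",
              st[["censored"]], st[["unresolved"]]))
  ok <- x$estimates$half_life[x$estimates$status %in% .ok_status]
  if (length(ok) > 0) {
    cat(sprintf("  half-life mean %.1f min, median %.1f min\n",
                mean(ok), stats::median(ok)))
  }
  invisible(x)
}

#' Summarize a half-life fit
#'
#' Mean and median half-life over accepted estimates only, status counts
#' and a histogram of half-lives in 1-minute bins \code{[k, k+1)}.
#'
#' @param object a \code{"halflife_fit"}.
#' @param ... unused.
#' @return object of class \code{"summary.halflife_fit"}: list with
#'   \code{n_ok}, \code{mean}, \code{median}, \code{range},
#'   \code{status_counts}, \code{histogram} (data.frame \code{bin_start},
#'   \code{bin_end}, \code{count}).
#' @export
summary.halflife_fit <- function(object, ...) {
  est <- object$estimates
  ok <- est$half_life[est$status %in% .ok_status]
  if (length(ok) == 0L) stop("no accepted half-life estimates to summarize")
  edges <- seq(floor(min(ok)), ceiling(max(ok)) + 1)
  counts <- tabulate(findInterval(ok, edges), nbins = length(edges) - 1L)
  structure(list(
    n_ok = length(ok),
    mean = mean(ok),
    median = stats::median(ok),
    range = range(ok),
    status_counts = table(est$status),
    histogram = data.frame(bin_start = edges[-length(edges)],
                           bin_end = edges[-1], count = counts),
    gate = object$gate
  ), class = "summary.halflife_fit")
}

#' @export
print.summary.halflife_fit <- function(x, ...) {
  cat(sprintf("Accepted half-lives: %d genes (gate R-squared > %s)\n",
              x$n_ok, format(x$gate)))
  cat(sprintf("  mean %.1f min, median %.1f min, range %.1f-%.1f min\n",
              x$mean, x$median, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.halflife_fit <- function(object, ...) {
  est <- object$estimates
  m <- cbind(slope = est$slope, intercept = est$intercept)
  rownames(m) <- est$gene_id
  m
}

#' Predicted log2 ratios from a half-life fit
#'
#' @param object a \code{"halflife_fit"}.
#' @param times timepoints in minutes (defaults to the fitted ones).
#' @param genes genes to predict for (defaults to all with a defined fit).
#' @param ... unused.
#' @return matrix of fitted log2 ratios, genes x times.
#' @export
predict.halflife_fit <- function(object, times = object$timepoints,
                                 genes = NULL, ...) {
  est <- object$estimates
  if (!is.null(genes)) est <- est[est$gene_id %in% genes, , drop = FALSE]
  est <- est[!is.na(est$slope), , drop = FALSE]
  out <- outer(est$slope, times) + est$intercept
  dimnames(out) <- list(est$gene_id, times)
  out
}

#' @export
residuals.halflife_fit <- function(object, ...) {
  fitted <- predict(object)
  obs <- object$profiles[rownames(fitted), colnames(fitted), drop = FALSE]
  obs - fitted
}

#' Histogram of accepted half-lives
#'
#' @param x a \code{"halflife_fit"}.
#' @param ... passed to [graphics::hist()].
#' @export
plot.halflife_fit <- function(x, ...) {
  est <- x$estimates
  ok <- est$half_life[est$status %in% .ok_status]
  graphics::hist(ok, breaks = seq(floor(min(ok)), ceiling(max(ok)) + 1),
                 right = FALSE, xlab = "mRNA half-life (min)",
                 main = "Distribution of mRNA half-lives", ...)
  invisible(x)
}

#' Average half-lives over operon members
#'
#' Arithmetic mean of the accepted member half-lives per operon, at full
#' precision (column \code{mean_half_life}) and rounded to one decimal for
#' reporting (column \code{half_life_reported}). Operons with no accepted
#' member estimate are omitted; their ids are attached as attribute
#' \code{omitted}.
#'
#' @param fit a \code{"halflife_fit"} or its \code{estimates} data.frame.
#' @param operon_map data.frame with columns \code{operon_id},
#'   \code{gene_id}.
#' @return data.frame with columns \code{operon_id}, \code{n_members},
#'   \code{n_members_estimated}, \code{mean_half_life},
#'   \code{half_life_reported}.
#' @export
operon_half_lives <- function(fit, operon_map) {
  est <- if (inherits(fit, "halflife_fit")) fit$estimates else fit
  stopifnot(all(c("operon_id", "gene_id") %in% names(operon_map)))
  ok <- est[est$status %in% .ok_status, c("gene_id", "half_life")]
  merged <- merge(operon_map, ok, by = "gene_id", all.x = TRUE)
  sp <- split(merged, merged$operon_id)
  rows <- lapply(sp, function(d) {
    hl <- d$half_life[!is.na(d$half_life)]
    data.frame(operon_id = d$operon_id[1],
               n_members = nrow(d),
               n_members_estimated = length(hl),
               mean_half_life = if (length(hl) > 0) mean(hl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  omitted <- out$operon_id[out$n_members_estimated == 0L]
  out <- out[out$n_members_estimated > 0L, , drop = FALSE]
  out$half_life_reported <- round(out$mean_half_life, 1)
  attr(out, "omitted") <- omitted
  out
}
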