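#' One-way ANOVA over functional categories
#'
#' Fixed-effects one-way analysis of variance computed directly from the
#' between- and within-group sums of squares:
#' F = (SSB/dfB) / (SSW/dfW), with the p-value from the F distribution.
#'
#' @param values numeric responses (half-lives, minutes).
#' @param groups group labels, same length; at least two groups, each with
#'   at least two values.
#' @return list with \code{f_statistic}, \code{df_between},
#'   \code{df_within}, \code{p_value}, \code{ss_between}, \code{ss_within}.
#' @export
anova_halflife <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(sizes < 2L)) stop("every group needs at least two values")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssw == 0 && ssb == 0) stop("no variance within or between groups")
  f <- (ssb / dfb) / (ssw / dfw)
  list(f_statistic = f, df_between = dfb, df_within = dfw,
       p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

#' Post-hoc tests of category means against the global mean
#'
#' For each category with at least two estimated half-lives, a two-sided
#' one-sample t-test of the category values against the global mean
#' half-life (treated as a fixed constant), Bonferroni-corrected by the
#' number of categories actually tested. Categories with zero within-group
#' variance are flagged degenerate and assigned p = 0 (mean differs from the
#' global mean) or p = 1 (mean equals it).
#'
#' @param values half-lives, minutes.
#' @param categories category labels, same length.
#' @param global_mean the overall mean half-life to test against; defaults
#'   to the mean of \code{values}.
#' @return data.frame with one row per tested category: \code{category},
#'   \code{n_genes}, \code{mean_half_life}, \code{t_statistic},
#'   \code{p_value}, \code{p_bonferroni}, \code{degenerate}.
#' @export
category_posthoc <- function(values, categories, global_mean = mean(values)) {
  keep <- is.finite(values) & !is.na(categories)
  values <- values[keep]
  categories <- as.character(categories[keep])
  sp <- split(values, categories)
  sp <- sp[vapply(sp, length, integer(1)) >= 2L]
  if (length(sp) == 0L) stop("no category has at least two values")
  m <- length(sp)
  rows <- lapply(names(sp), function(cat) {
    x <- sp[[cat]]
    if (stats::sd(x) == 0) {
      p <- if (mean(x) == global_mean) 1 else 0
      data.frame(category = cat, n_genes = length(x),
                 mean_half_life = mean(x), t_statistic = NA_real_,
                 p_value = p, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x, mu = global_mean)
      data.frame(category = cat, n_genes = length(x),
                 mean_half_life = mean(x),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, m * out$p_value)
  out[, c("category", "n_genes", "mean_half_life", "t_statistic",
          "p_value", "p_bonferroni", "degenerate")]
}

#' Pearson correlation of half-life with abundance or ORF length
#'
#' Pearson's r with a two-sided p-value from the t transform on n - 2
#' degrees of freedom. For abundance data the default transform is
#' log10 applied to strictly positive values (log-scale expression axis);
#' pairs where the transformed covariate is unavailable are dropped.
#'
#' @param half_life half-lives in minutes.
#' @param x covariate (e.g. FPKM or ORF length in nt), same length.
#' @param transform \code{"log10"} (drop x <= 0, then log10) or
#'   \code{"raw"}.
#' @return list with \code{r}, \code{n}, \code{p_value},
#'   \code{variable_transform}.
#' @export
cor_half_life <- function(half_life, x, transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  stopifnot(length(half_life) == length(x))
  if (transform == "log10") {
    keep <- is.finite(half_life) & is.finite(x) & x > 0
    x <- log10(x[keep])
    half_life <- half_life[keep]
  } else {
    keep <- is.finite(half_life) & is.finite(x)
    x <- x[keep]
    half_life <- half_life[keep]
  }
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(half_life) == 0) {
    stop("correlation undefined: a variable is constant")
  }
  ct <- stats::cor.test(x, half_life, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value,
       variable_transform = transform)
}
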