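#' Draw a ground-truth table of gene half-lives and abundances
#'
#' Half-lives are drawn log-normally so that the distribution median equals
#' \code{median_half_life}; baseline abundances (linear units feeding the
#' channel-intensity model of [sim_hybridizations()]) are drawn log-normally
#' around \code{abundance_meanlog}. The defaults centre the half-life
#' distribution at 5.7 min with log-sd 0.4, i.e. most genes fall between
#' roughly 2 and 16 min, the range typical of fast-growing bacteria.
#'
#' @param n_genes number of genes to simulate (>= 1).
#' @param median_half_life median of the half-life distribution, minutes.
#' @param log_sd standard deviation of log half-life (natural log scale);
#'   0 gives every gene exactly \code{median_half_life}.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   baseline abundance.
#' @param seed optional integer seed; the same seed reproduces the table.
#' @return data.frame with columns \code{gene_id}, \code{true_half_life}
#'   (minutes) and \code{baseline_abundance}.
#' @export
#' @examples
#' truth <- sim_decay_truth(5, seed = 1)
sim_decay_truth <- function(n_genes, median_half_life = 5.7, log_sd = 0.4,
                            abundance_meanlog = log(1000), abundance_sdlog = 1,
                            seed = NULL) {
  if (length(n_genes) != 1L || n_genes < 1) {
    stop("'n_genes' must be a single value >= 1")
  }
  stopifnot(median_half_life > 0, log_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes)
  data.frame(
    gene_id = sprintf("GSYN%05d", seq_len(n_genes)),
    true_half_life = exp(stats::rnorm(n_genes, log(median_half_life), log_sd)),
    baseline_abundance = exp(stats::rnorm(n_genes, abundance_meanlog,
                                          abundance_sdlog)),
    stringsAsFactors = FALSE
  )
}

#' Describe a spike-in control series
#'
#' A spike-in specification names one exogenous control RNA that is present
#' in both labelling mixes at a known A:B ratio and printed on several array
#' spots. Controls spiked 1:1 anchor the per-hybridization normalization.
#'
#' @param control_id identifier used as the spot's gene field.
#' @param spots_per_array number of spots carrying this control (>= 1).
#' @param nominal_ratio true A/B ratio of the control (> 0).
#' @return list of class \code{"spike_in_spec"}.
#' @export
spike_in_spec <- function(control_id, spots_per_array = 32, nominal_ratio = 1) {
  stopifnot(is.character(control_id), length(control_id) == 1L,
            spots_per_array >= 1, nominal_ratio > 0)
  structure(list(control_id = control_id,
                 spots_per_array = as.integer(spots_per_array),
                 nominal_ratio = nominal_ratio),
            class = "spike_in_spec")
}

#' Default 1:1 spike-in controls
#'
#' The two Agilent one-to-one control RNAs, each printed on 32 spots.
#' @return list of two [spike_in_spec()] objects.
#' @export
default_spike_ins <- function() {
  list(spike_in_spec("(+)E1A_r60_1"), spike_in_spec("(+)E1A_r60_a20"))
}

#' Identifiers of the default 1:1 spike-in controls
#' @return character vector of control spot identifiers.
#' @export
spike_control_ids <- function() c("(+)E1A_r60_1", "(+)E1A_r60_a20")

#' Simulate a rifampicin-chase two-color hybridization series
#'
#' For gene g with half-life h the true abundance ratio between the sample
#' taken t minutes after transcription arrest and the untreated sample is
#' 2^(-t/h). Each (timepoint, replicate) pair becomes one two-color
#' hybridization: multiplicative log-normal spot noise (sd
#' \code{noise_sd_log2} on the log2 ratio), one global scale factor per
#' array (dye/labelling imbalance, sd \code{array_scale_sd_log2} log2
#' units), alternating dye orientation across replicates (dye swap), spike-in
#' control spots carrying their nominal ratio times the same array scale, and
#' a fraction \code{bad_spot_prob} of spots flagged bad (Flags = -50).
#'
#' Channel foregrounds are \code{scale x abundance + background} so that the
#' background-corrected ratio of medians recovers the simulated ratio
#' exactly; with all noise terms zero the whole pipeline is exact.
#'
#' @param truth data.frame from [sim_decay_truth()].
#' @param timepoints minutes after transcription arrest (> 0).
#' @param replicates number of biological replicates per timepoint.
#' @param noise_sd_log2 sd of spot-level noise on the log2 ratio.
#' @param bad_spot_prob probability a spot is flagged bad.
#' @param spikes list of [spike_in_spec()] controls printed on every array.
#' @param array_scale_sd_log2 sd (log2) of the per-array global scale factor.
#' @param bg_mean,bg_sd background intensity distribution (units; truncated
#'   at zero).
#' @param intensity_scale multiplies baseline abundance into foreground
#'   intensity units.
#' @param seed optional integer seed.
#' @return list of hybridizations; each is a list with fields
#'   \code{array_id}, \code{timepoint}, \code{replicate},
#'   \code{dye_orientation} (\code{"t0_in_cy3"} or \code{"t0_in_cy5"}) and
#'   \code{spots}, a data.frame with columns \code{spot_id}, \code{gene_id},
#'   \code{flags}, \code{f635_median}, \code{b635_median},
#'   \code{f532_median}, \code{b532_median}, \code{ratio_of_medians}.
#' @export
sim_hybridizations <- function(truth, timepoints = c(2, 5, 10, 15),
                               replicates = 3, noise_sd_log2 = 0.2,
                               bad_spot_prob = 0.02,
                               spikes = default_spike_ins(),
                               array_scale_sd_log2 = 0.25,
                               bg_mean = 50, bg_sd = 5,
                               intensity_scale = 1000, seed = NULL) {
  if (nrow(truth) == 0L) stop("'truth' must contain at least one gene")
  stopifnot(all(timepoints > 0), replicates >= 1,
            noise_sd_log2 >= 0, bad_spot_prob >= 0, bad_spot_prob <= 1,
            array_scale_sd_log2 >= 0)
  if (!is.null(seed)) set.seed(seed)

  spike_ids <- vapply(spikes, `[[`, character(1), "control_id")
  spike_n <- vapply(spikes, `[[`, integer(1), "spots_per_array")
  spike_ratio <- vapply(spikes, `[[`, numeric(1), "nominal_ratio")

  hybs <- list()
  for (rep_i in seq_len(replicates)) {
    orientation <- if (rep_i %% 2L == 1L) "t0_in_cy3" else "t0_in_cy5"
    for (t in timepoints) {
      scale <- 2^stats::rnorm(1, 0, array_scale_sd_log2)

      # gene spots: true tx/t0 ratio with multiplicative noise
      rho <- 2^(-t / truth$true_half_life +
                  stats::rnorm(nrow(truth), 0, noise_sd_log2))
      gene_abund <- truth$baseline_abundance * intensity_scale
      # spike spots: nominal A/B ratio with the same noise model
      sp_id <- rep(spike_ids, spike_n)
      sp_rho <- 2^(log2(rep(spike_ratio, spike_n)) +
                     stats::rnorm(sum(spike_n), 0, noise_sd_log2))
      sp_abund <- rep(500 * intensity_scale / 1000, sum(spike_n))

      ids <- c(truth$gene_id, sp_id)
      rho_all <- c(rho, sp_rho)
      abund <- c(gene_abund, sp_abund)
      n <- length(ids)

      # stored ratio of medians is always Cy5/Cy3 (F635 over F532)
      ratio_cy <- if (orientation == "t0_in_cy3") scale * rho_all
                  else scale / rho_all
      b635 <- pmax(stats::rnorm(n, bg_mean, bg_sd), 0)
      b532 <- pmax(stats::rnorm(n, bg_mean, bg_sd), 0)
      if (orientation == "t0_in_cy3") {
        level_cy3 <- abund               # t0 sample in Cy3
        level_cy5 <- ratio_cy * level_cy3
      } else {
        level_cy5 <- abund               # t0 sample in Cy5
        level_cy3 <- level_cy5 / ratio_cy
      }
      flags <- ifelse(stats::runif(n) < bad_spot_prob, -50L, 0L)

      spots <- data.frame(
        spot_id = sprintf("S%05d", seq_len(n)),
        gene_id = ids,
        flags = flags,
        f635_median = level_cy5 + b635,
        b635_median = b635,
        f532_median = level_cy3 + b532,
        b532_median = b532,
        ratio_of_medians = ratio_cy,
        stringsAsFactors = FALSE
      )
      hybs[[length(hybs) + 1L]] <- list(
        array_id = sprintf("array_t%02d_r%d", as.integer(t), rep_i),
        timepoint = t,
        replicate = rep_i,
        dye_orientation = orientation,
        true_scale = scale,
        spots = spots
      )
    }
  }
  hybs
}

#' Simulate a per-gene fragment count table
#'
#' Counts are negative-binomial with expectation proportional to gene length
#' times a log-normal expression level, the standard overdispersed model for
#' sequencing counts. The realized library size (sum of counts) is attached
#' as attribute \code{library_size}.
#'
#' @param n_genes number of genes.
#' @param lengths gene lengths in nt, length \code{n_genes}.
#' @param mean_fpkm expected expression level scale.
#' @param dispersion negative-binomial size parameter.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{gene_id}, \code{length},
#'   \code{count}; attribute \code{library_size}.
#' @export
sim_count_table <- function(n_genes, lengths, mean_fpkm = 200,
                            dispersion = 2, seed = NULL) {
  if (length(lengths) != n_genes) {
    stop("'lengths' must have one entry per gene")
  }
  stopifnot(all(lengths > 0))
  if (!is.null(seed)) set.seed(seed)
  expr <- exp(stats::rnorm(n_genes, 0, 1))
  mu <- mean_fpkm * expr * lengths / 1e3
  counts <- stats::rnbinom(n_genes, mu = mu, size = dispersion)
  out <- data.frame(gene_id = sprintf("GSYN%05d", seq_len(n_genes)),
                    length = as.integer(lengths),
                    count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "library_size") <- sum(counts)
  out
}
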