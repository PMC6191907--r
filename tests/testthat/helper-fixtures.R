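# small fixtures shared across test files; everything is built in code

# truth table with known, hand-picked half-lives
fixed_truth <- function(h = c(2, 5, 10, 25)) {
  data.frame(gene_id = sprintf("gene%02d", seq_along(h)),
             true_half_life = h,
             baseline_abundance = rep(1000, length(h)),
             stringsAsFactors = FALSE)
}

# noise-free hybridization series (per-array scale still optional)
noiseless_hybs <- function(truth, scale_sd = 0, seed = 1) {
  sim_hybridizations(truth, noise_sd_log2 = 0, bad_spot_prob = 0,
                     array_scale_sd_log2 = scale_sd, seed = seed)
}

# one bare-bones spot table for filter tests
spot_row <- function(flags = 0, f635 = 300, b635 = 100, f532 = 300,
                     b532 = 100, ratio = NULL) {
  data.frame(spot_id = "S1", gene_id = "g",
             flags = flags, f635_median = f635, b635_median = b635,
             f532_median = f532, b532_median = b532,
             ratio_of_medians = if (is.null(ratio))
               (f635 - b635) / (f532 - b532) else ratio,
             stringsAsFactors = FALSE)
}
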