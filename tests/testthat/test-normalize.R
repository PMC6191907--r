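test_that("quality filter applies the flag veto and either-channel S/N rule", {
  # boundary inclusive: S/N exactly 3 in one channel passes
  expect_true(passes_quality(spot_row(flags = 0, f635 = 300, b635 = 100,
                                      f532 = 100, b532 = 100)))
  # flagged spots always fail
  expect_false(passes_quality(spot_row(flags = -50, f635 = 1e5, b635 = 1,
                                       f532 = 1e5, b532 = 1)))
  # below threshold in both channels fails
  expect_false(passes_quality(spot_row(flags = 0, f635 = 290, b635 = 100,
                                       f532 = 290, b532 = 100)))
  # zero background with positive foreground counts as passing that channel
  expect_true(passes_quality(spot_row(flags = 0, f635 = 10, b635 = 0,
                                      f532 = 1, b532 = 100, ratio = 1)))
  expect_false(passes_quality(spot_row(flags = 0, f635 = 0, b635 = 0,
                                       f532 = 1, b532 = 100, ratio = 1)))
})

test_that("quality filter is monotone in the foreground medians", {
  set.seed(8)
  for (i in 1:200) {
    f635 <- runif(1, 0, 600); f532 <- runif(1, 0, 600)
    base <- spot_row(flags = 0, f635 = f635, b635 = 100,
                     f532 = f532, b532 = 100, ratio = 1)
    raised <- spot_row(flags = 0, f635 = f635 + runif(1, 0, 500), b635 = 100,
                       f532 = f532 + runif(1, 0, 500), b532 = 100, ratio = 1)
    expect_true(!passes_quality(base) || passes_quality(raised))
  }
})

test_that("spike-in factor recentres the 1:1 controls at zero log-ratio", {
  mk <- function(ratios) {
    spots <- do.call(rbind, lapply(ratios, function(r)
      spot_row(ratio = r)))
    spots$gene_id <- spike_control_ids()[1]
    list(array_id = "a", timepoint = 2, replicate = 1,
         dye_orientation = "t0_in_cy3", spots = spots)
  }
  expect_equal(normalization_factor(mk(c(1, 1, 1))), 1)
  expect_equal(normalization_factor(mk(c(2, 2, 2))), 0.5)
  expect_equal(normalization_factor(mk(c(4, 0.25))), 1)

  # post-normalization control mean log2 is zero to 1e-9
  hyb <- mk(c(1.7, 0.4, 2.3, 0.9))
  f <- normalization_factor(hyb)
  expect_lt(abs(mean(log2(hyb$spots$ratio_of_medians * f))), 1e-9)

  # no passing controls -> rejection with diagnostic
  bad <- mk(c(1, 2))
  bad$spots$flags <- -50L
  expect_error(normalization_factor(bad), "rejected")
})

test_that("normalization orients stored ratios to tx/t0", {
  hyb <- function(r, orientation) {
    s <- spot_row(ratio = r)
    list(array_id = "a", timepoint = 2, replicate = 1,
         dye_orientation = orientation, spots = s)
  }
  expect_equal(normalize_log2_ratios(hyb(0.5, "t0_in_cy3"), 1)$log2_ratio, -1)
  expect_equal(normalize_log2_ratios(hyb(2.0, "t0_in_cy5"), 1)$log2_ratio, -1)
  expect_equal(normalize_log2_ratios(hyb(0.8, "t0_in_cy3"), 0.5)$log2_ratio,
               log2(0.4))
  # nonpositive ratios are dropped, with a count
  two <- hyb(0.5, "t0_in_cy3")
  two$spots <- rbind(two$spots, spot_row(ratio = -1))
  out <- normalize_log2_ratios(two, 1)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("replicate averaging is an arithmetic mean in log space", {
  long <- data.frame(gene_id = c("g", "g", "g", "h", "h", "k"),
                     timepoint = c(2, 2, 2, 2, 2, 5),
                     log2_ratio = c(-1, -1, -1, -0.8, -1.2, -2))
  prof <- average_replicates(long)
  expect_equal(prof$log2_ratio["g", "2"], -1)
  expect_equal(prof$n_replicates["g", "2"], 3)
  expect_equal(prof$log2_ratio["h", "2"], -1)
  expect_equal(prof$n_replicates["h", "2"], 2)
  # single replicate rule: the value itself, n = 1
  expect_equal(prof$log2_ratio["k", "5"], -2)
  expect_equal(prof$n_replicates["k", "5"], 1)
  # missing combinations stay NA with n = 0
  expect_true(is.na(prof$log2_ratio["k", "2"]))
  expect_equal(prof$n_replicates["k", "2"], 0)
})

test_that("profiles are invariant under a consistent dye swap of a replicate", {
  truth <- fixed_truth(c(4, 8))
  hybs <- noiseless_hybs(truth, scale_sd = 0.3, seed = 21)
  prof <- build_decay_profiles(hybs)
  # swap every array: exchange channels and invert the stored ratio
  swapped <- lapply(hybs, function(h) {
    s <- h$spots
    h$spots <- data.frame(
      spot_id = s$spot_id, gene_id = s$gene_id, flags = s$flags,
      f635_median = s$f532_median, b635_median = s$b532_median,
      f532_median = s$f635_median, b532_median = s$b635_median,
      ratio_of_medians = 1 / s$ratio_of_medians,
      stringsAsFactors = FALSE)
    h$dye_orientation <- if (h$dye_orientation == "t0_in_cy3")
      "t0_in_cy5" else "t0_in_cy3"
    h
  })
  prof_sw <- build_decay_profiles(swapped)
  expect_equal(prof$log2_ratio, prof_sw$log2_ratio, tolerance = 1e-12)
})

test_that("GPR files and samplesheets round-trip through the reader", {
  truth <- sim_decay_truth(8, seed = 13)
  hybs <- sim_hybridizations(truth, seed = 13)
  dir <- withr::local_tempdir()
  files <- vapply(seq_along(hybs), function(i) {
    p <- file.path(dir, sprintf("h%02d.gpr", i))
    write_gpr(hybs[[i]], p)
    basename(p)
  }, character(1))
  sheet <- data.frame(
    file = files,
    timepoint = vapply(hybs, `[[`, numeric(1), "timepoint"),
    replicate = vapply(hybs, `[[`, numeric(1), "replicate"),
    dye_orientation = vapply(hybs, `[[`, character(1), "dye_orientation"))
  sheet_path <- file.path(dir, "samplesheet.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)

  back <- read_hybridizations(sheet_path)
  expect_equal(length(back), length(hybs))
  expect_equal(back[[3]]$timepoint, hybs[[3]]$timepoint)
  expect_equal(back[[3]]$spots$ratio_of_medians,
               hybs[[3]]$spots$ratio_of_medians, tolerance = 1e-12)
  # profiles from files match profiles from memory
  expect_equal(build_decay_profiles(back)$log2_ratio,
               build_decay_profiles(hybs)$log2_ratio, tolerance = 1e-9)

  # ratio column reconstructed from channels when absent
  one <- readLines(file.path(dir, files[1]))
  drop_last <- function(line) {          # the ratio column is written last
    x <- strsplit(line, "\t")[[1]]
    paste(x[-length(x)], collapse = "\t")
  }
  stripped <- ifelse(startsWith(one, "#"), one,
                     vapply(one, drop_last, character(1)))
  p2 <- file.path(dir, "noratio.gpr")
  writeLines(stripped, p2)
  h2 <- read_gpr(p2)
  full <- read_gpr(file.path(dir, files[1]))
  expect_equal(h2$spots$ratio_of_medians, full$spots$ratio_of_medians,
               tolerance = 1e-6)
})
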