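.gpr_columns <- c(
  spot_id = "Spot",
  gene_id = "ID",
  flags = "Flags",
  f635_median = "F635 Median",
  b635_median = "B635 Median",
  f532_median = "F532 Median",
  b532_median = "B532 Median",
  ratio_of_medians = "Ratio of Medians"
)

#' Write a hybridization as a GPR-dialect spot table
#'
#' Tab-delimited table with the GenePix-style column names (\code{ID},
#' \code{Flags}, \code{F635 Median}, \code{B635 Median}, \code{F532 Median},
#' \code{B532 Median}, \code{Ratio of Medians}). Array metadata (array id,
#' timepoint, replicate, dye orientation) is written as leading \code{#}
#' comment lines so a single file round-trips through [read_gpr()].
#'
#' @param hyb one hybridization as produced by [sim_hybridizations()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gpr <- function(hyb, path) {
  meta <- sprintf("# %s=%s", c("array_id", "timepoint", "replicate",
                               "dye_orientation"),
                  c(hyb$array_id, hyb$timepoint, hyb$replicate,
                    hyb$dye_orientation))
  spots <- hyb$spots[, names(.gpr_columns)]
  names(spots) <- unname(.gpr_columns)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(spots, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GPR-dialect spot table
#'
#' Lines before the header starting with \code{#} are parsed as
#' \code{key=value} metadata when possible and otherwise ignored. Column
#' names can be remapped via \code{col_map} for dialects that deviate from
#' the defaults. If the ratio column is absent, the ratio of medians is
#' computed as \code{(F635 - B635) / (F532 - B532)} only where both the
#' numerator and the denominator are positive (\code{NA} otherwise).
#'
#' @param path file to read.
#' @param col_map named character vector mapping internal names
#'   (\code{gene_id}, \code{flags}, \code{f635_median}, ...) to the column
#'   names used in the file; defaults cover the GenePix naming.
#' @param timepoint,replicate,dye_orientation optional metadata overriding
#'   whatever the file's comment lines carry (needed when the files come
#'   from a scanner and the design lives in a samplesheet).
#' @return a hybridization list (see [sim_hybridizations()] for fields).
#' @export
read_gpr <- function(path, col_map = NULL, timepoint = NULL,
                     replicate = NULL, dye_orientation = NULL) {
  cols <- .gpr_columns
  if (!is.null(col_map)) cols[names(col_map)] <- col_map

  lines <- readLines(path)
  is_comment <- cumprod(startsWith(lines, "#")) == 1
  meta <- list()
  for (cl in lines[is_comment]) {
    kv <- sub("^#\\s*", "", cl)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  tab <- utils::read.delim(text = lines[!is_comment], check.names = FALSE,
                           stringsAsFactors = FALSE)

  required <- setdiff(names(cols), c("spot_id", "ratio_of_medians"))
  missing <- required[!cols[required] %in% names(tab)]
  if (length(missing) > 0L) {
    stop("missing GPR columns: ", paste(cols[missing], collapse = ", "))
  }
  spots <- data.frame(
    spot_id = if (cols[["spot_id"]] %in% names(tab))
      as.character(tab[[cols[["spot_id"]]]]) else sprintf("S%05d", seq_len(nrow(tab))),
    gene_id = as.character(tab[[cols[["gene_id"]]]]),
    flags = as.integer(tab[[cols[["flags"]]]]),
    f635_median = as.numeric(tab[[cols[["f635_median"]]]]),
    b635_median = as.numeric(tab[[cols[["b635_median"]]]]),
    f532_median = as.numeric(tab[[cols[["f532_median"]]]]),
    b532_median = as.numeric(tab[[cols[["b532_median"]]]]),
    stringsAsFactors = FALSE
  )
  if (cols[["ratio_of_medians"]] %in% names(tab)) {
    spots$ratio_of_medians <- as.numeric(tab[[cols[["ratio_of_medians"]]]])
  } else {
    num <- spots$f635_median - spots$b635_median
    den <- spots$f532_median - spots$b532_median
    spots$ratio_of_medians <- ifelse(num > 0 & den > 0, num / den, NA_real_)
  }

  pick <- function(arg, key, coerce = identity) {
    if (!is.null(arg)) return(arg)
    if (!is.null(meta[[key]])) return(coerce(meta[[key]]))
    NULL
  }
  list(
    array_id = pick(NULL, "array_id") %||% basename(path),
    timepoint = pick(timepoint, "timepoint", as.numeric),
    replicate = pick(replicate, "replicate", as.integer),
    dye_orientation = pick(dye_orientation, "dye_orientation"),
    spots = spots
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a set of hybridizations described by a samplesheet
#'
#' The samplesheet is a TSV with columns \code{file}, \code{timepoint},
#' \code{replicate}, \code{dye_orientation}; relative file paths are
#' resolved against the samplesheet's directory.
#'
#' @param samplesheet path to the samplesheet TSV.
#' @param col_map passed to [read_gpr()].
#' @return list of hybridizations.
#' @export
read_hybridizations <- function(samplesheet, col_map = NULL) {
  sheet <- utils::read.delim(samplesheet, stringsAsFactors = FALSE)
  needed <- c("file", "timepoint", "replicate", "dye_orientation")
  if (!all(needed %in% names(sheet))) {
    stop("samplesheet must have columns: ", paste(needed, collapse = ", "))
  }
  base <- dirname(samplesheet)
  lapply(seq_len(nrow(sheet)), function(i) {
    f <- sheet$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_gpr(f, col_map = col_map,
             timepoint = sheet$timepoint[i],
             replicate = sheet$replicate[i],
             dye_orientation = sheet$dye_orientation[i])
  })
}
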