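# Readers for the plain-text exchange formats: ABIDE-style phenotype CSV and
# ".1D" tab-delimited ROI time series.

#' Read a phenotype table
#'
#' Requires `SUB_ID`, `SITE_ID`, `AGE_AT_SCAN`, `SEX`, `DX_GROUP` columns;
#' extra columns are preserved. `DX_GROUP` may be coded 0/1 (1 = case) or
#' the ABIDE convention 1/2 (1 = case, 2 = control), which is mapped to 0/1.
#'
#' @param path CSV file path.
#' @return Typed tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("`%s` not found", path))
  ph <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(ph) == 0) abort("empty phenotype file")
  required <- c("SUB_ID", "SITE_ID", "AGE_AT_SCAN", "SEX", "DX_GROUP")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    abort(sprintf("missing phenotype column `%s`", missing_cols[1]))
  }
  if (!is.numeric(ph$AGE_AT_SCAN)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ph$AGE_AT_SCAN))))
    abort(sprintf("non-numeric AGE_AT_SCAN at row %d", bad[1]))
  }
  ph$SITE_ID <- as.character(ph$SITE_ID)
  if (all(ph$DX_GROUP %in% c(1, 2))) ph$DX_GROUP <- 2L - as.integer(ph$DX_GROUP)
  if (!all(ph$DX_GROUP %in% c(0, 1))) abort("DX_GROUP must be 0/1 (or ABIDE 1/2)")
  ph$DX_GROUP <- as.integer(ph$DX_GROUP)
  ph
}

#' Read one ROI time-series file
#'
#' Whitespace- or tab-delimited numeric text, one row per timepoint, one
#' column per ROI, no header; trailing whitespace tolerated.
#'
#' @param path File path.
#' @return T x M numeric matrix.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("`%s` not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("`%s` is empty", path))
  rows <- lapply(lines, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged row at line %d of `%s`", bad, path))
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) abort(sprintf("non-numeric value in `%s`", path))
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `phenotypes.csv` and `<SUB_ID>_<atlas>.1D`
#'   files.
#' @param atlases Optional atlas names; default inferred from file names.
#' @return A `popconn_cohort` (without a generator spec).
#' @export
read_cohort <- function(dir, atlases = NULL) {
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  files <- list.files(dir, pattern = "\\.1D$")
  if (is.null(atlases)) {
    atlases <- unique(sub("^[0-9]+_(.*)\\.1D$", "\\1", files))
  }
  series <- lapply(atlases, function(atlas) {
    lapply(seq_len(nrow(ph)), function(i) {
      p <- file.path(dir, sprintf("%d_%s.1D", ph$SUB_ID[i], atlas))
      if (!file.exists(p)) {
        abort(sprintf("missing series file for subject %d, atlas %s",
                      ph$SUB_ID[i], atlas))
      }
      read_timeseries(p)
    })
  })
  names(series) <- atlases
  structure(list(phenotypes = ph, series = series, spec = NULL),
            class = "popconn_cohort")
}
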