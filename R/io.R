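#' Read a tidy concentration-toxicity table
#'
#' Reads the delimited-text schema shared by real and synthetic data: one
#' row per (compound-or-ray, exposure time, concentration) with the mean
#' effect in percent, optional replicate columns `rep1..repN`, and
#' optional observed CI bounds. Malformed input is reported with the
#' offending rows.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_toxicity_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_toxicity_table(tb)
}

validate_toxicity_table <- function(tb) {
  required <- c("id", "role", "p_a", "p_b", "time_h", "conc_total", "effect")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mixray_io_error")
  }
  for (col in c("p_a", "p_b", "time_h", "conc_total", "effect")) {
    bad <- which(!is.finite(as.numeric(tb[[col]])))
    if (length(bad)) {
      abort(sprintf("non-numeric or missing `%s` in row(s) %s",
                    col, paste(head(bad, 5L), collapse = ", ")),
            class = "mixray_io_error")
    }
  }
  bad <- which(tb$conc_total <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive conc_total in row(s) %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "mixray_io_error")
  }
  key <- paste(tb$id, tb$time_h, tb$conc_total)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    abort(sprintf("duplicate (id, time_h, conc_total) key in row(s) %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "mixray_io_error")
  }
  if (!all(c("conc_a", "conc_b") %in% names(tb))) {
    tb$conc_a <- tb$p_a * tb$conc_total
    tb$conc_b <- tb$p_b * tb$conc_total
  }
  tibble::as_tibble(tb)
}

#' Write a tidy concentration-toxicity table
#'
#' @param data Tibble in the package's tidy schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toxicity_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Bioluminescence inhibition ratio from relative light units
#'
#' The toxicity readout of the assay: percent inhibition of
#' bioluminescence relative to controls,
#' `E = 100 (I_control - I_treatment) / I_control`. Stimulation
#' (hormesis) gives negative E.
#'
#' @param rlu_control Mean relative light units of control wells.
#' @param rlu_treatment Mean relative light units of exposed wells.
#' @return Effect in percent.
#' @export
inhibition_ratio <- function(rlu_control, rlu_treatment) {
  check_positive(rlu_control, "rlu_control")
  100 * (rlu_control - rlu_treatment) / rlu_control
}
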