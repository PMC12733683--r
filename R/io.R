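timecourse_columns <- c("condition", "replicate", "time_h", "biomass",
                        "product")

#' Read a time-course CSV
#'
#' Parses a long-format time-course table with header columns `condition`,
#' `replicate`, `time_h`, `biomass`, `product` (the `product` field may be
#' empty on any row). Rows are normalised to (condition, replicate, time)
#' order. Each violation — missing columns, non-numeric values, duplicated
#' (replicate, time) observations, negative values — raises a distinct,
#' messaged error.
#'
#' @param path Path to a UTF-8 CSV file.
#'
#' @return A tibble with the five canonical columns; `replicate` integer,
#'   `time_h`/`biomass`/`product` numeric (`product` may be `NA`).
#' @examples
#' tc <- simulate_timecourse(default_scenarios()$normal)
#' f <- tempfile(fileext = ".csv")
#' write_timecourse_csv(tc, f)
#' read_timecourse_csv(f)
#' @export
read_timecourse_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  miss <- setdiff(timecourse_columns, names(raw))
  if (length(miss) > 0) {
    stop("time-course CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  to_num <- function(col, required) {
    v <- raw[[col]]
    blank <- is.na(v) | trimws(v) == ""
    if (required && any(blank)) {
      stop("column `", col, "` has empty values", call. = FALSE)
    }
    out <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(out)
    if (any(bad)) {
      stop("column `", col, "` has non-numeric value(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    }
    out
  }

  tc <- tibble::tibble(
    condition = raw$condition,
    replicate = to_num("replicate", required = TRUE),
    time_h = to_num("time_h", required = TRUE),
    biomass = to_num("biomass", required = TRUE),
    product = to_num("product", required = FALSE)
  )
  if (any(tc$replicate != as.integer(tc$replicate))) {
    stop("column `replicate` must be integer-valued", call. = FALSE)
  }
  tc$replicate <- as.integer(tc$replicate)

  neg <- c("time_h", "biomass", "product")[c(
    any(tc$time_h < 0), any(tc$biomass < 0),
    any(tc$product < 0, na.rm = TRUE))]
  if (length(neg) > 0) {
    stop("negative values in column(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }

  tc <- dplyr::arrange(tc, .data$condition, .data$replicate, .data$time_h)
  dup <- duplicated(tc[c("condition", "replicate", "time_h")])
  if (any(dup)) {
    stop("duplicated (replicate, time) observation(s) within a condition",
         call. = FALSE)
  }
  tc
}

#' Write a time-course CSV
#'
#' Serialises a time-course table in canonical form: fixed column order,
#' rows sorted by (condition, replicate, time), numbers rendered with six
#' significant digits, missing product values as empty fields. Writing the
#' same table twice produces byte-identical files.
#'
#' @param tc A tibble with the canonical time-course columns (see
#'   [read_timecourse_csv()]).
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  miss <- setdiff(timecourse_columns, names(tc))
  if (length(miss) > 0) {
    stop("time course is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tc <- dplyr::arrange(tc, .data$condition, .data$replicate, .data$time_h)
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
  out <- tibble::tibble(
    condition = as.character(tc$condition),
    replicate = sprintf("%d", as.integer(tc$replicate)),
    time_h = fmt(tc$time_h),
    biomass = fmt(tc$biomass),
    product = fmt(tc$product)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
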