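#' Read a cohort CSV
#'
#' The cohort schema has columns `mouse_id` (string), `group` (string),
#' `day` (days), `volume_mm3` (positive), `censored` (0/1); UTF-8, header
#' row, `.` decimal separator. `(mouse_id, day)` pairs must be unique, and
#' no measurement may follow a mouse's censoring flag. Unknown extra columns
#' are accepted with a warning (forward compatibility).
#'
#' @param path file path.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "day", "volume_mm3", "censored")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(x), need)
  if (length(extra))
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  bad <- which(!is.finite(x$volume_mm3) | x$volume_mm3 <= 0)
  if (length(bad))
    stop(sprintf("cohort schema error: non-positive volume_mm3 at row %d",
                 bad[1]))
  dup <- duplicated(x[, c("mouse_id", "day")])
  if (any(dup))
    stop(sprintf("cohort schema error: duplicate (mouse_id, day) at row %d",
                 which(dup)[1]))
  for (id in unique(x$mouse_id)) {
    rows <- which(x$mouse_id == id)
    rows <- rows[order(x$day[rows])]
    cz <- which(x$censored[rows] == 1)
    if (length(cz) && cz[1] < length(rows))
      stop(sprintf(
        "cohort schema error: measurement after censoring flag for mouse %s (row %d)",
        id, rows[cz[1] + 1]))
  }
  x[, need]
}

#' Write a cohort CSV
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  need <- c("mouse_id", "group", "day", "volume_mm3", "censored")
  stopifnot(all(need %in% names(cohort)))
  utils::write.csv(cohort[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
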