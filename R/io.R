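#' Read a CD4 observation table
#'
#' Tab-delimited text with a header row and columns \code{SUBJID},
#' \code{AGE0_DAYS}, \code{TIME_DAYS}, \code{CD4}, then 0/1 covariate
#' columns.  The missing-value token is \code{"."}.  Rows with missing or
#' non-positive CD4 are dropped (count reported via a message and the
#' \code{"n_dropped"} attribute).  Duplicate (subject, time) rows are
#' retained -- replicate measurements are legal.
#'
#' @param path file path.
#' @return A \code{\link{cd4_dataset}} with attribute \code{n_dropped}.
#' @export
read_cd4_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                    colClasses = "character", check.names = FALSE)
  required <- c("SUBJID", "AGE0_DAYS", "TIME_DAYS", "CD4")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad)) {
      stop(sprintf("unparseable number in column %s, row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]))
    }
    x
  }
  covs <- setdiff(names(raw), required)
  df <- data.frame(SUBJID = raw$SUBJID, AGE0_DAYS = num("AGE0_DAYS"),
                   TIME_DAYS = num("TIME_DAYS"), CD4 = num("CD4"),
                   stringsAsFactors = FALSE)
  for (cv in covs) df[[cv]] <- num(cv)
  drop <- is.na(df$CD4) | df$CD4 <= 0
  n_dropped <- sum(drop)
  if (n_dropped) {
    message(sprintf("%s: dropped %d row(s) with missing or non-positive CD4",
                    basename(path), n_dropped))
  }
  out <- cd4_dataset(df[!drop, , drop = FALSE], covariates = covs)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a CD4 observation table
#'
#' Deterministic tab-delimited output: concentrations rounded to 0.01
#' cells/uL, ages and times to 0.01 days, covariate columns in declaration
#' order.  An empty dataset produces a header-only file.
#'
#' @param dataset a \code{\link{cd4_dataset}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cd4_table <- function(dataset, path) {
  covs <- attr(dataset, "covariates")
  df <- as.data.frame(dataset)[, c("SUBJID", "AGE0_DAYS", "TIME_DAYS",
                                   "CD4", covs), drop = FALSE]
  df$AGE0_DAYS <- sprintf("%.2f", df$AGE0_DAYS)
  df$TIME_DAYS <- sprintf("%.2f", df$TIME_DAYS)
  df$CD4 <- sprintf("%.2f", df$CD4)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  invisible(path)
}
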