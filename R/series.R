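#' Truncation series of NMR readouts
#'
#' Ordered readouts of one size-defined unsaturated parent fraction after
#' 0, 1, 2, ... exolytic cuts. Each cut exposes the next internal residue
#' as the neighbour of the Delta terminus, so the series turns internal
#' positions into directly readable H-4 signals; the reducing end is
#' unaffected by exolytic truncation.
#'
#' @param dp parent degree of polymerization (>= 2).
#' @param readouts list of [nmr_readout()] objects, named by cut count
#'   (`"0"`, `"1"`, ...) or unnamed and taken as cuts `0, 1, ...`. The
#'   `cuts = 0` (parent) entry is required.
#' @return Object of class `truncation_series`.
#' @export
truncation_series <- function(dp, readouts) {
  dp <- as.integer(dp)
  stopifnot(dp >= 2L, is.list(readouts), length(readouts) >= 1L)
  if (is.null(names(readouts)) || all(names(readouts) == ""))
    names(readouts) <- as.character(seq_along(readouts) - 1L)
  cuts <- as.integer(names(readouts))
  if (anyNA(cuts) || any(cuts < 0L) || anyDuplicated(cuts))
    stop("readouts must be keyed by distinct non-negative cut counts", call. = FALSE)
  if (!0L %in% cuts)
    stop("the cuts = 0 (parent) readout is required", call. = FALSE)
  if (any(cuts > dp - 2L))
    stop("cut count exceeds dp - 2; the truncated product would have no Delta neighbour",
         call. = FALSE)
  ok <- vapply(readouts, inherits, logical(1L), what = "nmr_readout")
  if (!all(ok)) stop("all readouts must be nmr_readout objects", call. = FALSE)
  o <- order(cuts)
  structure(list(dp = dp, readouts = readouts[o]), class = "truncation_series")
}

#' @export
print.truncation_series <- function(x, ...) {
  cat(sprintf("<truncation_series> parent DP %d, readouts at cuts {%s}\n",
              x$dp, paste(names(x$readouts), collapse = ", ")))
  invisible(x)
}

series_readout <- function(series, cuts) series$readouts[[as.character(cuts)]]

#' Read / write a truncation series as JSON
#'
#' Schema: `{dp, readouts: [{cuts, h4_dG, h4_dM, re_G, re_M}, ...]}`.
#'
#' @param path file path.
#' @return [read_series_json()] returns a [truncation_series()].
#' @export
read_series_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$dp) || is.null(x$readouts))
    stop("series JSON must have fields 'dp' and 'readouts'", call. = FALSE)
  readouts <- list()
  for (r in x$readouts) {
    for (f in c("cuts", "h4_dG", "h4_dM", "re_G", "re_M"))
      if (is.null(r[[f]])) stop("series readout is missing field '", f, "'", call. = FALSE)
    readouts[[as.character(r$cuts)]] <-
      nmr_readout(r$h4_dG, r$h4_dM, r$re_G, r$re_M)
  }
  truncation_series(x$dp, readouts)
}

#' @rdname read_series_json
#' @param series a [truncation_series()].
#' @export
write_series_json <- function(series, path) {
  readouts <- lapply(names(series$readouts), function(k) {
    r <- series$readouts[[k]]
    list(cuts = as.integer(k), h4_dG = r$h4_dG, h4_dM = r$h4_dM,
         re_G = r$re_G, re_M = r$re_M)
  })
  jsonlite::write_json(list(meta = report_meta(), dp = series$dp,
                            readouts = readouts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
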