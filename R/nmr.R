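#' Chemical-shift assignment table (documentation constants)
#'
#' The four diagnostic 1H resonances used for quantification, in ppm:
#' the H-4 proton of the Delta terminus reports whether its neighbour is G
#' (5.71 or 5.67 ppm) or M (5.61 or 5.56 ppm), and the beta-anomeric proton
#' of the reducing-end residue is a doublet at 4.71 ppm (3J_HH = 8.4 Hz)
#' for G versus a singlet in 4.70-4.80 ppm for M. Quantification itself
#' uses integrated areas, never ppm; this table is reference metadata.
#'
#' @return Named list of assignment constants.
#' @export
assignment_table <- function() {
  list(h4_dG_ppm = c(5.71, 5.67),
       h4_dM_ppm = c(5.61, 5.56),
       re_G_ppm = 4.71, re_G_J_Hz = 8.4,
       re_M_ppm_range = c(4.70, 4.80))
}

#' Integrated NMR signal areas for one sample
#'
#' Four integrated areas, in arbitrary units (only ratios are meaningful):
#' H-4 of the Delta unit with a G neighbour (`h4_dG`), with an M neighbour
#' (`h4_dM`), and the beta-anomeric reducing-end areas for G (`re_G`,
#' doublet) and M (`re_M`, singlet).
#'
#' @param h4_dG,h4_dM,re_G,re_M non-negative signal areas.
#' @return Object of class `nmr_readout`.
#' @export
nmr_readout <- function(h4_dG, h4_dM, re_G, re_M) {
  v <- c(h4_dG = h4_dG, h4_dM = h4_dM, re_G = re_G, re_M = re_M)
  if (any(!is.finite(v)) || any(v < 0))
    stop("signal areas must be finite and >= 0", call. = FALSE)
  structure(as.list(v), class = "nmr_readout")
}

#' @export
print.nmr_readout <- function(x, ...) {
  cat(sprintf("<nmr_readout> h4_dG=%g h4_dM=%g re_G=%g re_M=%g\n",
              x$h4_dG, x$h4_dM, x$re_G, x$re_M))
  invisible(x)
}

#' Forward NMR model: mixture to integrated signal areas
#'
#' Each chain contributes exactly one H-4 Delta proton and one reducing-end
#' beta-anomeric proton, so areas are proportional to moles with constant
#' 1: `h4_dG` is the summed fraction of chains whose position-1 residue
#' (the neighbour of the Delta unit) is G, `h4_dM` likewise for M, and
#' `re_G`/`re_M` give the reducing-end composition.
#'
#' @param mix an unsaturated [oligo_mixture()] with DP >= 2.
#' @return An [nmr_readout()].
#' @export
forward_readout <- function(mix) {
  if (!is_unsaturated(mix))
    stop("no Delta signal: mixture is saturated", call. = FALSE)
  if (attr(mix, "dp") < 2L)
    stop("forward model requires DP >= 2", call. = FALSE)
  first <- vapply(mix$sequence, function(s) parse_sequence(s)$residues[1L],
                  character(1L))
  last <- vapply(mix$sequence, function(s) {
    r <- parse_sequence(s)$residues
    r[length(r)]
  }, character(1L))
  nmr_readout(h4_dG = sum(mix$fraction[first == "G"]),
              h4_dM = sum(mix$fraction[first == "M"]),
              re_G = sum(mix$fraction[last == "G"]),
              re_M = sum(mix$fraction[last == "M"]))
}

#' Fraction of G adjacent to the Delta terminus
#'
#' @param readout an [nmr_readout()].
#' @return `h4_dG / (h4_dG + h4_dM)`, in \[0, 1\].
#' @export
neighbor_marginal <- function(readout) {
  s <- readout$h4_dG + readout$h4_dM
  if (s <= 0)
    stop("undefined marginal: both H-4 Delta areas are zero", call. = FALSE)
  readout$h4_dG / s
}

#' Reducing-end composition from anomeric areas
#'
#' @param readout an [nmr_readout()].
#' @return Named numeric `c(G = ..., M = ...)` summing to 1.
#' @export
reducing_end_composition <- function(readout) {
  s <- readout$re_G + readout$re_M
  if (s <= 0)
    stop("undefined reducing-end composition: both anomeric areas are zero",
         call. = FALSE)
  c(G = readout$re_G / s, M = readout$re_M / s)
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- strsplit(ratio, ":", fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) stop("malformed ratio string: ", ratio, call. = FALSE)
  } else {
    v <- as.numeric(ratio)
  }
  if (length(v) < 2L || any(!is.finite(v)) || any(v <= 0))
    stop("ratio components must be positive numbers", call. = FALSE)
  v
}

#' Convert a molar ratio to rounded percentages
#'
#' Display-rounding convention for size-class composition tables: integers
#' for two-component ratios, one decimal for three or more components.
#'
#' @param ratio a string `"a:b"` / `"a:b:c"` or a numeric vector.
#' @return Numeric vector of percentages (rounded per the convention).
#' @examples
#' ratio_to_fractions("3.4:1.0")        # 77 23
#' ratio_to_fractions("1:1.5:3.5:5.25") # 8.9 13.3 31.1 46.7
#' @export
ratio_to_fractions <- function(ratio) {
  v <- parse_ratio(ratio)
  pct <- 100 * v / sum(v)
  if (length(v) == 2L) round(pct) else round(pct, 1L)
}

#' Read / write NMR readouts
#'
#' JSON form: `{"h4_dG": x, "h4_dM": x, "re_G": x, "re_M": x}`. TSV form:
#' one row per sample with a `sample_id` column plus the four area columns.
#'
#' @param path file path.
#' @return [read_readout_json()] returns an [nmr_readout()];
#'   [read_readouts_tsv()] a named list of readouts keyed by `sample_id`.
#' @export
read_readout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("h4_dG", "h4_dM", "re_G", "re_M"))
    if (is.null(x[[f]])) stop("readout JSON is missing field '", f, "'", call. = FALSE)
  nmr_readout(x$h4_dG, x$h4_dM, x$re_G, x$re_M)
}

#' @rdname read_readout_json
#' @param readout an [nmr_readout()].
#' @export
write_readout_json <- function(readout, path) {
  jsonlite::write_json(c(list(meta = report_meta()), unclass(readout)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_readout_json
#' @export
read_readouts_tsv <- function(path) {
  df <- read_tsv_skip_header(path)
  need <- c("sample_id", "h4_dG", "h4_dM", "re_G", "re_M")
  if (!all(need %in% names(df)))
    stop("readout TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    nmr_readout(df$h4_dG[i], df$h4_dM[i], df$re_G[i], df$re_M[i]))
  stats::setNames(out, df$sample_id)
}

#' @rdname read_readout_json
#' @param readouts named list of [nmr_readout()] objects.
#' @export
write_readouts_tsv <- function(readouts, path) {
  df <- do.call(rbind, lapply(names(readouts), function(id) {
    r <- readouts[[id]]
    data.frame(sample_id = id, h4_dG = r$h4_dG, h4_dM = r$h4_dM,
               re_G = r$re_G, re_M = r$re_M, stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(df, path)
}
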