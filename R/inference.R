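#' Positional G marginals from a truncation series
#'
#' Position `k + 1` of the parent chain becomes the neighbour of the Delta
#' terminus after `k` exolytic cuts, so its G frequency is read directly
#' from the H-4 areas of the k-cut readout; the final (reducing-end)
#' position comes from the parent's anomeric areas, since exolytic
#' truncation never touches the reducing end.
#'
#' @param series a [truncation_series()] complete for cuts `0 .. dp - 3`.
#' @return Numeric vector `p[1..dp-1]` of G fractions per residue position.
#' @export
marginals_from_series <- function(series) {
  n <- series$dp
  if (n == 2L) {
    # one residue letter: position 1 is the reducing end; the H-4 areas
    # read it directly.
    return(neighbor_marginal(series_readout(series, 0L)))
  }
  need <- 0:(n - 3L)
  have <- as.integer(names(series$readouts))
  missing <- setdiff(need, have)
  if (length(missing))
    stop("incomplete series: missing readouts at cuts ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- vapply(need, function(k) neighbor_marginal(series_readout(series, k)),
              numeric(1L))
  re <- reducing_end_composition(series_readout(series, 0L))
  c(p, re[["G"]])
}

#' Joint composition under positional independence
#'
#' Reconstructs the mixture as the outer product of the positional G
#' marginals: `fraction(seq) = prod(p_i if G at i else 1 - p_i)`.
#' Positional marginals alone cannot identify correlations between
#' positions; independence is the maximum-entropy completion and is
#' surfaced as an explicit assumption in every report. Species below
#' `prune_threshold` are dropped and the remainder renormalized.
#'
#' @param p numeric vector of per-position G fractions, each in \[0, 1\].
#' @param prune_threshold drop species with fraction below this (default
#'   0.5\%).
#' @return Object of class `inferred_composition`: list with `mixture`
#'   (an [oligo_mixture()]), `marginals`, `pruned_mass`, and `assumption`.
#' @examples
#' joint_under_independence(c(3.5 / 4.5, 1.5 / 2.5, 0, 0))
#' @export
joint_under_independence <- function(p, prune_threshold = 0.005) {
  p <- as.numeric(p)
  stopifnot(length(p) >= 1L, all(p >= 0 & p <= 1))
  if (length(p) > 20L) stop("enumeration over 2^", length(p),
                            " sequences refused", call. = FALSE)
  grid <- expand.grid(rep(list(c("G", "M")), length(p)),
                      stringsAsFactors = FALSE)
  fr <- apply(grid, 1L, function(row)
    prod(ifelse(row == "G", p, 1 - p)))
  seqs <- apply(grid, 1L, function(row) paste0("Δ", paste(row, collapse = "")))
  keep <- fr >= prune_threshold & fr > 0
  pruned_mass <- sum(fr[!keep])
  fr <- fr[keep]; seqs <- seqs[keep]
  mix <- oligo_mixture(seqs, fr / sum(fr))
  structure(list(mixture = mix, marginals = p, pruned_mass = pruned_mass,
                 assumption = "positional independence (joint = outer product of marginals; correlations are not identifiable from marginal readouts)"),
            class = "inferred_composition")
}

#' @export
print.inferred_composition <- function(x, ...) {
  cat(sprintf("<inferred_composition> DP %d, %d species (pruned mass %.4f)\n",
              attr(x$mixture, "dp"), nrow(x$mixture), x$pruned_mass))
  tab <- x$mixture[order(-x$mixture$fraction), ]
  tab$percent <- table2_percent(tab$fraction)
  print.data.frame(tab, row.names = FALSE)
  cat("marginals (G fraction by position):",
      paste(sprintf("%.3f", x$marginals), collapse = " "), "\n")
  cat("assumption:", x$assumption, "\n")
  if (!is.null(x$consistency))
    cat(sprintf("consistency residual: %.4g%s\n", x$consistency$residual,
                if (x$consistency$flagged) "  [exceeds tolerance]" else ""))
  invisible(x)
}

#' Composition-table display rounding
#'
#' Integers for two-species mixtures, one decimal otherwise; full precision
#' is always retained internally.
#'
#' @param fractions numeric molar fractions (summing to 1) or percentages.
#' @return Percentages rounded per the convention.
#' @export
table2_percent <- function(fractions) {
  pct <- if (sum(fractions) <= 1.5) 100 * fractions else fractions
  if (length(pct) == 2L) round(pct) else round(pct, 1L)
}

#' Direct sequencing of disaccharide / trisaccharide fractions
#'
#' Small unsaturated fractions are sequenced from a single readout: for
#' DP 2 the composition is read from the H-4 Delta areas alone (the one
#' residue letter is both the Delta neighbour and the reducing end); for
#' DP 3 position 1 comes from the H-4 areas and position 2 from the
#' anomeric reducing-end areas, joined under independence when both are
#' mixed.
#'
#' @param readout an [nmr_readout()].
#' @param dp 2 or 3.
#' @param prune_threshold see [joint_under_independence()].
#' @return An `inferred_composition`.
#' @export
sequence_small <- function(readout, dp, prune_threshold = 0.005) {
  dp <- as.integer(dp)
  if (!dp %in% c(2L, 3L)) stop("sequence_small handles dp 2 and 3 only", call. = FALSE)
  p <- if (dp == 2L) {
    neighbor_marginal(readout)
  } else {
    c(neighbor_marginal(readout), reducing_end_composition(readout)[["G"]])
  }
  joint_under_independence(p, prune_threshold = prune_threshold)
}

#' Self-consistency of an inferred composition against its series
#'
#' Recomputes forward readouts of the inferred mixture and of each of its
#' truncations and compares the implied positional marginals with those
#' extracted from the observed series. An independence-constructed joint
#' always reproduces the observed marginals (moment matching), so a
#' residual above tolerance indicates a processing inconsistency; a zero
#' residual does NOT establish the joint, because anti-correlated mixtures
#' share the same marginals.
#'
#' @param inferred an `inferred_composition`.
#' @param series the [truncation_series()] it was produced from.
#' @param tolerance residual above which the result is flagged.
#' @return list with `residual` (max abs marginal deviation), `flagged`,
#'   `per_position` data.frame, and `note` on identifiability.
#' @export
consistency_check <- function(inferred, series, tolerance = 0.02) {
  observed <- marginals_from_series(series)
  mix <- inferred$mixture
  n <- attr(mix, "dp")
  implied <- numeric(n - 1L)
  for (k in 0:(max(n - 3L, 0L))) {
    tr <- truncate_mixture(mix, k)
    implied[k + 1L] <- neighbor_marginal(forward_readout(tr))
  }
  implied[n - 1L] <- reducing_end_composition(forward_readout(mix))[["G"]]
  per <- data.frame(position = seq_len(n - 1L),
                    observed = as.numeric(observed),
                    implied = implied)
  residual <- max(abs(per$observed - per$implied))
  list(residual = residual, flagged = residual > tolerance,
       per_position = per,
       note = paste("marginal agreement does not identify the joint:",
                    "mixtures with correlated positions share these marginals;",
                    "the reconstruction assumes positional independence"))
}

#' Sequence a size fraction from a truncation series
#'
#' Top-level inference: extracts positional marginals, builds the
#' independence joint, and attaches the self-consistency report.
#'
#' @param series a [truncation_series()].
#' @param prune_threshold see [joint_under_independence()].
#' @param tolerance see [consistency_check()].
#' @return An `inferred_composition` with a `consistency` element.
#' @export
infer_sequences <- function(series, prune_threshold = 0.005, tolerance = 0.02) {
  p <- marginals_from_series(series)
  inferred <- joint_under_independence(p, prune_threshold = prune_threshold)
  inferred$consistency <- consistency_check(inferred, series, tolerance = tolerance)
  inferred
}

#' Write an inference report
#'
#' Machine-readable JSON twin plus a sequences/fractions TSV. The JSON
#' embeds package version and the marginals, pruned mass, assumption text
#' and consistency residuals.
#'
#' @param inferred an `inferred_composition`.
#' @param path_json JSON output path (`NULL` to skip).
#' @param path_tsv TSV output path (`NULL` to skip).
#' @return list of written paths, invisibly.
#' @export
write_inference_report <- function(inferred, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    payload <- list(
      meta = report_meta(config = inferred$marginals),
      dp = attr(inferred$mixture, "dp"),
      sequences = inferred$mixture$sequence,
      fractions = inferred$mixture$fraction,
      percent_display = table2_percent(inferred$mixture$fraction),
      marginals = inferred$marginals,
      pruned_mass = inferred$pruned_mass,
      assumption = inferred$assumption)
    if (!is.null(inferred$consistency))
      payload$consistency <- inferred$consistency[c("residual", "flagged", "note")]
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_tsv)) {
    df <- data.frame(sequence = inferred$mixture$sequence,
                     molar_fraction = inferred$mixture$fraction,
                     percent_display = table2_percent(inferred$mixture$fraction),
                     stringsAsFactors = FALSE)
    write_tsv_with_header(df, path_tsv)
  }
  invisible(list(json = path_json, tsv = path_tsv))
}
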