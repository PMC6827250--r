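#' Molar mixture of chains within one size class
#'
#' A mixture is a molar composition over distinct chains that share the same
#' degree of polymerization, terminal saturation state and reducing-end
#' label (the situation of a gel-filtration size fraction). Fractions are
#' dimensionless, strictly positive, and must sum to 1.
#'
#' @param sequences character vector of chain notation strings (see
#'   [parse_sequence()]); duplicates are not allowed.
#' @param fractions numeric molar fractions, same length as `sequences`.
#' @param renormalize if `TRUE`, fractions are rescaled to sum to 1 (with a
#'   warning when the deviation exceeds `1e-6`); if `FALSE` a sum deviating
#'   from 1 by more than `1e-9` is an error.
#' @return An object of class `oligo_mixture`: a data.frame with columns
#'   `sequence` and `fraction` and attributes `dp`, `unsaturated`,
#'   `label_2ab`.
#' @examples
#' udp5 <- oligo_mixture(c("ΔGGMM", "ΔMGMM", "ΔGMMM", "ΔMMMM"),
#'                       c(0.467, 0.133, 0.311, 0.089))
#' @export
oligo_mixture <- function(sequences, fractions, renormalize = FALSE) {
  stopifnot(length(sequences) == length(fractions), length(sequences) >= 1L)
  chains <- lapply(sequences, as_glycan_chain)
  canon <- vapply(chains, format, character(1L))
  if (anyDuplicated(canon))
    stop("duplicate sequences in mixture: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "), call. = FALSE)
  dps <- vapply(chains, dp, integer(1L))
  unsat <- vapply(chains, function(ch) ch$unsaturated, logical(1L))
  lab <- vapply(chains, function(ch) ch$label_2ab, logical(1L))
  if (length(unique(dps)) != 1L)
    stop("all chains in a mixture must share one DP; got ",
         paste(sort(unique(dps)), collapse = ", "), call. = FALSE)
  if (length(unique(unsat)) != 1L || length(unique(lab)) != 1L)
    stop("all chains in a mixture must share NRE state and RE label", call. = FALSE)
  fractions <- as.numeric(fractions)
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("molar fractions must be finite and > 0", call. = FALSE)
  s <- sum(fractions)
  if (renormalize) {
    if (abs(s - 1) > 1e-6)
      warning(sprintf("mixture fractions sum to %.8f; renormalizing", s),
              call. = FALSE)
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("mixture fractions must sum to 1 (got %.10f); use renormalize = TRUE", s),
         call. = FALSE)
  } else {
    fractions <- fractions / s
  }
  out <- data.frame(sequence = canon, fraction = fractions,
                    stringsAsFactors = FALSE)
  structure(out, class = c("oligo_mixture", "data.frame"),
            dp = dps[[1L]], unsaturated = unsat[[1L]], label_2ab = lab[[1L]])
}

#' @export
dp.oligo_mixture <- function(x) attr(x, "dp")

is_unsaturated <- function(mix) isTRUE(attr(mix, "unsaturated"))

#' @export
print.oligo_mixture <- function(x, ...) {
  cat(sprintf("<oligo_mixture> DP %d, %s, %d species\n", attr(x, "dp"),
              if (attr(x, "unsaturated")) "unsaturated" else "saturated",
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' G frequency at one chain position
#'
#' Position 1 is the first residue letter after the Delta terminus (for an
#' unsaturated mixture) or the NRE residue itself (saturated).
#'
#' @param mix an [oligo_mixture()].
#' @param position integer residue-letter position.
#' @return Molar frequency of G at that position, in \[0, 1\].
#' @export
position_g_frequency <- function(mix, position) {
  letters <- vapply(mix$sequence,
                    function(s) parse_sequence(s)$residues[position],
                    character(1L))
  sum(mix$fraction[letters == "G"])
}

#' Read / write a mixture TSV
#'
#' Columns `sequence` and `molar_fraction`, header required. On load,
#' fractions are renormalized with a warning if their sum deviates from 1
#' by more than `1e-6`.
#'
#' @param path file path.
#' @return [read_mixture_tsv()] returns an [oligo_mixture()];
#'   [write_mixture_tsv()] returns `path` invisibly.
#' @export
read_mixture_tsv <- function(path) {
  df <- read_tsv_skip_header(path)
  if (!all(c("sequence", "molar_fraction") %in% names(df)))
    stop("mixture TSV must have columns 'sequence' and 'molar_fraction'",
         call. = FALSE)
  oligo_mixture(df$sequence, df$molar_fraction, renormalize = TRUE)
}

#' @rdname read_mixture_tsv
#' @param mix an [oligo_mixture()].
#' @export
write_mixture_tsv <- function(mix, path) {
  df <- data.frame(sequence = mix$sequence, molar_fraction = mix$fraction,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path)
}
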