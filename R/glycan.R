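#' Construct an alginate glycan chain
#'
#' An alginate chain is an ordered run of uronate residues written from the
#' non-reducing end (NRE). Residue letters are `M` (beta-D-mannuronate) and
#' `G` (alpha-L-guluronate). Lyase cleavage by beta-elimination leaves a
#' 4,5-unsaturated ring (the "Delta unit") at the NRE whose original M/G
#' identity is destroyed; unsaturation is therefore stored as a terminal
#' *state*, not as a residue letter, and an unsaturated chain of degree of
#' polymerization (DP) n carries only n - 1 residue letters.
#'
#' @param residues character vector of residue letters, `"M"` or `"G"`,
#'   non-reducing end first. At least one letter is required.
#' @param unsaturated logical; `TRUE` if the NRE carries the 4,5-unsaturated
#'   Delta ring.
#' @param label_2ab logical; `TRUE` if the reducing end is derivatized with
#'   2-aminobenzamide (2-AB) for fluorescent detection.
#' @return An object of class `glycan_chain`.
#' @seealso [parse_sequence()], [dp()], [composition()]
#' @examples
#' glycan_chain(c("G", "M", "M"), unsaturated = TRUE)  # "ΔGMM", DP 4
#' @export
glycan_chain <- function(residues, unsaturated = FALSE, label_2ab = FALSE) {
  residues <- as.character(residues)
  if (length(residues) < 1L)
    stop("a glycan chain needs at least one M/G residue letter", call. = FALSE)
  bad <- which(!residues %in% c("M", "G"))
  if (length(bad))
    stop(sprintf("invalid residue code '%s' at residue position %d (only M and G exist)",
                 residues[bad[1L]], bad[1L]), call. = FALSE)
  stopifnot(is.logical(unsaturated), length(unsaturated) == 1L,
            is.logical(label_2ab), length(label_2ab) == 1L)
  structure(list(residues = residues,
                 unsaturated = unsaturated,
                 label_2ab = label_2ab),
            class = "glycan_chain")
}

#' Parse chain notation
#'
#' Grammar: `[Δ|d]? [MG]+ (-2AB)?`, leftmost symbol = non-reducing end.
#' `d` is an ASCII alias for the Greek Delta so files survive
#' encoding-hostile tooling; [format()] always emits the canonical
#' `"Δ"` form.
#'
#' @param text a single notation string such as `"ΔGMM"`, `"dGMM"`,
#'   `"MMMM"` or `"ΔMMM-2AB"`.
#' @return A [glycan_chain()].
#' @examples
#' parse_sequence("ΔGMM")
#' format(parse_sequence("dMMMM-2AB"))  # "ΔMMMM-2AB"
#' @export
parse_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string", call. = FALSE)
  s <- text
  label_2ab <- grepl("-2AB$", s)
  if (label_2ab) s <- sub("-2AB$", "", s)
  chars <- strsplit(s, "", fixed = FALSE)[[1L]]
  if (!length(chars))
    stop(sprintf("empty sequence in \"%s\"", text), call. = FALSE)
  unsaturated <- chars[1L] %in% c("Δ", "d")
  offset <- 0L
  if (unsaturated) {
    chars <- chars[-1L]
    offset <- 1L
  }
  if (!length(chars))
    stop(sprintf("\"%s\" has no M/G residue letters", text), call. = FALSE)
  bad <- which(!chars %in% c("M", "G"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d in \"%s\"",
                 chars[bad[1L]], bad[1L] + offset, text), call. = FALSE)
  glycan_chain(chars, unsaturated = unsaturated, label_2ab = label_2ab)
}

#' @export
format.glycan_chain <- function(x, ...) {
  paste0(if (x$unsaturated) "Δ" else "",
         paste(x$residues, collapse = ""),
         if (x$label_2ab) "-2AB" else "")
}

#' @export
print.glycan_chain <- function(x, ...) {
  cat(sprintf("<glycan_chain> %s  (DP %d, NRE %s, RE %s)\n",
              format(x), dp(x),
              if (x$unsaturated) "unsaturated" else "saturated",
              if (x$label_2ab) "2-AB" else "free"))
  invisible(x)
}

#' Coerce to a glycan chain
#' @param x a `glycan_chain` or a notation string.
#' @return A [glycan_chain()].
#' @export
as_glycan_chain <- function(x) {
  if (inherits(x, "glycan_chain")) return(x)
  if (is.character(x)) return(parse_sequence(x))
  stop("cannot coerce object of class '", class(x)[1L], "' to glycan_chain",
       call. = FALSE)
}

#' Degree of polymerization
#'
#' Number of monosaccharide rings in a chain. The Delta terminus counts as
#' one ring even though its residue identity is erased, so an unsaturated
#' chain has `length(residues) + 1` rings.
#'
#' @param x a [glycan_chain()] or notation string.
#' @return integer DP.
#' @export
dp <- function(x) UseMethod("dp")

#' @export
dp.glycan_chain <- function(x) length(x$residues) + as.integer(x$unsaturated)

#' @export
dp.character <- function(x) vapply(x, function(s) dp(parse_sequence(s)), integer(1L))

#' Residue composition of a chain
#'
#' @param x a [glycan_chain()] or notation string.
#' @return A list with integer counts `M` and `G` and logical `delta`
#'   (whether the chain carries a Delta terminus).
#' @examples
#' composition("ΔGGMM")  # list(M = 2, G = 2, delta = TRUE)
#' @export
composition <- function(x) {
  x <- as_glycan_chain(x)
  list(M = sum(x$residues == "M"),
       G = sum(x$residues == "G"),
       delta = x$unsaturated)
}

#' Construct a released monomer
#'
#' Monomeric species released by exolytic digestion. `UDP1` is the
#' unsaturated monomer, which is non-enzymatically converted to DEH
#' (4-deoxy-L-erythro-5-hexoseulose uronic acid) and then to TPC (its
#' cyclized hydrate); conversion order is UDP1 -> DEH -> TPC only. `M` and
#' `G` are saturated free uronic acids with intact ring identity.
#'
#' @param species one of `"UDP1"`, `"DEH"`, `"TPC"`, `"M"`, `"G"`.
#' @return An object of class `monomer`.
#' @export
monomer <- function(species) {
  species <- as.character(species)
  if (length(species) != 1L || !species %in% c("UDP1", "DEH", "TPC", "M", "G"))
    stop("monomer species must be one of UDP1, DEH, TPC, M, G", call. = FALSE)
  structure(list(species = species), class = "monomer")
}

#' @export
format.monomer <- function(x, ...) x$species

#' @export
print.monomer <- function(x, ...) {
  cat(sprintf("<monomer> %s\n", x$species))
  invisible(x)
}

is_monomer <- function(x) inherits(x, "monomer")
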