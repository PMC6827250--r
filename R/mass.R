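# Monoisotopic constants (CODATA-derived, fixed in code).
# A glycosidically linked uronate residue is C6H8O6; a saturated free
# oligouronate adds one water of condensation. The unsaturated chain loses
# that water through beta-elimination, so its neutral mass is n * residue.
.mass_residue <- 176.03209   # C6H8O6
.mass_water   <- 18.010565   # H2O
.mass_proton  <- 1.007276    # H+

#' Monoisotopic mass constants
#'
#' @return Named list with `residue_mass` (glycosidically linked uronate,
#'   C6H8O6), `water_mass` and `proton_mass`, all monoisotopic in Da.
#' @export
mass_constants <- function() {
  list(residue_mass = .mass_residue,
       water_mass = .mass_water,
       proton_mass = .mass_proton)
}

#' Negative-mode m/z of an oligouronate or released monomer
#'
#' Computes the monoisotopic `[M - H]-` m/z and its nominal (integer)
#' value for a free-reducing-end chain or a released monomer:
#' an unsaturated DP n chain is `n * 176.0321 - 1.00728`; a saturated DP n
#' chain adds one water; UDP1 and DEH share the C6H8O6 skeleton
#' (nominal 175) and TPC is its hydrate C6H10O7 (nominal 193, identical to
#' a saturated free uronic acid).
#'
#' @param x a [glycan_chain()], [monomer()], or a notation string (monomer
#'   species names are recognised before chain notation).
#' @return List with `mz` (monoisotopic m/z) and `nominal` (integer).
#' @examples
#' mz_negative("ΔM")$nominal    # 351  (unsaturated disaccharide)
#' mz_negative("ΔGMM")$nominal  # 703
#' mz_negative("TPC")$nominal   # 193
#' @export
mz_negative <- function(x) UseMethod("mz_negative")

#' @export
mz_negative.glycan_chain <- function(x) {
  if (x$label_2ab)
    stop("unsupported adduct: 2-AB label mass is not modelled", call. = FALSE)
  n <- dp(x)
  neutral <- n * .mass_residue + if (x$unsaturated) 0 else .mass_water
  mz <- neutral - .mass_proton
  list(mz = mz, nominal = as.integer(round(mz)))
}

#' @export
mz_negative.monomer <- function(x) {
  neutral <- switch(x$species,
                    UDP1 = .mass_residue,
                    DEH = .mass_residue,
                    TPC = .mass_residue + .mass_water,
                    M = .mass_residue + .mass_water,
                    G = .mass_residue + .mass_water)
  mz <- neutral - .mass_proton
  list(mz = mz, nominal = as.integer(round(mz)))
}

#' @export
mz_negative.character <- function(x) {
  stopifnot(length(x) == 1L)
  if (x %in% c("UDP1", "DEH", "TPC")) return(mz_negative(monomer(x)))
  mz_negative(parse_sequence(x))
}

#' Tabulate masses for a set of sequences
#'
#' @param sequences character vector of chain notation strings or monomer
#'   species names.
#' @return data.frame with columns `sequence`, `dp`, `mz_monoisotopic`,
#'   `mz_nominal`.
#' @export
mass_report <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    r <- mz_negative(s)
    n <- if (s %in% c("UDP1", "DEH", "TPC")) 1L else dp(parse_sequence(s))
    data.frame(sequence = s, dp = n,
               mz_monoisotopic = r$mz, mz_nominal = r$nominal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a mass report TSV
#'
#' @param report data.frame from [mass_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mass_report <- function(report, path) {
  write_tsv_with_header(report, path)
}
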