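#' Endolytic cleavage-rate table
#'
#' Relative cleavage rate `k(a, b)` for the glycosidic bond a(1->4)b, where
#' `a` is the residue nearer the non-reducing end. A 2x2 bond-pair table is
#' the smallest model that can express a block preference such as
#' "G-block-preferring"; the default is a G-preferring preset (high k(G,G),
#' low k(M,M)), exposed as tunable configuration rather than a measured
#' fact. `min_nre_frag` / `min_re_frag` are the smallest fragment sizes (in
#' rings) the enzyme can leave on the non-reducing / reducing side; the
#' defaults of 2 reflect that endolytic digests contain no monomer.
#'
#' @param k named numeric vector with entries `GG`, `GM`, `MG`, `MM`
#'   (name = `a` then `b`); all >= 0, at least one > 0.
#' @param min_nre_frag,min_re_frag minimum fragment DP on each side.
#' @return Object of class `endo_rate_table`.
#' @export
endo_rate_table <- function(k = c(GG = 1.0, GM = 0.1, MG = 0.25, MM = 0.01),
                            min_nre_frag = 2L, min_re_frag = 2L) {
  stopifnot(all(c("GG", "GM", "MG", "MM") %in% names(k)))
  k <- k[c("GG", "GM", "MG", "MM")]
  if (any(k < 0) || all(k == 0))
    stop("rates must be >= 0 with at least one > 0", call. = FALSE)
  structure(list(k = k,
                 min_nre_frag = as.integer(min_nre_frag),
                 min_re_frag = as.integer(min_re_frag)),
            class = "endo_rate_table")
}

endo_k <- function(table, a, b) unname(table$k[paste0(a, b)])

#' Exolytic substrate-size rate profile
#'
#' Relative exolytic rate `r(dp)` as a piecewise-linear function of chain
#' length, with a flat "polymer" tail. The default profile encodes only two
#' anchors: the optimum sits at DP 4, and r(4)/r(polymer) = 6.5; the
#' remaining knots fall off smoothly on either side and are configuration,
#' not measurement.
#'
#' @param rates named numeric vector of knots, names = DP.
#' @param polymer tail value for `dp >= polymer_from`.
#' @param polymer_from DP at and beyond which the tail value applies.
#' @return Object of class `exo_rate_profile`.
#' @export
exo_rate_profile <- function(rates = c(`2` = 3.0, `3` = 5.0, `4` = 6.5,
                                       `5` = 5.5, `6` = 4.5, `7` = 3.8,
                                       `8` = 3.2, `9` = 2.6, `10` = 2.0),
                             polymer = 1.0, polymer_from = 20L) {
  dps <- as.integer(names(rates))
  stopifnot(!anyNA(dps), all(dps >= 2L), all(rates >= 0), polymer >= 0)
  o <- order(dps)
  structure(list(dp = dps[o], r = unname(rates[o]),
                 polymer = polymer, polymer_from = as.integer(polymer_from)),
            class = "exo_rate_profile")
}

#' Evaluate an exolytic rate profile
#'
#' @param profile an [exo_rate_profile()].
#' @param dp numeric vector of chain lengths; `Inf` denotes the polymer tail.
#' @return Relative rates `r(dp)`, linearly interpolated between knots and
#'   between the last knot and the polymer tail.
#' @export
exo_rate <- function(profile, dp) {
  knots_x <- c(profile$dp, profile$polymer_from)
  knots_y <- c(profile$r, profile$polymer)
  vapply(dp, function(n) {
    if (is.infinite(n) || n >= profile$polymer_from) return(profile$polymer)
    if (n <= knots_x[1L]) return(knots_y[1L])
    stats::approx(knots_x, knots_y, xout = n)$y
  }, numeric(1L))
}

#' Endolytic cleavage of one bond
#'
#' Cleaves the glycosidic bond between residue letters `bond_index` and
#' `bond_index + 1` (counted from the non-reducing end; for an unsaturated
#' chain the Delta terminus is not a residue letter and its bond to the
#' first letter is not indexable). Beta-elimination erases the identity of
#' the residue on the reducing-end side of the cut: the upstream fragment
#' inherits the parent NRE state and gains a free saturated reducing end,
#' while the downstream fragment becomes unsaturated with its first ring's
#' identity destroyed. A 2-AB label stays on the downstream (reducing-end)
#' fragment.
#'
#' @param chain a [glycan_chain()] or notation string.
#' @param bond_index integer in `1 .. length(residues) - 1`.
#' @return list with `upstream` (a `glycan_chain`) and `downstream`
#'   (a `glycan_chain`, or the `UDP1` [monomer()] in the edge case where
#'   the downstream fragment is the single erased ring).
#' @examples
#' endo_cleave("GGMM", 2)    # "GG" + "ΔM"
#' endo_cleave("ΔGGMM", 1)   # "ΔG" + "ΔMM"
#' @export
endo_cleave <- function(chain, bond_index) {
  chain <- as_glycan_chain(chain)
  n <- length(chain$residues)
  bond_index <- as.integer(bond_index)
  if (bond_index < 1L || bond_index > n - 1L)
    stop(sprintf("bond_index must be in 1..%d", n - 1L), call. = FALSE)
  upstream <- glycan_chain(chain$residues[seq_len(bond_index)],
                           unsaturated = chain$unsaturated, label_2ab = FALSE)
  down_letters <- if (bond_index + 2L <= n) chain$residues[(bond_index + 2L):n] else character(0L)
  downstream <- if (length(down_letters) == 0L && !chain$label_2ab) {
    monomer("UDP1")  # single erased ring; unreachable when min_re_frag >= 2
  } else if (length(down_letters) == 0L) {
    stop("cleavage would leave a bare labelled Delta ring", call. = FALSE)
  } else {
    glycan_chain(down_letters, unsaturated = TRUE, label_2ab = chain$label_2ab)
  }
  list(upstream = upstream, downstream = downstream)
}

#' One exolytic step from the non-reducing end
#'
#' Removes the terminal NRE ring. The released monomer inherits the parent
#' NRE state: `UDP1` if the parent was unsaturated, otherwise the saturated
#' free uronic acid of residue 1. The newly exposed ring becomes the Delta
#' terminus of the remainder (identity erased) -- except when the parent is
#' a disaccharide, in which case the remaining reducing-end ring is released
#' as a saturated monomer with its identity intact (no glycosidic bond is
#' left to eliminate into). 2-AB-labelled disaccharides are resistant
#' (steric hindrance of the label), so labelled trajectories stop at the
#' labelled unsaturated disaccharide.
#'
#' @param chain a [glycan_chain()] or notation string with DP >= 2.
#' @return list with `released` (a [monomer()]) and `remainder` (a
#'   `glycan_chain`, or a `monomer` when the parent was a free disaccharide).
#' @examples
#' exo_step("ΔGM")  # UDP1 released; remainder "ΔM"
#' exo_step("MM")   # saturated M released; remainder saturated M monomer
#' @export
exo_step <- function(chain) {
  chain <- as_glycan_chain(chain)
  n_rings <- dp(chain)
  if (n_rings < 2L)
    stop("nothing to cleave: chain has a single ring", call. = FALSE)
  if (chain$label_2ab && n_rings <= 2L)
    stop("blocked substrate: 2-AB-labelled disaccharides resist exolytic cleavage",
         call. = FALSE)
  if (chain$unsaturated) {
    released <- monomer("UDP1")
    rest <- chain$residues            # identities of rings 2..dp
  } else {
    released <- monomer(chain$residues[1L])
    rest <- chain$residues[-1L]       # identities of rings 2..dp
  }
  # rest[1] is the newly exposed ring: erased by beta-elimination unless it
  # is the final reducing-end ring.
  remainder <- if (length(rest) == 1L) {
    monomer(rest[1L])
  } else {
    glycan_chain(rest[-1L], unsaturated = TRUE, label_2ab = chain$label_2ab)
  }
  list(released = released, remainder = remainder)
}

#' Deterministic exolytic truncation of a mixture
#'
#' The truncation operator behind the sequencing procedure: each chain
#' `Δ X1..Xm` maps to `Δ X(cuts+1)..Xm` (the identities of the first `cuts`
#' letters are released/erased), and fractions of now-identical sequences
#' are aggregated. This is the noiseless limit of partial exolytic
#' digestion of a size fraction followed by re-fractionation.
#'
#' @param mix an unsaturated [oligo_mixture()].
#' @param cuts number of exolytic cuts, `0 <= cuts <= dp - 2` (free RE) or
#'   `dp - 3` (2-AB label).
#' @return An [oligo_mixture()] of DP `dp - cuts`.
#' @examples
#' m <- oligo_mixture(c("ΔGGMM", "ΔMGMM", "ΔGMMM", "ΔMMMM"),
#'                    c(0.467, 0.133, 0.311, 0.089))
#' truncate_mixture(m, 1)  # {ΔGMM 0.6, ΔMMM 0.4}
#' @export
truncate_mixture <- function(mix, cuts) {
  if (!is_unsaturated(mix))
    stop("truncation is defined for unsaturated mixtures", call. = FALSE)
  cuts <- as.integer(cuts)
  n <- attr(mix, "dp")
  max_cuts <- n - 2L - as.integer(attr(mix, "label_2ab"))
  if (cuts < 0L || cuts > max_cuts)
    stop(sprintf("over-digestion: cuts must be in 0..%d for DP %d", max_cuts, n),
         call. = FALSE)
  if (cuts == 0L) return(mix)
  trunc_seq <- vapply(mix$sequence, function(s) {
    ch <- parse_sequence(s)
    format(glycan_chain(ch$residues[-seq_len(cuts)], unsaturated = TRUE,
                        label_2ab = ch$label_2ab))
  }, character(1L))
  agg <- tapply(mix$fraction, trunc_seq, sum)
  oligo_mixture(names(agg), as.numeric(agg), renormalize = TRUE)
}
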