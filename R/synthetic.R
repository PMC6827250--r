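#' First-order Markov model of alginate block structure
#'
#' Chains are sampled residue by residue from a two-state Markov chain over
#' {M, G}: `g_stay` and `m_stay` are the probabilities of remaining in the
#' current block, so mean block lengths are `1 / (1 - stay)`. Chain lengths
#' are Poisson around `length_mean`, floored at `length_min`. This is the
#' simplest generator expressing homopolymeric (polyM/polyG) and
#' heteropolymeric (polyMG) blockiness; higher-order structure is out of
#' scope.
#'
#' @param g_stay,m_stay block-stay probabilities in \[0, 1\].
#' @param init_g probability that the first (NRE) residue is G.
#' @param length_mean,length_min chain-length distribution parameters.
#' @return Object of class `alginate_model`.
#' @export
alginate_model <- function(g_stay = 0.7, m_stay = 0.7, init_g = 0.5,
                           length_mean = 50, length_min = 10) {
  probs <- c(g_stay, m_stay, init_g)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(length_mean >= 2, length_min >= 2)
  structure(list(g_stay = g_stay, m_stay = m_stay, init_g = init_g,
                 length_mean = length_mean, length_min = length_min),
            class = "alginate_model")
}

#' Preset substrate models
#'
#' `"polyG"` and `"polyM"` emulate enriched block preparations (>= 90\%
#' of the named residue at stationarity); `"mixed"` is a balanced blocky
#' alginate.
#'
#' @param name one of `"polyG"`, `"polyM"`, `"mixed"`.
#' @param ... overrides passed to [alginate_model()].
#' @return An [alginate_model()].
#' @export
alginate_preset <- function(name = c("mixed", "polyG", "polyM"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    mixed = list(g_stay = 0.7, m_stay = 0.7, init_g = 0.5),
    polyG = list(g_stay = 0.95, m_stay = 0.5, init_g = 0.9),
    polyM = list(g_stay = 0.5, m_stay = 0.95, init_g = 0.1))
  do.call(alginate_model, utils::modifyList(args, list(...)))
}

#' Stationary G fraction of the block model
#' @param model an [alginate_model()].
#' @return Expected long-run G frequency.
#' @export
stationary_g_fraction <- function(model) {
  leave_g <- 1 - model$g_stay
  leave_m <- 1 - model$m_stay
  if (leave_g + leave_m == 0) return(model$init_g)
  leave_m / (leave_g + leave_m)
}

#' Generate a pool of saturated alginate chains
#'
#' @param model an [alginate_model()].
#' @param n number of chains.
#' @param seed integer seed; generation is a pure function of
#'   `(model, n, seed)`.
#' @return Character vector of `n` chain notation strings (saturated,
#'   free reducing end).
#' @export
generate_chains <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "alginate_model"), n >= 1L)
  set.seed(as.integer(seed))
  lens <- pmax(model$length_min, stats::rpois(n, model$length_mean))
  vapply(seq_len(n), function(i) {
    L <- lens[i]
    res <- character(L)
    res[1L] <- if (stats::runif(1L) < model$init_g) "G" else "M"
    if (L > 1L) for (j in 2:L) {
      stay <- if (res[j - 1L] == "G") model$g_stay else model$m_stay
      res[j] <- if (stats::runif(1L) < stay) res[j - 1L]
                else setdiff(c("G", "M"), res[j - 1L])
    }
    paste(res, collapse = "")
  }, character(1L))
}

#' Synthetic truncation series with multiplicative noise
#'
#' In-silico surrogate of the wet sequencing procedure: the mixture is
#' truncated at each cut level, passed through the forward NMR model, and
#' every signal area is multiplied by an independent lognormal factor with
#' unit mean and coefficient of variation `cv`.
#'
#' @param mix an unsaturated [oligo_mixture()].
#' @param cv multiplicative coefficient of variation (0 = noiseless).
#' @param seed integer seed.
#' @param cuts cut levels to include (default the full `0 .. dp - 3`
#'   ladder, or just the parent for DP 2).
#' @return A [truncation_series()].
#' @export
generate_series <- function(mix, cv = 0, seed = 1L, cuts = NULL) {
  if (!is_unsaturated(mix))
    stop("series generation requires an unsaturated mixture", call. = FALSE)
  stopifnot(cv >= 0)
  n <- attr(mix, "dp")
  if (is.null(cuts)) cuts <- 0:max(n - 3L, 0L)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(x) {
    if (cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  readouts <- lapply(cuts, function(k) {
    r <- forward_readout(truncate_mixture(mix, k))
    v <- noisy(c(r$h4_dG, r$h4_dM, r$re_G, r$re_M))
    nmr_readout(v[1L], v[2L], v[3L], v[4L])
  })
  names(readouts) <- as.character(cuts)
  truncation_series(n, readouts)
}

#' Gel-filtration-style synthetic chromatogram
#'
#' Gaussian peaks at size-dependent elution positions with areas
#' proportional to molar proportions (each unsaturated chain carries one
#' 235 nm chromophore, so area tracks moles regardless of size). Peak
#' centres default to a linear size ladder with larger species eluting
#' earlier.
#'
#' @param proportions named numeric molar proportions summing to 1; names
#'   like `"UDP2"` set default centres from DP.
#' @param centers optional named elution centres (ml).
#' @param sigma common peak SD (ml).
#' @param grid elution-volume grid (ml).
#' @param noise_sd additive baseline noise SD.
#' @param seed seed for baseline noise.
#' @return data.frame `elution_ml`, `absorbance_235`, with attribute
#'   `peaks` (data.frame species/center/area) and `unresolved_pairs`.
#' @export
fixture_chromatogram <- function(proportions, centers = NULL, sigma = 0.12,
                                 grid = seq(8, 24, by = 0.01),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-6, all(proportions > 0))
  species <- names(proportions)
  if (is.null(species)) stop("proportions must be named by species", call. = FALSE)
  if (is.null(centers)) {
    dps <- suppressWarnings(as.integer(sub("^UDP", "", species)))
    if (anyNA(dps)) dps <- seq_along(species)
    centers <- stats::setNames(20 - dps, species)  # larger species elute earlier
  }
  centers <- centers[species]
  unresolved <- character(0L)
  cs <- sort(centers)
  if (length(cs) > 1L) {
    gaps <- diff(cs)
    close_idx <- which(gaps < 4 * sigma)
    if (length(close_idx)) {
      unresolved <- paste(names(cs)[close_idx], names(cs)[close_idx + 1L], sep = "|")
      warning("peaks may not be resolvable: ", paste(unresolved, collapse = ", "),
              call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  absorb <- rowSums(vapply(species, function(sp)
    proportions[[sp]] * stats::dnorm(grid, centers[[sp]], sigma),
    numeric(length(grid))))
  if (noise_sd > 0) absorb <- pmax(0, absorb + stats::rnorm(length(grid), 0, noise_sd))
  out <- data.frame(elution_ml = grid, absorbance_235 = absorb)
  attr(out, "peaks") <- data.frame(species = species,
                                   center = unname(centers),
                                   area = unname(proportions),
                                   stringsAsFactors = FALSE)
  attr(out, "unresolved_pairs") <- unresolved
  out
}

#' Integrate a chromatogram back to molar proportions
#'
#' Trapezoidal integration in valley windows midway between adjacent peak
#' centres; with the default resolution this recovers the generating
#' proportions to well within 1\%.
#'
#' @param chrom data.frame from [fixture_chromatogram()] (or any
#'   `elution_ml` / `absorbance_235` table).
#' @param centers named peak centres; defaults to the `peaks` attribute.
#' @return data.frame `species`, `area`, `molar_percent`.
#' @export
integrate_chromatogram <- function(chrom, centers = NULL) {
  if (is.null(centers)) {
    pk <- attr(chrom, "peaks")
    if (is.null(pk)) stop("no peak centres supplied or attached", call. = FALSE)
    centers <- stats::setNames(pk$center, pk$species)
  }
  cs <- sort(centers)
  bounds <- c(-Inf, cs[-length(cs)] + diff(cs) / 2, Inf)
  x <- chrom$elution_ml; y <- chrom$absorbance_235
  areas <- vapply(seq_along(cs), function(i) {
    inside <- x >= bounds[i] & x < bounds[i + 1L]
    xi <- x[inside]; yi <- y[inside]
    if (length(xi) < 2L) return(0)
    sum(diff(xi) * (utils::head(yi, -1L) + utils::tail(yi, -1L)) / 2)
  }, numeric(1L))
  data.frame(species = names(cs), area = areas,
             molar_percent = 100 * areas / sum(areas),
             stringsAsFactors = FALSE)
}

#' Write a chromatogram / integration report
#'
#' @param chrom data.frame from [fixture_chromatogram()].
#' @param path peak-table TSV path (`elution_ml`, `absorbance_235`).
#' @return `path`, invisibly.
#' @export
write_chromatogram_tsv <- function(chrom, path) {
  write_tsv_with_header(chrom, path)
}
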