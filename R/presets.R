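#' Enzyme presets
#'
#' Two frozen presets covering the endo/exo pair the simulator models:
#' `"endo_G_preferring"` is a G-block-preferring endolytic table (high
#' k(G,G), very low k(M,M), minimum fragment size 2 on both sides so no
#' monomer is ever released endolytically), and `"exo_size_dependent"` is
#' the exolytic size profile with its optimum at DP 4 and a 6.5-fold drop
#' to the polymer tail.
#'
#' @param name preset name.
#' @return An [endo_rate_table()] or [exo_rate_profile()].
#' @export
enzyme_preset <- function(name = c("endo_G_preferring", "exo_size_dependent")) {
  name <- match.arg(name)
  switch(name,
         endo_G_preferring = endo_rate_table(),
         exo_size_dependent = exo_rate_profile())
}
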