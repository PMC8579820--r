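#' Packaged *Argylia* example data
#'
#' The worked example shipped with the package: a 13-taxon dated phylogeny
#' of the Andean plant genus *Argylia* (Bignoniaceae), the species-by-
#' bioclimatic-variable niche summary table (weighted means of 11 CHELSA
#' bioclimatic variables derived from predicted niche occupancy), the
#' 4-area tip-range codings (A Pacific Coast, B Central Andes 20-33S,
#' C Central Andes south of 33S, D Patagonia) and the four-epoch
#' Andean-uplift time-slice scheme (50-35, 35-15, 15-5, 5-0 Ma).
#'
#' Six internal node ages (38.21, 28.04, 25.77, 19.25, 16.33 and 9.76 Ma)
#' are fixed from the published divergence-time estimates; the remaining
#' internal ages are interpolated evenly between their enclosing dated
#' nodes, and one subclade's internal resolution follows the published
#' species listing order, ladderised. The tree is therefore an
#' approximation of the published chronogram, adequate for qualitative
#' signal analysis but not for reproducing exact parameter estimates.
#' Tip-range codings are taken from the published species-distribution
#' statements.
#'
#' @return `argylia_fixtures()` returns a list: `tree` (a [dated_tree]),
#'   `traits` (data frame, `species` + 11 variables), `ranges` (named
#'   list of area vectors), `epochs` (an [epoch_spec]).
#' @export
argylia_fixtures <- function() {
  list(tree = argylia_tree(), traits = argylia_traits(),
       ranges = argylia_ranges(), epochs = argylia_epochs())
}

#' @rdname argylia_fixtures
#' @export
argylia_tree <- function() {
  parse_newick(file = system.file("extdata", "argylia_tree.nwk",
                                  package = "nicherange", mustWork = TRUE),
               require_bifurcating = TRUE)
}

#' @rdname argylia_fixtures
#' @export
argylia_traits <- function() {
  utils::read.csv(system.file("extdata", "argylia_traits.csv",
                              package = "nicherange", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname argylia_fixtures
#' @export
argylia_ranges <- function() {
  g <- read_geography(system.file("extdata", "argylia_geography.txt",
                                  package = "nicherange", mustWork = TRUE))
  g$ranges
}

#' @rdname argylia_fixtures
#' @export
argylia_epochs <- function() {
  read_epochs(system.file("extdata", "argylia_epochs.yml",
                          package = "nicherange", mustWork = TRUE))
}
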