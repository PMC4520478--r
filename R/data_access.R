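#' Bundled Istrian case-study tables
#'
#' Two small published summary tables from the Istrian \emph{Niphargus}
#' four-species case study, bundled for worked examples and checks:
#' \code{niphargus_traits()} returns the binary feeding-trait states of the
#' four species (coded 1 = filtration-associated state: single-nail
#' maxilliped dactylus, carpal extra setae present, ischium extra setae
#' present), and \code{niphargus_axes()} the per-pair niche-axis
#' similarities (feeding, epi-hypogean, and Schoener's D under three
#' correlation-pruning thresholds) together with the published joint-niche
#' values.
#'
#' @return \code{niphargus_traits()}: a \code{\link{trait_matrix}};
#'   \code{niphargus_axes()}: a data.frame.
#' @export
niphargus_traits <- function() {
  df <- utils::read.csv(system.file("extdata", "niphargus_feeding_traits.csv",
                                    package = "nicheclone"))
  trait_matrix(`rownames<-`(as.matrix(df[, -1L]), df$species))
}

#' @rdname niphargus_traits
#' @export
niphargus_axes <- function() {
  utils::read.csv(system.file("extdata", "niphargus_niche_axes.csv",
                              package = "nicheclone"),
                  check.names = FALSE)
}
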