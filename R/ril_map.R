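#' Count recombination breakpoints and convert them to centimorgans
#'
#' For each interval between adjacent markers in the anchored order, the
#' breakpoint count is the number of samples whose parental label changes
#' across the interval, and the interval genetic distance is
#' `100 * breakpoints / (generations_of_crossover * n_samples)` —
#' the published rule of one expected crossover per chromosome per
#' generation over a fixed number of effective generations. Cumulative cM
#' are prefix sums along the order.
#'
#' @param h A `parental_haplotypes` object.
#' @param order Integer or character vector giving the anchored marker
#'   order (indices into, or ids of, `h$markers$marker_id`). Intervals
#'   spanning two different linkage groups should be handled by calling
#'   this per linkage group.
#' @param config A [pipeline_config()]; uses `generations_of_crossover`.
#' @return data.frame per marker in order: `marker_id`, `breakpoints`
#'   (into the previous marker; 0 for the first), `interval_cm`, `cM`.
#' @export
count_breakpoints_and_estimate_cm <- function(h, order,
                                              config = pipeline_config()) {
  if (is.character(order)) order <- match(order, h$markers$marker_id)
  if (anyNA(order)) stop("unknown marker ids in order")
  lab <- h$labels[order, , drop = FALSE]
  n <- ncol(lab)
  if (nrow(lab) == 0L)
    return(data.frame(marker_id = character(), breakpoints = integer(),
                      interval_cm = numeric(), cM = numeric()))
  bp <- c(0L, rowSums(lab[-1, , drop = FALSE] !=
                        lab[-nrow(lab), , drop = FALSE]))
  interval_cm <- 100 * bp / (config$generations_of_crossover * n)
  data.frame(marker_id = h$markers$marker_id[order],
             breakpoints = bp,
             interval_cm = interval_cm,
             cM = cumsum(interval_cm))
}

#' Kosambi mapping function
#'
#' Converts a recombination fraction to centimorgans under the Kosambi
#' map function, `25 * ln((1 + 2r) / (1 - 2r))`, which allows for partial
#' crossover interference.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @return Genetic distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Effective recombination opportunities of a selfed RIL line
#'
#' The breakpoint-to-cM rule divides by an effective number of crossover
#' generations. For a line taken to generation F_t by single-seed-descent
#' selfing, the expected junction density of the collapsed parental
#' mosaic is `2 * (1 - 2^-(t-1))` per Morgan (2 at fixation, the
#' Haldane-Waddington limit), so using this value as
#' `generations_of_crossover` makes the estimator unbiased against the
#' simulator. The published analyses instead use the round constant 5.
#'
#' @param n_selfing_generations Selfing rounds (7 for F8).
#' @return Effective generations of crossover.
#' @export
ril_effective_meioses <- function(n_selfing_generations) {
  2 * (1 - 2^(-n_selfing_generations))
}
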