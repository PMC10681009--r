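#' Synthetic multi-region biopsy fixture
#'
#' Generates a biopsy table emulating multi-region exome data from a
#' single tumour (e.g. ~23 spatially scattered biopsies with binary
#' mutation presence and spatially decaying sharing).  Biopsies are
#' placed uniformly in a unit disc.  Each sub-clonal mutation originates
#' in one biopsy (where it is always present) and is detected in another
#' biopsy at distance \eqn{d} with probability
#' \eqn{q \cdot e^{-\mathrm{decay} \cdot d}}: large `spatial_decay` gives
#' tight local clones whose sharing falls off with distance (negative
#' Jaccard-distance correlation), `spatial_decay = 0` removes all spatial
#' structure (sharing independent of distance, correlation near zero).
#' A `clonal_fraction` of mutations is present in every biopsy.
#'
#' This generator stands in for real patient tables in examples and
#' tests; it is synthetic data, not a reconstruction of any dataset.
#'
#' @param n_samples Number of biopsies (at least 2).
#' @param n_mutations Total number of mutations.
#' @param spatial_decay Non-negative decay rate of sharing with distance
#'   (distances in the unit disc are at most 2).
#' @param clonal_fraction Fraction of mutations present in all biopsies.
#' @param base_rate Sharing probability at zero distance (`q` above).
#' @param seed Optional RNG seed.
#' @return A [biopsy_table()].
#' @export
generate_biopsy_fixture <- function(n_samples = 23, n_mutations = 300,
                                    spatial_decay = 8,
                                    clonal_fraction = 0.1,
                                    base_rate = 0.5, seed = NULL) {
  stopifnot(n_samples >= 2, n_mutations >= 1, spatial_decay >= 0,
            clonal_fraction >= 0, clonal_fraction <= 1,
            base_rate > 0, base_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  # uniform points in the unit disc
  r <- sqrt(stats::runif(n_samples))
  th <- stats::runif(n_samples, 0, 2 * pi)
  coords <- cbind(x = r * cos(th), y = r * sin(th))
  dmat <- as.matrix(stats::dist(coords))

  n_clonal <- round(clonal_fraction * n_mutations)
  pres <- matrix(0, n_samples, n_mutations)
  if (n_clonal > 0) pres[, seq_len(n_clonal)] <- 1
  for (m in seq_len(n_mutations - n_clonal)) {
    origin <- sample.int(n_samples, 1)
    p_share <- base_rate * exp(-spatial_decay * dmat[origin, ])
    carried <- stats::runif(n_samples) < p_share
    carried[origin] <- TRUE
    pres[, n_clonal + m] <- as.numeric(carried)
  }
  rownames(pres) <- sprintf("S%02d", seq_len(n_samples))
  colnames(pres) <- sprintf("M%04d", seq_len(n_mutations))
  rownames(coords) <- rownames(pres)
  biopsy_table(pres, coords = coords)
}
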