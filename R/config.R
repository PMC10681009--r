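#' Simulation configuration
#'
#' Collects and validates every parameter of a tumour growth run.  Defaults
#' follow the reference parameterisation of the model: mutation rate
#' \eqn{\lambda = 10} new mutations per daughter per division, target size
#' \eqn{2^{14}} cells, detection limit 0.01 and three truncation points for
#' the cumulative-VAF regression.
#'
#' @param push_rate Probability \eqn{p \in [0, 1]} that a fully enclosed
#'   cell creates division space by pushing neighbours outward.  `p = 0`
#'   gives surface growth, `p = 1` exponential growth.
#' @param mutation_rate Mean number \eqn{\lambda \ge 0} of new point
#'   mutations per daughter cell per division (Poisson).
#' @param dimension Lattice dimension, 2 or 3 (Moore neighbourhoods of 8
#'   and 26 sites respectively).
#' @param target_size Stop at the end of the first generation in which the
#'   population reaches this many cells.
#' @param max_generations Hard cap on the number of synchronous
#'   generations; reaching it without `target_size` is not an error (the
#'   tumour grown so far is returned), which is the normal situation for
#'   fixed-duration surface-growth runs.
#' @param push_algorithm `"random_direction"` pushes a whole ray of cells
#'   behind a uniformly chosen Moore neighbour outward one step;
#'   `"shortest_path"` locates the nearest empty lattice site (Euclidean,
#'   ties at random) and shifts the cells on a discretised straight-line
#'   path towards it.
#' @param seed Integer RNG seed; `NULL` leaves the current RNG state
#'   untouched.
#' @param detection_limit Minimum cell fraction considered detectable when
#'   filtering frequency spectra (inclusive).
#' @param truncation_points Number of lowest-frequency points dropped from
#'   cumulative-VAF curves before regression.
#' @param lattice_side Optional explicit lattice side length; by default
#'   `4 * ceiling(target_size^(1/dimension))`, seed at the centre.  Growth
#'   reaching the lattice boundary aborts with an error rather than
#'   clamping.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(push_rate = 1, target_size = 2^10, seed = 1)
#' cfg
#' @export
sim_config <- function(push_rate, mutation_rate = 10, dimension = 2,
                       target_size = 2^14, max_generations = 1000L,
                       push_algorithm = c("random_direction",
                                          "shortest_path"),
                       seed = NULL, detection_limit = 0.01,
                       truncation_points = 3L, lattice_side = NULL) {
  push_algorithm <- match.arg(push_algorithm)
  stopifnot(is.numeric(push_rate), length(push_rate) == 1L,
            push_rate >= 0, push_rate <= 1,
            is.numeric(mutation_rate), mutation_rate >= 0,
            is.numeric(target_size), target_size >= 1,
            is.numeric(max_generations), max_generations >= 1,
            is.numeric(detection_limit),
            detection_limit > 0, detection_limit < 1,
            is.numeric(truncation_points), truncation_points >= 0)
  if (!dimension %in% c(2, 3))
    stop("`dimension` must be 2 or 3", call. = FALSE)
  target_size <- as.integer(round(target_size))
  if (is.null(lattice_side))
    lattice_side <- 4L * as.integer(ceiling(target_size^(1 / dimension)))
  lattice_side <- max(8L, as.integer(lattice_side))
  if (lattice_side^dimension > 2^28)
    stop("lattice would exceed 2^28 sites; reduce `target_size` ",
         "or pass a smaller `lattice_side`", call. = FALSE)
  structure(list(push_rate = push_rate,
                 mutation_rate = mutation_rate,
                 dimension = as.integer(dimension),
                 target_size = target_size,
                 max_generations = as.integer(max_generations),
                 push_algorithm = push_algorithm,
                 seed = if (!is.null(seed)) as.integer(seed),
                 detection_limit = detection_limit,
                 truncation_points = as.integer(truncation_points),
                 lattice_side = lattice_side),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tumour simulation configuration\n")
  cat(sprintf("  push rate p          : %g (%s)\n", x$push_rate,
              if (x$push_rate == 0) "surface growth"
              else if (x$push_rate == 1) "exponential growth"
              else "intermediate"))
  cat(sprintf("  mutation rate lambda : %g per daughter per division\n",
              x$mutation_rate))
  cat(sprintf("  lattice              : %dD, side %d, %s push\n",
              x$dimension, x$lattice_side, x$push_algorithm))
  cat(sprintf("  stop                 : %d cells or %d generations\n",
              x$target_size, x$max_generations))
  if (!is.null(x$seed)) cat(sprintf("  seed                 : %d\n", x$seed))
  invisible(x)
}
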