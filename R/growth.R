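#' Moore neighbourhood of a lattice site
#'
#' All sites differing by -1/0/+1 in each axis, excluding the site itself:
#' 8 neighbours in 2D, 26 in 3D.  The order is deterministic
#' (lexicographic over the offsets), so any randomisation is the caller's
#' responsibility.
#'
#' @param coord Integer coordinate vector of length `dimension`.
#' @param dimension 2 or 3.
#' @return An integer matrix with one neighbour per row.
#' @examples
#' nrow(neighbor_sites(c(0, 0), 2))       # 8
#' nrow(neighbor_sites(c(0, 0, 0), 3))    # 26
#' @export
neighbor_sites <- function(coord, dimension = length(coord)) {
  if (!dimension %in% c(2, 3))
    stop("`dimension` must be 2 or 3", call. = FALSE)
  if (length(coord) != dimension)
    stop("`coord` must have length `dimension`", call. = FALSE)
  off <- as.matrix(expand.grid(rep(list(-1:1), dimension),
                               KEEP.OUT.ATTRS = FALSE))
  # lexicographic with the first axis slowest
  ord <- if (dimension == 3) order(off[, 1], off[, 2], off[, 3])
         else order(off[, 1], off[, 2])
  off <- off[ord, , drop = FALSE]
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  res <- sweep(off, 2, as.integer(coord), `+`)
  dimnames(res) <- NULL
  res
}

#' Grow a tumour from a single seeded cell
#'
#' Runs the agent-based lattice model: one cell is seeded at the lattice
#' centre and the population grows by synchronous generations.  Within a
#' generation every cell alive at its start is visited in uniformly
#' shuffled order.  A cell with at least one empty Moore neighbour always
#' divides, placing one daughter at a uniformly chosen empty neighbour; a
#' fully enclosed cell divides with probability `push_rate`, creating
#' space with the configured pushing algorithm.  Both division products
#' are new cells (the parent record is retired), and each daughter draws
#' an independent Poisson(`mutation_rate`) number of new private
#' mutations.  Newborns first act in the following generation.
#'
#' Growth stops at the end of the first generation in which the population
#' reaches `target_size`, or after `max_generations`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `tumour`: a list with elements
#'   \describe{
#'     \item{cells}{data frame with one row per cell ever created:
#'       `cell_id`, `parent_id` (0 for the seed), `birth_generation`,
#'       integer lattice coordinates `x`, `y` (and `z` in 3D, seed at the
#'       origin), `alive`, and the private-mutation range `mut_start`,
#'       `mut_n` (mutation ids `mut_start ... mut_start + mut_n - 1`).}
#'     \item{generations}{number of completed synchronous generations.}
#'     \item{n_alive}{final cell count.}
#'     \item{n_mutations}{total mutations ever created.}
#'     \item{config}{the configuration used.}
#'   }
#'   Coordinates of retired (divided) cells are their positions at
#'   retirement; pushes after that time do not move them.
#' @examples
#' tum <- grow_tumour(sim_config(push_rate = 1, mutation_rate = 1,
#'                               target_size = 2^6, seed = 1))
#' tum$generations        # 6: exponential doubling
#' tum$n_alive            # 64
#' @export
grow_tumour <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .grow_engine(config$push_rate, config$mutation_rate,
                      config$dimension, config$target_size,
                      config$max_generations,
                      match(config$push_algorithm,
                            c("random_direction", "shortest_path")) - 1L,
                      config$lattice_side)
  n <- length(res$parent_id)
  cells <- data.frame(cell_id = seq_len(n),
                      parent_id = res$parent_id,
                      birth_generation = res$birth_generation,
                      x = res$x, y = res$y)
  if (config$dimension == 3) cells$z <- res$z
  cells$alive <- res$alive
  cells$mut_start <- res$mut_start
  cells$mut_n <- res$mut_n
  structure(list(cells = cells,
                 generations = res$generations,
                 n_alive = res$n_alive,
                 n_mutations = res$n_mutations,
                 dimension = config$dimension,
                 config = config),
            class = "tumour")
}

#' @export
print.tumour <- function(x, ...) {
  cat(sprintf("<tumour> %d cells after %d generations (%dD, p = %g, lambda = %g)\n",
              x$n_alive, x$generations, x$dimension,
              x$config$push_rate, x$config$mutation_rate))
  cat(sprintf("  %d cells ever created, %d mutations, radius %.1f\n",
              nrow(x$cells), x$n_mutations, tumour_radius(x)))
  invisible(x)
}

#' Cell ids of the currently alive cells
#' @param tumour A `tumour` object.
#' @return Integer vector of cell ids.
#' @export
alive_cells <- function(tumour) {
  stopifnot(inherits(tumour, "tumour"))
  tumour$cells$cell_id[tumour$cells$alive]
}

# alive-cell coordinates as an n x dim integer matrix
.alive_coords <- function(tumour) {
  cc <- tumour$cells[tumour$cells$alive, , drop = FALSE]
  if (tumour$dimension == 3) cbind(cc$x, cc$y, cc$z) else cbind(cc$x, cc$y)
}

#' Tumour radius
#'
#' Maximum Euclidean distance from the seed site (the origin) to any
#' occupied lattice site; 0 for a single seed cell.  Used by the
#' centre/margin partition, which labels a sample "centre" when its centre
#' lies within two-thirds of this radius.
#'
#' @param tumour A `tumour` object.
#' @return A non-negative length.
#' @export
tumour_radius <- function(tumour) {
  stopifnot(inherits(tumour, "tumour"))
  xy <- .alive_coords(tumour)
  sqrt(max(rowSums(xy^2)))
}
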