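#' Poisson draw of new mutation counts
#'
#' The number of new mutations acquired by each daughter cell at a
#' division is Poisson with mean `lambda` (the per-division mutation
#' rate), i.e. \eqn{P(k) = \lambda^k e^{-\lambda} / k!}.  The growth
#' engine performs these draws internally for every daughter; this
#' function exposes the same distribution for analysis code and tests.
#'
#' @param lambda Mean new mutations per daughter per division.
#' @param n Number of independent draws.
#' @return Integer vector of mutation counts.
#' @export
draw_new_mutations <- function(lambda, n = 1) {
  stopifnot(lambda >= 0)
  rpois(n, lambda)
}

#' Full mutation set of one cell
#'
#' The genotype of a cell is the union of the private mutations along its
#' ancestry chain back to the seed (which carries none).  Genotypes are
#' stored as ancestry deltas, so this walks parent pointers and expands
#' the private-mutation id ranges.
#'
#' @param tumour A `tumour` object.
#' @param cell_id A single cell id.
#' @return Sorted integer vector of mutation ids (possibly empty).
#' @export
resolve_mutation_set <- function(tumour, cell_id) {
  stopifnot(inherits(tumour, "tumour"), length(cell_id) == 1L)
  cells <- tumour$cells
  if (cell_id < 1 || cell_id > nrow(cells))
    stop("unknown cell_id: ", cell_id, call. = FALSE)
  ids <- integer(0)
  cur <- as.integer(cell_id)
  while (cur > 0L) {
    k <- cells$mut_n[cur]
    if (k > 0L)
      ids <- c(ids, seq.int(cells$mut_start[cur], length.out = k))
    cur <- cells$parent_id[cur]
  }
  sort(ids)
}

# For every cell ever created, the number of `universe` cells that are
# descendants-or-self of it.  A mutation private to cell c is carried by
# exactly the universe cells counted at c, so these counts are the carrier
# counts of all of c's private mutations.  Implemented as a vectorised
# walk up the parent pointers (one round per ancestry depth level).
.subtree_counts <- function(tumour, universe) {
  parent <- tumour$cells$parent_id
  visited <- vector("list", 64L)
  cur <- as.integer(universe)
  i <- 0L
  while (length(cur)) {
    i <- i + 1L
    visited[[i]] <- cur
    cur <- parent[cur]
    cur <- cur[cur > 0L]
  }
  tabulate(unlist(visited[seq_len(i)]), nbins = length(parent))
}

#' Mutation frequency spectrum over a cell universe
#'
#' For every mutation carried by at least one cell of the universe,
#' computes the cell fraction \eqn{f_c = } carriers / universe size.  The
#' universe defaults to all alive cells (whole tumour) but can be any
#' subset, e.g. the member cells of a spatial sample, in which case
#' frequencies are re-normalised within the sample.
#'
#' @param tumour A `tumour` object.
#' @param cells Integer vector of alive cell ids forming the universe;
#'   default all alive cells.
#' @return A `frequency_spectrum`: a data frame with columns
#'   `mutation_id`, `origin_cell_id`, `origin_generation`, `carriers`,
#'   `cell_fraction`, with attributes `universe_size` and
#'   `convention = "cell_fraction"`.  Divide `cell_fraction` by two for
#'   the diploid heterozygous VAF.
#' @export
mutation_frequencies <- function(tumour, cells = NULL) {
  stopifnot(inherits(tumour, "tumour"))
  if (is.null(cells)) cells <- alive_cells(tumour)
  if (length(cells) == 0L) stop("empty cell universe", call. = FALSE)
  tab <- tumour$cells
  if (any(!tab$alive[cells]))
    stop("universe must consist of alive cells", call. = FALSE)
  counts <- .subtree_counts(tumour, cells)
  idx <- which(tab$mut_n > 0L & counts > 0L)
  mut_n <- tab$mut_n[idx]
  spec <- data.frame(
    mutation_id = sequence(mut_n, from = tab$mut_start[idx]),
    origin_cell_id = rep.int(tab$cell_id[idx], mut_n),
    origin_generation = rep.int(tab$birth_generation[idx], mut_n),
    carriers = rep.int(counts[idx], mut_n))
  spec <- spec[order(spec$mutation_id), , drop = FALSE]
  rownames(spec) <- NULL
  spec$cell_fraction <- spec$carriers / length(cells)
  structure(spec, universe_size = length(cells),
            convention = "cell_fraction",
            class = c("frequency_spectrum", "data.frame"))
}

#' Final frequencies of early mutations
#'
#' Tracks the mutations that arose during the first generations of growth
#' (identity and origin time are recorded at birth) and reports the cell
#' fraction each reaches in the final tumour.  Under exponential growth
#' the mean final fraction of generation-\eqn{g} mutations is
#' \eqn{2^{-g}}; lower push rates keep the same mean but inflate the
#' variance.
#'
#' @param tumour A `tumour` object.
#' @param up_to_generation Include mutations originating at generations
#'   `1 ... up_to_generation`.
#' @return Data frame `mutation_id`, `origin_generation`, `cell_fraction`
#'   (empty if no mutation originated that early).
#' @export
track_early_mutations <- function(tumour, up_to_generation) {
  spec <- mutation_frequencies(tumour)
  out <- spec[spec$origin_generation <= up_to_generation,
              c("mutation_id", "origin_generation", "cell_fraction")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
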