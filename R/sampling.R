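# encode integer lattice coordinates as doubles for hashed lookup;
# exact for |coord| well below 2^20
.encode_sites <- function(xy) {
  B <- 2^20
  if (ncol(xy) == 2) (xy[, 1] + B) * (2 * B) + (xy[, 2] + B)
  else ((xy[, 1] + B) * (2 * B) + (xy[, 2] + B)) * (2 * B) + (xy[, 3] + B)
}

# region of points relative to the tumour: "centre" within (2/3) R of the
# seed (inclusive), "margin" beyond
.classify_region <- function(points, radius) {
  d <- sqrt(rowSums(points^2))
  ifelse(d <= (2 / 3) * radius, "centre", "margin")
}

#' Random square (cubic) spatial samples
#'
#' Draws samples the way a spatially blind multi-region protocol would:
#' candidate centres are chosen uniformly among occupied lattice sites and
#' a candidate is accepted only if the axis-aligned square (cube in 3D) of
#' side `s = round(sample_size^(1/dimension))` around it is fully
#' occupied, so every sample contains exactly `s^dimension` cells.
#' Samples may overlap one another; overlap is detected downstream with
#' [non_overlapping()].  With `region` the accepted centres are restricted
#' to the central disc (two-thirds of the tumour radius, inclusive) or the
#' marginal ring, mirroring centre/margin sampling designs.
#'
#' @param tumour A `tumour` object.
#' @param sample_size Target number of cells per sample; rounded to the
#'   nearest perfect square (2D) or cube (3D).
#' @param n_samples Number of samples to accept.
#' @param region `"any"` (default), `"centre"` or `"margin"`.
#' @param max_attempts Cap on candidate draws before giving up with an
#'   error reporting the acceptance rate.
#' @return A `sample_set`: list with
#'   \describe{
#'     \item{samples}{data frame `sample_id`, geometric centre `cx`, `cy`
#'       (`cz`), box bounds `lo_*`/`hi_*`, `side`, `region`, `n_cells`.}
#'     \item{members}{list of integer vectors of member cell ids.}
#'   }
#' @export
random_square_samples <- function(tumour, sample_size, n_samples = 500,
                                  region = c("any", "centre", "margin"),
                                  max_attempts = 1e6) {
  stopifnot(inherits(tumour, "tumour"), sample_size >= 1,
            n_samples >= 1)
  region <- match.arg(region)
  dim <- tumour$dimension
  s <- max(1L, as.integer(round(sample_size^(1 / dim))))
  if (s^dim > tumour$n_alive)
    stop("sample_size exceeds the tumour size", call. = FALSE)
  ids <- alive_cells(tumour)
  xy <- .alive_coords(tumour)
  keys <- .encode_sites(xy)
  ord <- order(keys)
  keys <- keys[ord]
  ids <- ids[ord]
  xy <- xy[ord, , drop = FALSE]
  R <- tumour_radius(tumour)

  # offsets of the s^dim box sites relative to the low corner
  offs <- as.matrix(expand.grid(rep(list(0:(s - 1L)), dim),
                                KEEP.OUT.ATTRS = FALSE))
  half <- (s - 1L) %/% 2L

  centres <- matrix(0, n_samples, dim)
  members <- vector("list", n_samples)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_samples) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "sampling attempt cap reached (%d accepted of %d; acceptance rate %.4f)",
        accepted, n_samples, accepted / attempts), call. = FALSE)
    anchor <- xy[sample.int(nrow(xy), 1L), ]
    lo <- anchor - half
    geo <- lo + (s - 1) / 2
    if (region != "any" &&
        .classify_region(matrix(geo, 1L), R) != region) next
    box <- sweep(offs, 2L, lo, `+`)
    hit <- match(.encode_sites(box), keys)
    if (anyNA(hit)) next
    accepted <- accepted + 1L
    centres[accepted, ] <- geo
    members[[accepted]] <- ids[hit]
  }

  samples <- data.frame(sample_id = seq_len(n_samples),
                        cx = centres[, 1], cy = centres[, 2])
  if (dim == 3) samples$cz <- centres[, 3]
  samples$lo_x <- as.integer(round(centres[, 1] - (s - 1) / 2))
  samples$lo_y <- as.integer(round(centres[, 2] - (s - 1) / 2))
  if (dim == 3) samples$lo_z <- as.integer(round(centres[, 3] - (s - 1) / 2))
  samples$side <- s
  samples$region <- if (region == "any")
    .classify_region(centres, R) else region
  samples$n_cells <- lengths(members)
  structure(list(samples = samples, members = members,
                 dimension = dim, side = s),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples of %d cells (side %d, %dD)\n",
              nrow(x$samples), x$side^x$dimension, x$side, x$dimension))
  print(table(x$samples$region))
  invisible(x)
}

#' Centre/margin label of samples
#'
#' Labels each sample `"centre"` if its centre lies within two-thirds of
#' the tumour radius of the seed (inclusive at the boundary), `"margin"`
#' otherwise.
#'
#' @param sample_set A `sample_set`.
#' @param tumour The `tumour` the samples came from.
#' @return Character vector of region labels, one per sample.
#' @export
centre_margin_partition <- function(sample_set, tumour) {
  stopifnot(inherits(sample_set, "sample_set"), inherits(tumour, "tumour"))
  sm <- sample_set$samples
  pts <- if (sample_set$dimension == 3) cbind(sm$cx, sm$cy, sm$cz)
         else cbind(sm$cx, sm$cy)
  .classify_region(pts, tumour_radius(tumour))
}

# geometric centres of a sample_set as a matrix
.sample_centres <- function(sample_set) {
  sm <- sample_set$samples
  if (sample_set$dimension == 3) cbind(sm$cx, sm$cy, sm$cz)
  else cbind(sm$cx, sm$cy)
}

#' Euclidean distance between sample centres
#'
#' @param sample_set A `sample_set`.
#' @param i,j Sample ids (vectors are recycled elementwise).
#' @return Numeric distances.
#' @export
sample_distance <- function(sample_set, i, j) {
  ctr <- .sample_centres(sample_set)
  sqrt(rowSums((ctr[i, , drop = FALSE] - ctr[j, , drop = FALSE])^2))
}

#' Are two samples spatially non-overlapping?
#'
#' TRUE iff the two axis-aligned boxes share no lattice site, i.e. they
#' are separated along at least one axis.  For equal-sized samples the
#' shortest centre distance of a non-overlapping pair equals the sample
#' side (the sample diameter).
#'
#' @inheritParams sample_distance
#' @return Logical vector.
#' @export
non_overlapping <- function(sample_set, i, j) {
  sm <- sample_set$samples
  s <- sample_set$side
  sep <- abs(sm$lo_x[i] - sm$lo_x[j]) >= s |
         abs(sm$lo_y[i] - sm$lo_y[j]) >= s
  if (sample_set$dimension == 3)
    sep <- sep | abs(sm$lo_z[i] - sm$lo_z[j]) >= s
  sep
}
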