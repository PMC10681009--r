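#' Multi-region biopsy table
#'
#' Container for generic multi-region sequencing data: a binary
#' sample-by-mutation presence matrix plus either per-sample coordinates
#' or a pairwise distance matrix.  This is the interface through which
#' the heterogeneity metrics apply to patient-style data (e.g. exome
#' presence calls across ~23 biopsies of one tumour).
#'
#' @param presence Binary (logical or 0/1) matrix, samples in rows,
#'   mutations in columns; dimnames are used as sample and mutation ids.
#' @param coords Optional numeric matrix / data frame of per-sample
#'   coordinates (2 columns), one row per sample.
#' @param distances Optional symmetric pairwise distance matrix with zero
#'   diagonal; computed from `coords` when omitted.
#' @return An object of class `biopsy_table`.
#' @export
biopsy_table <- function(presence, coords = NULL, distances = NULL) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "numeric"
  if (!all(presence %in% c(0, 1)))
    stop("`presence` must be binary", call. = FALSE)
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("S", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("M", seq_len(ncol(presence)))
  if (is.null(distances)) {
    if (is.null(coords))
      stop("provide `coords` or `distances`", call. = FALSE)
    coords <- as.matrix(coords)
    distances <- as.matrix(stats::dist(coords))
  } else {
    distances <- as.matrix(distances)
    if (!isTRUE(all.equal(distances, t(distances))) ||
        any(diag(distances) != 0))
      stop("`distances` must be symmetric with zero diagonal",
           call. = FALSE)
  }
  structure(list(presence = presence, coords = coords,
                 distances = distances),
            class = "biopsy_table")
}

#' @export
print.biopsy_table <- function(x, ...) {
  cat(sprintf("<biopsy_table> %d samples x %d mutations\n",
              nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' Read a biopsy table from TSV files
#'
#' The presence file is long-format with columns `sample_id` and
#' `mutation_id` (one row per detected mutation per sample).  Supply
#' either a coordinates file (`sample_id`, `x`, `y`) or a distance-matrix
#' file (square TSV with sample ids as both header and first column).
#'
#' @param presence_file Path to the long-format presence TSV.
#' @param coords_file,dist_file Exactly one of the two.
#' @return A [biopsy_table()].
#' @export
read_biopsy_table <- function(presence_file, coords_file = NULL,
                              dist_file = NULL) {
  long <- read.delim(presence_file, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "mutation_id") %in% names(long)))
  sid <- sort(unique(as.character(long$sample_id)))
  mid <- sort(unique(as.character(long$mutation_id)))
  pres <- matrix(0, length(sid), length(mid), dimnames = list(sid, mid))
  pres[cbind(match(as.character(long$sample_id), sid),
             match(as.character(long$mutation_id), mid))] <- 1
  if (!is.null(coords_file)) {
    co <- read.delim(coords_file, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "x", "y") %in% names(co)))
    co <- co[match(sid, as.character(co$sample_id)), , drop = FALSE]
    biopsy_table(pres, coords = as.matrix(co[, c("x", "y")]))
  } else if (!is.null(dist_file)) {
    dm <- as.matrix(read.delim(dist_file, row.names = 1))
    biopsy_table(pres, distances = dm[sid, sid])
  } else stop("provide `coords_file` or `dist_file`", call. = FALSE)
}

#' Write a biopsy table to TSV files
#'
#' Inverse of [read_biopsy_table()]: writes the long-format presence
#' table and the coordinates table.
#'
#' @param x A `biopsy_table` (must carry coordinates).
#' @param presence_file,coords_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_biopsy_table <- function(x, presence_file, coords_file) {
  stopifnot(inherits(x, "biopsy_table"), !is.null(x$coords))
  idx <- which(x$presence == 1, arr.ind = TRUE)
  long <- data.frame(sample_id = rownames(x$presence)[idx[, 1]],
                     mutation_id = colnames(x$presence)[idx[, 2]])
  long <- long[order(long$sample_id, long$mutation_id), , drop = FALSE]
  write.table(long, presence_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  co <- data.frame(sample_id = rownames(x$presence),
                   x = x$coords[, 1], y = x$coords[, 2])
  write.table(co, coords_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(presence_file, coords_file))
}

#' Sub-clonal mutation filter
#'
#' Removes (near-)clonal mutations from a mutation universe before
#' Jaccard comparison: clonal mutations shared by everything add no
#' discriminating signal and only compress the Jaccard index into a
#' narrow range.  For a [biopsy_table()], `"present_in_all_samples"`
#' drops mutations detected in every biopsy and
#' `"present_in_more_than_half_of_samples"` drops those detected in more
#' than half of them (the tolerant variant for impure real samples, where
#' truly clonal mutations rarely appear in literally all biopsies).  For
#' a `frequency_spectrum`, `"whole_tumour_clonal"` drops mutations with
#' cell fraction 1.
#'
#' @param x A `biopsy_table` or `frequency_spectrum`.
#' @param mode Filter mode (see above).
#' @return The same class as `x`, with the excluded mutations removed.
#' @export
subclonal_filter <- function(x, mode) UseMethod("subclonal_filter")

#' @rdname subclonal_filter
#' @export
subclonal_filter.biopsy_table <- function(x,
    mode = c("present_in_more_than_half_of_samples",
             "present_in_all_samples")) {
  mode <- match.arg(mode)
  n <- nrow(x$presence)
  cs <- colSums(x$presence)
  keep <- if (mode == "present_in_all_samples") cs < n else cs <= n / 2
  x$presence <- x$presence[, keep, drop = FALSE]
  x
}

#' @rdname subclonal_filter
#' @export
subclonal_filter.frequency_spectrum <- function(x,
    mode = "whole_tumour_clonal") {
  if (!identical(mode, "whole_tumour_clonal"))
    stop("unknown mode for a frequency spectrum: ", mode, call. = FALSE)
  out <- x[x$cell_fraction < 1, , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       attributes(x)[c("universe_size", "convention")])
  out
}

#' Pairwise Jaccard index for a biopsy table
#'
#' Computes the Jaccard index of every biopsy pair from the presence
#' matrix, after optional sub-clonal filtering, together with the
#' pairwise sampling distance.  Distances are by default normalised so
#' the largest pairwise distance is 100 (a relative scale comparable
#' across tumours of different physical size).
#'
#' @param x A [biopsy_table()].
#' @param filter_mode `"none"`, `"present_in_all_samples"` or
#'   `"present_in_more_than_half_of_samples"`.
#' @param normalize_distance Rescale distances to a 0-100 range.
#' @param pairing `"unordered"` (default) or `"ordered"`.
#' @return Data frame `sample_i`, `sample_j`, `jaccard`, `distance`,
#'   `non_overlapping` (TRUE: biopsies are distinct tissue pieces).
#' @export
biopsy_jaccard_table <- function(x,
    filter_mode = c("none", "present_in_all_samples",
                    "present_in_more_than_half_of_samples"),
    normalize_distance = TRUE, pairing = c("unordered", "ordered")) {
  stopifnot(inherits(x, "biopsy_table"))
  filter_mode <- match.arg(filter_mode)
  pairing <- match.arg(pairing)
  if (filter_mode != "none") x <- subclonal_filter(x, filter_mode)
  P <- x$presence
  n <- nrow(P)
  inter <- tcrossprod(P)
  sizes <- rowSums(P)
  pi <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  ii <- inter[cbind(pi, pj)]
  un <- sizes[pi] + sizes[pj] - ii
  d <- x$distances[cbind(pi, pj)]
  if (normalize_distance && max(d) > 0) d <- 100 * d / max(d)
  rec <- data.frame(sample_i = rownames(P)[pi], sample_j = rownames(P)[pj],
                    jaccard = ifelse(un > 0, ii / un, 0),
                    distance = d, non_overlapping = TRUE)
  if (pairing == "ordered") {
    mirror <- rec
    mirror$sample_i <- rec$sample_j
    mirror$sample_j <- rec$sample_i
    rec <- rbind(rec, mirror)
    rownames(rec) <- NULL
  }
  rec
}
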