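#' Jaccard index of two mutation sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}, the fraction of shared
#' mutations; 1 for identical non-empty sets, 0 for disjoint sets.  Two
#' empty sets give 0 by convention: after sub-clonal filtering, samples
#' sharing nothing informative should not count as identical.
#'
#' @param a,b Vectors of mutation ids (any atomic type).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))   # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(a) + length(b) - sum(a %in% b)
  if (u == 0L) return(0)
  sum(a %in% b) / u
}

# one ancestor-id set per sample: the union of the parent chains of all
# member cells.  All private mutations of an ancestor are carried by every
# member below it, so a sample's mutation set is exactly its ancestor set
# weighted by the per-cell private mutation counts.
.ancestor_sets <- function(tumour, members) {
  parent <- tumour$cells$parent_id
  lapply(members, function(m) {
    visited <- vector("list", 64L)
    cur <- as.integer(m)
    i <- 0L
    while (length(cur)) {
      i <- i + 1L
      visited[[i]] <- cur
      cur <- parent[cur]
      cur <- cur[cur > 0L]
    }
    unique(unlist(visited[seq_len(i)]))
  })
}

#' Pairwise Jaccard index versus sampling distance
#'
#' Compares the mutation sets of every pair of spatial samples and
#' records, per pair, the Jaccard index, the Euclidean distance between
#' sample centres, and whether the two sample boxes are spatially
#' non-overlapping.  With 500 samples the default ordered pairing yields
#' 500 * 499 = 249,500 records; `pairing = "unordered"` halves this by
#' symmetry.
#'
#' Sub-clonal filtering (`filter_mode`) removes mutations from the
#' comparison universe before the Jaccard computation:
#' `"whole_tumour_clonal"` drops mutations carried by every alive cell of
#' the tumour, `"present_in_all_samples"` and
#' `"present_in_more_than_half_of_samples"` drop mutations by their
#' presence across the sampled set (the filters used for noisy biopsy
#' data, where clonal mutations rarely appear in literally every sample).
#'
#' @param tumour A `tumour` object.
#' @param sample_set A `sample_set` drawn from it.
#' @param filter_mode One of `"none"`, `"whole_tumour_clonal"`,
#'   `"present_in_all_samples"`,
#'   `"present_in_more_than_half_of_samples"`.
#' @param pairing `"ordered"` (default, n(n-1) records) or `"unordered"`
#'   (n(n-1)/2).
#' @return Data frame of `JaccardRecord`s: `sample_i`, `sample_j`,
#'   `jaccard`, `distance`, `non_overlapping`.
#' @export
jaccard_distance_table <- function(tumour, sample_set,
                                   filter_mode = c(
                                     "none", "whole_tumour_clonal",
                                     "present_in_all_samples",
                                     "present_in_more_than_half_of_samples"),
                                   pairing = c("ordered", "unordered")) {
  stopifnot(inherits(tumour, "tumour"), inherits(sample_set, "sample_set"))
  filter_mode <- match.arg(filter_mode)
  pairing <- match.arg(pairing)
  n <- nrow(sample_set$samples)
  ncells <- nrow(tumour$cells)
  sets <- .ancestor_sets(tumour, sample_set$members)
  X <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lengths(sets)),
                            j = unlist(sets), x = 1,
                            dims = c(n, ncells))
  w <- as.numeric(tumour$cells$mut_n)
  if (filter_mode == "whole_tumour_clonal") {
    cnt <- .subtree_counts(tumour, alive_cells(tumour))
    w[cnt == tumour$n_alive] <- 0
  } else if (filter_mode == "present_in_all_samples") {
    w[Matrix::colSums(X) == n] <- 0
  } else if (filter_mode == "present_in_more_than_half_of_samples") {
    w[Matrix::colSums(X) > n / 2] <- 0
  }
  sizes <- as.numeric(X %*% w)
  inter <- as.matrix(X %*% Matrix::Diagonal(x = w) %*% Matrix::t(X))

  pi <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  ii <- inter[cbind(pi, pj)]
  un <- sizes[pi] + sizes[pj] - ii
  jac <- ifelse(un > 0, ii / un, 0)
  rec <- data.frame(sample_i = pi, sample_j = pj, jaccard = jac,
                    distance = sample_distance(sample_set, pi, pj),
                    non_overlapping = non_overlapping(sample_set, pi, pj))
  if (pairing == "ordered") {
    mirror <- rec
    mirror$sample_i <- rec$sample_j
    mirror$sample_j <- rec$sample_i
    rec <- rbind(rec, mirror)
    rec <- rec[order(rec$sample_i, rec$sample_j), , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Summarise the Jaccard-distance relationship
#'
#' Bins the (distance, Jaccard) records into equal-width distance bins
#' (by default restricted to non-overlapping pairs, whose minimum
#' possible distance is the sample side) and reports per-bin mean and
#' median Jaccard together with the Pearson correlation of Jaccard
#' against distance.  A negative correlation means heterogeneity grows
#' with sampling distance.
#'
#' @param records Output of [jaccard_distance_table()] or
#'   [biopsy_jaccard_table()].
#' @param n_bins Number of equal-width distance bins.
#' @param non_overlapping_only Use only non-overlapping pairs (default).
#' @return List with elements `bins` (data frame `bin_mid`, `mean_j`,
#'   `median_j`, `n`), `r`, `p_value`, `n_pairs`, and `degenerate`
#'   (TRUE when the correlation is undefined because distances or
#'   Jaccard values are constant).
#' @export
distance_trend_summary <- function(records, n_bins = 20,
                                   non_overlapping_only = TRUE) {
  if (non_overlapping_only && "non_overlapping" %in% names(records))
    records <- records[records$non_overlapping, , drop = FALSE]
  if (nrow(records) < 3L)
    stop("need at least 3 records with distinct distances", call. = FALSE)
  d <- records$distance
  j <- records$jaccard
  breaks <- seq(min(d), max(d), length.out = n_bins + 1L)
  breaks[1L] <- breaks[1L] - 1e-9
  bin <- cut(d, breaks, labels = FALSE)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  bins <- data.frame(
    bin_mid = mids,
    mean_j = vapply(seq_len(n_bins),
                    function(b) mean(j[bin == b]), numeric(1)),
    median_j = vapply(seq_len(n_bins),
                      function(b) median(j[bin == b]), numeric(1)),
    n = tabulate(bin, n_bins))
  degenerate <- stats::sd(d) == 0 || stats::sd(j) == 0
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(j, d, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(bins = bins[bins$n > 0L, , drop = FALSE], r = r, p_value = p,
       n_pairs = nrow(records), degenerate = degenerate)
}
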