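test_that("Jaccard index on explicit sets", {
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(5:1, 1:5), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(integer(0), integer(0)), 0)   # convention
  expect_equal(jaccard(integer(0), 1:3), 0)
  # invariant to relabeling
  expect_equal(jaccard(c("a", "b"), c("b", "c")),
               jaccard(c(101, 102), c(102, 103)))
})

test_that("pairwise tables have n(n-1) ordered / n(n-1)/2 unordered records", {
  tum <- grown_fixture("p1_256", push_rate = 1, mutation_rate = 10,
                       target_size = 2^8, seed = 3)
  set.seed(4)
  ss <- random_square_samples(tum, 16, 10)
  ord <- jaccard_distance_table(tum, ss, pairing = "ordered")
  uno <- jaccard_distance_table(tum, ss, pairing = "unordered")
  expect_equal(nrow(ord), 10 * 9)
  expect_equal(nrow(uno), 45)
  # symmetry: the ordered table contains each unordered pair twice with
  # identical Jaccard and distance
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  m <- match(key(ord$sample_i, ord$sample_j), key(uno$sample_i, uno$sample_j))
  expect_false(anyNA(m))
  expect_equal(ord$jaccard, uno$jaccard[m])
  expect_equal(ord$distance, uno$distance[m])
})

test_that("sparse-matrix Jaccard equals brute-force mutation-set Jaccard", {
  tum <- grown_fixture("p05_64", push_rate = 0.5, mutation_rate = 3,
                       target_size = 2^6, seed = 9)
  set.seed(10)
  ss <- random_square_samples(tum, 4, 8)
  rec <- jaccard_distance_table(tum, ss, pairing = "unordered")
  sets <- lapply(ss$members, function(m) brute_sample_mutations(tum, m))
  for (r in seq_len(nrow(rec))) {
    expect_equal(rec$jaccard[r],
                 jaccard(sets[[rec$sample_i[r]]], sets[[rec$sample_j[r]]]))
  }
})

test_that("sub-clonal filters drop mutations by cross-sample presence", {
  # 23 biopsies; mutations engineered to sit at specific presence counts
  pres <- matrix(0, 23, 4)
  pres[1:23, 1] <- 1    # clonal: in all biopsies
  pres[1:12, 2] <- 1    # 12 of 23 (> half)
  pres[1:11, 3] <- 1    # 11 of 23 (<= half)
  pres[1, 4] <- 1       # private
  bt <- biopsy_table(pres, coords = cbind(runif(23), runif(23)))
  half <- subclonal_filter(bt, "present_in_more_than_half_of_samples")
  expect_identical(colnames(half$presence), c("M3", "M4"))
  all_ <- subclonal_filter(bt, "present_in_all_samples")
  expect_identical(colnames(all_$presence), c("M2", "M3", "M4"))
  expect_error(subclonal_filter(bt, "no_such_mode"))

  # frequency-spectrum flavour: drop whole-tumour clonal mutations
  spec <- make_spectrum(c(1, 1, 0.5, 0.1))
  expect_equal(subclonal_filter(spec, "whole_tumour_clonal")$cell_fraction,
               c(0.5, 0.1))
})

test_that("distance trend: negative in spatial tumours, null when unstructured", {
  # null construction: Jaccard drawn independently of distance
  set.seed(11)
  null_rec <- data.frame(sample_i = 1, sample_j = 2,
                         jaccard = runif(1e4), distance = runif(1e4),
                         non_overlapping = TRUE)
  s0 <- distance_trend_summary(null_rec)
  expect_lt(abs(s0$r), 0.05)

  tum <- grown_fixture("p0_4k", push_rate = 0, mutation_rate = 1,
                       target_size = 2^12, seed = 11)
  set.seed(12)
  ss <- random_square_samples(tum, 100, 80)
  rec <- jaccard_distance_table(tum, ss, pairing = "unordered")
  s1 <- distance_trend_summary(rec)
  expect_lt(s1$r, -0.1)
  expect_lt(s1$p_value, 0.01)
  expect_lt(s1$bins$mean_j[nrow(s1$bins)], s1$bins$mean_j[1])

  # degenerate input is flagged rather than fitted
  const <- data.frame(jaccard = rep(0.5, 10), distance = 1:10,
                      non_overlapping = TRUE)
  expect_true(distance_trend_summary(const)$degenerate)
  expect_error(distance_trend_summary(const[1:2, ]), "at least 3")
})

test_that("biopsy fixture: spatial decay controls the Jaccard-distance relation", {
  bt <- generate_biopsy_fixture(n_samples = 60, n_mutations = 400,
                                spatial_decay = 12, seed = 21)
  rec <- biopsy_jaccard_table(bt,
           filter_mode = "present_in_more_than_half_of_samples")
  s <- distance_trend_summary(rec, non_overlapping_only = FALSE)
  expect_lt(s$r, -0.1)
  expect_equal(max(rec$distance), 100)   # normalised distances

  # decay 0: sharing independent of space
  bt0 <- generate_biopsy_fixture(n_samples = 200, n_mutations = 300,
                                 spatial_decay = 0, seed = 22)
  s0 <- distance_trend_summary(biopsy_jaccard_table(bt0),
                               non_overlapping_only = FALSE)
  expect_lt(abs(s0$r), 0.05)

  # all-clonal table filtered on presence-in-all leaves nothing
  btc <- generate_biopsy_fixture(n_samples = 10, n_mutations = 50,
                                 clonal_fraction = 1, seed = 23)
  expect_equal(ncol(subclonal_filter(btc,
                    "present_in_all_samples")$presence), 0)
  recc <- biopsy_jaccard_table(btc, filter_mode = "present_in_all_samples")
  expect_true(all(recc$jaccard == 0))    # empty sets: J = 0 by convention
})

test_that("biopsy tables round-trip through their TSV reader and writer", {
  bt <- generate_biopsy_fixture(n_samples = 12, n_mutations = 40,
                                seed = 31)
  pf <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  write_biopsy_table(bt, pf, cf)
  bt2 <- read_biopsy_table(pf, coords_file = cf)
  expect_equal(bt2$presence[rownames(bt$presence), ],
               bt$presence[, colSums(bt$presence) > 0])
  expect_equal(unname(bt2$distances), unname(bt$distances),
               tolerance = 1e-6)
})
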