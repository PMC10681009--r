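# Hand-built perfect binary tree tumour: G synchronous generations,
# deterministic k private mutations per daughter.  Heap numbering (cell i
# has children 2i and 2i+1) so every structural quantity is enumerable by
# hand; geometry is meaningless (x = cell id) and must not be used.
build_tree_tumour <- function(G, k) {
  n <- 2L^(G + 1L) - 1L
  cell_id <- seq_len(n)
  mut_n <- c(0L, rep.int(as.integer(k), n - 1L))
  cells <- data.frame(
    cell_id = cell_id,
    parent_id = c(0L, rep(seq_len(2L^G - 1L), each = 2L)),
    birth_generation = as.integer(floor(log2(cell_id))),
    x = cell_id, y = 0L,
    alive = cell_id >= 2L^G,
    mut_start = cumsum(c(1L, mut_n))[seq_len(n)],
    mut_n = mut_n)
  structure(list(cells = cells, generations = G, n_alive = 2L^G,
                 n_mutations = sum(mut_n), dimension = 2L,
                 config = sim_config(push_rate = 1, mutation_rate = k,
                                     target_size = 2^G, seed = 1)),
            class = "tumour")
}

# frequency_spectrum built directly from cell fractions (for curve tests)
make_spectrum <- function(fractions, universe_size = 100L) {
  structure(data.frame(mutation_id = seq_along(fractions),
                       origin_cell_id = rep(NA_integer_,
                                            length(fractions)),
                       origin_generation = rep(NA_integer_,
                                               length(fractions)),
                       carriers = round(fractions * universe_size),
                       cell_fraction = fractions),
            universe_size = universe_size, convention = "cell_fraction",
            class = c("frequency_spectrum", "data.frame"))
}

# minimal sample_set for geometry tests: boxes of side s at given low
# corners
make_sample_set <- function(lo, s) {
  n <- nrow(lo)
  structure(list(
    samples = data.frame(sample_id = seq_len(n),
                         cx = lo[, 1] + (s - 1) / 2,
                         cy = lo[, 2] + (s - 1) / 2,
                         lo_x = lo[, 1], lo_y = lo[, 2],
                         side = s, region = "centre", n_cells = s^2),
    members = rep(list(integer(0)), n),
    dimension = 2L, side = as.integer(s)), class = "sample_set")
}

# grown tumours are expensive enough to share across tests in a file run
.fixtures <- new.env(parent = emptyenv())
grown_fixture <- function(key, ...) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- grow_tumour(sim_config(...))
  .fixtures[[key]]
}

# brute-force mutation set of a whole sample (oracle for the sparse path)
brute_sample_mutations <- function(tumour, members) {
  unique(unlist(lapply(members, function(m)
    resolve_mutation_set(tumour, m))))
}
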