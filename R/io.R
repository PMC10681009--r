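# Plain-TSV writers: one-line header, tab-separated, no quoting.  Every
# table round-trips through read.delim() without loss.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the cell table
#'
#' One row per cell ever created: `cell_id`, `parent_id`,
#' `birth_generation`, integer lattice coordinates `x`, `y` (`z` in 3D)
#' with the seed at the origin.
#'
#' @param tumour A `tumour` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(tumour, path) {
  stopifnot(inherits(tumour, "tumour"))
  cols <- c("cell_id", "parent_id", "birth_generation", "x", "y",
            if (tumour$dimension == 3) "z")
  .write_tsv(tumour$cells[, cols], path)
}

#' Write the mutation table
#'
#' One row per mutation: `mutation_id`, `origin_cell_id`,
#' `origin_generation`.
#'
#' @inheritParams write_cell_table
#' @export
write_mutation_table <- function(tumour, path) {
  stopifnot(inherits(tumour, "tumour"))
  cc <- tumour$cells
  idx <- which(cc$mut_n > 0L)
  .write_tsv(data.frame(
    mutation_id = sequence(cc$mut_n[idx], from = cc$mut_start[idx]),
    origin_cell_id = rep.int(cc$cell_id[idx], cc$mut_n[idx]),
    origin_generation = rep.int(cc$birth_generation[idx],
                                cc$mut_n[idx])), path)
}

#' Write a frequency table
#'
#' Columns `mutation_id`, `carriers`, `universe_size`, `cell_fraction`.
#'
#' @param spectrum A `frequency_spectrum`.
#' @param path Output TSV path.
#' @export
write_frequency_table <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  df <- data.frame(mutation_id = spectrum$mutation_id,
                   carriers = spectrum$carriers,
                   universe_size = attr(spectrum, "universe_size"),
                   cell_fraction = spectrum$cell_fraction)
  .write_tsv(df, path)
}

#' Write a sample table
#'
#' Wide format (one row per sample, member cell ids semicolon-joined) and
#' optionally a long-format membership table (`sample_id`, `cell_id`).
#'
#' @param sample_set A `sample_set`.
#' @param path Output TSV path.
#' @param members_path Optional path for the long membership table.
#' @export
write_sample_table <- function(sample_set, path, members_path = NULL) {
  stopifnot(inherits(sample_set, "sample_set"))
  sm <- sample_set$samples
  wide <- data.frame(sample_id = sm$sample_id, region = sm$region,
                     cx = sm$cx, cy = sm$cy)
  if (sample_set$dimension == 3) wide$cz <- sm$cz
  wide$side <- sm$side
  wide$cell_ids <- vapply(sample_set$members,
                          function(m) paste(m, collapse = ";"),
                          character(1))
  .write_tsv(wide, path)
  if (!is.null(members_path)) {
    long <- data.frame(
      sample_id = rep.int(sm$sample_id, lengths(sample_set$members)),
      cell_id = unlist(sample_set$members))
    .write_tsv(long, members_path)
  }
  invisible(path)
}

#' Write a Jaccard record table
#'
#' Columns `sample_i`, `sample_j`, `jaccard`, `distance`,
#' `non_overlapping`.
#'
#' @param records Output of [jaccard_distance_table()] or
#'   [biopsy_jaccard_table()].
#' @param path Output TSV path.
#' @export
write_jaccard_table <- function(records, path) .write_tsv(records, path)
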