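#' Derive a reproducible sub-seed for a named random table
#'
#' Every synthetic table draws from its own RNG stream, seeded by the master
#' seed and the table name, so that adding or re-ordering tables never
#' perturbs the others.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the stream (e.g. `"contacts"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- as.double(seed) %% 2147483647
  for (ch in codes) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a table-specific RNG stream
#' @keywords internal
with_table_seed <- function(seed, name, code) {
  withr::with_seed(derive_seed(seed, name), code,
                   .rng_kind = "Mersenne-Twister")
}

#' Canonical key for a 10 kb genomic bin
#'
#' @param chrom chromosome name(s).
#' @param bin_start 0-based bin start coordinate(s).
#' @return character vector `"chrom:bin_start"`.
#' @export
bin_key <- function(chrom, bin_start) {
  paste0(chrom, ":", format(bin_start, scientific = FALSE, trim = TRUE))
}

#' Tile chromosomes into fixed-width bins
#'
#' Bins are 0-based half-open `[start, start + bin_size)`; the last bin of a
#' chromosome may be short.
#'
#' @param chromosomes tibble with columns `chrom`, `length`.
#' @param bin_size bin width in bp (default 10000).
#' @return tibble with `chrom`, `bin_start`, `bin_end`, `bin` (key).
#' @export
tile_bins <- function(chromosomes, bin_size = 10000) {
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  purrr::pmap_dfr(chromosomes[, c("chrom", "length")], function(chrom, length) {
    starts <- seq(0, length - 1, by = bin_size)
    tibble(chrom = chrom, bin_start = starts,
           bin_end = pmin(starts + bin_size, length))
  }) |>
    mutate(bin = bin_key(.data$chrom, .data$bin_start))
}

#' Assign positions to bin start coordinates (half-open binning)
#'
#' @param pos genomic position(s), 0-based.
#' @param bin_size bin width, bp.
#' @return 0-based bin start coordinate(s).
#' @export
pos_to_bin <- function(pos, bin_size = 10000) {
  as.integer(floor(pos / bin_size)) * as.integer(bin_size)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
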