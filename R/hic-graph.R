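#' Filter a Hi-C interaction table into a significant-interaction graph
#'
#' Duplicate bin pairs are collapsed by summing read pairs (keeping the
#' smallest q-value) before filtering; self-loops are dropped; edges with at
#' least `min_pairs` read pairs and q-value at most `max_q` (both inclusive)
#' form an undirected graph over 10 kb bins.
#'
#' @param raw tibble with `chrom`, `bin_i_start`, `bin_j_start`,
#'   `read_pairs`, `q_value` (intra-chromosomal pairs).
#' @param min_pairs,max_q inclusive significance thresholds.
#' @return object of class `lnct_hic_graph`: list with `graph` (igraph,
#'   vertices named by [bin_key()]), `edges` (the surviving tibble).
#' @export
filter_hic <- function(raw, min_pairs = 5, max_q = 0.05) {
  assert_cols(raw, c("chrom", "bin_i_start", "bin_j_start", "read_pairs",
                     "q_value"))
  bad <- which(!complete.cases(raw[, c("chrom", "bin_i_start", "bin_j_start",
                                       "read_pairs", "q_value")]) |
                 raw$read_pairs < 0 | raw$q_value < 0 | raw$q_value > 1)
  if (length(bad) > 0) {
    abort(sprintf("malformed Hi-C rows at line(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "lnct_malformed_hic")
  }
  edges <- raw |>
    mutate(lo = pmin(.data$bin_i_start, .data$bin_j_start),
           hi = pmax(.data$bin_i_start, .data$bin_j_start)) |>
    filter(.data$lo != .data$hi) |>
    group_by(.data$chrom, .data$lo, .data$hi) |>
    summarise(read_pairs = sum(.data$read_pairs),
              q_value = min(.data$q_value), .groups = "drop") |>
    filter(.data$read_pairs >= min_pairs, .data$q_value <= max_q) |>
    mutate(bin_i = bin_key(.data$chrom, .data$lo),
           bin_j = bin_key(.data$chrom, .data$hi)) |>
    rename(bin_i_start = "lo", bin_j_start = "hi")

  g <- igraph::graph_from_data_frame(
    edges[, c("bin_i", "bin_j")], directed = FALSE)
  structure(list(graph = g, edges = edges), class = "lnct_hic_graph")
}

#' @export
print.lnct_hic_graph <- function(x, ...) {
  cat("<lnct_hic_graph>", igraph::vcount(x$graph), "bins,",
      igraph::ecount(x$graph), "significant interactions\n")
  invisible(x)
}

#' Degree of separation between two bins in the Hi-C graph
#'
#' Shortest-path hop count by breadth-first search, capped at `max_k`
#' (larger finite degrees and unreachable bins both return `Inf`); 0 iff
#' `source_bin == target_bin`.
#'
#' @param hic an [filter_hic()] graph.
#' @param source_bin,target_bin bin keys ([bin_key()]).
#' @param max_k cap on the reported degree.
#' @return numeric degree in `0..max_k`, or `Inf`.
#' @export
degree_of_separation <- function(hic, source_bin, target_bin, max_k = 2) {
  stopifnot(inherits(hic, "lnct_hic_graph"))
  if (source_bin == target_bin) return(0)
  d <- bin_degrees(hic, source_bin)[target_bin]
  d <- unname(ifelse(is.na(d), Inf, d))
  if (d > max_k) Inf else d
}

#' Hop distances from a reference bin to every bin in the graph
#'
#' @param hic an [filter_hic()] graph.
#' @param ref_bin reference bin key.
#' @return named numeric vector of hop counts over graph vertices
#'   (`Inf` = unreachable); empty vector when `ref_bin` is not a vertex.
#' @export
bin_degrees <- function(hic, ref_bin) {
  stopifnot(inherits(hic, "lnct_hic_graph"))
  vs <- igraph::V(hic$graph)$name
  if (!ref_bin %in% vs) {
    return(setNames(rep(Inf, length(vs)), vs))
  }
  d <- igraph::distances(hic$graph, v = ref_bin, to = igraph::V(hic$graph))
  setNames(as.numeric(d[1, ]), colnames(d))
}
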