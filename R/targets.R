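#' Define a lncRNA's candidate target regions from the Hi-C graph
#'
#' The reference region is the 10 kb bin overlapping the lncRNA's strongest
#' promoter. Candidate target bins are all bins connected to it by up to
#' `k` degrees of significant Hi-C interactions within the A or B
#' compartment run in which the reference bin is situated, extended by
#' `pad` on each side. With `constrain = "path"` (default) every bin on the
#' path must lie wholly inside the padded interval, preventing leakage
#' through excluded territory; `"endpoints"` only requires the target bin
#' itself to lie inside. The reference bin is excluded from the targets.
#'
#' @param ref_chrom,ref_pos strongest-promoter position of the lncRNA.
#' @param hic an [filter_hic()] graph.
#' @param compartments labeled compartment map
#'   ([reassign_compartments()]).
#' @param k maximum degree of separation.
#' @param pad compartment extension, bp.
#' @param bin_size bin width, bp.
#' @param constrain `"path"` or `"endpoints"`.
#' @return tibble `bin`, `chrom`, `bin_start`, `degree`, with attributes
#'   `interval` (`c(lo, hi)`), `label` and `ref_bin`; `NULL` (with a
#'   message) when the promoter falls in an unlabeled compartment.
#' @export
define_target_regions <- function(ref_chrom, ref_pos, hic, compartments,
                                  k = 2, pad = 100000, bin_size = 10000,
                                  constrain = c("path", "endpoints")) {
  constrain <- match.arg(constrain)
  stopifnot(inherits(hic, "lnct_hic_graph"))
  ref_start <- pos_to_bin(ref_pos, bin_size)
  ref_bin <- bin_key(ref_chrom, ref_start)
  mid <- ref_start + bin_size / 2
  label <- compartment_label_at(compartments, ref_chrom, mid)
  if (is.na(label)) {
    message("promoter bin ", ref_bin,
            " lies in an unlabeled compartment; lncRNA skipped")
    return(NULL)
  }
  runs <- compartment_runs(compartments)
  run <- runs[runs$chrom == ref_chrom & runs$start <= mid &
                runs$end > mid & runs$label == label, ]
  lo <- run$start[1] - pad
  hi <- run$end[1] + pad

  empty <- tibble(bin = character(0), chrom = character(0),
                  bin_start = numeric(0), degree = numeric(0))
  vs <- igraph::V(hic$graph)$name
  v_chrom <- sub(":.*", "", vs)
  v_start <- as.numeric(sub(".*:", "", vs))
  inside <- v_chrom == ref_chrom & v_start >= lo & v_start + bin_size <= hi

  if (!ref_bin %in% vs || k < 1) {
    return(structure(empty, interval = c(lo, hi), label = label,
                     ref_bin = ref_bin))
  }
  if (constrain == "path") {
    keep <- vs[inside | vs == ref_bin]
    sub <- igraph::induced_subgraph(hic$graph, keep)
    d <- igraph::distances(sub, v = ref_bin, to = igraph::V(sub))
    deg <- setNames(as.numeric(d[1, ]), colnames(d))
  } else {
    deg <- bin_degrees(hic, ref_bin)
    deg <- deg[names(deg) %in% vs[inside] | names(deg) == ref_bin]
  }
  deg <- deg[is.finite(deg) & deg >= 1 & deg <= k]
  out <- tibble(bin = names(deg),
                chrom = sub(":.*", "", names(deg)),
                bin_start = as.numeric(sub(".*:", "", names(deg))),
                degree = unname(deg)) |>
    arrange(.data$bin_start)
  structure(out, interval = c(lo, hi), label = label, ref_bin = ref_bin)
}

#' Map expressed promoters and enhancers into target regions
#'
#' All strongest promoters whose position falls in a target bin and all
#' expressed enhancers overlapping a target bin are returned; when one bin
#' holds features of several genes, each gene is counted separately.
#'
#' @param regions tibble with a `bin` column ([define_target_regions()]).
#' @param promoters strongest promoters: `promoter_id`, `gene_id`,
#'   `chrom`, `pos`.
#' @param enhancers expressed enhancers: `enhancer_id`, `chrom`, `start`,
#'   `end`; may be `NULL`.
#' @param bin_size bin width, bp.
#' @return list with `genes` (tibble `target_gene`, `promoter_id`, `bin`)
#'   and `enhancers` (tibble `enhancer_id`, `bin`).
#' @export
map_target_genes <- function(regions, promoters, enhancers = NULL,
                             bin_size = 10000) {
  genes <- tibble(target_gene = character(0), promoter_id = character(0),
                  bin = character(0))
  enh <- tibble(enhancer_id = character(0), bin = character(0))
  if (!is.null(regions) && nrow(regions) > 0) {
    prom <- promoters |>
      mutate(bin = bin_key(.data$chrom, pos_to_bin(.data$pos, bin_size)))
    genes <- prom |>
      filter(.data$bin %in% regions$bin) |>
      select(target_gene = "gene_id", promoter_id = "promoter_id", "bin")
    if (!is.null(enhancers) && nrow(enhancers) > 0) {
      spans <- purrr::pmap_dfr(
        enhancers[, c("enhancer_id", "chrom", "start", "end")],
        function(enhancer_id, chrom, start, end) {
          bs <- seq(pos_to_bin(start, bin_size),
                    pos_to_bin(end - 1, bin_size), by = bin_size)
          tibble(enhancer_id = enhancer_id, bin = bin_key(chrom, bs))
        })
      enh <- spans |> filter(.data$bin %in% regions$bin) |> distinct()
    }
  }
  list(genes = genes, enhancers = enh)
}
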