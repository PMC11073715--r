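#' Cumulative distribution of degrees of separation for significant bins
#'
#' For the significant RNA-chromatin bins of one lncRNA, computes the
#' cumulative fraction within `k` degrees of Hi-C separation from the
#' reference bin, for `k = 0..max_k`, plus the unreachable residual mass.
#'
#' @param sig_bins character vector of significant bin keys.
#' @param hic an [filter_hic()] graph.
#' @param ref_bin reference bin key.
#' @param max_k largest degree reported.
#' @return tibble `k`, `cum_fraction` with attribute `unreachable`
#'   (fraction beyond `max_k` or disconnected); zero-row tibble for empty
#'   input.
#' @export
degree_cdf <- function(sig_bins, hic, ref_bin, max_k = 5) {
  if (length(sig_bins) == 0) {
    return(structure(tibble(k = integer(0), cum_fraction = numeric(0)),
                     unreachable = NA_real_))
  }
  deg <- bin_degrees(hic, ref_bin)
  d <- ifelse(sig_bins == ref_bin, 0,
              unname(deg[sig_bins]))
  d[is.na(d)] <- Inf
  ks <- 0:max_k
  cum <- vapply(ks, function(k) mean(d <= k), numeric(1))
  structure(tibble(k = ks, cum_fraction = cum),
            unreachable = mean(d > max_k))
}

#' Sensitivity and specificity of "within k degrees" as a predictor
#'
#' Treating membership within `k` Hi-C degrees of the reference bin as a
#' predictor of RNA-chromatin significance over a bin universe:
#' sensitivity = fraction of significant bins within `k` degrees,
#' specificity = fraction of non-significant bins beyond `k` degrees.
#'
#' @param sig_bins significant bin keys (subset of `universe`).
#' @param hic an [filter_hic()] graph.
#' @param ref_bin reference bin key.
#' @param universe candidate bin keys.
#' @param max_k largest degree evaluated.
#' @return tibble `k`, `sensitivity`, `specificity`,
#'   `one_minus_specificity`; an empty significant or non-significant class
#'   yields `NA` for the undefined coordinate.
#' @export
sensitivity_specificity_by_degree <- function(sig_bins, hic, ref_bin,
                                              universe, max_k = 5) {
  stopifnot(all(sig_bins %in% universe))
  deg <- bin_degrees(hic, ref_bin)
  d <- ifelse(universe == ref_bin, 0, unname(deg[universe]))
  d[is.na(d)] <- Inf
  is_sig <- universe %in% sig_bins
  purrr::map_dfr(0:max_k, function(k) {
    within <- d <= k
    sens <- if (any(is_sig)) mean(within[is_sig]) else NA_real_
    spec <- if (any(!is_sig)) mean(!within[!is_sig]) else NA_real_
    tibble(k = k, sensitivity = sens, specificity = spec,
           one_minus_specificity = 1 - spec)
  })
}

#' Enrichment of significant RNA-chromatin bins in Hi-C-supported regions
#'
#' Tabulates {significant, not} x {within <= k degrees, not} over a bin
#' universe and applies a two-sided Fisher's exact test. With
#' `randomize = TRUE` the significant set is replaced by a same-size
#' uniform sample from the universe (seeded), which destroys the
#' association and serves as the negative control.
#'
#' @inheritParams sensitivity_specificity_by_degree
#' @param k degree threshold for "Hi-C supported".
#' @param randomize replace significant bins by a random same-size set.
#' @param seed seed for the randomization (required when
#'   `randomize = TRUE`).
#' @return a one-row [fisher_exact()] result with counts `a` (sig,
#'   within), `b` (sig, beyond), `c` (non-sig, within), `d`.
#' @export
hic_support_enrichment <- function(sig_bins, hic, ref_bin, universe, k = 2,
                                   randomize = FALSE, seed = NULL) {
  stopifnot(all(sig_bins %in% universe))
  if (randomize) {
    if (is.null(seed)) abort("randomize = TRUE requires a seed")
    sig_bins <- withr::with_seed(seed,
                                 sample(universe, length(sig_bins)))
  }
  deg <- bin_degrees(hic, ref_bin)
  d <- ifelse(universe == ref_bin, 0, unname(deg[universe]))
  d[is.na(d)] <- Inf
  within <- d <= k
  is_sig <- universe %in% sig_bins
  fisher_exact(sum(is_sig & within), sum(is_sig & !within),
               sum(!is_sig & within), sum(!is_sig & !within),
               side = "two")
}

#' Linear genomic distance and compartment co-membership of interactions
#'
#' For same-chromosome (lncRNA, bin) pairs: the distance between the bin
#' midpoint and the lncRNA's strongest-promoter position, and whether the
#' bin lies in the same A/B compartment as the promoter.
#'
#' @param pairs tibble with `gene_id`, `chrom`, `bin_start`.
#' @param promoters strongest promoters (`gene_id`, `chrom`, `pos`).
#' @param compartments labeled compartment map.
#' @param bin_size bin width, bp.
#' @return `pairs` with added `distance_bp` and `same_compartment`.
#' @export
linear_distance_stats <- function(pairs, promoters, compartments,
                                  bin_size = 10000) {
  assert_cols(pairs, c("gene_id", "chrom", "bin_start"))
  pr <- promoters[match(pairs$gene_id, promoters$gene_id), ]
  stopifnot(all(pairs$chrom == pr$chrom))
  mid <- pairs$bin_start + bin_size / 2
  lab_bin <- compartment_label_at(compartments, pairs$chrom, mid)
  lab_prom <- compartment_label_at(compartments, pr$chrom, pr$pos)
  pairs |>
    mutate(distance_bp = abs(mid - pr$pos),
           same_compartment = lab_bin == lab_prom)
}

#' Pooled comparison of RNA-chromatin interactions with the Hi-C graph
#'
#' For each lncRNA with significant intra-chromosomal RNA-chromatin bins,
#' computes hop degrees from the lncRNA's promoter bin, then pools across
#' lncRNAs: the degree CDF, per-degree sensitivity/specificity, the
#' 2x2 Hi-C-support enrichment (observed and with randomized interactions),
#' and per-interaction linear distances with compartment co-membership.
#' The universe per lncRNA is the set of Hi-C graph bins on its chromosome
#' together with its significant bins.
#'
#' @param sig caller output ([iterative_binomial_caller()]).
#' @param lnc_ids lncRNA gene ids to include.
#' @param hic an [filter_hic()] graph.
#' @param promoters strongest promoters (`gene_id`, `chrom`, `pos`).
#' @param compartments labeled compartment map.
#' @param bin_size bin width, bp.
#' @param max_k largest degree tabulated.
#' @param k degree threshold for the enrichment table.
#' @param seed seed for the randomized control.
#' @return list `degree_cdf`, `sens_spec`, `enrichment`,
#'   `enrichment_random`, `distances`, `per_lnc` (tibble of per-lncRNA bin
#'   degrees).
#' @export
rnachrom_hic_comparison <- function(sig, lnc_ids, hic, promoters,
                                    compartments, bin_size = 10000,
                                    max_k = 5, k = 2, seed = 1) {
  sig_intra <- sig |>
    filter(.data$cis, .data$gene_id %in% lnc_ids)
  vs <- igraph::V(hic$graph)$name
  v_chrom <- sub(":.*", "", vs)

  per_lnc <- purrr::map_dfr(unique(sig_intra$gene_id), function(L) {
    pr <- promoters[promoters$gene_id == L, ]
    if (nrow(pr) == 0) return(NULL)
    ref <- bin_key(pr$chrom[1], pos_to_bin(pr$pos[1], bin_size))
    bins <- sig_intra$bin[sig_intra$gene_id == L]
    deg <- bin_degrees(hic, ref)
    d <- ifelse(bins == ref, 0, unname(deg[bins]))
    d[is.na(d)] <- Inf
    tibble(gene_id = L, bin = bins, ref_bin = ref, degree = d)
  })
  if (nrow(per_lnc) == 0) {
    return(list(degree_cdf = tibble(k = integer(0), cum_fraction = numeric(0)),
                sens_spec = NULL, enrichment = NULL,
                enrichment_random = NULL, distances = NULL,
                per_lnc = per_lnc))
  }

  cdf <- tibble(k = 0:max_k,
                cum_fraction = vapply(0:max_k, function(kk) {
                  mean(per_lnc$degree <= kk)
                }, numeric(1)))

  ## pooled confusion counts and 2x2 cells over per-lncRNA universes
  cells <- purrr::map_dfr(unique(per_lnc$gene_id), function(L) {
    ref <- per_lnc$ref_bin[per_lnc$gene_id == L][1]
    chrom <- sub(":.*", "", ref)
    universe <- union(vs[v_chrom == chrom],
                      per_lnc$bin[per_lnc$gene_id == L])
    deg <- bin_degrees(hic, ref)
    d <- ifelse(universe == ref, 0, unname(deg[universe]))
    d[is.na(d)] <- Inf
    is_sig <- universe %in% per_lnc$bin[per_lnc$gene_id == L]
    rnd_sig <- universe %in% withr::with_seed(
      derive_seed(seed, paste0("randomize_", L)),
      sample(universe, sum(is_sig)))
    purrr::map_dfr(0:max_k, function(kk) {
      w <- d <= kk
      tibble(gene_id = L, k = kk,
             a = sum(is_sig & w), b = sum(is_sig & !w),
             c = sum(!is_sig & w), d = sum(!is_sig & !w),
             ra = sum(rnd_sig & w), rb = sum(rnd_sig & !w),
             rc = sum(!rnd_sig & w), rd = sum(!rnd_sig & !w))
    })
  })
  pooled <- cells |>
    group_by(.data$k) |>
    summarise(dplyr::across(c("a", "b", "c", "d", "ra", "rb", "rc", "rd"),
                            sum), .groups = "drop")
  sens_spec <- pooled |>
    mutate(sensitivity = .data$a / (.data$a + .data$b),
           specificity = .data$d / (.data$c + .data$d),
           one_minus_specificity = 1 - .data$specificity) |>
    select("k", "sensitivity", "specificity", "one_minus_specificity")
  at_k <- pooled[pooled$k == k, ]
  enrichment <- fisher_exact(at_k$a, at_k$b, at_k$c, at_k$d, side = "two")
  enrichment_random <- fisher_exact(at_k$ra, at_k$rb, at_k$rc, at_k$rd,
                                    side = "two")

  distances <- per_lnc |>
    mutate(chrom = sub(":.*", "", .data$bin),
           bin_start = as.numeric(sub(".*:", "", .data$bin))) |>
    linear_distance_stats(promoters, compartments, bin_size = bin_size)

  list(degree_cdf = cdf, sens_spec = sens_spec, enrichment = enrichment,
       enrichment_random = enrichment_random, distances = distances,
       per_lnc = per_lnc)
}
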