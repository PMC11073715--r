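#' Enrichment of knockdown-differential genes among lncRNA targets
#'
#' For each knocked-down lncRNA, tabulates {target, non-target} x
#' {DE in the requested direction, not} over the gene universe, where a
#' gene is DE when its FDR-corrected p-value is at most `fdr_cut` in at
#' least one ASO and its fold change has the requested sign. A one-sided
#' (right-tail) Fisher test is the default; `sidedness = "two"` is
#' available. lncRNAs with fewer than `min_de_targets` DE genes (either
#' direction) among their targets are flagged out of the headline summary,
#' and per-lncRNA p-values of the remaining ones are combined with
#' Fisher's method.
#'
#' @param targets named list: lncRNA id -> character vector of target
#'   gene ids.
#' @param de knockdown DE table: `lncrna`, `aso`, `gene_id`, `log2fc`,
#'   `fdr`.
#' @param universe character vector of all genes under consideration.
#' @param fdr_cut DE threshold (inclusive).
#' @param direction `"up"` or `"down"`: which fold-change sign counts as DE.
#' @param sidedness `"one"` or `"two"`.
#' @param min_de_targets headline inclusion threshold.
#' @return list with `results` (one row per lncRNA: counts, `odds_ratio`,
#'   `log2_or`, `p_value`, `n_de_targets`, `included`) and `combined_p`.
#' @export
kd_de_enrichment <- function(targets, de, universe, fdr_cut = 0.1,
                             direction = c("up", "down"),
                             sidedness = c("one", "two"),
                             min_de_targets = 3) {
  direction <- match.arg(direction)
  sidedness <- match.arg(sidedness)
  assert_cols(de, c("lncrna", "aso", "gene_id", "log2fc", "fdr"))
  side <- if (sidedness == "one") "right" else "two"

  rows <- purrr::map_dfr(names(targets), function(L) {
    sub <- de[de$lncrna == L, ]
    if (nrow(sub) == 0) {
      message("lncRNA ", L, " absent from DE table; skipped")
      return(NULL)
    }
    de_dir <- sub |>
      filter(.data$fdr <= fdr_cut,
             if (direction == "up") .data$log2fc > 0 else .data$log2fc < 0) |>
      pull(.data$gene_id) |> unique()
    de_any <- sub |>
      filter(.data$fdr <= fdr_cut) |> pull(.data$gene_id) |> unique()
    targ <- intersect(targets[[L]], universe)
    nontarg <- setdiff(universe, c(targ, L))
    fe <- fisher_exact(length(intersect(targ, de_dir)),
                       length(setdiff(targ, de_dir)),
                       length(intersect(nontarg, de_dir)),
                       length(setdiff(nontarg, de_dir)), side = side)
    fe$lncrna <- L
    fe$n_de_targets <- length(intersect(targ, de_any))
    fe
  })
  if (nrow(rows) == 0) {
    return(list(results = rows, combined_p = NA_real_))
  }
  rows <- rows |>
    mutate(log2_or = log2(.data$odds_ratio),
           included = .data$n_de_targets >= min_de_targets) |>
    select("lncrna", "a", "b", "c", "d", "odds_ratio", "log2_or",
           "p_value", "side", "n_de_targets", "included")
  usable <- rows$p_value[rows$included]
  list(results = rows,
       combined_p = if (length(usable) > 0) fisher_combine(usable) else 1)
}

#' Gene Ontology (term-set) enrichment of per-lncRNA targets
#'
#' For each lncRNA, a one-sided Fisher test per term that shares at least
#' one gene with the lncRNA's target list. The background is all target
#' genes of all other lncRNAs, excluding the reference lncRNA's own
#' targets. P-values are BH-adjusted across terms per lncRNA; a term is
#' significant at `fdr <= fdr_cut` with an overlap of at least
#' `min_overlap` genes.
#'
#' @param targets named list: lncRNA id -> mRNA target gene ids.
#' @param go_sets named list: term -> gene ids.
#' @param fdr_cut,min_overlap significance thresholds.
#' @return tibble `lncrna`, `term`, counts, `odds_ratio`, `p_value`,
#'   `fdr`, `overlap`, `significant`.
#' @export
go_enrichment <- function(targets, go_sets, fdr_cut = 0.1, min_overlap = 3) {
  stopifnot(length(targets) > 0, length(go_sets) > 0)
  all_targets <- unique(unlist(targets))
  purrr::map_dfr(names(targets), function(L) {
    T <- unique(targets[[L]])
    B <- setdiff(all_targets, T)
    if (length(B) == 0) {
      abort(paste0("empty background for lncRNA ", L),
            class = "lnct_empty_background")
    }
    rows <- purrr::map_dfr(names(go_sets), function(term) {
      S <- go_sets[[term]]
      ov <- length(intersect(T, S))
      if (ov == 0) return(NULL)   # terms without overlap are not tested
      fe <- fisher_exact(ov, length(setdiff(T, S)),
                         length(intersect(B, S)), length(setdiff(B, S)),
                         side = "right")
      fe$term <- term
      fe$overlap <- ov
      fe
    })
    if (nrow(rows) == 0) return(NULL)
    rows$fdr <- bh_fdr(rows$p_value)
    rows$lncrna <- L
    rows$significant <- rows$fdr <= fdr_cut & rows$overlap >= min_overlap
    rows[, c("lncrna", "term", "a", "b", "c", "d", "odds_ratio",
             "p_value", "fdr", "overlap", "significant")]
  })
}

#' TFBS motif enrichment in per-lncRNA target promoters and enhancers
#'
#' For each lncRNA with at least `min_targets` target regions, a one-sided
#' Fisher test per motif of {target region, other region} x {motif
#' assigned, not}, BH-adjusted across motifs per lncRNA; a Fisher-combined
#' p-value per lncRNA over its motifs; and per motif, a chi-square test of
#' whether the motif's occurrence among target regions varies across
#' lncRNAs.
#'
#' @param assignments TFBS assignments: tibble `region_id`, `motif`,
#'   `assigned` (see [assign_tfbs()]); only `assigned` rows count.
#' @param targets named list: lncRNA id -> target region ids (promoters
#'   and enhancers).
#' @param all_regions character universe of region ids.
#' @param min_targets minimal target-region count per tested lncRNA.
#' @param fdr_cut BH threshold.
#' @return list with `results` (per lncRNA x motif), `combined` (tibble
#'   `lncrna`, `combined_p`), `motif_chisq` (tibble `motif`, `statistic`,
#'   `p_value`) and `excluded` (lncRNAs under the target minimum).
#' @export
tfbs_enrichment <- function(assignments, targets, all_regions,
                            min_targets = 5, fdr_cut = 0.1) {
  assert_cols(assignments, c("region_id", "motif", "assigned"))
  assigned <- assignments[as.logical(assignments$assigned) %in% TRUE, ]
  motif_regions <- split(assigned$region_id, assigned$motif)

  n_targ <- vapply(targets, function(x) length(unique(x)), integer(1))
  excluded <- names(targets)[n_targ < min_targets]
  tested <- setdiff(names(targets), excluded)

  results <- purrr::map_dfr(tested, function(L) {
    T <- unique(targets[[L]])
    O <- setdiff(all_regions, T)
    rows <- purrr::map_dfr(names(motif_regions), function(m) {
      R <- motif_regions[[m]]
      fe <- fisher_exact(length(intersect(T, R)), length(setdiff(T, R)),
                         length(intersect(O, R)), length(setdiff(O, R)),
                         side = "right")
      fe$motif <- m
      fe
    })
    if (nrow(rows) == 0) return(NULL)
    rows$fdr <- bh_fdr(rows$p_value)
    rows$lncrna <- L
    rows$significant <- rows$fdr <= fdr_cut
    rows[, c("lncrna", "motif", "a", "b", "c", "d", "odds_ratio",
             "p_value", "fdr", "significant")]
  })

  combined <- results |>
    group_by(.data$lncrna) |>
    summarise(combined_p = fisher_combine(.data$p_value), .groups = "drop")

  motif_chisq <- purrr::map_dfr(names(motif_regions), function(m) {
    R <- motif_regions[[m]]
    with_m <- vapply(tested, function(L) {
      length(intersect(unique(targets[[L]]), R))
    }, integer(1))
    without <- n_targ[tested] - with_m
    tab <- rbind(with_m, without)
    if (any(colSums(tab) == 0) || sum(with_m) == 0 || sum(without) == 0) {
      return(tibble(motif = m, statistic = 0, p_value = 1))
    }
    exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
    if (exp_min < 5) {
      message("motif ", m, ": chi-square expected count below 5")
    }
    ct <- suppressWarnings(chisq.test(tab))
    tibble(motif = m, statistic = unname(ct$statistic),
           p_value = ct$p.value)
  })
  list(results = results, combined = combined, motif_chisq = motif_chisq,
       excluded = excluded)
}

#' Expression-correlation preference of lncRNA targets
#'
#' Spearman correlation between each lncRNA and each of its target genes
#' across cell types; a one-sample t-test of the correlations against 0
#' classifies the lncRNA as having positive, negative or no correlation
#' preference (p <= `p_cut` with matching t sign). Per-pair correlation
#' test p-values at `pair_p_cut` give the percentage of significantly
#' positively/negatively correlated targets.
#'
#' @param expr numeric matrix, genes x cell types (rownames = gene ids).
#' @param targets named list: lncRNA id -> target gene ids.
#' @param p_cut t-test threshold for the category call.
#' @param pair_p_cut per-pair correlation-test threshold.
#' @return tibble `lncrna`, `n_pairs`, `n_dropped`, `mean_rho`,
#'   `t_statistic`, `p_value`, `category`, `pct_sig_pos`, `pct_sig_neg`.
#' @export
correlation_preference <- function(expr, targets, p_cut = 0.05,
                                   pair_p_cut = 0.01) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), ncol(expr) >= 3)
  purrr::map_dfr(names(targets), function(L) {
    if (!L %in% rownames(expr)) return(NULL)
    x <- expr[L, ]
    tg <- intersect(unique(targets[[L]]), rownames(expr))
    rho <- rep(NA_real_, length(tg))
    pp <- rep(NA_real_, length(tg))
    for (i in seq_along(tg)) {
      y <- expr[tg[i], ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      rho[i] <- unname(ct$estimate)
      pp[i] <- ct$p.value
    }
    ok <- !is.na(rho)
    n_dropped <- sum(!ok)
    rho <- rho[ok]; pp <- pp[ok]
    if (length(rho) < 2 || stats::sd(rho) == 0) {
      return(tibble(lncrna = L, n_pairs = length(rho),
                    n_dropped = n_dropped, mean_rho = mean(rho),
                    t_statistic = NA_real_, p_value = NA_real_,
                    category = "none",
                    pct_sig_pos = 100 * mean(pp <= pair_p_cut & rho > 0),
                    pct_sig_neg = 100 * mean(pp <= pair_p_cut & rho < 0)))
    }
    tt <- t.test(rho, mu = 0)
    category <- if (tt$p.value <= p_cut) {
      if (unname(tt$statistic) > 0) "positive" else "negative"
    } else "none"
    tibble(lncrna = L, n_pairs = length(rho), n_dropped = n_dropped,
           mean_rho = mean(rho), t_statistic = unname(tt$statistic),
           p_value = tt$p.value, category = category,
           pct_sig_pos = 100 * mean(pp <= pair_p_cut & rho > 0),
           pct_sig_neg = 100 * mean(pp <= pair_p_cut & rho < 0))
  })
}

#' Filter eCLIP gene-level statistics into reliable RBP target sets
#'
#' Reliable RNA targets pass 5% FDR and log2 fold change strictly above
#' `lfc_cut`; RBPs with fewer than `min_lnc_targets` lncRNA targets are
#' dropped.
#'
#' @param stats eCLIP table: `rbp`, `gene_id`, `log2fc`, `fdr`.
#' @param lnc_ids character vector of lncRNA gene ids.
#' @param fdr_cut inclusive FDR threshold.
#' @param lfc_cut exclusive log2FC threshold.
#' @param min_lnc_targets minimal lncRNA target count per retained RBP.
#' @return named list: RBP -> target gene ids; attribute `dropped` lists
#'   RBPs under the minimum.
#' @export
eclip_target_filter <- function(stats, lnc_ids, fdr_cut = 0.05,
                                lfc_cut = 0.5, min_lnc_targets = 15) {
  assert_cols(stats, c("rbp", "gene_id", "log2fc", "fdr"))
  hits <- stats |>
    filter(.data$fdr <= fdr_cut, .data$log2fc > lfc_cut)
  sets <- split(hits$gene_id, hits$rbp)
  n_lnc <- vapply(sets, function(g) length(intersect(g, lnc_ids)),
                  integer(1))
  dropped <- names(sets)[n_lnc < min_lnc_targets]
  structure(sets[n_lnc >= min_lnc_targets], dropped = dropped)
}

#' RBP enrichment batteries over lncRNA targets
#'
#' Four analyses tying RNA-binding proteins (RBPs) to lncRNA target genes:
#'
#' 1. `kd`: for each RBP binding at most `max_lnc` lncRNAs, one-tailed
#'    Fisher test of whether genes differentially expressed after RBP
#'    knockdown are enriched among target genes of RBP-bound lncRNAs
#'    (versus target genes of unbound lncRNAs).
#' 2. `promoter`: per (lncRNA, RBP binding it), right-tailed Fisher test of
#'    whether the lncRNA's target promoters are enriched for the RBP's
#'    ChIP-bound promoters; BH over RBPs per lncRNA, significant at
#'    `fdr <= fdr_cut` with at least `min_rbp_targets` RBP-bound target
#'    promoters.
#' 3. `ppi`: as 2, with the RBP's promoter set expanded through
#'    protein-protein interaction partners with score strictly above
#'    `ppi_min`.
#' 4. `nc_test`: one-tailed Mann-Whitney U test that RBP-bound lncRNAs
#'    have a higher nuclear-to-cytoplasmic ratio than unbound ones.
#'
#' Fisher-combined p-values are reported per battery. A battery whose
#' input table is `NULL` is skipped with a message.
#'
#' @param rbp_targets named list RBP -> bound gene ids
#'   ([eclip_target_filter()]).
#' @param lnc_targets named list lncRNA -> target gene ids.
#' @param rbp_kd_de RBP knockdown DE table: `rbp`, `gene_id`, `fdr`.
#' @param chip ChIP table: `rbp`, `promoter_id`.
#' @param promoters strongest promoters: `gene_id`, `promoter_id`.
#' @param ppi PPI table: `rbp_a`, `rbp_b`, `score`.
#' @param nc nuclear classification for lncRNAs: `gene_id`, `nc_ratio`.
#' @param max_lnc RBPs binding more lncRNAs than this are excluded from
#'   the knockdown battery.
#' @param kd_fdr DE threshold in the knockdown battery.
#' @param ppi_min exclusive PPI score threshold.
#' @param fdr_cut,min_rbp_targets significance rules for batteries 2-3.
#' @return list `kd`, `promoter`, `ppi` (tibbles), `nc_test` (list),
#'   `combined` (named numeric).
#' @export
rbp_batteries <- function(rbp_targets, lnc_targets, rbp_kd_de = NULL,
                          chip = NULL, promoters = NULL, ppi = NULL,
                          nc = NULL, max_lnc = 500, kd_fdr = 0.1,
                          ppi_min = 0.4, fdr_cut = 0.1,
                          min_rbp_targets = 3) {
  lncs <- names(lnc_targets)
  bound_lncs_of <- lapply(rbp_targets, intersect, y = lncs)
  all_target_genes <- unique(unlist(lnc_targets))
  combined <- c()

  kd <- NULL
  if (!is.null(rbp_kd_de)) {
    assert_cols(rbp_kd_de, c("rbp", "gene_id", "fdr"))
    kd <- purrr::map_dfr(names(rbp_targets), function(r) {
      bl <- bound_lncs_of[[r]]
      if (length(bl) == 0 || length(bl) > max_lnc) return(NULL)
      sub <- rbp_kd_de[rbp_kd_de$rbp == r, ]
      if (nrow(sub) == 0) return(NULL)
      de <- unique(sub$gene_id[sub$fdr <= kd_fdr])
      g_bound <- unique(unlist(lnc_targets[bl]))
      g_other <- setdiff(all_target_genes, g_bound)
      fe <- fisher_exact(length(intersect(g_bound, de)),
                         length(setdiff(g_bound, de)),
                         length(intersect(g_other, de)),
                         length(setdiff(g_other, de)), side = "right")
      fe$rbp <- r
      fe$n_bound_lnc <- length(bl)
      fe
    })
    if (!is.null(kd) && nrow(kd) > 0) {
      combined["kd"] <- fisher_combine(kd$p_value)
    }
  } else message("knockdown battery skipped: no RBP knockdown DE table")

  run_promoter_battery <- function(chip_sets) {
    all_prom <- unique(promoters$promoter_id)
    rows <- purrr::map_dfr(names(chip_sets), function(r) {
      bl <- bound_lncs_of[[r]]
      if (is.null(bl) || length(bl) == 0) return(NULL)
      purrr::map_dfr(bl, function(L) {
        tp <- unique(promoters$promoter_id[
          promoters$gene_id %in% lnc_targets[[L]]])
        op <- setdiff(all_prom, tp)
        R <- chip_sets[[r]]
        fe <- fisher_exact(length(intersect(tp, R)),
                           length(setdiff(tp, R)),
                           length(intersect(op, R)),
                           length(setdiff(op, R)), side = "right")
        fe$rbp <- r
        fe$lncrna <- L
        fe
      })
    })
    if (nrow(rows) == 0) return(rows)
    rows |>
      group_by(.data$lncrna) |>
      mutate(fdr = bh_fdr(.data$p_value)) |>
      ungroup() |>
      mutate(significant = .data$fdr <= fdr_cut &
               .data$a >= min_rbp_targets)
  }

  promoter_res <- NULL
  if (!is.null(chip) && !is.null(promoters)) {
    assert_cols(chip, c("rbp", "promoter_id"))
    chip_sets <- split(chip$promoter_id, chip$rbp)
    chip_sets <- chip_sets[intersect(names(chip_sets), names(rbp_targets))]
    promoter_res <- run_promoter_battery(chip_sets)
    if (nrow(promoter_res) > 0) {
      combined["promoter"] <- fisher_combine(promoter_res$p_value)
    }
  } else message("promoter battery skipped: no ChIP/promoter table")

  ppi_res <- NULL
  if (!is.null(ppi) && !is.null(chip) && !is.null(promoters)) {
    assert_cols(ppi, c("rbp_a", "rbp_b", "score"))
    strong <- ppi[ppi$score > ppi_min, ]
    chip_sets <- split(chip$promoter_id, chip$rbp)
    expanded <- lapply(names(rbp_targets), function(r) {
      partners <- union(strong$rbp_b[strong$rbp_a == r],
                        strong$rbp_a[strong$rbp_b == r])
      unique(unlist(chip_sets[intersect(c(r, partners),
                                        names(chip_sets))]))
    })
    names(expanded) <- names(rbp_targets)
    expanded <- expanded[vapply(expanded, length, integer(1)) > 0]
    ppi_res <- run_promoter_battery(expanded)
    if (nrow(ppi_res) > 0) {
      combined["ppi"] <- fisher_combine(ppi_res$p_value)
    }
  } else message("PPI battery skipped: no PPI/ChIP table")

  nc_test <- NULL
  if (!is.null(nc)) {
    assert_cols(nc, c("gene_id", "nc_ratio"))
    ## bound = bound by any retained RBP, over all classified lncRNAs
    bound_any <- intersect(unique(unlist(rbp_targets)), nc$gene_id)
    x <- nc$nc_ratio[nc$gene_id %in% bound_any]
    y <- nc$nc_ratio[!nc$gene_id %in% bound_any]
    nc_test <- if (length(x) == 0 || length(y) == 0) {
      list(p_value = NA_real_, statistic = NA_real_,
           n_bound = length(x), n_unbound = length(y))
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
      list(p_value = wt$p.value, statistic = unname(wt$statistic),
           n_bound = length(x), n_unbound = length(y))
    }
  }
  list(kd = kd, promoter = promoter_res, ppi = ppi_res, nc_test = nc_test,
       combined = combined)
}
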