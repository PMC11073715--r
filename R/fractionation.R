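#' Normalize CAGE tag counts to tags per million (tpm)
#'
#' Each library column is scaled so that it sums to 10^6 over all promoters.
#'
#' @param tag_counts numeric matrix or data frame, promoters x libraries;
#'   rownames (or a `promoter_id` column) identify promoters.
#' @return a matrix of the same shape in tpm.
#' @export
normalize_tpm <- function(tag_counts) {
  m <- as.matrix(tag_counts)
  if (!is.numeric(m)) abort("tag counts must be numeric")
  if (any(m < 0)) abort("tag counts must be non-negative")
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    abort(sprintf("library with all-zero counts: %s",
                  paste(colnames(m)[zero] %||% which(zero), collapse = ", ")),
          class = "lnct_zero_library")
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Select each gene's strongest expressed promoter
#'
#' Per gene, the promoter with the highest mean tpm among promoters with a
#' minimum mean expression of 0.5 tpm and at least 3 tag counts in at least
#' one library. Ties are broken by lexicographically smallest promoter id.
#' Genes with no passing promoter are absent from the result.
#'
#' @param expr tibble with columns `promoter_id`, `gene_id`, `mean_tpm`
#'   (mean tpm across libraries) and `max_tags` (max raw tag count over
#'   libraries). [promoter_expression()] builds this from wide counts.
#' @param min_tpm,min_tags inclusive thresholds.
#' @return tibble `gene_id`, `promoter_id`, `mean_tpm`.
#' @export
strongest_promoter <- function(expr, min_tpm = 0.5, min_tags = 3) {
  assert_cols(expr, c("promoter_id", "gene_id", "mean_tpm", "max_tags"))
  expr |>
    filter(.data$mean_tpm >= min_tpm, .data$max_tags >= min_tags) |>
    arrange(.data$gene_id, dplyr::desc(.data$mean_tpm), .data$promoter_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("gene_id", "promoter_id", "mean_tpm")
}

#' Summarise a wide promoter count table into per-promoter expression
#'
#' Computes per-library tpm, then the mean tpm across all libraries, the
#' max raw tag count, and mean tpm per subcellular fraction (libraries are
#' named `<fraction>_<replicate>`).
#'
#' @param counts wide tibble: `promoter_id`, `gene_id`, one column per
#'   library.
#' @return tibble `promoter_id`, `gene_id`, `mean_tpm`, `max_tags`, and one
#'   `tpm_<fraction>` column per fraction.
#' @export
promoter_expression <- function(counts) {
  assert_cols(counts, c("promoter_id", "gene_id"))
  libs <- setdiff(names(counts), c("promoter_id", "gene_id"))
  if (length(libs) == 0) abort("no library columns found")
  tpm <- normalize_tpm(counts[, libs])
  fractions <- sub("_[^_]*$", "", libs)
  out <- counts[, c("promoter_id", "gene_id")]
  out$mean_tpm <- rowMeans(tpm)
  out$max_tags <- do.call(pmax, as.data.frame(counts[, libs]))
  for (fr in unique(fractions)) {
    out[[paste0("tpm_", fr)]] <-
      rowMeans(tpm[, fractions == fr, drop = FALSE])
  }
  out
}

#' Filter enhancers by aggregate CAGE tag count
#'
#' Keeps enhancers whose tag counts summed across all libraries (ignoring
#' directionality) reach `min_total`.
#'
#' @param enhancer_counts wide tibble: `enhancer_id` plus library columns.
#' @param min_total inclusive aggregate threshold.
#' @return character vector of expressed enhancer ids.
#' @export
expressed_enhancers <- function(enhancer_counts, min_total = 5) {
  assert_cols(enhancer_counts, "enhancer_id")
  libs <- setdiff(names(enhancer_counts), "enhancer_id")
  m <- as.matrix(enhancer_counts[, libs])
  if (any(m < 0)) abort("enhancer counts must be non-negative")
  enhancer_counts$enhancer_id[rowSums(m) >= min_total]
}

#' Nuclear-to-cytoplasmic expression ratio
#'
#' Two-fraction form `nuclear / (nuclear + cytoplasmic)`; when chromatin and
#' nucleoplasm expression are available instead of a single nuclear value,
#' the three-fraction form
#' `mean(chromatin, nucleoplasm) / (mean(chromatin, nucleoplasm) + cytoplasmic)`
#' is used. A 0/0 ratio is undefined and returned as `NA` (such genes are
#' excluded from nuclear classification).
#'
#' @param nuclear,cytoplasmic,chromatin,nucleoplasm non-negative tpm
#'   vectors; give either `nuclear`, or both `chromatin` and `nucleoplasm`.
#' @return numeric vector of ratios in `[0, 1]` (`NA` where undefined).
#' @export
nc_ratio <- function(nuclear = NULL, cytoplasmic, chromatin = NULL,
                     nucleoplasm = NULL) {
  if (is.null(nuclear)) {
    if (is.null(chromatin) || is.null(nucleoplasm)) {
      abort("give either `nuclear`, or both `chromatin` and `nucleoplasm`")
    }
    if (any(chromatin < 0, na.rm = TRUE) ||
        any(nucleoplasm < 0, na.rm = TRUE)) {
      abort("expression values must be non-negative")
    }
    nuclear <- (chromatin + nucleoplasm) / 2
  }
  if (any(nuclear < 0, na.rm = TRUE) || any(cytoplasmic < 0, na.rm = TRUE)) {
    abort("expression values must be non-negative")
  }
  total <- nuclear + cytoplasmic
  ifelse(total == 0, NA_real_, nuclear / total)
}

#' Classify lncRNAs as nuclear by their N/C ratio
#'
#' `is_nuclear` is `ratio >= threshold` (inclusive). Genes with an undefined
#' ratio (`NA`) receive the average ratio over the other contexts in
#' `fallback` when provided (e.g. the same gene's ratios in other cell
#' types), otherwise they are dropped; the number dropped is reported as an
#' attribute.
#'
#' @param ratios tibble with `gene_id`, `nc_ratio` (may contain `NA`).
#' @param threshold inclusive nuclear threshold.
#' @param fallback optional tibble `gene_id`, `nc_ratio` with ratios
#'   observed in other contexts, averaged (unweighted) per gene to fill
#'   missing values.
#' @return tibble `gene_id`, `nc_ratio`, `is_nuclear`; attribute
#'   `n_dropped` counts genes with no defined ratio anywhere.
#' @export
classify_nuclear <- function(ratios, threshold = 0.5, fallback = NULL) {
  assert_cols(ratios, c("gene_id", "nc_ratio"))
  out <- ratios
  if (!is.null(fallback)) {
    fb <- fallback |>
      filter(!is.na(.data$nc_ratio)) |>
      group_by(.data$gene_id) |>
      summarise(fb_ratio = mean(.data$nc_ratio), .groups = "drop")
    out <- out |>
      left_join(fb, by = "gene_id") |>
      mutate(nc_ratio = ifelse(is.na(.data$nc_ratio), .data$fb_ratio,
                               .data$nc_ratio)) |>
      select(-"fb_ratio")
  }
  n_dropped <- sum(is.na(out$nc_ratio))
  out <- out |>
    filter(!is.na(.data$nc_ratio)) |>
    mutate(is_nuclear = .data$nc_ratio >= threshold)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-gene nuclear classification from a wide promoter count table
#'
#' Convenience wrapper: summarises promoter expression, sums fraction tpm
#' over each gene's promoters, computes N/C ratios and classifies.
#'
#' @inheritParams promoter_expression
#' @inheritParams classify_nuclear
#' @return result of [classify_nuclear()].
#' @export
fractionation_pipeline <- function(counts, threshold = 0.5) {
  pe <- promoter_expression(counts)
  frac_cols <- grep("^tpm_", names(pe), value = TRUE)
  gene_expr <- pe |>
    group_by(.data$gene_id) |>
    summarise(dplyr::across(dplyr::all_of(frac_cols), sum), .groups = "drop")
  ratio <- if (all(c("tpm_chromatin", "tpm_nucleoplasm") %in% frac_cols)) {
    nc_ratio(cytoplasmic = gene_expr$tpm_cytoplasmic,
             chromatin = gene_expr$tpm_chromatin,
             nucleoplasm = gene_expr$tpm_nucleoplasm)
  } else {
    nc_ratio(nuclear = gene_expr$tpm_nuclear,
             cytoplasmic = gene_expr$tpm_cytoplasmic)
  }
  classify_nuclear(tibble(gene_id = gene_expr$gene_id, nc_ratio = ratio),
                   threshold = threshold)
}
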