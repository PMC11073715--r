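#' Reassign A/B compartment signs by CAGE expression
#'
#' Per chromosome, the mean expression of CAGE peaks lying in positive-sign
#' (A) segments is compared to the mean in negative-sign (B) segments; when
#' the B mean exceeds the A mean all eigenvalue signs on that chromosome
#' are flipped. Labels are then A for positive and B for negative
#' eigenvalues; zero eigenvalues (including all-zero chromosomes) are
#' labeled `NA` and excluded from targeting. The operation is idempotent.
#'
#' @param eigs tibble with `chrom`, `start`, `end`, `eigenvalue` (1 Mb
#'   segments).
#' @param expr CAGE peak expression: tibble with `chrom`, `pos`, `value`.
#' @return tibble `chrom`, `start`, `end`, `eigenvalue`, `label` (the
#'   compartment map).
#' @export
reassign_compartments <- function(eigs, expr) {
  assert_cols(eigs, c("chrom", "start", "end", "eigenvalue"))
  assert_cols(expr, c("chrom", "pos", "value"))
  out <- eigs
  for (ch in unique(eigs$chrom)) {
    seg <- eigs[eigs$chrom == ch, ]
    if (all(seg$eigenvalue == 0)) next
    pk <- expr[expr$chrom == ch, ]
    if (nrow(pk) == 0) next
    si <- findInterval(pk$pos, sort(seg$start))
    seg_sorted <- seg[order(seg$start), ]
    sign_at <- sign(seg_sorted$eigenvalue)[si]
    mean_a <- mean(pk$value[sign_at > 0])
    mean_b <- mean(pk$value[sign_at < 0])
    if (!is.na(mean_a) && !is.na(mean_b) && mean_b > mean_a) {
      out$eigenvalue[out$chrom == ch] <- -out$eigenvalue[out$chrom == ch]
    }
  }
  out$label <- dplyr::case_when(out$eigenvalue > 0 ~ "A",
                                out$eigenvalue < 0 ~ "B",
                                TRUE ~ NA_character_)
  out
}

#' Merge contiguous same-label segments into compartment runs
#'
#' @param compartments tibble with `chrom`, `start`, `end`, `label`.
#' @return tibble `chrom`, `start`, `end`, `label`, one row per maximal run
#'   of contiguous same-label segments (NA labels dropped).
#' @export
compartment_runs <- function(compartments) {
  assert_cols(compartments, c("chrom", "start", "end", "label"))
  compartments |>
    filter(!is.na(.data$label)) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(new_run = .data$start != dplyr::lag(.data$end,
                                               default = dplyr::first(.data$start)) |
             .data$label != dplyr::lag(.data$label,
                                       default = dplyr::first(.data$label)),
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              label = .data$label[1], .groups = "drop") |>
    select("chrom", "start", "end", "label")
}

#' Compartment label at genomic positions
#'
#' Bins are assigned to the 1 Mb segment containing their midpoint.
#'
#' @param compartments labeled compartment map (see
#'   [reassign_compartments()]).
#' @param chrom,pos vectors of positions (e.g. bin midpoints).
#' @return character vector of labels (`NA` outside the map).
#' @export
compartment_label_at <- function(compartments, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    hit <- compartments$chrom == chrom[i] & compartments$start <= pos[i] &
      compartments$end > pos[i]
    if (any(hit)) compartments$label[which(hit)[1]] else NA_character_
  }, character(1))
}
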