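#' Remove nascent-transcription contacts
#'
#' Discards contacts whose RNA tag lies wholly within an intron of the gene
#' of origin, or whose DNA tag position overlaps the gene-of-origin's
#' genomic span. A tag spanning an exon-intron junction is retained (not
#' wholly intronic).
#'
#' @param contacts tibble with `gene_id`, `chrom_rna`, `start_rna`,
#'   `end_rna`, `chrom_dna`, `pos_dna`.
#' @param genes gene models: tibble with `gene_id`, `chrom`, `start`, `end`
#'   and list-columns `exon_starts`, `exon_ends`.
#' @return list with `contacts` (surviving rows) and `removed`, a named
#'   count per rule (`intronic_rna`, `own_gene_dna`).
#' @export
filter_nascent <- function(contacts, genes) {
  assert_cols(contacts, c("gene_id", "chrom_rna", "start_rna", "end_rna",
                          "chrom_dna", "pos_dna"))
  unknown <- setdiff(unique(contacts$gene_id), genes$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("contacts reference unknown gene_id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "lnct_unknown_gene")
  }
  gi <- match(contacts$gene_id, genes$gene_id)
  own_dna <- contacts$chrom_dna == genes$chrom[gi] &
    contacts$pos_dna >= genes$start[gi] & contacts$pos_dna < genes$end[gi]

  intronic <- logical(nrow(contacts))
  for (g in unique(contacts$gene_id)) {
    k <- which(contacts$gene_id == g)
    j <- match(g, genes$gene_id)
    intr <- introns_of(genes$exon_starts[[j]], genes$exon_ends[[j]])
    if (nrow(intr) == 0) next
    for (r in seq_len(nrow(intr))) {
      intronic[k] <- intronic[k] |
        (contacts$start_rna[k] >= intr$start[r] &
           contacts$end_rna[k] <= intr$end[r])
    }
  }
  drop <- intronic | own_dna
  list(contacts = contacts[!drop, , drop = FALSE],
       removed = c(intronic_rna = sum(intronic),
                   own_gene_dna = sum(own_dna & !intronic),
                   total = sum(drop)))
}

#' Aggregate contacts into fixed-width genomic bins
#'
#' Bin assignment is half-open: `bin_start = floor(pos / bin_size) *
#' bin_size` on the DNA-tag chromosome. Each contact is flagged cis when its
#' DNA tag chromosome equals the RNA (gene) chromosome.
#'
#' @param contacts surviving contact tibble (see [filter_nascent()]).
#' @param genes gene models (for the gene class annotation).
#' @param bin_size bin width, bp.
#' @return object of class `lnct_binned`: list with `counts` (tibble
#'   `gene_id`, `class`, `chrom`, `bin_start`, `bin`, `cis`, `reads`),
#'   `gene_totals` (tibble `gene_id`, `n`), and `bin_size`.
#' @export
bin_contacts <- function(contacts, genes, bin_size = 10000) {
  assert_cols(contacts, c("gene_id", "chrom_rna", "chrom_dna", "pos_dna"))
  counts <- contacts |>
    mutate(bin_start = pos_to_bin(.data$pos_dna, bin_size),
           cis = .data$chrom_dna == .data$chrom_rna) |>
    count(.data$gene_id, chrom = .data$chrom_dna, .data$bin_start,
          .data$cis, name = "reads") |>
    mutate(bin = bin_key(.data$chrom, .data$bin_start)) |>
    left_join(genes[, c("gene_id", "class")], by = "gene_id")
  gene_totals <- counts |>
    group_by(.data$gene_id) |>
    summarise(n = sum(.data$reads), .groups = "drop")
  structure(list(counts = counts, gene_totals = gene_totals,
                 bin_size = bin_size),
            class = "lnct_binned")
}

#' Estimate the per-bin background probability from trans-mRNA contacts
#'
#' The background probability of a bin is the count of trans mRNA contacts
#' in that bin divided by the total number of trans mRNA contacts. Bins
#' with zero trans coverage get probability 0 and are excluded from testing.
#'
#' @param binned an [bin_contacts()] object.
#' @return object of class `lnct_background`: tibble `bin`, `p` plus
#'   attribute `total_trans_mrna`.
#' @export
estimate_background <- function(binned) {
  stopifnot(inherits(binned, "lnct_binned"))
  trans_mrna <- binned$counts |>
    filter(.data$class == "mRNA", !.data$cis)
  total <- sum(trans_mrna$reads)
  if (total == 0) {
    abort("no trans mRNA contacts; background unestimable",
          class = "lnct_no_background")
  }
  bg <- trans_mrna |>
    group_by(.data$bin) |>
    summarise(p = sum(.data$reads) / total, .groups = "drop")
  structure(bg, class = c("lnct_background", class(bg)),
            total_trans_mrna = total)
}

#' Call significant RNA-chromatin interactions (iterative binomial test)
#'
#' Per gene, each bin with background support is tested with a one-sided
#' (upper-tail) exact binomial test of its read count `x` against `n` (the
#' gene's remaining reads) and the bin's background probability `p`.
#' P-values are Benjamini-Hochberg adjusted across the gene's currently
#' tested bins; bins reaching `fdr <= fdr_cut` are moved to the significant
#' set and their reads subtracted from `n`. This repeats until an iteration
#' adds no interaction. The final set is filtered to bins supported by at
#' least `min_reads` reads. This iterative subtraction damps the influence
#' of a few very hot windows (typically near the gene of origin) on the
#' rest of the distribution.
#'
#' @param binned an [bin_contacts()] object.
#' @param background an [estimate_background()] object.
#' @param fdr_cut per-iteration FDR threshold.
#' @param min_reads minimal read support in the final set.
#' @param scope `"intra"` (cis bins only), `"inter"` (trans only) or
#'   `"both"`.
#' @return tibble `gene_id`, `chrom`, `bin_start`, `bin`, `reads`,
#'   `p_value`, `fdr`, `iteration`, `cis`.
#' @export
iterative_binomial_caller <- function(binned, background, fdr_cut = 0.01,
                                      min_reads = 3,
                                      scope = c("intra", "inter", "both")) {
  stopifnot(inherits(binned, "lnct_binned"))
  scope <- match.arg(scope)
  counts <- binned$counts |>
    left_join(as_tibble(background)[, c("bin", "p")], by = "bin") |>
    mutate(p = dplyr::coalesce(.data$p, 0))

  res <- lapply(split(counts, counts$gene_id), function(df) {
    n <- sum(df$reads)            # all remaining reads of the gene
    test <- df
    if (scope == "intra") test <- test[test$cis, , drop = FALSE]
    if (scope == "inter") test <- test[!test$cis, , drop = FALSE]
    test <- test[test$p > 0, , drop = FALSE]  # p_b = 0 bins are untestable
    if (nrow(test) == 0 || n == 0) return(NULL)

    sig <- NULL
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (nrow(test) == 0 || n <= 0) break
      pv <- pbinom(test$reads - 1, n, test$p, lower.tail = FALSE)
      fdr <- p.adjust(pv, method = "BH")
      hit <- fdr <= fdr_cut
      if (!any(hit)) break
      found <- test[hit, , drop = FALSE]
      found$p_value <- pv[hit]
      found$fdr <- fdr[hit]
      found$iteration <- iter
      sig <- bind_rows(sig, found)
      n <- n - sum(found$reads)
      test <- test[!hit, , drop = FALSE]
    }
    sig
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(0), chrom = character(0),
                  bin_start = numeric(0), bin = character(0),
                  reads = integer(0), p_value = numeric(0),
                  fdr = numeric(0), iteration = integer(0),
                  cis = logical(0)))
  }
  out |>
    filter(.data$reads >= min_reads) |>
    select("gene_id", "chrom", "bin_start", "bin", "reads",
           "p_value", "fdr", "iteration", "cis") |>
    arrange(.data$gene_id, .data$chrom, .data$bin_start)
}

#' Annotate significant bins with the genes whose strongest promoter they hold
#'
#' Each significant bin is paired with every strongest promoter whose
#' position falls inside the bin; when promoters of several genes share a
#' bin, one pair is emitted per gene. Bins without promoters yield no pair
#' but remain part of the interaction set.
#'
#' @param sig output of [iterative_binomial_caller()].
#' @param promoters tibble of strongest promoters: `promoter_id`,
#'   `gene_id`, `chrom`, `pos`.
#' @param bin_size bin width, bp.
#' @return tibble of (lncRNA/gene, target gene) pairs: `gene_id`, `bin`,
#'   `target_gene`, `target_promoter`.
#' @export
annotate_interactions <- function(sig, promoters, bin_size = 10000) {
  assert_cols(promoters, c("promoter_id", "gene_id", "chrom", "pos"))
  prom <- promoters |>
    mutate(bin = bin_key(.data$chrom, pos_to_bin(.data$pos, bin_size))) |>
    select(target_gene = "gene_id", target_promoter = "promoter_id", "bin")
  sig |>
    select("gene_id", "bin") |>
    inner_join(prom, by = "bin", relationship = "many-to-many")
}
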