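#' Compile a degenerate DNA pattern with bracketed alternatives
#'
#' Patterns are strings over `A`, `C`, `G`, `T` where a bracket group such
#' as `[CT]` denotes a single position allowing either base (as in the
#' SIRLOIN representative motif). Ambiguity codes outside brackets are
#' rejected.
#'
#' @param pattern character scalar.
#' @return object of class `lnct_pattern`: list with `sets` (list of
#'   allowed-base character vectors per position) and `iupac` (equivalent
#'   IUPAC string).
#' @export
compile_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) > 0)
  chars <- strsplit(pattern, "")[[1]]
  sets <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j) || j == i + 1) abort("malformed bracket group in pattern")
      grp <- unique(chars[(i + 1):(j - 1)])
      if (!all(grp %in% c("A", "C", "G", "T"))) {
        abort("bracket groups may only contain A, C, G, T")
      }
      sets[[length(sets) + 1]] <- sort(grp)
      i <- j + 1
    } else {
      if (!ch %in% c("A", "C", "G", "T")) {
        abort(sprintf("invalid pattern character '%s'", ch))
      }
      sets[[length(sets) + 1]] <- ch
      i <- i + 1
    }
  }
  iupac_map <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                        Biostrings::IUPAC_CODE_MAP)
  iupac <- vapply(sets, function(s) {
    iupac_map[[paste(sort(s), collapse = "")]]
  }, character(1))
  structure(list(sets = sets, iupac = paste(iupac, collapse = "")),
            class = "lnct_pattern")
}

#' U1 and SIRLOIN representative motifs
#'
#' Sequence elements associated with nuclear retention of transcripts,
#' searchable with [search_motif()].
#' @export
U1_MOTIF <- "CAGGTGAGT"

#' @rdname U1_MOTIF
#' @export
SIRLOIN_MOTIF <- paste0("[CT][GA]CCTCCC[GA][GA]GTTCAAG[CT]GAT[TC]CTCCT",
                        "[GA]CCTCAGCCTCCCGA")

#' Count degenerate motif matches in sequences
#'
#' Counts (possibly overlapping) exact degenerate matches on the given
#' strand of each sequence.
#'
#' @param seqs named character vector of DNA sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param pattern a pattern string or [compile_pattern()] object.
#' @param overlap count overlapping matches (default, fuzznuc-compatible).
#' @return named integer vector of match counts per sequence.
#' @export
search_motif <- function(seqs, pattern, overlap = TRUE) {
  if (!inherits(pattern, "lnct_pattern")) pattern <- compile_pattern(pattern)
  if (is.character(seqs)) {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      abort(sprintf("sequence(s) with invalid characters: %s",
                    paste(head(names(seqs)[bad] %||% which(bad), 5),
                          collapse = ", ")))
    }
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  counts <- Biostrings::vcountPattern(pattern$iupac, seqs, fixed = FALSE)
  if (!overlap) {
    ## non-overlapping greedy left-to-right count
    counts <- vapply(seq_along(seqs), function(i) {
      m <- Biostrings::matchPattern(pattern$iupac, seqs[[i]], fixed = FALSE)
      st <- Biostrings::start(m)
      en <- Biostrings::end(m)
      taken <- 0L
      last_end <- 0L
      for (j in seq_along(st)) {
        if (st[j] > last_end) {
          taken <- taken + 1L
          last_end <- en[j]
        }
      }
      taken
    }, integer(1))
  }
  setNames(as.integer(counts), names(seqs))
}

#' Enrichment of motif-bearing lncRNAs among nuclear lncRNAs
#'
#' Tabulates {nuclear, not} x {motif-bearing (count >= 1), not} and applies
#' a right-tailed Fisher test.
#'
#' @param counts named integer vector of motif counts per lncRNA gene.
#' @param nuclear classification tibble (`gene_id`, `is_nuclear`).
#' @return one-row [fisher_exact()] result.
#' @export
motif_nuclear_enrichment <- function(counts, nuclear) {
  assert_cols(nuclear, c("gene_id", "is_nuclear"))
  nuc <- nuclear$gene_id[nuclear$is_nuclear]
  non <- nuclear$gene_id[!nuclear$is_nuclear]
  bearing <- names(counts)[counts >= 1]
  fisher_exact(length(intersect(nuc, bearing)),
               length(setdiff(nuc, bearing)),
               length(intersect(non, bearing)),
               length(setdiff(non, bearing)), side = "right")
}

#' Assign TFBS motifs to promoter/enhancer regions by aggregate posterior
#'
#' Sites are intersected with regions extended by `pad` on both sides
#' (any nonzero overlap counts); per (region, motif) the posterior scores
#' of overlapping sites are summed, and the motif is assigned when the
#' aggregate reaches `min_score`. Motifs whose sites overlap fewer than
#' `min_regions` regions are excluded entirely.
#'
#' @param sites tibble `chrom`, `start`, `end`, `motif`, `posterior`.
#' @param regions tibble `region_id`, `chrom`, `start`, `end`.
#' @param pad region extension, bp.
#' @param min_score inclusive aggregate-score threshold.
#' @param min_regions minimal overlapped-region count per retained motif.
#' @return tibble `region_id`, `motif`, `score`, `assigned`.
#' @export
assign_tfbs <- function(sites, regions, pad = 250, min_score = 0.1,
                        min_regions = 200) {
  assert_cols(sites, c("chrom", "start", "end", "motif", "posterior"))
  assert_cols(regions, c("region_id", "chrom", "start", "end"))
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    return(tibble(region_id = character(0), motif = character(0),
                  score = numeric(0), assigned = logical(0)))
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1, sites$end))
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(regions$start - pad, 0) + 1, regions$end + pad))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_regions)
  ov <- tibble(motif = sites$motif[S4Vectors::queryHits(hits)],
               posterior = sites$posterior[S4Vectors::queryHits(hits)],
               region_id = regions$region_id[S4Vectors::subjectHits(hits)])
  agg <- ov |>
    group_by(.data$region_id, .data$motif) |>
    summarise(score = sum(.data$posterior), .groups = "drop") |>
    mutate(assigned = .data$score >= min_score)
  coverage <- agg |> count(.data$motif, name = "n_regions")
  keep <- coverage$motif[coverage$n_regions >= min_regions]
  agg |>
    filter(.data$motif %in% keep) |>
    arrange(.data$region_id, .data$motif)
}
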