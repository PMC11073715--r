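#' Generate a synthetic genome with planted lncRNA regulatory structure
#'
#' Builds the ground-truth "world" that every other simulator draws from:
#' chromosomes tiled into 10 kb bins, 1 Mb A/B compartment segments, gene
#' models (mRNAs and lncRNAs) with alternating exon/intron blocks and 1-3
#' promoters each, a set of planted nuclear lncRNAs, and for each of those a
#' set of planted target bins (bins holding mRNA promoters inside the same
#' A/B compartment run as the lncRNA promoter).
#'
#' The emitted compartment eigenvalues are deliberately sign-flipped on
#' even-numbered chromosomes, so the expression-based sign reassignment of
#' [reassign_compartments()] is exercised: the true labels are stored in
#' `world$compartments$label_true`.
#'
#' All randomness flows from `seed` through per-table RNG streams
#' ([derive_seed()]); calling any generator twice with the same seed yields
#' identical output.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (all chromosomes equal).
#' @param bin_size genomic bin width, bp.
#' @param compartment_size A/B compartment segment size, bp.
#' @param n_mrna,n_lncrna gene counts per class.
#' @param n_nuclear number of lncRNAs to plant as nuclear with target bins.
#' @param n_targets_per_lnc planted target bins per nuclear lncRNA.
#' @param n_enhancers number of bidirectional enhancers.
#' @param seed master integer seed.
#' @return an object of class `lnct_world`.
#' @export
generate_world <- function(n_chrom = 2, chrom_len = 5e6, bin_size = 10000,
                           compartment_size = 1e6, n_mrna = 200,
                           n_lncrna = 20, n_nuclear = 6,
                           n_targets_per_lnc = 8, n_enhancers = 60,
                           seed = 1) {
  if (n_chrom < 1 || n_mrna < 1 || n_lncrna < 1 || bin_size <= 0 ||
      chrom_len <= 0 || compartment_size <= 0) {
    abort("gene counts and sizes must be positive", class = "lnct_config_error")
  }
  if (chrom_len < 10 * bin_size) {
    abort("chrom_len must be at least 10 * bin_size",
          class = "lnct_config_error")
  }

  with_table_seed(seed, "world", {
    chromosomes <- tibble(chrom = paste0("chr", seq_len(n_chrom)),
                          length = as.numeric(chrom_len))

    ## A/B compartment truth: 1 Mb segments, sign runs of length 2.
    compartments <- purrr::pmap_dfr(chromosomes, function(chrom, length) {
      starts <- seq(0, length - 1, by = compartment_size)
      n_seg <- length(starts)
      signs <- rep(rep(c(1, -1), each = 2), length.out = n_seg)
      tibble(chrom = chrom, start = starts,
             end = pmin(starts + compartment_size, length),
             eigen_true = signs * runif(n_seg, 0.3, 1.5))
    })
    compartments$label_true <- ifelse(compartments$eigen_true > 0, "A", "B")
    ## Emitted eigenvalues are mis-signed on even chromosomes.
    flip <- as.integer(sub("chr", "", compartments$chrom)) %% 2 == 0
    compartments$eigenvalue <- ifelse(flip, -compartments$eigen_true,
                                      compartments$eigen_true)

    ## Gene models with alternating exon/intron blocks (>= 300 bp each).
    n_genes <- n_mrna + n_lncrna
    gene_class <- c(rep("mRNA", n_mrna), rep("lncRNA", n_lncrna))
    gene_id <- c(sprintf("MRNA%04d", seq_len(n_mrna)),
                 sprintf("LNC%04d", seq_len(n_lncrna)))
    gchrom <- sample(chromosomes$chrom, n_genes, replace = TRUE)
    glen <- sample(10000:40000, n_genes, replace = TRUE)
    gstart <- floor(runif(n_genes, 0, chrom_len - glen))
    gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
    n_exons <- sample(2:4, n_genes, replace = TRUE)

    blocks <- purrr::map2(glen, n_exons, function(len, ne) {
      nb <- 2 * ne - 1
      extra <- len - nb * 300
      props <- runif(nb)
      widths <- 300 + floor(extra * props / sum(props))
      widths[nb] <- widths[nb] + (len - sum(widths))
      bounds <- cumsum(c(0, widths))
      list(starts = bounds[seq(1, nb, by = 2)],
           ends = bounds[seq(1, nb, by = 2) + 1])
    })

    seg_of <- function(chrom, pos) {
      i <- match(paste0(chrom, ":", floor(pos / compartment_size)),
                 paste0(compartments$chrom, ":",
                        compartments$start / compartment_size))
      i
    }
    in_A <- vapply(seq_len(n_genes), function(i) {
      compartments$label_true[seg_of(gchrom[i], gstart[i])] == "A"
    }, logical(1))

    genes <- tibble(
      gene_id = gene_id, class = gene_class, chrom = gchrom,
      start = gstart, end = gstart + glen, strand = gstrand,
      n_exons = n_exons,
      exon_starts = purrr::map2(blocks, gstart, ~ .x$starts + .y),
      exon_ends = purrr::map2(blocks, gstart, ~ .x$ends + .y),
      in_A = in_A,
      base_expr = exp(rnorm(n_genes, log(30), 0.6)) * ifelse(in_A, 3, 1),
      nuclear_share = NA_real_
    )
    genes$nuclear_share[genes$class == "mRNA"] <-
      runif(n_mrna, 0.1, 0.45)
    genes$nuclear_share[genes$class == "lncRNA"] <-
      runif(n_lncrna, 0.15, 0.8)

    ## Promoters: 1-3 per gene; rank 1 (at the TSS) is the designated
    ## strongest and receives a 5x expression margin.
    promoters <- purrr::pmap_dfr(
      genes[, c("gene_id", "chrom", "start", "end", "strand")],
      function(gene_id, chrom, start, end, strand) {
        np <- sample(1:3, 1)
        offs <- c(0, sort(sample(500:4000, np - 1)))
        pos <- if (strand == "+") start + offs else (end - 1) - offs
        tibble(promoter_id = sprintf("%s_p%d", gene_id, seq_len(np)),
               gene_id = gene_id, chrom = chrom, pos = pos,
               rank = seq_len(np),
               expr_scale = c(1, runif(np - 1, 0.02, 0.15)))
      })

    ## Plant nuclear lncRNAs inside A runs with enough mRNA promoters around.
    runs <- compartment_runs(
      compartments[, c("chrom", "start", "end")] |>
        mutate(label = compartments$label_true))
    main_prom <- promoters[promoters$rank == 1, ]
    mrna_prom <- main_prom[grepl("^MRNA", main_prom$gene_id), ]
    mrna_prom$bin <- bin_key(mrna_prom$chrom,
                             pos_to_bin(mrna_prom$pos, bin_size))

    lnc_ids <- genes$gene_id[genes$class == "lncRNA"]
    candidates <- list()
    for (id in lnc_ids) {
      g <- genes[genes$gene_id == id, ]
      pp <- main_prom[main_prom$gene_id == id, ]
      run <- runs[runs$chrom == pp$chrom & runs$start <= pp$pos &
                    runs$end > pp$pos & runs$label == "A", ]
      if (nrow(run) != 1) next
      own_bin <- bin_key(pp$chrom, pos_to_bin(pp$pos, bin_size))
      cand <- mrna_prom[mrna_prom$chrom == pp$chrom &
                          mrna_prom$pos >= run$start &
                          mrna_prom$pos < run$end, ]
      ## exclude bins overlapping the lncRNA gene body or its promoter bin
      bs <- as.numeric(sub(".*:", "", cand$bin))
      keep <- cand$bin != own_bin &
        !(bs < g$end & bs + bin_size > g$start)
      cand <- cand[keep, ]
      if (length(unique(cand$bin)) >= max(5, floor(n_targets_per_lnc / 2))) {
        candidates[[id]] <- unique(cand$bin)
      }
    }
    planted_nuclear <- head(names(candidates), n_nuclear)
    planted_target_bins <- lapply(candidates[planted_nuclear], function(b) {
      sample(b, min(n_targets_per_lnc, length(b)))
    })
    planted_target_genes <- lapply(planted_target_bins, function(bins) {
      sort(unique(mrna_prom$gene_id[mrna_prom$bin %in% bins]))
    })
    genes$nuclear_share[match(planted_nuclear, genes$gene_id)] <-
      runif(length(planted_nuclear), 0.7, 0.9)

    ## Enhancers: ~1/3 placed inside planted target bins, rest uniform.
    target_bin_pool <- unique(unlist(planted_target_bins))
    n_in_targets <- min(length(target_bin_pool), floor(n_enhancers / 3))
    enh_bins <- if (n_in_targets > 0) {
      sample(target_bin_pool, n_in_targets)
    } else character(0)
    enh_in <- tibble(
      chrom = sub(":.*", "", enh_bins),
      start = as.numeric(sub(".*:", "", enh_bins)) +
        sample(0:(bin_size - 401), length(enh_bins), replace = TRUE))
    n_rand <- n_enhancers - nrow(enh_in)
    enh_rand <- tibble(
      chrom = sample(chromosomes$chrom, n_rand, replace = TRUE),
      start = floor(runif(n_rand, 0, chrom_len - 400)))
    enhancers <- bind_rows(enh_in, enh_rand) |>
      mutate(end = .data$start + 400,
             enhancer_id = sprintf("ENH%03d", dplyr::row_number()))

    structure(list(
      chromosomes = chromosomes, bin_size = bin_size,
      compartment_size = compartment_size,
      genes = genes, promoters = promoters, enhancers = enhancers,
      compartments = compartments,
      planted_nuclear = planted_nuclear,
      planted_target_bins = planted_target_bins,
      planted_target_genes = planted_target_genes,
      rng_seed = seed
    ), class = "lnct_world")
  })
}

#' @export
print.lnct_world <- function(x, ...) {
  cat("<lnct_world>", nrow(x$chromosomes), "chromosomes,",
      nrow(x$genes), "genes (", sum(x$genes$class == "lncRNA"), "lncRNA ),",
      length(x$planted_nuclear), "planted nuclear lncRNAs, seed",
      x$rng_seed, "\n")
  invisible(x)
}

#' Intron intervals of a gene model
#'
#' @param exon_starts,exon_ends numeric vectors of exon block coordinates
#'   (0-based half-open), in increasing order.
#' @return tibble with `start`, `end` of each intron (may be empty).
#' @export
introns_of <- function(exon_starts, exon_ends) {
  ne <- length(exon_starts)
  if (ne < 2) return(tibble(start = numeric(0), end = numeric(0)))
  tibble(start = exon_ends[-ne], end = exon_starts[-1])
}
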