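#' Simulate RNA-chromatin contacts with planted local enrichment
#'
#' Every gene emits mature contacts whose DNA tags are uniform over all
#' genomic bins (Poisson `background_rate` reads per bin); for a planted
#' nuclear lncRNA the rate in its planted target bins is
#' `enrichment_fold * background_rate` instead, so the expected planted-bin
#' count is `enrichment_fold * background_rate` independent of the other
#' parameters. Nascent-like contacts are then added on top so that they
#' make up a `nascent_frac` share of the gene's total in expectation: the
#' RNA tag placed wholly inside an intron, or the DNA tag inside the
#' gene-of-origin body, so the nascent filter is exercisable. Mature
#' contacts carry exonic RNA tags and DNA tags outside the gene of origin.
#'
#' @param world an [generate_world()] object.
#' @param background_rate expected background reads per (gene, bin).
#' @param enrichment_fold rate multiplier in planted target bins (>= 1;
#'   1 means no enrichment).
#' @param nascent_frac expected proportion of contacts flagged nascent.
#' @return tibble with columns `gene_id`, `chrom_rna`, `start_rna`,
#'   `end_rna`, `chrom_dna`, `pos_dna`, and a ground-truth `nascent` flag.
#' @export
simulate_contacts <- function(world, background_rate = 0.5,
                              enrichment_fold = 20, nascent_frac = 0.15) {
  stopifnot(inherits(world, "lnct_world"))
  if (background_rate <= 0) abort("background_rate must be > 0",
                                  class = "lnct_config_error")
  if (enrichment_fold < 1) abort("enrichment_fold must be >= 1",
                                 class = "lnct_config_error")
  if (nascent_frac < 0 || nascent_frac >= 1) {
    abort("nascent_frac must be in [0, 1)", class = "lnct_config_error")
  }
  if (!any(world$genes$class == "mRNA")) {
    abort("world has no mRNA genes; trans background would be unestimable",
          class = "lnct_config_error")
  }

  bins <- tile_bins(world$chromosomes, world$bin_size)
  with_table_seed(world$rng_seed, "contacts", {
    rows <- purrr::pmap(world$genes, function(gene_id, chrom, start, end,
                                              exon_starts, exon_ends, ...) {
      rate <- rep(background_rate, nrow(bins))
      planted <- world$planted_target_bins[[gene_id]]
      if (!is.null(planted)) {
        rate[match(planted, bins$bin)] <- enrichment_fold * background_rate
      }
      counts <- rpois(nrow(bins), rate)
      idx <- rep.int(seq_len(nrow(bins)), counts)
      m <- length(idx)
      if (m == 0) return(NULL)
      dna_chrom <- bins$chrom[idx]
      dna_pos <- bins$bin_start[idx] +
        floor(runif(m, 0, bins$bin_end[idx] - bins$bin_start[idx]))
      ## resample DNA tags landing in the gene of origin (not nascent here);
      ## the bin is redrawn too, since a bin wholly inside the gene body
      ## could never escape it
      bad <- which(dna_chrom == chrom & dna_pos >= start & dna_pos < end)
      while (length(bad) > 0) {
        idx[bad] <- sample.int(nrow(bins), length(bad), replace = TRUE)
        dna_chrom[bad] <- bins$chrom[idx[bad]]
        dna_pos[bad] <- bins$bin_start[idx[bad]] +
          floor(runif(length(bad), 0,
                      bins$bin_end[idx[bad]] - bins$bin_start[idx[bad]]))
        bad <- bad[dna_chrom[bad] == chrom & dna_pos[bad] >= start &
                     dna_pos[bad] < end]
      }
      ## exonic 30 bp RNA tags for the mature contacts
      ex <- sample.int(length(exon_starts), m, replace = TRUE)
      rna_start <- floor(exon_starts[ex] +
                           runif(m) * (exon_ends[ex] - exon_starts[ex] - 30))
      mature <- tibble(gene_id = gene_id, chrom_rna = chrom,
                       start_rna = rna_start, end_rna = rna_start + 30,
                       chrom_dna = dna_chrom, pos_dna = dna_pos,
                       nascent = FALSE)
      ## nascent contacts are extra reads on top of the mature signal
      n_nasc <- if (nascent_frac > 0) {
        rpois(1, m * nascent_frac / (1 - nascent_frac))
      } else 0L
      if (n_nasc == 0) return(mature)
      introns <- introns_of(exon_starts, exon_ends)
      intronic <- runif(n_nasc) < 0.5 & nrow(introns) > 0
      n_rna <- floor(exon_starts[1] + runif(n_nasc) *
                       (exon_ends[1] - exon_starts[1] - 30))
      n_idx <- sample.int(nrow(bins), n_nasc, replace = TRUE)
      n_chrom <- bins$chrom[n_idx]
      n_pos <- bins$bin_start[n_idx] +
        floor(runif(n_nasc, 0, bins$bin_end[n_idx] - bins$bin_start[n_idx]))
      wi <- which(intronic)     # intronic RNA tag, DNA tag anywhere
      if (length(wi) > 0) {
        ii <- sample.int(nrow(introns), length(wi), replace = TRUE)
        n_rna[wi] <- floor(introns$start[ii] + runif(length(wi)) *
                             (introns$end[ii] - introns$start[ii] - 30))
      }
      wd <- which(!intronic)    # exonic RNA tag, DNA tag in own gene body
      if (length(wd) > 0) {
        n_chrom[wd] <- chrom
        n_pos[wd] <- floor(runif(length(wd), start, end))
      }
      bind_rows(mature,
                tibble(gene_id = gene_id, chrom_rna = chrom,
                       start_rna = n_rna, end_rna = n_rna + 30,
                       chrom_dna = n_chrom, pos_dna = n_pos,
                       nascent = TRUE))
    })
    bind_rows(rows)
  })
}

#' Simulate a filtered-Hi-C interaction table with a planted scaffold
#'
#' A scaffold of significant edges guarantees that every planted target bin
#' of every planted nuclear lncRNA is within two graph hops of the lncRNA's
#' promoter bin: roughly half the planted bins get a direct edge to the
#' promoter bin, and the rest attach to one of those direct neighbours.
#' Random local edges (bins up to 30 apart on a chromosome) are added with
#' probability `p_neighbor`; each non-scaffold edge is made to fail the
#' significance filter (read pairs < 5 or q > 0.05) with probability
#' `q_noise`.
#'
#' @param world an [generate_world()] object.
#' @param p_neighbor probability of a random local edge.
#' @param q_noise probability that a random edge fails the filter.
#' @return tibble `chrom`, `bin_i_start`, `bin_j_start`, `read_pairs`,
#'   `q_value` plus a ground-truth `scaffold` flag.
#' @export
simulate_hic <- function(world, p_neighbor = 0.02, q_noise = 0.05) {
  stopifnot(inherits(world, "lnct_world"))
  if (p_neighbor < 0 || p_neighbor > 1 || q_noise < 0 || q_noise > 1) {
    abort("p_neighbor and q_noise must be probabilities",
          class = "lnct_config_error")
  }
  bs <- world$bin_size
  main_prom <- world$promoters[world$promoters$rank == 1, ]

  with_table_seed(world$rng_seed, "hic", {
    scaffold <- purrr::map_dfr(world$planted_nuclear, function(id) {
      pp <- main_prom[main_prom$gene_id == id, ]
      pbin <- pos_to_bin(pp$pos, bs)
      tbins <- as.numeric(sub(".*:", "",
                              world$planted_target_bins[[id]]))
      k <- length(tbins)
      n_direct <- ceiling(k / 2)
      direct <- tbins[seq_len(n_direct)]
      second <- if (k > n_direct) tbins[(n_direct + 1):k] else numeric(0)
      via <- if (length(second) > 0) {
        direct[sample.int(n_direct, length(second), replace = TRUE)]
      } else numeric(0)
      tibble(chrom = pp$chrom,
             bin_i_start = c(rep(pbin, n_direct), via),
             bin_j_start = c(direct, second))
    })
    scaffold <- scaffold |>
      mutate(read_pairs = 5L + rpois(n(), 20),
             q_value = runif(n(), 0, 0.049),
             scaffold = TRUE)

    random <- purrr::pmap_dfr(world$chromosomes, function(chrom, length) {
      n_bins <- ceiling(length / bs)
      pairs <- purrr::map_dfr(1:30, function(d) {
        i <- seq_len(n_bins - d) - 1L
        tibble(chrom = chrom, bin_i_start = i * bs, bin_j_start = (i + d) * bs)
      })
      pairs[runif(nrow(pairs)) < p_neighbor, ]
    })
    if (nrow(random) > 0) {
      fail <- runif(nrow(random)) < q_noise
      fail_mode <- runif(nrow(random)) < 0.5  # low count vs high q
      random <- random |>
        mutate(read_pairs = ifelse(fail & fail_mode,
                                   sample(1:4, n(), replace = TRUE),
                                   5L + rpois(n(), 15)),
               q_value = ifelse(fail & !fail_mode,
                                runif(n(), 0.051, 1),
                                runif(n(), 0, 0.049)),
               scaffold = FALSE)
    }
    bind_rows(scaffold, random) |>
      mutate(lo = pmin(.data$bin_i_start, .data$bin_j_start),
             hi = pmax(.data$bin_i_start, .data$bin_j_start)) |>
      arrange(.data$chrom, .data$lo, .data$hi, dplyr::desc(.data$scaffold)) |>
      distinct(.data$chrom, .data$lo, .data$hi, .keep_all = TRUE) |>
      mutate(bin_i_start = .data$lo, bin_j_start = .data$hi) |>
      select(-"lo", -"hi")
  })
}

#' Simulate knockdown differential-expression tables (two ASOs per lncRNA)
#'
#' For each planted nuclear lncRNA, a `frac_responsive` share of its planted
#' target genes is differentially expressed with the lncRNA's planted sign
#' in both antisense-oligo (ASO) knockdowns; all other genes are DE at a
#' small background rate in a random direction.
#'
#' @param world an [generate_world()] object.
#' @param effect_direction +1 (targets go up on knockdown) or -1, either a
#'   scalar or a named vector per planted lncRNA.
#' @param frac_responsive share of planted target genes that respond.
#' @param background_de_rate DE rate among non-target genes.
#' @return tibble `lncrna`, `aso`, `gene_id`, `log2fc`, `fdr`.
#' @export
simulate_knockdown_de <- function(world, effect_direction = 1,
                                  frac_responsive = 0.8,
                                  background_de_rate = 0.02) {
  stopifnot(inherits(world, "lnct_world"))
  if (frac_responsive < 0 || frac_responsive > 1) {
    abort("frac_responsive must be in [0, 1]", class = "lnct_config_error")
  }
  lncs <- world$planted_nuclear
  dirs <- if (length(effect_direction) == 1) {
    setNames(rep(effect_direction, length(lncs)), lncs)
  } else effect_direction[lncs]

  with_table_seed(world$rng_seed, "knockdown_de", {
    purrr::map_dfr(lncs, function(id) {
      targets <- world$planted_target_genes[[id]]
      n_resp <- round(frac_responsive * length(targets))
      resp <- if (n_resp > 0) sample(targets, n_resp) else character(0)
      purrr::map_dfr(c("ASO1", "ASO2"), function(aso) {
        g <- world$genes$gene_id
        is_resp <- g %in% resp
        bg_de <- !is_resp & runif(length(g)) < background_de_rate
        log2fc <- rnorm(length(g), 0, 0.2)
        fdr <- runif(length(g), 0.3, 1)
        log2fc[is_resp] <- dirs[id] * (1.2 + abs(rnorm(sum(is_resp), 0, 0.3)))
        fdr[is_resp] <- runif(sum(is_resp), 0, 0.05)
        log2fc[bg_de] <- sample(c(-1, 1), sum(bg_de), replace = TRUE) *
          (1 + abs(rnorm(sum(bg_de), 0, 0.3)))
        fdr[bg_de] <- runif(sum(bg_de), 0, 0.08)
        tibble(lncrna = id, aso = aso, gene_id = g,
               log2fc = log2fc, fdr = fdr)
      })
    })
  })
}

#' Simulate CAGE-like tag counts for promoters and enhancers
#'
#' Counts are Poisson around each gene's expression level, split across
#' subcellular fractions by the gene's nuclear share, with the rank-1
#' promoter carrying a large margin so it is recoverable as the strongest.
#'
#' @param world an [generate_world()] object.
#' @param fractions subcellular fractions to emit.
#' @param n_libs libraries per fraction.
#' @return list of two wide tibbles, `promoters` (promoter_id, gene_id, one
#'   column per `<fraction>_<lib>`) and `enhancers` (enhancer_id + library
#'   columns).
#' @export
simulate_expression <- function(world,
                                fractions = c("nuclear", "cytoplasmic"),
                                n_libs = 2) {
  stopifnot(inherits(world, "lnct_world"))
  with_table_seed(world$rng_seed, "expression", {
    pm <- world$promoters |>
      left_join(world$genes[, c("gene_id", "base_expr", "nuclear_share")],
                by = "gene_id")
    out <- pm[, c("promoter_id", "gene_id")]
    for (fr in fractions) {
      share <- switch(fr,
                      nuclear = pm$nuclear_share,
                      chromatin = pm$nuclear_share,
                      nucleoplasm = pm$nuclear_share,
                      cytoplasmic = 1 - pm$nuclear_share,
                      rep(0.5, nrow(pm)))
      for (lib in seq_len(n_libs)) {
        lam <- pm$base_expr * pm$expr_scale * share * runif(1, 0.8, 1.2)
        out[[paste0(fr, "_", lib)]] <- rpois(nrow(pm), lam)
      }
    }
    enh <- world$enhancers[, "enhancer_id"]
    for (lib in seq_len(2)) {
      enh[[paste0("lib_", lib)]] <-
        rpois(nrow(enh), exp(rnorm(nrow(enh), log(4), 0.8)))
    }
    list(promoters = out, enhancers = enh)
  })
}

#' Simulate gene-level eCLIP statistics for a panel of RBPs
#'
#' Half of the RBPs are "broad binders" that bind most lncRNAs (including
#' all planted nuclear ones) and survive the >= 15 lncRNA-target filter;
#' the rest bind few lncRNAs and should be dropped by it.
#'
#' @param world an [generate_world()] object.
#' @param n_rbp number of RBPs (>= 2).
#' @return list: `stats` tibble (`rbp`, `gene_id`, `log2fc`, `fdr`) and
#'   `bound` named list of ground-truth bound gene sets per RBP.
#' @export
simulate_eclip <- function(world, n_rbp = 6) {
  stopifnot(inherits(world, "lnct_world"), n_rbp >= 2)
  with_table_seed(world$rng_seed, "eclip", {
    rbps <- sprintf("RBP%02d", seq_len(n_rbp))
    broad <- rbps[seq_len(ceiling(n_rbp / 2))]
    lncs <- world$genes$gene_id[world$genes$class == "lncRNA"]
    mrnas <- world$genes$gene_id[world$genes$class == "mRNA"]
    ## broad RBPs bind every planted nuclear lncRNA plus most other
    ## lncRNAs, but a few lncRNAs stay unbound by every RBP so the
    ## bound-vs-unbound N/C comparison has both groups
    n_unbound <- max(2, floor(length(lncs) * 0.15))
    never_bound <- sample(setdiff(lncs, world$planted_nuclear), n_unbound)
    bound <- lapply(rbps, function(r) {
      p_lnc <- if (r %in% broad) 0.8 else 0.15
      pool <- setdiff(lncs, never_bound)
      bl <- union(if (r %in% broad) world$planted_nuclear else character(0),
                  pool[runif(length(pool)) < p_lnc])
      bm <- mrnas[runif(length(mrnas)) < 0.2]
      sort(c(bl, bm))
    })
    names(bound) <- rbps
    stats <- purrr::map_dfr(rbps, function(r) {
      g <- world$genes$gene_id
      is_b <- g %in% bound[[r]]
      tibble(rbp = r, gene_id = g,
             log2fc = ifelse(is_b, 0.8 + abs(rnorm(length(g), 0, 0.4)),
                             rnorm(length(g), 0, 0.3)),
             fdr = ifelse(is_b, runif(length(g), 0, 0.04),
                          runif(length(g), 0.1, 1)))
    })
    list(stats = stats, bound = bound)
  })
}

#' Simulate RBP ChIP promoters, protein-protein interactions and RBP
#' knockdown differential expression
#'
#' ChIP: broad RBPs bind the promoters of planted target genes at high rate
#' and background promoters at low rate. PPI: scores above/below the 0.4
#' threshold, with broad RBPs interconnected. RBP knockdown DE: genes
#' targeted by lncRNAs bound by the RBP are DE at a higher rate.
#'
#' @param world an [generate_world()] object.
#' @param eclip result of [simulate_eclip()] (for the bound sets).
#' @return list of tibbles `chip` (`rbp`, `promoter_id`), `ppi`
#'   (`rbp_a`, `rbp_b`, `score`), `rbp_de` (`rbp`, `gene_id`, `log2fc`,
#'   `fdr`).
#' @export
simulate_rbp_suite <- function(world, eclip) {
  stopifnot(inherits(world, "lnct_world"))
  rbps <- names(eclip$bound)
  broad <- rbps[seq_len(ceiling(length(rbps) / 2))]
  main_prom <- world$promoters[world$promoters$rank == 1, ]
  planted_genes <- unique(unlist(world$planted_target_genes))

  with_table_seed(world$rng_seed, "rbp_suite", {
    chip <- purrr::map_dfr(rbps, function(r) {
      p <- ifelse(main_prom$gene_id %in% planted_genes & r %in% broad,
                  0.7, 0.1)
      tibble(rbp = r,
             promoter_id = main_prom$promoter_id[runif(nrow(main_prom)) < p])
    })
    pairs <- t(utils::combn(rbps, 2))
    both_broad <- pairs[, 1] %in% broad & pairs[, 2] %in% broad
    ppi <- tibble(rbp_a = pairs[, 1], rbp_b = pairs[, 2],
                  score = ifelse(both_broad, runif(nrow(pairs), 0.5, 0.95),
                                 runif(nrow(pairs), 0.05, 0.4)))
    rbp_de <- purrr::map_dfr(rbps, function(r) {
      bound_lncs <- intersect(eclip$bound[[r]], world$planted_nuclear)
      tg <- unique(unlist(world$planted_target_genes[bound_lncs]))
      g <- world$genes$gene_id
      de <- (g %in% tg & runif(length(g)) < 0.5) |
        (!(g %in% tg) & runif(length(g)) < 0.05)
      tibble(rbp = r, gene_id = g,
             log2fc = ifelse(de, sample(c(-1, 1), length(g), TRUE) *
                               (1 + abs(rnorm(length(g), 0, 0.3))),
                             rnorm(length(g), 0, 0.2)),
             fdr = ifelse(de, runif(length(g), 0, 0.08),
                          runif(length(g), 0.3, 1)))
    })
    list(chip = chip, ppi = ppi, rbp_de = rbp_de)
  })
}

#' Simulate predicted TFBS sites with posterior scores
#'
#' Sites are dropped around the strongest-promoter and enhancer regions.
#' Most motifs are common (`base_rate` per region, mirroring genome-wide
#' TFBS predictions where frequent motifs cover most regulatory regions);
#' the last two motifs are rare (`rare_rate`) so the coverage exclusion of
#' [assign_tfbs()] is exercised. Motifs `M01` and `M02` are additionally
#' planted at a high rate in the promoters of planted target genes.
#'
#' @param world an [generate_world()] object.
#' @param n_motifs number of motifs (>= 3).
#' @param base_rate per-(region, motif) presence probability for common
#'   motifs.
#' @param rare_rate presence probability for the two rare motifs.
#' @return tibble `chrom`, `start`, `end`, `motif`, `posterior`.
#' @export
simulate_tfbs_sites <- function(world, n_motifs = 8, base_rate = 0.85,
                                rare_rate = 0.3) {
  stopifnot(inherits(world, "lnct_world"), n_motifs >= 3)
  regions <- bind_rows(
    world$promoters |>
      filter(.data$rank == 1) |>
      mutate(start = pmax(.data$pos - 200, 0), end = .data$pos + 200) |>
      select(region_id = "promoter_id", "chrom", "start", "end"),
    world$enhancers |>
      select(region_id = "enhancer_id", "chrom", "start", "end"))
  planted_genes <- unique(unlist(world$planted_target_genes))
  planted_regions <- world$promoters$promoter_id[
    world$promoters$gene_id %in% planted_genes]

  with_table_seed(world$rng_seed, "tfbs", {
    motifs <- sprintf("M%02d", seq_len(n_motifs))
    rare <- utils::tail(motifs, 2)
    purrr::map_dfr(motifs, function(m) {
      p <- rep(if (m %in% rare) rare_rate else base_rate, nrow(regions))
      if (m %in% c("M01", "M02")) {
        p[regions$region_id %in% planted_regions] <- 0.95
      }
      hit <- which(runif(nrow(regions)) < p)
      n_sites <- sample(1:2, length(hit), replace = TRUE)
      idx <- rep.int(hit, n_sites)
      s <- floor(regions$start[idx] +
                   runif(length(idx)) * (regions$end[idx] -
                                           regions$start[idx] - 12))
      tibble(chrom = regions$chrom[idx], start = s, end = s + 12,
             motif = m, posterior = runif(length(idx), 0.06, 0.4))
    })
  })
}

#' Simulate exon sequences with planted nuclear-retention motifs
#'
#' Each gene gets a random DNA sequence over its concatenated exons
#' (truncated to `max_len`). Planted nuclear lncRNAs receive U1
#' (`CAGGTGAGT`) insertions at high probability and one concrete SIRLOIN
#' instance; other genes carry U1 at a low background rate.
#'
#' @param world an [generate_world()] object.
#' @param max_len cap on emitted sequence length per gene, bp.
#' @return named character vector of sequences (one per gene).
#' @export
simulate_exon_seqs <- function(world, max_len = 3000) {
  stopifnot(inherits(world, "lnct_world"))
  u1 <- "CAGGTGAGT"
  sirloin_example <- "CGCCTCCCGAGTTCAAGCGATTCTCCTGCCTCAGCCTCCCGA"
  with_table_seed(world$rng_seed, "exons", {
    seqs <- purrr::pmap_chr(
      world$genes[, c("gene_id", "exon_starts", "exon_ends")],
      function(gene_id, exon_starts, exon_ends) {
        len <- min(sum(exon_ends - exon_starts), max_len)
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        planted <- gene_id %in% world$planted_nuclear
        p_u1 <- if (planted) 0.9 else 0.15
        if (runif(1) < p_u1) {
          for (k in seq_len(sample(1:3, 1))) {
            at <- sample.int(nchar(s) - nchar(u1), 1)
            substr(s, at, at + nchar(u1) - 1) <- u1
          }
        }
        if (planted && runif(1) < 0.7) {
          at <- sample.int(nchar(s) - nchar(sirloin_example), 1)
          substr(s, at, at + nchar(sirloin_example) - 1) <- sirloin_example
        }
        s
      })
    setNames(seqs, world$genes$gene_id)
  })
}
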