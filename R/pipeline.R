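#' Pipeline configuration with the study's default thresholds
#'
#' Bundles every tunable threshold of the pipeline, the master seed, and
#' the synthetic-generator parameters. The defaults are the thresholds the
#' analysis is defined with: binomial-caller FDR 0.01 with at least 3
#' reads; Hi-C significance at 5 read pairs and q <= 0.05; target regions
#' within 2 degrees inside the compartment padded by 100 kb; nuclear
#' classification at N/C ratio 0.5; TFBS aggregate posterior 0.1 in
#' regions padded by 250 bp with motifs covering at least 200 regions and
#' lncRNAs with at least 5 target regions; GO and knockdown-DE batteries
#' at FDR 0.1 with at least 3 overlapping genes; eCLIP targets at 5% FDR
#' and log2FC > 0.5 with at least 15 lncRNA targets per RBP and RBPs
#' binding at most 500 lncRNAs; PPI edges at score > 0.4.
#'
#' @param outdir run directory (outputs are write-once per run).
#' @param seed master seed; all randomness flows from it.
#' @param ... overrides for any default listed above (unknown names
#'   rejected).
#' @return a named list of class `lnct_config`.
#' @export
lnct_config <- function(outdir = tempfile("lnct_run_"), seed = 1, ...) {
  cfg <- list(
    outdir = outdir, seed = seed,
    ## caller
    fdr_rnachrom = 0.01, min_reads = 3, scope = "intra",
    ## Hi-C graph and targeting
    hic_min_pairs = 5, hic_max_q = 0.05, max_degree = 2, pad = 100000,
    constrain = "path",
    ## expression
    nc_threshold = 0.5, min_tpm = 0.5, min_tags = 3, enh_min_total = 5,
    ## TFBS
    tfbs_min_score = 0.1, tfbs_pad = 250, tfbs_min_regions = 200,
    tfbs_min_targets = 5,
    ## batteries
    go_fdr = 0.1, go_min_overlap = 3, kd_fdr = 0.1, kd_direction = "up",
    eclip_fdr = 0.05, eclip_lfc = 0.5, eclip_min_lnc = 15,
    rbp_max_lnc = 500, ppi_min = 0.4,
    ## shared geometry
    bin_size = 10000,
    ## generator
    n_chrom = 2, chrom_len = 5e6, n_mrna = 200, n_lncrna = 20,
    n_nuclear = 6, n_targets_per_lnc = 8, n_enhancers = 60,
    background_rate = 0.5, enrichment_fold = 20, nascent_frac = 0.15,
    p_neighbor = 0.02, q_noise = 0.05, effect_direction = 1,
    frac_responsive = 0.8
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "lnct_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "lnct_config")
}

stage_deps <- list(
  simulate = character(0),
  fractionation = c("expression.tsv", "enhancer_expression.tsv",
                    "promoters.tsv"),
  rnachrom = c("contacts.tsv", "genes.bed", "strongest_promoters.tsv"),
  targets = c("hic.tsv", "compartments.tsv", "strongest_promoters.tsv",
              "nuclear_classification.tsv", "interactions.tsv",
              "expressed_enhancers.tsv"),
  motifs = c("exons.fasta", "nuclear_classification.tsv", "tfbs.tsv",
             "strongest_promoters.tsv", "enhancers.bed"),
  enrich = c("target_genes.tsv", "target_regions.tsv", "de.tsv",
             "go_sets.gmt", "tfbs_assignments.tsv", "eclip.tsv",
             "celltype_expression.tsv", "nuclear_classification.tsv")
)
stage_producers <- c(
  expression.tsv = "simulate", enhancer_expression.tsv = "simulate",
  promoters.tsv = "simulate", contacts.tsv = "simulate",
  genes.bed = "simulate", hic.tsv = "simulate",
  compartments.tsv = "simulate", exons.fasta = "simulate",
  tfbs.tsv = "simulate", de.tsv = "simulate", go_sets.gmt = "simulate",
  celltype_expression.tsv = "simulate", eclip.tsv = "simulate",
  enhancers.bed = "simulate",
  strongest_promoters.tsv = "fractionation",
  nuclear_classification.tsv = "fractionation",
  expressed_enhancers.tsv = "fractionation",
  interactions.tsv = "rnachrom",
  target_genes.tsv = "targets", target_regions.tsv = "targets",
  tfbs_assignments.tsv = "motifs"
)

#' Run the annotation pipeline end to end
#'
#' Executes the requested stages in dependency order (simulate ->
#' fractionation -> rnachrom -> targets -> motifs -> enrich), reading and
#' writing TSVs under `config$outdir`, and records a deterministic run
#' manifest (`manifest.json`) with the configuration, per-stage record
#' counts and MD5 hashes of every output file. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config an [lnct_config()].
#' @param stages subset of stage names (default: all).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = lnct_config(),
                         stages = names(stage_deps)) {
  stopifnot(inherits(config, "lnct_config"))
  stages <- match.arg(stages, names(stage_deps), several.ok = TRUE)
  stages <- names(stage_deps)[names(stage_deps) %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  for (st in stages) {
    missing <- stage_deps[[st]][
      !file.exists(file.path(config$outdir, stage_deps[[st]]))]
    if (length(missing) > 0) {
      abort(sprintf(
        "stage '%s' is missing input(s) %s; run stage '%s' first",
        st, paste(missing, collapse = ", "),
        paste(unique(stage_producers[missing]), collapse = "', '")),
        class = "lnct_dependency_error")
    }
    switch(st,
           simulate = stage_simulate(config),
           fractionation = stage_fractionation(config),
           rnachrom = stage_rnachrom(config),
           targets = stage_targets(config),
           motifs = stage_motifs(config),
           enrich = stage_enrich(config))
  }

  files <- sort(list.files(config$outdir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(config$outdir, files))
  names(hashes) <- files
  counts <- vapply(files, function(f) {
    p <- file.path(config$outdir, f)
    if (grepl("\\.(tsv|bed|gmt)$", f)) length(readLines(p)) else NA_integer_
  }, integer(1))
  manifest <- list(config = unclass(config), stages = stages,
                   files = files, md5 = as.list(hashes),
                   lines = as.list(counts))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

read_tsv_q <- function(path, ...) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE, ...)
}

stage_simulate <- function(cfg) {
  world <- generate_world(
    n_chrom = cfg$n_chrom, chrom_len = cfg$chrom_len,
    bin_size = cfg$bin_size, n_mrna = cfg$n_mrna, n_lncrna = cfg$n_lncrna,
    n_nuclear = cfg$n_nuclear, n_targets_per_lnc = cfg$n_targets_per_lnc,
    n_enhancers = cfg$n_enhancers, seed = cfg$seed)
  write_world_inputs(world, cfg$outdir,
                     background_rate = cfg$background_rate,
                     enrichment_fold = cfg$enrichment_fold,
                     nascent_frac = cfg$nascent_frac,
                     p_neighbor = cfg$p_neighbor, q_noise = cfg$q_noise,
                     effect_direction = cfg$effect_direction,
                     frac_responsive = cfg$frac_responsive)
  invisible(world)
}

stage_fractionation <- function(cfg) {
  d <- cfg$outdir
  counts <- read_tsv_q(file.path(d, "expression.tsv"))
  prom_pos <- read_tsv_q(file.path(d, "promoters.tsv"))
  pe <- promoter_expression(counts)
  sp <- strongest_promoter(pe, min_tpm = cfg$min_tpm,
                           min_tags = cfg$min_tags) |>
    left_join(prom_pos[, c("promoter_id", "chrom", "pos")],
              by = "promoter_id")
  cls <- fractionation_pipeline(counts, threshold = cfg$nc_threshold)
  enh_counts <- read_tsv_q(file.path(d, "enhancer_expression.tsv"))
  enh_ids <- expressed_enhancers(enh_counts, min_total = cfg$enh_min_total)
  enh <- read_tsv_q(file.path(d, "enhancers.bed")) |>
    filter(.data$enhancer_id %in% enh_ids)
  write_tsv_q(sp, file.path(d, "strongest_promoters.tsv"))
  write_tsv_q(cls, file.path(d, "nuclear_classification.tsv"))
  write_tsv_q(enh, file.path(d, "expressed_enhancers.tsv"))
}

stage_rnachrom <- function(cfg) {
  d <- cfg$outdir
  contacts <- read_tsv_q(file.path(d, "contacts.tsv"))
  genes <- read_genes_bed(file.path(d, "genes.bed"))
  fn <- filter_nascent(contacts, genes)
  binned <- bin_contacts(fn$contacts, genes, bin_size = cfg$bin_size)
  bg <- estimate_background(binned)
  sig <- iterative_binomial_caller(binned, bg, fdr_cut = cfg$fdr_rnachrom,
                                   min_reads = cfg$min_reads,
                                   scope = cfg$scope)
  out <- sig |>
    mutate(bin_end = .data$bin_start + cfg$bin_size,
           scope = ifelse(.data$cis, "intra", "inter"))
  write_tsv_q(out[, c("gene_id", "chrom", "bin_start", "bin_end", "reads",
                      "p_value", "fdr", "iteration", "scope")],
              file.path(d, "interactions.tsv"))
  sp <- read_tsv_q(file.path(d, "strongest_promoters.tsv"))
  pairs <- annotate_interactions(sig, sp, bin_size = cfg$bin_size)
  write_tsv_q(pairs, file.path(d, "rnachrom_pairs.tsv"))
  write_tsv_q(tibble(rule = names(fn$removed),
                     removed = as.integer(fn$removed)),
              file.path(d, "nascent_filter_counts.tsv"))
}

read_interactions <- function(d, bin_size) {
  read_tsv_q(file.path(d, "interactions.tsv")) |>
    mutate(bin = bin_key(.data$chrom, .data$bin_start),
           cis = .data$scope == "intra")
}

stage_targets <- function(cfg) {
  d <- cfg$outdir
  graph <- filter_hic(read_tsv_q(file.path(d, "hic.tsv")),
                      min_pairs = cfg$hic_min_pairs, max_q = cfg$hic_max_q)
  eigs <- read_tsv_q(file.path(d, "compartments.tsv"))
  sp <- read_tsv_q(file.path(d, "strongest_promoters.tsv"))
  comp <- reassign_compartments(
    eigs, sp |> select("chrom", "pos", value = "mean_tpm"))
  write_tsv_q(comp, file.path(d, "compartments_labeled.tsv"))

  genes <- read_genes_bed(file.path(d, "genes.bed"))
  cls <- read_tsv_q(file.path(d, "nuclear_classification.tsv"))
  nuclear_lnc <- cls$gene_id[cls$is_nuclear &
                               cls$gene_id %in%
                               genes$gene_id[genes$class == "lncRNA"]]
  sig <- read_interactions(d, cfg$bin_size)
  enh <- read_tsv_q(file.path(d, "expressed_enhancers.tsv"))

  regions <- list(); tgenes <- list(); tenh <- list(); skipped <- character(0)
  for (L in intersect(nuclear_lnc, sp$gene_id)) {
    pr <- sp[sp$gene_id == L, ]
    reg <- define_target_regions(pr$chrom, pr$pos, graph, comp,
                                 k = cfg$max_degree, pad = cfg$pad,
                                 bin_size = cfg$bin_size,
                                 constrain = cfg$constrain)
    if (is.null(reg)) {
      skipped <- c(skipped, L)
      next
    }
    if (nrow(reg) == 0) next
    regions[[L]] <- mutate(reg, lncrna = L)
    mapped <- map_target_genes(reg, sp, enh, bin_size = cfg$bin_size)
    if (nrow(mapped$genes) > 0) {
      tgenes[[L]] <- mutate(mapped$genes, lncrna = L)
    }
    if (nrow(mapped$enhancers) > 0) {
      tenh[[L]] <- mutate(mapped$enhancers, lncrna = L)
    }
  }
  write_tsv_q(bind_rows(regions), file.path(d, "target_regions.tsv"))
  write_tsv_q(bind_rows(tgenes) |>
                filter(.data$target_gene != .data$lncrna),
              file.path(d, "target_genes.tsv"))
  write_tsv_q(bind_rows(tenh), file.path(d, "target_enhancers.tsv"))
  if (length(skipped) > 0) {
    message("lncRNA(s) in unlabeled compartments skipped: ",
            paste(skipped, collapse = ", "))
  }

  fig <- rnachrom_hic_comparison(sig, nuclear_lnc, graph, sp, comp,
                                 bin_size = cfg$bin_size,
                                 k = cfg$max_degree, seed = cfg$seed)
  figdir <- file.path(d, "figstats")
  dir.create(figdir, showWarnings = FALSE)
  write_tsv_q(fig$degree_cdf, file.path(figdir, "degree_cdf.tsv"))
  if (!is.null(fig$sens_spec)) {
    write_tsv_q(fig$sens_spec, file.path(figdir, "sens_spec.tsv"))
    write_tsv_q(bind_rows(observed = fig$enrichment,
                          randomized = fig$enrichment_random,
                          .id = "which"),
                file.path(figdir, "enrichment_2x2.tsv"))
    write_tsv_q(fig$distances, file.path(figdir, "distances.tsv"))
  }
}

stage_motifs <- function(cfg) {
  d <- cfg$outdir
  seqs <- read_exons_fasta(file.path(d, "exons.fasta"))
  counts <- tibble(gene_id = names(seqs),
                   u1 = unname(search_motif(seqs, U1_MOTIF)),
                   sirloin = unname(search_motif(seqs, SIRLOIN_MOTIF)))
  write_tsv_q(counts, file.path(d, "motif_counts.tsv"))

  genes <- read_genes_bed(file.path(d, "genes.bed"))
  cls <- read_tsv_q(file.path(d, "nuclear_classification.tsv")) |>
    filter(.data$gene_id %in% genes$gene_id[genes$class == "lncRNA"])
  enr <- bind_rows(
    u1 = motif_nuclear_enrichment(
      setNames(counts$u1, counts$gene_id)[cls$gene_id], cls),
    sirloin = motif_nuclear_enrichment(
      setNames(counts$sirloin, counts$gene_id)[cls$gene_id], cls),
    .id = "motif")
  write_tsv_q(enr, file.path(d, "motif_enrichment.tsv"))

  sites <- read_tsv_q(file.path(d, "tfbs.tsv"))
  sp <- read_tsv_q(file.path(d, "strongest_promoters.tsv"))
  enh <- read_tsv_q(file.path(d, "enhancers.bed"))
  regions <- bind_rows(
    sp |> mutate(start = .data$pos, end = .data$pos + 1) |>
      select(region_id = "promoter_id", "chrom", "start", "end"),
    enh |> select(region_id = "enhancer_id", "chrom", "start", "end"))
  assignments <- assign_tfbs(sites, regions, pad = cfg$tfbs_pad,
                             min_score = cfg$tfbs_min_score,
                             min_regions = cfg$tfbs_min_regions)
  write_tsv_q(assignments, file.path(d, "tfbs_assignments.tsv"))
}

stage_enrich <- function(cfg) {
  d <- cfg$outdir
  genes <- read_genes_bed(file.path(d, "genes.bed"))
  lnc_ids <- genes$gene_id[genes$class == "lncRNA"]
  mrna_ids <- genes$gene_id[genes$class == "mRNA"]
  tg <- read_tsv_q(file.path(d, "target_genes.tsv"))
  targets_all <- split(tg$target_gene, tg$lncrna)
  targets_mrna <- lapply(targets_all, intersect, y = mrna_ids)
  summary <- list()

  ## knockdown DE battery
  de <- read_tsv_q(file.path(d, "de.tsv"))
  kd <- kd_de_enrichment(targets_all[names(targets_all) %in% de$lncrna],
                         de, universe = unique(de$gene_id),
                         fdr_cut = cfg$kd_fdr,
                         direction = cfg$kd_direction)
  write_tsv_q(kd$results, file.path(d, "kd_enrichment.tsv"))
  summary$kd_combined_p <- kd$combined_p

  ## GO battery
  go_sets <- read_gmt(file.path(d, "go_sets.gmt"))
  go <- go_enrichment(targets_mrna[lengths(targets_mrna) > 0], go_sets,
                      fdr_cut = cfg$go_fdr,
                      min_overlap = cfg$go_min_overlap)
  write_tsv_q(go, file.path(d, "go_enrichment.tsv"))

  ## TFBS battery
  assignments <- read_tsv_q(file.path(d, "tfbs_assignments.tsv"))
  sp <- read_tsv_q(file.path(d, "strongest_promoters.tsv"))
  tenh <- read_tsv_q(file.path(d, "target_enhancers.tsv"))
  region_targets <- lapply(names(targets_all), function(L) {
    c(tg$promoter_id[tg$lncrna == L],
      tenh$enhancer_id[tenh$lncrna == L])
  })
  names(region_targets) <- names(targets_all)
  enh <- read_tsv_q(file.path(d, "enhancers.bed"))
  all_regions <- c(sp$promoter_id, enh$enhancer_id)
  tf <- tfbs_enrichment(assignments, region_targets, all_regions,
                        min_targets = cfg$tfbs_min_targets,
                        fdr_cut = cfg$go_fdr)
  write_tsv_q(tf$results, file.path(d, "tfbs_enrichment.tsv"))
  write_tsv_q(tf$combined, file.path(d, "tfbs_combined.tsv"))
  write_tsv_q(tf$motif_chisq, file.path(d, "tfbs_chisq.tsv"))

  ## expression correlation
  ct <- read_tsv_q(file.path(d, "celltype_expression.tsv"))
  m <- as.matrix(ct[, -1])
  rownames(m) <- ct$gene_id
  corr <- correlation_preference(m, targets_mrna[lengths(targets_mrna) >= 2])
  write_tsv_q(corr, file.path(d, "correlation_preference.tsv"))

  ## RBP batteries
  eclip <- read_tsv_q(file.path(d, "eclip.tsv"))
  rbp_targets <- eclip_target_filter(eclip, lnc_ids,
                                     fdr_cut = cfg$eclip_fdr,
                                     lfc_cut = cfg$eclip_lfc,
                                     min_lnc_targets = cfg$eclip_min_lnc)
  cls <- read_tsv_q(file.path(d, "nuclear_classification.tsv"))
  rb <- rbp_batteries(
    rbp_targets, targets_all,
    rbp_kd_de = read_tsv_q(file.path(d, "rbp_de.tsv")),
    chip = read_tsv_q(file.path(d, "chip.tsv")),
    promoters = sp, ppi = read_tsv_q(file.path(d, "ppi.tsv")),
    nc = cls |> filter(.data$gene_id %in% lnc_ids),
    max_lnc = cfg$rbp_max_lnc, kd_fdr = cfg$kd_fdr,
    ppi_min = cfg$ppi_min, fdr_cut = cfg$go_fdr)
  if (!is.null(rb$kd)) write_tsv_q(rb$kd, file.path(d, "rbp_kd.tsv"))
  if (!is.null(rb$promoter)) {
    write_tsv_q(rb$promoter, file.path(d, "rbp_promoter.tsv"))
  }
  if (!is.null(rb$ppi)) write_tsv_q(rb$ppi, file.path(d, "rbp_ppi.tsv"))
  summary$rbp_combined <- as.list(rb$combined)
  summary$rbp_nc_test <- rb$nc_test

  jsonlite::write_json(summary, file.path(d, "enrich_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
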