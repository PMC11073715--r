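#' Read and write the pipeline's tab-separated interchange files
#'
#' All TSVs carry a single header line and 0-based half-open coordinates.
#' `genes.bed` is BED12-like (no header) with exon blocks and a 13th
#' gene-class column.
#'
#' @name lnct_io
NULL

write_tsv_q <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname lnct_io
#' @param genes gene-model tibble (see [generate_world()]).
#' @param path file path.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- genes |>
    mutate(score = 0L, thick_start = .data$start, thick_end = .data$end,
           rgb = "0,0,0",
           block_count = lengths(.data$exon_starts),
           block_sizes = purrr::map2_chr(.data$exon_starts, .data$exon_ends,
                                         ~ paste(.y - .x, collapse = ",")),
           block_starts = purrr::map2_chr(.data$exon_starts, .data$start,
                                          ~ paste(.x - .y, collapse = ","))) |>
    select("chrom", "start", "end", name = "gene_id", "score", "strand",
           "thick_start", "thick_end", "rgb", "block_count", "block_sizes",
           "block_starts", "class")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname lnct_io
#' @export
read_genes_bed <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "gene_id", "score",
                        "strand", "thick_start", "thick_end", "rgb",
                        "block_count", "block_sizes", "block_starts",
                        "class"),
    col_types = "ciiciciiciccc", progress = FALSE)
  bed |>
    mutate(
      exon_starts = purrr::map2(.data$block_starts, .data$start, function(bs, s) {
        as.numeric(strsplit(bs, ",")[[1]]) + s
      }),
      exon_ends = purrr::map2(.data$exon_starts, .data$block_sizes, function(es, sz) {
        es + as.numeric(strsplit(sz, ",")[[1]])
      })) |>
    select("gene_id", "class", "chrom", "start", "end", "strand",
           "exon_starts", "exon_ends")
}

#' @rdname lnct_io
#' @param seqs named character vector of sequences.
#' @export
write_exons_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname lnct_io
#' @export
read_exons_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname lnct_io
#' @param go_sets named list term -> gene ids.
#' @export
write_gmt <- function(go_sets, path) {
  lines <- vapply(names(go_sets), function(t) {
    paste(c(t, "na", go_sets[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname lnct_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Generate synthetic GO-like gene sets
#'
#' Random term sets drawn from the mRNA genes, plus one planted term per
#' planted nuclear lncRNA consisting mostly of that lncRNA's target genes,
#' so downstream term enrichment has a recoverable signal.
#'
#' @param world an [generate_world()] object.
#' @param n_terms number of random terms.
#' @param term_size range of random-term sizes.
#' @return named list term -> gene ids.
#' @export
simulate_go_sets <- function(world, n_terms = 30, term_size = c(10, 50)) {
  stopifnot(inherits(world, "lnct_world"))
  mrnas <- world$genes$gene_id[world$genes$class == "mRNA"]
  with_table_seed(world$rng_seed, "go_sets", {
    sets <- lapply(seq_len(n_terms), function(i) {
      sample(mrnas, sample(term_size[1]:min(term_size[2], length(mrnas)), 1))
    })
    names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    planted <- lapply(world$planted_nuclear, function(L) {
      unique(c(world$planted_target_genes[[L]], sample(mrnas, 5)))
    })
    names(planted) <- paste0("TARGETSET_", world$planted_nuclear)
    c(sets, planted)
  })
}

#' Simulate a gene-by-cell-type expression matrix
#'
#' Each planted nuclear lncRNA follows a latent trajectory across cell
#' types; its planted target genes track the same trajectory (positive
#' coupling) plus noise, while all other genes vary independently. This
#' gives the expression-correlation analysis a planted positive
#' preference.
#'
#' @param world an [generate_world()] object.
#' @param n_celltypes number of cell types (columns).
#' @param coupling strength of the shared trajectory in targets.
#' @return numeric matrix, genes x cell types.
#' @export
simulate_celltype_expression <- function(world, n_celltypes = 18,
                                         coupling = 1.5) {
  stopifnot(inherits(world, "lnct_world"))
  g <- world$genes$gene_id
  with_table_seed(world$rng_seed, "celltype_expression", {
    m <- matrix(rnorm(length(g) * n_celltypes, 5, 1), nrow = length(g),
                dimnames = list(g, sprintf("ct%02d", seq_len(n_celltypes))))
    for (L in world$planted_nuclear) {
      latent <- rnorm(n_celltypes, 0, 1)
      m[L, ] <- 5 + 2 * latent + rnorm(n_celltypes, 0, 0.3)
      for (t in world$planted_target_genes[[L]]) {
        m[t, ] <- 5 + coupling * latent + rnorm(n_celltypes, 0, 0.8)
      }
    }
    m
  })
}

#' Write every synthetic input table for a world
#'
#' Runs all simulators and writes the pipeline's input files into `dir`:
#' `contacts.tsv`, `hic.tsv`, `genes.bed`, `expression.tsv`,
#' `enhancer_expression.tsv`, `enhancers.bed`, `compartments.tsv`,
#' `de.tsv`, `eclip.tsv`, `chip.tsv`, `ppi.tsv`, `rbp_de.tsv`,
#' `tfbs.tsv`, `go_sets.gmt`, `celltype_expression.tsv`, `exons.fasta`,
#' and the ground truth (`truth.json`).
#'
#' @param world an [generate_world()] object.
#' @param dir output directory (created if needed).
#' @param background_rate,enrichment_fold,nascent_frac see
#'   [simulate_contacts()].
#' @param p_neighbor,q_noise see [simulate_hic()].
#' @param effect_direction,frac_responsive see [simulate_knockdown_de()].
#' @return (invisibly) a named list of the generated tables and truth.
#' @export
write_world_inputs <- function(world, dir, background_rate = 0.4,
                               enrichment_fold = 20, nascent_frac = 0.15,
                               p_neighbor = 0.02, q_noise = 0.05,
                               effect_direction = 1,
                               frac_responsive = 0.8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contacts <- simulate_contacts(world, background_rate, enrichment_fold,
                                nascent_frac)
  hic <- simulate_hic(world, p_neighbor, q_noise)
  de <- simulate_knockdown_de(world, effect_direction, frac_responsive)
  expr <- simulate_expression(world)
  eclip <- simulate_eclip(world)
  rbp <- simulate_rbp_suite(world, eclip)
  tfbs <- simulate_tfbs_sites(world)
  go_sets <- simulate_go_sets(world)
  ct_expr <- simulate_celltype_expression(world)
  seqs <- simulate_exon_seqs(world)

  write_tsv_q(select(contacts, -"nascent"), file.path(dir, "contacts.tsv"))
  write_tsv_q(world$promoters[, c("promoter_id", "gene_id", "chrom", "pos")],
              file.path(dir, "promoters.tsv"))
  write_tsv_q(select(hic, -"scaffold"), file.path(dir, "hic.tsv"))
  write_genes_bed(world$genes, file.path(dir, "genes.bed"))
  write_tsv_q(expr$promoters, file.path(dir, "expression.tsv"))
  write_tsv_q(expr$enhancers, file.path(dir, "enhancer_expression.tsv"))
  write_tsv_q(world$enhancers[, c("chrom", "start", "end", "enhancer_id")],
              file.path(dir, "enhancers.bed"))
  write_tsv_q(world$compartments[, c("chrom", "start", "end", "eigenvalue")],
              file.path(dir, "compartments.tsv"))
  write_tsv_q(de, file.path(dir, "de.tsv"))
  write_tsv_q(eclip$stats, file.path(dir, "eclip.tsv"))
  write_tsv_q(rbp$chip, file.path(dir, "chip.tsv"))
  write_tsv_q(rbp$ppi, file.path(dir, "ppi.tsv"))
  write_tsv_q(rbp$rbp_de, file.path(dir, "rbp_de.tsv"))
  write_tsv_q(tfbs, file.path(dir, "tfbs.tsv"))
  write_gmt(go_sets, file.path(dir, "go_sets.gmt"))
  write_tsv_q(as_tibble(ct_expr, rownames = "gene_id"),
              file.path(dir, "celltype_expression.tsv"))
  write_exons_fasta(seqs, file.path(dir, "exons.fasta"))

  truth <- list(planted_nuclear = world$planted_nuclear,
                planted_target_bins = world$planted_target_bins,
                planted_target_genes = world$planted_target_genes,
                rbp_bound = eclip$bound,
                seed = world$rng_seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(contacts = contacts, hic = hic, de = de, expr = expr,
                 eclip = eclip, rbp = rbp, tfbs = tfbs, go_sets = go_sets,
                 ct_expr = ct_expr, seqs = seqs, truth = truth))
}
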