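# One gene on chr1 with exons [0, 1000) and [2000, 3000); intron [1000, 2000).
one_gene <- tibble::tibble(
  gene_id = "g1", class = "lncRNA", chrom = "chr1",
  start = 0, end = 3000, strand = "+",
  exon_starts = list(c(0, 2000)), exon_ends = list(c(1000, 3000)))

test_that("nascent filter removes intronic RNA tags and own-gene DNA tags", {
  contacts <- tibble::tibble(
    gene_id = "g1", chrom_rna = "chr1",
    start_rna = c(1100, 950, 100, 100),
    end_rna   = c(1200, 1050, 130, 130),
    chrom_dna = c("chr2", "chr2", "chr1", "chr2"),
    pos_dna   = c(50000, 50000, 2500, 50000))
  fn <- filter_nascent(contacts, one_gene)
  # row 1: wholly intronic RNA tag -> removed
  # row 2: spans the exon-intron junction -> retained
  # row 3: DNA tag inside the gene body -> removed
  expect_equal(nrow(fn$contacts), 2)
  expect_equal(unname(fn$removed["intronic_rna"]), 1L)
  expect_equal(unname(fn$removed["own_gene_dna"]), 1L)

  bad <- dplyr::mutate(contacts, gene_id = "nope")
  expect_error(filter_nascent(bad, one_gene), class = "lnct_unknown_gene")
})

test_that("the generator's nascent fraction is recovered by the filter", {
  w <- tiny_world(seed = 12)
  co <- simulate_contacts(w, nascent_frac = 0.3)
  fn <- filter_nascent(co, w$genes)
  removed_frac <- fn$removed[["total"]] / nrow(co)
  se <- sqrt(0.3 * 0.7 / nrow(co))
  expect_lt(abs(removed_frac - 0.3), 5 * se)
  # the filter removes exactly the flagged contacts
  expect_false(any(fn$contacts$nascent))
})

test_that("binning is half-open and conserves counts", {
  contacts <- tibble::tibble(
    gene_id = "g1", chrom_rna = "chr1",
    start_rna = 0, end_rna = 30,
    chrom_dna = "chr1", pos_dna = c(0, 9999, 10000))
  b <- bin_contacts(contacts, one_gene)
  expect_equal(sort(unique(b$counts$bin_start)), c(0, 10000))
  expect_equal(b$counts$reads[b$counts$bin_start == 0], 2)
  expect_equal(sum(b$counts$reads), nrow(contacts))

  w <- tiny_world(seed = 13)
  co <- simulate_contacts(w)
  bb <- bin_contacts(co, w$genes)
  # per-gene conservation
  by_gene <- table(co$gene_id)
  expect_equal(bb$gene_totals$n[match(names(by_gene),
                                      bb$gene_totals$gene_id)],
               as.integer(by_gene))
  # brute-force groupby oracle
  oracle <- stats::aggregate(
    rep(1, nrow(co)),
    by = list(gene = co$gene_id, chrom = co$chrom_dna,
              bin = floor(co$pos_dna / 10000) * 10000), FUN = sum)
  oracle <- oracle[order(oracle$gene, oracle$chrom, oracle$bin), ]
  got <- bb$counts[order(bb$counts$gene_id, bb$counts$chrom,
                         bb$counts$bin_start), ]
  expect_equal(got$reads, oracle$x)
  expect_equal(got$bin_start, oracle$bin)
})

test_that("background probabilities are trans-mRNA frequencies", {
  counts <- tibble::tibble(
    gene_id = c("m1", "m1", "m2", "l1"),
    class = c("mRNA", "mRNA", "mRNA", "lncRNA"),
    chrom = "chr2", bin_start = c(0, 10000, 0, 0),
    cis = c(FALSE, FALSE, FALSE, FALSE),
    reads = c(2, 1, 1, 50))
  bg <- estimate_background(make_binned(counts))
  expect_equal(bg$p[bg$bin == "chr2:0"], 0.75)
  expect_equal(bg$p[bg$bin == "chr2:10000"], 0.25)
  expect_equal(attr(bg, "total_trans_mrna"), 4)

  cis_only <- dplyr::mutate(counts, cis = TRUE)
  expect_error(estimate_background(make_binned(cis_only)),
               class = "lnct_no_background")
})

test_that("background converges to uniform as trans reads grow", {
  w <- tiny_world(seed = 14)
  co <- simulate_contacts(w, background_rate = 20, enrichment_fold = 1,
                          nascent_frac = 0)
  b <- bin_contacts(co, w$genes)
  bg <- estimate_background(b)
  n_bins <- nrow(tile_bins(w$chromosomes))
  expect_lt(max(abs(bg$p - 1 / n_bins)), 0.25 / n_bins)
})

test_that("iterative caller matches the worked 3-bin fixture", {
  counts <- tibble::tibble(
    gene_id = "g", class = "lncRNA", chrom = "chr1",
    bin_start = c(0, 10000, 20000), cis = TRUE,
    reads = c(8, 1, 1))
  bins <- bin_key("chr1", (0:99) * 10000)
  bg <- make_background(bins, rep(0.01, 100))
  sig <- iterative_binomial_caller(make_binned(counts), bg)

  # independent non-iterative oracle with manual subtraction and hand BH
  p1 <- vapply(c(8, 1, 1), binom_tail_oracle, numeric(1), n = 10, p = 0.01)
  adj1 <- bh_oracle(p1)
  expect_true(adj1[1] <= 0.01 && all(adj1[-1] > 0.01))
  p2 <- vapply(c(1, 1), binom_tail_oracle, numeric(1), n = 2, p = 0.01)
  expect_true(all(bh_oracle(p2) > 0.01))

  expect_equal(nrow(sig), 1)
  expect_equal(sig$bin_start, 0)
  expect_equal(sig$iteration, 1L)
  expect_equal(sig$reads, 8)
  expect_equal(sig$p_value, p1[1])
  expect_equal(sig$fdr, adj1[1])
})

test_that("caller edge cases: no reads, low support, untestable bins", {
  bins <- bin_key("chr1", (0:9) * 10000)
  bg <- make_background(bins, rep(0.001, 10))
  # every bin below the 3-read support rule stays out even when significant
  low <- tibble::tibble(gene_id = "g", class = "lncRNA", chrom = "chr1",
                        bin_start = c(0, 10000), cis = TRUE, reads = c(2, 2))
  expect_equal(nrow(iterative_binomial_caller(make_binned(low), bg)), 0)
  # bins with zero background probability are untestable
  hot <- tibble::tibble(gene_id = "g", class = "lncRNA", chrom = "chr9",
                        bin_start = 0, cis = TRUE, reads = 50)
  expect_equal(nrow(iterative_binomial_caller(make_binned(hot), bg)), 0)
})

test_that("caller is invariant to gene order and terminates within bin count", {
  withr::with_seed(42, {
    counts <- tibble::tibble(
      gene_id = rep(sprintf("g%02d", 1:12), each = 8),
      class = "lncRNA", chrom = "chr1",
      bin_start = rep((0:7) * 10000, 12), cis = TRUE,
      reads = rpois(96, 3) + 1)
  })
  bins <- bin_key("chr1", (0:19) * 10000)
  bg <- make_background(bins, rep(1 / 20, 20))
  a <- iterative_binomial_caller(make_binned(counts), bg)
  b <- iterative_binomial_caller(make_binned(counts[sample(nrow(counts)), ]),
                                 bg)
  expect_equal(a, b)
  expect_true(all(a$iteration <= 8))
})

test_that("upper-tail binomial p-values are monotone in n (convergence basis)", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(5:200, 1)
      x <- sample.int(n, 1)
      p <- runif(1, 1e-4, 0.2)
      drop <- sample.int(max(n - x, 1), 1) - 1
      expect_lte(pbinom(x - 1, n - drop, p, lower.tail = FALSE),
                 pbinom(x - 1, n, p, lower.tail = FALSE) + 1e-12)
    }
  })
})

test_that("significant bins pair with every strongest promoter they contain", {
  sig <- tibble::tibble(gene_id = "l1", chrom = "chr1", bin_start = 0,
                        bin = "chr1:0", reads = 5, p_value = 1e-5,
                        fdr = 1e-4, iteration = 1L, cis = TRUE)
  promoters <- tibble::tibble(
    promoter_id = c("a_p1", "b_p1", "c_p1"),
    gene_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(500, 9000, 20000))
  pairs <- annotate_interactions(sig, promoters)
  expect_equal(sort(pairs$target_gene), c("a", "b"))
  # a bin with no promoter yields no pair
  sig2 <- dplyr::mutate(sig, bin = "chr1:90000", bin_start = 90000)
  expect_equal(nrow(annotate_interactions(sig2, promoters)), 0)
})

test_that("interval-overlap pairing matches a brute-force oracle", {
  w <- tiny_world(seed = 15)
  prom <- w$promoters[w$promoters$rank == 1, ]
  withr::with_seed(16, {
    sig <- tibble::tibble(
      gene_id = "l", chrom = "chr1",
      bin_start = sample((0:99) * 10000, 30))
  })
  sig$bin <- bin_key(sig$chrom, sig$bin_start)
  pairs <- annotate_interactions(sig, prom)
  oracle <- unlist(lapply(seq_len(nrow(sig)), function(i) {
    hit <- prom$pos >= sig$bin_start[i] & prom$pos < sig$bin_start[i] + 10000 &
      prom$chrom == sig$chrom[i]
    prom$gene_id[hit]
  }))
  expect_setequal(pairs$target_gene, oracle)
  expect_equal(nrow(pairs), length(oracle))
})
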