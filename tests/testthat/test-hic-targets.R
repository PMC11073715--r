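simple_graph <- function(edges) {
  # edges: list of c(i, j) bin indices on chr1
  tab <- tibble::tibble(
    chrom = "chr1",
    bin_i_start = vapply(edges, `[`, numeric(1), 1) * 10000,
    bin_j_start = vapply(edges, `[`, numeric(1), 2) * 10000,
    read_pairs = 10, q_value = 0.01)
  filter_hic(tab)
}

flat_compartments <- function(len = 5e6, label = "A") {
  tibble::tibble(chrom = "chr1", start = 0, end = len,
                 eigenvalue = if (label == "A") 1 else -1,
                 label = label)
}

test_that("Hi-C filter thresholds are inclusive and duplicates collapse", {
  tab <- tibble::tibble(
    chrom = "chr1",
    bin_i_start = c(0, 0, 10000, 10000, 30000),
    bin_j_start = c(10000, 20000, 20000, 20000, 30000),
    read_pairs = c(4, 5, 3, 2, 50),
    q_value = c(0.001, 0.05, 0.02, 0.01, 0.001))
  g <- filter_hic(tab)
  keys <- paste(g$edges$bin_i_start, g$edges$bin_j_start)
  expect_false("0 10000" %in% keys)        # 4 read pairs: excluded
  expect_true("0 20000" %in% keys)         # q = 0.05 inclusive
  expect_true("10000 20000" %in% keys)     # 3 + 2 duplicates sum to 5
  expect_false("30000 30000" %in% keys)    # self loop dropped
  expect_equal(g$edges$read_pairs[keys == "10000 20000"], 5)
})

test_that("Hi-C filter matches a brute-force oracle and flags bad rows", {
  tab <- random_hic_table(seed = 21)
  g <- filter_hic(tab)
  ora <- tab
  lo <- pmin(ora$bin_i_start, ora$bin_j_start)
  hi <- pmax(ora$bin_i_start, ora$bin_j_start)
  agg <- stats::aggregate(cbind(rp = ora$read_pairs, q = ora$q_value),
                          by = list(lo = lo, hi = hi),
                          FUN = function(x) x[1])
  agg$rp <- stats::aggregate(ora$read_pairs, list(lo = lo, hi = hi),
                             sum)$x
  agg$q <- stats::aggregate(ora$q_value, list(lo = lo, hi = hi), min)$x
  keep <- agg[agg$lo != agg$hi & agg$rp >= 5 & agg$q <= 0.05, ]
  expect_equal(nrow(g$edges), nrow(keep))
  expect_setequal(paste(g$edges$bin_i_start, g$edges$bin_j_start),
                  paste(keep$lo, keep$hi))

  tab$q_value[3] <- NA
  expect_error(filter_hic(tab), class = "lnct_malformed_hic")
})

test_that("compartment signs flip when B out-expresses A, idempotently", {
  eigs <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 2),
                         start = rep(c(0, 1e6), 2),
                         end = rep(c(1e6, 2e6), 2),
                         eigenvalue = c(1, -1, 0.5, -0.5))
  expr <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 2),
    pos = rep(c(5e5, 1.5e6), 2),
    value = c(10, 2,    # chr1: positive segments richer -> unchanged
              2, 10))   # chr2: negative segments richer -> flip
  cm <- reassign_compartments(eigs, expr)
  expect_equal(cm$eigenvalue[cm$chrom == "chr1"], c(1, -1))
  expect_equal(cm$label[cm$chrom == "chr1"], c("A", "B"))
  expect_equal(cm$eigenvalue[cm$chrom == "chr2"], c(-0.5, 0.5))
  expect_equal(cm$label[cm$chrom == "chr2"], c("B", "A"))
  # idempotence
  cm2 <- reassign_compartments(cm[, 1:4], expr)
  expect_equal(cm2, cm)
  # post-condition: A's mean expression >= B's on every chromosome
  for (ch in unique(cm$chrom)) {
    lab <- compartment_label_at(cm, expr$chrom, expr$pos)
    sel <- expr$chrom == ch
    expect_gte(mean(expr$value[sel & lab == "A"]),
               mean(expr$value[sel & lab == "B"]))
  }
  # all-zero chromosome stays unlabeled
  z <- tibble::tibble(chrom = "chrZ", start = 0, end = 1e6, eigenvalue = 0)
  expect_true(is.na(reassign_compartments(z, expr)$label))
})

test_that("degree of separation equals the BFS oracle", {
  g <- simple_graph(list(c(0, 1), c(1, 2), c(2, 3), c(5, 6)))
  expect_equal(degree_of_separation(g, "chr1:0", "chr1:0"), 0)
  expect_equal(degree_of_separation(g, "chr1:0", "chr1:10000"), 1)
  expect_equal(degree_of_separation(g, "chr1:0", "chr1:20000", max_k = 5), 2)
  expect_equal(degree_of_separation(g, "chr1:0", "chr1:30000", max_k = 2),
               Inf)   # capped
  expect_equal(degree_of_separation(g, "chr1:0", "chr1:50000", max_k = 10),
               Inf)   # disconnected

  for (seed in 1:5) {
    tab <- random_hic_table(n_bins = 30, n_edges = 40, seed = seed)
    g <- filter_hic(tab)
    edges <- data.frame(from = g$edges$bin_i, to = g$edges$bin_j)
    vs <- igraph::V(g$graph)$name
    for (src in vs[1:3]) {
      oracle <- bfs_oracle(edges, src)
      got <- bin_degrees(g, src)
      expect_equal(got[vs], oracle[vs])
    }
  }
})

test_that("degree is symmetric and obeys the triangle inequality", {
  tab <- random_hic_table(n_bins = 25, n_edges = 60, seed = 31)
  g <- filter_hic(tab)
  vs <- igraph::V(g$graph)$name
  withr::with_seed(32, {
    for (i in 1:30) {
      trip <- sample(vs, 3)
      dab <- degree_of_separation(g, trip[1], trip[2], max_k = 100)
      dba <- degree_of_separation(g, trip[2], trip[1], max_k = 100)
      dbc <- degree_of_separation(g, trip[2], trip[3], max_k = 100)
      dac <- degree_of_separation(g, trip[1], trip[3], max_k = 100)
      expect_equal(dab, dba)
      if (is.finite(dab) && is.finite(dbc)) {
        expect_lte(dac, dab + dbc)
      }
    }
  })
})

test_that("target regions respect degree cap and compartment interval", {
  # chain 0-1-2-3; bin 150 attaches to bin 1 but lies in compartment B,
  # outside the A interval [0, 1 Mb) + 100 kb pad
  g <- simple_graph(list(c(0, 1), c(1, 2), c(2, 3), c(1, 150)))
  comp <- tibble::tibble(chrom = "chr1", start = c(0, 1e6),
                         end = c(1e6, 5e6), eigenvalue = c(1, -1),
                         label = c("A", "B"))
  reg <- define_target_regions("chr1", 500, g, comp, k = 2)
  expect_setequal(reg$bin, c("chr1:10000", "chr1:20000"))
  expect_equal(reg$degree[reg$bin == "chr1:10000"], 1)
  expect_equal(reg$degree[reg$bin == "chr1:20000"], 2)
  expect_false("chr1:0" %in% reg$bin)       # reference bin excluded
  expect_false("chr1:1500000" %in% reg$bin) # outside padded compartment

  # k = 0 yields no targets
  expect_equal(nrow(define_target_regions("chr1", 500, g, comp, k = 0)), 0)

  # unlabeled compartment -> NULL with a reason
  comp_na <- dplyr::mutate(comp, label = NA_character_)
  out <- define_target_regions("chr1", 500, g, comp_na)
  expect_null(out)
})

test_that("path constraint blocks routes through excluded territory", {
  # 0 -> 150 -> 2: with the path constraint bin 2 is unreachable because
  # the intermediate bin 150 lies outside the compartment interval
  g <- simple_graph(list(c(0, 150), c(150, 2)))
  comp <- tibble::tibble(chrom = "chr1", start = c(0, 1e6),
                         end = c(1e6, 5e6), eigenvalue = c(1, -1),
                         label = c("A", "B"))
  path_mode <- define_target_regions("chr1", 500, g, comp, k = 2,
                                     constrain = "path")
  expect_equal(nrow(path_mode), 0)
  end_mode <- define_target_regions("chr1", 500, g, comp, k = 2,
                                    constrain = "endpoints")
  expect_equal(end_mode$bin, "chr1:20000")
})

test_that("planted scaffolds are fully recovered as target regions", {
  w <- tiny_world(seed = 17)
  g <- filter_hic(simulate_hic(w))
  comp <- dplyr::mutate(w$compartments, label = .data$label_true,
                        eigenvalue = .data$eigen_true)
  prom <- w$promoters[w$promoters$rank == 1, ]
  for (L in w$planted_nuclear) {
    p <- prom[prom$gene_id == L, ]
    reg <- define_target_regions(p$chrom, p$pos, g, comp, k = 2)
    expect_true(all(w$planted_target_bins[[L]] %in% reg$bin))
  }
})

test_that("feature mapping counts every promoter and enhancer in a bin", {
  regions <- tibble::tibble(bin = c("chr1:0", "chr1:10000"),
                            chrom = "chr1", bin_start = c(0, 10000),
                            degree = c(1, 1))
  promoters <- tibble::tibble(
    promoter_id = c("a_p1", "b_p1", "far_p1"),
    gene_id = c("a", "b", "far"), chrom = "chr1",
    pos = c(100, 9000, 500000))
  enhancers <- tibble::tibble(enhancer_id = "e1", chrom = "chr1",
                              start = 9500, end = 12000)
  mp <- map_target_genes(regions, promoters, enhancers)
  expect_equal(sort(mp$genes$target_gene), c("a", "b"))
  # enhancer spans the bin boundary: overlaps both bins, listed once each
  expect_equal(nrow(mp$enhancers), 2)
  # empty region set -> empty lists
  empty <- map_target_genes(regions[0, ], promoters, enhancers)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$enhancers), 0)
})

test_that("target regions are invariant to edge insertion order", {
  tab <- random_hic_table(n_bins = 40, n_edges = 60, seed = 41)
  comp <- flat_compartments()
  shuffled <- withr::with_seed(42, tab[sample(nrow(tab)), ])
  r1 <- define_target_regions("chr1", 500, filter_hic(tab), comp, k = 2)
  r2 <- define_target_regions("chr1", 500, filter_hic(shuffled), comp, k = 2)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("degree CDF is monotone and saturates on planted scaffolds", {
  w <- tiny_world(seed = 18)
  g <- filter_hic(simulate_hic(w))
  prom <- w$promoters[w$promoters$rank == 1, ]
  L <- w$planted_nuclear[1]
  p <- prom[prom$gene_id == L, ]
  ref <- bin_key(p$chrom, pos_to_bin(p$pos))
  cdf <- degree_cdf(w$planted_target_bins[[L]], g, ref)
  expect_true(!is.unsorted(cdf$cum_fraction))
  expect_equal(cdf$cum_fraction[cdf$k == 2], 1)
  # empty input -> explicit empty result
  empty <- degree_cdf(character(0), g, ref)
  expect_equal(nrow(empty), 0)
})

test_that("sensitivity/specificity match a confusion-matrix oracle", {
  g <- simple_graph(list(c(0, 1), c(1, 2), c(0, 3), c(3, 4)))
  universe <- bin_key("chr1", (0:9) * 10000)
  sig <- c("chr1:10000", "chr1:40000", "chr1:90000")
  ss <- sensitivity_specificity_by_degree(sig, g, "chr1:0", universe,
                                          max_k = 3)
  deg <- c(0, 1, 2, 1, 2, Inf, Inf, Inf, Inf, Inf)
  for (k in 0:3) {
    within <- deg <= k
    is_sig <- universe %in% sig
    expect_equal(ss$sensitivity[ss$k == k], mean(within[is_sig]))
    expect_equal(ss$specificity[ss$k == k], mean(!within[!is_sig]))
  }
  # k covering the whole universe -> sensitivity 1, specificity 0
  g_full <- simple_graph(lapply(1:9, function(i) c(0, i)))
  ss_full <- sensitivity_specificity_by_degree(sig, g_full, "chr1:0",
                                               universe, max_k = 1)
  expect_equal(ss_full$sensitivity[ss_full$k == 1], 1)
  expect_equal(ss_full$specificity[ss_full$k == 1], 0)
})

test_that("Hi-C support enrichment is found when planted and lost when randomized", {
  w <- tiny_world(seed = 19)
  g <- filter_hic(simulate_hic(w))
  prom <- w$promoters[w$promoters$rank == 1, ]
  L <- w$planted_nuclear[1]
  p <- prom[prom$gene_id == L, ]
  ref <- bin_key(p$chrom, pos_to_bin(p$pos))
  universe <- bin_key(p$chrom, (0:99) * 10000)
  sig <- w$planted_target_bins[[L]]
  obs <- hic_support_enrichment(sig, g, ref, universe, k = 2)
  expect_gt(obs$odds_ratio, 1)
  expect_lt(obs$p_value, 0.01)
  rnd <- hic_support_enrichment(sig, g, ref, universe, k = 2,
                                randomize = TRUE, seed = 99)
  expect_gt(rnd$p_value, 0.01)
})

test_that("distance and co-membership arithmetic follows the bin midpoint", {
  comp <- tibble::tibble(chrom = "chr1", start = c(0, 2e6),
                         end = c(2e6, 5e6), eigenvalue = c(1, -1),
                         label = c("A", "B"))
  promoters <- tibble::tibble(gene_id = "l1", chrom = "chr1",
                              pos = 1005000)
  pairs <- tibble::tibble(gene_id = "l1", chrom = "chr1",
                          bin_start = c(3000000, 1000000))
  d <- linear_distance_stats(pairs, promoters, comp)
  expect_equal(d$distance_bp[1], 2000000, tolerance = 5000 / 2e6)
  expect_lt(d$distance_bp[2], 10000)
  expect_equal(d$same_compartment, c(FALSE, TRUE))
})
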