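test_that("Fisher exact p-values match enumeration and stats::fisher.test", {
  # all tables with total up to 12 here; the acceptance suite goes to 30
  tabs <- expand.grid(a = 0:12, b = 0:12, cc = 0:12, d = 0:12)
  tabs <- tabs[rowSums(tabs) <= 12 & rowSums(tabs) >= 2, ]
  for (side in c("right", "left", "two")) {
    got <- vapply(seq_len(nrow(tabs)), function(r) {
      fisher_exact(tabs$a[r], tabs$b[r], tabs$cc[r], tabs$d[r],
                   side = side)$p_value
    }, numeric(1))
    want <- vapply(seq_len(nrow(tabs)), function(r) {
      fisher_enum_oracle(tabs$a[r], tabs$b[r], tabs$cc[r], tabs$d[r], side)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  two <- vapply(seq_len(nrow(tabs)), function(r) {
    fisher_exact(tabs$a[r], tabs$b[r], tabs$cc[r], tabs$d[r],
                 side = "two")$p_value
  }, numeric(1))
  ft <- vapply(seq_len(nrow(tabs)), function(r) {
    stats::fisher.test(matrix(c(tabs$a[r], tabs$cc[r], tabs$b[r],
                                tabs$d[r]), 2))$p.value
  }, numeric(1))
  expect_equal(two, ft, tolerance = 1e-9)
})

test_that("Fisher odds ratio uses sample OR with sentinels", {
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_equal(fisher_exact(0, 10, 10, 0, side = "right")$p_value, 1)
  expect_equal(fisher_exact(0, 10, 10, 0)$odds_ratio, 0)
  perfect <- fisher_exact(10, 0, 0, 10)
  expect_equal(perfect$odds_ratio, Inf)
  expect_equal(perfect$p_value, fisher_enum_oracle(10, 0, 0, 10, "two"))
  # degenerate margin
  expect_equal(fisher_exact(0, 0, 3, 4)$p_value, 1)
  expect_error(fisher_exact(1.5, 2, 3, 4), "integer")
})

test_that("one-sided p equals the direct hypergeometric tail sum", {
  got <- fisher_exact(8, 2, 2, 8, side = "right")$p_value
  tail_sum <- sum(dhyper(8:10, 10, 10, 10))
  expect_equal(got, tail_sum)
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(1:20, 1))
      adj <- bh_fdr(p)
      expect_equal(adj, bh_oracle(p))
      expect_true(all(adj >= p - 1e-12))
      perm <- sample(length(p))
      expect_equal(bh_fdr(p[perm]), adj[perm])
    }
  })
  # idempotent on flat-tail adjusted sequences (BH fixed points)
  adj <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_fdr(adj), adj)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher's method matches the chi-square closed form", {
  expect_equal(fisher_combine(0.2), 0.2)
  for (m in c(2, 5, 10)) {
    expect_equal(fisher_combine(rep(0.5, m)),
                 pchisq(-2 * m * log(0.5), 2 * m, lower.tail = FALSE))
  }
  # p = 1 contributes nothing but costs degrees of freedom
  expect_gte(fisher_combine(c(0.5, 1)), 0.5)
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clipped")
  expect_gt(out, 0)
})

test_that("knockdown DE enrichment recovers planted upregulation", {
  w <- tiny_world(seed = 20)
  de <- simulate_knockdown_de(w, effect_direction = 1,
                              frac_responsive = 0.8)
  targets <- w$planted_target_genes
  res <- kd_de_enrichment(targets, de, universe = w$genes$gene_id)
  expect_true(all(res$results$log2_or > 0))
  expect_lt(res$combined_p, 0.01)
  # oracle for one lncRNA's table
  L <- w$planted_nuclear[1]
  sub <- de[de$lncrna == L, ]
  de_up <- unique(sub$gene_id[sub$fdr <= 0.1 & sub$log2fc > 0])
  targ <- intersect(targets[[L]], w$genes$gene_id)
  nont <- setdiff(w$genes$gene_id, c(targ, L))
  a <- length(intersect(targ, de_up)); b <- length(targ) - a
  cc <- length(intersect(nont, de_up)); d <- length(nont) - cc
  expect_equal(res$results$p_value[res$results$lncrna == L],
               fisher_enum_oracle(a, b, cc, d, "right"))
})

test_that("knockdown battery exclusion and degenerate rules", {
  de <- tibble::tibble(
    lncrna = "L", aso = rep(c("ASO1", "ASO2"), each = 4),
    gene_id = rep(c("g1", "g2", "g3", "g4"), 2),
    log2fc = rep(c(2, 2, 0.1, 0.1), 2),
    fdr = rep(c(0.01, 0.05, 0.9, 0.9), 2))
  # two DE targets -> excluded from the headline summary
  res <- kd_de_enrichment(list(L = c("g1", "g2")), de,
                          universe = c("g1", "g2", "g3", "g4"))
  expect_false(res$results$included)
  # all FDR at 1 -> no DE genes -> degenerate table, combined p = 1
  de1 <- dplyr::mutate(de, fdr = 1)
  res1 <- kd_de_enrichment(list(L = c("g1", "g2")), de1,
                           universe = c("g1", "g2", "g3", "g4"))
  expect_equal(res1$results$a + res1$results$c, 0)
  expect_equal(res1$results$p_value, 1)
  expect_equal(res1$combined_p, 1)
})

test_that("GO enrichment follows the overlap and background rules", {
  targets <- list(L1 = c("g1", "g2", "g3", "g4"),
                  L2 = c("g5", "g6", "g7"))
  sets <- list(hit = c("g1", "g2", "g3", "g4"),
               partial = c("g1", "g2", "x1"),
               none = c("x2", "x3"))
  res <- go_enrichment(targets, sets)
  r1 <- res[res$lncrna == "L1", ]
  # term equal to the target set, disjoint background: closed-form p
  expect_equal(r1$p_value[r1$term == "hit"],
               fisher_enum_oracle(4, 0, 0, 3, "right"))
  expect_true(r1$significant[r1$term == "hit"])
  # overlap 2 is never significant even at tiny FDR
  expect_false(r1$significant[r1$term == "partial"])
  # zero-overlap terms are not tested
  expect_false("none" %in% r1$term)
})

test_that("GO enrichment weakens as term members join the background", {
  targets <- c("g1", "g2", "g3")
  term <- c("g1", "g2", "b1", "b2", "b3", "b4", "b5")
  p_small <- go_enrichment(list(L = targets, other = c("b1", "b2")),
                           list(t = term))
  p_large <- go_enrichment(list(L = targets,
                                other = c("b1", "b2", "b3", "b4", "b5")),
                           list(t = term))
  expect_gte(p_large$p_value[p_large$lncrna == "L"],
             p_small$p_value[p_small$lncrna == "L"])
})

test_that("TFBS battery excludes small target sets and combines correctly", {
  assignments <- tibble::tibble(
    region_id = rep(sprintf("r%02d", 1:20), 2),
    motif = rep(c("m1", "m2"), each = 20),
    assigned = c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 20)))
  all_regions <- sprintf("r%02d", 1:20)
  targets <- list(big = sprintf("r%02d", 1:6),
                  small = sprintf("r%02d", 1:4))
  tf <- tfbs_enrichment(assignments, targets, all_regions)
  expect_equal(tf$excluded, "small")
  expect_setequal(unique(tf$results$lncrna), "big")
  # combined p equals Fisher's method over the lncRNA's motifs
  ps <- tf$results$p_value[tf$results$lncrna == "big"]
  expect_equal(tf$combined$combined_p[tf$combined$lncrna == "big"],
               fisher_combine(ps))
  # motif present in every region: chi-square statistic 0
  chis <- tf$motif_chisq
  expect_equal(chis$statistic[chis$motif == "m2"], 0)
  expect_equal(chis$p_value[chis$motif == "m2"], 1)
})

test_that("Spearman correlations equal the rank-transform Pearson oracle", {
  withr::with_seed(6, {
    expr <- matrix(rnorm(10 * 18), nrow = 10,
                   dimnames = list(c("L", paste0("g", 1:9)), NULL))
  })
  res <- correlation_preference(expr, list(L = paste0("g", 1:9)),
                                pair_p_cut = 0.01)
  oracle_rho <- vapply(paste0("g", 1:9), function(g) {
    cor(rank(expr["L", ]), rank(expr[g, ]))
  }, numeric(1))
  expect_equal(res$mean_rho, mean(oracle_rho), tolerance = 1e-12)
  # strongly coupled targets -> positive category
  pos <- expr
  for (g in paste0("g", 1:9)) pos[g, ] <- pos["L", ] + rnorm(18, 0, 0.1)
  res_pos <- correlation_preference(pos, list(L = paste0("g", 1:9)))
  expect_equal(res_pos$category, "positive")
  # rhos symmetric around zero -> no preference
  sym <- expr
  sym["g1", ] <- sym["L", ]; sym["g2", ] <- -sym["L", ]
  res_sym <- correlation_preference(sym, list(L = c("g1", "g2")))
  expect_equal(res_sym$category, "none")
  # constant vector dropped with a count
  const <- expr; const["g1", ] <- 3
  res_c <- correlation_preference(const, list(L = paste0("g", 1:9)))
  expect_equal(res_c$n_dropped, 1)
})

test_that("eCLIP target filter applies strict and inclusive thresholds", {
  stats <- tibble::tibble(
    rbp = "R1",
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(0.5, 0.51, 2, 2),
    fdr = c(0.04, 0.05, 0.06, 0.01))
  sets <- eclip_target_filter(stats, lnc_ids = c("b", "d"),
                              min_lnc_targets = 2)
  # log2FC exactly 0.5 excluded (strict >); FDR exactly 0.05 included
  expect_setequal(sets$R1, c("b", "d"))

  # RBP with too few lncRNA targets is dropped
  sets2 <- eclip_target_filter(stats, lnc_ids = c("b", "d"),
                               min_lnc_targets = 15)
  expect_equal(length(sets2), 0)
  expect_equal(attr(sets2, "dropped"), "R1")

  big <- withr::with_seed(7, tibble::tibble(
    rbp = rep(c("R1", "R2"), each = 100),
    gene_id = rep(sprintf("g%03d", 1:100), 2),
    log2fc = rnorm(200, 0.5, 0.5), fdr = runif(200)))
  sets3 <- eclip_target_filter(big, lnc_ids = sprintf("g%03d", 1:50),
                               min_lnc_targets = 1)
  oracle <- big[big$fdr <= 0.05 & big$log2fc > 0.5, ]
  for (r in names(sets3)) {
    expect_setequal(sets3[[r]], oracle$gene_id[oracle$rbp == r])
  }
})

test_that("RBP batteries handle unbound worlds and planted N/C shifts", {
  lnc_targets <- list(L1 = c("g1", "g2"), L2 = c("g3", "g4"))
  # no RBP binds any lncRNA: contingency batteries empty, U-test undefined
  rbp_targets <- list(R1 = c("g1", "g9"))
  nc <- tibble::tibble(gene_id = c("L1", "L2"), nc_ratio = c(0.8, 0.3))
  out <- rbp_batteries(rbp_targets, lnc_targets,
                       rbp_kd_de = tibble::tibble(
                         rbp = "R1", gene_id = "g1", fdr = 0.01),
                       nc = nc)
  expect_equal(nrow(out$kd), 0)
  expect_true(is.na(out$nc_test$p_value))

  # planted shift: bound lncRNAs have higher N/C ratio
  withr::with_seed(8, {
    nc2 <- tibble::tibble(
      gene_id = sprintf("L%03d", 1:100),
      nc_ratio = pmin(1, pmax(0, c(rnorm(50, 0.7, 0.15),
                                   rnorm(50, 0.5, 0.15)))))
  })
  rbp2 <- list(R1 = sprintf("L%03d", 1:50))
  out2 <- rbp_batteries(rbp2, lnc_targets, nc = nc2)
  expect_lt(out2$nc_test$p_value, 0.05)
  oracle <- wilcox.test(nc2$nc_ratio[1:50], nc2$nc_ratio[51:100],
                        alternative = "greater")
  expect_equal(out2$nc_test$p_value, oracle$p.value)
})

test_that("PPI expansion uses a strict score threshold", {
  lnc_targets <- list(L1 = c("g1", "g2"))
  rbp_targets <- list(R1 = "L1")
  promoters <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                              promoter_id = paste0("p", 1:4))
  chip <- tibble::tibble(rbp = c("R1", "R2", "R3"),
                         promoter_id = c("p1", "p2", "p3"))
  ppi <- tibble::tibble(rbp_a = c("R1", "R1"), rbp_b = c("R2", "R3"),
                        score = c(0.41, 0.4))
  out <- rbp_batteries(rbp_targets, lnc_targets, chip = chip,
                       promoters = promoters, ppi = ppi)
  # R2 joins through PPI (0.41 > 0.4); R3 at exactly 0.4 does not
  row <- out$ppi[out$ppi$rbp == "R1" & out$ppi$lncrna == "L1", ]
  expect_equal(row$a, 2)   # p1 (own ChIP) + p2 (partner) among targets
})
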