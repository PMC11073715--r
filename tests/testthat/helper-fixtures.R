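# Shared fixtures and independent oracles used across the suite.

# Two chromosomes so that a trans-mRNA background always exists.
tiny_world <- function(seed = 7, ...) {
  generate_world(n_chrom = 2, chrom_len = 1e6, n_mrna = 40, n_lncrna = 6,
                 n_nuclear = 2, n_targets_per_lnc = 5, n_enhancers = 10,
                 seed = seed, ...)
}

# Hand-coded breadth-first search over an edge list (independent of igraph).
bfs_oracle <- function(edges, source) {
  nodes <- unique(c(edges$from, edges$to, source))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Hand step-up Benjamini-Hochberg, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail binomial p-value by direct summation of the pmf.
binom_tail_oracle <- function(x, n, p) {
  sum(dbinom(x:n, n, p))
}

# Exact Fisher p-values by full enumeration of tables with fixed margins.
fisher_enum_oracle <- function(a, b, c, d, side) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  probs <- probs / sum(probs)
  obs <- probs[match(a, support)]
  switch(side,
         right = sum(probs[support >= a]),
         left = sum(probs[support <= a]),
         two = sum(probs[probs <= obs * (1 + 1e-7)]))
}

# A random Hi-C table over one chromosome, mostly passing the filters.
random_hic_table <- function(n_bins = 50, n_edges = 80, seed = 1,
                             chrom = "chr1") {
  withr::with_seed(seed, {
    i <- sample.int(n_bins, n_edges, replace = TRUE) - 1L
    j <- sample.int(n_bins, n_edges, replace = TRUE) - 1L
    tibble::tibble(chrom = chrom, bin_i_start = i * 10000,
                   bin_j_start = j * 10000,
                   read_pairs = sample(1:30, n_edges, replace = TRUE),
                   q_value = runif(n_edges))
  })
}

# Assemble a binned-contact object directly from a per-(gene, bin) table.
make_binned <- function(counts, bin_size = 10000) {
  counts$bin <- bin_key(counts$chrom, counts$bin_start)
  if (is.null(counts$cis)) counts$cis <- TRUE
  if (is.null(counts$class)) counts$class <- "lncRNA"
  totals <- dplyr::summarise(dplyr::group_by(counts, gene_id),
                             n = sum(reads), .groups = "drop")
  structure(list(counts = counts, gene_totals = totals,
                 bin_size = bin_size), class = "lnct_binned")
}

make_background <- function(bins, p) {
  structure(tibble::tibble(bin = bins, p = p),
            class = c("lnct_background", "tbl_df", "tbl", "data.frame"))
}
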