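# Fixture builders and independent test oracles, all generated in code.

make_map_df <- function(map_id, lg, ids, pos, genes = ids,
                        type = "SNP") {
  data.frame(map_id = map_id, linkage_group = lg, marker_id = ids,
             gene_id = genes, marker_type = type, position_cM = pos,
             stringsAsFactors = FALSE)
}

make_map <- function(...) input_map(make_map_df(...))

# two collinear three-marker maps sharing all genes
collinear_pair <- function() {
  list(A = make_map("A", 1, c("x-1", "y-1", "z-1"), c(0, 10, 20),
                    c("x", "y", "z")),
       B = make_map("B", 1, c("x-2", "y-2", "z-2"), c(0, 20, 40),
                    c("x", "y", "z")))
}

# Kendall tau between a map's marker order and a reference order
order_tau <- function(ids_test, ids_ref) {
  shared <- intersect(ids_test, ids_ref)
  stats::cor(match(shared, ids_test), match(shared, ids_ref),
             method = "kendall")
}

# Weir-Cockerham two-population Fst estimator (multi-locus ratio of sums);
# independent oracle for the Balding-Nichols divergence parameter
wc_fst <- function(X, pop) {
  r <- 2
  n_i <- as.numeric(table(pop))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  num <- den <- 0
  for (j in seq_len(ncol(X))) {
    p_i <- tapply(X[, j], pop, mean) / 2
    h_i <- tapply(X[, j], pop, function(g) mean(g == 1))
    pbar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    num <- num + a
    den <- den + a + b + hbar / 2
  }
  num / den
}

# brute-force anchor oracle: enumerate one marker per spacing window and
# return the subset with maximal total GIC
anchor_oracle <- function(pos, gic, ids, spacing) {
  ord <- order(pos, ids)
  pos <- pos[ord]; gic <- gic[ord]; ids <- ids[ord]
  win <- integer(length(pos))
  w <- 1L; start <- pos[1]; win[1] <- 1L
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - start >= spacing) { w <- w + 1L; start <- pos[i] }
    win[i] <- w
  }
  choices <- split(seq_along(pos), win)
  grids <- do.call(expand.grid, choices)
  tot <- apply(grids, 1, function(rows) sum(gic[as.integer(rows)]))
  best <- as.integer(grids[which.max(tot), ])
  sort(ids[best])
}

# tiny CP genotype fixture: two testcross loci + one hkxhk locus
cp_fixture <- function() {
  calls <- cbind(
    L1 = c("ll", "lm", "ll", "lm", "lm", "ll"),
    L2 = c("nn", "np", "np", "nn", "np", "nn"),
    L3 = c("hh", "hk", "kk", "hk", "hh", "kk"))
  rownames(calls) <- paste0("i", 1:6)
  genotype_matrix(calls, dialect = "CP")
}
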