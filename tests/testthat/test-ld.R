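test_that("pedigree relationship matrix reproduces textbook coefficients", {
  ped <- pedigree(data.frame(
    id = c("s", "d", "d2", "kid1", "kid2", "half"),
    sire = c(NA, NA, NA, "s", "s", "s"),
    dam = c(NA, NA, NA, "d", "d", "d2"),
    cohort = "x"))
  A <- pedigree_relationship_matrix(ped)
  expect_equal(A["kid1", "kid2"], 0.5)    # full sibs
  expect_equal(A["kid1", "half"], 0.25)   # half sibs
  expect_equal(A["s", "d"], 0)            # founders unrelated
  expect_equal(A["s", "kid1"], 0.5)       # parent-offspring
  expect_equal(unname(diag(A)), rep(1, 6))
  expect_true(isSymmetric(A))
})

test_that("minor allele frequency handles ploidy and missingness", {
  expect_equal(minor_allele_frequency(c(0, 0, 1)), 1 / 6)
  expect_equal(minor_allele_frequency(c(2, 2, 2, 0)), 0.25)
  expect_equal(minor_allele_frequency(c(0, 0, 0)), 0)
  expect_equal(minor_allele_frequency(c(0, 1, 1, NA), ploidy = 1), 1 / 3)
  expect_true(is.na(minor_allele_frequency(c(NA, NA))))
})

test_that("r-squared matches hand-computed Pearson values", {
  expect_equal(r_squared(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(r_squared(c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)), 1)  # relabeling
  # manual covariance arithmetic: cov 3/5, var 4/5 each -> r2 = 0.5625
  a <- c(0, 0, 1, 1, 2, 2); b <- c(0, 1, 0, 1, 2, 2)
  expect_equal(r_squared(a, b), 0.5625)
  expect_equal(r_squared(a, 2 - b), 0.5625)
  expect_true(is.na(r_squared(c(0, 1), c(1, 0))))
  expect_true(is.na(r_squared(c(1, 1, 1, 1), c(0, 1, 0, 1))))
})

test_that("identity kinship and uninformative Q reduce to raw r-squared", {
  set.seed(60)
  a <- stats::rbinom(40, 2, 0.4); b <- stats::rbinom(40, 2, 0.3)
  raw <- r_squared(a, b)
  expect_equal(adjusted_r_squared(a, b, "kinship", V = diag(40)), raw,
               tolerance = 1e-10)
  Q <- matrix(0.5, 40, 2)
  expect_equal(adjusted_r_squared(a, b, "structure", Q = Q), raw,
               tolerance = 1e-10)
})

test_that("structure adjustment removes divergence-driven LD", {
  tm <- simulate_true_map(2, 30, 100, seed = 61)
  f <- simulate_founders(tm, K = 2, F_div = 0.3, n_per_subpop = 80,
                         seed = 62)
  X <- t(vapply(f$haplotypes, rowSums, numeric(nrow(tm))))
  # unlinked pair (different LGs) with divergent frequencies
  i <- which(tm$linkage_group == 1)[1:15]
  j <- which(tm$linkage_group == 2)[1:15]
  raw <- adj <- c()
  for (k in 1:15) {
    raw <- c(raw, r_squared(X[, i[k]], X[, j[k]]))
    adj <- c(adj, adjusted_r_squared(X[, i[k]], X[, j[k]], "structure",
                                     Q = f$Q))
  }
  expect_lt(mean(adj, na.rm = TRUE), mean(raw, na.rm = TRUE))
})

test_that("kinship whitening shrinks family-driven LD between LGs", {
  tm <- simulate_true_map(2, 25, 100, seed = 63)
  ped <- simulate_pedigree("circular_multifamily", n_parents = 10,
                           n_families = 10, n_progeny = 120)
  f <- simulate_founders(tm, 1, 0, 10, seed = 64, ids = paste0("P", 1:10))
  gm <- drop_genotypes(tm, ped, f, seed = 65)
  A <- pedigree_relationship_matrix(ped)[gm$individuals, gm$individuals]
  X <- dosage(gm)
  i <- which(tm$linkage_group == 1)[1:12]
  j <- which(tm$linkage_group == 2)[1:12]
  raw <- adj <- c()
  for (k in 1:12) {
    raw <- c(raw, r_squared(X[, i[k]], X[, j[k]]))
    adj <- c(adj, adjusted_r_squared(X[, i[k]], X[, j[k]], "kinship",
                                     V = A))
  }
  expect_lt(mean(adj, na.rm = TRUE), mean(raw, na.rm = TRUE))
})

test_that("ld_pair_table classifies pairs and nests MAF strata", {
  tm <- simulate_true_map(2, 20, 60, prop_multi_snp = 0.3, seed = 66)
  ped <- simulate_pedigree("single_fullsib", n_progeny = 80)
  f <- simulate_founders(tm, 1, 0, 2, seed = 67, ids = c("P1", "P2"))
  gm <- drop_genotypes(tm, ped, f, seed = 68)
  cm <- list(map = data.frame(linkage_group = tm$linkage_group,
                              marker = tm$marker_id,
                              position_cM = tm$position_cM))
  class(cm) <- "consensus_map"
  lt <- ld_pair_table(gm, cm, adjustment = "none")
  p <- lt$pairs
  # class consistency with positions
  wg <- p[p$class == "within_gene", ]
  expect_true(all(wg$gene_a == wg$gene_b))
  lt1 <- p[p$class == "within_LG_lt1cM", ]
  expect_true(all(lt1$distance_cM < 1 & lt1$gene_a != lt1$gene_b))
  ge1 <- p[p$class == "within_LG_ge1cM", ]
  expect_true(all(ge1$distance_cM >= 1))
  bw <- p[p$class == "between_LG", ]
  expect_true(all(bw$lg_a != bw$lg_b))
  # same-gene pairs never enter the distance-classed table
  tab <- lt$table
  expect_equal(sum(tab$n_pairs[tab$maf_threshold == 0.001]),
               sum(!p$class %in% c("within_gene", "unmapped") &
                     p$maf_a > 0.001 & p$maf_b > 0.001))
  # counts shrink as the MAF threshold rises (subset property)
  for (cl in unique(tab$class)) {
    cnt <- tab$n_pairs[tab$class == cl][order(unique(tab$maf_threshold))]
    expect_true(all(diff(cnt) <= 0))
    hits <- tab$n_raw_gt[tab$class == cl][order(unique(tab$maf_threshold))]
    expect_true(all(diff(hits) <= 0))
  }
  # r2 range sanity
  expect_true(all(p$r2_raw >= 0 & p$r2_raw <= 1 + 1e-12, na.rm = TRUE))
})

test_that("unmapped loci are excluded from classes but kept as records", {
  X <- matrix(rbinom(200, 2, 0.5), 50, 4,
              dimnames = list(NULL, c("a-1", "b-1", "c-1", "zz-1")))
  gm <- genotype_matrix(X, dialect = "dosage")
  cm <- list(map = data.frame(linkage_group = 1, marker = c("a", "b", "c"),
                              position_cM = c(0, 0.5, 5)))
  class(cm) <- "consensus_map"
  lt <- ld_pair_table(gm, cm)
  expect_equal(sum(lt$pairs$class == "unmapped"), 3)  # zz against a, b, c
  expect_false(any(lt$table$class == "unmapped"))
})

test_that("matrix-path adjusted r2 equals the per-pair computation", {
  set.seed(69)
  n <- 30
  X <- matrix(stats::rbinom(n * 4, 2, 0.5), n, 4,
              dimnames = list(NULL, paste0("g", 1:4, "-1")))
  V <- crossprod(matrix(stats::rnorm(n * n), n)) / n + diag(n)
  V <- V / mean(diag(V))
  gm <- genotype_matrix(X, dialect = "dosage")
  cm <- list(map = data.frame(linkage_group = 1, marker = paste0("g", 1:4),
                              position_cM = c(0, 2, 4, 6)))
  class(cm) <- "consensus_map"
  lt <- ld_pair_table(gm, cm, adjustment = "kinship", V = V)
  for (r in seq_len(nrow(lt$pairs))) {
    i <- lt$pairs$locus_a[r]; j <- lt$pairs$locus_b[r]
    expect_equal(lt$pairs$r2_adjusted[r],
                 adjusted_r_squared(X[, i], X[, j], "kinship", V = V),
                 tolerance = 1e-8)
  }
})

test_that("singular structure designs raise an advisory error", {
  a <- c(0, 1, 2, 1, 0, 2)
  Q <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1),
             c(0, 0, 0, 0, 0, 0))
  # K columns + intercept with a redundant column: drop and proceed
  expect_no_error(adjusted_r_squared(a, rev(a), "structure", Q = Q))
})

test_that("decay regression is flat for constant r2 and order-invariant", {
  set.seed(70)
  pairs <- data.frame(distance_cM = stats::runif(50, 0, 30),
                      r2_raw = 0.3)
  dr <- ld_decay_regression(pairs)
  expect_true(all(abs(dr$r2_smooth - 0.3) < 1e-12, na.rm = TRUE))
  sh <- pairs[sample(nrow(pairs)), ]
  expect_equal(ld_decay_regression(sh), dr)
  expect_error(ld_decay_regression(pairs[1:5, ]), ">= 10")
})

test_that("decay regression is non-increasing from near to far in pedigrees", {
  tm <- simulate_true_map(1, 40, 100, seed = 71)
  ped <- simulate_pedigree("circular_multifamily", n_parents = 8,
                           n_families = 8, n_progeny = 120)
  f <- simulate_founders(tm, 1, 0, 8, seed = 72, ids = paste0("P", 1:8))
  gm <- drop_genotypes(tm, ped, f, seed = 73)
  cm <- list(map = data.frame(linkage_group = tm$linkage_group,
                              marker = tm$marker_id,
                              position_cM = tm$position_cM))
  class(cm) <- "consensus_map"
  lt <- ld_pair_table(gm, cm)
  dr <- ld_decay_regression(lt, bandwidth_cM = 10)
  near <- mean(dr$r2_smooth[dr$distance_cM <= 1], na.rm = TRUE)
  far <- mean(dr$r2_smooth[dr$distance_cM >= 50], na.rm = TRUE)
  expect_gt(near, far)
})

test_that("extended-LD critical value recovers a known beta quantile", {
  expect_equal(extended_ld_critical_value(stats::rbeta(135, 2, 8), 558,
                                          alpha = 0.05)$per_test_level,
               0.05 / 558)
  set.seed(1)
  x <- stats::rbeta(135, 2, 8)
  cv <- extended_ld_critical_value(x, 558)
  expect_lt(abs(cv$critical_value - stats::qbeta(1 - 0.05 / 558, 2, 8)),
            0.02)
  expect_lte(cv$empirical_max, 1)
  # n_tests = 1 reduces to the plain upper quantile
  cv1 <- extended_ld_critical_value(x, 1)
  expect_equal(cv1$critical_value,
               stats::qbeta(0.95, cv1$shape1, cv1$shape2))
  expect_error(extended_ld_critical_value(x[1:10], 10), ">= 20")
  expect_error(extended_ld_critical_value(rep(0.5, 30), 10), "variance")
})
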