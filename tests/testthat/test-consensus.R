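test_that("marker names normalize to gene-level merge keys", {
  expect_equal(normalize_marker_name("UMN_1234-567"), "UMN_1234")
  expect_equal(normalize_marker_name("PtSIFG_0345"), "PtSIFG_0345")
  expect_equal(normalize_marker_name(c("X-101", "X-222")), c("X", "X"))
  expect_equal(normalize_marker_name("0_8898_01-438"), "0_8898_01")
})

test_that("shared markers match by key and LG, reporting cross-LG hits", {
  a <- make_map("A", 1, c("x-1", "y-1"), c(0, 5), c("x", "y"))
  b <- make_map("B", 1, c("p-1", "q-1"), c(0, 5), c("p", "q"))
  expect_equal(nrow(shared_markers(a, b)$pairs), 0)
  expect_equal(nrow(shared_markers(a, a)$pairs), 2)

  b2 <- input_map(make_map_df("B", c(1, 2), c("x-2", "y-2"), c(0, 5),
                              c("x", "y")))
  sm <- shared_markers(a, b2)
  expect_equal(sm$pairs$key, "x")
  expect_equal(sm$cross_lg$key, "y")

  tm <- simulate_true_map(2, 40, 100, seed = 40)
  maps <- realize_input_maps(tm, c("A", "B"), 0.4, 0, 1,
                             shared_quota = 50, seed = 41)
  sm2 <- shared_markers(maps$A, maps$B)
  planted <- intersect(maps$A$marker_id, maps$B$marker_id)
  expect_equal(nrow(sm2$pairs), length(unique(normalize_marker_name(planted))))
})

test_that("merging identical maps is a fixed point", {
  m <- collinear_pair()$A
  cm <- merge_maps(list(A = m, B = m), c(A = 0.7, B = 0.3))
  expect_equal(cm$map$marker, c("x", "y", "z"))
  expect_equal(cm$map$position_cM, c(0, 10, 20))
  expect_equal(nrow(cm$conflicts), 0)
  expect_true(all(cm$map$in_A & cm$map$in_B))
})

test_that("consensus distances are weight-weighted means of input distances", {
  # single shared interval: 10 cM (w 0.75) and 20 cM (w 0.25) -> 12.5 cM
  a <- make_map("A", 1, c("u-1", "v-1"), c(0, 10), c("u", "v"))
  b <- make_map("B", 1, c("u-2", "v-2"), c(0, 20), c("u", "v"))
  cm <- merge_maps(list(A = a, B = b), c(A = 0.75, B = 0.25))
  expect_equal(cm$map$position_cM, c(0, 12.5))

  # property: every pair adjacent in all inputs gets the weighted mean
  p <- collinear_pair()   # distances (10,10) vs (20,20)
  w <- c(A = 0.6, B = 0.4)
  cm2 <- merge_maps(p, w)
  expect_equal(diff(cm2$map$position_cM), rep(0.6 * 10 + 0.4 * 20, 2))
})

test_that("minimum-weight occurrence deletion matches brute force", {
  # two maps order A<B (weights 0.4, 0.35), one orders B<A (0.25):
  # exhaustive enumeration says delete the single 0.25 occurrence
  m1 <- make_map("M1", 1, c("A-1", "B-1"), c(0, 5), c("A", "B"))
  m2 <- make_map("M2", 1, c("A-2", "B-2"), c(0, 6), c("A", "B"))
  m3 <- make_map("M3", 1, c("B-3", "A-3"), c(0, 5), c("B", "A"))
  cm <- merge_maps(list(M1 = m1, M2 = m2, M3 = m3),
                   c(M1 = 0.4, M2 = 0.35, M3 = 0.25))
  expect_equal(cm$map$marker, c("A", "B"))
  expect_equal(nrow(cm$conflicts), 1)
  expect_equal(cm$conflicts$weight_deleted, 0.25)
  expect_equal(cm$conflicts$method, "exact")
  expect_match(cm$conflicts$deleted, "^M3:")

  # a two-occurrence deletion of total weight 0.4 must beat the single
  # 0.5 deletion: the search is over total weight, not deletion count
  m4 <- make_map("M4", 1, c("A-4", "B-4"), c(0, 5), c("A", "B"))
  m5 <- make_map("M5", 1, c("B-5", "A-5"), c(0, 5), c("B", "A"))
  m6 <- make_map("M6", 1, c("B-6", "A-6"), c(0, 5), c("B", "A"))
  cm2 <- merge_maps(list(M4 = m4, M5 = m5, M6 = m6),
                    c(M4 = 0.6, M5 = 0.2, M6 = 0.2))
  expect_equal(cm2$map$marker, c("A", "B"))
  expect_equal(cm2$conflicts$weight_deleted, 0.4)
})

test_that("mutually collinear maps merge with perfect order agreement", {
  tm <- simulate_true_map(2, 30, 100, seed = 42)
  maps <- realize_input_maps(tm, c("A", "B", "C"), c(0.8, 0.7, 0.9),
                             0, c(1, 1.3, 0.8), shared_quota = 25,
                             seed = 43)
  cm <- merge_maps(maps, c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(nrow(cm$conflicts), 0)
  for (nm in names(maps)) {
    for (lg in 1:2) {
      cons <- cm$map[cm$map$linkage_group == lg, ]
      im <- maps[[nm]][maps[[nm]]$linkage_group == lg, ]
      tau <- order_tau(normalize_marker_name(im$marker_id), cons$marker)
      expect_equal(tau, 1)
    }
  }
  # conservation audit: all union keys survive a conflict-free merge
  all_keys <- unique(normalize_marker_name(
    unlist(lapply(maps, `[[`, "marker_id"))))
  expect_equal(nrow(cm$map), length(all_keys))
  expect_equal(length(cm$dropped), 0)
})

test_that("consensus positions are monotone and anchored at zero", {
  tm <- simulate_true_map(2, 40, 100, seed = 44)
  maps <- realize_input_maps(tm, c("A", "B", "C"), 0.8, 1.5, 1,
                             shared_quota = 30, seed = 45)
  cm <- merge_maps(maps, c(A = 0.4, B = 0.35, C = 0.25))
  for (lg in unique(cm$map$linkage_group)) {
    pos <- cm$map$position_cM[cm$map$linkage_group == lg]
    expect_equal(pos[1], 0)
    expect_true(all(diff(pos) >= -1e-9))
  }
  # every surviving marker is present in at least one input map
  pres <- as.matrix(cm$map[, grep("^in_", names(cm$map))])
  expect_true(all(rowSums(pres) >= 1))
})

test_that("merging noisy maps recovers order as well as the inputs do", {
  # the consensus order clearly beats the average input and effectively
  # ties the best one (strict dominance does not hold in general)
  for (sd in c(46, 100)) {
    tm <- simulate_true_map(1, 50, 100, seed = sd)
    maps <- realize_input_maps(tm, c("A", "B", "C"), 0.9, 2, 1,
                               shared_quota = 40, seed = sd + 1)
    cm <- merge_maps(maps, c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
    truth_keys <- normalize_marker_name(tm$marker_id)
    tau_cons <- order_tau(cm$map$marker, truth_keys)
    tau_inputs <- vapply(maps, function(m)
      order_tau(normalize_marker_name(m$marker_id), truth_keys),
      numeric(1))
    expect_gt(tau_cons, mean(tau_inputs))
    expect_gte(tau_cons, max(tau_inputs) - 0.02)
  }
})

test_that("single-map linkage groups pass through unchanged", {
  a <- make_map("A", 1, c("x-1", "y-1"), c(0, 7), c("x", "y"))
  b <- input_map(make_map_df("B", 2, c("p-1", "q-1"), c(3, 9),
                             c("p", "q")))
  expect_message(cm <- merge_maps(list(A = a, B = b), c(A = 0.5, B = 0.5)),
                 "single map")
  lg2 <- cm$map[cm$map$linkage_group == 2, ]
  expect_equal(lg2$marker, c("p", "q"))
  expect_equal(lg2$position_cM, c(0, 6))   # re-anchored at 0
})

test_that("replicate CIs are zero without noise and grow with it", {
  tm <- simulate_true_map(1, 20, 80, seed = 48)
  maps <- realize_input_maps(tm, c("A", "B"), 0.9, 0.5, 1,
                             shared_quota = 14, seed = 49)
  w <- c(A = 0.6, B = 0.4)
  pu0 <- position_uncertainty(maps, w, n_reps = 10, noise_sd = 0, seed = 1)
  expect_true(all(pu0$ci$ci_half == 0, na.rm = TRUE))
  pu1 <- position_uncertainty(maps, w, n_reps = 10, noise_sd = 0.05,
                              seed = 1)
  pu2 <- position_uncertainty(maps, w, n_reps = 10, noise_sd = 0.3,
                              seed = 1)
  expect_gt(pu2$genome_mean_ci, pu1$genome_mean_ci)
  expect_gt(pu1$genome_mean_ci, 0)
})

test_that("order RMSE is computed on the standardized 0-100 scale", {
  cons <- data.frame(linkage_group = 1, marker = c("a", "b", "c", "d"),
                     position_cM = c(0, 30, 60, 90))
  im_same <- make_map("I", 1, c("a-1", "b-1", "c-1", "d-1"),
                      c(0, 30, 60, 90), c("a", "b", "c", "d"))
  expect_equal(rmse_order_agreement(cons, im_same)$rmse_standardized, 0)

  # one marker displaced by 10 standardized units -> RMSE sqrt(100/4) = 5
  im_disp <- make_map("I", 1, c("a-1", "b-1", "c-1", "d-1"),
                      c(0, 30 + 9, 60, 90), c("a", "b", "c", "d"))
  r <- rmse_order_agreement(cons, im_disp)
  expect_equal(r$rmse_standardized, 5)

  # merged consensus agrees with collinear inputs at least as well as the
  # inputs agree with each other
  p <- collinear_pair()
  cm <- merge_maps(p, c(A = 0.5, B = 0.5))
  r_a <- rmse_order_agreement(cm, p$A)$rmse_standardized
  r_b <- rmse_order_agreement(cm, p$B)$rmse_standardized
  cross <- rmse_order_agreement(
    data.frame(linkage_group = 1, marker = c("x", "y", "z"),
               position_cM = p$A$position_cM), p$B)$rmse_standardized
  expect_lte(max(r_a, r_b), cross + 1e-9)
})

test_that("map summaries report lengths, spacing, and gaps", {
  df <- data.frame(linkage_group = 1, position_cM = c(0, 10))
  s <- map_summary(df)
  expect_equal(s$length_cM[1], 10)
  expect_equal(s$avg_spacing_cM[1], 10)
  expect_equal(s$max_spacing_cM[1], 10)
  s2 <- map_summary_from_counts(c(305, 279), c(184.89, 202.48))
  expect_equal(round(s2$avg_spacing_cM[1:2], 2), c(0.61, 0.73))
})
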