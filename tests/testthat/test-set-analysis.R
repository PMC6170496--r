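# Shared-DMP algebra, dose intensity, removal re-clustering, lability
# overlap, cross-experiment overlap.

mk_set <- function(pos, dir, delta = NA_real_, label = "x") {
  dmp_set(data.frame(chrom = "Chr1", pos = pos, direction = dir,
                     delta = delta, stringsAsFactors = FALSE), label)
}

test_that("direction-aware intersection implements the shared/opposite rule", {
  a <- mk_set(c(1, 2, 3), c("hyper", "hypo", "hyper"), label = "A")
  b <- mk_set(c(2, 3, 4), c("hypo", "hypo", "hyper"), label = "B")
  s <- intersect_dmps(a, b)
  expect_equal(sort(s$shared$pos), 2)
  expect_equal(sort(s$a_only$pos), c(1, 3))
  expect_equal(sort(s$b_only$pos), c(3, 4))
  expect_equal(s$counts$section_sum, 4)
  expect_equal(s$counts$n_opposite, 1)
  expect_equal(s$counts$unique_union, 3)

  # disjoint sets
  s2 <- intersect_dmps(mk_set(1:3, rep("hyper", 3)), mk_set(4:6, rep("hypo", 3)))
  expect_equal(s2$counts$n_shared, 0)
  expect_equal(s2$counts$unique_union, 6)

  # identical sets
  s3 <- intersect_dmps(a, a)
  expect_equal(nrow(s3$shared), 3)
  expect_equal(s3$counts$section_sum, 0)
})

test_that("the shared-summary partition law holds on random sets", {
  set.seed(14)
  for (i in 1:25) {
    na <- sample(5:60, 1); nb <- sample(5:60, 1)
    a <- mk_set(sample(1:80, na), sample(c("hyper", "hypo"), na, TRUE), label = "A")
    b <- mk_set(sample(1:80, nb), sample(c("hyper", "hypo"), nb, TRUE), label = "B")
    s <- intersect_dmps(a, b)
    expect_equal(s$counts$unique_union, s$counts$section_sum - s$counts$n_opposite)
    expect_equal(s$counts$n_shared + s$counts$unique_union,
                 length(unique(c(paste(a$chrom, a$pos), paste(b$chrom, b$pos)))))
    # bookkeeping symmetric under argument swap
    sw <- intersect_dmps(b, a)
    expect_equal(sw$counts$n_shared, s$counts$n_shared)
    expect_equal(sw$counts$n_a_only, s$counts$n_b_only)
    expect_equal(sw$counts$n_b_only, s$counts$n_a_only)
    expect_equal(sw$counts$n_opposite, s$counts$n_opposite)
  }
})

test_that("dose intensity applies the signed 20-point rule per direction", {
  tab <- data.frame(
    direction = c("hyper", "hyper", "hypo", "hypo", "hyper"),
    delta_low = c(15, 30, -15, -40, 10),
    delta_high = c(40, 30, -40, -15, NA))
  d <- dose_intensity(tab, threshold = 20)
  expect_equal(d$counts$hyper_high, 1)   # +15 -> +40
  expect_equal(d$counts$hypo_high, 1)    # -15 -> -40
  expect_equal(d$counts$hypo_low, 1)     # -40 -> -15 mirrored
  expect_equal(d$counts$hyper_low, 0)
  expect_equal(d$counts$neither, 1)      # equal deltas
  expect_equal(d$counts$excluded_missing, 1)
})

test_that("an additive 3:1 dose effect yields far more SSS-pronounced DMPs", {
  sim <- small_study(seed = 17, n_cg = 3000, n_resp = 400)
  u <- study_united(sim)
  d_smm <- call_dmps(u, "SMM", "MMM")
  d_sss <- call_dmps(u, "SSS", "MMM")
  s <- add_partner_deltas(
    intersect_dmps(as_dmp_set(d_smm, "SMM"), as_dmp_set(d_sss, "SSS")),
    as_dmp_set(d_sss, "SSS"))
  di <- dose_intensity(s, threshold = 20)
  high <- di$counts$hyper_high + di$counts$hypo_high
  low <- di$counts$hyper_low + di$counts$hypo_low
  expect_gt(high, 0)
  expect_gt(high / max(low, 1), 5)
})

test_that("shared-DMP recovery increases with effect size", {
  shared_n <- vapply(c(0.05, 0.15), function(ds) {
    sim <- small_study(seed = 23, n_cg = 1500, n_resp = 300, delta_stress = ds)
    u <- study_united(sim)
    s <- intersect_dmps(as_dmp_set(call_dmps(u, "SMM", "MMM"), "SMM"),
                        as_dmp_set(call_dmps(u, "SSS", "MMM"), "SSS"))
    s$counts$n_shared
  }, 1)
  expect_gt(shared_n[2], shared_n[1])
})

test_that("removal bookkeeping separates removable from absent positions", {
  idx <- data.frame(chrom = "Chr1", pos = 1:100)
  rem <- data.frame(chrom = "Chr1", pos = c(1:20, 200:204))
  acc <- removal_accounting(idx, rem)
  expect_equal(acc$n_before, 100)
  expect_equal(acc$n_removed, 20)
  expect_equal(acc$n_absent, 5)
  expect_equal(acc$n_after, 80)
})

test_that("removing the responsive set destroys the treatment clade; a random set does not", {
  sim <- small_study(seed = 29, design = c(M1 = "MMM", M2 = "MMM",
                                           S1 = "SSS", S2 = "SSS"),
                     n_cg = 2500, n_resp = 300)
  u <- study_united(sim)
  treat <- grep("^S", u$design$sample, value = TRUE)
  resp <- sim$truth$responsive

  rr <- removal_reclustering(u, resp, treat, nboot = 150, seed = 5)
  expect_true(supported_clade(rr$verdict_before))
  expect_false(supported_clade(rr$verdict_after))
  expect_equal(rr$n_removed + rr$n_absent, nrow(resp))

  # equally sized random non-responsive removal keeps the clade
  set.seed(31)
  pool <- setdiff(sim$truth$classes$pos, resp$pos)
  rand <- data.frame(chrom = "Chr1", pos = sample(pool, nrow(resp)))
  rr2 <- removal_reclustering(u, rand, treat, nboot = 150, seed = 5)
  expect_true(supported_clade(rr2$verdict_after))

  # removing nothing reproduces the original tree
  rr0 <- removal_reclustering(u, resp[0, ], treat, nboot = 120, seed = 5)
  expect_equal(methTAR:::edge_keys(rr0$before$edges),
               methTAR:::edge_keys(rr0$after$edges))
  expect_equal(rr0$before$bp, rr0$after$bp)
})

test_that("lability overlap matches hypergeometric enumeration", {
  classes <- data.frame(chrom = "Chr1", pos = 1:200,
                        class = rep(c("labile", "stable"), each = 100))
  # extreme table: all-labile set vs all-stable comparator
  s_lab <- mk_set(1:30, rep("hypo", 30))
  s_sta <- mk_set(101:130, rep("hypo", 30))
  ov <- lability_overlap(s_lab, classes, s_sta)
  expect_lt(ov$p, 1e-10)
  expect_gt(ov$odds_ratio, 1)

  # identical composition -> no shift
  ov2 <- lability_overlap(s_lab, classes, s_lab)
  expect_equal(ov2$p, 1)

  # [[30,10],[15,25]] against full enumeration of the 2x2 hypergeometric
  s1 <- mk_set(c(1:30, 101:110), rep("hypo", 40))
  s2 <- mk_set(c(31:45, 111:135), rep("hypo", 40))
  ov3 <- lability_overlap(s1, classes, s2)
  expect_equal(unname(ov3$table2x2[1, ]), c(30, 10))
  expect_equal(unname(ov3$table2x2[2, ]), c(15, 25))
  enum <- fisher_enum_oracle(matrix(c(30, 10, 15, 25), 2, byrow = TRUE))
  expect_equal(ov3$p, enum, tolerance = 1e-9)
  expect_error(lability_overlap(s1, classes, s2[0, ]), "empty comparator")
})

test_that("simulated stress DMPs are enriched for labile positions", {
  sim <- small_study(seed = 37, n_cg = 3000, n_resp = 300)
  u <- study_united(sim)
  tar <- as_dmp_set(call_dmps(u, "SSS", "MMM"), "SSS")
  # comparator: equally sized draw from the genome background
  set.seed(38)
  bg_pos <- sample(sim$truth$classes$pos, 300)
  bg <- mk_set(bg_pos, rep("hypo", 300), label = "background")
  ov <- lability_overlap(tar, sim$truth$classes, bg)
  expect_gt(ov$odds_ratio, 1)
  expect_lt(ov$p, 0.05)
})

test_that("cross-experiment overlap reports counts and half-up percentages", {
  a <- mk_set(1:4, c("hyper", "hyper", "hyper", "hypo"), label = "exp1")
  b <- mk_set(c(1, 2, 4, 9), c("hyper", "hypo", "hypo", "hyper"), label = "exp2")
  ov <- cross_experiment_overlap(a, b)
  expect_equal(ov$n_overlap, 2)   # pos 1 (hyper) and pos 4 (hypo)
  expect_equal(ov$pct_a, 50)
  expect_equal(ov$pct_b, 50)
  expect_equal(cross_experiment_overlap(a, a)$pct_a, 100)
  d <- cross_experiment_overlap(mk_set(1:3, rep("hyper", 3)),
                                mk_set(7:9, rep("hyper", 3)))
  expect_equal(d$n_overlap, 0)
  expect_equal(d$pct_b, 0)
})
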