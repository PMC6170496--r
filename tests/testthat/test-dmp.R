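# Differential methylation testing: dispersion estimation, both backends,
# BH adjustment, DMP calling error control/power, DMR segmentation.

test_that("dispersion estimation has the right limits and recovers a known phi", {
  # identical proportions across replicates at high coverage -> raw phi ~ 0
  n <- 50
  M <- matrix(rep(c(50, 50, 50, 10, 10, 10), each = n), n)
  C <- matrix(100, n, 6)
  u <- united_table(data.frame(chrom = "c", pos = 1:n), M, C,
                    rep(c("a", "b"), each = 3))
  d <- estimate_dispersion(u, "a", "b")
  expect_true(all(d$phi_raw < 0.02))
  expect_true(all(d$phi >= 0))

  # identical data at every position -> zero prior variance -> shrunk = raw
  expect_equal(d$phi, rep(d$phi[1], n))
  expect_equal(d$phi[1], d$prior$mean, tolerance = 1e-6)

  # shrunk estimate lies between raw and the prior mean
  u2 <- sim_united(runif(500, .2, .8), runif(500, .2, .8), phi = 0.1, seed = 2)
  d2 <- estimate_dispersion(u2, "t", "c")
  ok <- !is.na(d2$phi_raw)
  lo <- pmin(d2$phi_raw[ok], d2$prior$mean) - 1e-9
  hi <- pmax(d2$phi_raw[ok], d2$prior$mean) + 1e-9
  expect_true(all(d2$phi[ok] >= lo & d2$phi[ok] <= hi))
})

test_that("mean shrunk dispersion recovers the generative phi within 0.02", {
  set.seed(13)
  n <- 5000; reps <- 4
  C <- matrix(rnbinom(n * 2 * reps, mu = 30, size = 3), n) + 1
  p0 <- runif(n, 0.1, 0.9)
  M <- matrix(rbb(length(C), as.vector(C), rep(p0, 2 * reps), 0.1), n)
  u <- united_table(data.frame(chrom = "c", pos = 1:n), M, C,
                    rep(c("a", "b"), each = reps))
  d <- estimate_dispersion(u, "a", "b")
  expect_lt(abs(mean(d$phi) - 0.1), 0.02)
})

test_that("the Wald test matches the closed-form z statistic on the toy table", {
  trt <- data.frame(M = c(9, 8), C = c(10, 10))
  ctl <- data.frame(M = c(1, 2), C = c(10, 10))
  r <- test_position(trt, ctl, phi = 0)
  # hand-computed: p_t = 17/20, p_c = 3/20, var = p(1-p)/20 each
  p_t <- 17 / 20; p_c <- 3 / 20
  se <- sqrt(p_t * (1 - p_t) / 20 + p_c * (1 - p_c) / 20)
  expect_equal(r$delta, 0.7)
  expect_equal(r$stat, 0.7 / se)
  expect_equal(r$p, 2 * pnorm(-0.7 / se))

  # identical groups
  r0 <- test_position(data.frame(M = 5, C = 10), data.frame(M = 5, C = 10))
  expect_equal(r0$delta, 0)
  expect_equal(r0$p, 1)
  expect_error(test_position(data.frame(M = 0, C = 0), ctl), "zero total")
})

test_that("with phi = 0 the Wald test equals the two-proportion z-test on pooled counts", {
  set.seed(21)
  for (i in 1:20) {
    Mt <- rbinom(3, 20, 0.6); Mc <- rbinom(3, 20, 0.4)
    r <- test_position(data.frame(M = Mt, C = 20), data.frame(M = Mc, C = 20), phi = 0)
    pt <- sum(Mt) / 60; pc <- sum(Mc) / 60
    if (pt %in% c(0, 1) || pc %in% c(0, 1)) next
    z <- (pt - pc) / sqrt(pt * (1 - pt) / 60 + pc * (1 - pc) / 60)
    expect_equal(r$stat, z, tolerance = 1e-12)
  }
})

test_that("the logistic backend agrees with the Wald backend", {
  trt <- data.frame(M = c(9, 8), C = c(10, 10))
  ctl <- data.frame(M = c(1, 2), C = c(10, 10))
  rl <- test_position_logistic(trt, ctl)
  rw <- test_position(trt, ctl, phi = 0)
  expect_equal(rl$delta, rw$delta)
  # cross-backend p agreement on the evidence (log) scale
  expect_lt(abs(log10(rl$p) - log10(rw$p)) / abs(log10(rw$p)), 0.10)

  # identical groups -> p = 1
  r0 <- test_position_logistic(data.frame(M = c(5, 5), C = c(10, 10)),
                               data.frame(M = c(5, 5), C = c(10, 10)))
  expect_equal(r0$p, 1)

  # the scale factor is the Pearson chi-square over df
  trt2 <- data.frame(M = c(9, 3), C = c(12, 12))
  ctl2 <- data.frame(M = c(2, 6), C = c(12, 12))
  r2 <- test_position_logistic(trt2, ctl2)
  fit <- glm(cbind(M, C - M) ~ g,
             data = data.frame(M = c(9, 3, 2, 6), C = 12,
                               g = c("t", "t", "c", "c")),
             family = binomial())
  expect_equal(r2$scale, sum(residuals(fit, "pearson")^2) / 2, tolerance = 1e-8)

  # separation handled without degenerate p
  rs <- test_position_logistic(data.frame(M = c(10, 10), C = c(10, 10)),
                               data.frame(M = c(0, 0), C = c(10, 10)))
  expect_gt(rs$p, 0)
  expect_lt(rs$p, 0.05)
})

test_that("backends agree in direction and mostly in significance on a panel", {
  set.seed(31)
  n <- 1000; reps <- 3
  C <- matrix(rnbinom(n * 2 * reps, mu = 20, size = 3), n) + 1
  p0 <- runif(n, 0.1, 0.9)
  p1 <- p0
  p1[1:150] <- pmin(0.95, pmax(0.05, p0[1:150] + sample(c(-1, 1), 150, TRUE) * 0.35))
  M <- cbind(matrix(rbb(n * reps, as.vector(C[, 1:reps]), rep(p1, reps), 0.05), n),
             matrix(rbb(n * reps, as.vector(C[, 4:6]), rep(p0, reps), 0.05), n))
  u <- united_table(data.frame(chrom = "c", pos = 1:n), M, C,
                    rep(c("t", "c"), each = reps))
  dw <- call_dmps(u, "t", "c", backend = "wald")
  dl <- call_dmps(u, "t", "c", backend = "logistic")
  expect_true(all(sign(dw$delta) == sign(dl$delta)))
  expect_gte(mean(dw$significant == dl$significant), 0.95)
})

test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0,1")
  set.seed(5)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("delta is antisymmetric and p invariant under group swap", {
  u <- sim_united(runif(300, .2, .8), runif(300, .2, .8), phi = 0.05, seed = 6)
  d1 <- call_dmps(u, "t", "c")
  d2 <- call_dmps(u, "c", "t")
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$p, d2$p)
})

test_that("DMP calling controls the false-call rate under the null", {
  u <- sim_united(p_t <- runif(5000, .05, .95), p_t, phi = 0.05, seed = 9)
  d <- call_dmps(u, "t", "c", alpha = 0.05)
  frac <- mean(d$q < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(d)))
  d0 <- call_dmps(u, "t", "c", alpha = 0)
  expect_equal(sum(d0$significant), 0)
})

test_that("simulated responsive positions are recovered with high sensitivity", {
  set.seed(12)
  n <- 2000; n_true <- 200
  p0 <- runif(n, 0.1, 0.5)
  p1 <- p0; p1[1:n_true] <- p0[1:n_true] + 0.4
  u <- sim_united(p1, p0, reps = 3, cov_mu = 20, phi = 0, seed = 12)
  d <- call_dmps(u, "t", "c")
  sens <- mean(d$significant[match(1:n_true * 10L, d$pos)], na.rm = TRUE)
  expect_gte(sens, 0.7)
})

test_that("DMP BED export is 0-based half-open with -log10 q scores", {
  u <- sim_united(c(0.9, 0.5), c(0.1, 0.5), reps = 3, cov_mu = 60, seed = 4)
  d <- call_dmps(u, "t", "c")
  path <- withr::local_tempfile(fileext = ".bed")
  export_dmp_bed(d, path)
  lines <- readLines(path)
  expect_equal(length(lines), sum(d$significant))
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(f[3]) - as.integer(f[2]), 1L)
  expect_equal(as.integer(f[3]), d$pos[d$significant][1])
  expect_equal(as.numeric(f[5]),
               round(-log10(d$q[d$significant][1]), 3), tolerance = 1e-3)
})

test_that("DMR segmentation follows the qualifying-position rules", {
  # 5 qualifying CGs within 80 bp at strong delta -> one DMR
  pos <- c(100L, 120L, 140L, 160L, 180L, 2000L)
  M <- rbind(matrix(rep(c(28, 27, 29, 6, 5, 7), 5), 5, byrow = TRUE),
             c(15, 15, 15, 15, 15, 15))
  C <- matrix(30, 6, 6)
  u <- united_table(data.frame(chrom = "Chr1", pos = pos), M, C,
                    rep(c("t", "c"), each = 3))
  dmrs <- call_dmrs(u, "t", "c", backend = "wald")
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$chrom, "Chr1")
  expect_equal(dmrs$start, 100L)
  expect_equal(dmrs$end, 180L)
  expect_equal(dmrs$n_positions, 5L)
  expect_equal(dmrs$direction, "hyper")
  expect_gte(abs(dmrs$mean_delta), 0.10)

  # qualifying positions but regional mean delta 0.08 -> region filtered out
  p_rows <- c(0.50, 0.50, 0.50, 0.40, 0.40)   # vs control 0.38: deltas .12/.02
  M2 <- rbind(t(sapply(p_rows, function(p) round(c(rep(p, 3), rep(0.38, 3)) * 400))),
              c(15, 15, 15, 15, 15, 15))
  C2 <- matrix(400, 6, 6); C2[6, ] <- 30
  u2 <- united_table(data.frame(chrom = "Chr1", pos = pos), M2, C2,
                     rep(c("t", "c"), each = 3))
  d2 <- methTAR:::test_united(u2, "t", "c", "wald", 2, phi = 0)
  expect_true(sum(d2$p[1:5] < 0.01 & abs(d2$delta[1:5]) >= 0.1) >= 3)
  expect_lt(abs(mean(d2$delta[1:5])), 0.10)    # premise of the filter check
  expect_equal(nrow(call_dmrs(u2, "t", "c")), 0)

  # no qualifying positions -> empty result
  u3 <- sim_united(rep(0.5, 20), rep(0.5, 20), seed = 3)
  expect_equal(nrow(call_dmrs(u3, "t", "c")), 0)
})
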