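# Pedigree simulator: design validation, epimutation dynamics, pooling,
# count sampling, end-to-end determinism and truth-table structure.

test_that("pedigree validates designs and records the layout", {
  ped <- pedigree(c("MMM", "SMM", "SSS"), replicates = 3, pool_size = 10)
  expect_equal(nrow(ped$lines), 3)
  expect_equal(ped$generations, 3)
  expect_equal(ped$pool_size, 10)

  expect_equal(pedigree("M", replicates = 1)$generations, 1)
  expect_error(pedigree(c("MM", "MMM")), "same length")
  expect_error(pedigree("MXS"), "characters")
  expect_error(pedigree("MM", pool_size = 0), "pool_size")
})

test_that("propagation is the identity at zero epimutation and flips with certainty at one", {
  m0 <- epigenome_model(n_cg = 500, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                        eps_labile = 0, eps_stable = 0, n_stress_responsive = 0)
  f <- founder_methylome(m0)
  set.seed(1)
  child <- propagate_generation(f, "M")
  expect_identical(child$states, f$states)

  m1 <- epigenome_model(n_cg = 500, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                        labile_fraction = 1, eps_labile = 1, eps_stable = 1,
                        n_stress_responsive = 0)
  f1 <- founder_methylome(m1)
  set.seed(1)
  c1 <- propagate_generation(f1, "M")
  expect_true(all(c1$states != f1$states))
  expect_true(all(c1$states %in% c(0, 0.5, 1)))
})

test_that("epimutation counts match the binomial expectation", {
  m <- epigenome_model(n_cg = 10000, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                       labile_fraction = 1, eps_labile = 0.002,
                       eps_stable = 0.002, n_stress_responsive = 0)
  f <- founder_methylome(m)
  set.seed(42)
  flips <- replicate(60, {
    ch <- propagate_generation(f, "M")
    sum(ch$states != f$states)
  })
  # E = n * eps = 20; MC error of the mean over 60 draws ~ sqrt(20/60)
  expect_lt(abs(mean(flips) - 20), 3 * sqrt(20 / 60))
})

test_that("pooling averages states and rejects empty pools", {
  expect_equal(pool_population(list(c(1, 1), c(1, 0))), c(1, 0.5))
  expect_equal(pool_population(list(rep(1, 3)))[1], 1)
  p <- pool_population(lapply(1:10, function(i) as.numeric(i <= 3)))
  expect_equal(p, 0.3)
  expect_error(pool_population(list()), "at least one")
  expect_error(pool_population(list(c(0, 1), c(0, 1, 1))), "position set")
})

test_that("count sampling respects conversion and boundary fractions", {
  m <- epigenome_model(n_cg = 200, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                       n_stress_responsive = 0, conversion_rate = 1,
                       coverage_mean = 30)
  g <- methTAR:::make_genome(m)
  set.seed(3)
  tab <- sample_counts(rep(0, 200), m, g)
  expect_true(all(tab$M == 0))

  set.seed(3)
  tab1 <- sample_counts(rep(1, 200), m, g)
  expect_true(all(tab1$U == 0))   # p = 1 -> M = C regardless of c

  # chloroplast apparent methylation ~ 1 - c
  mc <- epigenome_model(n_cg = 0, n_chg = 0, n_chh = 0, n_chloroplast = 20000,
                        n_stress_responsive = 0, conversion_rate = 0.995,
                        coverage_mean = 20)
  gc <- methTAR:::make_genome(mc)
  set.seed(4)
  ctl <- attr(sample_counts(numeric(0), mc, gc), "control")
  apparent <- sum(ctl$M) / sum(ctl$M + ctl$U)
  expect_lt(abs(apparent - 0.005), 3 * sqrt(0.005 / sum(ctl$M + ctl$U)))
  expect_true(all(ctl$M >= 0 & ctl$U >= 0))
})

test_that("simulate_study is reproducible and writes byte-identical reports", {
  ped <- pedigree(c(A = "SM", B = "MM"), replicates = 2, pool_size = 5)
  m <- epigenome_model(n_cg = 300, n_chg = 50, n_chh = 50, n_chloroplast = 100,
                       n_stress_responsive = 30, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(ped, m, dir = d1)
  s2 <- simulate_study(ped, m, dir = d2)
  expect_identical(s1$samples, s2$samples)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_named(s1$samples, c("A_1", "A_2", "B_1", "B_2"))
  # counts sane
  for (t in s1$samples) expect_true(all(t$M >= 0 & t$U >= 0 & t$M + t$U > 0))
})

test_that("truth tables encode the additive dose model", {
  ped <- pedigree(c(MMM = "MMM", SMM = "SMM", SSS = "SSS"))
  m <- epigenome_model(n_cg = 200, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                       n_stress_responsive = 40, delta_stress = 0.15,
                       penetrance = 0.8, seed = 2)
  sim <- simulate_study(ped, m)
  sh <- sim$truth$lines
  e_smm <- sh$expected_shift[sh$line_id == "SMM"]
  e_sss <- sh$expected_shift[sh$line_id == "SSS"]
  e_mmm <- sh$expected_shift[sh$line_id == "MMM"]
  expect_equal(e_mmm, 0)
  expect_equal(e_sss - e_mmm, 3 * (e_smm - e_mmm))
  expect_equal(nrow(sim$truth$responsive), 40)
  expect_setequal(unique(sim$truth$classes$class), c("labile", "stable"))
})

test_that("a null model without epimutation or stress leaves lines identical", {
  ped <- pedigree(c(A = "SSS", B = "MMM"))
  m <- epigenome_model(n_cg = 400, n_chg = 0, n_chh = 0, n_chloroplast = 0,
                       eps_labile = 0, eps_stable = 0, n_stress_responsive = 0,
                       conversion_rate = 1, coverage_mean = 200, seed = 5)
  sim <- simulate_study(ped, m)
  # with no stochastic state changes, all samples share the founder fractions:
  # pooled percent methylation differs only through read sampling
  u <- study_united(sim, groups = sub("_[0-9]+$", "", names(sim$samples)))
  x <- percent_matrix(u)
  expect_true(all(abs(rowMeans(x[, 1:3], na.rm = TRUE) -
                        rowMeans(x[, 4:6], na.rm = TRUE)) < 15))
  d <- call_dmps(u, "A", "B")
  expect_lt(mean(d$significant), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(d)))
})

test_that("YAML configs round-trip the design", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model:", "  n_cg: 123", "  seed: 4", "  delta_stress: 0.2",
    "pedigree:", "  design: [MMM, SSS]", "  replicates: 2", "  pool_size: 5"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$model$n_cg, 123L)
  expect_equal(cfg$model$delta_stress, 0.2)
  expect_equal(cfg$pedigree$replicates, 2L)
  expect_equal(cfg$pedigree$lines$treatment, c("MMM", "SSS"))
})
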