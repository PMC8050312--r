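# Correlation statistics, Fisher aggregation, summary layout.

truth_cop <- function(tr) tr$truth_total_cop
truth_com <- function(tr) tr$truth_com

test_that("kinetic correlation is -1 for the noiseless pendulum and matches the direct formula", {
  tr <- simulate_trial(noiseless_config(duration = 10))
  for (dir in c("AP", "ML")) {
    res <- kinetic_ip_corr(truth_cop(tr), truth_com(tr), dir)
    expect_equal(res$r, -1, tolerance = 1e-6)
  }
  # stochastic trial equals an independently coded Pearson formula
  trs <- simulate_trial(quick_config(duration = 10, seed = 23))
  res <- kinetic_ip_corr(truth_cop(trs), truth_com(trs), "AP",
                         limb = "total")
  d <- trs$truth_total_cop$x - trs$truth_com$ap
  expect_equal(res$r, pearson_direct(d, trs$truth_com$acc_ap),
               tolerance = 1e-12)
  expect_equal(res$n_samples, 1000L)
})

test_that("degenerate kinetic inputs raise errors rather than NaN", {
  n <- 100
  w <- plate_wrench(matrix(rep(c(0, 0, 700), each = n), n, 3),
                    matrix(rep(c(0, -35, 0), each = n), n, 3), fs = 100)
  cop <- cop_from_wrench(w)
  com <- com_series(rep(0.01, n), rep(0, n), fs = 100)
  expect_error(kinetic_ip_corr(cop, com, "AP"), "degenerate")
  # misaligned series
  com2 <- com_series(rnorm(n + 1), rnorm(n + 1), fs = 100)
  expect_error(kinetic_ip_corr(cop, com2, "AP"), "aligned")
})

test_that("kinematic correlation: exact proportionality, degeneracy, oracle", {
  hm <- data.frame(mean_height = c(0.4, 0.8, 1.2, 1.6),
                   movement = c(0.4, 0.8, 1.2, 1.6) * 0.05)
  expect_equal(kinematic_ip_corr(hm, "AP")$r, 1, tolerance = 1e-9)
  # pure translation: equal movements -> degenerate
  hm_tr <- data.frame(mean_height = c(0.4, 0.8, 1.2), movement = rep(0.1, 3))
  expect_error(kinematic_ip_corr(hm_tr, "AP"), "pure translation")
  hm_flat <- data.frame(mean_height = rep(1, 3), movement = c(1, 2, 3))
  expect_error(kinematic_ip_corr(hm_flat, "AP"), "heights equal")
  set.seed(4)
  hm_n <- data.frame(mean_height = runif(12, 0, 1.8),
                     movement = runif(12, 0, 0.5))
  expect_equal(kinematic_ip_corr(hm_n, "ML")$r,
               pearson_direct(hm_n$mean_height, hm_n$movement),
               tolerance = 1e-12)
})

test_that("Pearson statistic is scale- and offset-invariant with sign flips", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(50); y <- rnorm(50)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    c_ <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    hm1 <- data.frame(mean_height = x, movement = y)
    hm2 <- data.frame(mean_height = a * x + 2, movement = c_ * y - 3)
    r1 <- kinematic_ip_corr(hm1, "AP")$r
    r2 <- kinematic_ip_corr(hm2, "AP")$r
    expect_equal(r2, sign(a * c_) * r1, tolerance = 1e-12)
  }
})

test_that("fisher_aggregate matches the independent transform chain", {
  z0 <- fisher_aggregate(c(0, 0, 0))
  expect_equal(z0$mean_r, 0)
  expect_equal(z0$ci_low, -z0$ci_high)
  one <- fisher_aggregate(0.5)
  expect_equal(one$mean_r, 0.5)
  expect_true(is.na(one$ci_low) && is.na(one$ci_high))
  rs <- c(0.2, 0.4, 0.6)
  got <- fisher_aggregate(rs)
  ora <- fisher_chain(rs)
  expect_equal(got$mean_r, ora$mean_r, tolerance = 1e-12)
  expect_equal(got$ci_low, ora$ci_low, tolerance = 1e-12)
  expect_equal(got$ci_high, ora$ci_high, tolerance = 1e-12)
  # negative-heavy sets (the kinetic table is mostly negative)
  rs2 <- c(-0.82, -0.71, -0.45, -0.6)
  expect_equal(fisher_aggregate(rs2)$mean_r, fisher_chain(rs2)$mean_r,
               tolerance = 1e-12)
  expect_error(fisher_aggregate(numeric()), "empty")
  expect_error(fisher_aggregate(c(0.2, 1.4)), "within")
  expect_warning(res1 <- fisher_aggregate(c(1, 0.5)), "clamped")
  expect_lt(res1$mean_r, 1)
  # back-transform round trip across the open interval
  r_grid <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(tanh(atanh(r_grid)), r_grid, tolerance = 1e-12)
})

test_that("summary_table emits the full design and matches two-stage oracle", {
  res <- fabricate_results()
  tab <- summary_table(res)
  expect_s3_class(tab, "summary_table")
  expect_equal(sum(tab$definition == "kinetic"), 36)   # 2 x 2 x 3 x 3
  expect_equal(sum(tab$definition == "kinematic"), 12) # 2 x 2 x 3
  expect_true(all(tab$ci_low <= tab$mean_r + 1e-12 &
                    tab$mean_r <= tab$ci_high + 1e-12))
  expect_true(all(abs(tab$mean_r) <= 1))
  # oracle recomputation of one kinetic cell, two-stage on the z scale
  cell <- res[res$direction == "AP" & res$group == "TPU" &
                !is.na(res$limb) & res$limb == "total" &
                res$condition == "EC", ]
  zs <- tapply(atanh(cell$r), cell$subject_id, mean)
  ora <- fisher_chain(tanh(as.numeric(zs)))
  got <- tab[tab$definition == "kinetic" & tab$direction == "AP" &
               tab$group == "TPU" & !is.na(tab$limb) & tab$limb == "total" &
               tab$condition == "EC", ]
  expect_equal(got$mean_r, ora$mean_r, tolerance = 1e-12)
  expect_equal(got$ci_low, ora$ci_low, tolerance = 1e-12)
  expect_equal(got$n_subjects, 8L)
  # single-stage pooling differs from two-stage in general
  tab1 <- summary_table(res, two_stage = FALSE)
  expect_equal(nrow(tab1), nrow(tab))
})

test_that("summary_table: identical inputs collapse, missing cells warn", {
  res <- fabricate_results()
  res$r[res$definition == "kinetic"] <- -0.4
  tab <- summary_table(res)
  kin <- tab[tab$definition == "kinetic", ]
  expect_equal(kin$mean_r, rep(-0.4, 36), tolerance = 1e-12)
  expect_equal(kin$ci_high - kin$ci_low, rep(0, 36), tolerance = 1e-12)
  # drop one whole cell
  res2 <- fabricate_results()
  drop <- res2$group == "TPU" & res2$condition == "FB" &
    !is.na(res2$limb) & res2$limb == "total" & res2$direction == "ML"
  expect_warning(tab2 <- summary_table(res2[!drop, ]), "empty summary cells")
  na_row <- tab2[tab2$group == "TPU" & tab2$condition == "FB" &
                   !is.na(tab2$limb) & tab2$limb == "total" &
                   tab2$direction == "ML", ]
  expect_true(is.na(na_row$mean_r))
  # incomplete metadata rejected
  res3 <- fabricate_results()
  res3$condition[1] <- NA
  expect_error(summary_table(res3), "complete grouping metadata")
})
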