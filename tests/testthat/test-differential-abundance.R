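test_that("log transform floors values before log2", {
  expect_equal(log_transform(matrix(0), floor = 0.1)[1], log2(0.1))
  expect_equal(log_transform(matrix(44.6))[1], log2(44.6))
  expect_equal(log_transform(matrix(1), floor = 1)[1], 0)
  expect_error(log_transform(matrix(1), floor = 0))
})

test_that("variance prior: degenerate and error cases", {
  # identical variances carry no spread beyond sampling: d0 collapses
  pr <- fit_variance_prior(rep(2, 50), residual_df = 10)
  expect_identical(pr$d0, Inf)
  expect_gt(pr$s0_sq, 0)
  expect_error(fit_variance_prior(c(1, 2), 10), "at least 3")
  expect_warning(fit_variance_prior(c(0, 1, 2, 3), 10), "non-positive")
})

test_that("variance prior recovers scaled-F truth by moments", {
  d1 <- 12; d0_true <- 4; s0_true <- 1
  est <- t(vapply(1:20, function(i) {
    set.seed(5000 + i)
    s2 <- s0_true * stats::rf(2000, d1, d0_true)
    pr <- fit_variance_prior(s2, d1)
    c(pr$d0, pr$s0_sq)
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) - d0_true), 1.5)
  expect_lt(abs(median(est[, 2]) / s0_true - 1), 0.2)
})

test_that("variance prior matches limma's scaled-F moment fit", {
  set.seed(51)
  s2 <- stats::rf(500, 8, 6) * 2
  mine <- fit_variance_prior(s2, 8)
  ref <- limma::fitFDist(s2, df1 = 8)
  expect_equal(mine$d0, ref$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t reduces to the pooled t at d0 = 0", {
  # hand-checked pooled t: A=(1,2,3), B=(3,4,5) -> t = -2/sqrt(2/3)
  res <- moderated_t(c(1, 2, 3), c(3, 4, 5), list(d0 = 0, s0_sq = 99))
  expect_equal(res$t, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  expect_equal(res$df_total, 4)

  set.seed(52)
  for (i in 1:1000) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = 0.5)
    mine <- moderated_t(a, b, list(d0 = 0, s0_sq = 1))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t limits: identical groups and infinite prior df", {
  res <- moderated_t(c(1, 2, 3), c(1, 2, 3), list(d0 = 0, s0_sq = 1))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # as d0 -> Inf every statistic uses the common prior variance s0_sq
  set.seed(53)
  a <- rnorm(5); b <- rnorm(5, 1)
  big <- moderated_t(a, b, list(d0 = 1e12, s0_sq = 2))
  inf <- moderated_t(a, b, list(d0 = Inf, s0_sq = 2))
  manual <- (mean(a) - mean(b)) / sqrt(2 * (1 / 5 + 1 / 5))
  expect_equal(inf$t, manual, tolerance = 1e-12)
  expect_equal(big$t, manual, tolerance = 1e-6)
  expect_error(moderated_t(1, c(1, 2), list(d0 = 0, s0_sq = 1)),
               "at least 2")
})

test_that("moderated t agrees with limma's eBayes under a shared prior", {
  set.seed(54)
  y <- matrix(rnorm(30 * 10), 30, 10)
  grp <- rep(c(1, 0), each = 5)
  fit <- limma::lmFit(y, cbind(1, grp))
  eb <- limma::eBayes(fit)
  prior <- list(d0 = eb$df.prior, s0_sq = eb$s2.prior)
  for (j in 1:30) {
    mine <- moderated_t(y[j, grp == 1], y[j, grp == 0], prior)
    expect_equal(mine$t, unname(eb$t[j, 2]), tolerance = 1e-8)
    expect_equal(mine$p, unname(eb$p.value[j, 2]), tolerance = 1e-8)
  }
})

test_that("bh_fdr equals the brute-force step-up definition", {
  brute <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
    }
    q
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(55)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), brute(p), tolerance = 1e-12)
  }
})

test_that("q-values are monotone along sorted p-values", {
  set.seed(56)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("differential screen: calls respect the fold and FDR criteria", {
  set.seed(57)
  st <- make_study(simulation_config(seed = 57))
  res <- suppressWarnings(
    differential_otus(st$table, "treatment", c("splenda", "streptomycin")))
  expect_setequal(res$otu_id, otu_ids(st$table))
  with_calls <- res[res$significant, ]
  expect_true(all(with_calls$q_value <= 0.05))
  expect_true(all(pmax(2^with_calls$log2_fold_change,
                       2^-with_calls$log2_fold_change) >= 1.2))
  # infinite fold requirement disables every call
  none <- suppressWarnings(
    differential_otus(st$table, "treatment", c("splenda", "streptomycin"),
                      fc_min = Inf))
  expect_false(any(none$significant))
  expect_error(differential_otus(st$table, "treatment",
                                 c("splenda", "nope")), "at least 2")
})

test_that("null comparisons rarely produce calls; strong shifts are found", {
  prof <- reference_profile("splenda")$mean_abundance
  base <- list(a = group_profile("a", prof), b = group_profile("b", prof))
  shifted <- prof; shifted["Helicobacter"] <- shifted["Helicobacter"] * 8
  shift <- list(a = group_profile("a", shifted), b = group_profile("b", prof))
  run <- function(profiles, seed) {
    cfg <- simulation_config(group_profiles = profiles,
                             n_per_group = c(a = 8, b = 6),
                             nondko_groups = "b", seed = seed)
    st <- make_study(cfg)
    suppressWarnings(differential_otus(st$table, "group", c("a", "b")))
  }
  any_sig <- vapply(1:200, function(i) any(run(base, 6000 + i)$significant),
                    logical(1))
  expect_lte(mean(any_sig), 0.10)
  hit <- vapply(1:200, function(i) {
    res <- run(shift, 7000 + i)
    res$significant[res$otu_id == "Helicobacter"] &&
      res$log2_fold_change[res$otu_id == "Helicobacter"] > 0
  }, logical(1))
  expect_gte(mean(hit), 0.80)
})
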