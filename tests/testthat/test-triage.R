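test_that("extreme stratification applies the score thresholds", {
  scores <- c(m1 = 0.5, m2 = 1, m3 = 3, m4 = 5, m5 = 8)
  g <- stratify_extremes(scores)
  expect_equal(g$cured_ids, c("m1", "m2"))
  expect_equal(g$sick_ids, c("m4", "m5"))
  expect_length(intersect(g$cured_ids, g$sick_ids), 0L)
  expect_warning(stratify_extremes(c(a = 3, b = 3, c = 3)), "empty")
  # non-DKO mice are excluded when genotype is supplied
  g2 <- stratify_extremes(scores, genotype = c("DKO", "nonDKO", "DKO",
                                               "DKO", "DKO"))
  expect_equal(g2$cured_ids, "m1")
  expect_error(stratify_extremes(unname(scores)), "named")
})

test_that("cured/sick screen: ratio direction and degenerate p", {
  set.seed(61)
  v <- rbind(matrix(rnorm(4 * 2, c(2, 9)), 4, 2, byrow = TRUE),
             matrix(rnorm(4 * 2, c(8, 9)), 4, 2, byrow = TRUE))
  v <- pmax(v, 0)
  colnames(v) <- c("prov", "flat")
  rownames(v) <- sprintf("m%d", 1:8)
  tab <- toy_table(v)
  g <- structure(list(cured_ids = rownames(v)[1:4],
                      sick_ids = rownames(v)[5:8]),
                 class = "extreme_groups")
  scr <- cured_sick_screen(tab, g)
  expect_equal(scr$direction[scr$otu_id == "prov"], "provocative")
  expect_lt(scr$ratio_cured_over_sick[scr$otu_id == "prov"], 1)
  # exact arithmetic on constructed means
  v2 <- rbind(c(a = 2), c(a = 2), c(a = 8), c(a = 8))
  rownames(v2) <- sprintf("x%d", 1:4)
  t2 <- toy_table(v2)
  g2 <- structure(list(cured_ids = c("x1", "x2"), sick_ids = c("x3", "x4")),
                  class = "extreme_groups")
  expect_equal(cured_sick_screen(t2, g2)$ratio_cured_over_sick, 0.25)
  # empty group is an error
  g3 <- structure(list(cured_ids = character(0), sick_ids = "x3"),
                  class = "extreme_groups")
  expect_error(cured_sick_screen(t2, g3), "non-empty")
})

test_that("cured/sick screen p-values are near-uniform under the null", {
  set.seed(62)
  p <- vapply(1:200, function(i) {
    v <- matrix(rlnorm(12, 1, 0.4), 12, 1,
                dimnames = list(sprintf("m%d", 1:12), "otu"))
    g <- structure(list(cured_ids = rownames(v)[1:6],
                        sick_ids = rownames(v)[7:12]),
                   class = "extreme_groups")
    cured_sick_screen(toy_table(v), g)$pairwise_p
  }, numeric(1))
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p), 0.55)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("multiplicity family: candidates get adjusted, others NA", {
  set.seed(63)
  v <- cbind(strong = c(rep(1, 5), rep(9, 5)) + rnorm(10, 0, 0.1),
             noise1 = rnorm(10, 5, 0.5), noise2 = rnorm(10, 5, 0.5))
  rownames(v) <- sprintf("m%d", 1:10)
  g <- structure(list(cured_ids = rownames(v)[1:5],
                      sick_ids = rownames(v)[6:10]),
                 class = "extreme_groups")
  scr <- cured_sick_screen(toy_table(v), g)
  fam <- sum(scr$pairwise_p <= 0.05)
  expect_equal(scr$adjusted_p[scr$otu_id == "strong"],
               min(1, scr$pairwise_p[scr$otu_id == "strong"] * fam))
  expect_true(all(is.na(scr$adjusted_p[scr$pairwise_p > 0.05])))
  all_fam <- cured_sick_screen(toy_table(v), g, family = "all")
  expect_equal(all_fam$adjusted_p, pmin(1, all_fam$pairwise_p * 3))
})

test_that("correlation panel: perfect, degenerate and noisy cases", {
  set.seed(64)
  n <- 12
  score <- seq(1, 8, length.out = n)
  v <- cbind(tracks = score * 10, flat = rep(3, n),
             noisy = 0.1 * score + rnorm(n, 0, 1e-3))
  rownames(v) <- sprintf("m%d", 1:n)
  tab <- toy_table(v)
  panel <- data.frame(sample_id = rownames(v), overall_score = score,
                      exfoliation_fraction = runif(n),
                      paneth_fraction = runif(n),
                      abscesses_per_field = runif(n),
                      apoptosis_per_crypt = runif(n))
  pan <- marker_correlation_panel(tab, panel)
  expect_equal(pan$r_overall_score[pan$otu_id == "tracks"], 1)
  expect_equal(pan$r_overall_score[pan$otu_id == "flat"], 0)
  expect_equal(pan$n_degenerate[pan$otu_id == "flat"], 5L)
  expect_gt(pan$r_overall_score[pan$otu_id == "noisy"], 0.95)
  expect_error(marker_correlation_panel(tab, panel[-1, ]), "missing sample")
})

test_that("harmonized average flips only health-positive markers", {
  dirs <- marker_directions()
  r <- setNames(c(0.5, 0.5, -0.5, 0.5, 0.5), names(dirs))
  expect_equal(harmonized_average(r), 0.5)   # Paneth flip makes all +0.5
  expect_equal(harmonized_average(setNames(rep(0, 5), names(dirs))), 0)
  # antisymmetry: negating every coefficient negates the average
  set.seed(65)
  for (i in 1:20) {
    r <- setNames(runif(5, -1, 1), names(dirs))
    expect_equal(harmonized_average(-r), -harmonized_average(r))
  }
  expect_error(harmonized_average(c(a = 1, b = 2, c = 3, d = 4, e = 5)),
               "marker names")
})

test_that("sign convention: pathogenic abundance harmonizes positive", {
  # higher abundance -> higher score/exfoliation/abscess/apoptosis and
  # lower Paneth fraction; every contribution should point positive
  set.seed(66)
  n <- 20
  a <- runif(n, 0, 50)
  panel <- data.frame(
    sample_id = sprintf("m%d", 1:n),
    overall_score = 0.1 * a + rnorm(n, 0, 0.1),
    exfoliation_fraction = 0.005 * a + rnorm(n, 0, 0.01),
    paneth_fraction = 1 - 0.01 * a + rnorm(n, 0, 0.01),
    abscesses_per_field = 0.02 * a + rnorm(n, 0, 0.02),
    apoptosis_per_crypt = 0.005 * a + rnorm(n, 0, 0.005))
  v <- matrix(a, n, 1, dimnames = list(panel$sample_id, "bug"))
  pan <- marker_correlation_panel(toy_table(v), panel)
  dirs <- marker_directions()
  harmonized <- ifelse(dirs, 1, -1) *
    unlist(pan[1, paste0("r_", names(dirs))])
  expect_true(all(harmonized > 0))
  expect_gt(pan$harmonized_mean_r[1], 0.9)
})

test_that("combined correlation reduces to the single-OTU panel entry", {
  set.seed(67)
  tab <- random_table(10, 4)
  marker <- rnorm(10)
  single <- combined_correlation(tab, "otu02", marker)
  expect_equal(single$r, cor(tab$values[, "otu02"], marker))
  expect_equal(single$r_squared, single$r^2, tolerance = 1e-12)
  # an OTU combined with itself keeps its panel correlation exactly
  both <- combined_correlation(tab, c("otu02", "otu02"), marker)
  expect_equal(both$r, single$r)
  # perfectly anti-correlated pair sums to a constant: degenerate
  v <- cbind(up = 1:6, down = 6:1 + 0)
  rownames(v) <- sprintf("m%d", 1:6)
  anti <- combined_correlation(toy_table(v), c("up", "down"), rnorm(6))
  expect_true(anti$degenerate)
  expect_equal(anti$r, 0)
  expect_error(combined_correlation(tab, "ghost", marker), "unknown OTU")
})

test_that("dilution adjustment renormalizes against the diluter", {
  expect_equal(dilution_adjust(40, 20), 50)
  expect_equal(dilution_adjust(7, 0), 7)
  expect_error(dilution_adjust(1, 100), "below 100")
  # vectorized over mice
  expect_equal(dilution_adjust(c(10, 20), c(50, 0)), c(20, 20))
})

test_that("consensus verdicts follow the two-concordant-signals rule", {
  records <- data.frame(
    otu_id = c("prov", "benef", "weak"),
    ratio_cured_over_sick = c(0.2, 3, 0.9),
    harmonized_mean_r = c(0.5, -0.3, 0.1))
  shift <- data.frame(otu_id = c("prov", "benef", "weak"),
                      log2_fold_change = c(1, -0.1, 0.05),
                      significant = c(TRUE, FALSE, FALSE))
  out <- consensus_classify(records, shift)
  expect_equal(out$verdict,
               c("provocative", "beneficial_or_opportunistic",
                 "indeterminate"))
  # without the shift table the ratio + correlation signals still decide
  out2 <- consensus_classify(records, NULL)
  expect_equal(out2$verdict[1], "provocative")
  expect_equal(out2$verdict[3], "indeterminate")
})

test_that("screen and differential module share the fold convention", {
  set.seed(68)
  v <- matrix(rlnorm(8 * 3, 0, 1), 8, 3,
              dimnames = list(sprintf("m%d", 1:8), c("a", "b", "c")))
  tab <- toy_table(v)
  g <- structure(list(cured_ids = rownames(v)[1:4],
                      sick_ids = rownames(v)[5:8]),
                 class = "extreme_groups")
  cfg <- pipeline_config()
  scr <- cured_sick_screen(tab, g, floor = cfg$floor)
  manual <- vapply(colnames(v), function(j) {
    floored_mean_ratio(v[1:4, j], v[5:8, j], cfg$floor)
  }, numeric(1))
  expect_equal(scr$ratio_cured_over_sick, unname(manual))
  tab$samples$treatment <- rep(c("splenda", "vancomycin"), each = 4)
  res <- suppressWarnings(
    differential_otus(tab, "treatment", c("splenda", "vancomycin"),
                      floor = cfg$floor))
  expect_equal(res$log2_fold_change, unname(log2(manual)))
})

test_that("full triage recovers a designated provocative OTU", {
  hit <- vapply(1:30, function(i) {
    st <- make_study(simulation_config(provocative_otus = "Lactobacillus",
                                       seed = 6900 + i))
    tri <- suppressWarnings(triage_otus(st$table, st$panels))
    tri$records$verdict[tri$records$otu_id == "Lactobacillus"] ==
      "provocative"
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
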