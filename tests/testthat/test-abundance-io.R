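test_that("reading a delimited table round-trips and validates", {
  tab <- reference_fixture()
  expect_equal(ncol(tab$values), 24L)

  dir <- withr::local_tempdir()
  write_abundance_table(tab, file.path(dir, "ab.tsv"),
                        file.path(dir, "meta.csv"))
  back <- read_abundance_table(file.path(dir, "ab.tsv"),
                               file.path(dir, "meta.csv"))
  expect_equal(back$values, tab$values)
  expect_equal(back$samples$sample_id, tab$samples$sample_id)

  # empty file -> no samples
  writeLines("sample_id\tA\tB", file.path(dir, "empty.tsv"))
  expect_error(read_abundance_table(file.path(dir, "empty.tsv"),
                                    file.path(dir, "meta.csv")),
               "no samples")
})

test_that("construction rejects malformed input, names the offender", {
  meta <- data.frame(sample_id = c("a", "b"), genotype = "DKO",
                     treatment = "splenda")
  v <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(abundance_table(v, meta), "abundance_table")

  neg <- v; neg[2, 2] <- -1
  expect_error(abundance_table(neg, meta), "sample 'b', OTU 'y'")

  dup <- v; colnames(dup) <- c("x", "x")
  expect_error(abundance_table(dup, meta), "duplicate OTU")

  expect_error(abundance_table(v, meta[1, ]), "without metadata: b")

  over <- v; over[1, ] <- c(60, 60)
  expect_error(abundance_table(over, meta), "exceeds 100")

  # non-DKO treated with an antibiotic is inconsistent metadata
  bad <- meta; bad$genotype <- c("DKO", "nonDKO")
  bad$treatment <- c("splenda", "vancomycin")
  expect_error(abundance_table(v, bad), "non-DKO")

  # a sample of all zeros is a valid degenerate row
  zero <- v; zero[1, ] <- 0
  tab <- abundance_table(zero, meta)
  expect_equal(unname(rowSums(tab$values)["a"]), 0)
})

test_that("mothur .shared counts convert to percent of row total", {
  dir <- withr::local_tempdir()
  writeLines(c("label\tGroup\tnumOtus\tOtu001\tOtu002",
               "0.03\tm1\t2\t30\t70",
               "0.03\tm2\t2\t5\t15"),
             file.path(dir, "x.shared"))
  meta <- data.frame(sample_id = c("m1", "m2"), genotype = "DKO",
                     treatment = "splenda")
  tab <- read_mothur_shared(file.path(dir, "x.shared"), meta)
  expect_equal(unname(tab$values["m1", ]), c(30, 70))
  expect_equal(unname(tab$values["m2", ]), c(25, 75))
  expect_equal(unname(rowSums(tab$values)), c(100, 100))
})

test_that("filter_otus applies a strict detection rule and is idempotent", {
  v <- rbind(s1 = c(a = 0.4, b = 0.6, c = 0.5, d = 0),
             s2 = c(a = 0.3, b = 0.1, c = 0.5, d = 2))
  tab <- toy_table(v)
  f <- filter_otus(tab)           # > 0.5% in >= 1 sample
  expect_equal(otu_ids(f), c("b", "d"))   # 0.4 max removed; 0.5 not > 0.5
  expect_equal(sample_ids(f), sample_ids(tab))
  # idempotent
  expect_equal(filter_otus(f)$values, f$values)
  # min_percent = 0: identity on OTUs with any positive value
  expect_equal(otu_ids(filter_otus(tab, min_percent = 0)),
               c("a", "b", "c", "d"))
  v0 <- cbind(v, e = c(0, 0))
  expect_equal(otu_ids(filter_otus(toy_table(v0), min_percent = 0)),
               c("a", "b", "c", "d"))
  # stricter sample requirement
  expect_equal(otu_ids(filter_otus(tab, 0.4, min_samples = 2)), "c")
})

test_that("group means are arithmetic means with exact group structure", {
  v <- rbind(s1 = c(a = 10, b = 1), s2 = c(a = 30, b = 3),
             s3 = c(a = 7, b = 2))
  tab <- toy_table(v, treatment = c("splenda", "splenda", "vancomycin"))
  gm <- group_means(tab, "treatment")
  expect_equal(unname(gm$splenda$mean_abundance["a"]), 20)
  # single-sample group equals that sample
  expect_equal(gm$vancomycin$mean_abundance, v["s3", ])
  # missing group assignment is an error
  tab$samples$treatment[1] <- NA
  expect_error(group_means(tab, "treatment"), "missing group")
  expect_error(group_means(reference_fixture(), "nope"), "unknown metadata")
})

test_that("total_classified is linear in the mean of row totals", {
  set.seed(11)
  tab <- random_table(9, 6)
  tab$samples$treatment <- rep(c("splenda", "vancomycin", "streptomycin"),
                               each = 3)
  gm <- group_means(tab, "treatment")
  for (g in names(gm)) {
    rows <- tab$samples$treatment == g
    expect_equal(total_classified(gm[[g]]),
                 mean(rowSums(tab$values[rows, , drop = FALSE])),
                 tolerance = 1e-9)
  }
  expect_error(group_profile("x", numeric(0)), "named vector")
  expect_equal(total_classified(group_profile("z", c(a = 0, b = 0))), 0)
})

test_that("core microbiota rule: strict fold bound, p bound, mean floor", {
  # direct ratio: 10 vs 4.9 is fold 2.04, excluded
  a <- group_profile("dko", c(x = 10, y = 4, z = 0.05))
  b <- group_profile("ctl", c(x = 4.9, y = 3, z = 0.08))
  expect_equal(core_microbiota(a, b), "y")
  # trace OTUs below the mean floor never enter the core
  expect_false("z" %in% core_microbiota(a, b, min_mean = 0.2))
  # identical profiles: every OTU above the floor
  expect_equal(core_microbiota(a, a), c("x", "y"))
  # p-value bound is strict
  expect_equal(core_microbiota(a, b, per_otu_p = c(y = 0.09)), character(0))
  expect_equal(core_microbiota(a, b, per_otu_p = c(y = 0.091)), "y")
  # symmetric in the two profiles
  expect_setequal(core_microbiota(a, b), core_microbiota(b, a))
  # mismatched OTU sets are an error
  d <- group_profile("d", c(x = 1, w = 2))
  expect_error(core_microbiota(a, d), "only one profile")
})

test_that("core microbiota is argument-order invariant on the reference", {
  dko <- reference_profile("splenda")
  ctl <- reference_profile("nondko")
  expect_setequal(core_microbiota(dko, ctl), core_microbiota(ctl, dko))
})
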