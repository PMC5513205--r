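test_that("log_ratio follows the correction-factor formula", {
  expect_equal(log_ratio(0.02, 0.02), 0)
  expect_equal(log_ratio(0, 0.01), log10(1e-5 / 1.001e-2))
  expect_equal(log_ratio(0, 0.01), -3.0004, tolerance = 1e-4)
  expect_equal(log_ratio(0, 0), 0)          # both-missing discontinuity removed
  expect_error(log_ratio(-0.1, 0.2), class = "mgmp_domain_error")
  expect_error(log_ratio(0.1, 0.2, cf = 0), class = "mgmp_domain_error")
  # strictly increasing in a, decreasing in b
  a <- sort(runif(20)); b <- 0.3
  expect_true(all(diff(log_ratio(a, b)) > 0))
  expect_true(all(diff(log_ratio(b, a)) < 0))
})

test_that("bh_adjust reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)  # m = 1 identity
  expect_error(bh_adjust(c(0.2, 1.2)), class = "mgmp_domain_error")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("vectorised t statistics agree with stats::t.test", {
  set.seed(5)
  lr <- matrix(rnorm(8 * 12, sd = 0.3), nrow = 8,
               dimnames = list(paste0("f", 1:8), paste0("S", 1:12)))
  tabA <- abundance_table(matrix(0.1, 8, 12, dimnames = dimnames(lr)), "MP", "KO")
  # build tables whose log ratios equal lr exactly: a = b * 10^lr with cf shift
  cf <- 1e-5
  b <- matrix(0.1, 8, 12, dimnames = dimnames(lr))
  a <- (b + cf) * 10^lr - cf
  rt <- ratio_test(abundance_table(a, "MP", "KO"), abundance_table(b, "MG", "KO"),
                   contrast_spec(filter_threshold = NULL))
  for (i in 1:8) {
    tt <- t.test(lr[i, ])
    j <- match(rownames(lr)[i], rt$table$feature)
    expect_equal(rt$table$t_statistic[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rt$table$p_raw[j], tt$p.value, tolerance = 1e-10)
    expect_equal(rt$table$mean_log_ratio[j], mean(lr[i, ]), tolerance = 1e-10)
  }
})

test_that("ratio_test handles degenerate and misaligned inputs", {
  subj <- paste0("S", 1:4)
  a <- matrix(c(rep(0.5, 4), rep(0.5, 4)), 2, 4, byrow = TRUE,
              dimnames = list(c("f1", "f2"), subj))
  rt <- ratio_test(abundance_table(a, "MP", "KO"), abundance_table(a, "MG", "KO"),
                   contrast_spec(filter_threshold = NULL))
  expect_true(all(rt$table$p_raw == 1))       # all ratios identically zero
  expect_true(all(rt$table$t_statistic == 0))
  expect_false(any(rt$table$significant))

  # zero-variance nonzero mean -> degenerate flag, p floored not zero
  b <- a; b["f1", ] <- 0.25
  expect_message(
    rt2 <- ratio_test(abundance_table(a, "MP", "KO"),
                      abundance_table(b, "MG", "KO"),
                      contrast_spec(filter_threshold = NULL)),
    "degenerate")
  i <- match("f1", rt2$table$feature)
  expect_true(rt2$table$degenerate[i])
  expect_gt(rt2$table$p_raw[i], 0)

  # subject mismatch
  cc <- a; colnames(cc) <- paste0("X", 1:4)
  expect_error(ratio_test(abundance_table(a, "MP", "KO"),
                          abundance_table(cc, "MG", "KO")),
               class = "mgmp_alignment_error")
})

test_that("ratio_test is antisymmetric and filters on the pooled mean", {
  rec <- null_cohort(n_subjects = 8, n_features = 20, depth = 1e4, seed = 51)
  tr <- attr(rec, "spec")$taxonomy
  mp <- relative_abundance(rec, "genus", tr, layer = "MP")
  mg <- relative_abundance(rec, "genus", tr, layer = "MG")
  ab <- ratio_test(mp, mg)
  ba <- ratio_test(mg, mp)
  expect_equal(ab$table$mean_log_ratio, -ba$table$mean_log_ratio)
  expect_equal(ab$table$p_raw, ba$table$p_raw)
  expect_equal(ab$table$p_adjusted, ba$table$p_adjusted)

  # a feature absent from both tables' high-abundance set is filtered
  v <- mp$values
  v <- rbind(v, rare = rep(1e-6, ncol(v)))
  w <- mg$values
  w <- rbind(w, rare = rep(1e-6, ncol(w)))
  rt <- ratio_test(abundance_table(v, "MP", "genus"),
                   abundance_table(w, "MG", "genus"))
  expect_false("rare" %in% rt$table$feature)

  # invariants of the result object
  expect_true(all(rt$table$p_adjusted >= rt$table$p_raw - 1e-15))
  expect_true(all(rt$table$significant == (rt$table$p_adjusted <= 0.05)))
  expect_equal(rt$table$mean_log_ratio, unname(rowMeans(rt$log_ratios)))
  expect_equal(unname(coef(rt)), rt$table$mean_log_ratio)
})

test_that("partition_contrast builds disjoint renormalised KO tables", {
  tr <- fixture_tree()
  rec <- rbind(
    make_records(c("g__Faecalibacterium|K00001" = 60, "g__Roseburia|K00002" = 20,
                   "g__Bacteroides|K00001" = 20), "S01"),
    make_records(c("g__Faecalibacterium|K00001" = 30, "g__Bacteroides|K00003" = 70),
                 "S02")
  )
  pc <- partition_contrast(rec, "p__Firmicutes", "p__Bacteroidetes", tr)
  # Firmicutes side renormalised within partition
  expect_equal(pc$a$values["K00001", "S01"], 0.75)
  expect_equal(pc$a$values["K00002", "S01"], 0.25)
  expect_equal(pc$b$values["K00001", "S01"], 1)
  # S02 has no Firmicutes K00002: zero
  expect_equal(pc$a$values["K00002", "S02"], 0)
  expect_error(partition_contrast(rec, "p__Firmicutes", "f__Ruminococcaceae", tr),
               class = "mgmp_config_error")

  # one-sided partition: all records under one subtree
  solo <- make_records(c("g__Faecalibacterium|K00001" = 10), "S01")
  solo <- rbind(solo, make_records(c("g__Faecalibacterium|K00001" = 10), "S02"))
  expect_error(partition_contrast(solo, "p__Firmicutes", "p__Bacteroidetes", tr),
               class = "mgmp_config_error")  # nothing mappable on the empty side
})

test_that("planted phylum-specific KO tops the partition log ratios", {
  spec <- null_cohort_spec(n_subjects = 10, n_features = 20, depth = 2e4, seed = 61)
  rec <- generate_cohort(spec)
  tr <- spec$taxonomy
  # genera alternate p__A / p__B; K00001 belongs to g__T001 (p__A) only
  pc <- partition_contrast(rec, "p__A", "p__B", tr, layer = "MG")
  rt <- ratio_test(pc$a, pc$b, contrast_spec(mode = "partition"))
  tab <- rt$table[order(-rt$table$mean_log_ratio), ]
  # every p__A-private KO has a large positive ratio, p__B-private negative
  expect_true(all(tab$mean_log_ratio[tab$feature == "K00001"] > 1))
  expect_true(all(rt$table$mean_log_ratio[rt$table$feature == "K00002"] < -1))
})
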