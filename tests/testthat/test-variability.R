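test_that("bray_curtis matches closed-form toy cases", {
  subj <- c("S1", "S2")
  ident <- abundance_table(matrix(c(0.5, 0.5, 0.5, 0.5), 2,
                                  dimnames = list(c("a", "b"), subj)), "MG", "genus")
  expect_equal(bray_curtis(ident)$bc, 0)
  disj <- abundance_table(matrix(c(1, 0, 0, 1), 2,
                                 dimnames = list(c("a", "b"), subj)), "MG", "genus")
  expect_equal(bray_curtis(disj)$bc, 1)
  cross <- abundance_table(matrix(c(0.7, 0.3, 0.3, 0.7), 2,
                                  dimnames = list(c("a", "b"), subj)), "MG", "genus")
  expect_equal(bray_curtis(cross)$bc, 0.4)
})

test_that("bray_curtis is symmetric, bounded and ordered lexicographically", {
  rec <- null_cohort(n_subjects = 6, n_features = 15, depth = 5e3, seed = 71)
  tr <- attr(rec, "spec")$taxonomy
  tab <- relative_abundance(rec, "genus", tr, layer = "MG")
  bc <- bray_curtis(tab)
  expect_equal(nrow(bc), choose(6, 2))
  expect_true(all(bc$bc >= 0 & bc$bc <= 1))
  expect_true(all(bc$subject_a < bc$subject_b))
  # zero iff equal columns
  expect_true(all(bc$bc > 0))
  # all-zero column reported as NA pairs
  v <- tab$values
  v[, "S01"] <- 0
  expect_warning(bc0 <- bray_curtis(abundance_table(v, "MG", "genus")), "S01")
  expect_true(all(is.na(bc0$bc[bc0$subject_a == "S01"])))
})

test_that("compare_dissimilarity matches exact signed-rank enumeration on 6 pairs", {
  x <- c(0.40, 0.55, 0.38, 0.61, 0.52, 0.47)
  y <- c(0.31, 0.42, 0.40, 0.50, 0.40, 0.39)  # distinct |differences|, no zeros
  got <- compare_dissimilarity(x, y)
  # oracle: enumerate all 2^6 sign assignments of the ranked |d|
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% r
  p_exact <- mean(v_all >= max(v_obs, sum(r) - v_obs)) +
    mean(v_all <= min(v_obs, sum(r) - v_obs))
  expect_equal(got$p_two_tailed, p_exact)
  expect_equal(got$statistic, v_obs)
  # identical sets -> p = 1
  same <- compare_dissimilarity(x, x)
  expect_equal(same$p_two_tailed, 1)
  expect_equal(same$statistic, 0)
  expect_error(compare_dissimilarity(x, y[1:3]), class = "mgmp_alignment_error")
})

test_that("higher MP functional dispersion yields the expected direction", {
  spec <- null_cohort_spec(n_subjects = 8, n_features = 20, depth = 1e4, seed = 81,
                           dispersion = 50)
  spec$mp_function_dispersion <- 5  # noisy expressed profiles
  # give every genus a spread repertoire so profile noise can act
  k <- length(spec$functions)
  prof <- matrix(1 / k, k, k, dimnames = dimnames(spec$function_profile))
  spec$function_profile <- prof
  rec <- generate_cohort(spec)
  tr <- spec$taxonomy
  bmg <- bray_curtis(relative_abundance(rec, "KO", tr, layer = "MG"))
  bmp <- bray_curtis(relative_abundance(rec, "KO", tr, layer = "MP"))
  cmp <- compare_dissimilarity(bmp, bmg)
  expect_gt(cmp$median_difference, 0)  # MP more dissimilar than MG
  expect_lt(cmp$p_two_tailed, 0.05)
})

test_that("cv_classify computes CV in percent with strict thresholds", {
  v <- rbind(const = rep(2e-3, 5),
             spike = c(1, 1, 1, 1, 21) * 1e-3,
             zero  = rep(0, 5))
  colnames(v) <- paste0("S", 1:5)
  tab <- abundance_table(v, "MG", "genus")
  expect_message(cv <- cv_classify(tab), "zero mean")
  expect_equal(nrow(cv), 2)
  expect_equal(cv$cv_percent[cv$feature == "const"], 0)
  expect_equal(cv$klass[cv$feature == "const"], "conserved")
  i <- cv$feature == "spike"
  expect_equal(cv$mean_abundance[i], 5e-3)
  expect_equal(cv$cv_percent[i], 100 * sd(c(1, 1, 1, 1, 21) * 1e-3) / 5e-3)
  expect_equal(cv$cv_percent[i], 178.9, tolerance = 1e-3)
  expect_equal(cv$klass[i], "variable")

  # boundary: cv exactly at the threshold is intermediate (strict inequality)
  x <- c(0, 0, 3)  # mean 1, sample sd sqrt(3): cv = 173.2%
  xm <- matrix(x, 1, 3, dimnames = list("f", paste0("S", 1:3)))
  cv150 <- cv_classify(abundance_table(xm, "MG", "genus"),
                       high = 100 * sd(x) / mean(x), low = 60)
  expect_equal(cv150$klass, "intermediate")

  # scale invariance
  tab2 <- abundance_table(v[1:2, ] * 7, "MG", "genus")
  cv2 <- cv_classify(tab2)
  expect_equal(cv2$cv_percent, cv$cv_percent)
})

test_that("spearman_between_layers matches a rank-then-Pearson oracle", {
  subj <- paste0("S", 1:3)
  feats <- paste0("f", 1:6)
  set.seed(9)
  a <- matrix(runif(18), 6, 3, dimnames = list(feats, subj))
  b <- matrix(runif(18), 6, 3, dimnames = list(feats, subj))
  b[2, ] <- a[2, ]  # introduce ties against itself elsewhere
  a[3, 1] <- a[4, 1]  # tie within a subject vector
  sp <- spearman_between_layers(abundance_table(a, "MG", "KO"),
                                abundance_table(b, "MP", "KO"))
  for (j in seq_along(subj)) {
    oracle <- cor(rank(a[, j]), rank(b[, j]), method = "pearson")
    expect_equal(unname(sp$per_subject[j]), oracle, tolerance = 1e-12)
  }
  # identical and reversed vectors
  one <- matrix(c(1:6) / 21, 6, 1, dimnames = list(feats, "S1"))
  two <- matrix(c(6:1) / 21, 6, 1, dimnames = list(feats, "S1"))
  both <- cbind(one, S2 = one[, 1])
  rev2 <- cbind(two, S2 = one[, 1])
  sp2 <- spearman_between_layers(abundance_table(both, "MG", "KO"),
                                 abundance_table(rev2, "MP", "KO"))
  expect_equal(unname(sp2$per_subject), c(-1, 1))

  # < 3 detected features -> subject excluded
  small_a <- matrix(c(0.5, 0.5, 0, 0, 0, 0), 6, 1, dimnames = list(feats, "S1"))
  small_b <- small_a
  expect_message(
    sp3 <- spearman_between_layers(
      abundance_table(cbind(small_a, S2 = a[, 1]), "MG", "KO"),
      abundance_table(cbind(small_b, S2 = b[, 1]), "MP", "KO")),
    "undefined")
  expect_true(is.na(sp3$per_subject["S1"]))
  expect_equal(sp3$n_used, 1)
})
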