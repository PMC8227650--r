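test_that("fishers_ratio matches hand computation and its invariances", {
  expect_equal(fishers_ratio(c(0, 2), c(4, 6)), 1.0)
  x <- rnorm(20); expect_equal(fishers_ratio(x, x), 0)
  expect_error(fishers_ratio(1, c(1, 2)), "at least 2")
  expect_error(fishers_ratio(rep(1, 5), rep(1, 5)), "zero total variance")

  set.seed(1)
  x0 <- rnorm(15); x1 <- rnorm(15, 1)
  expect_equal(fishers_ratio(x0 + 7, x1 + 7), fishers_ratio(x0, x1))
  for (s in c(0.5, 3)) {
    expect_equal(fishers_ratio(s * x0, s * x1), fishers_ratio(x0, x1) / s,
                 tolerance = 1e-12)
  }
})

test_that("auroc equals brute-force pair counting and handles edge cases", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), ci = FALSE)$auroc,
               0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), ci = FALSE)$auroc, 1)
  expect_equal(auroc(rep(2, 10), rep(0:1, 5), ci = FALSE)$auroc, 0.5)
  expect_error(auroc(1:5, rep(1, 5)), "both classes")

  set.seed(2)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(auroc(scores, labels, ci = FALSE)$auroc,
                 auroc_brute(scores, labels))
  }
})

test_that("auroc bootstrap CI brackets the point estimate and is seeded", {
  set.seed(3)
  subj <- rep(paste0("s", 1:6), each = 10)
  lab <- rep(rep(0:1, each = 5), 6)
  sc <- rnorm(60) + lab
  a1 <- auroc(sc, lab, subjects = subj, n_boot = 300, seed = 5)
  a2 <- auroc(sc, lab, subjects = subj, n_boot = 300, seed = 5)
  expect_identical(a1, a2)
  expect_lte(a1$ci_low, a1$auroc)
  expect_gte(a1$ci_high, a1$auroc)
})

test_that("KS normality test is calibrated on normal and exponential data", {
  set.seed(4)
  p_norm <- replicate(60, ks_normality(rnorm(500)))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(60, ks_normality(rexp(500)))
  expect_gte(mean(p_exp < 0.05), 0.9)
  expect_error(ks_normality(1:4), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "degenerate")
})

test_that("nested rank test detects separation, reduces cleanly, reproduces", {
  set.seed(5)
  n_sub <- 5
  subj <- rep(paste0("s", 1:n_sub), each = 10)
  lab <- rep(rep(0:1, each = 5), n_sub)
  sep <- lab * 10 + rnorm(50, 0, 0.1)     # complete separation in every subject
  r <- nested_rank_test(sep, lab, subj, n_perm = 500, seed = 1)
  expect_lt(r$p_value, 0.01)

  # single subject reduces to a within-subject permutation rank-sum
  one <- subj == "s1"
  direct <- local({
    v <- sep[one]; l <- lab[one]
    zs <- function(ll) {
      r <- rank(v); n1 <- sum(ll); n0 <- sum(!ll); n <- n0 + n1
      (sum(r[ll == 1]) - n1 * (n + 1) / 2) / sqrt(n0 * n1 * (n + 1) / 12)
    }
    obs <- zs(l)
    set.seed(9)
    perm <- replicate(500, zs(l[sample.int(length(l))]))
    (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / 501
  })
  pkg <- nested_rank_test(sep[one], lab[one], subj[one], n_perm = 500, seed = 9)
  expect_equal(pkg$p_value, direct)

  # reproducibility under a fixed seed; subjects lacking a class are dropped
  a <- nested_rank_test(sep, lab, subj, n_perm = 300, seed = 2)
  b <- nested_rank_test(sep, lab, subj, n_perm = 300, seed = 2)
  expect_identical(a, b)
  lab2 <- lab; lab2[subj == "s5"] <- 0
  expect_warning(r2 <- nested_rank_test(sep, lab2, subj, n_perm = 100, seed = 1),
                 "excluded")
  expect_equal(r2$n_subjects, n_sub - 1L)
})

test_that("feature comparison table covers the six features", {
  set.seed(6)
  seg <- tidyr::expand_grid(subject_id = paste0("s", 1:6), event = 1:5,
                            label = 0:1)
  for (f in edapain:::feature_names()) {
    seg[[f]] <- rnorm(nrow(seg)) + seg$label * (f == "mtvsymp_max")
  }
  cmp <- compare_segment_features(seg, n_perm = 200, n_boot = 200, seed = 1)
  expect_equal(nrow(cmp), 6L)
  expect_true(all(cmp$fishers_ratio >= 0))
  expect_true(all(cmp$auroc >= 0 & cmp$auroc <= 1))
  expect_equal(glance(cmp)$best_feature, "mtvsymp_max")
})
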