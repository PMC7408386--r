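test_that("total area closes each sample to sum one and is idempotent", {
  m <- matrix(c(2, 3, 5), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(total_area(m)[1, ]), c(0.2, 0.3, 0.5))
  x <- rand_pos_matrix(10, 6, seed = 3)
  ta <- total_area(x)
  expect_equal(unname(rowSums(ta)), rep(1, 10), tolerance = 1e-12)
  expect_equal(total_area(ta), ta, tolerance = 1e-12)
  bad <- x; bad[4, ] <- 0
  expect_error(total_area(bad), "S4")
})

test_that("closure induces at least one negative covariance entry per row", {
  for (seed in 1:50) {
    x <- rand_pos_matrix(12, 6, seed = seed)
    cv <- stats::cov(total_area(x))
    expect_true(all(apply(cv, 1, function(r) any(r < 0))),
                label = paste("seed", seed))
  }
})

test_that("median centering subtracts the right median in both modes", {
  m <- matrix(c(1, 2, 9), 1, 3)
  expect_equal(unname(median_center(m)[1, ]), c(-1, 0, 7))
  mc <- matrix(c(1, 3, 5), 3, 1)
  expect_equal(unname(median_center(mc, "per_glycan")[, 1]), c(-2, 0, 2))
  const <- matrix(4, 5, 3)
  expect_true(all(median_center(const) == 0))
  expect_true(all(median_center(const, "per_glycan") == 0))
})

test_that("probabilistic quotient recovers the dilution structure", {
  base <- c(1, 2, 4, 8)
  m <- rbind(s1 = base, s2 = 2 * base, s3 = base)
  out <- probabilistic_quotient(m)
  f <- dilution_factors(out)
  expect_equal(unname(f), c(1, 2, 1))
  expect_equal(unname(out["s2", ]), base)   # 2x reference maps onto it
  # dataset equal to its reference everywhere -> identity, all f = 1
  same <- matrix(rep(base, 3), 3, byrow = TRUE)
  out2 <- probabilistic_quotient(same)
  expect_equal(unname(dilution_factors(out2)), rep(1, 3))
  expect_equal(abundmat(out2), same)
})

test_that("quotient normalization recovers injected log-normal dilution
           factors", {
  pw <- igg1_pathway()
  cfg <- simulation_config(pw, n = 200, rho = 0.3, sigma = 0.05,
                           sigma_d = 0.5, seed = 5)
  d <- apply_artifacts(sample_abundances(cfg), cfg)
  fhat <- dilution_factors(probabilistic_quotient(d))
  ftrue <- simulation_truth(d)$dilution
  expect_gte(stats::cor(fhat, ftrue, method = "spearman"), 0.99)
})

test_that("TA+quotient composes the two audited steps in fixed order", {
  x <- rand_pos_matrix(15, 7, seed = 4)
  expect_equal(abundmat(ta_quotient(x)),
               abundmat(probabilistic_quotient(total_area(x))))
  # single-sample quotient is identity: f = 1
  one <- matrix(c(2, 3, 5), 1, 3)
  expect_equal(unname(ta_quotient(one)[1, ]), c(0.2, 0.3, 0.5))
  # scale invariance: rescaling one sample changes nothing after TA
  y <- x; y[3, ] <- 10 * y[3, ]
  expect_equal(abundmat(ta_quotient(y)), abundmat(ta_quotient(x)),
               tolerance = 1e-12)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))
  same <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantile_normalize(same), same)
  x <- rand_pos_matrix(50, 8, seed = 6)
  qx <- quantile_normalize(x)
  sorted <- apply(qx, 2, sort)
  for (j in 2:8) expect_equal(sorted[, j], sorted[, 1])
})

test_that("rank transform assigns average ranks per glycan", {
  expect_equal(unname(rank_transform(matrix(c(10, 30, 20), 3, 1))[, 1]),
               c(1, 3, 2))
  expect_equal(unname(rank_transform(matrix(c(5, 5, 1), 3, 1))[, 1]),
               c(2.5, 2.5, 1))
})

test_that("monotone per-column transforms leave ranks unchanged and the
           quantile-normalized rank structure intact", {
  x <- rand_pos_matrix(30, 5, seed = 7)
  y <- x
  y[, 1] <- exp(y[, 1]); y[, 2] <- y[, 2]^3; y[, 3] <- 2 * y[, 3] + 1
  expect_equal(rank_transform(y), rank_transform(x))
  # quantile normalization maps values through the pooled quantile means,
  # so its output values change with the input scale — but which sample
  # lands on which quantile is purely rank-based and hence invariant
  expect_equal(rank_transform(quantile_normalize(y)),
               rank_transform(quantile_normalize(x)))
})

test_that("log transform is the natural log and rejects non-positive cells", {
  expect_equal(unname(log_transform(matrix(1, 1, 1))), matrix(0, 1, 1),
               ignore_attr = TRUE)
  expect_equal(unname(log_transform(matrix(c(exp(1), exp(2)), 1, 2))[1, ]),
               c(1, 2))
  bad <- rand_pos_matrix(3, 2, seed = 8)
  bad[2, 1] <- 0
  expect_error(log_transform(bad), "S2.*G1")
  # not a no-op: correlations change on skewed data
  x <- rand_pos_matrix(100, 3, seed = 9, sdlog = 2)
  expect_false(isTRUE(all.equal(stats::cor(x), stats::cor(log(x)))))
})

test_that("per-subclass application normalizes blocks independently", {
  d <- lc_dataset(n = 30, seed = 10)
  ta_sub <- apply_per_subclass(d, total_area)
  for (sc in unique(d$glycan_meta$subclass)) {
    sel <- d$glycan_meta$subclass == sc
    expect_equal(unname(rowSums(ta_sub$abundance[, sel])), rep(1, 30),
                 tolerance = 1e-12)
  }
  # single-subclass dataset: per-subclass equals whole-dataset application
  one <- d
  one$abundance <- d$abundance[, 1:20]
  one$glycan_meta <- d$glycan_meta[1:20, , drop = FALSE]
  expect_equal(apply_per_subclass(one, total_area)$abundance,
               total_area(one)$abundance)
  no_meta <- glycomics_dataset(rand_pos_matrix(5, 4))
  expect_error(apply_per_subclass(no_meta, total_area), "subclass")
})

test_that("per-subclass quotient equals whole-dataset quotient when blocks
           share the dilution structure", {
  # build data where each block is the same matrix scaled per sample
  set.seed(11)
  n <- 20
  f <- exp(rnorm(n, 0, 0.4))
  block <- rand_pos_matrix(n, 5, seed = 12)
  m <- cbind(block * f, 3 * block * f)
  colnames(m) <- paste0("g", 1:10)
  sub <- rep(c("A", "B"), each = 5)
  whole <- probabilistic_quotient(m)
  per <- apply_per_subclass(m, probabilistic_quotient, subclass = sub)
  expect_equal(abundmat(per), abundmat(whole), tolerance = 1e-12)
})

test_that("strategy specs enforce the menu's validity rules", {
  expect_error(normalization_spec("median", log = TRUE), "log")
  expect_error(normalization_spec("raw", per_subclass = TRUE), "per-subclass")
  expect_error(normalization_spec("median", per_subclass = TRUE))
  sp <- normalization_spec("taquotient", log = TRUE, per_subclass = TRUE)
  expect_equal(sp$label, "TAQuotient log subclass")
})

test_that("the strategy enumerator yields 13 base and 23 subclass-platform
           strategies with the canonical labels", {
  base13 <- c("Raw", "Quantile", "Rank", "TA", "Median", "Quotient",
              "TAQuotient", "Raw log", "Quantile log", "Rank log", "TA log",
              "Quotient log", "TAQuotient log")
  sub10 <- c("Quantile subclass", "Rank subclass", "TA subclass",
             "Quotient subclass", "TAQuotient subclass",
             "Quantile log subclass", "Rank log subclass",
             "TA log subclass", "Quotient log subclass",
             "TAQuotient log subclass")
  for (pf in c("uhplc-fld", "maldi-fticr-ms", "generic")) {
    labs <- strategy_labels(enumerate_strategies(pf))
    expect_length(labs, 13)
    expect_setequal(labs, base13)
  }
  labs <- strategy_labels(enumerate_strategies("lc-esi-ms"))
  expect_length(labs, 23)
  expect_setequal(labs, c(base13, sub10))
  expect_false(anyDuplicated(labs) > 0)
})

test_that("apply_strategy dispatches base, log and subclass composition", {
  m <- matrix(c(2, 3, 5), 1, 3)
  expect_identical(apply_strategy(normalization_spec("raw"), m), m)
  expect_equal(unname(apply_strategy(normalization_spec("ta", log = TRUE),
                                     m)[1, ]),
               log(c(0.2, 0.3, 0.5)))
  d <- lc_dataset(n = 25, seed = 13)
  for (spec in enumerate_strategies("lc-esi-ms")) {
    out <- apply_strategy(spec, d)
    expect_true(all(is.finite(out$abundance)), label = spec$label)
    expect_equal(dim(out$abundance), dim(d$abundance))
  }
})

test_that("a log strategy equals log_transform of its base strategy", {
  d <- lc_dataset(n = 25, seed = 14)
  for (base in c("raw", "ta", "quotient", "taquotient", "quantile", "rank")) {
    with_log <- apply_strategy(normalization_spec(base, log = TRUE), d)
    without <- apply_strategy(normalization_spec(base), d)
    expect_equal(with_log$abundance, log_transform(without)$abundance,
                 label = base)
  }
})
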