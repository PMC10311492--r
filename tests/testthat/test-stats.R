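test_that("the quantitative decision tree matches direct Shapiro/Levene checks", {
  withr::with_seed(31, {
    xn <- rnorm(40, 10, 2); yn <- rnorm(35, 11, 2)
    xe <- rexp(40); ye <- rexp(35, 0.7)
    yw <- rnorm(35, 11, 8)
  })
  res <- compare_quantitative(xn, yn, variable = "normal-equal")
  expect_true(shapiro.test(xn)$p.value > 0.05 && shapiro.test(yn)$p.value > 0.05)
  expect_identical(res$test_name, "pooled-t")
  expect_identical(length(res$selection_trace), 3L)

  res_e <- compare_quantitative(xe, ye)
  expect_true(shapiro.test(xe)$p.value <= 0.05)
  expect_identical(res_e$test_name, "mann-whitney")
  expect_equal(res_e$p_value,
               suppressWarnings(wilcox.test(xe, ye, exact = FALSE, correct = TRUE)$p.value))

  res_w <- compare_quantitative(xn, yw, variable = "normal-unequal")
  if (shapiro.test(yw)$p.value > 0.05) {
    lev <- fracmap3d:::levene_test(xn, yw)
    expect_identical(res_w$test_name, if (lev$p.value > 0.05) "pooled-t" else "welch-t")
  }
})

test_that("pooled-t on samples matches the closed-form evaluation to 1e-10", {
  withr::with_seed(8, { x <- rnorm(25, 5, 1); y <- rnorm(30, 5.5, 1) })
  res <- compare_quantitative(x, y)
  expect_identical(res$test_name, "pooled-t")
  ref <- t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 30, "pooled")
  expect_equal(res$p_value, ref$p_value, tolerance = 1e-10)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
})

test_that("identical samples give t = 0, p = 1; constants route to Mann-Whitney", {
  withr::with_seed(3, x <- rnorm(20, 5, 1))
  res <- compare_quantitative(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  resc <- compare_quantitative(rep(2, 10), rep(2.5, 12))
  expect_identical(resc$test_name, "mann-whitney")
  expect_match(resc$selection_trace[[1]]$decision, "constant")
  expect_error(compare_quantitative(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("summary t-tests handle degenerate inputs per contract", {
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10, "pooled")$p_value, 1)
  r0 <- t_from_summary(5, 0, 10, 5, 0, 10, "pooled")
  expect_equal(r0$p_value, 1)
  expect_error(t_from_summary(5, 0, 10, 6, 0, 10, "pooled"), "undefined")
  expect_error(t_from_summary(5, -1, 10, 6, 1, 10), ">= 0")
  w <- t_from_summary(10, 2, 12, 11, 5, 40, "welch")
  v1 <- 4 / 12; v2 <- 25 / 40
  expect_equal(w$df, (v1 + v2)^2 / (v1^2 / 11 + v2^2 / 39))
})

test_that("categorical comparison selects chi-square vs Fisher by the 20% rule", {
  mech <- matrix(c(13, 31, 5, 4, 8, 7, 5, 1), ncol = 2)
  expected <- outer(rowSums(mech), colSums(mech)) / sum(mech)
  expect_gt(mean(expected < 5), 0.2)
  expect_identical(compare_categorical(mech)$test_name, "fisher-exact")

  sex <- matrix(c(25, 28, 15, 6), 2)
  expect_identical(compare_categorical(sex)$test_name, "chi-square")
  # no continuity correction
  expect_equal(compare_categorical(sex)$p_value,
               chisq.test(sex, correct = FALSE)$p.value)

  prop <- matrix(c(10, 20, 5, 10), 2)
  res <- compare_categorical(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(compare_categorical(matrix(c(0, 3, 0, 4), 2)),
               "zero margin in row")
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2)),
               "zero margin in column")
  expect_error(compare_categorical(matrix(c(1, 2), 1)), "2 x 2")
})

test_that("Fisher p equals brute-force enumeration over fixed margins", {
  # independent oracle: enumerate all tables with the observed margins,
  # two-sided p = sum of probabilities <= observed (hypergeometric model)
  fisher_oracle_2x2 <- function(tab) {
    r <- rowSums(tab); cs <- colSums(tab)
    a_range <- max(0, r[1] - cs[2]):min(r[1], cs[1])
    probs <- vapply(a_range, function(a) {
      m <- matrix(c(a, cs[1] - a, r[1] - a, cs[2] - r[1] + a), 2)
      exp(sum(lfactorial(r)) + sum(lfactorial(cs)) -
            lfactorial(sum(m)) - sum(lfactorial(m)))
    }, numeric(1))
    p_obs <- probs[match(tab[1, 1], a_range)]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tables <- list(matrix(c(3, 5, 7, 2), 2), matrix(c(1, 9, 8, 2), 2),
                 matrix(c(6, 6, 6, 6), 2), matrix(c(0, 10, 10, 5), 2),
                 matrix(c(12, 3, 4, 11), 2))
  for (tab in tables)
    expect_equal(fisher.test(tab)$p.value, fisher_oracle_2x2(tab),
                 tolerance = 1e-7, label = paste(tab, collapse = ","))

  # 2x3: enumerate exhaustively
  fisher_oracle_2x3 <- function(tab) {
    r <- rowSums(tab); cs <- colSums(tab)
    dens <- function(m) exp(sum(lfactorial(r)) + sum(lfactorial(cs)) -
                              lfactorial(sum(m)) - sum(lfactorial(m)))
    p_obs <- dens(tab)
    total <- 0
    for (a in 0:min(r[1], cs[1])) for (b in 0:min(r[1] - a, cs[2])) {
      cxx <- r[1] - a - b
      if (cxx > cs[3]) next
      m <- rbind(c(a, b, cxx), c(cs[1] - a, cs[2] - b, cs[3] - cxx))
      if (any(m < 0)) next
      d <- dens(m)
      if (d <= p_obs * (1 + 1e-7)) total <- total + d
    }
    total
  }
  t23 <- matrix(c(4, 2, 3, 6, 1, 7), 2)
  expect_equal(fisher.test(t23)$p.value, fisher_oracle_2x3(t23), tolerance = 1e-7)
  t23b <- matrix(c(1, 5, 6, 2, 3, 3), 2)
  expect_equal(fisher.test(t23b)$p.value, fisher_oracle_2x3(t23b), tolerance = 1e-7)
})

test_that("categorical p-values are invariant to row/column permutation", {
  mech <- matrix(c(13, 31, 5, 4, 8, 7, 5, 1), ncol = 2)
  p0 <- compare_categorical(mech)$p_value
  expect_equal(compare_categorical(mech[c(3, 1, 4, 2), ])$p_value, p0)
  expect_equal(compare_categorical(mech[, c(2, 1)])$p_value, p0)
  sex <- matrix(c(25, 28, 15, 6), 2)
  expect_equal(compare_categorical(sex[c(2, 1), ])$p_value,
               compare_categorical(sex)$p_value)
})

test_that("summary cells follow the normality gate", {
  withr::with_seed(10, {
    xn <- rnorm(30, 20, 3)
    xl <- exp(rnorm(20, 0, 1.5))
  })
  sn <- summarize_sample(xn)
  expect_identical(sn$mode, if (shapiro.test(xn)$p.value > 0.05) "mean_sd" else "median_iqr")
  sl <- summarize_sample(xl)
  expect_identical(sl$mode, "median_iqr")
  expect_equal(unname(sl$values["iqr"]),
               unname(diff(quantile(xl, c(0.25, 0.75)))))
  s1 <- summarize_sample(5)
  expect_identical(s1$mode, "median_iqr")
  expect_equal(unname(s1$values), c(5, 0))
  expect_match(s1$note, "n < 3")
})

test_that("cohort reports cover every variable and flag the planted effect", {
  recs <- simulate_cohort_records(53, 21, seed = 19)
  rep <- cohort_report(recs)
  expect_setequal(rep$variable,
                  c("age", "height", "weight", "bmi", "n_fragments", "n_comminuted",
                    "mean_comminuted_volume", "sex", "side", "mechanism",
                    "has_comminution"))
  expect_false(anyNA(rep$p_value))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_error(cohort_report(recs[recs$ao_class == "33A", ]), "both fracture classes")
})

test_that("the planted fragment-count difference is detected in >= 18/20 seeds", {
  hits <- vapply(1:20, function(s) {
    recs <- simulate_cohort_records(53, 21, seed = 100 + s)
    rep <- cohort_report(recs)
    rep$p_value[rep$variable == "n_fragments"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("null cohorts produce no more false flags than chance allows", {
  null_cfg <- cohort_config()
  for (nm in c("sex_male_prob", "side_left_prob", "mechanism_prob",
               "main_fragments", "comminution"))
    null_cfg[[nm]][["33C"]] <- null_cfg[[nm]][["33A"]]
  false_flags <- vapply(1:20, function(s) {
    recs <- simulate_cohort_records(37, 37, config = null_cfg, seed = 500 + s)
    rep <- tryCatch(cohort_report(recs), error = function(e) NULL)
    if (is.null(rep)) return(NA_real_)
    mean(rep$significant)
  }, numeric(1))
  # ~11 variables at alpha 0.05: average false-flag rate should stay near 5%
  expect_lt(mean(false_flags, na.rm = TRUE), 0.15)
})
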