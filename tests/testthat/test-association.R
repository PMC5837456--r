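# Regression dispatch and the scan-level filters, checked against independent
# oracles: normal equations, the 2x2 odds-ratio closed form, a grid-search
# proportional-odds maximiser, and directly evaluated multinomial likelihoods.

test_that("linear test recovers the identity and matches the normal equations", {
  # outcome == trait: slope exactly 1, zero residual variance
  tr <- rnorm(10)
  ds <- make_dataset(tr)
  res <- suppressWarnings(test_linear(dv(tr, "CONTINUOUS"), ds, no_conf_spec()))
  expect_equal(res$estimate, 1.0, tolerance = 1e-10)
  expect_equal(res$n, 10L)

  # small dataset with one confounder: coefficient from the normal equations
  set.seed(21)
  z <- rnorm(6); t6 <- rnorm(6); y <- 0.5 * t6 + 0.3 * z + rnorm(6)
  ds2 <- make_dataset(t6, confounders = data.frame(z = z))
  res2 <- test_linear(dv(y, "CONTINUOUS"), ds2, model_spec("trait", "z"))
  beta <- ols_oracle(y, cbind(t6, z))
  expect_equal(res2$estimate, beta[2], tolerance = 1e-8)

  # seeded permutation null: near-zero estimate, unremarkable p
  set.seed(77)
  t10k <- rnorm(10000)
  y0 <- sample(t10k)
  res3 <- test_linear(dv(y0, "CONTINUOUS"), make_dataset(t10k), no_conf_spec())
  expect_lt(abs(res3$estimate), 0.05)
  expect_gt(res3$p_value, 1e-4)

  # constant trait on complete cases
  expect_error(test_linear(dv(rnorm(10), "CONTINUOUS"), make_dataset(rep(1, 10)),
                           no_conf_spec()),
               class = "phs_degenerate_exposure")
})

test_that("logistic test matches the 2x2 closed-form odds ratio", {
  # exposed cases a=100, exposed controls b=200, unexposed cases c=300,
  # unexposed controls d=400
  a <- 100; b <- 200; cc <- 300; d <- 400
  trait <- c(rep(1, a + b), rep(0, cc + d))
  outcome <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  res <- test_logistic(dv(outcome, "BINARY"), make_dataset(trait), no_conf_spec())
  expect_equal(res$estimate, (a * d) / (b * cc), tolerance = 1e-6)
  expect_true(res$ci_lower <= res$estimate && res$estimate <= res$ci_upper)

  # single outcome class
  expect_error(test_logistic(dv(rep(1, 600), "BINARY"),
                             make_dataset(rnorm(600)), no_conf_spec()),
               class = "phs_degenerate_outcome")

  # complete separation: retained with converged = FALSE and no p-value
  x <- c(rnorm(50, -3), rnorm(50, 3))
  y <- rep(c(0, 1), each = 50)
  res2 <- test_logistic(dv(y, "BINARY"), make_dataset(x), no_conf_spec())
  expect_false(res2$converged)
  expect_true(is.na(res2$p_value))
})

test_that("ordered test maximises the proportional-odds likelihood", {
  set.seed(31)
  n <- 600
  x <- rnorm(n)
  latent <- 0.6 * x + rlogis(n)
  y <- cut(latent, c(-Inf, -0.5, 0.7, Inf), labels = FALSE)
  ds <- make_dataset(x)
  res <- test_ordered(dv(y, "ORDERED"), ds, no_conf_spec())
  b_grid <- polr3_grid_oracle(y, x)
  expect_equal(log(res$estimate), b_grid, tolerance = 1e-3)
  expect_lt(res$p_value, 1e-6)

  # wald and lrt p-values agree to leading order here
  res_w <- test_ordered(dv(y, "ORDERED"), ds, no_conf_spec(), p_method = "wald")
  expect_equal(res_w$estimate, res$estimate)
  expect_equal(log(res_w$p_value), log(res$p_value), tolerance = 0.2)

  # an ordered outcome observed at 2 levels equals the logistic route
  y2 <- as.integer(y >= 2) + 1L
  res2 <- test_ordered(dv(y2, "ORDERED"), ds, no_conf_spec())
  res2l <- test_logistic(dv(y2, "BINARY"), ds, no_conf_spec())
  expect_equal(res2$estimate, res2l$estimate, tolerance = 1e-6)
  expect_equal(res2$p_value, res2l$p_value, tolerance = 1e-6)

  expect_error(test_ordered(dv(y, "ORDERED"), make_dataset(rep(0, n)),
                            no_conf_spec()),
               class = "phs_degenerate_exposure")
})

test_that("unordered LRT equals twice the independently evaluated log-likelihood gap", {
  set.seed(41)
  n <- 800
  x <- rnorm(n)
  util <- matrix(rnorm(n * 4), n, 4)
  util[, 2] <- util[, 2] + 0.5 * x
  y <- max.col(util)
  ds <- make_dataset(x)
  res <- test_unordered_lrt(dv(y, "UNORDERED"), ds, no_conf_spec())
  expect_true(is.na(res$estimate) && is.na(res$ci_lower) && is.na(res$ci_upper))

  yf <- factor(y)
  fit1 <- nnet::multinom(yf ~ x, trace = FALSE)
  fit0 <- nnet::multinom(yf ~ 1, trace = FALSE)
  stat_oracle <- 2 * (multinom_loglik_oracle(fit1, yf) -
                        multinom_loglik_oracle(fit0, yf))
  stat_pkg <- qchisq(res$p_value, df = 3, lower.tail = FALSE)
  expect_equal(stat_pkg, stat_oracle, tolerance = 1e-6)

  # nesting: the statistic is non-negative across seeded null datasets
  for (s in 1:25) {
    set.seed(s)
    yn <- sample(1:3, 600, TRUE)
    xn <- rnorm(600)
    r <- test_unordered_lrt(dv(yn, "UNORDERED"), make_dataset(xn), no_conf_spec())
    expect_gte(qchisq(r$p_value, df = 2, lower.tail = FALSE), 0)
    expect_gt(r$p_value, 0)
  }
})

test_that("scan filters: sample size boundary at 500, category limit at 1000", {
  set.seed(51)
  n <- 1200
  trait <- rnorm(n)
  ds <- make_dataset(trait)
  spec <- no_conf_spec()

  vals499 <- c(rnorm(499), rep(NA, n - 499))
  vals500 <- c(rnorm(500), rep(NA, n - 500))
  out <- run_scan(list(dv(vals499, "CONTINUOUS", name = "a", field_id = 1L),
                       dv(vals500, "CONTINUOUS", name = "b", field_id = 2L)),
                  ds, spec)
  expect_equal(out$counters$removed_small_n, 1L)
  expect_equal(out$results$varName, "b")
  expect_equal(out$results$n, 500L)

  # 1000 categories admitted, 1001 removed and counted
  y1000 <- rep(1:1000, length.out = 3000)
  y1001 <- rep(1:1001, length.out = 3003)
  ds2 <- make_dataset(rnorm(3003))
  out2 <- run_scan(list(dv(y1001, "UNORDERED", name = "big", field_id = 3L)),
                   ds2, spec)
  expect_equal(out2$counters$removed_too_many_categories, 1L)
  expect_equal(nrow(out2$results), 0L)
  ds3 <- make_dataset(rnorm(3000))
  out3 <- run_scan(list(dv(y1000, "UNORDERED", name = "ok", field_id = 4L)),
                   ds3, spec)
  expect_equal(nrow(out3$results), 1L)
  expect_false(is.na(out3$results$p_value))
})

test_that("dispatch is total over a mixed variable set", {
  set.seed(61)
  n <- 700
  trait <- rnorm(n)
  ds <- make_dataset(trait, confounders = data.frame(
    age = round(runif(n, 40, 70)), sex = rbinom(n, 1, 0.5)))
  spec <- model_spec("trait", c("age", "sex"))
  derived <- list(
    dv(rnorm(n), "CONTINUOUS", name = "c", field_id = 1L),
    dv(sample(1:4, n, TRUE), "ORDERED", name = "o", field_id = 2L),
    dv(sample(1:4, n, TRUE), "UNORDERED", name = "u", field_id = 3L),
    dv(rbinom(n, 1, 0.4), "BINARY", name = "b", field_id = 4L),
    dv(c(rnorm(400), rep(NA, n - 400)), "CONTINUOUS", name = "small", field_id = 5L),
    dv(rep(1, n), "BINARY", name = "flat", field_id = 6L))
  out <- run_scan(derived, ds, spec)
  ct <- out$counters
  expect_equal(ct$variables_entered,
               ct$tested + ct$removed_small_n + ct$removed_too_many_categories +
                 ct$removed_degenerate)
  expect_equal(nrow(out$results), 4L)
  expect_setequal(out$results$data_type,
                  c("CONTINUOUS", "ORDERED", "UNORDERED", "BINARY"))
  # estimate present iff the model has an overall estimate
  expect_true(all(is.na(out$results[data_type == "UNORDERED", estimate])))
  expect_true(all(!is.na(out$results[data_type != "UNORDERED", estimate])))
})

test_that("confounder adjustment removes confounding bias", {
  # phenotype depends on age; trait correlates with age: the crude estimate is
  # biased away from the null, the adjusted one covers the truth
  covered <- 0L
  for (rep in 1:100) {
    set.seed(100 + rep)
    n <- 1000
    age <- rnorm(n)
    trait <- 0.7 * age + rnorm(n)
    y <- 0.5 * age + rnorm(n)  # true trait effect: zero
    ds <- make_dataset(trait, confounders = data.frame(age = age))
    crude <- test_linear(dv(y, "CONTINUOUS"), ds, no_conf_spec())
    adj <- test_linear(dv(y, "CONTINUOUS"), ds, model_spec("trait", "age"))
    expect_gt(abs(crude$estimate), abs(adj$estimate))
    if (adj$ci_lower <= 0 && 0 <= adj$ci_upper) covered <- covered + 1L
  }
  expect_gte(covered, 90L)  # >= 90% coverage of the true (null) effect
})

test_that("a constant confounder (sex-specific field) is dropped, not fatal", {
  set.seed(71)
  n <- 900
  sex <- rbinom(n, 1, 0.5)
  y <- ifelse(sex == 1, rnorm(n), NA)  # female-only measure
  ds <- make_dataset(rnorm(n), confounders = data.frame(sex = sex))
  res <- test_linear(dv(y, "CONTINUOUS"), ds, model_spec("trait", "sex"))
  expect_true(res$converged)
  expect_equal(res$n, sum(sex == 1))
})
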