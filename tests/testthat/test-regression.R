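test_that("univariate screening keeps real associations and ranks by R2", {
  set.seed(2)
  n <- 200
  x <- rnorm(n)
  noise <- rnorm(n, 0, 1)
  dat <- tibble::tibble(y = 2 * x + noise, x = x, junk = rnorm(n),
                        flat = rep(1, n))
  sc <- univariate_screen(dat, "y", c("x", "junk", "flat"))
  expect_true(sc$keep[sc$candidate == "x"])
  # R2 near its generating value 4 / (4 + 1) = 0.8
  expect_equal(sc$r_squared[sc$candidate == "x"], 0.8, tolerance = 0.05)
  expect_false("flat" %in% sc$candidate)
  expect_match(attr(sc, "warnings"), "flat", all = FALSE)
})

test_that("an uncorrelated candidate is rejected in most seeds (type-I rate)", {
  rejected <- 0
  n_seeds <- 200
  for (s in 1:n_seeds) {
    set.seed(9000 + s)
    n <- 200
    dat <- tibble::tibble(y = rnorm(n), junk = rnorm(n))
    sc <- univariate_screen(dat, "y", "junk")
    rejected <- rejected + !sc$keep[1]
  }
  expect_gte(rejected / n_seeds, 0.85)
})

test_that("screening on a simulated cohort reproduces the reported order:
           sprint velocity, then relative strength, then sport", {
  co <- synth_cohort(2000, seed = 12)
  sc <- univariate_screen(co, "p30_per_kg",
                          c("sprint_v_mean", "f_iso_per_kg", "sport"))
  expect_equal(sc$candidate, c("sprint_v_mean", "f_iso_per_kg", "sport"))
  expect_true(all(sc$keep))
  expect_equal(sc$r_squared, c(0.77, 0.45, 0.31), tolerance = 0.12)
})

test_that("collinearity pruning keeps the best family member above |r| 0.8", {
  set.seed(4)
  n <- 120
  a <- rnorm(n)
  b <- a + rnorm(n, 0, 0.2)          # r(a, b) ~ 0.98
  c_ <- rnorm(n)                     # independent family member
  y <- a + rnorm(n, 0, 0.5)
  dat <- tibble::tibble(y = y, a = a, b = b, c_ = c_)
  sc <- univariate_screen(dat, "y", c("a", "b", "c_"), alpha_in = 1)
  kept <- collinearity_prune(sc, dat, families = list(f = c("a", "b", "c_")))
  expect_true("a" %in% kept)   # higher univariate R2 than b
  expect_false("b" %in% kept)
  expect_true("c_" %in% kept)  # |r| < 0.8 with a, stays

  # family with all pairwise |r| < 0.8 is untouched
  kept2 <- collinearity_prune(sc, dat, families = list(f = c("a", "c_")))
  expect_setequal(kept2, sc$candidate[sc$keep])

  # brute-force rule check on the synthetic sprint block
  co <- synth_cohort(300, seed = 13)
  fam <- c("sprint_v_mean", "sprint_v_max", "sprint_po_mean", "sprint_po_max")
  sc2 <- univariate_screen(co, "p30_per_kg", fam)
  kept3 <- collinearity_prune(sc2, co, families = list(sprint = fam))
  best <- sc2$candidate[which.max(sc2$r_squared)]
  cors <- vapply(setdiff(fam, best), function(v)
    abs(cor(co[[v]], co[[best]])), numeric(1))
  expect_true(best %in% kept3)
  expect_true(all(!names(cors)[cors > 0.8] %in% kept3))
})

test_that("backward elimination drops noise, keeps signal, blocks sport", {
  # single significant predictor: identical to its univariate fit
  set.seed(6)
  n <- 80
  x <- rnorm(n)
  dat <- tibble::tibble(y = 1 + 0.8 * x + rnorm(n, 0, 0.4), x = x)
  m <- backward_eliminate(dat, "y", "x")
  uni <- lm(y ~ x, data = dat)
  expect_equal(m$coefficients$estimate, unname(coef(uni)), tolerance = 1e-12)
  expect_equal(m$r_squared, summary(uni)$r.squared)

  # pure-noise extra predictor at n = 200 is eliminated in most seeds
  dropped <- 0
  for (s in 1:100) {
    set.seed(7000 + s)
    n <- 200
    x <- rnorm(n)
    dat <- tibble::tibble(y = 1 + x + rnorm(n), x = x, junk = rnorm(n))
    m2 <- backward_eliminate(dat, "y", c("x", "junk"))
    dropped <- dropped + !("junk" %in% m2$terms)
  }
  expect_gte(dropped / 100, 0.95)

  # the sport dummies leave as one block or stay as one block
  co <- synth_cohort(43, seed = 77)
  m3 <- backward_eliminate(co, "p30_per_kg", c("sprint_v_mean", "sport"))
  if ("sport" %in% m3$terms) {
    expect_setequal(grep("^sport", m3$coefficients$term, value = TRUE),
                    c("sportracing", "sportbasketball", "sportrugby"))
  } else {
    expect_length(grep("^sport", m3$coefficients$term), 0)
  }
  # protected terms survive regardless of significance
  m4 <- backward_eliminate(co, "p30_per_kg", c("sprint_v_mean", "sport"),
                           protected = "sport")
  expect_true("sport" %in% m4$terms)
})

test_that("backward elimination is invariant to predictor ordering", {
  co <- synth_cohort(60, seed = 21)
  a <- backward_eliminate(co, "p30_per_kg",
                          c("sprint_v_mean", "sport", "f_iso_per_kg", "age"))
  b <- backward_eliminate(co, "p30_per_kg",
                          c("age", "f_iso_per_kg", "sport", "sprint_v_mean"))
  expect_setequal(a$terms, b$terms)
  expect_equal(a$r_squared, b$r_squared)
})

test_that("a refitted model converts to a usable prediction equation", {
  co <- synth_cohort(400, seed = 31)
  m <- backward_eliminate(co, "p30_per_kg", c("sprint_v_mean", "sport"))
  eq <- as_prediction_equation(m, "refit_sprint")
  pro <- std_profile(mass = 70, sport = "rugby")
  pred <- predict_p30(pro, list(sprint_v_mean = 3.0), eq)
  cf <- m$coefficients
  manual <- cf$estimate[cf$term == "(Intercept)"] +
    cf$estimate[cf$term == "sprint_v_mean"] * 3.0 +
    cf$estimate[cf$term == "sportrugby"]
  expect_equal(pred$per_kg, manual)
})

test_that("pred-vs-meas comparison picks its test from the Shapiro-Wilk", {
  # identical vectors: identity, no test
  cmp0 <- compare_pred_meas(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(cmp0$test, "identity")
  expect_equal(cmp0$mean_percent_difference, 0)

  # Gaussian differences, n = 40: paired t chosen in most seeds
  t_chosen <- 0
  for (s in 1:100) {
    set.seed(500 + s)
    meas <- rnorm(40, 100, 10)
    pred <- meas + rnorm(40, 2, 3)
    t_chosen <- t_chosen + (compare_pred_meas(pred, meas)$test == "paired t")
  }
  expect_gte(t_chosen / 100, 0.90)

  # heavily skewed differences: Wilcoxon
  set.seed(99)
  meas <- rnorm(40, 100, 5)
  pred <- meas + rexp(40, 1 / 20)^2 / 10
  expect_equal(compare_pred_meas(pred, meas)$test, "wilcoxon")

  # antisymmetry of the mean percent difference on a fixed denominator
  set.seed(3)
  a <- rnorm(30, 100, 8); b <- rnorm(30, 95, 8)
  d1 <- mean(100 * (a - b) / b)
  cmp <- compare_pred_meas(a, b)
  expect_equal(cmp$mean_percent_difference, d1)
  swapped <- mean(100 * (b - a) / b)  # same denominator convention
  expect_equal(swapped, -d1)
})

test_that("deviation boundaries classify at 20% around the identity line", {
  b <- deviation_bounds(100)
  expect_equal(b$lower, 80)
  expect_equal(b$upper, 120)
  expect_equal(as.character(b$classify(119)), "within")
  expect_equal(as.character(b$classify(121)), "above")
  expect_equal(as.character(b$classify(79)), "below")

  # vectorized classification matches brute-force thresholding
  set.seed(8)
  pred <- runif(200, 50, 150)
  meas <- pred * runif(200, 0.6, 1.4)
  got <- classify_deviation(pred, meas)
  brute <- ifelse(meas > 1.2 * pred, "above",
                  ifelse(meas < 0.8 * pred, "below", "within"))
  expect_equal(as.character(got), brute)

  p <- plot_deviation(pred, meas, lab = "P30 (W)")
  expect_s3_class(p, "ggplot")
})
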