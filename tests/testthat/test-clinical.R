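test_that("KM product-limit matches hand computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)
  # (1+, 2, 2, 3+): only event time 2, three at risk, two events -> S(2) = 1/3
  km2 <- kmEstimate(c(1, 2, 2, 3), c(0, 1, 1, 0))
  expect_equal(km2$curve$time, 2)
  expect_identical(km2$curve$nRisk, 3L)
  expect_equal(km2$curve$survival, 1 / 3, tolerance = 1e-12)
  expect_equal(km2$median, 2)
})

test_that("subjects censored at an event time still count as at risk", {
  km <- kmEstimate(c(2, 2, 2), c(0, 1, 1))
  expect_identical(km$curve$nRisk, 3L)
  expect_equal(km$curve$survival, 1 / 3, tolerance = 1e-12)
})

test_that("all-censored data give S identically 1 and no median", {
  km <- kmEstimate(c(5, 8, 13), c(0, 0, 0))
  expect_identical(nrow(km$curve), 0L)
  expect_true(is.na(km$median))
  expect_error(kmEstimate(c(NA, NA), c(NA, NA)), "no subjects")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(1)
  t <- rexp(50)
  km <- kmEstimate(t, rep(1, 50))
  ecdfS <- 1 - ecdf(t)(km$curve$time)
  expect_equal(km$curve$survival, ecdfS, tolerance = 1e-12)
})

test_that("log-rank on identical groups is exactly null", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  lr <- logrankTest(t, e, t, e)
  expect_equal(lr$chiSquare, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("log-rank matches the written-out 6-subject O/E/V table", {
  # A: events at 1, 3, censored 5; B: events at 2, 4, 6.
  # t=1: n=6 n1=3 d=1 -> E1=1/2,  V=1/4
  # t=2: n=5 n1=2 d=1 -> E1=2/5,  V=6/25
  # t=3: n=4 n1=2 d=1 -> E1=1/2,  V=1/4
  # t=4: n=3 n1=1 d=1 -> E1=1/3,  V=2/9
  # t=6: n=1 n1=0 d=1 -> E1=0,    V=0
  lr <- logrankTest(c(1, 3, 5), c(1, 1, 0), c(2, 4, 6), c(1, 1, 1))
  E1 <- 1 / 2 + 2 / 5 + 1 / 2 + 1 / 3
  V <- 1 / 4 + 6 / 25 + 1 / 4 + 2 / 9
  expect_equal(lr$chiSquare, (2 - E1)^2 / V, tolerance = 1e-10)
  expect_equal(unname(lr$observed), c(2, 3))
  expect_equal(unname(lr$expected), c(E1, 5 - E1), tolerance = 1e-10)
  # independent oracle: survival::survdiff computes the same statistic
  d <- data.frame(time = c(1, 3, 5, 2, 4, 6), event = c(1, 1, 0, 1, 1, 1),
                  g = rep(c("A", "B"), each = 3))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  expect_equal(lr$chiSquare, unname(sd$chisq), tolerance = 1e-10)
})

test_that("log-rank is invariant under group-label swap", {
  set.seed(2)
  tA <- rexp(30); eA <- rbinom(30, 1, 0.7)
  tB <- rexp(25, 1.5); eB <- rbinom(25, 1, 0.7)
  l1 <- logrankTest(tA, eA, tB, eB)
  l2 <- logrankTest(tB, eB, tA, eA)
  expect_equal(l1$chiSquare, l2$chiSquare, tolerance = 1e-12)
  expect_error(logrankTest(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("Cox wrapper recovers direction and handles coding conventions", {
  set.seed(3)
  n <- 400
  subtype <- sample(c("MUT1", "MUT2"), n, TRUE)
  rate <- ifelse(subtype == "MUT2", 1.74, 1) * log(2) / 15
  T <- rexp(n, rate); U <- runif(n, 0, 40)
  d <- data.frame(sample_id = 1:n, subtype = subtype,
                  os_months = pmin(T, U), os_event = as.integer(T <= U),
                  age = rnorm(n, 66, 10),
                  sex = sample(c("male", "female"), n, TRUE),
                  smoking = sample(c("never", "former", "current"), n, TRUE))
  fit <- coxFit(d, c("subtype", "age", "sex", "smoking"))
  tab <- fit$table
  # MUT1 is the reference: the subtype term is MUT2 excess hazard
  expect_identical(tab$term[1], "subtypeMUT2")
  expect_gt(tab$hr[1], 1)
  expect_true(tab$lo[1] < tab$hr[1] && tab$hr[1] < tab$hi[1])
  # smoking coded as former/current dummies vs never
  expect_true(all(c("smokingformer", "smokingcurrent") %in% tab$term))
  # sign agreement with the log-rank direction: MUT1 (group A) observes
  # fewer events than expected exactly when the Cox HR for MUT2 exceeds 1
  lr <- logrankTest(d$os_months[d$subtype == "MUT1"], d$os_event[d$subtype == "MUT1"],
                    d$os_months[d$subtype == "MUT2"], d$os_event[d$subtype == "MUT2"])
  expect_identical(lr$observed[["A"]] < lr$expected[["A"]], tab$hr[1] > 1)
})

test_that("Cox null: CI covers HR = 1 at roughly nominal rate", {
  set.seed(4)
  cover <- logical(100)
  for (r in 1:100) {
    n <- 150
    g <- rep(c("MUT1", "MUT2"), each = n / 2)
    T <- rexp(n, 0.1); U <- runif(n, 0, 20)
    d <- data.frame(subtype = g, os_months = pmin(T, U),
                    os_event = as.integer(T <= U))
    f <- coxFit(d, "subtype")
    cover[r] <- f$table$lo[1] <= 1 && 1 <= f$table$hi[1]
  }
  expect_gte(mean(cover), 0.9)
})

test_that("Cox input validation catches degenerate designs", {
  d <- data.frame(subtype = rep("MUT1", 10), os_months = 1:10,
                  os_event = rep(1, 10))
  expect_error(coxFit(d, "subtype"), "constant")
  d2 <- data.frame(subtype = rep(c("MUT1", "MUT2"), 5), os_months = 1:10,
                   os_event = rep(0, 10))
  expect_error(coxFit(d2, "subtype"), "events")
})

test_that("chi-square matches hand arithmetic and is row-swap invariant", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chiSquareTest(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  tab <- matrix(c(20, 40, 30, 10), 2)  # rows (20,30), (40,10)
  r2 <- chiSquareTest(tab)
  expect_equal(r2$statistic, 50 / 3, tolerance = 1e-10)  # 16.667 by hand
  expect_identical(r2$df, 1L)
  r3 <- chiSquareTest(tab[2:1, ])
  expect_equal(r2$statistic, r3$statistic, tolerance = 1e-12)
  expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chiSquareTest(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("half-up rounding matches table formatting", {
  expect_equal(roundHalfUp(0.05, 1), 0.1)     # base round() would give 0
  expect_equal(roundHalfUp(75.7739, 1), 75.8)
  expect_equal(roundHalfUp(24.0466, 1), 24.0)
  expect_equal(roundHalfUp(-0.05, 1), -0.1)
})

test_that("pooled summary reproduces simple hand arithmetic", {
  counts <- data.frame(cohort = c("x", "y"), characteristic = "sex",
                       category = "Male", count = c(5, 15))
  s <- cohortSummary(counts, c(x = 10, y = 30))
  expect_equal(s$pooled$count, 20)
  expect_equal(s$pooled$percent, 50.0)
  expect_equal(s$perCohort$percent, c(50.0, 50.0))
  # single cohort: pooled equals input
  s1 <- cohortSummary(counts[1, ], c(x = 10))
  expect_equal(s1$pooled$count, 5)
  expect_equal(s1$pooled$percent, 50.0)
  expect_error(cohortSummary(counts, c(x = 10)), "without a size")
})

test_that("exhaustive categories sum to 100 within rounding", {
  counts <- data.frame(cohort = "x", characteristic = "smoking",
                       category = c("a", "b", "c"), count = c(33, 33, 34))
  s <- cohortSummary(counts, c(x = 100))
  expect_lt(abs(sum(s$pooled$percent) - 100), 0.2)
})

test_that("raw clinical records tabulate into summary input", {
  clin <- data.frame(cohort = c("x", "x", "y"),
                     sex = c("male", "female", "male"),
                     os_event = c(1, 0, NA),
                     subtype = c("MUT1", "MUT2", "MUT1"))
  counts <- tabulateClinical(clin)
  male <- counts[counts$characteristic == "sex" & counts$category == "male", ]
  expect_equal(sum(male$count), 2)
  ev <- counts[counts$characteristic == "os_event", ]
  expect_setequal(unique(ev$category), c("Event", "Censored", "NA"))
})
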