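test_that("single correctly and incorrectly ordered triples bound the VUS", {
  expect_equal(vus_estimate(1, 2, 3), 1)
  expect_equal(vus_estimate(3, 2, 1), 0)
  # one strict triple and one d = m tie: (1 + 1/2) / 2
  expect_equal(vus_estimate(c(1, 2), 2, 3), 0.75)
  # full triple tie gets 1/6
  expect_equal(vus_estimate(2, 2, 2), 1 / 6)
})

test_that("VUS equals brute-force triple enumeration on random tied instances", {
  set.seed(50)
  for (rep in 1:30) {
    dem <- sample(0:8, sample(2:10, 1), replace = TRUE)
    mci <- sample(2:10, sample(2:10, 1), replace = TRUE)
    nc <- sample(4:12, sample(2:10, 1), replace = TRUE)
    expect_equal(vus_estimate(dem, mci, nc), brute_vus(dem, mci, nc),
                 tolerance = 1e-12)
  }
})

test_that("VUS is invariant under common strictly increasing transforms", {
  set.seed(51)
  dem <- rnorm(12, -2); mci <- rnorm(12, -1); nc <- rnorm(12)
  v <- vus_estimate(dem, mci, nc)
  expect_equal(vus_estimate(exp(dem), exp(mci), exp(nc)), v, tolerance = 1e-12)
  f <- function(x) x^3 + 2 * x
  expect_equal(vus_estimate(f(dem), f(mci), f(nc)), v, tolerance = 1e-12)
})

test_that("three i.i.d. continuous groups sit at the exchangeability null 1/6", {
  set.seed(52)
  v <- vus_estimate(rnorm(200), rnorm(200), rnorm(200))
  expect_lt(abs(v - 1 / 6), 0.02)
})

test_that("classification rates follow the interval convention", {
  g <- list(dementia = c(-5, -4), MCI = c(-2, -1), NC = c(1, 2))
  r <- three_class_rates(g, -3, 0)
  expect_equal(unname(r$tpr), c(1, 1, 1))
  expect_equal(r$objective, 3)
  expect_equal(r$vus, 1)

  r2 <- three_class_rates(g, -Inf, Inf)
  expect_equal(unname(r2$tpr), c(0, 1, 0))

  g3 <- list(dementia = c(-3, -1), MCI = c(-2, 0), NC = c(-1, 1))
  r3 <- three_class_rates(g3, -2, 0)
  expect_equal(unname(r3$tpr), c(0.5, 0.5, 0.5))
  expect_equal(r3$objective, 1.5)

  expect_error(three_class_rates(g, 1, -1), class = "cogdx_validation_error")
  expect_error(three_class_rates(list(dementia = 1, MCI = 2), -1, 1),
               class = "cogdx_validation_error")
})

test_that("separated groups reach objective 3 with the widest-margin cutoffs", {
  g <- list(dementia = c(-5, -4), MCI = c(-2, -1), NC = c(1, 2))
  r <- optimal_cutoff_pair(g)
  expect_equal(r$objective, 3)
  expect_equal(r$t_minus, -3)  # the only candidate midpoints inside the gaps
  expect_equal(r$t_plus, 0)
  expect_equal(r$vus, 1)
})

test_that("three identical groups cannot beat one fully captured class", {
  x <- c(-1, 0, 1)
  r <- optimal_cutoff_pair(list(dementia = x, MCI = x, NC = x))
  expect_equal(r$objective, 1)
  expect_true(is.infinite(r$t_minus) || is.infinite(r$t_plus))
})

test_that("the cutoff-pair search matches brute force on random instances", {
  set.seed(53)
  for (rep in 1:25) {
    g <- list(dementia = round(rnorm(sample(3:15, 1), -2), 1),
              MCI = round(rnorm(sample(3:15, 1), -1), 1),
              NC = round(rnorm(sample(3:15, 1), 0), 1))
    r <- optimal_cutoff_pair(g)
    expect_equal(r$objective, brute_best_objective(g), tolerance = 1e-12)
    expect_lte(r$t_minus, r$t_plus)
    # the reported rates re-evaluate to the same objective
    r2 <- three_class_rates(g, r$t_minus, r$t_plus)
    expect_equal(r2$objective, r$objective, tolerance = 1e-12)
  }
})

test_that("the weighted objective maximizes overall accuracy", {
  set.seed(54)
  g <- list(dementia = round(rnorm(10, -2), 1),
            MCI = round(rnorm(4, -1), 1),
            NC = round(rnorm(16, 0), 1))
  n <- vapply(g, length, integer(1))
  w <- n / sum(n)
  r <- optimal_cutoff_pair(g, objective = "weighted")
  expect_equal(r$objective,
               brute_best_objective(g, weights = w[c("dementia", "MCI", "NC")]),
               tolerance = 1e-12)
})

test_that("worsening dementia scores never decreases the VUS", {
  set.seed(55)
  for (rep in 1:10) {
    dem <- rnorm(15, -1); mci <- rnorm(15, -0.5); nc <- rnorm(15)
    v0 <- vus_estimate(dem, mci, nc)
    v1 <- vus_estimate(dem - runif(1, 0, 2), mci, nc)
    expect_gte(v1, v0)
  }
})
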