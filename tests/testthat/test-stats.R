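# Mann-Whitney U (exact and approximate branches) and the t test.

test_that("Mann-Whitney matches hand-enumerable cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of C(6,3)=20 labelings as extreme
  expect_equal(r$method, "exact")
  expect_false(r$significant)

  r <- mann_whitney_u(c(2, 4, 6), c(2, 4, 6))
  expect_equal(r$p_value, 1)

  r <- mann_whitney_u(1, 2)  # single observation per group
  expect_equal(r$p_value, 1)

  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact p agrees with the null U distribution for all n <= 8", {
  for (n in 1:8) {
    # every achievable U value, via one dataset per U (tieless)
    for (u in 0:floor(n * n / 2)) {
      # construct group a with rank sum giving U_a = u
      ranks <- 1:(2 * n)
      a_ranks <- seq_len(n)           # U_a = 0
      give <- u
      i <- n
      while (give > 0 && i >= 1) {
        bump <- min(give, n)
        a_ranks[i] <- a_ranks[i] + bump
        give <- give - bump
        i <- i - 1
      }
      a <- sort(a_ranks)
      b <- setdiff(ranks, a)
      got <- mann_whitney_u(a, b)
      umin <- got$statistic
      # independent oracle: R's exact Wilcoxon distribution
      p_oracle <- min(1, stats::pwilcox(umin, n, n) +
                        (1 - stats::pwilcox(n * n - umin - 1, n, n)))
      expect_lt(abs(got$p_value - p_oracle), 1e-10,
                label = paste0("n=", n, " U=", u))
    }
  }
})

test_that("U_a + U_b == n_a * n_b and the test is label-symmetric", {
  set.seed(71)
  for (i in 1:200) {
    na <- sample(1:15, 1); nb <- sample(1:15, 1)
    a <- rnorm(na); b <- rnorm(nb)
    ra <- rank(c(a, b))[seq_len(na)]
    ua <- sum(ra) - na * (na + 1) / 2
    ub <- na * nb - ua
    r1 <- mann_whitney_u(a, b)
    r2 <- mann_whitney_u(b, a)
    expect_equal(r1$statistic, min(ua, ub))
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$significant, r2$significant)
  }
})

test_that("the normal approximation tracks the exact branch at n = 8", {
  # measured worst-case |approx - exact| over all U at n_a = n_b = 8 is
  # 0.0109 with continuity correction; assert it stays there
  worst <- 0
  for (u in 0:64) {
    a <- (1:8); b <- (1:8) + 0.5  # placeholder; p depends only on U and n
    p_exact <- min(1, stats::pwilcox(min(u, 64 - u), 8, 8) +
                     (1 - stats::pwilcox(64 - min(u, 64 - u) - 1, 8, 8)))
    sigma <- sqrt(64 * 17 / 12)
    p_approx <- min(1, 2 * pnorm((min(u, 64 - u) - 32 + 0.5) / sigma))
    worst <- max(worst, abs(p_exact - p_approx))
  }
  expect_lt(worst, 0.011)
  # and the package's approximate branch equals that formula (forced by
  # exceeding exact_max_n)
  set.seed(77)
  a <- sample(1:100, 8) + 0.1; b <- sample(101:200, 8) + 0.2
  r_apx <- mann_whitney_u(a, b, exact_max_n = 2)
  expect_equal(r_apx$method, "normal_approx")
  u <- r_apx$statistic
  expect_equal(r_apx$p_value,
               min(1, 2 * pnorm((u - 32 + 0.5) / sqrt(64 * 17 / 12))))
})

test_that("tied data falls back to the corrected approximation", {
  a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 4)
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal_approx")
  # cross-check against R's implementation (same correction family)
  w <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_lt(abs(r$p_value - w$p.value), 0.02)
  # fully degenerate ties
  expect_equal(mann_whitney_u(rep(1, 5), rep(1, 5))$p_value, 1)
})

test_that("t test handles standard and degenerate inputs", {
  r <- two_sample_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- two_sample_t(c(0, 0), c(1, 1))
  expect_equal(r$p_value, 0)
  expect_equal(r$method, "degenerate")

  set.seed(72)
  a <- rnorm(20); b <- rnorm(20, 1)
  r <- two_sample_t(a, b)
  ht <- t.test(a, b)
  expect_equal(r$p_value, ht$p.value)
  expect_equal(r$df, unname(ht$parameter))
  rs <- two_sample_t(a, b, welch = FALSE)
  expect_equal(rs$p_value, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("t p-values are uniform under the null", {
  set.seed(73)
  ps <- replicate(1000, two_sample_t(rnorm(10), rnorm(10))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cohort comparison flags planted differences and not null ones", {
  mk_cohort <- function(rates, prefix) {
    purrr::map2(rates, seq_along(rates), function(r, i) {
      n <- stats::rpois(1, r)
      if (n == 0) return(NULL)
      tibble::tibble(sample_id = sprintf("%s%02d", prefix, i),
                     chrom = "chr1",
                     pos = sample.int(1e6, n), virus_id = "v",
                     evidence = "softclip", support = 1L,
                     dnase = sample(c(0L, 1L), n, replace = TRUE),
                     region_class = "intergenic")
    }) |> purrr::list_rbind()
  }
  set.seed(74)
  case <- mk_cohort(rep(30, 20), "c")
  ctrl <- mk_cohort(rep(15, 20), "k")
  cmp <- summarize_cohorts(case, ctrl,
                           case_samples = sprintf("c%02d", 1:20),
                           control_samples = sprintf("k%02d", 1:20))
  expect_true(cmp$count_test$significant)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$n_case, 20L)

  # identical cohorts: nothing significant
  cmp0 <- summarize_cohorts(case, case)
  expect_equal(cmp0$count_test$p_value, 1, tolerance = 1e-6)
  expect_false(any(cmp0$per_chromosome$significant))

  # a planted 2x rate is detected in nearly every replicate
  set.seed(75)
  hits <- sum(replicate(100, {
    x <- stats::rpois(20, 30); y <- stats::rpois(20, 15)
    mann_whitney_u(x, y)$p_value < 0.05
  }))
  expect_gte(hits, 95)
})
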