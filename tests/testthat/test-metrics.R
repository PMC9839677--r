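test_that("TEWL is the order-free daily sum of hourly losses", {
  expect_equal(tewl(rep(0.1, 24)), 2.4)
  expect_equal(tewl(rep(0, 24)), 0)
  set.seed(1)
  x <- runif(24)
  expect_equal(tewl(x), tewl(sample(x)))
  expect_error(tewl(c(rep(0.1, 23), -0.1)), ">= 0")
})

test_that("ADR is the worst 3-hour window as percent of mass", {
  expect_equal(adr(rep(0.39, 24), 39), 3) # 1.17 g in 3 h on 39 g
  spike <- c(1, rep(0, 23))
  expect_equal(adr(spike, 39), 1 / 39 * 100)
  # brute force over all 22 windows
  set.seed(7)
  for (i in 1:20) {
    x <- runif(24, 0, 2)
    brute <- max(vapply(1:22, function(j) sum(x[j:(j + 2)]), numeric(1)))
    expect_equal(adr(x, 50), brute / 50 * 100)
    expect_gte(adr(x, 50), 3 * min(x) / 50 * 100 - 1e-12)
    expect_lte(adr(x, 50), 3 * max(x) / 50 * 100 + 1e-12)
  }
  expect_error(adr(rep(0.1, 24), 0), "positive")
  expect_error(adr(rep(0.1, 24), -3), "positive")
})

test_that("lethal dehydration flips exactly at 15 percent", {
  expect_true(lethal_dehydration(15))
  expect_false(lethal_dehydration(14.99))
  expect_false(lethal_dehydration(0))
  expect_identical(lethal_dehydration(c(14.999, 15, 15.001)),
                   c(FALSE, TRUE, TRUE))
  expect_error(lethal_dehydration(-1))
})

test_that("density overlap is exact for identical and disjoint samples", {
  set.seed(2)
  x <- rnorm(30, 5, 2)
  expect_identical(density_overlap(x, x), 1)
  expect_lt(density_overlap(rnorm(50), rnorm(50) + 100), 1e-6)
  # degenerate samples
  expect_identical(density_overlap(rep(3, 5), rep(3, 5)), 1)
  expect_lt(density_overlap(rep(3, 5), rep(300, 5)), 1e-6)
})

test_that("density overlap is symmetric and affine-invariant", {
  set.seed(3)
  a <- rnorm(40, 1, 1); b <- rnorm(40, 2, 1.5)
  o1 <- density_overlap(a, b)
  expect_equal(o1, density_overlap(b, a), tolerance = 1e-12)
  expect_equal(density_overlap(3 * a - 7, 3 * b - 7), o1, tolerance = 1e-9)
  expect_true(o1 >= 0 && o1 <= 1)
})

test_that("density overlap approximates the closed-form normal overlap", {
  # overlap of N(0,1) and N(1,1) is 2*pnorm(-1/2)
  set.seed(4)
  est <- replicate(5, density_overlap(rnorm(4000), rnorm(4000, 1)))
  expect_lt(abs(mean(est) - 2 * pnorm(-0.5)), 0.025)
})

test_that("impact surface is the identity on unchanged climate", {
  set.seed(5)
  cur <- list(tewl = matrix(runif(60, 5, 8), 6), adr = matrix(runif(60), 6))
  surf <- impact_surface(cur, cur)
  expect_equal(surf$tewl_overlap, rep(1, 6))
  expect_equal(surf$tewl_delta, rep(0, 6))
  expect_equal(surf$adr_overlap, rep(1, 6))
  # shifting the future by +5 sets the delta and shrinks the overlap
  fut <- list(tewl = cur$tewl + 5, adr = cur$adr)
  surf2 <- impact_surface(cur, fut)
  expect_equal(surf2$tewl_delta, rep(5, 6))
  expect_true(all(surf2$tewl_overlap < surf$tewl_overlap))
  expect_true(all(surf2$tewl_overlap >= 0 & surf2$tewl_overlap <= 1))
  # missing data flows through as NA and is logged
  cur$tewl[2, 1] <- NA
  surf3 <- impact_surface(cur, fut)
  expect_true(is.na(surf3$tewl_overlap[2]))
  expect_identical(attr(surf3, "missing_pixels"), 2L)
})

test_that("Kruskal-Wallis H matches an independent rank computation", {
  g_id <- kruskal_wallis_epsilon(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(g_id$H, 0)
  expect_equal(g_id$epsilon_sq, 0)
  # two fully separated groups of 5, no ties: direct rank formula
  groups <- list(1:5, 11:15)
  n <- 10
  ranks <- rank(unlist(groups))
  rbar <- tapply(ranks, rep(1:2, each = 5), mean)
  H <- 12 / (n * (n + 1)) * sum(5 * (rbar - (n + 1) / 2)^2)
  got <- kruskal_wallis_epsilon(groups)
  expect_equal(got$H, H, tolerance = 1e-12)
  expect_equal(got$epsilon_sq, H / (n - 1))
  set.seed(6)
  r <- kruskal_wallis_epsilon(split(rnorm(60), rep(1:3, 20)))
  expect_true(r$epsilon_sq >= 0 && r$epsilon_sq <= 1)
  expect_error(kruskal_wallis_epsilon(list(1:3)))
})

test_that("Pearson correlation handles identities and degeneracy", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 1, 5, 4, 8)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), manual, tolerance = 1e-12)
  expect_warning(r0 <- pearson_r(x, rep(2, 5)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")
})
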