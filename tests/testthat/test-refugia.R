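test_that("bivariate classes cover ~6.25% each for independent maps", {
  set.seed(10)
  n <- 8000
  realm <- matrix(1L, 80, 100)
  imp <- matrix(runif(n), 80)
  div <- matrix(runif(n), 80)
  bc <- bivariate_classes(imp, div, realm)
  tab <- bc$area_table
  se3 <- 3 * 100 * sqrt(0.0625 * (1 - 0.0625) / n)
  for (k in c("HH", "HL", "LH", "LL"))
    expect_lt(abs(tab$percent[tab$class == k] - 6.25), se3)
  expect_lte(sum(tab$percent), 100)
  # comonotone maps occupy only the diagonal classes
  bc2 <- bivariate_classes(div, div, realm)
  expect_true(all(bc2$area_table$percent[
    bc2$area_table$class %in% c("HL", "LH")] == 0))
  expect_true(all(bc2$area_table$percent[
    bc2$area_table$class %in% c("HH", "LL")] > 0))
  # small realms are skipped
  expect_message(
    bc3 <- bivariate_classes(matrix(runif(4), 2), matrix(runif(4), 2),
                             matrix(1L, 2, 2)), "skipped")
  expect_true(all(is.na(bc3$class)))
})

test_that("fixed-threshold refugia match the independence prediction", {
  set.seed(11)
  n <- 10000
  realm <- matrix(1L, 100, 100)
  tewl <- matrix(runif(n), 100)
  adrm <- matrix(runif(n), 100)
  div <- matrix(runif(n), 100)
  r <- refugia_fixed(tewl, adrm, div, realm, threshold = 75)
  p <- 0.25 * (1 - 0.75^2) # diversity AND (TEWL OR ADR) above the 75th pct
  expect_lt(abs(r$area_fraction[["1"]] - p), 3 * sqrt(p * (1 - p) / n))
  # the all-three-AND rule selects fewer pixels
  r_and <- refugia_fixed(tewl, adrm, div, realm, threshold = 75,
                         rule = "and")
  expect_lt(sum(r_and$mask), sum(r$mask))
  p_and <- 0.25^3
  expect_lt(abs(r_and$area_fraction[["1"]] - p_and),
            3 * sqrt(p_and * (1 - p_and) / n))
  # degenerate and nested thresholds
  expect_equal(sum(refugia_fixed(tewl, adrm, div, realm,
                                 threshold = 100)$mask), 0)
  m60 <- refugia_fixed(tewl, adrm, div, realm, threshold = 60)$mask
  m80 <- refugia_fixed(tewl, adrm, div, realm, threshold = 80)$mask
  expect_true(all(m60[m80])) # higher threshold is nested in lower
  expect_error(refugia_fixed(tewl, adrm, div, realm, threshold = 0))
})

test_that("floating threshold is the largest one meeting the area target", {
  set.seed(12)
  n <- 3000
  realm <- matrix(rep(1:2, each = n / 2), 50)
  tewl <- matrix(runif(n), 50)
  adrm <- matrix(runif(n), 50)
  div <- matrix(runif(n), 50)
  fl <- refugia_floating(tewl, adrm, div, realm, target = 0.05)
  # independence prediction: (1-q)(1-q^2) = 0.05 at q ~ 0.835
  q <- uniroot(function(q) (1 - q) * (1 - q^2) - 0.05, c(0.5, 0.99))$root
  for (rid in c("1", "2")) {
    expect_gte(fl$area_fraction[[rid]], 0.05)
    expect_lt(abs(fl$threshold[[rid]] - 100 * q), 5)
  }
  # the threshold is the largest meeting the target: one step higher fails
  for (rid in 1:2) {
    t_up <- fl$threshold[[as.character(rid)]] + 0.1
    r_up <- refugia_fixed(tewl, adrm, div, realm, threshold = t_up)
    expect_lt(r_up$area_fraction[[as.character(rid)]], 0.05)
    # and re-running the returned threshold reproduces >= target
    r_at <- refugia_fixed(tewl, adrm, div, realm,
                          threshold = fl$threshold[[as.character(rid)]])
    expect_gte(r_at$area_fraction[[as.character(rid)]], 0.05)
  }
  # an already-satisfied target returns a threshold of at least 75
  fl2 <- refugia_floating(tewl, adrm, div, realm, target = 0.02)
  expect_true(all(fl2$threshold >= 75))
  # unreachable targets are flagged
  empty <- matrix(NA_real_, 50, 60)
  fl3 <- refugia_floating(empty, empty, empty, realm, target = 0.05)
  expect_setequal(fl3$unmet_realms, 1:2)
})

test_that("PA coverage counts refugia cells inside protected areas", {
  realm <- matrix(1L, 8, 10)
  refug <- matrix(FALSE, 8, 10); refug[1:40] <- TRUE
  pa_all <- matrix(TRUE, 8, 10)
  expect_equal(pa_coverage(refug, pa_all, realm)[["1"]], 100)
  pa_none <- matrix(FALSE, 8, 10)
  expect_equal(pa_coverage(refug, pa_none, realm)[["1"]], 0)
  pa10 <- pa_none; pa10[1:10] <- TRUE
  expect_equal(pa_coverage(refug, pa10, realm)[["1"]], 25)
  expect_true(is.na(pa_coverage(pa_none, pa10, realm)[["1"]]))
})

test_that("weighted Jaccard generalizes the 0/1 Jaccard index", {
  expect_equal(weighted_jaccard(c(1, 2), c(2, 1)), 0.5)
  x <- c(0.3, 1.2, 0)
  expect_equal(weighted_jaccard(x, x), 1)
  expect_equal(weighted_jaccard(c(1, 0, 2), c(0, 3, 0)), 0)
  set.seed(13)
  a <- runif(50); b <- runif(50)
  expect_equal(weighted_jaccard(a, b), weighted_jaccard(b, a))
  expect_equal(weighted_jaccard(7 * a, 7 * b), weighted_jaccard(a, b),
               tolerance = 1e-12)
  m1 <- runif(50) > 0.5; m2 <- runif(50) > 0.5
  expect_equal(weighted_jaccard(as.numeric(m1), as.numeric(m2)),
               sum(m1 & m2) / sum(m1 | m2))
  expect_error(weighted_jaccard(c(-1, 2), c(1, 2)), "negative")
  expect_error(weighted_jaccard(c(0, 0), c(0, 0)), "all zero")
})

test_that("protection mismatch reports under- and over-protection", {
  m <- function(cells) { x <- matrix(FALSE, 5, 8); x[cells] <- TRUE; x }
  expect_equal(protection_mismatch(m(1:20), m(1:20)),
               c(under = 0, over = 0))
  expect_equal(protection_mismatch(m(1:20), m(21:40)),
               c(under = 100, over = 100))
  expect_equal(protection_mismatch(m(1:20), m(11:30)),
               c(under = 50, over = 50))
  expect_true(all(is.na(protection_mismatch(m(integer(0)), m(integer(0))))))
})

test_that("safe-site consistency is 100 for identity, ~25 for noise", {
  set.seed(14)
  v <- runif(400)
  expect_equal(safe_site_consistency(v, v), 100)
  cons <- replicate(20, safe_site_consistency(v, sample(v)))
  expect_lt(abs(mean(cons) - 25), 10)
  expect_true(all(cons >= 0 & cons <= 100))
  expect_error(safe_site_consistency(runif(3), runif(3)), "at least 4")
  expect_error(safe_site_consistency(runif(5), runif(6)), "differ")
})
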