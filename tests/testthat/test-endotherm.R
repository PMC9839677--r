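test_that("trait scaling follows the cube-root-of-mass rule", {
  ref <- bird_template()
  expect_equal(make_model_bird(39, ref), ref)
  b13 <- make_model_bird(13, ref)
  expect_equal(b13$depth_dorsal_mm / ref$depth_dorsal_mm, (13 / 39)^(1 / 3),
               tolerance = 1e-12)
  b185 <- make_model_bird(185, ref)
  expect_equal(b185$feather_len_dorsal_mm / ref$feather_len_dorsal_mm,
               (185 / 39)^(1 / 3), tolerance = 1e-12)
  # non-size parameters are copied, basal metabolism re-evaluated
  expect_equal(b185$tb_norm, ref$tb_norm)
  expect_equal(b185$qbasal, ref$bmr_c1 * 185^ref$bmr_c2)
  expect_error(make_model_bird(-5), "positive")
  expect_error(make_model_bird(0), "positive")
})

test_that("body geometry is an exact prolate ellipsoid", {
  b <- bird_template()
  g1 <- body_geometry(b, 1)
  expect_equal(g1$volume_m3, 39 / 1000 / 1000) # V = M / rho
  expect_equal(g1$area_m2, (36 * pi)^(1 / 3) * g1$volume_m3^(2 / 3),
               tolerance = 1e-9) # sphere closed form
  expect_equal(g1$char_dim_m, g1$volume_m3^(1 / 3))
  ratios <- seq(1.1, 3, by = 0.1)
  areas <- vapply(ratios, function(r) body_geometry(b, r)$area_m2, numeric(1))
  expect_true(all(diff(areas) > 0)) # stretching increases area
})

test_that("heat-balance residual decomposes and is linear in solar", {
  b <- bird_template()
  env <- list(tair = 35, rh = 10, solar = 400, wind = 2, tsky = 15,
              tground = 45)
  st <- solve_thermoregulation(env, b)
  r1 <- heat_balance_residual(st, env, b)
  expect_lt(abs(r1), 1e-4)
  # doubling absorbed solar at a frozen state raises the residual by
  # exactly the added absorbed flux
  env2 <- env; env2$solar <- 800
  r2 <- heat_balance_residual(st, env2, b)
  added <- b$alpha_solar *
    body_geometry(b, b$shape_range[1])$area_m2 / 2 * 400
  expect_equal(as.numeric(r2) - as.numeric(r1), added, tolerance = 1e-9)
  # no thermal gradients, no generation: residual = -Q_evap(baseline)
  st0 <- st
  st0$qgen <- 0; st0$tb <- st0$ts <- st0$tsurf <- 41; st0$pmult <- 1
  env0 <- list(tair = 41, rh = 10, solar = 0, wind = 2, tsky = 41,
               tground = 41)
  r0 <- heat_balance_residual(st0, env0, b)
  comp <- attr(r0, "components")
  expect_equal(as.numeric(r0), -(comp[["qresp"]] + comp[["qcut"]]))
  expect_equal(comp[["qresp"]], 0) # zero generation -> zero ventilation
  expect_error(heat_balance_residual(st0, list(tair = 120, rh = 10,
    solar = 0, wind = 2, tsky = 41, tground = 41), b), "non-physical")
})

test_that("cascade engages in order with bounded Tb and panting", {
  b <- bird_template()
  cold <- solve_thermoregulation(list(tair = 20, rh = 20, solar = 0,
    wind = 2, tsky = 5, tground = 20), b)
  expect_equal(cold$tb, b$tb_norm)
  expect_equal(cold$pmult, 1)
  expect_true(cold$stage == 0)

  hot <- solve_thermoregulation(list(tair = 45, rh = 10, solar = 800,
    wind = 1, tsky = 30, tground = 55), b)
  expect_gte(hot$stage, 4)
  expect_true(hot$tb > b$tb_norm && hot$tb <= 44)
  expect_true(hot$pmult > 1 && hot$pmult <= 7.5)
  warm <- solve_thermoregulation(list(tair = 30, rh = 10, solar = 800,
    wind = 1, tsky = 15, tground = 40), b)
  expect_gt(hot$water_gph, warm$water_gph)
})

test_that("solver states satisfy the oracle's flux recomputation", {
  b <- make_model_bird(39)
  envs <- o_random_envs(25, seed = 11)
  for (i in seq_len(nrow(envs))) {
    env <- o_env_row(envs, i)
    st <- solve_thermoregulation(env, b)
    if (st$flag != 0) next
    ctl <- list(s = st$ptilo, r = st$shape, kf = st$kflesh, tb = st$tb,
                p = st$pmult, w = st$wet, qgen = st$qgen)
    o <- o_state(b, env, ctl)
    expect_lt(abs(o$resid), 2e-4)
    expect_equal(o$water_gph, st$water_gph, tolerance = 1e-4)
  }
})

test_that("solver water loss matches the brute-force minimum", {
  b <- make_model_bird(39)
  envs <- o_random_envs(12, seed = 21)
  for (i in seq_len(nrow(envs))) {
    env <- o_env_row(envs, i)
    st <- solve_thermoregulation(env, b, tol = 1e-5)
    if (st$flag != 0) next
    brute <- o_min_water(b, env, tol = 1e-4)
    expect_lt(abs(st$water_gph - brute) / max(brute, 1e-6), 0.02)
  }
})

test_that("water loss rises with air temperature, solar load and mass", {
  birds <- lapply(c(13, 39, 185), make_model_bird)
  ta <- seq(25, 50, by = 2.5)
  water <- sapply(birds, function(b) respirometry_curve(b, ta)$water_gph)
  expect_true(all(apply(water, 2, function(w) all(diff(w) >= -1e-9))))
  # above thermoneutrality bigger birds lose more water in absolute terms
  expect_true(all(water[ta >= 35, 1] < water[ta >= 35, 2]))
  expect_true(all(water[ta >= 35, 2] < water[ta >= 35, 3]))
  env <- list(tair = 40, rh = 10, solar = 200, wind = 2, tsky = 25,
              tground = 45)
  env2 <- env; env2$solar <- 600
  expect_gt(solve_thermoregulation(env2, birds[[2]])$water_gph,
            solve_thermoregulation(env, birds[[2]])$water_gph)
})

test_that("shade-shifting takes the hourly minimum of open and shade", {
  b <- make_model_bird(39)
  open <- build_microclimate(toy_site(), 0)
  shade <- build_microclimate(toy_site(), 0.9)
  day <- hourly_water_loss(open, shade, b)
  expect_equal(nrow(day), 24)
  expect_true(all(day$water_gph <= day$water_open + 1e-12))
  expect_true(all(day$water_gph <= day$water_shade + 1e-12))
  expect_true(all(day$water_gph ==
                    pmin(day$water_open, day$water_shade)))
  # shade is chosen when it saves water at sunny hours
  sunny <- open$solar > 400
  expect_true(any(sunny) && all(day$habitat[sunny] == "shade"))
  night <- open$solar == 0
  expect_equal(day$water_open[night], day$water_shade[night])
  # open-only mode
  day_open <- hourly_water_loss(open, NULL, b)
  expect_true(all(day_open$habitat == "open"))
  expect_true(all(day_open$water_gph >= day$water_gph - 1e-12))
  expect_error(hourly_water_loss(open, shade[1:12, ], b), "share hours")
})

test_that("respirometry mode: flat Tb below onset, monotone above", {
  b <- make_model_bird(39)
  rc <- respirometry_curve(b, seq(20, 50, by = 1))
  expect_equal(rc$tb[rc$ta <= 26], rep(b$tb_norm, sum(rc$ta <= 26)))
  expect_true(all(diff(rc$tb) >= -1e-9))
  expect_true(all(rc$tb <= 44 + 1e-12))
  onset <- min(rc$ta[rc$tb > b$tb_norm + 1e-9])
  above <- rc$water_gph[rc$ta >= onset]
  expect_true(all(diff(above) > 0))
  # brute-force check at three chamber temperatures
  for (ta in c(38, 44, 50)) {
    env <- list(tair = ta, rh = 5, solar = 0, wind = 0.1, tsky = ta,
                tground = ta)
    st <- solve_thermoregulation(env, b)
    expect_lt(abs(st$water_gph - o_min_water(b, env)) /
                max(st$water_gph, 1e-6), 0.02)
  }
})
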