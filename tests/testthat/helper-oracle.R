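# Independent pure-R recomputation of the steady-state heat/water balance
# and a brute-force minimal-water search over the physiological control
# space. Deliberately separate from the package's solver: node temperatures
# are found with stats::uniroot / Newton here, and the optimum by grid
# enumeration, so these functions can serve as oracles for it.

o_const <- list(sigma = 5.670374419e-8, rv = 461.5, lambda = 2.406e6,
                kair = 0.0263, nuair = 1.6e-5, rhoair = 1.13, cpair = 1006,
                eo2 = 20.1, fo2 = 0.2094, extr = 0.2, dvap = 2.5e-5)

o_esat <- function(t) 0.61094 * exp(17.625 * t / (t + 243.04))
o_rhov <- function(e_kpa, t) e_kpa * 1000 / (o_const$rv * (t + 273.15))

o_geom <- function(bird, r) {
  v <- bird$mass_g / 1000 / bird$density
  bs <- (3 * v / (4 * pi * r))^(1 / 3)
  a <- r * bs
  area <- if (r <= 1 + 1e-9) 4 * pi * bs^2 else {
    e <- sqrt(1 - bs^2 / a^2)
    2 * pi * bs^2 * (1 + a / (bs * e) * asin(e))
  }
  list(v = v, area = area, d = v^(1 / 3), bs = bs)
}

# steady-state fluxes for a full control vector
# ctl: list(s, r, kf, tb, p, w, qgen)
o_state <- function(bird, env, ctl) {
  k <- o_const
  g <- o_geom(bird, ctl$r)
  depth <- mean(c(bird$depth_dorsal_mm, bird$depth_ventral_mm)) / 1000
  gp <- bird$k_plume * g$area / (depth * ctl$s)
  gf <- ctl$kf * g$area / (bird$tf_frac * g$bs)
  re <- max(env$wind, 0.05) * g$d / k$nuair
  hc <- max(2, 0.35 * re^0.6) * k$kair / g$d
  hm <- hc / (k$rhoair * k$cpair)
  # posture-independent silhouette: half the rest-shape surface area
  qsol <- bird$alpha_solar *
    o_geom(bird, bird$shape_range[1])$area / 2 * env$solar
  rva <- o_rhov(env$rh / 100 * o_esat(env$tair), env$tair)
  vent <- ctl$qgen / k$eo2 * 1e-6 / (k$fo2 * k$extr) * ctl$p
  mresp <- vent * max(0, o_rhov(o_esat(ctl$tb), ctl$tb) - rva)
  gv <- 1 / (1 / hm + depth * ctl$s / k$dvap)
  t4 <- function(t) (t + 273.15)^4
  tp_of <- function(ts) {
    tp <- env$tair
    for (i in 1:60) {
      f <- gp * (ts - tp) + qsol - hc * g$area * (tp - env$tair) -
        bird$emissivity * k$sigma * g$area *
        (t4(tp) - 0.5 * t4(env$tsky) - 0.5 * t4(env$tground))
      df <- -gp - hc * g$area -
        4 * bird$emissivity * k$sigma * g$area * (tp + 273.15)^3
      step <- f / df
      tp <- tp - step
      if (abs(step) < 1e-11) break
    }
    tp
  }
  f1 <- function(ts) {
    mcut <- gv * g$area * ctl$w * max(0, o_rhov(o_esat(ts), ts) - rva)
    gf * (ctl$tb - ts) - gp * (ts - tp_of(ts)) - mcut * k$lambda
  }
  lo <- min(env$tair, ctl$tb) - 80
  hi <- max(env$tair, ctl$tb) + 80
  ts <- if (f1(lo) < 0) lo else if (f1(hi) > 0) hi else
    stats::uniroot(f1, c(lo, hi), tol = 1e-10)$root
  mcut <- gv * g$area * ctl$w * max(0, o_rhov(o_esat(ts), ts) - rva)
  list(resid = ctl$qgen - mresp * k$lambda - gf * (ctl$tb - ts),
       water_gph = (mresp + mcut) * 3.6e6, ts = ts, tp = tp_of(ts))
}

o_resid <- function(bird, env, ctl) o_state(bird, env, ctl)$resid

# normalized stage engagements -> control vector
o_ctl_u <- function(bird, u) {
  list(s = 1 + u[1] * (bird$ptilo_range[1] - 1),
       r = bird$shape_range[1] + u[2] * diff(bird$shape_range),
       kf = bird$k_flesh_range[1] + u[3] * diff(bird$k_flesh_range),
       tb = bird$tb_norm + u[4] * (bird$tb_max - bird$tb_norm),
       p = 1 + u[4] * (bird$p_max - 1),
       w = bird$wet_baseline + u[5] * (1 - bird$wet_baseline),
       qgen = bird$qbasal)
}

# brute-force minimal hourly water loss over the model's physiological
# state space: every cascade-compliant state has at most one partially
# engaged stage, any mix of saturated/skipped stages below it and resting
# stages above it; enumerate all below-patterns and solve the partial
# stage exactly, keeping the water minimum. Wetness below baseline and metabolic heat above basal are only reachable
# from the all-rest state (the cold-side reversal).
o_min_water <- function(bird, env, tol = 1e-4) {
  resid_u <- function(u) o_resid(bird, env, o_ctl_u(bird, u))
  water_u <- function(u) o_state(bird, env, o_ctl_u(bird, u))$water_gph
  best <- Inf
  r_rest <- resid_u(rep(0, 5))
  if (abs(r_rest) <= tol) best <- water_u(rep(0, 5))
  if (r_rest < -tol) {
    # cold side: shed baseline wetness, then raise metabolic heat
    ctl0 <- o_ctl_u(bird, rep(0, 5))
    f_w <- function(w) o_resid(bird, env, modifyList(ctl0, list(w = w)))
    fw0 <- f_w(0)
    if (fw0 >= -tol) {
      w <- if (fw0 <= tol) 0 else
        stats::uniroot(f_w, c(0, bird$wet_baseline), tol = 1e-9)$root
      best <- min(best, o_state(bird, env,
                                modifyList(ctl0, list(w = w)))$water_gph)
    } else {
      ctl1 <- modifyList(ctl0, list(w = 0))
      f_q <- function(q) o_resid(bird, env, modifyList(ctl1, list(qgen = q)))
      qhi <- bird$qbasal * bird$qgen_max_mult
      fq1 <- f_q(qhi)
      if (fq1 >= -tol) {
        q <- if (fq1 <= tol) qhi else
          stats::uniroot(f_q, c(bird$qbasal, qhi), tol = 1e-9)$root
        best <- min(best, o_state(bird, env,
                                  modifyList(ctl1, list(qgen = q)))$water_gph)
      }
    }
    return(best)
  }
  for (k in 1:5) {
    below <- k - 1
    for (pat in seq_len(2^below) - 1) {
      u <- rep(0, 5)
      if (below > 0)
        u[seq_len(below)] <- as.integer(intToBits(pat)[seq_len(below)])
      f <- function(x) { u[k] <- x; resid_u(u) }
      f1 <- f(1)
      cand <- FALSE
      if (abs(f1) <= tol) {
        u[k] <- 1
        cand <- TRUE
      } else {
        f0 <- f(0)
        if (abs(f0) <= tol) {
          cand <- TRUE
        } else if (sign(f0) != sign(f1)) {
          u[k] <- stats::uniroot(f, c(0, 1), tol = 1e-9)$root
          cand <- TRUE
        }
      }
      if (cand) best <- min(best, water_u(u))
    }
  }
  best
}

# seeded random environment draws spanning desert-like conditions
o_random_envs <- function(n, seed) {
  set.seed(seed)
  data.frame(tair = runif(n, 5, 52), rh = runif(n, 2, 60),
             solar = runif(n, 0, 1000), wind = runif(n, 0.1, 8),
             tsky_off = runif(n, -25, 0), tgnd_off = runif(n, 0, 15))
}

o_env_row <- function(d, i) {
  list(tair = d$tair[i], rh = d$rh[i], solar = d$solar[i], wind = d$wind[i],
       tsky = d$tair[i] + d$tsky_off[i], tground = d$tair[i] + d$tgnd_off[i])
}
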