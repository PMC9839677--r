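# Physiological impact metrics and summary statistics.

#' Total evaporative water loss over a day
#'
#' @param series An `hourly_water_loss` object or a numeric vector of hourly
#'   losses (g/h).
#' @return TEWL in g/day (sum of hourly losses).
#' @export
tewl <- function(series) {
  x <- if (inherits(series, "hourly_water_loss")) series$water_gph else series
  if (any(!is.finite(x)) || any(x < 0)) stop("hourly losses must be >= 0")
  sum(x)
}

#' Acute dehydration risk over a day
#'
#' Maximum water lost in any three consecutive hours (windows confined to
#' the 24-h day, no wrap across midnight) as a percentage of body mass.
#'
#' @param series An `hourly_water_loss` object or numeric vector (g/h).
#' @param mass_g Body mass (g); taken from the object if absent.
#' @return ADR in percent of body mass.
#' @export
adr <- function(series, mass_g = NULL) {
  x <- if (inherits(series, "hourly_water_loss")) series$water_gph else series
  if (is.null(mass_g)) mass_g <- attr(series, "mass_g")
  if (is.null(mass_g) || !is.finite(mass_g) || mass_g <= 0)
    stop("'mass_g' must be a positive number")
  if (any(!is.finite(x)) || any(x < 0)) stop("hourly losses must be >= 0")
  n <- length(x)
  if (n < 3) stop("need at least 3 hourly values")
  win <- vapply(seq_len(n - 2), function(i) sum(x[i:(i + 2)]), numeric(1))
  max(win) / mass_g * 100
}

#' Lethal-dehydration flag
#'
#' Birds are treated as unlikely to survive when accumulated water loss
#' reaches 15% of body mass within three hours.
#'
#' @param adr_value ADR in percent of body mass (>= 0).
#' @return `TRUE` iff `adr_value >= 15`; vectorised.
#' @export
lethal_dehydration <- function(adr_value) {
  stopifnot(all(adr_value >= 0))
  adr_value >= 15
}

# Silverman bandwidth; degenerate (zero-spread) samples get a tiny floor
# instead of bw.nrd0's own fallback
.bw_safe <- function(x) {
  floor_ <- 1e-6 * abs(mean(x)) + 1e-9
  if (length(x) < 2 || stats::sd(x) == 0) return(floor_)
  b <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  max(b, floor_)
}

#' Overlap of two kernel density estimates
#'
#' Gaussian kernels with Silverman's bandwidth per sample, evaluated on a
#' common 512-point grid spanning both samples plus/minus 3 pooled
#' bandwidths; each density is normalized to unit mass on the grid and the
#' overlap is the integral of the pointwise minimum (trapezoid rule), so
#' identical samples give exactly 1. Degenerate (zero-variance) samples use
#' a floored bandwidth.
#'
#' @param sample_a,sample_b Numeric samples (each length >= 1).
#' @param n_grid Number of grid points (default 512).
#' @return Overlap coefficient in `[0, 1]`.
#' @export
density_overlap <- function(sample_a, sample_b, n_grid = 512) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (!length(a) || !length(b)) stop("samples must contain finite values")
  if (length(a) == length(b) && all(sort(a) == sort(b))) return(1)
  ha <- .bw_safe(a); hb <- .bw_safe(b)
  # essentially disjoint supports (relative to the kernel widths)
  if (min(b) - max(a) > 6 * (ha + hb) || min(a) - max(b) > 6 * (ha + hb))
    return(0)
  hp <- (ha + hb) / 2
  lo <- min(a, b) - 3 * hp
  hi <- max(a, b) + 3 * hp
  grid <- seq(lo, hi, length.out = n_grid)
  dx <- grid[2] - grid[1]
  kde <- function(x, h) {
    f <- rowMeans(outer(grid, x, function(g, xi) dnorm(g, xi, h)))
    area <- sum((f[-1] + f[-n_grid]) / 2) * dx
    f / area
  }
  fa <- kde(a, ha); fb <- kde(b, hb)
  fm <- pmin(fa, fb)
  ov <- sum((fm[-1] + fm[-n_grid]) / 2) * dx
  ov <- min(1, max(0, ov))
  if (1 - ov < 1e-12) ov <- 1
  ov
}

#' Per-pixel impact surface: overlaps and mean changes
#'
#' For each pixel and each metric, the overlap of the kernel densities of
#' current versus future yearly values and the change in mean
#' (future - current).
#'
#' @param current,future Named lists of matrices `[pixel, year]`; shared
#'   names (typically `tewl`, `adr`, `tair`) are processed.
#' @return `data.frame` of class `impact_surface` with one row per pixel and
#'   columns `<metric>_overlap`, `<metric>_delta`; pixels with missing data
#'   in either period get `NA` and are listed in attribute `missing_pixels`.
#' @export
impact_surface <- function(current, future) {
  metrics <- intersect(names(current), names(future))
  if (!length(metrics)) stop("no shared metrics between periods")
  np <- nrow(current[[metrics[1]]])
  out <- data.frame(pixel = seq_len(np))
  missing <- integer(0)
  for (m in metrics) {
    cm <- current[[m]]; fm <- future[[m]]
    stopifnot(nrow(fm) == np)
    ov <- de <- rep(NA_real_, np)
    for (i in seq_len(np)) {
      cv <- cm[i, ]; fv <- fm[i, ]
      if (all(is.finite(cv)) && all(is.finite(fv))) {
        ov[i] <- density_overlap(cv, fv)
        de[i] <- mean(fv) - mean(cv)
      } else {
        missing <- c(missing, i)
      }
    }
    out[[paste0(m, "_overlap")]] <- ov
    out[[paste0(m, "_delta")]] <- de
  }
  attr(out, "missing_pixels") <- sort(unique(missing))
  class(out) <- c("impact_surface", "data.frame")
  out
}

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Rank-based H with tie correction (via [stats::kruskal.test()]) and the
#' effect size epsilon^2 = H / (n - 1). Equivalent published forms divide by
#' (n^2 - 1)/(n + 1), which equals n - 1.
#'
#' @param groups List (>= 2) of non-empty numeric vectors, one per realm.
#' @return List with `H`, `p`, `epsilon_sq`, `n`.
#' @export
kruskal_wallis_epsilon <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(!lengths(groups)))
    stop("'groups' must be a list of >= 2 non-empty vectors")
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, epsilon_sq = 0, n = n))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)
  list(H = H, p = kt$p.value, epsilon_sq = H / (n - 1), n = n)
}

#' Pearson correlation over shared valid pixels
#'
#' @param x,y Numeric vectors (maps flattened), paired; `NA`s dropped
#'   pairwise; requires >= 3 complete pairs.
#' @return Correlation coefficient; `NA` with a warning if either side has
#'   zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}
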