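# Bivariate classification, refugia identification, protected-area
# accounting and map-comparison statistics. All thresholds are within-realm
# percentiles (linear-interpolation quantiles over valid desert pixels),
# with strict ">" at the threshold, matching a "top 25%" reading.

.valid_cells <- function(map, realm_id, realm, mask = NULL) {
  ok <- realm == realm_id & is.finite(map)
  if (!is.null(mask)) ok <- ok & mask
  which(ok)
}

#' Bivariate diversity-impact classes per realm
#'
#' Each valid pixel is classified by whether its diversity and impact-overlap
#' values fall in the top or bottom 25% of its realm: labels `"HH"`, `"HL"`,
#' `"LH"`, `"LL"` (first letter diversity, second overlap), with middle
#' pixels unclassified (`NA`). Realms with fewer than `min_pixels` valid
#' pixels are skipped.
#'
#' @param impact_overlap Matrix of impact overlaps (higher = lower impact).
#' @param diversity Matrix of diversity values.
#' @param realm Integer realm raster.
#' @param mask Optional logical mask restricting the analysis (desert mask).
#' @param probs Lower/upper percentile cut points (default 0.25/0.75).
#' @param min_pixels Minimum valid pixels per realm (default 8).
#' @return List with `class` (character matrix) and `area_table`
#'   (data.frame: realm, class, percent of realm area).
#' @export
bivariate_classes <- function(impact_overlap, diversity, realm, mask = NULL,
                              probs = c(0.25, 0.75), min_pixels = 8) {
  stopifnot(all(dim(impact_overlap) == dim(diversity)),
            all(dim(realm) == dim(diversity)))
  cls <- matrix(NA_character_, nrow(realm), ncol(realm))
  rows <- list()
  for (rid in sort(unique(as.vector(realm)))) {
    cells <- .valid_cells(impact_overlap, rid, realm, mask)
    cells <- cells[is.finite(diversity[cells])]
    if (length(cells) < min_pixels) {
      message("realm ", rid, " skipped (<", min_pixels, " valid pixels)")
      next
    }
    qo <- stats::quantile(impact_overlap[cells], probs, names = FALSE)
    qd <- stats::quantile(diversity[cells], probs, names = FALSE)
    dhi <- diversity[cells] >= qd[2]; dlo <- diversity[cells] <= qd[1]
    ohi <- impact_overlap[cells] >= qo[2]; olo <- impact_overlap[cells] <= qo[1]
    lab <- rep(NA_character_, length(cells))
    lab[dhi & ohi] <- "HH"; lab[dhi & olo] <- "HL"
    lab[dlo & ohi] <- "LH"; lab[dlo & olo] <- "LL"
    cls[cells] <- lab
    for (k in c("HH", "HL", "LH", "LL"))
      rows[[paste(rid, k)]] <- data.frame(
        realm = rid, class = k,
        percent = 100 * sum(lab == k, na.rm = TRUE) / length(cells))
  }
  list(class = cls, area_table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

# realm-wise refugia mask at given percentile thresholds
.refugia_mask_at <- function(tewl_ov, adr_ov, diversity, realm, mask,
                             threshold, rule) {
  refug <- matrix(FALSE, nrow(realm), ncol(realm))
  frac <- c()
  for (rid in sort(unique(as.vector(realm)))) {
    cells <- .valid_cells(diversity, rid, realm, mask)
    cells <- cells[is.finite(tewl_ov[cells]) & is.finite(adr_ov[cells])]
    if (!length(cells)) { frac[as.character(rid)] <- NA_real_; next }
    p <- threshold / 100
    qd <- stats::quantile(diversity[cells], p, names = FALSE)
    qt <- stats::quantile(tewl_ov[cells], p, names = FALSE)
    qa <- stats::quantile(adr_ov[cells], p, names = FALSE)
    imp <- if (rule == "or")
      tewl_ov[cells] > qt | adr_ov[cells] > qa
    else
      tewl_ov[cells] > qt & adr_ov[cells] > qa
    sel <- diversity[cells] > qd & imp
    refug[cells[sel]] <- TRUE
    frac[as.character(rid)] <- mean(sel)
  }
  list(mask = refug, fraction = frac)
}

#' Fixed-threshold climate refugia
#'
#' A pixel is a refugium iff its diversity exceeds the realm's `threshold`
#' percentile AND its climate-change impact is low by the chosen rule:
#' TEWL overlap OR ADR overlap above the same percentile (default), or both
#' (`rule = "and"`).
#'
#' @param tewl_overlap,adr_overlap Impact-overlap matrices.
#' @param diversity Diversity matrix (RWR).
#' @param realm Integer realm raster.
#' @param mask Optional logical analysis mask (desert).
#' @param threshold Percentile threshold in (0, 100] (default 75; 100 gives
#'   an empty refugia set under the strict ">" rule).
#' @param rule `"or"` (either impact metric) or `"and"` (all three).
#' @return List of class `refugia_result`: `mask` (logical matrix),
#'   `threshold` (per realm), `area_fraction` (per realm), `rule`.
#' @export
refugia_fixed <- function(tewl_overlap, adr_overlap, diversity, realm,
                          mask = NULL, threshold = 75,
                          rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0, threshold <= 100)
  r <- .refugia_mask_at(tewl_overlap, adr_overlap, diversity, realm, mask,
                        threshold, rule)
  structure(list(mask = r$mask,
                 threshold = setNames(rep(threshold, length(r$fraction)),
                                      names(r$fraction)),
                 area_fraction = r$fraction, rule = rule),
            class = "refugia_result")
}

#' Floating-threshold climate refugia
#'
#' Per realm, finds the largest percentile threshold (descending scan in
#' steps of `step`) whose refugia cover at least `target` of the realm's
#' valid area, and applies it.
#'
#' @inheritParams refugia_fixed
#' @param target Required area fraction per realm, in (0, 1) (default 0.05).
#' @param step Percentile scan step (default 0.1).
#' @return A `refugia_result` with per-realm thresholds and fractions;
#'   realms where the target is unreachable are `NA` and listed in
#'   `unmet_realms`.
#' @export
refugia_floating <- function(tewl_overlap, adr_overlap, diversity, realm,
                             mask = NULL, target = 0.05, step = 0.1,
                             rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(target > 0, target < 1)
  refug <- matrix(FALSE, nrow(realm), ncol(realm))
  thresholds <- fractions <- c()
  unmet <- integer(0)
  for (rid in sort(unique(as.vector(realm)))) {
    cells <- .valid_cells(diversity, rid, realm, mask)
    cells <- cells[is.finite(tewl_overlap[cells]) &
                     is.finite(adr_overlap[cells])]
    found <- FALSE
    if (length(cells)) {
      dv <- diversity[cells]; tv <- tewl_overlap[cells]
      av <- adr_overlap[cells]
      sel_at <- function(t) {
        p <- t / 100
        imp <- if (rule == "or")
          tv > stats::quantile(tv, p, names = FALSE) |
            av > stats::quantile(av, p, names = FALSE)
        else
          tv > stats::quantile(tv, p, names = FALSE) &
            av > stats::quantile(av, p, names = FALSE)
        dv > stats::quantile(dv, p, names = FALSE) & imp
      }
      for (t in rev(seq(step, 100 - step, by = step))) {
        sel <- sel_at(t)
        if (mean(sel) >= target) {
          refug[cells[sel]] <- TRUE
          thresholds[as.character(rid)] <- t
          fractions[as.character(rid)] <- mean(sel)
          found <- TRUE
          break
        }
      }
    }
    if (!found) {
      thresholds[as.character(rid)] <- NA_real_
      fractions[as.character(rid)] <- NA_real_
      unmet <- c(unmet, rid)
    }
  }
  structure(list(mask = refug, threshold = thresholds,
                 area_fraction = fractions, rule = rule,
                 unmet_realms = unmet),
            class = "refugia_result")
}

#' Protected-area coverage of refugia per realm
#'
#' @param refugia Logical refugia mask (or `refugia_result`).
#' @param pa Logical protected-area mask (categories Ia-IV assumed already
#'   selected on ingestion).
#' @param realm Integer realm raster.
#' @return Named vector: 100 * area(refugia & PA) / area(refugia) per realm;
#'   `NA` where a realm has no refugia.
#' @export
pa_coverage <- function(refugia, pa, realm) {
  if (inherits(refugia, "refugia_result")) refugia <- refugia$mask
  stopifnot(all(dim(refugia) == dim(pa)), all(dim(pa) == dim(realm)))
  out <- c()
  for (rid in sort(unique(as.vector(realm)))) {
    rcells <- refugia & realm == rid
    out[as.character(rid)] <-
      if (!any(rcells)) NA_real_ else 100 * sum(rcells & pa) / sum(rcells)
  }
  out
}

#' Weighted Jaccard similarity of two non-negative maps
#'
#' sum(min(x, y)) / sum(max(x, y)) over shared valid pixels; equals the
#' ordinary Jaccard index on 0/1 masks.
#'
#' @param x,y Non-negative matrices/vectors of equal shape, not both
#'   all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
weighted_jaccard <- function(x, y) {
  if (length(x) != length(y)) stop("maps are not aligned")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x < 0) || any(y < 0))
    stop("negative values: shift or normalize the maps upstream")
  denom <- sum(pmax(x, y))
  if (denom == 0) stop("both maps are all zero")
  sum(pmin(x, y)) / denom
}

#' Under- and over-protection between two refugia maps
#'
#' `under` is the percentage of the physiology-based refugia missed by the
#' air-temperature-based map; `over` the percentage of the air-temperature
#' refugia absent from the physiology-based map.
#'
#' @param refugia_physio,refugia_tair Logical masks (or `refugia_result`s).
#' @return Named vector `c(under, over)` in percent; `NA` where a reference
#'   mask is empty.
#' @export
protection_mismatch <- function(refugia_physio, refugia_tair) {
  if (inherits(refugia_physio, "refugia_result"))
    refugia_physio <- refugia_physio$mask
  if (inherits(refugia_tair, "refugia_result"))
    refugia_tair <- refugia_tair$mask
  stopifnot(all(dim(refugia_physio) == dim(refugia_tair)))
  np <- sum(refugia_physio); nt <- sum(refugia_tair)
  under <- if (np == 0) NA_real_ else
    100 * sum(refugia_physio & !refugia_tair) / np
  over <- if (nt == 0) NA_real_ else
    100 * sum(refugia_tair & !refugia_physio) / nt
  c(under = under, over = over)
}

#' Safe-site consistency between a base and a perturbed model run
#'
#' Safe sites are the top `fraction` of sites by impact overlap (largest
#' overlap = least impacted), ties broken by site index; consistency is the
#' percentage of base safe sites recovered under the perturbed parameters.
#'
#' @param base_overlap,perturbed_overlap Site-level overlap values, same
#'   site order.
#' @param fraction Top fraction defining safe sites (default 0.25).
#' @return Consistency in percent.
#' @export
safe_site_consistency <- function(base_overlap, perturbed_overlap,
                                  fraction = 0.25) {
  n <- length(base_overlap)
  if (length(perturbed_overlap) != n) stop("site sets differ")
  if (n < 4) stop("need at least 4 sites")
  k <- max(1L, round(fraction * n))
  top <- function(v) order(-v, seq_along(v))[seq_len(k)]
  100 * length(intersect(top(base_overlap), top(perturbed_overlap))) / k
}
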