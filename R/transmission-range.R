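# Links quantal (functional) release-site estimates to anatomy: boutons are
# counted at increasing radial distances from the postsynaptic dendrite and
# the monotone count curve is inverted at the Nfrs estimate to yield an
# effective volume-transmission range.

point_segment_dist2 <- function(px, py, pz, ax, ay, az, bx, by, bz) {
  vx <- bx - ax; vy <- by - ay; vz <- bz - az
  wx <- px - ax; wy <- py - ay; wz <- pz - az
  vv <- vx^2 + vy^2 + vz^2
  t <- ifelse(vv > 0, pmin(pmax((wx * vx + wy * vy + wz * vz) / vv, 0), 1), 0)
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2 + (pz - (az + t * vz))^2
}

# minimum distance from each point to a set of polylines
min_dist_to_polylines <- function(points, dendrite) {
  stopifnot(all(c("x", "y", "z") %in% names(dendrite)))
  if (nrow(dendrite) < 2)
    abort("dendrite needs at least one segment.", class = "ngf_error_geometry")
  path_col <- if ("path" %in% names(dendrite)) dendrite$path else
    rep(1L, nrow(dendrite))
  segs <- NULL
  for (p in unique(path_col)) {
    d <- dendrite[path_col == p, , drop = FALSE]
    if (nrow(d) < 2) next
    segs <- rbind(segs, cbind(d$x[-nrow(d)], d$y[-nrow(d)], d$z[-nrow(d)],
                              d$x[-1], d$y[-1], d$z[-1]))
  }
  if (is.null(segs))
    abort("dendrite polylines are degenerate.", class = "ngf_error_geometry")
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min(point_segment_dist2(points$x[i], points$y[i], points$z[i],
                                 segs[, 1], segs[, 2], segs[, 3],
                                 segs[, 4], segs[, 5], segs[, 6])))
  }, numeric(1))
}

#' Count presynaptic boutons near a postsynaptic dendrite
#'
#' For each radius, counts the boutons whose minimal Euclidean distance to
#' the dendrite polylines is `<= r` (boundary inclusive).  If the dendrite
#' table has a `radius` column, the local dendrite radius is subtracted
#' from the centerline distance.
#'
#' @param pre an `axon_morphology` with boutons placed, or a tibble of
#'   bouton positions (`x, y, z`).
#' @param post_dendrite tibble of dendrite polyline vertices (`x, y, z`,
#'   optional `path` to separate branches, optional `radius`).
#' @param radii radii to evaluate, um, sorted ascending
#'   (default 0.25-3.0 um in 0.25 um steps).
#' @param pair identifier copied into the output.
#' @return Tibble of class `bouton_count_curve`: `pair`, `radius`, `count`
#'   (cumulative, nondecreasing).
#' @export
count_boutons_near_dendrite <- function(pre, post_dendrite,
                                        radii = seq(0.25, 3, 0.25),
                                        pair = 1) {
  boutons <- if (inherits(pre, "axon_morphology")) pre$boutons else pre
  stopifnot(all(c("x", "y", "z") %in% names(boutons)))
  if (is.unsorted(radii))
    abort("`radii` must be sorted ascending.", class = "ngf_error_config")
  d <- min_dist_to_polylines(boutons, post_dendrite)
  if ("radius" %in% names(post_dendrite))
    d <- pmax(d - mean(post_dendrite$radius), 0)
  out <- tibble(pair = pair, radius = radii,
                count = vapply(radii, function(r) sum(d <= r), numeric(1)))
  class(out) <- c("bouton_count_curve", class(out))
  out
}

#' Effective volume-transmission range from Nfrs and bouton-count curves
#'
#' Per connection, the monotone cumulative bouton-count curve is inverted
#' (linear interpolation between radii) at `nfrs_mean - nfrs_sd` and
#' `nfrs_mean + nfrs_sd`; the per-connection intervals are aggregated as
#' the mean of their endpoints.
#'
#' @param nfrs_mean,nfrs_sd Nfrs estimate (mean and SD across or per
#'   connection; scalars are recycled).
#' @param curves list of `bouton_count_curve`s (or one).
#' @return One-row tibble: `range_lower`, `range_upper` (um),
#'   `lower_flagged`, `upper_flagged` (TRUE when an Nfrs fell below the
#'   curve minimum or above its maximum).
#' @export
estimate_range <- function(nfrs_mean, nfrs_sd, curves) {
  if (inherits(curves, "bouton_count_curve")) curves <- list(curves)
  n <- length(curves)
  nfrs_mean <- rep_len(nfrs_mean, n)
  nfrs_sd <- rep_len(nfrs_sd, n)
  invert <- function(curve, target) {
    r <- curve$radius; ct <- curve$count
    if (target <= ct[1]) return(list(r = r[1], flag = TRUE))
    if (target > ct[length(ct)]) return(list(r = r[length(r)], flag = TRUE))
    list(r = approx(ct, r, xout = target, ties = "ordered")$y, flag = FALSE)
  }
  lo <- hi <- numeric(n); flag_lo <- flag_hi <- logical(n)
  for (i in seq_len(n)) {
    a <- invert(curves[[i]], nfrs_mean[i] - nfrs_sd[i])
    b <- invert(curves[[i]], nfrs_mean[i] + nfrs_sd[i])
    lo[i] <- a$r; hi[i] <- b$r
    flag_lo[i] <- a$flag; flag_hi[i] <- b$flag
  }
  tibble(range_lower = mean(lo), range_upper = mean(hi),
         lower_flagged = any(flag_lo), upper_flagged = any(flag_hi))
}

#' Correlation between Nfrs and bouton counts as a function of radius
#'
#' Pearson r between per-pair Nfrs estimates and per-pair bouton counts at
#' each radius; the best radius maximizes r.  Radii with constant counts
#' across pairs are skipped with a warning (r undefined).
#'
#' @param nfrs_per_pair tibble `pair`, `nfrs` (>= 3 pairs).
#' @param curves list of `bouton_count_curve`s, one per pair.
#' @return Tibble of class `radius_correlation` with `radius`, `r`,
#'   `p_value`; attribute `best_radius`.
#' @export
correlation_vs_radius <- function(nfrs_per_pair, curves) {
  stopifnot(all(c("pair", "nfrs") %in% names(nfrs_per_pair)))
  if (nrow(nfrs_per_pair) < 3)
    abort("need >= 3 pairs.", class = "ngf_error_stats")
  counts <- bind_rows(curves)
  merged <- left_join(counts, nfrs_per_pair, by = "pair")
  radii <- unique(merged$radius)
  rows <- lapply(radii, function(rr) {
    d <- merged[merged$radius == rr, ]
    if (sd(d$count) == 0) {
      warn(sprintf("constant counts at radius %.2f; skipped.", rr))
      return(NULL)
    }
    ct <- cor.test(d$nfrs, d$count)
    tibble(radius = rr, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    abort("no radius with non-constant counts.", class = "ngf_error_stats")
  attr(out, "best_radius") <- out$radius[which.max(out$r)]
  class(out) <- c("radius_correlation", class(out))
  out
}
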