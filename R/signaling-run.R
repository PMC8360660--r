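# Driver for the particle simulator plus result summaries.

#' Run the particle-based GABA_B/GIRK cascade simulation
#'
#' Propagates GABA in 3D (effective diffusion
#' `D_gaba_free / tortuosity^2`, first-order clearance, reflecting box,
#' optional excluded dendrite volume) and the surface species in the 2D
#' membrane parameterization.  Bimolecular events are resolved by
#' reaction-radius sampling with per-pair event probabilities chosen so the
#' well-mixed limit reproduces mass action; the run aborts if any per-step
#' event probability exceeds 0.2 (time step too large).
#'
#' @param geometry a `membrane_geometry` from [synth_dendrite()].
#' @param lattice an [ecs_lattice()]; contributes the tortuosity and, by
#'   default, the bounding box.
#' @param layout a `cluster_layout` from [place_surface_molecules()].
#' @param scheme a [reaction_scheme()].
#' @param schedule a [release_schedule()].
#' @param dt time step, ms (default 0.001 ms = 1 us).
#' @param t_end simulated time, ms.
#' @param seed integer seed.
#' @param report_every reporting interval, ms.
#' @param box simulation box, um (defaults to the lattice bounding box).
#' @param exclude_dendrite treat the dendrite cylinder as an obstacle for
#'   GABA.  When `FALSE` the reaction volume at surface receptors is the
#'   full sphere (used by the well-mixed mass-action checks); when `TRUE`
#'   it is the accessible half-sphere.
#' @return Object of class `sim_result`: tibble `series` (per-report
#'   species counts) plus totals and the configuration.
#' @export
run_simulation <- function(geometry, lattice, layout, scheme, schedule,
                           dt = 0.001, t_end = 100, seed = 1,
                           report_every = 0.1, box = NULL,
                           exclude_dendrite = TRUE) {
  stopifnot(inherits(geometry, "membrane_geometry"),
            inherits(scheme, "reaction_scheme"),
            inherits(layout, "cluster_layout"))
  box <- box %||% lattice$bounding_box
  par <- geometry$param
  if (par$length > box[1] + 1e-9)
    abort("dendrite longer than the box.", class = "ngf_error_config")
  v_eff <- (if (exclude_dendrite) 2 / 3 else 4 / 3) * pi * scheme$rho_bind^3
  rates <- list(
    D_gaba = scheme$D_gaba_free / scheme$tortuosity^2,
    D_rec = scheme$D_receptor, D_gbg = scheme$D_gbg,
    k_clear = scheme$k_clear,
    k_on_micro = scheme$k_on / (602.214 * v_eff),
    rho_bind = scheme$rho_bind, k_off = scheme$k_off,
    k_cat_micro = scheme$k_cat / (pi * scheme$rho_cat^2),
    rho_cat = scheme$rho_cat,
    k_gb_micro = scheme$k_gb / (pi * scheme$rho_girk^2),
    rho_girk = scheme$rho_girk, k_gu = scheme$k_gu, k_re = scheme$k_re)
  geom <- list(box = as.double(box), dend_radius = par$radius,
               dend_y0 = box[2] / 2, dend_z0 = box[3] / 2,
               surf_len = par$length, surf_circ = par$circumference,
               exclude_dendrite = exclude_dendrite)
  comp_code <- function(x) ifelse(x == "spine", 1L, 0L)
  surf <- list(
    gabab = cbind(layout$gabab$u, layout$gabab$v, layout$gabab$size,
                  as.integer(layout$gabab$mobile),
                  comp_code(layout$gabab$compartment)),
    girk = cbind(layout$girk$u, layout$girk$v,
                 comp_code(layout$girk$compartment)),
    trimer = cbind(layout$trimers$u, layout$trimers$v))
  surf <- lapply(surf, function(m) {
    if (is.null(dim(m)) || nrow(m) == 0) matrix(0, 0, max(ncol(m), 2))
    else m
  })
  rel <- as.matrix(schedule[, c("time", "x", "y", "z", "n_molecules")])
  if (nrow(rel) == 0) rel <- matrix(numeric(), 0, 5)
  raw <- sim_cascade_cpp(geom, rel, surf, rates, dt, t_end, report_every,
                         as.integer(seed %% 2147483647))
  series <- as_tibble(raw[c("time", "gaba_free", "gabab_active_shaft",
                            "gabab_active_spine", "gabab_cum_shaft",
                            "gabab_cum_spine", "gbg_free", "gbg_cum",
                            "trimer", "gbg_bound", "girk_open_shaft",
                            "girk_open_spine", "girk_cum_shaft",
                            "girk_cum_spine")])
  structure(
    list(series = series,
         total_receptors = raw$total_receptors,
         total_channels = raw$total_channels,
         release_times = unique(schedule$time),
         dt = dt, t_end = t_end, seed = seed,
         exclude_dendrite = exclude_dendrite, box = box),
    class = "sim_result")
}

#' @describeIn run_simulation Per-report species counts.
#' @param x a `sim_result`.
#' @param ... unused.
#' @export
tidy.sim_result <- function(x, ...) x$series

#' @export
autoplot.sim_result <- function(object, ...) {
  d <- object$series |>
    select("time", "gaba_free", "gbg_free", "gbg_cum") |>
    tidyr::pivot_longer(-"time", names_to = "species")
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$species)) +
    geom_line() + labs(x = "time (ms)", y = "count")
}

#' Summarize a cascade simulation
#'
#' Totals per compartment: distinct GABA_B receptors activated, distinct
#' GIRK channels opened, their ratio (signaling effectiveness), peak free
#' Gbetagamma, total Gbetagamma produced, and the free-GABA decay time
#' constant fitted after the last release.
#'
#' @param result a `sim_result`.
#' @return One-row tibble with the summary quantities; effectiveness is
#'   `NA` (flagged) in compartments with zero activated receptors.
#' @export
summarize_signaling <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  s <- result$series
  if (nrow(s) < 2)
    abort("empty simulation result.", class = "ngf_error_config")
  last <- s[nrow(s), ]
  act_sh <- last$gabab_cum_shaft; act_sp <- last$gabab_cum_spine
  opn_sh <- last$girk_cum_shaft; opn_sp <- last$girk_cum_spine
  eff <- function(o, a) if (a > 0) o / a else NA_real_
  # free-GABA decay tau from the log-linear tail after the last release
  tau <- NA_real_
  t_last <- max(result$release_times, -Inf)
  tail_ <- s[s$time > t_last + 1 & s$gaba_free > 0, ]
  if (nrow(tail_) > 5) {
    fit <- stats::lm(log(gaba_free) ~ time, data = tail_)
    sl <- unname(stats::coef(fit)[2])
    if (is.finite(sl) && sl < 0) tau <- -1 / sl
  }
  tibble(
    activated_total = act_sh + act_sp,
    activated_shaft = act_sh, activated_spine = act_sp,
    opened_total = opn_sh + opn_sp,
    opened_shaft = opn_sh, opened_spine = opn_sp,
    effectiveness_shaft = eff(opn_sh, act_sh),
    effectiveness_spine = eff(opn_sp, act_sp),
    peak_gbg = max(s$gbg_free + s$gbg_bound),
    gbg_produced = last$gbg_cum,
    gaba_decay_tau = tau)
}

#' Linearity of GIRK recruitment across action-potential counts
#'
#' Compares the number of distinct GIRK channels opened by k consecutive
#' releases to k times the single-release count:
#' `deviation_k = 100 * (opened_k - k * opened_1) / (k * opened_1)` (%),
#' reported in total and per compartment.
#'
#' @param results list of `sim_result` (or [summarize_signaling()] rows)
#'   ordered by AP count, the 1-AP reference first.
#' @return Tibble with `n_ap`, `deviation_total`, `deviation_shaft`,
#'   `deviation_spine` for k >= 2; deviations are `NA` (flagged) where the
#'   1-AP count is zero.
#' @export
girk_summation_linearity <- function(results) {
  sums <- lapply(results, function(r)
    if (inherits(r, "sim_result")) summarize_signaling(r) else r)
  if (length(sums) < 2)
    abort("need a 1-AP reference plus at least one multi-AP result.",
          class = "ngf_error_config")
  ref <- sums[[1]]
  dev <- function(xk, x1, k) if (x1 > 0) 100 * (xk - k * x1) / (k * x1)
    else NA_real_
  bind_rows(lapply(seq_along(sums)[-1], function(k) {
    sk <- sums[[k]]
    tibble(n_ap = k,
           deviation_total = dev(sk$opened_total, ref$opened_total, k),
           deviation_shaft = dev(sk$opened_shaft, ref$opened_shaft, k),
           deviation_spine = dev(sk$opened_spine, ref$opened_spine, k))
  }))
}

#' Check conservation invariants of a simulation result
#'
#' Verifies at every report time that (i) heterotrimers + free + bound
#' Gbetagamma equals the initial heterotrimer count, (ii) currently open
#' GIRK channels never exceed the channel total, (iii) active receptors
#' never exceed the receptor total, and (iv) free GABA is nonincreasing
#' between release events.
#'
#' @param result a `sim_result`.
#' @return `TRUE` if all invariants hold, otherwise a character vector of
#'   violated invariants.
#' @export
check_conservation <- function(result) {
  s <- result$series
  bad <- character()
  gbg_total <- s$trimer + s$gbg_free + s$gbg_bound
  if (any(gbg_total != gbg_total[1]))
    bad <- c(bad, "G-protein pool not conserved")
  if (any(s$girk_open_shaft + s$girk_open_spine > result$total_channels))
    bad <- c(bad, "open channels exceed channel total")
  if (any(s$gabab_active_shaft + s$gabab_active_spine >
          result$total_receptors))
    bad <- c(bad, "active receptors exceed receptor total")
  rel <- sort(result$release_times)
  g <- s$gaba_free
  between <- !vapply(seq_len(nrow(s) - 1), function(i)
    any(rel > s$time[i] & rel <= s$time[i + 1]), logical(1))
  if (any(diff(g)[between] > 0))
    bad <- c(bad, "free GABA increased between releases")
  if (length(bad) == 0) TRUE else bad
}
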