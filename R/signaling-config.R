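# Configuration of the GABA_B -> Gbetagamma -> GIRK signaling simulator:
# reaction scheme (rates and diffusion coefficients), release schedule and
# the distance-dependent GABA release profile.

#' Distance-dependent peak GABA concentration profile
#'
#' Piecewise log-linear (exponential-segment) interpolation through the
#' anchor points; beyond the last anchor the final exponential slope is
#' continued.  Default anchors: 1 mM at the release site, 60 uM at 0.5 um,
#' 1 uM at 2.0 um.
#'
#' @param distance distance from the release site, um (>= 0, vectorized).
#' @param anchors tibble/data frame with `distance_um` and `conc_uM`
#'   (strictly decreasing concentration).
#' @return Peak concentration, uM.
#' @export
#' @examples
#' release_profile(c(0, 0.5, 2))
release_profile <- function(distance,
                            anchors = data.frame(
                              distance_um = c(0, 0.5, 2),
                              conc_uM = c(1000, 60, 1))) {
  if (any(distance < 0))
    abort("`distance` must be >= 0.", class = "ngf_error_domain")
  if (any(diff(anchors$conc_uM) >= 0))
    abort("anchor concentrations must decrease with distance.",
          class = "ngf_error_config")
  lc <- approx(anchors$distance_um, log(anchors$conc_uM), xout = distance,
               rule = 1)$y
  # extrapolate beyond the last anchor with the final slope
  n <- nrow(anchors)
  slope <- (log(anchors$conc_uM[n]) - log(anchors$conc_uM[n - 1])) /
    (anchors$distance_um[n] - anchors$distance_um[n - 1])
  beyond <- distance > anchors$distance_um[n]
  lc[beyond] <- log(anchors$conc_uM[n]) +
    slope * (distance[beyond] - anchors$distance_um[n])
  exp(lc)
}

#' Kinetic scheme of the GABA_B/GIRK cascade
#'
#' Rate constants and diffusion coefficients of the simulated cascade:
#' GABA binds GABA_B receptors (consuming the transmitter), active
#' receptors catalyze the dissociation of nearby G-protein heterotrimers
#' into Gbetagamma, free Gbetagamma diffuses laterally, binds GIRK channels
#' (a channel opens when all four sites are occupied) and reassociates into
#' heterotrimers.  None of the rates is experimentally printed; defaults
#' are literature-scale values calibrated once to the reference behavior
#' (~6 receptors activated per action potential at default geometry) and
#' are all configurable.
#'
#' @param D_gaba_free free GABA diffusion coefficient, um^2/ms.
#' @param tortuosity extracellular tortuosity; the effective 3D diffusion
#'   used in the box is `D_gaba_free / tortuosity^2`.
#' @param D_receptor lateral diffusion of mobile GABA_B clusters, um^2/ms.
#' @param D_gbg lateral diffusion of Gbetagamma, um^2/ms (default
#'   0.1 um^2/s).
#' @param k_clear first-order GABA clearance rate, 1/ms (default set so the
#'   free-GABA decay time constant is ~11.5 ms).
#' @param k_on GABA-receptor binding rate, 1/(uM ms).
#' @param rho_bind 3D reaction radius for binding, um.
#' @param k_off active-receptor deactivation rate, 1/ms.
#' @param k_cat catalysis rate (active receptor x trimer), um^2/ms.
#' @param rho_cat 2D catalysis radius, um.
#' @param k_gb Gbetagamma-GIRK binding rate, um^2/ms.
#' @param rho_girk 2D binding radius at channels, um.
#' @param k_gu Gbetagamma unbinding from GIRK, 1/ms.
#' @param k_re Gbetagamma reassociation (back into heterotrimer), 1/ms.
#' @return List of class `reaction_scheme`.
#' @export
reaction_scheme <- function(D_gaba_free = 0.5, tortuosity = 1.6,
                            D_receptor = 1e-4, D_gbg = 1e-4,
                            k_clear = 1 / 11.52,
                            k_on = 0.1, rho_bind = 0.05, k_off = 0.02,
                            k_cat = 0.05, rho_cat = 0.15,
                            k_gb = 0.05, rho_girk = 0.1,
                            k_gu = 0.005, k_re = 0.01) {
  vals <- c(D_gaba_free, tortuosity, D_receptor, D_gbg, k_clear, k_on,
            rho_bind, k_off, k_cat, rho_cat, k_gb, rho_girk, k_gu, k_re)
  if (any(vals < 0))
    abort("all rates must be >= 0.", class = "ngf_error_config")
  structure(list(D_gaba_free = D_gaba_free, tortuosity = tortuosity,
                 D_receptor = D_receptor, D_gbg = D_gbg, k_clear = k_clear,
                 k_on = k_on, rho_bind = rho_bind, k_off = k_off,
                 k_cat = k_cat, rho_cat = rho_cat, k_gb = k_gb,
                 rho_girk = rho_girk, k_gu = k_gu, k_re = k_re),
            class = "reaction_scheme")
}

#' GABA release schedule around the dendrite
#'
#' Places `n_sites` release sites at random positions around the dendrite
#' at radial distances drawn from `N(dist_mean, dist_sd)` (truncated
#' positive), and schedules `n_ap` consecutive releases per site at 100 Hz
#' (10 ms apart).  The released amount per event is constant from event to
#' event.
#'
#' @param n_sites number of release sites (default 4).
#' @param dist_mean,dist_sd radial distance of sites from the dendrite
#'   surface, um (default 1.2 +/- 0.7).
#' @param n_ap number of action potentials (1..4 typical).
#' @param ap_interval inter-release interval, ms (default 10, i.e. 100 Hz).
#' @param n_molecules molecules released per site per event.
#' @param t_first time of the first release, ms.
#' @param seed integer seed for site placement.
#' @param box simulation box, um.
#' @param dend_axis_y,dend_axis_z dendrite axis position.
#' @param dend_radius dendrite radius, um.
#' @param dend_u extent of the dendrite along x, um.
#' @return Tibble of class `release_schedule`: `time`, `x`, `y`, `z`,
#'   `n_molecules`, `site`.
#' @export
release_schedule <- function(n_sites = 4, dist_mean = 1.2, dist_sd = 0.7,
                             n_ap = 1, ap_interval = 10, n_molecules = 3000,
                             t_first = 5, seed = 1, box = c(6, 6, 6),
                             dend_axis_y = 3, dend_axis_z = 3,
                             dend_radius = 0.5, dend_u = 6) {
  if (n_ap < 1) abort("`n_ap` must be >= 1.", class = "ngf_error_config")
  sites <- with_seed(seed, {
    d <- rtruncnorm_pos(n_sites, dist_mean, dist_sd)
    th <- runif(n_sites, 0, 2 * pi)
    ux <- runif(n_sites, 0.2 * dend_u, 0.8 * dend_u)
    tibble(site = seq_len(n_sites),
           x = ux,
           y = dend_axis_y + (dend_radius + d) * cos(th),
           z = dend_axis_z + (dend_radius + d) * sin(th))
  })
  sites$y <- pmin(pmax(sites$y, 0.05), box[2] - 0.05)
  sites$z <- pmin(pmax(sites$z, 0.05), box[3] - 0.05)
  out <- tidyr::crossing(ap = seq_len(n_ap), sites) |>
    mutate(time = t_first + (.data$ap - 1) * ap_interval,
           n_molecules = n_molecules) |>
    select("time", "x", "y", "z", "n_molecules", "site") |>
    arrange(.data$time, .data$site)
  class(out) <- c("release_schedule", class(out))
  out
}
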