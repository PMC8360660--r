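# Extracellular-space (ECS) geometry: a periodic array of cubic cells with
# dead-end cavities, spaced by a uniform gap, reproducing the volume
# fraction (~0.2) and tortuosity (~1.6) of cortical tissue.  Lengths in um.

#' Cuboid-lattice extracellular-space geometry
#'
#' Default dimensions: 0.8 x 0.8 um cubic cells carrying a 0.4 x 0.4 um,
#' 0.34 um deep cavity, spaced 0.032 um apart, tiling a
#' 13.28 x 13.28 x 6.592 um^3 bounding box.  The extracellular space is the
#' inter-cell gap network plus the dead-end cavities.
#'
#' @param cuboid cubic-cell edge, um.
#' @param cavity_width cavity side, um.
#' @param cavity_depth cavity depth, um.
#' @param gap inter-object spacing, um (> 0).
#' @param bounding_box simulation-domain dimensions, um.
#' @return List of class `ecs_lattice` with the geometry and the derived
#'   `volume_fraction` (analytic) and `domain_volume` (um^3).
#' @export
#' @examples
#' lat <- ecs_lattice()
#' round(lat$volume_fraction, 1)
ecs_lattice <- function(cuboid = 0.8, cavity_width = 0.4,
                        cavity_depth = 0.34, gap = 0.032,
                        bounding_box = c(13.28, 13.28, 6.592)) {
  if (gap <= 0) abort("`gap` must be > 0.", class = "ngf_error_geometry")
  if (cavity_width > cuboid || cavity_depth > cuboid)
    abort("cavity must fit inside the cuboid.", class = "ngf_error_geometry")
  pitch <- cuboid + gap
  solid <- cuboid^3 - cavity_width^2 * cavity_depth
  vf <- 1 - solid / pitch^3
  structure(
    list(cuboid = cuboid, cavity_width = cavity_width,
         cavity_depth = cavity_depth, gap = gap, pitch = pitch,
         bounding_box = bounding_box,
         volume_fraction = vf,
         domain_volume = prod(bounding_box)),
    class = "ecs_lattice"
  )
}

#' Extracellular volume fraction of a lattice
#'
#' @param lattice an [ecs_lattice()].
#' @param method `"analytic"` (closed form per unit cell) or `"voxel"`
#'   (fine voxelization of one unit cell; numeric cross-check).
#' @param n_voxel voxels per edge for the numeric method.
#' @return Extracellular volume fraction in `[0, 1]`.
#' @export
ecs_volume_fraction <- function(lattice, method = c("analytic", "voxel"),
                                n_voxel = 260) {
  stopifnot(inherits(lattice, "ecs_lattice"))
  method <- match.arg(method)
  if (method == "analytic") return(lattice$volume_fraction)
  p <- lattice$pitch
  g2 <- lattice$gap / 2
  ctr <- (seq_len(n_voxel) - 0.5) / n_voxel * p
  cav_lo <- g2 + (lattice$cuboid - lattice$cavity_width) / 2
  cav_hi <- cav_lo + lattice$cavity_width
  cav_zlo <- g2 + lattice$cuboid - lattice$cavity_depth
  in_cube1 <- ctr >= g2 & ctr < g2 + lattice$cuboid
  in_cav_xy <- ctr >= cav_lo & ctr < cav_hi
  in_cav_z <- ctr >= cav_zlo & ctr < g2 + lattice$cuboid
  # solid = cube minus cavity; count via separable indicator products
  n_cube <- sum(in_cube1)^3
  n_cav <- sum(in_cav_xy)^2 * sum(in_cav_z & in_cube1)
  1 - (n_cube - n_cav) / n_voxel^3
}

#' Tortuosity of the lattice extracellular space by random walk
#'
#' Releases point walkers at equilibrium positions in the extracellular
#' compartment and estimates the effective diffusion coefficient from the
#' long-time slope of the mean-squared displacement; the tortuosity is
#' `lambda = sqrt(D_free / D_eff)`.  Steps rejected into solid implement
#' reflecting boundaries.
#'
#' @param lattice an [ecs_lattice()].
#' @param n_walkers number of walkers (>= 100).
#' @param n_steps number of steps per walker.
#' @param seed integer seed.
#' @param step_nm walker step length, nm (must resolve the gap width).
#' @return One-row tibble: `lambda`, `d_eff_ratio` (`D_eff / D_free`),
#'   `n_walkers`, `n_steps`.  A warning is raised if the MSD curve is not
#'   yet linear (slope still drifting by > 10% across the fit window).
#' @export
estimate_tortuosity <- function(lattice, n_walkers = 10000, n_steps = 400000,
                                seed = 1, step_nm = 8) {
  stopifnot(inherits(lattice, "ecs_lattice"))
  if (n_walkers < 100)
    abort("use >= 100 walkers.", class = "ngf_error_config")
  res <- walk_lattice_msd(
    as.integer(n_walkers), as.integer(n_steps), step_nm,
    lattice$cuboid * 1000, lattice$gap * 1000,
    lattice$cavity_width * 1000, lattice$cavity_depth * 1000,
    n_checkpoints = 40L, seed = as.integer(seed %% 2147483647),
    free_space = FALSE)
  # fit MSD ~ steps over the second half; free-space MSD per step is h^2
  sel <- res$steps > max(res$steps) / 2
  fit <- stats::lm(msd ~ steps, data = data.frame(steps = res$steps[sel],
                                                  msd = res$msd[sel]))
  slope <- unname(stats::coef(fit)[2])
  ratio <- slope / step_nm^2
  # linearity check: compare slope over 3rd vs 4th quarter
  q3 <- res$steps > max(res$steps) / 2 & res$steps <= 3 * max(res$steps) / 4
  q4 <- res$steps > 3 * max(res$steps) / 4
  s3 <- stats::coef(stats::lm(res$msd[q3] ~ res$steps[q3]))[2]
  s4 <- stats::coef(stats::lm(res$msd[q4] ~ res$steps[q4]))[2]
  if (is.finite(s3) && is.finite(s4) && abs(s4 - s3) / abs(s3) > 0.1)
    warn("MSD slope still drifting; increase `n_steps`.",
         class = "ngf_warn_convergence")
  tibble(lambda = 1 / sqrt(ratio), d_eff_ratio = ratio,
         n_walkers = n_walkers, n_steps = n_steps)
}
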