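# Layer-1 population model: somata placed in a bounded cortical volume with
# a depth-dependent density, one model arbor per soma, and a voxelized map
# of how many boutons (and how many distinct source cells) reach each voxel
# within the volume-transmission radius.

#' Depth-density profile of layer-1 interneuron somata
#'
#' Relative soma density as a function of depth below the pia (z, um).
#' The default is a parametric stand-in peaking at 50-150 um depth,
#' matching the radial distribution of alpha-actinin2-positive somata;
#' override the bins to use measured histograms.
#'
#' @param edges depth-bin edges, um (increasing).
#' @param density relative density per bin (>= 0, at least one positive).
#' @return Tibble of class `depth_profile` with `z_lo`, `z_hi`, `density`.
#' @export
depth_density_profile <- function(edges = c(0, 25, 50, 100, 140),
                                  density = c(0.4, 0.8, 1, 0.9)) {
  if (length(edges) != length(density) + 1 || any(diff(edges) <= 0))
    abort("`edges` must be increasing with one more entry than `density`.",
          class = "ngf_error_config")
  if (any(density < 0) || sum(density) == 0)
    abort("densities must be >= 0 with at least one positive bin.",
          class = "ngf_error_config")
  out <- tibble(z_lo = edges[-length(edges)], z_hi = edges[-1],
                density = density)
  class(out) <- c("depth_profile", class(out))
  out
}

#' Sample soma positions in a bounded volume
#'
#' x and y are uniform over the volume footprint; z (depth) follows the
#' depth-density profile.  Defaults reproduce the population model of the
#' superficial neocortex: 374 somata in a 354 x 354 x 140 um^3 volume.
#'
#' @param profile a [depth_density_profile()].
#' @param dims volume dimensions `c(x, y, z)`, um.
#' @param n number of somata (>= 0).
#' @param seed integer seed.
#' @return Tibble `cell`, `x`, `y`, `z` (z = depth below pia).
#' @export
sample_somata <- function(profile = depth_density_profile(),
                          dims = c(354, 354, 140), n = 374, seed = 1) {
  if (n < 0) abort("`n` must be >= 0.", class = "ngf_error_config")
  if (sum(profile$density) == 0)
    abort("all-zero depth profile.", class = "ngf_error_config")
  prof <- profile[profile$z_lo < dims[3], , drop = FALSE]
  prof$z_hi <- pmin(prof$z_hi, dims[3])
  w <- prof$density * (prof$z_hi - prof$z_lo)
  with_seed(seed, {
    bin <- sample.int(nrow(prof), n, replace = TRUE, prob = w)
    tibble(cell = seq_len(n),
           x = runif(n, 0, dims[1]),
           y = runif(n, 0, dims[2]),
           z = runif(n, prof$z_lo[bin], prof$z_hi[bin]))
  })
}

#' Nearest-neighbor distances of a 3D point set
#'
#' Per-point Euclidean distance to its nearest neighbor, used to compare
#' modeled against immunolabeled soma distributions.
#'
#' @param positions data frame with columns `x`, `y`, `z` (>= 2 rows).
#' @return Numeric vector of distances, one per point.
#' @export
nn_distances <- function(positions) {
  stopifnot(all(c("x", "y", "z") %in% names(positions)))
  n <- nrow(positions)
  if (n < 2)
    abort("need at least 2 positions.", class = "ngf_error_stats")
  d <- as.matrix(stats::dist(positions[, c("x", "y", "z")]))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Build a population layout: somata plus per-cell bouton clouds
#'
#' Grows one model arbor per soma and decorates it with boutons, producing
#' the flat bouton table the coverage map consumes.
#'
#' @param somata tibble from [sample_somata()].
#' @param params a [growth_params()].
#' @param spacing_mean,spacing_sd inter-bouton spacing parameters, um.
#' @param seed integer seed.
#' @param dims volume dimensions, um.
#' @return Object of class `population_layout`: list with `somata`,
#'   `boutons` (tibble `cell, x, y, z`), `dims`.
#' @export
population_layout <- function(somata, params = growth_params(),
                              spacing_mean = 3.36, spacing_sd = 2.54,
                              seed = 1, dims = c(354, 354, 140)) {
  boutons <- bind_rows(lapply(seq_len(nrow(somata)), function(i) {
    m <- grow_axon(params, seed = derive_seed(seed, 2 * i),
                   soma = c(somata$x[i], somata$y[i], somata$z[i]))
    m <- place_boutons(m, spacing_mean, spacing_sd,
                       seed = derive_seed(seed, 2 * i + 1))
    if (nrow(m$boutons) == 0) return(NULL)
    tibble(cell = somata$cell[i], x = m$boutons$x, y = m$boutons$y,
           z = m$boutons$z)
  }))
  structure(list(somata = somata, boutons = boutons, dims = dims),
            class = "population_layout")
}

#' Voxelized bouton-coverage map
#'
#' For every voxel center inside the volume, counts the boutons lying
#' within the transmitter-diffusion radius and the number of distinct
#' source cells among them.  Voxels closer than `radius` to a volume face
#' are flagged `edge` (coverage there is deflated by the boundary).
#'
#' @param layout a `population_layout`, or any tibble with columns
#'   `cell, x, y, z` plus a `dims` attribute/argument.
#' @param radius interaction radius, um (default 1.5, the effective
#'   volume-transmission range).
#' @param voxel_size voxel edge, um (default 1).
#' @param dims volume dimensions (defaults to the layout's).
#' @return Tibble of class `coverage_map`: `ix, iy, iz` (0-based voxel
#'   indices), `boutons`, `sources`, `edge`.  Voxels with zero boutons are
#'   omitted from the table (counts of zero are implicit); attributes
#'   `dims`, `voxel_size`, `radius`, `n_voxels_total`.
#' @export
build_coverage <- function(layout, radius = 1.5, voxel_size = 1,
                           dims = NULL) {
  if (inherits(layout, "population_layout")) {
    boutons <- layout$boutons
    dims <- dims %||% layout$dims
  } else {
    boutons <- layout
    dims <- dims %||% attr(layout, "dims")
  }
  if (is.null(dims))
    abort("volume `dims` must be supplied.", class = "ngf_error_config")
  if (radius <= 0)
    abort("`radius` must be > 0.", class = "ngf_error_config")
  if (voxel_size <= 0)
    abort("`voxel_size` must be > 0.", class = "ngf_error_config")
  nv <- pmax(1L, floor(dims / voxel_size))
  # voxel-center offsets reached from a bouton's own voxel
  reach <- ceiling(radius / voxel_size)
  off <- expand.grid(dx = -reach:reach, dy = -reach:reach, dz = -reach:reach)
  keep_off <- sqrt(3) * voxel_size / 2  # conservative pre-filter
  hits <- vector("list", nrow(off))
  bx <- boutons$x; by <- boutons$y; bz <- boutons$z
  cell <- boutons$cell
  ivx <- floor(bx / voxel_size); ivy <- floor(by / voxel_size)
  ivz <- floor(bz / voxel_size)
  acc <- list()
  for (r in seq_len(nrow(off))) {
    jx <- ivx + off$dx[r]; jy <- ivy + off$dy[r]; jz <- ivz + off$dz[r]
    cx <- (jx + 0.5) * voxel_size
    cy <- (jy + 0.5) * voxel_size
    cz <- (jz + 0.5) * voxel_size
    d2 <- (bx - cx)^2 + (by - cy)^2 + (bz - cz)^2
    ok <- d2 <= radius^2 & jx >= 0 & jy >= 0 & jz >= 0 &
      jx < nv[1] & jy < nv[2] & jz < nv[3]
    if (any(ok))
      acc[[length(acc) + 1]] <- tibble(ix = jx[ok], iy = jy[ok],
                                       iz = jz[ok], cell = cell[ok])
  }
  if (length(acc) == 0) {
    out <- tibble(ix = integer(), iy = integer(), iz = integer(),
                  boutons = integer(), sources = integer(), edge = logical())
  } else {
    pairs <- bind_rows(acc)
    out <- pairs |>
      group_by(.data$ix, .data$iy, .data$iz) |>
      summarise(boutons = dplyr::n(),
                sources = dplyr::n_distinct(.data$cell),
                .groups = "drop")
    ctr <- cbind((out$ix + 0.5) * voxel_size, (out$iy + 0.5) * voxel_size,
                 (out$iz + 0.5) * voxel_size)
    out$edge <- ctr[, 1] < radius | ctr[, 1] > dims[1] - radius |
      ctr[, 2] < radius | ctr[, 2] > dims[2] - radius |
      ctr[, 3] < radius | ctr[, 3] > dims[3] - radius
  }
  attr(out, "dims") <- dims
  attr(out, "voxel_size") <- voxel_size
  attr(out, "radius") <- radius
  attr(out, "n_voxels_total") <- prod(nv)
  attr(out, "boutons") <- boutons
  class(out) <- c("coverage_map", class(out))
  out
}

#' Source-multiplicity distribution of a coverage map
#'
#' Subsamples active cells with probability `active_fraction`, recomputes
#' per-voxel distinct-source counts and reports the percentage of covered
#' voxels reached by exactly 1, 2, 3 or >= 4 distinct active cells.
#' Edge-flagged voxels are excluded by default.
#'
#' @param coverage a `coverage_map` from [build_coverage()].
#' @param active_fraction fraction of cells active, in (0, 1]; 1 is full
#'   population-level cooperativity, 2/3 approximates the fraction of cells
#'   coactive in vivo.
#' @param seed integer seed (used when `active_fraction < 1`).
#' @param include_edge include edge-flagged voxels?
#' @return Tibble `sources` (`"1", "2", "3", ">=4"`), `n_voxels`,
#'   `percent`; percentages sum to 100.
#' @export
source_multiplicity <- function(coverage, active_fraction = 1, seed = 1,
                                include_edge = FALSE) {
  if (active_fraction <= 0 || active_fraction > 1)
    abort("`active_fraction` must be in (0, 1].", class = "ngf_error_config")
  stopifnot(inherits(coverage, "coverage_map"))
  if (active_fraction < 1) {
    boutons <- attr(coverage, "boutons")
    cells <- unique(boutons$cell)
    keep <- with_seed(seed,
                      cells[runif(length(cells)) < active_fraction])
    sub <- boutons[boutons$cell %in% keep, , drop = FALSE]
    coverage <- build_coverage(sub, radius = attr(coverage, "radius"),
                               voxel_size = attr(coverage, "voxel_size"),
                               dims = attr(coverage, "dims"))
  }
  m <- coverage
  if (!include_edge) m <- m[!m$edge, , drop = FALSE]
  if (nrow(m) == 0)
    abort("no covered voxel.", class = "ngf_error_empty_coverage")
  cat4 <- cut(m$sources, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", ">=4"))
  tab <- table(cat4)
  tibble(sources = names(tab),
         n_voxels = as.integer(tab),
         percent = 100 * as.integer(tab) / sum(tab))
}

#' @export
autoplot.coverage_map <- function(object, slice = NULL, ...) {
  m <- object
  if (!is.null(slice)) m <- m[m$iz == slice, , drop = FALSE]
  ggplot(m, aes(x = .data$ix, y = .data$iy, fill = .data$boutons)) +
    ggplot2::geom_tile() +
    labs(x = "x voxel", y = "y voxel", fill = "boutons")
}
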