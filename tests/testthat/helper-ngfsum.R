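# Shared fixtures: all synthetic, built in code.

# straight unbranched axon of given length from the origin (single segment
# chain along +x), as an axon_morphology
straight_axon <- function(length, step = 5) {
  n <- ceiling(length / step)
  xs <- seq(0, length, length.out = n + 1)
  out <- list(
    soma = c(0, 0, 0),
    nodes = tibble::tibble(id = seq_len(n + 1),
                           parent = c(0L, seq_len(n)),
                           x = xs, y = 0, z = 0),
    boutons = tibble::tibble(x = double(), y = double(), z = double(),
                             path_dist = double()),
    total_length = length, step_length = step)
  class(out) <- "axon_morphology"
  out
}

# brute-force coverage oracle: per-voxel scan over all voxel centers
coverage_oracle <- function(boutons, dims, radius, voxel_size) {
  nv <- pmax(1L, floor(dims / voxel_size))
  grid <- expand.grid(ix = 0:(nv[1] - 1), iy = 0:(nv[2] - 1),
                      iz = 0:(nv[3] - 1))
  cx <- (grid$ix + 0.5) * voxel_size
  cy <- (grid$iy + 0.5) * voxel_size
  cz <- (grid$iz + 0.5) * voxel_size
  n <- nrow(grid)
  bout <- integer(n); src <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (boutons$x - cx[i])^2 + (boutons$y - cy[i])^2 +
      (boutons$z - cz[i])^2
    hit <- d2 <= radius^2
    bout[i] <- sum(hit)
    src[i] <- length(unique(boutons$cell[hit]))
  }
  cbind(grid, boutons = bout, sources = src)
}

# small deterministic event-feature set with three separated clusters
three_cluster_events <- function(n_per = 20, seed = 42) {
  centers <- data.frame(slope = c(0, 1.2, 3.5),
                        amplitude = c(0, 4.6, 12),
                        area = c(0, 40, 110))
  withr::with_seed(seed, {
    do.call(rbind, lapply(1:3, function(g) {
      data.frame(slope = rnorm(n_per, centers$slope[g], 0.1),
                 amplitude = rnorm(n_per, centers$amplitude[g], 0.3),
                 area = rnorm(n_per, centers$area[g], 2),
                 truth = c("failure", "uniquantal", "multiquantal")[g])
    }))
  })
}

# well-mixed signaling configuration used by the mass-action oracle tests:
# tiny box, fast diffusion, mobile receptors, no GIRK coupling
wellmixed_config <- function(n_trimers = 1500, n_rec_clusters = 10,
                             rec_size = 4) {
  box <- c(2, 2, 2)
  geom <- synth_dendrite(2, 0.3, n_spines = 0, seed = 1)
  sc <- reaction_scheme(D_gaba_free = 5, tortuosity = 1, D_receptor = 0.5,
                        D_gbg = 0.2, k_clear = 0.02, k_on = 0.1,
                        rho_bind = 0.05, k_off = 0.02, k_cat = 0.02,
                        rho_cat = 0.15, k_gb = 0, rho_girk = 0.1,
                        k_gu = 0, k_re = 0.01)
  layout_fn <- function(seed) {
    withr::with_seed(seed, {
      structure(list(
        gabab = tibble::tibble(u = runif(n_rec_clusters, 0.2, 1.8),
                               v = runif(n_rec_clusters, 0, 2 * pi * 0.3),
                               size = rec_size, mobile = TRUE,
                               compartment = "shaft"),
        girk = tibble::tibble(u = double(), v = double(),
                              compartment = character(),
                              cluster = integer()),
        trimers = tibble::tibble(u = runif(n_trimers, 0, 2),
                                 v = runif(n_trimers, 0, 2 * pi * 0.3)),
        circumference = 2 * pi * 0.3, length = 2),
        class = "cluster_layout")
    })
  }
  sch <- tibble::tibble(time = 1, x = 1, y = 0.4, z = 0.4,
                        n_molecules = 3000, site = 1)
  class(sch) <- c("release_schedule", class(sch))
  list(box = box, geom = geom, scheme = sc, layout_fn = layout_fn,
       schedule = sch, n_rec = n_rec_clusters * rec_size,
       n_trimers = n_trimers, area = 2 * pi * 0.3 * 2)
}

# mass-action ODE oracle for the well-mixed configuration (deSolve)
wellmixed_ode <- function(cfg, t_max = 59, g0 = 3000) {
  V <- prod(cfg$box)
  c_on <- cfg$scheme$k_on / (602.214 * V)
  c_cat <- cfg$scheme$k_cat / cfg$area
  k_clear <- cfg$scheme$k_clear; k_off <- cfg$scheme$k_off
  k_re <- cfg$scheme$k_re; Rtot <- cfg$n_rec
  fn <- function(t, y, p) {
    bind <- c_on * y[1] * (Rtot - y[2])
    cat_ <- c_cat * y[2] * y[3]
    list(c(-k_clear * y[1] - bind,
           bind - k_off * y[2],
           -cat_ + k_re * y[4],
           cat_ - k_re * y[4]))
  }
  deSolve::ode(c(G = g0, Ra = 0, T = cfg$n_trimers, B = 0),
               times = seq(0, t_max, 0.1), fn, NULL)
}

# reduced-scale cascade run (default rates) used by several tests
small_cascade_run <- function(seed, n_ap = 1,
                              densities = c(gabab_shaft = 5,
                                            gabab_spine = 5,
                                            girk_shaft = 8,
                                            girk_spine = 8),
                              cascade = cascade_params(),
                              n_molecules = 4000, dt = 0.005) {
  geom <- synth_dendrite(6, 0.5, n_spines = 6, seed = 2)
  lay <- place_surface_molecules(geom, densities = densities,
                                 cascade = cascade, seed = seed)
  sch <- release_schedule(n_ap = n_ap, n_molecules = n_molecules,
                          seed = seed, box = c(6, 6, 6), dend_u = 6)
  run_simulation(geom, ecs_lattice(), lay, reaction_scheme(), sch,
                 dt = dt, t_end = 140 + 10 * (n_ap - 1), seed = seed + 7,
                 box = c(6, 6, 6))
}
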