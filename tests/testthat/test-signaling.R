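test_that("release profile interpolates the anchors log-linearly", {
  expect_equal(release_profile(0), 1000)
  expect_equal(release_profile(0.5), 60)
  expect_equal(release_profile(2), 1)
  expect_equal(release_profile(1.25), 60 * (1 / 60)^(0.75 / 1.5),
               tolerance = 1e-9)
  # beyond the last anchor: the final exponential slope continues
  slope <- log(1 / 60) / 1.5
  expect_equal(release_profile(3), exp(log(1) + slope), tolerance = 1e-9)
  expect_error(release_profile(-0.1), class = "ngf_error_domain")
  expect_error(release_profile(1, anchors = data.frame(
    distance_um = c(0, 1), conc_uM = c(1, 2))), class = "ngf_error_config")
})

test_that("release schedule: sites, timing and determinism", {
  sch <- release_schedule(n_sites = 4, n_ap = 3, seed = 5)
  expect_equal(nrow(sch), 12)
  expect_equal(sort(unique(sch$time)), c(5, 15, 25))
  expect_identical(release_schedule(seed = 5), release_schedule(seed = 5))
  expect_error(release_schedule(n_ap = 0), class = "ngf_error_config")
})

test_that("surface placement: densities, cluster sizes, compartments", {
  geom <- synth_dendrite(6, 0.5, n_spines = 6, seed = 2)
  lay <- place_surface_molecules(geom, seed = 1)
  expect_true(all(lay$gabab$size >= 1 & lay$gabab$size <= 8))
  girk_sizes <- table(lay$girk$cluster)
  expect_true(all(girk_sizes >= 1 & girk_sizes <= 4))
  expect_true(all(!duplicated(lay$girk$cluster[!duplicated(lay$girk$cluster)])))

  # realized copy numbers within 10% of density x area
  par <- geom$param
  a_spine <- sum(par$spines$area)
  a_shaft <- par$length * par$circumference -
    sum(pi * par$spines$patch_radius^2)
  tgt_sp <- 4 * a_spine
  got_sp <- sum(lay$gabab$size[lay$gabab$compartment == "spine"])
  expect_lt(abs(got_sp - tgt_sp) / tgt_sp, 0.1)
  tgt_gk <- 8 * a_shaft
  got_gk <- sum(lay$girk$compartment == "shaft")
  expect_lt(abs(got_gk - tgt_gk) / tgt_gk, 0.1)

  # zero densities: empty layout
  lay0 <- place_surface_molecules(geom, densities = c(gabab_shaft = 0,
                                                      gabab_spine = 0,
                                                      girk_shaft = 0,
                                                      girk_spine = 0),
                                  trimer_density = 0, seed = 1)
  expect_equal(nrow(lay0$gabab), 0)
  expect_equal(nrow(lay0$girk), 0)

  # colocalization: spine receptor clusters sit nearer channels than shaft
  d <- cluster_distances(lay)
  med <- tapply(d, lay$gabab$compartment, median)
  expect_lt(med[["spine"]], med[["shaft"]])
})

test_that("cluster-placement calibration recovers known cascade parameters", {
  true_par <- cascade_params(delay = 30, forward_rate = 0.08)
  target <- ngfsum:::cascade_test_distances(true_par, n = 800, seed = 100)
  out <- calibrate_cluster_placement(target,
                                     init = cascade_params(delay = 5,
                                                           forward_rate = 0.3),
                                     seed = 1)
  expect_true(attr(out, "passed"))
  expect_gte(attr(out, "ks_p"), 0.05)
  # best-so-far energy is nonincreasing
  expect_true(all(diff(attr(out, "trace")) <= 1e-12))

  # limiting behavior: no delay, fast nucleation -> distances collapse
  tight <- ngfsum:::cascade_test_distances(
    cascade_params(delay = 0, forward_rate = 100), n = 300, seed = 1)
  expect_lt(median(tight), 0.01)
})

test_that("simulator trivial limits and stability guard", {
  cfg <- wellmixed_config(n_trimers = 100, n_rec_clusters = 4)
  empty_sched <- cfg$schedule[0, ]
  res0 <- run_simulation(cfg$geom, ecs_lattice(), cfg$layout_fn(1),
                         cfg$scheme, empty_sched, dt = 0.01, t_end = 10,
                         seed = 1, box = cfg$box, exclude_dendrite = FALSE)
  s0 <- res0$series
  expect_true(all(s0$gaba_free == 0))
  expect_true(all(s0$gabab_cum_shaft + s0$gabab_cum_spine == 0))

  # all rates zero: GABA only diffuses and decays, nothing downstream
  sc0 <- reaction_scheme(k_on = 0, k_cat = 0, k_gb = 0, k_clear = 0.2,
                         tortuosity = 1)
  res1 <- run_simulation(cfg$geom, ecs_lattice(), cfg$layout_fn(1), sc0,
                         cfg$schedule, dt = 0.01, t_end = 30, seed = 2,
                         box = cfg$box, exclude_dendrite = FALSE)
  s1 <- res1$series
  expect_true(all(s1$gabab_cum_shaft + s1$gabab_cum_spine == 0))
  expect_true(all(s1$gbg_cum == 0))
  expect_true(all(diff(s1$gaba_free[s1$time >= 1]) <= 0))

  # time step too large for the fastest rate
  fast <- reaction_scheme(k_on = 50)
  expect_error(run_simulation(cfg$geom, ecs_lattice(), cfg$layout_fn(1),
                              fast, cfg$schedule, dt = 0.05, t_end = 5,
                              seed = 1, box = cfg$box,
                              exclude_dendrite = FALSE),
               "p_event")
})

test_that("conservation invariants hold on a default reduced-scale run", {
  res <- small_cascade_run(seed = 3, n_ap = 2)
  expect_true(isTRUE(check_conservation(res)))
  s <- res$series
  # receptor and channel totals are fixed by construction
  expect_true(all(s$gabab_active_shaft + s$gabab_active_spine <=
                    res$total_receptors))
  expect_true(all(s$girk_cum_shaft + s$girk_cum_spine <=
                    res$total_channels))
  # determinism
  res2 <- small_cascade_run(seed = 3, n_ap = 2)
  expect_identical(res$series, res2$series)
})

test_that("more releases recruit at least as many receptors (over seeds)", {
  acts <- vapply(1:4, function(sd) {
    a1 <- summarize_signaling(small_cascade_run(sd))$activated_total
    a3 <- summarize_signaling(small_cascade_run(sd, n_ap = 3))$activated_total
    c(a1, a3)
  }, numeric(2))
  expect_true(all(acts[2, ] >= acts[1, ]))
})

test_that("summaries: effectiveness ratio and flagged degenerate cases", {
  fake <- structure(list(
    series = tibble::tibble(
      time = c(0, 1), gaba_free = c(0, 0),
      gabab_active_shaft = c(0, 0), gabab_active_spine = c(0, 0),
      gabab_cum_shaft = c(0, 10), gabab_cum_spine = c(0, 0),
      gbg_free = c(0, 0), gbg_cum = c(0, 0), trimer = c(5, 5),
      gbg_bound = c(0, 0), girk_open_shaft = c(0, 0),
      girk_open_spine = c(0, 0), girk_cum_shaft = c(0, 5),
      girk_cum_spine = c(0, 0)),
    total_receptors = 20, total_channels = 10, release_times = 0,
    dt = 0.01, t_end = 1, seed = 1, exclude_dendrite = TRUE,
    box = c(1, 1, 1)), class = "sim_result")
  sm <- summarize_signaling(fake)
  expect_equal(sm$effectiveness_shaft, 0.5)
  expect_true(is.na(sm$effectiveness_spine))

  # linearity bookkeeping
  mk <- function(op) { f <- fake; f$series$girk_cum_shaft <- c(0, op); f }
  dev <- girk_summation_linearity(list(mk(4), mk(8)))
  expect_equal(dev$deviation_total, 0)
  dev2 <- girk_summation_linearity(list(mk(4), mk(7.6)))
  expect_equal(dev2$deviation_total, -5, tolerance = 1e-9)
  dev0 <- girk_summation_linearity(list(mk(0), mk(3)))
  expect_true(is.na(dev0$deviation_total))
})
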