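dendrite_line <- function() {
  tibble::tibble(x = c(0, 20), y = 0, z = 0)
}

test_that("bouton counting near a dendrite is boundary-inclusive and exact", {
  b <- tibble::tibble(x = 5, y = 1, z = 0)  # exactly 1.0 um away
  cv <- count_boutons_near_dendrite(b, dendrite_line(),
                                    radii = c(0.9, 1.0, 1.5))
  expect_equal(cv$count, c(0, 1, 1))

  # random boutons against a dense point-sampling oracle
  set.seed(3)
  pts <- tibble::tibble(x = runif(20, -2, 22), y = runif(20, -3, 3),
                        z = runif(20, -3, 3))
  dend <- tibble::tibble(x = c(0, 10, 10), y = c(0, 0, 8), z = 0,
                         path = c(1, 1, 1))
  radii <- seq(0.5, 3, 0.5)
  cv2 <- count_boutons_near_dendrite(pts, dend, radii = radii)
  dense <- do.call(rbind, lapply(seq_len(nrow(dend) - 1), function(i) {
    f <- seq(0, 1, length.out = 2000)
    cbind(dend$x[i] + f * (dend$x[i + 1] - dend$x[i]),
          dend$y[i] + f * (dend$y[i + 1] - dend$y[i]),
          dend$z[i] + f * (dend$z[i + 1] - dend$z[i]))
  }))
  dmin <- vapply(seq_len(nrow(pts)), function(j)
    sqrt(min((dense[, 1] - pts$x[j])^2 + (dense[, 2] - pts$y[j])^2 +
               (dense[, 3] - pts$z[j])^2)), numeric(1))
  oracle <- vapply(radii, function(r) sum(dmin <= r + 1e-6), numeric(1))
  expect_equal(cv2$count, oracle)
  expect_true(all(diff(cv2$count) >= 0))
  expect_error(count_boutons_near_dendrite(pts, dend[1, , drop = FALSE]),
               class = "ngf_error_geometry")
})

test_that("range estimation inverts the count curve", {
  lin <- tibble::tibble(pair = 1, radius = seq(0.1, 3, 0.1),
                        count = 10 * seq(0.1, 3, 0.1))
  class(lin) <- c("bouton_count_curve", class(lin))
  r0 <- estimate_range(5, 0, lin)
  expect_equal(r0$range_lower, 0.5, tolerance = 1e-9)
  expect_equal(r0$range_upper, 0.5, tolerance = 1e-9)
  expect_false(r0$lower_flagged || r0$upper_flagged)

  # wider Nfrs SD gives a nested, wider interval
  r1 <- estimate_range(5, 1, lin)
  r2 <- estimate_range(5, 2, lin)
  expect_lt(r2$range_lower, r1$range_lower)
  expect_gt(r2$range_upper, r1$range_upper)

  # Nfrs below the curve minimum collapses to the smallest radius, flagged
  rlow <- estimate_range(0.5, 0, lin)
  expect_equal(rlow$range_lower, 0.1)
  expect_true(rlow$lower_flagged)
  # Nfrs above the maximum is flagged open-ended
  rhigh <- estimate_range(50, 0, lin)
  expect_true(rhigh$upper_flagged)
})

test_that("a generative pipeline recovers the known transmission radius", {
  # boutons exactly the functional sites within r* = 1.5 um
  set.seed(21)
  dend <- dendrite_line()
  r_star <- 1.5
  curves <- list(); nfrs <- integer()
  for (p in 1:4) {
    b <- tibble::tibble(x = runif(40, 0, 20),
                        y = runif(40, -3, 3), z = runif(40, -3, 3))
    cv <- count_boutons_near_dendrite(b, dend, radii = seq(0.25, 3, 0.25),
                                      pair = p)
    curves[[p]] <- cv
    nfrs[p] <- cv$count[cv$radius == r_star]
  }
  est <- estimate_range(nfrs, rep(0.5, 4), curves)
  expect_lte(est$range_lower, r_star)
  expect_gte(est$range_upper + 0.25, r_star)

  # correlation vs radius peaks where counts were read off
  cor_res <- correlation_vs_radius(tibble::tibble(pair = 1:4, nfrs = nfrs),
                                   curves)
  expect_gte(max(cor_res$r), 0.9)
})

test_that("correlation across radii: exact case and closed form", {
  mk <- function(pair, counts) {
    out <- tibble::tibble(pair = pair, radius = c(1, 2), count = counts)
    class(out) <- c("bouton_count_curve", class(out))
    out
  }
  # counts proportional to nfrs at radius 2 only
  curves <- list(mk(1, c(3, 2)), mk(2, c(3, 4)), mk(3, c(3, 6)))
  nf <- tibble::tibble(pair = 1:3, nfrs = c(1, 2, 3))
  expect_warning(res <- correlation_vs_radius(nf, curves),
                 "constant counts")
  expect_equal(res$radius, 2)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_equal(attr(res, "best_radius"), 2)

  # 3-pair hand-computable case
  curves2 <- list(mk(1, c(1, 5)), mk(2, c(4, 6)), mk(3, c(2, 10)))
  res2 <- correlation_vs_radius(nf, curves2)
  hand <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$r[res2$radius == 1], hand(c(1, 2, 3), c(1, 4, 2)))
  expect_equal(res2$r[res2$radius == 2], hand(c(1, 2, 3), c(5, 6, 10)))
  expect_error(correlation_vs_radius(nf[1:2, ], curves2),
               class = "ngf_error_stats")
})
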