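test_that("binning arithmetic: residence time, strata, zero-count bins", {
  # 10 s at one spot, 0.168 m3/s -> 1.68 m3
  track <- data.frame(time_s = 0:10, depth_m = 10.5, along_track_m = 100)
  vig <- data.frame(group = c("cope", "cope"), depth_m = c(10.2, 10.8),
                    along_track_m = c(100, 120))
  # depths 10.2 and 10.8 fall in the same [10, 11) stratum
  bins <- bin_vignettes(vig, track, volume_rate_m3_per_s = 0.168)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$imaged_volume_m3, 11 * 1 * 0.168)  # 11 samples x 1 s
  expect_equal(bins$count_cope, 2)
  expect_equal(bins$depth_m, 10)

  # zero vignettes: bins still exist with positive volume
  none <- vig[0, ]
  bins0 <- bin_vignettes(none, track)
  expect_equal(nrow(bins0), 1)
  expect_gt(bins0$imaged_volume_m3, 0)
})

test_that("out-of-range vignettes are rejected with a message", {
  track <- data.frame(time_s = 0:5, depth_m = 10, along_track_m = 0)
  vig <- data.frame(group = "x", depth_m = c(5, 500), along_track_m = 0)
  expect_message(bins <- bin_vignettes(vig, track, depth_max_m = 80),
                 "rejected")
})

test_that("sensor streams are averaged per bin", {
  track <- data.frame(time_s = 0:3, depth_m = c(5, 5, 6, 6),
                      along_track_m = 10, temperature = c(20, 22, 10, 12))
  bins <- bin_vignettes(data.frame(group = "x", depth_m = 5,
                                   along_track_m = 10)[0, ], track)
  expect_equal(bins$temperature[bins$depth_m == 5], 21)
  expect_equal(bins$temperature[bins$depth_m == 6], 11)
})

test_that("concentration arithmetic applies the correction factor and scales with volume", {
  bins <- data.frame(along_m = 250, depth_m = 10, imaged_volume_m3 = 2,
                     count_fish = 10, count_cope = 0)
  cf <- data.frame(group = c("fish", "cope"), correction_factor = c(2.14, 1))
  out <- to_concentration(bins, cf)
  expect_equal(out$conc_fish, 10 / 2 * 2.14)  # 10.7 ind/m3
  expect_equal(out$conc_cope, 0)

  bins2 <- bins; bins2$imaged_volume_m3 <- 4
  out2 <- to_concentration(bins2, cf)
  expect_equal(out2$conc_fish, out$conc_fish / 2)
})

test_that("uncorrectable groups pass through unchanged and are flagged", {
  bins <- data.frame(along_m = 250, depth_m = 10, imaged_volume_m3 = 2,
                     count_fish = 10)
  cf <- data.frame(group = "fish", correction_factor = NA_real_)
  out <- to_concentration(bins, cf)
  expect_equal(out$conc_fish, 5)
  expect_equal(attr(out, "uncorrected_groups"), "fish")
})

test_that("variogram fitting recognises nugget, smooth and constant regimes", {
  set.seed(5)
  n <- 300
  loc <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  # pure nugget: iid noise
  vm <- fit_variogram(loc, rnorm(n), family = "spherical")
  expect_true(vm$flag %in% c("weak_structure", "ok"))
  expect_gt(vm$nugget / vm$sill, 0.5)
  # smooth field sampled densely: tiny nugget
  vals <- sin(loc[, 1] / 8) + cos(loc[, 2] / 8)
  vm2 <- fit_variogram(loc, vals, family = "gaussian")
  expect_lt(vm2$nugget / vm2$sill, 0.1)
  # constant: zero sill, flagged
  vm3 <- fit_variogram(loc, rep(3, n))
  expect_equal(vm3$sill, 0)
  expect_equal(vm3$flag, "constant")
})

test_that("ordinary kriging is exact at data with zero nugget and weights sum to one", {
  set.seed(11)
  n <- 40
  loc <- cbind(runif(n, 0, 5000), runif(n, 0, 40))
  vals <- sin(loc[, 1] / 1000) + loc[, 2] / 40 + rnorm(n, 0, 0.01)
  vm <- structure(list(family = "spherical", nugget = 0, sill = 1,
                       range = 3, flag = "ok"), class = "variogram_model")
  # predict exactly at the first datum
  gf <- krige_field(loc, vals, vm, along_grid = loc[1, 1],
                    depth_grid = loc[1, 2], return_weights = TRUE)
  expect_equal(gf$values[1, 1], vals[1], tolerance = 1e-8)
  expect_equal(rowSums(gf$weights), 1, tolerance = 1e-8)

  # full grid: all weight rows sum to 1
  gf2 <- krige_field(loc, vals, vm, return_weights = TRUE)
  expect_true(max(abs(rowSums(gf2$weights) - 1)) < 1e-8)
})

test_that("two-point 1-D kriging matches the hand-solved system", {
  vm <- structure(list(family = "exponential", nugget = 0, sill = 1,
                       range = 1, flag = "ok"), class = "variogram_model")
  gf <- krige_field(cbind(c(0, 1), c(0, 0)), c(10, 20), vm,
                    along_grid = 0.5, depth_grid = 0,
                    along_res = 1, depth_res = 1, return_weights = TRUE)
  # oracle: solve the 2x2 ordinary-kriging system directly
  gam <- function(h) 1 - exp(-h)
  Kmat <- rbind(cbind(1 - gam(abs(outer(c(0, 1), c(0, 1), `-`))), 1),
                c(1, 1, 0))
  sol <- solve(Kmat, c(1 - gam(0.5), 1 - gam(0.5), 1))
  oracle <- sum(sol[1:2] * c(10, 20))
  expect_equal(gf$values[1, 1], oracle, tolerance = 1e-8)
  expect_gt(gf$values[1, 1], 10); expect_lt(gf$values[1, 1], 20)
})

test_that("constant data krige to a constant surface", {
  set.seed(3)
  loc <- cbind(runif(40, 0, 2000), runif(40, 0, 30))
  vm <- structure(list(family = "spherical", nugget = 0.1, sill = 1,
                       range = 2, flag = "ok"), class = "variogram_model")
  gf <- krige_field(loc, rep(7, 40), vm)
  expect_equal(as.numeric(gf$values), rep(7, length(gf$values)),
               tolerance = 1e-8)
})

test_that("kriged grid is invariant to input order and clips negatives when asked", {
  set.seed(9)
  n <- 60
  loc <- cbind(runif(n, 0, 5000), runif(n, 0, 40))
  vals <- rnorm(n, 0, 1)
  vm <- structure(list(family = "spherical", nugget = 0.05, sill = 1,
                       range = 3, flag = "ok"), class = "variogram_model")
  g1 <- krige_field(loc, vals, vm)
  ord <- sample(n)
  g2 <- krige_field(loc[ord, ], vals[ord], vm)
  expect_equal(g1$values, g2$values, tolerance = 1e-6)

  gc <- krige_field(loc, vals, vm, clip_negative = TRUE)
  expect_true(all(gc$values >= 0))
  expect_equal(sum(g1$values < 0), attr(gc, "n_clipped"))
})

test_that("end-to-end: tow -> bins -> corrected concentrations track the scenario truth", {
  sc <- gen_transect(transect_spec(length_km = 10, eddy_center_km = 4,
                                   eddy_radius_km = 2,
                                   interface_width_km = 1.5, seed = 29))
  taxa <- names(sc$taxa)
  # moderate group-level confusion, diagonal 0.85
  K <- length(taxa)
  conf <- matrix(0.15 / (K - 1), K, K); diag(conf) <- 0.85
  dimnames(conf) <- list(taxa, taxa)
  tow <- sample_tow(sc, group_confusion = conf, seed = 4)
  # correction factors measured on an independent draw from the same tow law
  cal <- sample_tow(sc, group_confusion = conf, seed = 5)
  gm <- group_metrics(cal$vignettes$group, cal$vignettes$pred_group)
  cf <- correction_factors(gm$metrics)
  vig <- data.frame(group = tow$vignettes$pred_group,
                    depth_m = tow$vignettes$depth_m,
                    along_track_m = tow$vignettes$along_track_m)
  bins <- bin_vignettes(vig, tow$track)
  conc <- to_concentration(bins, cf)
  # compare binned corrected concentration against the true field (log1p)
  ix <- pmin(pmax(findInterval(conc$along_m, c(0, sc$along_m + 250)), 1),
             length(sc$along_m))
  iz <- pmin(pmax(findInterval(conc$depth_m + 0.5, c(0, sc$depth_m + 0.5)), 1),
             length(sc$depth_m))
  truth <- sc$taxa$oithona[cbind(ix, iz)]
  keep <- conc$imaged_volume_m3 > 1      # bins with enough imaged water
  r <- cor(log1p(conc$conc_oithona[keep]), log1p(truth[keep]))
  expect_gt(r, 0.9)
})
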