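test_that("frame generator bookkeeping: empty case, truth count, determinism", {
  empty <- gen_frames(scene_spec(n_frames = 5, blob_count_per_frame = 0,
                                 seed = 2))
  expect_equal(nrow(empty$truth), 0)
  expect_length(empty$frames, 5)

  out <- fixture_scene(seed = 3, n_frames = 10)
  # every planted blob is recorded, boxes lie fully inside the frame
  expect_true(all(out$truth$row0 >= 0 & out$truth$col0 >= 0))
  expect_true(all(out$truth$row1 <= 160 & out$truth$col1 <= 240))
  for (f in out$frames) {
    expect_true(all(f$pixels >= 0 & f$pixels <= 1))
  }
  again <- fixture_scene(seed = 3, n_frames = 10)
  expect_identical(out$frames[[4]]$pixels, again$frames[[4]]$pixels)
  expect_identical(out$truth, again$truth)
})

test_that("oversized blobs are rejected at spec time", {
  expect_error(scene_spec(frame_height_px = 20, frame_width_px = 20,
                          blob_classes = data.frame(class = "x",
                                                    axis_a_px = 30,
                                                    axis_b_px = 5,
                                                    contrast = 0.5)),
               "larger than frame")
})

test_that("frame PNG round trip preserves pixels and metadata", {
  out <- fixture_scene(seed = 5, n_frames = 2)
  dir <- withr::local_tempdir()
  write_frames_png(out$frames, dir)
  back <- read_frames_png(dir)
  expect_equal(back[[1]]$depth_m, out$frames[[1]]$depth_m)
  # 8-bit quantisation
  expect_lt(max(abs(back[[2]]$pixels - out$frames[[2]]$pixels)), 1 / 255)
})

test_that("identity confusion gives a perfect classifier", {
  cmap <- fixture_class_map()
  K <- nrow(cmap)
  conf <- diag(K)
  dimnames(conf) <- list(cmap$fine, cmap$fine)
  sp <- confusion_spec(conf, cmap,
                       stats::setNames(rep(500, K), cmap$fine), seed = 4)
  v <- gen_classified_vignettes(sp)
  expect_identical(v$pred_fine, v$true_fine)
  gm <- group_metrics(map_to_groups(v$true_fine, cmap),
                      map_to_groups(v$pred_fine, cmap))
  expect_true(all(gm$metrics$precision == 1))
  expect_true(all(gm$metrics$recall == 1))
})

test_that("empirical group precision/recall matches the closed form from the confusion matrix", {
  # 2-class analogue of the spec example: off-diagonal leakage 0.2
  cmap <- data.frame(fine = c("A", "B"), group = c("gA", "gB"))
  conf <- matrix(c(0.8, 0.2, 0, 1), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  ab <- c(A = 25000, B = 25000)
  sp <- confusion_spec(conf, cmap, ab, seed = 11)
  v <- gen_classified_vignettes(sp)  # n = 50,000
  gm <- group_metrics(map_to_groups(v$true_fine, cmap),
                      map_to_groups(v$pred_fine, cmap))
  want <- expected_group_pr(conf, cmap, ab)
  expect_equal(gm$metrics$precision[gm$metrics$group == "gA"],
               unname(want["gA", "precision"]), tolerance = 0.02)
  expect_equal(gm$metrics$recall[gm$metrics$group == "gA"],
               unname(want["gA", "recall"]), tolerance = 0.02)
  expect_equal(gm$metrics$precision[gm$metrics$group == "gB"],
               unname(want["gB", "precision"]), tolerance = 0.02)
})

test_that("empirical confusion converges to the specified matrix (max-norm 0.02 at n = 50k)", {
  sp <- fixture_confusion_spec(n_per_class = 10000, seed = 21)
  v <- gen_classified_vignettes(sp)
  emp <- table(v$true_fine, v$pred_fine)
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - sp$confusion[rownames(emp), colnames(emp)])), 0.02)
})

test_that("a class with zero abundance appears only through confusion from other rows", {
  cmap <- fixture_class_map()
  K <- nrow(cmap)
  conf <- matrix(0.05, K, K); diag(conf) <- 0.8
  conf <- conf / rowSums(conf)
  dimnames(conf) <- list(cmap$fine, cmap$fine)
  ab <- stats::setNames(c(0, rep(1000, K - 1)), cmap$fine)
  sp <- confusion_spec(conf, cmap, ab, seed = 6)
  v <- gen_classified_vignettes(sp)
  expect_false("a1" %in% v$true_fine)
  expect_true("a1" %in% v$pred_fine)   # leakage from other true classes
})

test_that("probability vectors are simplex rows with argmax at the prediction", {
  sp <- fixture_confusion_spec(n_per_class = 200, seed = 9)
  v <- gen_classified_vignettes(sp, return_probs = TRUE)
  P <- attr(v, "probs")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_identical(colnames(P)[apply(P, 1, which.max)], v$pred_fine)
  expect_equal(apply(P, 1, max), v$max_prob, tolerance = 1e-12)
})

test_that("confidence distributions with invalid shapes are rejected", {
  expect_error(fixture_confusion_spec(conf_correct = c(-1, 2)), "Beta shapes")
  expect_error(fixture_confusion_spec(conf_incorrect = c(2, Inf)), "Beta shapes")
})

test_that("transect generator: determinism, finite velocities, labels and positivity", {
  sc1 <- gen_transect(transect_spec(seed = 13))
  sc2 <- gen_transect(transect_spec(seed = 13))
  expect_identical(sc1$u, sc2$u)
  expect_identical(sc1$taxa$oithona, sc2$taxa$oithona)
  expect_true(all(is.finite(sc1$u)) && all(is.finite(sc1$v)))
  expect_true(all(sc1$labels %in% c("FC", "IF", "ED")))
  expect_true(all(vapply(sc1$taxa, function(m) all(m >= 0), logical(1))))
})

test_that("speed field separates FC from ED when the current outruns the eddy rim", {
  sc <- gen_transect(transect_spec(seed = 5))
  expect_gt(max(sc$speed[sc$labels == "FC"]), max(sc$speed[sc$labels == "ED"]))
})

test_that("degenerate contrast (rim speed = current speed) still emits labels", {
  sc <- gen_transect(transect_spec(fc_speed = 0.3, tangential_speed = 0.3,
                                   seed = 8))
  expect_setequal(unique(as.vector(sc$labels)), c("FC", "IF", "ED"))
})

test_that("invalid transect specs are rejected", {
  expect_error(transect_spec(fc_speed = -1), "non-negative")
  expect_error(transect_spec(eddy_radius_km = -2), "positive")
  expect_error(transect_spec(eddy_center_km = 3, eddy_radius_km = 8), "fit")
})

test_that("zero prey coupling decouples larvae from prey given the physics", {
  # regress log larvae on the physical drivers; the prey residual term
  # should then add nothing (coefficient ~ 0)
  sc <- gen_transect(transect_spec(
    taxa = default_taxa_response(prey_coupling = 0), seed = 19))
  d <- data.frame(lf = log(as.numeric(sc$taxa$larval_fish)),
                  prey = log1p(as.numeric(sc$taxa$oithona)),
                  speed = as.numeric(sc$speed),
                  dist = as.numeric(sc$dist_to_fc_km),
                  wm = as.vector(sc$labels))
  fit <- lm(lf ~ wm + speed + dist + prey, data = d)
  expect_lt(abs(coef(fit)[["prey"]]), 0.05)
  # and with coupling on, the same coefficient recovers its true value
  sc2 <- gen_transect(transect_spec(
    taxa = default_taxa_response(prey_coupling = 0.5), seed = 19))
  d2 <- d
  d2$lf <- log(as.numeric(sc2$taxa$larval_fish))
  d2$prey <- log1p(as.numeric(sc2$taxa$oithona))
  fit2 <- lm(lf ~ wm + speed + dist + prey, data = d2)
  expect_equal(coef(fit2)[["prey"]], 0.5, tolerance = 0.1)
})

test_that("tow sampler covers the transect and yields Poisson-consistent counts", {
  sc <- gen_transect(transect_spec(length_km = 10, eddy_center_km = 4,
                                   eddy_radius_km = 2,
                                   interface_width_km = 1.5, seed = 23))
  tow <- sample_tow(sc, seed = 2)
  expect_true(all(tow$track$depth_m >= 3 - 1e-9))
  expect_true(max(tow$track$along_track_m) <= 10000)
  expect_gt(nrow(tow$vignettes), 0)
  # heavily sampled taxon should out-count a rare one
  expect_gt(sum(tow$vignettes$group == "detritus"),
            sum(tow$vignettes$group == "larval_fish"))
})
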