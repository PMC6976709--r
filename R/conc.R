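#' Bin classified vignettes into 1-m depth strata
#'
#' Joins vignettes to the tow track, accumulates per-group counts in
#' (along-track cell) x (1-m depth stratum) bins, computes the imaged
#' volume of each bin as `volume_rate x residence time` of the tow in that
#' bin, and averages the sensor streams per bin. Strata are half-open
#' `[d, d+1)` metres; along-track cells are `[k*w, (k+1)*w)` with centres
#' at `w/2 + k*w`.
#'
#' Bins the tow visited but where nothing was detected are retained with
#' zero counts and positive volume — absence is data. Vignettes with depth
#' outside `[0, depth_max]` are rejected with a message.
#'
#' @param vignettes data.frame with `group` (broad group or taxon label),
#'   `depth_m`, `along_track_m`.
#' @param track tow track data.frame with `time_s`, `depth_m`,
#'   `along_track_m` and optional sensor columns (averaged per bin).
#' @param volume_rate_m3_per_s imaged volume rate; the default 0.168 m3/s
#'   sits inside the 150-185 L/s envelope of towed shadowgraph imagers.
#' @param along_bin_m along-track bin width, metres.
#' @param stratum_m depth stratum height, metres.
#' @param depth_max_m maximum valid depth for vignettes.
#' @return data.frame of class `depth_bins`: `along_m` (cell centre),
#'   `depth_m` (stratum lower edge), `imaged_volume_m3`, one mean column
#'   per sensor, and one `count_<group>` column per group.
#' @export
bin_vignettes <- function(vignettes, track, volume_rate_m3_per_s = 0.168,
                          along_bin_m = 500, stratum_m = 1,
                          depth_max_m = NULL) {
  stopifnot(all(c("group", "depth_m", "along_track_m") %in% names(vignettes)),
            all(c("time_s", "depth_m", "along_track_m") %in% names(track)),
            volume_rate_m3_per_s > 0)
  if (is.unsorted(track$time_s))
    stop("track time must be monotone within a tow")
  if (is.null(depth_max_m)) depth_max_m <- max(track$depth_m) + stratum_m
  bad <- vignettes$depth_m < 0 | vignettes$depth_m > depth_max_m
  if (any(bad)) {
    message(sum(bad), " vignette(s) with depth outside [0, ", depth_max_m,
            "] m rejected")
    vignettes <- vignettes[!bad, , drop = FALSE]
  }
  bin_key <- function(along, depth) {
    paste(floor(along / along_bin_m), floor(depth / stratum_m), sep = "_")
  }
  # residence time: each track sample owns the interval to the next sample
  dt <- diff(track$time_s)
  dt <- c(dt, if (length(dt)) stats::median(dt) else 1)
  tkey <- bin_key(track$along_track_m, track$depth_m)
  vol <- tapply(dt * volume_rate_m3_per_s, tkey, sum)
  bins <- data.frame(key = names(vol), imaged_volume_m3 = as.numeric(vol))
  parts <- strsplit(bins$key, "_", fixed = TRUE)
  bins$along_m <- (as.numeric(vapply(parts, `[`, "", 1)) + 0.5) * along_bin_m
  bins$depth_m <- as.numeric(vapply(parts, `[`, "", 2)) * stratum_m
  # sensor means
  sensors <- setdiff(names(track), c("time_s", "depth_m", "along_track_m"))
  for (s in sensors)
    bins[[s]] <- as.numeric(tapply(track[[s]], tkey, mean)[bins$key])
  # per-group counts; vignettes outside any visited bin are dropped with note
  vkey <- bin_key(vignettes$along_track_m, vignettes$depth_m)
  orphan <- !(vkey %in% bins$key)
  if (any(orphan))
    message(sum(orphan), " vignette(s) fall in bins the track never visited; dropped")
  groups <- sort(unique(vignettes$group))
  count_cols <- if (length(groups)) paste0("count_", groups) else character(0)
  for (g in groups) {
    cnt <- table(vkey[!orphan & vignettes$group == g])
    col <- numeric(nrow(bins))
    col[match(names(cnt), bins$key)] <- as.numeric(cnt)
    bins[[paste0("count_", g)]] <- col
  }
  bins <- bins[order(bins$along_m, bins$depth_m),
               c("along_m", "depth_m", "imaged_volume_m3", sensors,
                 count_cols)]
  rownames(bins) <- NULL
  class(bins) <- c("depth_bins", "data.frame")
  bins
}

#' Convert binned counts to corrected concentrations
#'
#' `concentration = count / imaged_volume x CF(group)`, in individuals per
#' cubic metre. Groups without a usable correction factor (recall zero or
#' unknown) pass through uncorrected and are flagged.
#'
#' @param bins a [bin_vignettes()] table.
#' @param correction_factors data.frame `group`, `correction_factor` (as
#'   from [correction_factors()]); groups absent from the table get CF 1.
#' @return the bins table with one `conc_<group>` column per group and an
#'   attribute `"uncorrected_groups"` listing pass-through groups.
#' @export
to_concentration <- function(bins, correction_factors = NULL) {
  count_cols <- grep("^count_", names(bins), value = TRUE)
  groups <- sub("^count_", "", count_cols)
  if (any(bins$imaged_volume_m3 <= 0 &
          rowSums(bins[, count_cols, drop = FALSE]) > 0))
    stop("bin with zero imaged volume but nonzero count")
  uncorrected <- character(0)
  for (g in groups) {
    cf <- 1
    if (!is.null(correction_factors)) {
      i <- match(g, correction_factors$group)
      if (!is.na(i) && !is.na(correction_factors$correction_factor[i])) {
        cf <- correction_factors$correction_factor[i]
      } else {
        uncorrected <- c(uncorrected, g)
      }
    }
    bins[[paste0("conc_", g)]] <-
      bins[[paste0("count_", g)]] / bins$imaged_volume_m3 * cf
  }
  attr(bins, "uncorrected_groups") <- uncorrected
  bins
}

variogram_value <- function(h, model) {
  psill <- model$sill - model$nugget
  g <- switch(model$family,
    spherical = ifelse(h >= model$range, psill,
                       psill * (1.5 * h / model$range -
                                  0.5 * (h / model$range)^3)),
    exponential = psill * (1 - exp(-h / model$range)),
    gaussian = psill * (1 - exp(-(h / model$range)^2)),
    stop("unknown variogram family: ", model$family))
  ifelse(h == 0, 0, model$nugget + g)
}

#' Fit a variogram model to scattered transect data
#'
#' Computes the empirical semivariogram over `n_lags` equal-width lag bins
#' (up to half the maximum pairwise distance) and fits a
#' spherical/exponential/gaussian model by weighted least squares with
#' Cressie weights `N(h) / gamma_model(h)^2`.
#'
#' Coordinates must be pre-scaled so one isotropic model is appropriate;
#' for transect grids scale along-track by the target horizontal
#' resolution and depth by the vertical one (see [krige_field()]).
#'
#' @param locations two-column matrix/data.frame of (scaled) coordinates.
#' @param values numeric vector of observations.
#' @param family `"spherical"` (default), `"exponential"` or `"gaussian"`.
#' @param n_lags number of lag bins.
#' @param max_pairs cap on the number of point pairs used (subsampled
#'   deterministically given the RNG state) to bound memory.
#' @return list of class `variogram_model`: `family`, `nugget`, `sill`,
#'   `range`, `empirical` (lag table), `flag` (`"ok"`, `"constant"` for a
#'   constant field, or `"weak_structure"` when the structured part of the
#'   sill is small against the nugget).
#' @export
fit_variogram <- function(locations, values, family = "spherical",
                          n_lags = 15, max_pairs = 2e6) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2, nrow(locations) == length(values),
            nrow(locations) >= 30)
  if (stats::var(values) == 0) {
    return(structure(list(family = family, nugget = 0, sill = 0,
                          range = 1, empirical = NULL, flag = "constant"),
                     class = "variogram_model"))
  }
  n <- nrow(locations)
  if (n * (n - 1) / 2 > max_pairs) {
    keep <- sample.int(n, floor(sqrt(2 * max_pairs)))
    locations <- locations[keep, , drop = FALSE]
    values <- values[keep]
    n <- length(keep)
  }
  dmat <- as.matrix(stats::dist(locations))
  gsq <- 0.5 * outer(values, values, `-`)^2
  ut <- upper.tri(dmat)
  h <- dmat[ut]; g <- gsq[ut]
  hmax <- max(h) / 2
  brk <- seq(0, hmax, length.out = n_lags + 1)
  lag <- cut(h, brk, include.lowest = TRUE)
  emp <- data.frame(h = tapply(h, lag, mean),
                    gamma = tapply(g, lag, mean),
                    n = as.numeric(table(lag)))
  emp <- emp[emp$n > 0 & !is.na(emp$gamma), ]
  s0 <- stats::var(values)
  r0 <- max(emp$h) / 2
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], sill = par[1] + par[2],
              range = par[3])
    gm <- variogram_value(emp$h, m)
    sum(emp$n * (emp$gamma - gm)^2 / pmax(gm, 1e-10)^2)
  }
  fit <- stats::optim(c(0.1 * s0, 0.9 * s0, r0), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10 * s0, 1e-6),
                      upper = c(2 * s0, 4 * s0, 4 * max(emp$h)))
  nugget <- fit$par[1]; sill <- fit$par[1] + fit$par[2]; rng <- fit$par[3]
  flag <- if (fit$par[2] < 0.05 * sill || rng < min(emp$h))
    "weak_structure" else "ok"
  structure(list(family = family, nugget = nugget, sill = sill, range = rng,
                 empirical = emp, flag = flag),
            class = "variogram_model")
}

#' Ordinary kriging of binned data onto a regular transect grid
#'
#' Solves the ordinary-kriging system (covariance form with the
#' unbiasedness constraint via a Lagrange multiplier) once for all grid
#' nodes. Weights sum to 1 at every node; with zero nugget the predictor
#' is exact at the data points. Coordinates are scaled by the target
#' resolutions (`along/along_res`, `depth/depth_res`) before distances are
#' taken, so the single isotropic variogram acts on scaled space — this is
#' the anisotropy model for strongly flattened transect geometry.
#'
#' @param locations two-column matrix/data.frame of data coordinates
#'   (along_m, depth_m), unscaled.
#' @param values observations at `locations`.
#' @param variogram a [fit_variogram()] model (fitted on scaled
#'   coordinates).
#' @param along_grid,depth_grid grid node coordinates (m). Defaults: cell
#'   centres `along_res/2 + k*along_res` spanning the data, and 1-m
#'   stratum centres.
#' @param along_res,depth_res target resolutions used for coordinate
#'   scaling (m); defaults 500 and 1.
#' @param clip_negative clip negative predictions to zero (concentrations);
#'   the number clipped is reported via attribute `"n_clipped"`.
#' @param return_weights also return the full weight matrix (nodes x data);
#'   only sensible for small problems.
#' @param dedup_tol duplicate locations (within this scaled distance) are
#'   averaged before solving.
#' @return list of class `gridded_field`: `along_m`, `depth_m`, `values`
#'   (matrix, rows = along-track), `units`, and optionally `weights`.
#' @export
krige_field <- function(locations, values, variogram,
                        along_grid = NULL, depth_grid = NULL,
                        along_res = 500, depth_res = 1,
                        clip_negative = FALSE, return_weights = FALSE,
                        units = "", dedup_tol = 1e-8) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2, nrow(locations) == length(values),
            inherits(variogram, "variogram_model"))
  if (variogram$sill < variogram$nugget || variogram$range <= 0)
    stop("invalid variogram: need sill >= nugget > -Inf and range > 0")
  sc <- cbind(locations[, 1] / along_res, locations[, 2] / depth_res)
  # average duplicates (kriging systems are singular with repeated points)
  key <- paste(round(sc[, 1] / dedup_tol), round(sc[, 2] / dedup_tol))
  if (anyDuplicated(key)) {
    values <- as.numeric(tapply(values, key, mean))
    sc <- cbind(as.numeric(tapply(sc[, 1], key, mean)),
                as.numeric(tapply(sc[, 2], key, mean)))
  }
  n <- nrow(sc)
  if (is.null(along_grid))
    along_grid <- seq(along_res / 2, max(locations[, 1]), by = along_res)
  if (is.null(depth_grid))
    depth_grid <- seq(depth_res / 2, max(locations[, 2]), by = depth_res)
  cov_of <- function(h) {
    # C(h) = sill - gamma(h); full sill (incl. nugget) returned at h = 0
    variogram$sill - variogram_value(h, variogram)
  }
  K <- matrix(0, n + 1, n + 1)
  K[1:n, 1:n] <- cov_of(as.matrix(stats::dist(sc)))
  K[n + 1, 1:n] <- 1; K[1:n, n + 1] <- 1
  grid <- as.matrix(expand.grid(along = along_grid, depth = depth_grid))
  gsc <- cbind(grid[, 1] / along_res, grid[, 2] / depth_res)
  m <- nrow(gsc)
  dd <- sqrt(outer(gsc[, 1], sc[, 1], `-`)^2 +
               outer(gsc[, 2], sc[, 2], `-`)^2)
  rhs <- rbind(t(cov_of(dd)), rep(1, m))
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    # singular system: jitter the diagonal once, then give up
    K2 <- K
    diag(K2)[1:n] <- diag(K2)[1:n] + 1e-8 * max(variogram$sill, 1)
    tryCatch(solve(K2, rhs),
             error = function(e2) stop("kriging system singular even after jitter"))
  })
  w <- sol[1:n, , drop = FALSE]
  pred <- as.numeric(crossprod(w, values))
  n_clipped <- 0L
  if (clip_negative) {
    n_clipped <- sum(pred < 0)
    pred[pred < 0] <- 0
  }
  out <- structure(list(along_m = along_grid, depth_m = depth_grid,
                        values = matrix(pred, length(along_grid),
                                        length(depth_grid)),
                        units = units),
                   class = "gridded_field")
  attr(out, "n_clipped") <- n_clipped
  if (return_weights) {
    out$weights <- t(w)
    dimnames(out$weights) <- NULL
  }
  out
}

#' Write a gridded field as a CSV matrix
#'
#' Long format: `along_m`, `depth_m`, `value`.
#'
#' @param field a `gridded_field`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gridded_csv <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  df <- expand.grid(along_m = field$along_m, depth_m = field$depth_m)
  df$value <- as.numeric(field$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
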