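#' Default taxa response table for the eddy transect scenario
#'
#' Responses are additive on log-concentration: for taxon t in cell c,
#' `log E[conc] = intercept + b_<watermass(c)> + b_speed * speed(c) +
#' b_dist * dist_to_fc_km(c) + prey_coef * log1p(conc_prey(c))`, with
#' multiplicative lognormal noise on top. Additivity on the log scale gives
#' the downstream random-forest / ALE analyses known target shapes.
#'
#' The defaults sketch the biology of a decaying cyclonic eddy in a western
#' boundary current: a small cyclopoid copepod (`oithona`) accumulating in
#' eddy and interface water at slow current speeds, larval fish tracking it
#' through a prey-coupling term, passively advected detritus and diatoms,
#' and taxa indifferent to the eddy.
#'
#' @param prey_coupling coefficient linking `larval_fish` to `oithona`
#'   (0 = larvae respond to physics only).
#' @param n_null_taxa number of extra taxa with no environmental response
#'   (pure lognormal noise), useful as null predictors.
#' @return data.frame with columns `taxon`, `intercept`, `b_fc`, `b_if`,
#'   `b_ed`, `b_speed`, `b_dist`, `prey`, `prey_coef`.
#' @export
default_taxa_response <- function(prey_coupling = 0.5, n_null_taxa = 4) {
  base <- data.frame(
    taxon     = c("oithona", "larval_fish", "detritus", "diatoms",
                  "chaetognaths", "appendicularians"),
    intercept = c(log(5), log(0.3), log(40), log(15), log(3), log(8)),
    b_fc      = c(-1.2, -0.8, -0.8, -0.5, 0, 0),
    b_if      = c(0.6, 0.3, 0.5, 0.4, 0, 0.2),
    b_ed      = c(1.0, 0.6, 0.3, 0.2, 0.2, 0),
    b_speed   = c(-2.0, -1.5, -1.0, -0.8, 0, -0.3),
    b_dist    = c(0.04, 0.02, 0.02, 0.01, 0, 0),
    prey      = c(NA, "oithona", NA, NA, NA, NA),
    prey_coef = c(0, prey_coupling, 0, 0, 0, 0))
  if (n_null_taxa > 0) {
    null <- data.frame(taxon = paste0("taxon_null_", seq_len(n_null_taxa)),
                       intercept = log(2), b_fc = 0, b_if = 0, b_ed = 0,
                       b_speed = 0, b_dist = 0, prey = NA, prey_coef = 0)
    base <- rbind(base, null)
  }
  base
}

#' Transect specification: an eddy embedded in a boundary current
#'
#' Describes a 2-D transect section (along-track x depth) crossing a
#' cyclonic mesoscale eddy embedded in a fast boundary current. Three water
#' masses are defined by horizontal distance `d` from the eddy centre:
#' eddy water (ED, `d <= radius`), interface water (IF, the band of width
#' `interface_width_km` around the eddy), and boundary-current water (FC,
#' beyond). The velocity field is solid-body rotation inside the eddy
#' (tangential speed growing linearly to `tangential_speed` at the rim), a
#' uniform northward boundary current outside, and an intermediate interface
#' regime, blended smoothly over a fraction of the interface band. Water
#' masses are taken as vertically coherent over the imaged depth range.
#'
#' @param length_km,depth_m section extent.
#' @param dx_m,dz_m grid resolution (along-track, depth), metres.
#' @param fc_speed boundary-current speed, m/s.
#' @param eddy_center_km,eddy_center_depth_m eddy centre position.
#' @param eddy_radius_km eddy (ED water) radius.
#' @param tangential_speed eddy rim speed, m/s.
#' @param interface_width_km width of the IF band on each side of the eddy.
#' @param sensor_noise_sd named vector of additive noise sds for
#'   `temperature` (deg C), `salinity` (PSU), `sigma_t` (kg/m3),
#'   `chl` (mg/m3), `oxygen` (ml/l), `speed` (m/s).
#' @param taxa data.frame of taxa response functions
#'   (see [default_taxa_response()]).
#' @param lognormal_sd sd of the lognormal concentration noise (log scale).
#' @param seed integer seed.
#' @return An object of class `transect_spec`.
#' @export
transect_spec <- function(length_km = 40, depth_m = 80, dx_m = 500, dz_m = 1,
                          fc_speed = 0.8, eddy_center_km = 14,
                          eddy_center_depth_m = 40, eddy_radius_km = 8,
                          tangential_speed = 0.25, interface_width_km = 4,
                          sensor_noise_sd = c(temperature = 0.05,
                                              salinity = 0.01, sigma_t = 0.02,
                                              chl = 0.02, oxygen = 0.05,
                                              speed = 0.02),
                          taxa = default_taxa_response(),
                          lognormal_sd = 0.3, seed = 1L) {
  if (fc_speed < 0 || tangential_speed < 0)
    stop("speeds must be non-negative")
  if (eddy_radius_km <= 0) stop("eddy radius must be positive")
  if (eddy_center_km - eddy_radius_km < 0 ||
      eddy_center_km + eddy_radius_km > length_km)
    stop("eddy must fit within the transect bounds")
  stopifnot(length_km > 0, depth_m > 0, dx_m > 0, dz_m > 0,
            interface_width_km >= 0, lognormal_sd >= 0)
  # prey taxa must be defined before the taxa that consume them
  if (any(!is.na(taxa$prey))) {
    pos <- match(taxa$prey, taxa$taxon)
    bad <- which(!is.na(taxa$prey) & (is.na(pos) | pos >= seq_len(nrow(taxa))))
    if (length(bad))
      stop("prey taxa must appear earlier in the taxa table: ",
           paste(taxa$taxon[bad], collapse = ", "))
  }
  structure(list(length_km = length_km, depth_m = depth_m, dx_m = dx_m,
                 dz_m = dz_m, fc_speed = fc_speed,
                 eddy_center_km = eddy_center_km,
                 eddy_center_depth_m = eddy_center_depth_m,
                 eddy_radius_km = eddy_radius_km,
                 tangential_speed = tangential_speed,
                 interface_width_km = interface_width_km,
                 sensor_noise_sd = sensor_noise_sd, taxa = taxa,
                 lognormal_sd = lognormal_sd, seed = as.integer(seed)),
            class = "transect_spec")
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate an eddy transect scenario with known ground truth
#'
#' Realises a [transect_spec()] on a regular grid (cell centres at
#' `dx/2 + k*dx` along-track and `dz/2 + k*dz` in depth). Returns velocity
#' components, current speed, true water-mass labels, density /
#' temperature / salinity fields with an isopycnal-shoaling signature at the
#' eddy interface, chlorophyll and oxygen, and per-taxon concentration
#' fields produced by the taxa response functions plus lognormal noise.
#' Matrices are oriented along-track x depth (rows = along-track cells).
#'
#' @param spec a [transect_spec()].
#' @return An object of class `transect_scenario`: list with `along_m`,
#'   `depth_m` (cell-centre coordinates), `u`, `v`, `speed`, `labels`
#'   (character matrix, `"FC"`/`"IF"`/`"ED"`), `dist_to_fc_km`, sensor
#'   fields (`temperature`, `salinity`, `sigma_t`, `chl`, `oxygen`), `taxa`
#'   (named list of concentration matrices), and `truth` (the response
#'   table and spec, for recovery tests).
#' @export
gen_transect <- function(spec) {
  stopifnot(inherits(spec, "transect_spec"))
  set.seed(spec$seed)
  x_m <- seq(spec$dx_m / 2, spec$length_km * 1000 - spec$dx_m / 2,
             by = spec$dx_m)
  z_m <- seq(spec$dz_m / 2, spec$depth_m - spec$dz_m / 2, by = spec$dz_m)
  nx <- length(x_m); nz <- length(z_m)
  x_km <- x_m / 1000
  d_km <- abs(x_km - spec$eddy_center_km)          # horizontal distance to core
  R <- spec$eddy_radius_km; W <- spec$interface_width_km

  lab_col <- ifelse(d_km <= R, "ED", ifelse(d_km <= R + W, "IF", "FC"))
  labels <- matrix(lab_col, nx, nz)

  # radial speed profile: solid body inside, interface plateau, FC outside;
  # smooth blends confined to 5% of the interface band at each edge
  s_if <- (spec$tangential_speed + spec$fc_speed) / 2
  blend <- max(0.05 * W, 1e-6)
  s_col <- numeric(nx)
  for (i in seq_len(nx)) {
    d <- d_km[i]
    if (d <= R) {
      s <- spec$tangential_speed * d / R
    } else if (d <= R + W) {
      # interface plateau; smooth ramps confined to the band's edges so
      # each labelled regime stays internally homogeneous
      s <- spec$tangential_speed +
        (s_if - spec$tangential_speed) * smoothstep((d - R) / blend) +
        (spec$fc_speed - s_if) * smoothstep((d - (R + W - blend)) / blend)
    } else {
      s <- spec$fc_speed
    }
    s_col[i] <- s
  }
  # flow geometry: boundary current northward; eddy tangential flow reverses
  # sign across the core (cyclonic rotation seen along the section)
  northward <- ifelse(d_km > R, 1, sign(x_km - spec$eddy_center_km + 1e-12))
  v_col <- s_col * northward
  u_col <- 0.15 * s_col                             # slight eastward shear
  u <- matrix(u_col, nx, nz) +
    matrix(stats::rnorm(nx * nz, 0, spec$sensor_noise_sd["speed"]), nx, nz)
  v <- matrix(v_col, nx, nz) +
    matrix(stats::rnorm(nx * nz, 0, spec$sensor_noise_sd["speed"]), nx, nz)
  speed <- sqrt(u^2 + v^2)

  # distance to FC water from the true labels, km
  dist_km <- distance_to_fc(labels, along_m = x_m, depth_m = z_m)

  # hydrography: background stratification plus isopycnal shoaling centred
  # on the interface band, decaying with depth
  zmat <- matrix(z_m, nx, nz, byrow = TRUE)
  shoal <- exp(-((d_km - (R + W / 2))^2) / (2 * (W / 1.5)^2))
  shoal_m <- matrix(shoal, nx, nz) * exp(-zmat / 40)
  noise <- function(sd) matrix(stats::rnorm(nx * nz, 0, sd), nx, nz)
  sigma_t <- 22 + 0.05 * zmat + 0.5 * shoal_m + noise(spec$sensor_noise_sd["sigma_t"])
  temperature <- 28 - 0.12 * zmat - 1.5 * shoal_m + noise(spec$sensor_noise_sd["temperature"])
  salinity <- 36 + 0.008 * zmat + 0.1 * shoal_m + noise(spec$sensor_noise_sd["salinity"])
  chl <- 0.1 + 0.5 * exp(-((zmat - 35)^2) / (2 * 15^2)) * (1 + shoal_m) +
    noise(spec$sensor_noise_sd["chl"])
  chl[chl < 0] <- 0
  oxygen <- 5 - 0.015 * zmat - 0.3 * shoal_m + noise(spec$sensor_noise_sd["oxygen"])

  # taxa concentration fields from the additive log-scale response functions
  wm_effect <- function(row) {
    eff <- matrix(0, nx, nz)
    eff[labels == "FC"] <- row$b_fc
    eff[labels == "IF"] <- row$b_if
    eff[labels == "ED"] <- row$b_ed
    eff
  }
  taxa_fields <- list()
  for (i in seq_len(nrow(spec$taxa))) {
    row <- spec$taxa[i, ]
    logc <- row$intercept + wm_effect(row) + row$b_speed * speed +
      row$b_dist * dist_km
    if (!is.na(row$prey) && row$prey_coef != 0)
      logc <- logc + row$prey_coef * log1p(taxa_fields[[row$prey]])
    taxa_fields[[row$taxon]] <-
      exp(logc + noise(spec$lognormal_sd))
  }

  structure(list(along_m = x_m, depth_m = z_m, u = u, v = v, speed = speed,
                 labels = labels, dist_to_fc_km = dist_km,
                 temperature = temperature, salinity = salinity,
                 sigma_t = sigma_t, chl = chl, oxygen = oxygen,
                 taxa = taxa_fields,
                 truth = list(taxa = spec$taxa, spec = spec)),
            class = "transect_scenario")
}

#' Simulate an undulating imaging tow through a transect scenario
#'
#' Emulates a towed imager undulating between `depth_min` and the scenario's
#' maximum depth at a fixed ship speed, imaging a fixed water volume per
#' second. Per time step, the expected number of vignettes of each taxon is
#' `concentration x imaged volume`; counts are Poisson. Optionally a
#' group-level confusion matrix misclassifies the sampled vignettes, for
#' end-to-end tests of correction factors.
#'
#' @param scenario a [gen_transect()] result.
#' @param ship_speed_ms ship speed, m/s.
#' @param depth_min_m shallowest tow depth, m.
#' @param undulation_period_s seconds per full down-up cycle.
#' @param volume_rate_m3_per_s imaged volume rate, m3/s.
#' @param dt_s sampling interval, s.
#' @param group_confusion optional square row-stochastic matrix over taxa
#'   (dimnames = taxa); `pred_group` is drawn from the true taxon's row.
#' @param seed integer seed.
#' @return list with `track` (data.frame: `time_s`, `depth_m`,
#'   `along_track_m`, sensor columns) and `vignettes` (data.frame:
#'   `time_s`, `depth_m`, `along_track_m`, `group`, `pred_group`).
#' @export
sample_tow <- function(scenario, ship_speed_ms = 2.5, depth_min_m = 3,
                       undulation_period_s = 400,
                       volume_rate_m3_per_s = 0.168, dt_s = 1,
                       group_confusion = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "transect_scenario"))
  set.seed(seed)
  L <- max(scenario$along_m) + diff(scenario$along_m[1:2]) / 2
  t <- seq(0, L / ship_speed_ms, by = dt_s)
  along <- ship_speed_ms * t
  zmax <- max(scenario$depth_m)
  mid <- (depth_min_m + zmax) / 2
  amp <- (zmax - depth_min_m) / 2
  depth <- mid - amp * cos(2 * pi * t / undulation_period_s)
  ix <- findInterval(along, c(0, scenario$along_m +
                                diff(scenario$along_m[1:2]) / 2),
                     rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1), length(scenario$along_m))
  iz <- findInterval(depth, c(0, scenario$depth_m +
                                diff(scenario$depth_m[1:2]) / 2),
                     rightmost.closed = TRUE)
  iz <- pmin(pmax(iz, 1), length(scenario$depth_m))
  cell <- cbind(ix, iz)
  track <- data.frame(time_s = t, depth_m = depth, along_track_m = along,
                      temperature = scenario$temperature[cell],
                      salinity = scenario$salinity[cell],
                      sigma_t = scenario$sigma_t[cell],
                      chl = scenario$chl[cell],
                      oxygen = scenario$oxygen[cell])
  vol <- volume_rate_m3_per_s * dt_s
  vigs <- list()
  for (taxon in names(scenario$taxa)) {
    lam <- scenario$taxa[[taxon]][cell] * vol
    counts <- stats::rpois(length(lam), lam)
    keep <- which(counts > 0)
    if (length(keep)) {
      rep_ix <- rep(keep, counts[keep])
      vigs[[taxon]] <- data.frame(time_s = t[rep_ix], depth_m = depth[rep_ix],
                                  along_track_m = along[rep_ix],
                                  group = taxon)
    }
  }
  vigs <- do.call(rbind, vigs)
  if (is.null(vigs))
    vigs <- data.frame(time_s = numeric(0), depth_m = numeric(0),
                       along_track_m = numeric(0), group = character(0))
  rownames(vigs) <- NULL
  if (!is.null(group_confusion)) {
    stopifnot(all(rownames(group_confusion) %in% names(scenario$taxa)),
              all(abs(rowSums(group_confusion) - 1) < 1e-9))
    vigs$pred_group <- vigs$group
    for (g in rownames(group_confusion)) {
      sel <- which(vigs$group == g)
      if (length(sel))
        vigs$pred_group[sel] <- sample(colnames(group_confusion), length(sel),
                                       replace = TRUE,
                                       prob = group_confusion[g, ])
    }
  } else {
    vigs$pred_group <- vigs$group
  }
  list(track = track, vignettes = vigs)
}
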