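#' Current speed and direction from velocity components
#'
#' `speed = sqrt(u^2 + v^2)`; direction is the flow-toward bearing in
#' degrees clockwise from north (`0 =` northward, `90 =` eastward), the
#' oceanographic convention — deliberately not the meteorological
#' flow-from convention of wind tooling. Cells with `u = v = 0` get
#' direction 0 and are flagged.
#'
#' @param u,v zonal (eastward) and meridional (northward) velocity, m/s;
#'   vectors or matrices of equal shape, finite.
#' @return list with `speed`, `direction` (same shape as the input) and
#'   `undefined` (logical; TRUE where both components are zero).
#' @export
uv_to_speed_dir <- function(u, v) {
  stopifnot(all(is.finite(u)), all(is.finite(v)),
            length(u) == length(v))
  speed <- sqrt(u^2 + v^2)
  direction <- (atan2(u, v) * 180 / pi) %% 360
  undefined <- u == 0 & v == 0
  direction[undefined] <- 0
  list(speed = speed, direction = direction, undefined = undefined)
}

#' Delineate water masses by k-means clustering of current structure
#'
#' Clusters grid cells on the features `(|u|, |v|, speed)` (standardized
#' by default) with `stats::kmeans` (`nstart` restarts). Unless `k` is
#' given, the number of clusters is chosen from `k_range` at the elbow of
#' the total within-cluster sum of squares (maximum second difference).
#' Clusters are then ranked by mean current speed: the slowest is labelled
#' `"ED"` (eddy), the fastest `"FC"` (boundary current), intermediates
#' `"IF"` (interface; numbered `IF1, IF2, ...` when `k > 3`).
#'
#' @param u,v velocity matrices (along-track x depth) or vectors.
#' @param k_range candidate cluster counts for the elbow search.
#' @param k fixed cluster count (overrides the elbow choice; the
#'   three-water-mass setting of an eddy in a boundary current is `k = 3`).
#' @param n_init `nstart` for `stats::kmeans`.
#' @param standardize standardize features before clustering.
#' @param signed use signed `u`, `v` instead of magnitudes.
#' @param seed RNG seed for reproducible restarts.
#' @return list of class `water_mass_labels`: `labels` (same shape as
#'   `u`), `k`, `centers` (feature space, original units; one row per
#'   label), `sizes`, `variance_explained` (between-SS / total-SS on the
#'   clustering features), `twss` (per candidate `k`, when searched).
#' @export
cluster_water_masses <- function(u, v, k_range = 2:8, k = NULL, n_init = 25,
                                 standardize = TRUE, signed = FALSE,
                                 seed = 1L) {
  stopifnot(length(u) == length(v))
  feat <- cbind(u = if (signed) as.numeric(u) else abs(as.numeric(u)),
                v = if (signed) as.numeric(v) else abs(as.numeric(v)),
                speed = sqrt(as.numeric(u)^2 + as.numeric(v)^2))
  if (nrow(unique(feat)) < max(if (is.null(k)) k_range else k, 2))
    stop("fewer distinct feature rows than clusters; clustering rejected")
  X <- if (standardize) scale(feat) else feat
  set.seed(seed)
  twss <- NULL
  if (is.null(k)) {
    twss <- vapply(k_range, function(kk)
      stats::kmeans(X, centers = kk, nstart = n_init, iter.max = 50)$tot.withinss,
      numeric(1))
    names(twss) <- k_range
    if (length(k_range) >= 3) {
      d2 <- diff(diff(twss))              # elbow: largest curvature
      k <- k_range[which.max(d2) + 1]
    } else {
      k <- k_range[which.min(twss)]
    }
    set.seed(seed)                         # final fit reproducible on its own
  }
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 50)
  mean_speed <- tapply(feat[, "speed"], km$cluster, mean)
  ord <- order(mean_speed)                 # slowest ... fastest
  name_of <- character(k)
  name_of[ord[1]] <- "ED"
  name_of[ord[k]] <- "FC"
  if (k >= 3) {
    mid <- ord[2:(k - 1)]
    name_of[mid] <- if (k == 3) "IF" else paste0("IF", seq_along(mid))
  }
  labels <- name_of[km$cluster]
  if (is.matrix(u)) labels <- matrix(labels, nrow(u), ncol(u))
  centers <- do.call(rbind, lapply(ord, function(cl)
    colMeans(feat[km$cluster == cl, , drop = FALSE])))
  rownames(centers) <- name_of[ord]
  structure(list(labels = labels, k = k, centers = centers,
                 sizes = stats::setNames(as.numeric(table(km$cluster)[ord]),
                                         name_of[ord]),
                 variance_explained = km$betweenss / km$totss,
                 twss = twss),
            class = "water_mass_labels")
}

#' Distance from every grid cell to the nearest FC-labelled cell
#'
#' Minimum Euclidean distance in kilometres, computed in (along-track km,
#' depth km) coordinates — the vertical term is retained but negligible at
#' transect aspect ratios. FC cells get distance 0. With no FC cell all
#' distances are undefined (`NA`) and the result is flagged.
#'
#' @param labels character matrix of water-mass labels (rows = along-track)
#'   or vector.
#' @param along_m,depth_m cell-centre coordinates (m) matching `labels`.
#' @param fc_label label counting as the reference water mass.
#' @return matrix (or vector) of distances, km; attribute `"no_fc"` is TRUE
#'   when no reference cell exists.
#' @export
distance_to_fc <- function(labels, along_m, depth_m, fc_label = "FC") {
  if (is.matrix(labels)) {
    stopifnot(length(along_m) == nrow(labels),
              length(depth_m) == ncol(labels))
    x <- matrix(along_m / 1000, nrow(labels), ncol(labels))
    z <- matrix(depth_m / 1000, nrow(labels), ncol(labels), byrow = TRUE)
  } else {
    stopifnot(length(along_m) == length(labels),
              length(depth_m) == length(labels))
    x <- along_m / 1000; z <- depth_m / 1000
  }
  is_fc <- labels == fc_label
  if (!any(is_fc)) {
    warning("no cell carries the reference label '", fc_label,
            "'; distances undefined")
    out <- if (is.matrix(labels))
      matrix(NA_real_, nrow(labels), ncol(labels))
    else rep(NA_real_, length(labels))
    attr(out, "no_fc") <- TRUE
    return(out)
  }
  fx <- x[is_fc]; fz <- z[is_fc]
  qx <- as.numeric(x); qz <- as.numeric(z)
  res <- numeric(length(qx))
  chunk <- max(1L, floor(5e6 / length(fx)))
  for (s in seq(1, length(qx), by = chunk)) {
    e <- min(s + chunk - 1, length(qx))
    d2 <- outer(qx[s:e], fx, `-`)^2 + outer(qz[s:e], fz, `-`)^2
    res[s:e] <- sqrt(apply(d2, 1, min))
  }
  res[as.numeric(is_fc) > 0] <- 0
  out <- if (is.matrix(labels))
    matrix(res, nrow(labels), ncol(labels))
  else res
  attr(out, "no_fc") <- FALSE
  out
}

#' Mixed layer depth of a density profile by the threshold criterion
#'
#' The shallowest depth at or below `reference_depth` where the potential
#' density anomaly exceeds its reference value by `delta`, with linear
#' interpolation between samples. The default criterion (0.125 kg/m3
#' against a 5-m reference) is the classic threshold choice; the shallow
#' reference suits tows that start a few metres below the surface. If the
#' threshold is never exceeded the deepest sampled depth is returned,
#' flagged.
#'
#' @param depth_m,sigma_t profile depths (m, increasing) and density
#'   anomalies (kg/m3), finite.
#' @param reference_depth reference depth, m; must be covered by the
#'   profile.
#' @param delta density threshold, kg/m3.
#' @return list with `mld_m`, `reached` (FALSE when the threshold was
#'   never exceeded), `reference_depth`, `delta`.
#' @export
mixed_layer_depth <- function(depth_m, sigma_t, reference_depth = 5,
                              delta = 0.125) {
  stopifnot(length(depth_m) == length(sigma_t), !is.unsorted(depth_m))
  if (any(!is.finite(sigma_t))) stop("non-finite densities in profile")
  if (reference_depth < min(depth_m) || reference_depth > max(depth_m))
    stop("profile does not cover the reference depth")
  sig_ref <- stats::approx(depth_m, sigma_t, xout = reference_depth)$y
  below <- depth_m >= reference_depth
  d <- depth_m[below]; s <- sigma_t[below]
  d <- c(reference_depth, d); s <- c(sig_ref, s)
  excess <- s - sig_ref - delta
  if (delta <= 0)
    return(list(mld_m = reference_depth, reached = TRUE,
                reference_depth = reference_depth, delta = delta))
  idx <- which(excess >= 0)
  if (!length(idx))
    return(list(mld_m = max(depth_m), reached = FALSE,
                reference_depth = reference_depth, delta = delta))
  i <- idx[1]
  if (i == 1) {
    mld <- reference_depth
  } else {
    # linear interpolation to the crossing
    f <- -excess[i - 1] / (excess[i] - excess[i - 1])
    mld <- d[i - 1] + f * (d[i] - d[i - 1])
  }
  list(mld_m = mld, reached = TRUE, reference_depth = reference_depth,
       delta = delta)
}

#' Along-track anomaly of a gridded field
#'
#' Removes the along-track mean at each depth level:
#' `anomaly(x, z) = value(x, z) - mean_x value(., z)`. Per-level means of
#' the result are zero by construction.
#'
#' @param values matrix, rows = along-track cells, cols = depth levels.
#' @return anomaly matrix of the same shape.
#' @export
anomaly <- function(values) {
  stopifnot(is.matrix(values))
  sweep(values, 2, colMeans(values), `-`)
}
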