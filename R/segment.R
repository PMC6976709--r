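#' Per-column background profile for flat-fielding
#'
#' Line-scan imagers illuminate each scan line the same way, so the
#' background intensity is a function of the column (cross-scan) position.
#' The profile is estimated as the per-column mean intensity over a window
#' of frames. With `causal = TRUE` the profile for frame `i` uses only
#' frames up to `i` (at most `window` of them), mimicking on-line
#' flat-fielding during acquisition.
#'
#' @param frames list of `frame` objects with identical dimensions.
#' @param window number of frames in the running window.
#' @param causal if `TRUE`, return a matrix of profiles (one row per frame,
#'   causal running mean); if `FALSE`, a single profile over all frames.
#' @return numeric vector (length = frame width) or matrix (frames x width).
#' @export
background_profile <- function(frames, window = 100, causal = FALSE) {
  stopifnot(length(frames) > 0)
  colmeans <- t(vapply(frames, function(f) colMeans(f$pixels),
                       numeric(ncol(frames[[1]]$pixels))))
  if (!causal) {
    n <- min(window, nrow(colmeans))
    return(colMeans(colmeans[seq_len(n), , drop = FALSE]))
  }
  out <- matrix(NA_real_, nrow(colmeans), ncol(colmeans))
  csum <- apply(colmeans, 2, cumsum)
  for (i in seq_len(nrow(colmeans))) {
    lo <- max(1, i - window + 1)
    s <- csum[i, ] - if (lo > 1) csum[lo - 1, ] else 0
    out[i, ] <- s / (i - lo + 1)
  }
  out
}

#' Flat-field a frame against a per-column background profile
#'
#' Divides each pixel by the background intensity of its column and clips
#' to `[0, 1.5]`. A frame identical to its background maps to all ones;
#' organisms (darker than background) map below 1.
#'
#' @param frame a `frame` object.
#' @param background_profile numeric vector of per-column background
#'   intensities (strictly positive), length = frame width.
#' @return The corrected `frame`.
#' @export
flat_field <- function(frame, background_profile) {
  stopifnot(inherits(frame, "frame"),
            length(background_profile) == ncol(frame$pixels))
  zero <- which(background_profile <= 0)
  if (length(zero))
    stop("background profile is zero or negative at column(s): ",
         paste(zero, collapse = ", "))
  px <- sweep(frame$pixels, 2, background_profile, `/`)
  frame$pixels <- pmin(pmax(px, 0), 1.5)
  frame
}

#' k-harmonic-means clustering of 1-D intensities
#'
#' Minimises the k-harmonic-means objective
#' `KHM(X, C) = sum_i k / sum_j ||x_i - c_j||^(-p)` by the standard
#' harmonic-mean weighted centre recursion. Compared to k-means, the soft
#' harmonic weighting makes the optimum far less sensitive to
#' initialisation, which is why it is favoured for unsupervised foreground
#' detection in plankton shadowgraphs. Iteration stops when the objective
#' improves by less than `tol` (relative) or after `max_iter` sweeps; an
#' update that would increase the objective is rejected, so the reported
#' objective sequence is non-increasing.
#'
#' @param values numeric vector (e.g. flat-fielded pixel intensities).
#' @param k number of centres (>= 2).
#' @param p harmonic power (> 2); 3.5 is a common literature default.
#' @param max_iter,tol iteration controls.
#' @param centers optional initial centres; defaults to spread quantiles.
#' @return list with `centers` (sorted ascending), `assignments` (index of
#'   nearest centre per value), `objective` (per-iteration values,
#'   non-increasing), `iterations`, and `degenerate` (TRUE when the input
#'   carries a single distinct value, in which case one effective centre is
#'   returned there and the rest are flagged).
#' @export
khm_cluster <- function(values, k = 2, p = 3.5, max_iter = 100, tol = 1e-8,
                        centers = NULL) {
  stopifnot(is.numeric(values), length(values) >= k, k >= 2, p > 2)
  x <- as.numeric(values)
  if (length(unique(x)) == 1) {
    centers <- c(x[1], rep(NA_real_, k - 1))
    return(list(centers = centers, assignments = rep(1L, length(x)),
                objective = 0, iterations = 0L, degenerate = TRUE))
  }
  if (is.null(centers)) {
    # spread the initial centres across the full data range: with all
    # centres inside one dense mode the harmonic update oscillates
    centers <- seq(min(x), max(x), length.out = k)
  }
  stopifnot(length(centers) == k)
  eps <- 1e-12 * diff(range(x))
  # distances are factored as d_ij = dmin_i * r_ij with r_ij >= 1, so the
  # harmonic weights dmin_i^(p-2) * r_ij^(-p-2) / (sum_l r_il^(-p))^2 stay
  # finite; a point coinciding with a centre has weight ~ dmin^(p-2) -> 0
  dist_parts <- function(cen) {
    d <- abs(outer(x, cen, `-`))
    dmin <- do.call(pmin, as.data.frame(d))
    list(d = d, dmin = dmin, ok = dmin > eps)
  }
  objective_of <- function(parts) {
    with(parts, sum(k * dmin[ok]^p /
                      rowSums((d[ok, , drop = FALSE] / dmin[ok])^(-p))))
  }
  parts <- dist_parts(centers)
  obj <- objective_of(parts)
  objs <- obj
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- parts$d[parts$ok, , drop = FALSE] / parts$dmin[parts$ok]
    wt <- parts$dmin[parts$ok]^(p - 2) * r^(-p - 2) / rowSums(r^(-p))^2
    csum <- colSums(wt)
    if (any(csum == 0)) break                         # starved centre
    new_centers <- colSums(wt * x[parts$ok]) / csum
    new_parts <- dist_parts(new_centers)
    new_obj <- objective_of(new_parts)
    if (!is.finite(new_obj) || new_obj > obj) break   # safeguard: never ascend
    centers <- new_centers
    parts <- new_parts
    improved <- obj - new_obj
    obj <- new_obj
    objs <- c(objs, obj)
    if (improved < tol * max(obj, eps)) break
  }
  ord <- order(centers)
  centers <- centers[ord]
  d <- abs(outer(x, centers, `-`))
  assignments <- max.col(-d, ties.method = "first")
  list(centers = centers, assignments = assignments, objective = objs,
       iterations = iter, degenerate = FALSE)
}

# 8-connected component labelling of a logical matrix by iterative minimum-
# label propagation (vectorised; iterations ~ component diameter)
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  big <- .Machine$integer.max
  repeat {
    m <- matrix(big, nrow(mask), ncol(mask))
    m[mask] <- lab[mask]
    nr <- nrow(m); nc <- ncol(m)
    shift <- function(dr, dc) {
      out <- matrix(big, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    best <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) best <- pmin(best, shift(dr, dc))
    best <- pmin(m, best)
    changed <- any(best[mask] != lab[mask])
    lab[mask] <- best[mask]
    if (!changed) break
  }
  # compact labels to 1..n
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

#' Detect regions of interest in a flat-fielded frame
#'
#' Clusters the frame's pixel intensities with [khm_cluster()] (`k`
#' clusters), takes the cluster with the lowest centre as foreground (dark
#' organisms on a bright background), labels 8-connected foreground
#' components, and keeps components with at least `min_area_px` pixels.
#'
#' To keep the clustering affordable on large frames, centres are fitted on
#' a random subsample of at most `sample_px` pixels (deterministic given
#' the current RNG state) and all pixels are then assigned to the nearest
#' centre; the assignment step is exact.
#'
#' @param frame a flat-fielded `frame`.
#' @param k,p [khm_cluster()] parameters.
#' @param min_area_px minimum component area in pixels.
#' @param sample_px max pixels used to fit the KHM centres.
#' @return data.frame of ROIs: `frame`, `row0`, `col0`, `row1`, `col1`
#'   (0-based, half-open), `area_px`, `centroid_row`, `centroid_col`.
#'   Zero rows when nothing is detected (uniform frames included).
#' @export
detect_rois <- function(frame, k = 2, p = 3.5, min_area_px = 25,
                        sample_px = 20000) {
  stopifnot(inherits(frame, "frame"))
  px <- frame$pixels
  vals <- as.numeric(px)
  fit_vals <- if (length(vals) > sample_px) {
    vals[sample.int(length(vals), sample_px)]
  } else vals
  km <- khm_cluster(fit_vals, k = k, p = p)
  if (km$degenerate) return(empty_roi_df())
  centers <- km$centers[!is.na(km$centers)]
  # foreground = darkest cluster; require genuine contrast between the
  # darkest and brightest centres, else declare the frame featureless
  if (diff(range(centers)) < 0.05) return(empty_roi_df())
  lo <- min(centers)
  d <- abs(outer(vals, centers, `-`))
  assign <- max.col(-d, ties.method = "first")
  mask <- matrix(assign == which.min(centers), nrow(px), ncol(px))
  lab <- label_components(mask)
  if (!any(lab > 0)) return(empty_roi_df())
  tab <- tabulate(lab)
  keep <- which(tab >= min_area_px)
  if (!length(keep)) return(empty_roi_df())
  out <- lapply(keep, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(frame = frame$id,
               row0 = min(w[, 1]) - 1L, col0 = min(w[, 2]) - 1L,
               row1 = max(w[, 1]), col1 = max(w[, 2]),
               area_px = nrow(w),
               centroid_row = mean(w[, 1]) - 0.5,
               centroid_col = mean(w[, 2]) - 0.5)
  })
  do.call(rbind, out)
}

empty_roi_df <- function() {
  data.frame(frame = integer(0), row0 = integer(0), col0 = integer(0),
             row1 = integer(0), col1 = integer(0), area_px = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0))
}

#' Extract padded vignette crops for detected ROIs
#'
#' Crops each ROI's bounding box, padded by `pad_px` on every side and
#' clipped at the frame edges. Tow metadata (depth, along-track, time) is
#' propagated from the frame onto each vignette.
#'
#' @param frame the source `frame`.
#' @param rois data.frame as returned by [detect_rois()].
#' @param pad_px padding in pixels.
#' @return list with `images` (list of pixel matrices) and `meta`
#'   (data.frame: `frame`, box columns of the crop actually taken,
#'   `depth_m`, `along_track_m`, `time_s`).
#' @export
extract_vignettes <- function(frame, rois, pad_px = 10) {
  stopifnot(inherits(frame, "frame"), pad_px >= 0)
  h <- nrow(frame$pixels); w <- ncol(frame$pixels)
  images <- vector("list", nrow(rois))
  meta <- rois[0, c("frame", "row0", "col0", "row1", "col1")]
  for (i in seq_len(nrow(rois))) {
    r0 <- max(0L, rois$row0[i] - pad_px); c0 <- max(0L, rois$col0[i] - pad_px)
    r1 <- min(h, rois$row1[i] + pad_px); c1 <- min(w, rois$col1[i] + pad_px)
    images[[i]] <- frame$pixels[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    meta[i, ] <- list(frame$id, r0, c0, r1, c1)
  }
  meta$depth_m <- frame$depth_m
  meta$along_track_m <- frame$along_track_m
  meta$time_s <- frame$time_s
  list(images = images, meta = meta)
}

#' Match detected ROIs to ground-truth boxes by intersection-over-union
#'
#' Greedy one-to-one matching: pairs are accepted in decreasing IoU order
#' while IoU exceeds `iou_min`. Used to score detection against planted
#' truth from [gen_frames()].
#'
#' @param detected,truth data.frames with `frame`, `row0`, `col0`, `row1`,
#'   `col1` (0-based, half-open).
#' @param iou_min minimum IoU for a match.
#' @return list with `matches` (data.frame of index pairs and IoU),
#'   `precision`, `recall`.
#' @export
match_rois <- function(detected, truth, iou_min = 0.5) {
  iou <- function(a, b) {
    ir <- max(0, min(a$row1, b$row1) - max(a$row0, b$row0))
    ic <- max(0, min(a$col1, b$col1) - max(a$col0, b$col0))
    inter <- ir * ic
    area_a <- (a$row1 - a$row0) * (a$col1 - a$col0)
    area_b <- (b$row1 - b$row0) * (b$col1 - b$col0)
    inter / (area_a + area_b - inter)
  }
  pairs <- NULL
  for (i in seq_len(nrow(detected))) for (j in seq_len(nrow(truth))) {
    if (detected$frame[i] != truth$frame[j]) next
    v <- iou(detected[i, ], truth[j, ])
    if (v > iou_min) pairs <- rbind(pairs, data.frame(det = i, tru = j, iou = v))
  }
  matches <- data.frame(det = integer(0), tru = integer(0), iou = numeric(0))
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$iou), ]
    used_d <- logical(nrow(detected)); used_t <- logical(nrow(truth))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$det[r]; j <- pairs$tru[r]
      if (!used_d[i] && !used_t[j]) {
        matches <- rbind(matches, pairs[r, ])
        used_d[i] <- TRUE; used_t[j] <- TRUE
      }
    }
  }
  list(matches = matches,
       precision = if (nrow(detected)) nrow(matches) / nrow(detected) else NA_real_,
       recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_)
}
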