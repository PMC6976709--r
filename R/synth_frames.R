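#' Scene specification for synthetic shadowgraph frames
#'
#' Describes a set of grayscale line-scan frames with dark elliptical
#' "organisms" planted on a bright background, a smooth multiplicative
#' illumination gradient across the scan direction, and additive Gaussian
#' pixel noise. Frames emulate the raw material a towed shadowgraph imager
#' produces; they are not photorealistic.
#'
#' @param frame_height_px,frame_width_px frame dimensions in pixels.
#' @param n_frames number of frames to generate.
#' @param blob_count_per_frame Poisson mean of planted organisms per frame.
#' @param blob_classes a data.frame with one row per organism class and
#'   columns `class` (id), `axis_a_px`, `axis_b_px` (ellipse semi-axes in
#'   pixels) and `contrast` (intensity contrast in `[0, 1]`; the fraction of
#'   background intensity removed at the blob core).
#' @param illumination_gradient peak-to-peak relative amplitude of a smooth
#'   multiplicative illumination field across columns (0 = flat).
#' @param noise_sd additive Gaussian noise standard deviation, grayscale units.
#' @param background mean background intensity in `(0, 1]`.
#' @param seed integer seed; all frame randomness flows from it.
#'
#' @return An object of class `scene_spec`.
#' @seealso [gen_frames()]
#' @export
scene_spec <- function(frame_height_px = 160, frame_width_px = 240,
                       n_frames = 10, blob_count_per_frame = 5,
                       blob_classes = data.frame(
                         class = c("copepod", "chaetognath", "larval_fish"),
                         axis_a_px = c(6, 14, 10),
                         axis_b_px = c(4, 3, 5),
                         contrast = c(0.5, 0.4, 0.45)
                       ),
                       illumination_gradient = 0.2, noise_sd = 0.02,
                       background = 0.85, seed = 1L) {
  stopifnot(frame_height_px >= 8, frame_width_px >= 8, n_frames >= 0,
            blob_count_per_frame >= 0, noise_sd >= 0,
            background > 0, background <= 1,
            is.data.frame(blob_classes),
            all(c("class", "axis_a_px", "axis_b_px", "contrast") %in%
                  names(blob_classes)))
  if (any(blob_classes$contrast < 0 | blob_classes$contrast > 1))
    stop("blob contrast must lie in [0, 1]")
  # a blob must fit inside the frame with its soft edge
  max_ext <- 2 * ceiling(pmax(blob_classes$axis_a_px, blob_classes$axis_b_px)) + 4
  if (any(max_ext >= frame_height_px | max_ext >= frame_width_px))
    stop("blob class larger than frame: reduce ellipse axes or enlarge frame")
  structure(list(frame_height_px = as.integer(frame_height_px),
                 frame_width_px = as.integer(frame_width_px),
                 n_frames = as.integer(n_frames),
                 blob_count_per_frame = blob_count_per_frame,
                 blob_classes = blob_classes,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, background = background,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate synthetic shadowgraph frames with planted-organism ground truth
#'
#' Draws `n_frames` frames from a [scene_spec()]. Each frame starts as a
#' uniform bright background, is multiplied by a smooth illumination field
#' (half-sine across columns, emulating uneven line-scan lighting), receives
#' a Poisson number of dark soft-edged ellipses at random positions and
#' orientations, and finally additive Gaussian noise. All intensities are
#' clipped to `[0, 1]`.
#'
#' Planted blobs are whole: a blob whose bounding box would cross the frame
#' edge is re-positioned, so every ground-truth box lies fully inside the
#' frame. Output is deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{frames}{list of `frame` objects (see [make_frame()]); per-frame
#'       depth/along-track/time metadata follows a simple undulating tow.}
#'     \item{truth}{data.frame of planted ROIs: `frame`, `class`,
#'       `row0`, `col0`, `row1`, `col1` (0-based, half-open).}
#'   }
#' @export
gen_frames <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$frame_height_px; w <- spec$frame_width_px
  # multiplicative illumination: half-sine bump across columns
  illum <- 1 + spec$illumination_gradient * (sin(pi * (seq_len(w) - 0.5) / w) - 0.5)
  frames <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)
  # simple undulating tow for metadata: 3-80 m, 2.5 m/s ship speed
  t_s <- seq_len(spec$n_frames)
  depth_m <- 41.5 - 38.5 * cos(2 * pi * t_s / max(60, spec$n_frames))
  along_m <- 2.5 * t_s
  for (f in seq_len(spec$n_frames)) {
    px <- matrix(spec$background, h, w)
    px <- sweep(px, 2, illum, `*`)
    n_blobs <- stats::rpois(1, spec$blob_count_per_frame)
    boxes <- NULL
    if (n_blobs > 0) {
      cls_idx <- sample.int(nrow(spec$blob_classes), n_blobs, replace = TRUE)
      for (b in seq_len(n_blobs)) {
        cl <- spec$blob_classes[cls_idx[b], ]
        theta <- stats::runif(1, 0, pi)
        ext <- blob_extent(cl$axis_a_px, cl$axis_b_px, theta)
        # place so the soft-edged blob is fully inside the frame and does
        # not touch an earlier blob (organisms occupy distinct positions
        # in the thin imaged slab); give up after 50 tries
        for (try in 1:50) {
          cy <- stats::runif(1, ext$ry + 2, h - ext$ry - 2)
          cx <- stats::runif(1, ext$rx + 2, w - ext$rx - 2)
          # ground-truth box bounds the ellipse itself (soft-edge margin is
          # only a placement buffer)
          box <- data.frame(frame = f, class = cl$class,
                            row0 = floor(cy - (ext$ry - 2)),
                            col0 = floor(cx - (ext$rx - 2)),
                            row1 = ceiling(cy + (ext$ry - 2)),
                            col1 = ceiling(cx + (ext$rx - 2)))
          clear <- is.null(boxes) ||
            !any(boxes$row1 + 2 > box$row0 & boxes$row0 - 2 < box$row1 &
                   boxes$col1 + 2 > box$col0 & boxes$col0 - 2 < box$col1)
          if (clear) break
        }
        if (!clear) next                   # frame too crowded: skip blob
        px <- stamp_blob(px, cy, cx, cl$axis_a_px, cl$axis_b_px, theta,
                         cl$contrast)
        boxes <- rbind(boxes, box)
      }
    }
    if (spec$noise_sd > 0)
      px <- px + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    px <- pmin(pmax(px, 0), 1)
    frames[[f]] <- make_frame(px, depth_m = depth_m[f], along_track_m = along_m[f],
                              time_s = t_s[f], id = f)
    truth[[f]] <- boxes
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), class = character(0),
                        row0 = integer(0), col0 = integer(0),
                        row1 = integer(0), col1 = integer(0))
  list(frames = frames, truth = truth)
}

# axis-aligned half-extents of a rotated ellipse (plus soft-edge margin)
blob_extent <- function(a, b, theta) {
  rx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ry <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  list(rx = rx + 2, ry = ry + 2)
}

# multiply a dark soft-edged ellipse into the image; sigmoid edge profile
stamp_blob <- function(px, cy, cx, a, b, theta, contrast, softness = 0.15) {
  h <- nrow(px); w <- ncol(px)
  ext <- blob_extent(a, b, theta)
  r0 <- max(1L, floor(cy - ext$ry)); r1 <- min(h, ceiling(cy + ext$ry))
  c0 <- max(1L, floor(cx - ext$rx)); c1 <- min(w, ceiling(cx + ext$rx))
  rr <- r0:r1; cc <- c0:c1
  dy <- outer(rr - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cx)
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  depth <- contrast / (1 + exp((r - 1) / softness))
  px[rr, cc] <- px[rr, cc] * (1 - depth)
  px
}

#' Construct a frame object
#'
#' A frame is a 2-D grayscale pixel matrix in `[0, 1]` with tow metadata
#' (depth, along-track position, time) attached.
#'
#' @param pixels numeric matrix, values in `[0, 1]` (finite).
#' @param depth_m tow depth of the frame, metres (>= 0).
#' @param along_track_m along-track position, metres.
#' @param time_s time stamp, seconds.
#' @param id frame identifier.
#' @return An object of class `frame`.
#' @export
make_frame <- function(pixels, depth_m = 0, along_track_m = 0, time_s = 0,
                       id = NA) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), depth_m >= 0)
  structure(list(pixels = pixels, depth_m = depth_m,
                 along_track_m = along_track_m, time_s = time_s, id = id),
            class = "frame")
}

#' Write frames as 8-bit PNGs with a CSV sidecar
#'
#' @param frames list of `frame` objects.
#' @param dir output directory (created if absent).
#' @return Invisibly, the sidecar path.
#' @export
write_frames_png <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- data.frame(file = sprintf("frame_%05d.png", seq_along(frames)),
                     id = vapply(frames, function(f) f$id, numeric(1)),
                     depth_m = vapply(frames, function(f) f$depth_m, numeric(1)),
                     along_track_m = vapply(frames, function(f) f$along_track_m, numeric(1)),
                     time_s = vapply(frames, function(f) f$time_s, numeric(1)))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]]$pixels, file.path(dir, meta$file[i]))
  sidecar <- file.path(dir, "frames.csv")
  utils::write.csv(meta, sidecar, row.names = FALSE)
  invisible(sidecar)
}

#' Read frames written by [write_frames_png()]
#'
#' @param dir directory holding `frames.csv` and the PNGs.
#' @return List of `frame` objects.
#' @export
read_frames_png <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "frames.csv"))
  lapply(seq_len(nrow(meta)), function(i) {
    px <- png::readPNG(file.path(dir, meta$file[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    make_frame(px, depth_m = meta$depth_m[i],
               along_track_m = meta$along_track_m[i],
               time_s = meta$time_s[i], id = meta$id[i])
  })
}
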