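#' Detect landmark dots in a snapshot
#'
#' Automates the manual image measurement step: a global threshold chosen
#' by Otsu's between-class-variance criterion on the intensity histogram
#' (overridable), connected-component labelling, an area filter that
#' rejects the large grip tags and specks, and a sub-pixel
#' intensity-weighted centroid per component (weights are the darkness
#' relative to the background, so anti-aliased edges pull the centroid to
#' the true centre).
#'
#' Pixel coordinates: the centre of pixel column `j` / row `i` is
#' `(j, i)`.
#'
#' @param frame An `extensometer_frame` (from [render_frame()]) or a
#'   numeric matrix of 8-bit intensities (rows = y).
#' @param min_area_px,max_area_px Component area bounds in pixels.
#' @param polarity `"dark"` landmarks on bright background (default) or
#'   `"bright"`.
#' @param threshold Optional manual threshold (0--255); `NULL` = Otsu.
#' @return A tibble with one row per landmark: `id`, `x_px`, `y_px`,
#'   `area_px`. Empty (zero rows) for a blank, zero-variance image.
#' @export
detect_landmarks <- function(frame, min_area_px = 5, max_area_px = 600,
                             polarity = c("dark", "bright"),
                             threshold = NULL) {
  polarity <- match.arg(polarity)
  if (min_area_px <= 0 || max_area_px <= 0) {
    stop_microext("area bounds must be positive.", "microext_invalid_area")
  }
  img <- if (inherits(frame, "extensometer_frame")) frame$pixels else frame
  stopifnot(is.matrix(img))
  if (polarity == "bright") img <- 255 - img

  empty <- tibble(id = integer(), x_px = numeric(), y_px = numeric(),
                  area_px = integer())
  if (max(img) - min(img) < 1e-9) return(empty)  # zero-variance image

  thr <- threshold %||% otsu_threshold(img)
  mask <- img < thr
  if (!any(mask)) return(empty)

  # connected components (EBImage expects dim1 = x)
  lab <- EBImage::bwlabel(t(mask))
  lab <- t(EBImage::imageData(lab))

  bg <- stats::median(img[!mask])
  wts <- pmax(bg - img, 0)

  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area_px || area > max_area_px) return(NULL)
    # expand the support by 1 px so anti-aliased rims above threshold count
    i_rng <- max(1L, min(idx[, 1]) - 1L):min(nrow(img), max(idx[, 1]) + 1L)
    j_rng <- max(1L, min(idx[, 2]) - 1L):min(ncol(img), max(idx[, 2]) + 1L)
    w <- wts[i_rng, j_rng, drop = FALSE]
    sw <- sum(w)
    tibble(id = id,
           x_px = sum(w %*% diag(j_rng, nrow = length(j_rng))) / sw,
           y_px = sum(diag(i_rng, nrow = length(i_rng)) %*% w) / sw,
           area_px = area)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$x_px)
  out$id <- seq_len(nrow(out))
  out
}

#' Otsu threshold of an 8-bit image
#'
#' Maximizes the between-class variance over the 256-bin histogram.
#'
#' @param img Numeric matrix of intensities in 0--255.
#' @return Threshold value (pixels strictly below are foreground-dark).
#' @export
otsu_threshold <- function(img) {
  counts <- tabulate(pmin(pmax(floor(img), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  levels[which.max(bcv)] + 0.5
}

#' Track landmarks across a snapshot sequence
#'
#' Maintains stable landmark identities frame-to-frame by nearest-
#' neighbour matching with a maximum-displacement gate, so distances are
#' always measured between the same physical landmarks. The track fails
#' loudly (naming the frame) when the landmark count changes or a match
#' is ambiguous (more than one candidate within the gate, or a
#' non-bijective assignment) -- never with a silent identity swap.
#'
#' @param frames A list of `extensometer_frame`s (or matrices), or a list
#'   of per-frame centroid tibbles from [detect_landmarks()].
#' @param gate_px Maximum allowed displacement per frame; default 0.25 x
#'   the smallest initial pairwise separation.
#' @param scale_um_per_px Pixel scale carried into the track (taken from
#'   the first frame when available).
#' @param ... Passed to [detect_landmarks()].
#' @return A `landmark_track`: a tibble with columns `frame`, `time_us`,
#'   `id`, `x_px`, `y_px`, plus a `scale_um_per_px` attribute.
#' @export
track_landmarks <- function(frames, gate_px = NULL, scale_um_per_px = NULL,
                            ...) {
  if (length(frames) < 2) {
    stop_microext("need at least 2 frames to track.", "microext_track_error")
  }
  is_frame <- inherits(frames[[1]], "extensometer_frame") ||
    is.matrix(frames[[1]])
  dets <- if (is_frame) lapply(frames, detect_landmarks, ...) else frames
  times <- vapply(seq_along(frames), function(i) {
    if (inherits(frames[[i]], "extensometer_frame")) {
      frames[[i]]$timestamp_us
    } else {
      as.numeric(i)
    }
  }, numeric(1))
  if (is.null(scale_um_per_px) &&
      inherits(frames[[1]], "extensometer_frame")) {
    scale_um_per_px <- frames[[1]]$scale_um_per_px
  }

  n0 <- nrow(dets[[1]])
  if (n0 == 0) {
    stop_microext("no landmarks detected in frame 1.", "microext_track_error")
  }
  if (is.null(gate_px)) {
    if (n0 >= 2) {
      seps <- diff(sort(dets[[1]]$x_px))
      gate_px <- 0.25 * min(sqrt(seps^2))
    } else {
      gate_px <- Inf
    }
  }

  cur <- dets[[1]][order(dets[[1]]$x_px), ]
  cur$id <- seq_len(n0)
  out <- list(tibble(frame = 1L, time_us = times[1], id = cur$id,
                     x_px = cur$x_px, y_px = cur$y_px))

  for (f in 2:length(dets)) {
    nxt <- dets[[f]]
    if (nrow(nxt) != n0) {
      stop_microext(
        sprintf("landmark count changed from %d to %d at frame %d; partial track.",
                n0, nrow(nxt), f),
        "microext_track_partial")
    }
    d <- sqrt(outer(cur$x_px, nxt$x_px, "-")^2 +
                outer(cur$y_px, nxt$y_px, "-")^2)
    within <- d <= gate_px
    n_cand <- rowSums(within)
    if (any(n_cand == 0)) {
      stop_microext(
        sprintf("landmark %d lost at frame %d (no candidate within gate %.1f px).",
                cur$id[which(n_cand == 0)[1]], f, gate_px),
        "microext_track_partial")
    }
    if (any(n_cand > 1)) {
      stop_microext(
        sprintf("ambiguous match at frame %d: %d candidates within the gate for landmark %d.",
                f, max(n_cand), cur$id[which(n_cand > 1)[1]]),
        "microext_track_ambiguous")
    }
    assign <- apply(within, 1, which)
    if (anyDuplicated(assign)) {
      stop_microext(
        sprintf("ambiguous (non-bijective) match at frame %d.", f),
        "microext_track_ambiguous")
    }
    nxt <- nxt[assign, ]
    nxt$id <- cur$id
    out[[f]] <- tibble(frame = f, time_us = times[f], id = nxt$id,
                       x_px = nxt$x_px, y_px = nxt$y_px)
    cur <- nxt
  }
  res <- dplyr::bind_rows(out)
  attr(res, "scale_um_per_px") <- scale_um_per_px
  class(res) <- c("landmark_track", class(res))
  res
}

#' Pixel scale from a reference length
#'
#' A feature of known physical size in the image (for example the
#' 12.7-mm printed tag width) serves as a built-in scale bar.
#'
#' @param reference_length_um Known physical length (um).
#' @param measured_px Its measured extent in pixels.
#' @return Scale in um per pixel.
#' @examples
#' pixel_scale(12700, 1270)  # 10 um/px
#' @export
pixel_scale <- function(reference_length_um, measured_px) {
  if (reference_length_um <= 0 || measured_px <= 0) {
    stop_microext("reference length and measured pixels must be > 0.",
                  "microext_invalid_scale")
  }
  reference_length_um / measured_px
}

#' Engineering strain, percent
#'
#' \eqn{\varepsilon = (L - L_{ref})/L_{ref} \times 100}. Used by both the
#' landmark and the grip (actuator) strain pathways.
#'
#' @param length_um Current length(s).
#' @param reference_um Reference length (> 0).
#' @return Strain in percent.
#' @examples
#' strain_pct(352.8, 318.9)  # 10.6%
#' @export
strain_pct <- function(length_um, reference_um) {
  if (any(reference_um <= 0)) {
    stop_microext("reference length must be > 0.", "microext_invalid_ref")
  }
  (length_um - reference_um) / reference_um * 100
}

#' Landmark-based strain along a track
#'
#' Per-frame Euclidean separation of a landmark pair, converted with the
#' pixel scale, as strain relative to the separation in the reference
#' frame.
#'
#' @param track A `landmark_track` from [track_landmarks()].
#' @param pair Two landmark ids (default the outermost pair).
#' @param reference_frame Frame index defining \eqn{L_0} (default 1).
#' @param scale_um_per_px Pixel scale; defaults to the track's.
#' @return Tibble with `frame`, `time_us`, `separation_um`,
#'   `landmark_strain_pct`.
#' @export
landmark_strain <- function(track, pair = NULL, reference_frame = 1,
                            scale_um_per_px = NULL) {
  scale_um_per_px <- scale_um_per_px %||% attr(track, "scale_um_per_px")
  if (is.null(scale_um_per_px)) {
    stop_microext("no pixel scale available; supply `scale_um_per_px`.",
                  "microext_invalid_scale")
  }
  ids <- sort(unique(track$id))
  if (is.null(pair)) pair <- c(ids[1], ids[length(ids)])
  a <- track[track$id == pair[1], ]
  b <- track[track$id == pair[2], ]
  if (nrow(a) == 0 || nrow(b) == 0 || nrow(a) != nrow(b)) {
    stop_microext("pair not tracked in all frames.", "microext_track_error")
  }
  sep_um <- sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2) * scale_um_per_px
  d_ref <- sep_um[reference_frame]
  if (d_ref == 0) {
    stop_microext("reference separation is zero.", "microext_invalid_ref")
  }
  tibble(frame = a$frame, time_us = a$time_us, separation_um = sep_um,
         landmark_strain_pct = strain_pct(sep_um, d_ref))
}

#' Grip (actuator) strain from an experiment log
#'
#' The actuator pathway measures strain from grip displacement over the
#' same reference distance convention as the landmarks: the grip
#' separation at step `k` is `L0 + position_um(k)`, and strain is taken
#' relative to the separation at the reference step. Slippage inflates
#' this pathway relative to the landmark pathway.
#'
#' @param log An `experiment_log` (or its `records` tibble).
#' @param L0_um Grip-to-grip gauge length at the reference step.
#' @param reference_step Row index defining the reference (default 1,
#'   i.e. after the first step).
#' @return Tibble with `step`, `separation_um`, `grip_strain_pct`.
#' @export
grip_strain <- function(log, L0_um, reference_step = 1) {
  if (L0_um <= 0) stop_microext("`L0_um` must be > 0.", "microext_invalid_ref")
  records <- if (inherits(log, "experiment_log")) log$records else log
  pos_um <- records$position_nm / 1000
  sep_um <- L0_um + pos_um - pos_um[reference_step]
  tibble(step = records$step, separation_um = sep_um,
         grip_strain_pct = strain_pct(sep_um, sep_um[reference_step]))
}

#' Combine the two strain pathways
#'
#' Joins landmark- and grip-pathway strain per step; the slip strain is
#' their difference (grip minus landmark), non-negative whenever slip is
#' the only divergence source.
#'
#' @param landmark Tibble from [landmark_strain()] (frame k = step k).
#' @param grip Tibble from [grip_strain()].
#' @return A `strain_series` tibble: `step`, `landmark_strain_pct`,
#'   `grip_strain_pct`, `slip_strain_pct`.
#' @export
strain_series <- function(landmark, grip) {
  lm <- tibble(step = landmark$frame,
               landmark_strain_pct = landmark$landmark_strain_pct)
  out <- dplyr::inner_join(lm, grip[, c("step", "grip_strain_pct")],
                           by = "step")
  out$slip_strain_pct <- out$grip_strain_pct - out$landmark_strain_pct
  class(out) <- c("strain_series", class(out))
  out
}
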