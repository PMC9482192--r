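#' Photon-counting camera frame stack
#'
#' @param frames numeric H x W x T array of non-negative photon counts.
#' @param frame_interval frame duration (s), 0.2 s for the
#'   photon-counting-camera protocol.
#' @param injection index of the last pre-injection frame.
#' @param discharge index of the last pre-discharge frame.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 0.2, injection, discharge) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            all(is.finite(frames)), all(frames >= 0),
            frame_interval > 0)
  nt <- dim(frames)[3L]
  injection <- as.integer(injection); discharge <- as.integer(discharge)
  if (!(injection >= 1L && injection < discharge && discharge < nt))
    stop("frame markers must satisfy 1 <= injection < discharge < n_frames")
  structure(list(frames = frames, frame_interval = frame_interval,
                 injection = injection, discharge = discharge),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d x %d px, %d frames x %g s\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Per-frame photon counts inside a region of interest
#'
#' @param stack an [image_stack()].
#' @param roi logical H x W mask (non-empty, dimensions matching the
#'   stack).
#' @return numeric vector of summed counts per frame.
#' @export
roi_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), is.logical(roi))
  d <- dim(stack$frames)
  if (!identical(dim(roi), d[1:2]))
    stop("ROI mask dimensions do not match the stack")
  if (!any(roi)) stop("ROI mask is empty")
  idx <- which(roi)
  m <- matrix(stack$frames, nrow = d[1] * d[2], ncol = d[3])
  colSums(m[idx, , drop = FALSE])
}

#' L over Lmax normalisation of an ROI trace
#'
#' Luminescence counts per second divided by the total luminescence
#' counts remaining (inclusive of the current frame): an estimate of the
#' instantaneous fractional aequorin consumption rate (s^-1), invariant
#' to aequorin expression level.
#'
#' @param trace per-frame counts (e.g. from [roi_trace()]).
#' @param frame_interval frame duration (s).
#' @return numeric vector (s^-1); frames with zero remaining counts are
#'   `NA` and indexed in the `"flagged"` attribute.
#' @export
l_over_lmax <- function(trace, frame_interval = 0.2) {
  stopifnot(is.numeric(trace), all(is.finite(trace)), all(trace >= 0),
            frame_interval > 0)
  rem <- rev(cumsum(rev(trace)))
  out <- ifelse(rem > 0, (trace / frame_interval) / rem, NA_real_)
  structure(out, flagged = which(rem <= 0))
}

#' Peak normalised response per ROI
#'
#' Maximum of the L/Lmax-normalised trace over the post-injection,
#' pre-discharge frames, for every ROI in the set.
#'
#' @param stack an [image_stack()] spanning injection through discharge.
#' @param rois named list of logical masks.
#' @return data.frame with `roi` and `peak` (s^-1), sorted by ROI name.
#' @export
peak_map <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"), is.list(rois),
            length(rois) >= 1L, !is.null(names(rois)))
  win <- (stack$injection + 1L):stack$discharge
  peaks <- vapply(rois, function(m) {
    v <- l_over_lmax(roi_trace(stack, m), stack$frame_interval)
    max(v[win], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(roi = names(rois), peak = unname(peaks),
                    stringsAsFactors = FALSE)
  out[order(out$roi), , drop = FALSE]
}

#' Simulate a photon-counting stack of a responding leaf
#'
#' Renders the leaf blade as an axis-aligned rectangle divided into
#' equal-width bands (tip = band 1, matching 5-mm sections); each band
#' follows its preset's calcium kinetics, with per-pixel Poisson photon
#' emission from a per-pixel aequorin pool and Poisson background.
#'
#' @param presets ordered list of [signature_preset()]s, one per band
#'   (e.g. from [section_profile_presets()]).
#' @param frame_interval frame duration (s).
#' @param baseline_s,post_s,discharge_s phase durations (s).
#' @param band_px band width in pixels; `height_px` rows.
#' @param height_px leaf height in pixels.
#' @param a0_px initial aequorin pool per pixel.
#' @param background per-pixel background rate (counts/s).
#' @param discharge_rate saturating consumption rate during discharge
#'   (s^-1).
#' @param seed integer seed.
#' @param model an [aeq_calibration()].
#' @return list: `stack` (an [image_stack()]) and `rois` (one named band
#'   mask per preset, `"B1"` = tip).
#' @export
simulate_leaf_stack <- function(presets, frame_interval = 0.2,
                                baseline_s = 30, post_s = 120,
                                discharge_s = 60, band_px = 4L,
                                height_px = 8L, a0_px = 2e4,
                                background = 0.5, discharge_rate = 0.05,
                                seed = NULL, model = aeq_calibration()) {
  stopifnot(length(presets) >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nbands <- length(presets)
  cfg <- sim_config(tau = frame_interval, baseline_s = baseline_s,
                    post_s = post_s, discharge_s = discharge_s,
                    A0 = a0_px, background = background,
                    discharge_rate = discharge_rate)
  nb <- phase_bins(cfg)
  nt <- nb$n_base + nb$n_post + nb$n_dis
  H <- as.integer(height_px); W <- as.integer(band_px) * nbands
  frames <- array(0, dim = c(H, W, nt))
  for (b in seq_len(nbands)) {
    ca <- build_ca_trace(presets[[b]], cfg)
    k <- rate_from_calcium(ca, model)
    k[(nb$n_base + nb$n_post + 1L):nt] <- discharge_rate
    keep <- exp(-k * frame_interval)
    pool <- a0_px * c(1, cumprod(keep)[-nt])   # expected pool at frame start
    mu <- pool * (1 - keep) + background * frame_interval
    cols <- ((b - 1L) * band_px + 1L):(b * band_px)
    npix <- H * band_px
    draws <- matrix(stats::rpois(npix * nt, rep(mu, each = npix)),
                    nrow = npix, ncol = nt)
    frames[, cols, ] <- array(draws, dim = c(H, band_px, nt))
  }
  rois <- lapply(seq_len(nbands), function(b) {
    m <- matrix(FALSE, H, W)
    m[, ((b - 1L) * band_px + 1L):(b * band_px)] <- TRUE
    m
  })
  names(rois) <- sprintf("B%d", seq_len(nbands))
  list(stack = image_stack(frames, frame_interval,
                           injection = nb$n_base,
                           discharge = nb$n_base + nb$n_post),
       rois = rois)
}
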