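# Miniscope imaging pipeline: rigid motion correction, pixel activity map,
# ROI trace extraction with ring-neuropil and affine-baseline correction, the
# isosbestic-regression photometry dF/F, and cross-session ROI matching.

#' Construct an ROI set
#'
#' ROI masks plus the calibration regions used for the neuropil correction
#' factor: a blood-vessel region, a nearby ROI-free tissue region, and an
#' off-lens region. Calibration regions must be disjoint from the ROIs.
#'
#' @param masks List of logical matrices (one per ROI, frame-sized).
#' @param vessel,near_vessel,off_lens Logical matrices (frame-sized).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, vessel = NULL, near_vessel = NULL, off_lens = NULL) {
  stopifnot(length(masks) >= 1)
  any_roi <- Reduce(`|`, masks)
  for (nm in c("vessel", "near_vessel", "off_lens")) {
    m <- get(nm)
    if (!is.null(m) && any(m & any_roi))
      stop("calibration region '", nm, "' overlaps an ROI")
  }
  structure(list(masks = masks, vessel = vessel, near_vessel = near_vessel,
                 off_lens = off_lens, any_roi = any_roi),
            class = "roi_set")
}

disc_brush <- function(r) EBImage::makeBrush(2 * as.integer(ceiling(r)) + 1, "disc")

#' Neuropil ring masks for an ROI set
#'
#' Per ROI: a ring of `width_um` starting `offset_um` outside the ROI
#' perimeter, excluding all ROI pixels (and, when given, the vessel and
#' off-lens regions). Geometry is converted to pixels via `px_size_um`.
#'
#' @param rois A `roi_set`.
#' @param px_size_um Pixel size (um/px), default 1.2.
#' @param offset_um Gap between ROI perimeter and ring (default 5 um).
#' @param width_um Ring width (default 10 um).
#' @return List of logical ring masks, one per ROI.
#' @export
make_neuropil_rings <- function(rois, px_size_um = 1.2, offset_um = 5,
                                width_um = 10) {
  off_px <- offset_um / px_size_um
  out_px <- (offset_um + width_um) / px_size_um
  # all ROIs are excluded with a small safety margin so somatic fluorescence
  # bleeding just beyond a neighbouring ROI's outline does not contaminate
  # the ring
  excl <- EBImage::dilate(rois$any_roi, disc_brush(2)) > 0
  lapply(seq_along(rois$masks), function(k) {
    m <- rois$masks[[k]]
    inner <- EBImage::dilate(m, disc_brush(off_px)) > 0
    outer <- EBImage::dilate(m, disc_brush(out_px)) > 0
    ring <- outer & !inner & !excl
    if (!is.null(rois$off_lens)) ring <- ring & !rois$off_lens
    if (!is.null(rois$vessel)) ring <- ring & !rois$vessel
    if (!any(ring)) stop("neuropil ring of ROI ", k, " is empty after exclusions")
    ring
  })
}

highpass_frame <- function(m, sigma = 4) m - EBImage::gblur(m, sigma = sigma)

#' Rigid motion correction by cross-correlation
#'
#' Builds a spatially high-pass stack (each frame minus a Gaussian-blurred
#' copy of itself), then estimates per frame the integer (dx, dy) shift
#' maximizing the circular cross-correlation with a high-pass reference frame
#' and applies the inverse shift to the raw stack. Frames whose best shift
#' hits the search bound are flagged and left unshifted.
#'
#' @param movie Array `x_px x y_px x frames`.
#' @param reference High-pass reference image (matrix); defaults to the
#'   high-pass of `movie[ , , reference_frame]`.
#' @param reference_frame Frame index used for the default reference.
#' @param max_shift Search bound (px), default 6.
#' @param highpass_sigma Gaussian sigma of the spatial low-pass (px).
#' @return List: `movie` (corrected), `shifts` (data.frame dx, dy, flagged).
#' @export
motion_correct <- function(movie, reference = NULL, reference_frame = 1,
                           max_shift = 6, highpass_sigma = 4) {
  d <- dim(movie)
  if (is.null(reference))
    reference <- highpass_frame(movie[, , reference_frame], highpass_sigma)
  Fr <- Conj(fft(reference))
  nr <- d[1]; nc <- d[2]
  ok_dx <- c(0:max_shift, (nr - max_shift):(nr - 1))
  ok_dy <- c(0:max_shift, (nc - max_shift):(nc - 1))
  dx <- integer(d[3]); dy <- integer(d[3]); flagged <- logical(d[3])
  out <- movie
  for (i in seq_len(d[3])) {
    hp <- highpass_frame(movie[, , i], highpass_sigma)
    cc <- Re(fft(fft(hp) * Fr, inverse = TRUE))
    sub <- cc[ok_dx + 1, ok_dy + 1]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    sx <- ok_dx[w[1]]; sy <- ok_dy[w[2]]
    if (sx > nr / 2) sx <- sx - nr
    if (sy > nc / 2) sy <- sy - nc
    if (abs(sx) >= max_shift || abs(sy) >= max_shift) {
      flagged[i] <- TRUE
    } else {
      dx[i] <- sx; dy[i] <- sy
      if (sx != 0 || sy != 0) out[, , i] <- roll_matrix(movie[, , i], -sx, -sy)
    }
  }
  list(movie = out, shifts = data.frame(dx = dx, dy = dy, flagged = flagged))
}

box2 <- function(m) {
  # 2x2 box filter: mean of the pixel and its +x/+y neighbours (shrinking at
  # the far edges)
  nr <- nrow(m); nc <- ncol(m)
  xp <- m[c(2:nr, nr), ]; yp <- m[, c(2:nc, nc)]; xyp <- m[c(2:nr, nr), c(2:nc, nc)]
  (m + xp + yp + xyp) / 4
}

#' Pixel activity map
#'
#' Highlights pixels with strong temporal intensity variation: per frame the
#' normalized deviation `(f - fbar) / (fbar + f_avg)` (fbar = pixel temporal
#' mean, f_avg = grand mean), spatially smoothed with a 2x2 box filter, then
#' aggregated over time by the mean magnitude. (A plain temporal mean of the
#' deviation is identically zero, so the magnitude is what carries the map.)
#'
#' @param movie Array `x_px x y_px x frames`.
#' @return Matrix `x_px x y_px` (the activity map).
#' @export
activity_map <- function(movie) {
  d <- dim(movie)
  if (d[3] == 1) return(matrix(0, d[1], d[2]))
  flat <- matrix(movie, d[1] * d[2], d[3])
  fbar <- rowMeans(flat)
  favg <- mean(flat)
  acc <- matrix(0, d[1], d[2])
  denom <- matrix(fbar + favg, d[1], d[2])
  fbar_m <- matrix(fbar, d[1], d[2])
  for (i in seq_len(d[3])) {
    dev <- (movie[, , i] - fbar_m) / denom
    acc <- acc + abs(box2(dev))
  }
  acc / d[3]
}

#' Extract neuropil- and baseline-corrected dF/F traces
#'
#' Per ROI: the raw trace F(t) is the mean over ROI pixels per frame, the
#' neuropil trace F_np(t) the mean over the bordering ring. The session
#' correction factor c = (F_vessel - F_offlens) / (F_nearvessel - F_offlens)
#' (mean pixel intensities) scales the subtraction F_subt = F - c * F_np.
#' The baseline B(t) is the affine fit to F_subt samples at or below the
#' session 20th percentile, and dF/F = (F_subt - B) / B.
#'
#' @param movie Motion-corrected array `x_px x y_px x frames`.
#' @param rois A `roi_set` with calibration regions.
#' @param fs Frame rate (Hz).
#' @param px_size_um Pixel size for the ring geometry (um/px).
#' @param c_override Optional fixed correction factor (skips calibration).
#' @param baseline_quantile Low-activity quantile for the baseline fit (0.2).
#' @return List of class `roi_trace_set`: matrices `F`, `F_np`, `F_subt`,
#'   `B`, `dff` (ROIs x frames), scalar `c`, `fs`, `rings`.
#' @export
extract_dff <- function(movie, rois, fs, px_size_um = 1.2, c_override = NULL,
                        baseline_quantile = 0.2) {
  d <- dim(movie)
  flat <- matrix(movie, d[1] * d[2], d[3])
  rings <- make_neuropil_rings(rois, px_size_um)
  K <- length(rois$masks)
  cc <- c_override
  if (is.null(cc)) {
    if (is.null(rois$vessel) || is.null(rois$near_vessel) || is.null(rois$off_lens))
      stop("calibration regions (vessel, near_vessel, off_lens) are required")
    f_bv <- mean(flat[as.logical(rois$vessel), ])
    f_nbv <- mean(flat[as.logical(rois$near_vessel), ])
    f_off <- mean(flat[as.logical(rois$off_lens), ])
    cc <- (f_bv - f_off) / (f_nbv - f_off)
    if (cc <= 0 || cc >= 1.5)
      warning(sprintf("implausible neuropil correction factor c = %.3f", cc))
  }
  Fm <- t(vapply(rois$masks, function(m) colMeans(flat[as.logical(m), , drop = FALSE]),
                 numeric(d[3])))
  Fnp <- t(vapply(rings, function(m) colMeans(flat[as.logical(m), , drop = FALSE]),
                  numeric(d[3])))
  Fsub <- Fm - cc * Fnp
  tt <- (seq_len(d[3]) - 1) / fs
  B <- matrix(0, K, d[3])
  for (k in seq_len(K)) {
    thr <- quantile(Fsub[k, ], baseline_quantile, names = FALSE)
    sel <- Fsub[k, ] <= thr
    fit <- lm(y ~ t, data = data.frame(y = Fsub[k, sel], t = tt[sel]))
    B[k, ] <- coef(fit)[1] + coef(fit)[2] * tt
  }
  structure(list(F = Fm, F_np = Fnp, F_subt = Fsub, B = B,
                 dff = (Fsub - B) / B, c = cc, fs = fs, rings = rings),
            class = "roi_trace_set")
}

#' Fiber-photometry dF/F via isosbestic regression
#'
#' Both channels are low-pass filtered at 2 Hz (4th-order zero-phase
#' Butterworth); the 405 nm (calcium-independent) channel is fitted to the
#' 465 nm channel by linear regression; dF/F = (465 - fit) / fit. Bleaching
#' and shared motion artifacts cancel because they load on both channels.
#'
#' @param f465,f405 Numeric traces (same length).
#' @param fs Sampling rate (Hz).
#' @return List: `dff`, `fit`, `coef` (intercept, slope).
#' @export
photometry_dff <- function(f465, f405, fs) {
  stopifnot(length(f465) == length(f405))
  if (sd(f405) < 1e-9 * max(1, abs(mean(f405))))
    stop("405 nm channel is constant; isosbestic fit is degenerate")
  l465 <- lowpass_filter(f465, fs, 2)
  l405 <- lowpass_filter(f405, fs, 2)
  fit <- lm(y ~ x, data = data.frame(y = l465, x = l405))
  fv <- as.numeric(predict(fit))
  list(dff = (l465 - fv) / fv, fit = fv, coef = coef(fit))
}

rotate_mask <- function(m, deg) {
  if (deg == 0) return(m)
  th <- deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  gx <- matrix(seq_len(nr), nr, nc); gy <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # inverse mapping, nearest neighbour
  sx <- round(cx + cos(th) * (gx - cx) + sin(th) * (gy - cy))
  sy <- round(cy - sin(th) * (gx - cx) + cos(th) * (gy - cy))
  ok <- sx >= 1 & sx <= nr & sy >= 1 & sy <= nc
  out <- matrix(FALSE, nr, nc)
  out[ok] <- m[cbind(sx[ok], sy[ok])]
  out
}

shift_mask <- function(m, dx, dy) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)) - dx; ys <- seq_len(ncol(m)) - dy
  okx <- xs >= 1 & xs <= nrow(m); oky <- ys >= 1 & ys <= ncol(m)
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Match ROIs across two imaging sessions
#'
#' Finds the rigid transform (rotation + integer translation) of session B's
#' ROI map that maximizes total overlap with session A's map (coarse grid
#' search, then local refinement), then matches ROI pairs whose overlap is at
#' least `min_overlap` of the smaller ROI, greedily one-to-one by overlap.
#'
#' @param rois_a,rois_b `roi_set` objects on frames of equal size.
#' @param rot_deg Candidate rotations (degrees), default -10 ... 10 by 2.
#' @param max_shift_px Translation search bound, default 10.
#' @param min_overlap Overlap fraction of the smaller ROI (default 0.5).
#' @return List: `pairs` (data.frame a, b, overlap_frac), `transform`
#'   (list rot_deg, dx, dy), `score` (total overlapping pixels).
#' @export
match_rois <- function(rois_a, rois_b, rot_deg = seq(-10, 10, by = 2),
                       max_shift_px = 10, min_overlap = 0.5) {
  A <- rois_a$any_roi
  best <- list(score = 0, rot = 0, dx = 0, dy = 0)
  # (dx, dy) is B's displacement relative to A, so aligning B onto A applies
  # the inverse shift
  score_of <- function(Bt, dx, dy) sum(A & shift_mask(Bt, -dx, -dy))
  for (r in rot_deg) {
    Bt <- rotate_mask(rois_b$any_roi, r)
    # translation via cross-correlation of the binary maps
    cc <- Re(fft(fft(A * 1) * Conj(fft(Bt * 1)), inverse = TRUE))
    nr <- nrow(A); nc <- ncol(A)
    for (dx in -max_shift_px:max_shift_px) for (dy in -max_shift_px:max_shift_px) {
      # cc index s corresponds to B shifted by +s matching A
      s <- cc[((-dx) %% nr) + 1, ((-dy) %% nc) + 1] / (nr * nc)
      if (s > best$score) best <- list(score = s, rot = r, dx = dx, dy = dy)
    }
  }
  # local refinement at 1 degree around the coarse optimum
  base <- best
  for (r in base$rot + c(-1, 0, 1)) {
    Bt <- rotate_mask(rois_b$any_roi, r)
    for (dx in base$dx + -1:1) for (dy in base$dy + -1:1) {
      s <- score_of(Bt, dx, dy)
      if (s > best$score) best <- list(score = s, rot = r, dx = dx, dy = dy)
    }
  }
  if (best$score == 0)
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   overlap_frac = numeric(0)),
                transform = list(rot_deg = 0, dx = 0, dy = 0), score = 0))
  b_masks <- lapply(rois_b$masks, function(m)
    shift_mask(rotate_mask(m, best$rot), -best$dx, -best$dy))
  cand <- list()
  for (i in seq_along(rois_a$masks)) for (j in seq_along(b_masks)) {
    ov <- sum(rois_a$masks[[i]] & b_masks[[j]])
    if (ov == 0) next
    frac <- ov / min(sum(rois_a$masks[[i]]), sum(b_masks[[j]]))
    if (frac >= min_overlap)
      cand[[length(cand) + 1]] <- data.frame(a = i, b = j, overlap_frac = frac)
  }
  pairs <- data.frame(a = integer(0), b = integer(0), overlap_frac = numeric(0))
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$overlap_frac), ]
    used_a <- used_b <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (cand$a[i] %in% used_a || cand$b[i] %in% used_b) next
      pairs <- rbind(pairs, cand[i, ])
      used_a <- c(used_a, cand$a[i]); used_b <- c(used_b, cand$b[i])
    }
  }
  list(pairs = pairs,
       transform = list(rot_deg = best$rot, dx = best$dx, dy = best$dy),
       score = best$score)
}

#' Read / write ROI sets as labeled-matrix CSV
#'
#' On-disk form: an integer matrix (rows x cols, no header) where 0 is
#' background, 1..K are ROI labels, and the reserved labels -1, -2, -3 mark
#' the blood-vessel, near-vessel and off-lens calibration regions.
#'
#' @param path CSV path.
#' @return A `roi_set`.
#' @export
read_roi_masks_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  K <- max(m)
  if (K < 1) stop("no ROI labels (>= 1) found in ", path)
  roi_set(lapply(seq_len(K), function(k) m == k),
          vessel = if (any(m == -1)) m == -1 else NULL,
          near_vessel = if (any(m == -2)) m == -2 else NULL,
          off_lens = if (any(m == -3)) m == -3 else NULL)
}

#' @rdname read_roi_masks_csv
#' @param rois A `roi_set`.
#' @export
write_roi_masks_csv <- function(rois, path) {
  m <- matrix(0L, nrow(rois$masks[[1]]), ncol(rois$masks[[1]]))
  for (k in seq_along(rois$masks)) m[rois$masks[[k]]] <- k
  if (!is.null(rois$vessel)) m[rois$vessel] <- -1L
  if (!is.null(rois$near_vessel)) m[rois$near_vessel] <- -2L
  if (!is.null(rois$off_lens)) m[rois$off_lens] <- -3L
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Seed ROI masks from an activity map
#'
#' Helper for synthetic pipelines (manual polygon drawing is out of scope):
#' local maxima of the activity map above a quantile threshold become disk
#' ROIs of fixed radius.
#'
#' @param map Activity map matrix.
#' @param radius_px Disk radius (default 3).
#' @param threshold_quantile Minimum map quantile for a seed (default 0.97).
#' @param min_sep_px Minimum separation between seeds (default 6).
#' @return List of logical masks.
#' @export
seed_rois_from_map <- function(map, radius_px = 3, threshold_quantile = 0.97,
                               min_sep_px = 6) {
  thr <- quantile(map, threshold_quantile, names = FALSE)
  ord <- order(map, decreasing = TRUE)
  nr <- nrow(map); nc <- ncol(map)
  centers <- matrix(numeric(0), 0, 2)
  for (o in ord) {
    if (map[o] < thr) break
    x <- (o - 1) %% nr + 1; y <- (o - 1) %/% nr + 1
    if (nrow(centers) > 0 &&
        min(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2)) < min_sep_px) next
    centers <- rbind(centers, c(x, y))
  }
  gx <- matrix(seq_len(nr), nr, nc); gy <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lapply(seq_len(nrow(centers)), function(k)
    (gx - centers[k, 1])^2 + (gy - centers[k, 2])^2 <= radius_px^2)
}
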