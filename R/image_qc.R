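# Post-processing of cine label maps and valve-landmark tracks: connected
# component filtering, hole filling, dice-based slice rejection, landmark
# outlier repair and temporal smoothing, and label-to-contour extraction with
# the RV-epicardial offset.

#' Dice overlap score of two binary masks
#'
#' 2|A n B| / (|A| + |B|); defined as 1 when both masks are empty.
#' @param maskA,maskB logical (or 0/1) matrices of identical shape.
#' @return score in [0, 1].
#' @export
dice_score <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop("input error: mask shapes differ")
  a <- as.logical(maskA); b <- as.logical(maskB)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Clean a 2-D label image
#'
#' Applies the stated label post-processing rules: (a) per class, 4-connected
#' components with fewer than \code{min_pixels} pixels are set to background
#' (strictly fewer: a component of exactly \code{min_pixels} is kept);
#' (b) interior holes — background components not touching the image border —
#' are filled with the enclosing class (majority vote over the hole's
#' perimeter neighbours when several classes enclose it).
#'
#' @param img integer matrix of class codes (0 = background, see
#'   \code{LABEL_CLASSES}); attributes are preserved.
#' @param min_pixels island-removal threshold (default 50).
#' @return cleaned label image.
#' @export
clean_label_image <- function(img, min_pixels = 50) {
  out <- img
  for (cls in setdiff(sort(unique(as.vector(img))), 0L)) {
    lab <- cpp_label_components(img == cls)
    sizes <- tabulate(lab[lab > 0])
    kill <- which(sizes < min_pixels)
    if (length(kill)) out[lab %in% kill] <- 0L
  }
  # hole filling on the cleaned map
  bg <- cpp_label_components(out == 0L)
  nr <- nrow(out); nc <- ncol(out)
  border_ids <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  hole_ids <- setdiff(unique(bg[bg > 0]), border_ids)
  for (hid in hole_ids) {
    px <- which(bg == hid, arr.ind = TRUE)
    # perimeter neighbours
    neigh <- rbind(cbind(px[, 1] - 1, px[, 2]), cbind(px[, 1] + 1, px[, 2]),
                   cbind(px[, 1], px[, 2] - 1), cbind(px[, 1], px[, 2] + 1))
    neigh <- neigh[neigh[, 1] >= 1 & neigh[, 1] <= nr &
                   neigh[, 2] >= 1 & neigh[, 2] <= nc, , drop = FALSE]
    vals <- out[neigh]
    vals <- vals[vals != 0L]
    if (!length(vals)) next
    fill <- as.integer(names(sort(table(vals), decreasing = TRUE))[1])
    out[bg == hid] <- fill
  }
  attributes(out) <- attributes(img)
  out
}

#' Repair a valve-landmark track
#'
#' Landmarks are detected frame-by-frame, so individual frames fail in two
#' ways: a missing detection carrying the [0,0] sentinel, and an outlier
#' jump. A point is flagged when it equals the sentinel or its distance from
#' the landmark's temporal median position exceeds
#' \code{max(3 x 1.4826 x MAD, outlier_mm)}. Flagged frames are linearly
#' interpolated in time with periodic extension, then each coordinate is
#' smoothed with a zero-phase periodic low-pass filter (Fourier truncation at
#' \code{cutoff} cycles per cardiac cycle; exact unit DC gain).
#'
#' @param coords (n_frames x n_landmarks x 2) array; the last frame may
#'   repeat the first (periodic sampling) — it is treated as such when it
#'   does.
#' @param spacing mm per coordinate unit (default 1: coordinates in mm).
#' @param outlier_mm absolute outlier floor, mm (default 10).
#' @param cutoff low-pass cutoff in cycles per cardiac cycle (default 10).
#' @return list: \code{coords} (repaired array), \code{flagged} (logical
#'   n_frames x n_landmarks).
#' @export
repair_landmark_track <- function(coords, spacing = 1, outlier_mm = 10,
                                  cutoff = 10) {
  dims <- dim(coords)
  nf <- dims[1]; nl <- dims[2]
  periodic_dup <- nf > 2 && all(coords[nf, , ] == coords[1, , ])
  n <- if (periodic_dup) nf - 1 else nf
  flagged <- matrix(FALSE, nf, nl)
  out <- coords
  for (l in seq_len(nl)) {
    p <- coords[1:n, l, , drop = TRUE]
    sentinel <- p[, 1] == 0 & p[, 2] == 0
    med <- c(median(p[!sentinel, 1]), median(p[!sentinel, 2]))
    di <- sqrt((p[, 1] - med[1])^2 + (p[, 2] - med[2])^2) * spacing
    thr <- max(3 * 1.4826 * mad(di[!sentinel], constant = 1), outlier_mm)
    bad <- sentinel | di > thr
    if (sum(!bad) < 3)
      stop("unrecoverable track: landmark ", l, " has fewer than 3 valid frames")
    flagged[1:n, l] <- bad
    for (d in 1:2) {
      x <- p[, d]
      if (any(bad)) {
        # periodic linear interpolation across flagged frames
        idx <- which(!bad)
        xx <- c(idx - n, idx, idx + n)
        yy <- rep(x[idx], 3)
        x[bad] <- approx(xx, yy, xout = which(bad))$y
      }
      # zero-phase periodic low-pass: truncate harmonics above the cutoff
      X <- fft(x)
      k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
      X[abs(k) > cutoff] <- 0
      out[1:n, l, d] <- Re(fft(X, inverse = TRUE)) / n
    }
    if (periodic_dup) {
      out[nf, l, ] <- out[1, l, ]
      flagged[nf, l] <- flagged[1, l]
    }
  }
  list(coords = out, flagged = flagged)
}

#' Plane geometry of a 2-D image slice
#'
#' Maps pixel indices (i, j), 1-based at pixel centres, to 3-D positions
#' \code{origin + (i-1) spacing e1 + (j-1) spacing e2}.
#' @param origin 3-vector, mm. @param e1,e2 orthonormal in-plane axes.
#' @param spacing mm/pixel.
#' @export
plane_geometry <- function(origin, e1, e2, spacing) {
  e1 <- e1 / sqrt(sum(e1^2)); e2 <- e2 / sqrt(sum(e2^2))
  list(origin = origin, e1 = e1, e2 = e2, spacing = spacing,
       normal = c(e1[2] * e2[3] - e1[3] * e2[2],
                  e1[3] * e2[1] - e1[1] * e2[3],
                  e1[1] * e2[2] - e1[2] * e2[1]))
}

.pix_to_3d <- function(i, j, pg) {
  sweep(outer(i - 1, pg$e1) * pg$spacing + outer(j - 1, pg$e2) * pg$spacing,
        2, pg$origin, "+")
}

#' Dice score along the intersection line of two slices
#'
#' Rasterises both masks onto their common 3-D intersection line and returns
#' the dice overlap of the sampled in-mask indicators. Slices scoring below
#' \code{reject_below} are marked rejected.
#'
#' @param maskA,maskB binary masks.
#' @param pgA,pgB \code{\link{plane_geometry}} of each mask.
#' @param step_mm sampling step along the line.
#' @param reject_below rejection threshold (default 0.5).
#' @return list(score, rejected).
#' @export
intersection_dice <- function(maskA, maskB, pgA, pgB, step_mm = 1,
                              reject_below = 0.5) {
  d <- c(pgA$normal[2] * pgB$normal[3] - pgA$normal[3] * pgB$normal[2],
         pgA$normal[3] * pgB$normal[1] - pgA$normal[1] * pgB$normal[3],
         pgA$normal[1] * pgB$normal[2] - pgA$normal[2] * pgB$normal[1])
  if (sqrt(sum(d^2)) < 1e-9)
    stop("undefined-score error: slice planes are parallel")
  d <- d / sqrt(sum(d^2))
  # a point on the line: solve the two plane equations
  A <- rbind(pgA$normal, pgB$normal, d)
  b <- c(sum(pgA$normal * pgA$origin), sum(pgB$normal * pgB$origin), 0)
  p0 <- solve(A, b)
  ext <- max(dim(maskA)) * pgA$spacing + max(dim(maskB)) * pgB$spacing
  t <- seq(-ext, ext, by = step_mm)
  pts <- outer(t, d) + matrix(p0, length(t), 3, byrow = TRUE)
  sample_mask <- function(mask, pg) {
    rel <- sweep(pts, 2, pg$origin, "-")
    i <- round(rel %*% pg$e1 / pg$spacing) + 1
    j <- round(rel %*% pg$e2 / pg$spacing) + 1
    ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
    v <- logical(length(t))
    v[ok] <- mask[cbind(i[ok], j[ok])]
    v
  }
  a <- sample_mask(maskA != 0, pgA)
  b2 <- sample_mask(maskB != 0, pgB)
  sc <- if (sum(a) + sum(b2) == 0) 1 else 2 * sum(a & b2) / (sum(a) + sum(b2))
  list(score = sc, rejected = sc < reject_below)
}

# ordered boundary contour(s) of a binary mask, in pixel coordinates
.mask_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask
  cl <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1), z = z,
                                levels = 0.5)
  lapply(cl, function(c0) cbind(i = c0$x, j = c0$y))
}

#' Offset a closed contour along its outward normal
#'
#' Normals are computed from the (ordered) point tangents and oriented away
#' from the contour centroid; point count and orientation are preserved.
#' @param pts n x 2 ordered points (closed: first != last is fine).
#' @param dist offset distance (same units as pts; positive = outward).
#' @return n x 2 offset points.
#' @export
offset_contour <- function(pts, dist) {
  n <- nrow(pts)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  tang <- pts[nxt, ] - pts[prv, ]
  nrm <- cbind(tang[, 2], -tang[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  cen <- colMeans(pts)
  flip <- rowSums(nrm * sweep(pts, 2, cen, "-")) < 0
  nrm[flip, ] <- -nrm[flip, ]
  pts + dist * nrm
}

#' Extract labelled contours from a (cleaned) label image
#'
#' Boundary tracing yields: \code{lv_endo} (LV blood-pool boundary),
#' \code{lv_epi} (outer boundary of blood pool plus myocardium),
#' \code{rv_septum} and \code{rv_freewall} (RV blood-pool boundary split at
#' the junctions with the LV myocardium; the two split points are returned
#' as \code{rv_insertion}), and \code{rv_epi} generated by offsetting the
#' free-wall contour 3 mm along its outward normal (no RV myocardium label
#' exists in the data). Contour weights are the slice's intersection-dice
#' score (0 for rejected slices).
#'
#' @param img label image (class codes per \code{LABEL_CLASSES}).
#' @param pg \code{\link{plane_geometry}} of the slice.
#' @param dice_weight slice weight from dice scoring in [0,1] (default 1);
#'   slices with \code{dice_weight < reject_below} get weight 0.
#' @param rv_epi_offset_mm free-wall offset distance (default 3).
#' @param slice_id,frame identifiers copied to the output.
#' @param reject_below dice rejection threshold.
#' @return data.frame with x, y, z (mm), label, weight, slice_id, frame.
#' @export
labels_to_contours <- function(img, pg, dice_weight = 1, rv_epi_offset_mm = 3,
                               slice_id = 1L, frame = 1L, reject_below = 0.5) {
  cls <- LABEL_CLASSES
  if (!any(img == cls[["lv_myo"]])) {
    warning("slice ", slice_id, " has no myocardium label; skipped")
    return(NULL)
  }
  w <- if (dice_weight < reject_below) 0 else dice_weight
  res <- list()
  emit <- function(pts_px, label) {
    if (is.null(pts_px) || nrow(pts_px) < 3) return()
    p3 <- .pix_to_3d(pts_px[, 1], pts_px[, 2], pg)
    res[[length(res) + 1]] <<- data.frame(
      x = p3[, 1], y = p3[, 2], z = p3[, 3], label = label, weight = w,
      slice_id = slice_id, frame = frame)
  }
  lv_bp <- img == cls[["lv_bp"]]
  myo <- img == cls[["lv_myo"]]
  rv_bp <- img == cls[["rv_bp"]]
  ce <- .mask_contours(lv_bp)
  if (length(ce)) emit(ce[[which.max(vapply(ce, nrow, 1))]], "lv_endo")
  cp <- .mask_contours(lv_bp | myo)
  if (length(cp)) emit(cp[[which.max(vapply(cp, nrow, 1))]], "lv_epi")
  cr <- .mask_contours(rv_bp)
  if (length(cr)) {
    rvb <- cr[[which.max(vapply(cr, nrow, 1))]]
    # septal points lie within ~2 px of the myocardium
    myo_px <- which(myo, arr.ind = TRUE)
    near_myo <- vapply(seq_len(nrow(rvb)), function(q) {
      min((myo_px[, 1] - rvb[q, 1])^2 + (myo_px[, 2] - rvb[q, 2])^2) <= 4
    }, logical(1))
    emit(rvb[near_myo, , drop = FALSE], "rv_septum")
    fw <- rvb[!near_myo, , drop = FALSE]
    emit(fw, "rv_freewall")
    # insertion points: transitions between the two segments
    tr <- which(near_myo != c(near_myo[-1], near_myo[1]))
    if (length(tr) >= 2) {
      ins <- rbind(rvb[tr[1], ], rvb[tr[length(tr)], ], rvb[tr[1], ])
      emit(ins, "rv_insertion")
    }
    if (nrow(fw) >= 3) {
      # offset the free wall outward; contiguous run assumed after reordering
      fw_off <- offset_contour_open(rvb, near_myo, rv_epi_offset_mm / pg$spacing)
      emit(fw_off, "rv_epi")
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# offset only the free-wall (non-septal) part of the closed RV boundary,
# outward from the full contour's centroid
offset_contour_open <- function(rvb, near_myo, dist_px) {
  off <- offset_contour(rvb, dist_px)
  off[!near_myo, , drop = FALSE]
}

#' Apply label QC and contour generation to an image stack
#'
#' Convenience wrapper: cleans each slice, scores it against a reference
#' (optional), and concatenates contours.
#' @param images list of label images.
#' @param pgs list of \code{\link{plane_geometry}}, one per slice.
#' @param dice_weights numeric vector of slice weights (default all 1).
#' @param ... passed to \code{\link{labels_to_contours}}.
#' @export
stack_to_contours <- function(images, pgs, dice_weights = NULL, ...) {
  if (is.null(dice_weights)) dice_weights <- rep(1, length(images))
  out <- lapply(seq_along(images), function(s)
    labels_to_contours(clean_label_image(images[[s]]), pgs[[s]],
                       dice_weight = dice_weights[s], slice_id = s, ...))
  do.call(rbind, out)
}

#' Read / write label images as NIfTI
#' @param img label matrix with a `spacing` attribute (mm/px).
#' @param path file path (.nii or .nii.gz is written uncompressed as .nii).
#' @export
write_label_nifti <- function(img, path) {
  sp <- attr(img, "spacing"); if (is.null(sp)) sp <- 1
  arr <- structure(array(as.integer(img), dim = c(dim(img), 1)),
                   pixdim = c(sp, sp, 1))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_label_nifti
#' @export
read_label_nifti <- function(path) {
  x <- RNifti::readNifti(path)
  arr <- as.array(x)
  if (length(dim(arr)) > 2) arr <- arr[, , 1]
  img <- matrix(as.integer(arr), dim(arr)[1], dim(arr)[2])
  attr(img, "spacing") <- RNifti::pixdim(x)[1]
  img
}
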