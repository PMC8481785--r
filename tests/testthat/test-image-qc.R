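# Label cleaning, landmark repair, dice scoring and contour extraction.

test_that("island removal applies the strict fewer-than-50-pixel rule", {
  img <- matrix(0L, 80, 80)
  img[30:50, 30:50] <- 2L                  # large myocardium block
  img[5:11, 5:11] <- 1L                    # 49-pixel island
  stopifnot(sum(img == 1L) == 49)
  img[60:69, 70:74] <- 3L                  # 50-pixel island
  stopifnot(sum(img == 3L) == 50)
  cl <- clean_label_image(img)
  expect_equal(sum(cl == 1L), 0)           # removed
  expect_equal(sum(cl == 3L), 50)          # kept (exactly 50)
  expect_equal(sum(cl == 2L), sum(img == 2L))
})

test_that("interior holes are filled with the enclosing class", {
  img <- matrix(0L, 60, 60)
  img[20:40, 20:40] <- 2L
  img[29:31, 29:31] <- 0L                  # 9-px interior hole
  cl <- clean_label_image(img)
  expect_true(all(cl[29:31, 29:31] == 2L))
  # cleaning is idempotent
  expect_identical(clean_label_image(cl), cl)
})

test_that("dice score implements 2|AnB|/(|A|+|B|) with symmetric edge cases", {
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
  B <- matrix(FALSE, 20, 20); B[6:15, 1:10] <- TRUE
  expect_equal(dice_score(A, A), 1)
  expect_equal(dice_score(A, !A & FALSE), 0)
  expect_equal(dice_score(A, B), 2 * 50 / 200)
  expect_equal(dice_score(A, B), dice_score(B, A))
  expect_equal(dice_score(A & FALSE, B & FALSE), 1)   # both empty
  expect_error(dice_score(A, matrix(FALSE, 10, 10)), "shapes differ")
})

test_that("landmark repair interpolates, filters and flags as specified", {
  # linear midpoint example: missing frame between 0 mm and 2 mm
  n <- 20
  coords <- array(0, c(n, 1, 2))
  coords[, 1, 1] <- 50 + sin(2 * pi * (0:(n - 1)) / n)
  coords[, 1, 2] <- 60
  c2 <- coords
  c2[5, 1, ] <- c(0, 0)                    # sentinel
  rep <- repair_landmark_track(c2)
  expect_true(rep$flagged[5, 1])
  mid <- (coords[4, 1, 1] + coords[6, 1, 1]) / 2
  # interpolated value then lightly low-passed; the single harmonic passes
  expect_lt(abs(rep$coords[5, 1, 1] - mid), 0.05)
  # constant (DC) track is invariant under the low-pass filter
  cc <- array(7, c(n, 1, 2))
  rc <- repair_landmark_track(cc)
  expect_lt(max(abs(rc$coords - 7)), 1e-9)
  # injected 20 mm jump on a constant track is repaired to within 0.5 mm
  cj <- array(30, c(n, 1, 2))
  cj[8, 1, 1] <- 50
  rj <- repair_landmark_track(cj)
  expect_true(rj$flagged[8, 1])
  expect_lt(max(abs(rj$coords - 30)), 0.5)
  # fewer than 3 valid frames is unrecoverable
  cbad <- array(0, c(5, 1, 2)); cbad[1, 1, ] <- c(1, 1); cbad[2, 1, ] <- c(2, 2)
  expect_error(repair_landmark_track(cbad), "unrecoverable")
})

test_that("fixture corruptions are flagged at the specified rates", {
  fx <- generate_synthetic_labels_and_landmarks(seed = 1)
  rep <- repair_landmark_track(fx$landmarks, spacing = fx$spacing)
  inj <- rbind(fx$outlier_index, fx$missing_index)
  expect_gte(mean(rep$flagged[inj]), 0.95)
  clean_flags <- rep$flagged
  clean_flags[inj] <- FALSE
  expect_lte(mean(clean_flags), 0.02)
  expect_lt(max(abs(rep$coords - fx$landmarks_clean)) * fx$spacing, 0.6)
})

test_that("intersection dice scores and rejects slices", {
  pgA <- plane_geometry(c(0, -25, 0), c(1, 0, 0), c(0, 1, 0), 1)
  pgB <- plane_geometry(c(0, 0, -25), c(1, 0, 0), c(0, 0, 1), 1)
  mA <- matrix(FALSE, 50, 50); mA[10:30, 20:32] <- TRUE
  mB <- mA
  expect_equal(intersection_dice(mA, mB, pgA, pgB)$score, 1)
  mB2 <- matrix(FALSE, 50, 50); mB2[32:45, 20:32] <- TRUE
  d <- intersection_dice(mA, mB2, pgA, pgB)
  expect_equal(d$score, 0)
  expect_true(d$rejected)
  mB3 <- matrix(FALSE, 50, 50); mB3[20:40, 20:32] <- TRUE
  expect_equal(intersection_dice(mA, mB3, pgA, pgB)$score, 2 * 11 / 42,
               tolerance = 0.05)
  expect_error(intersection_dice(mA, mB, pgA, pgA), "parallel")
})

test_that("contour offset moves a circle radially by the offset distance", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- cbind(20 * cos(th), 20 * sin(th))
  off <- offset_contour(circ, 3)
  r <- sqrt(rowSums(off^2))
  expect_lt(max(abs(r - 23)), 0.2)
  expect_equal(nrow(off), nrow(circ))          # point count preserved
  # orientation preserved (same signed area sign)
  sa <- function(p) sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2])
  expect_equal(sign(sa(off)), sign(sa(circ)))
})

test_that("label-to-contour extraction yields all labelled contours", {
  fx <- generate_synthetic_labels_and_landmarks(seed = 4)
  img <- clean_label_image(fx$images[[2]])
  n <- nrow(img); half <- n * fx$spacing / 2
  pg <- plane_geometry(c(-half + fx$spacing / 2, -half + fx$spacing / 2,
                         fx$slice_z[2]), c(1, 0, 0), c(0, 1, 0), fx$spacing)
  ct <- labels_to_contours(img, pg, slice_id = 2)
  expect_true(all(c("lv_endo", "lv_epi", "rv_septum", "rv_freewall", "rv_epi")
                  %in% ct$label))
  # cavity cross-section area within 5% of the analytic ellipse section
  g <- fx$geom
  az <- g$lv_a * sqrt(1 - (fx$slice_z[2] / g$lv_c)^2)
  lv <- ct[ct$label == "lv_endo", ]
  A <- abs(sum(lv$x * c(lv$y[-1], lv$y[1]) - c(lv$x[-1], lv$x[1]) * lv$y)) / 2
  expect_lt(abs(A / (pi * az^2) - 1), 0.05)
  # rejected slice contributes zero-weight contours
  ct0 <- labels_to_contours(img, pg, dice_weight = 0.4, slice_id = 2)
  expect_true(all(ct0$weight == 0))
  # a slice without myocardium is skipped with a warning
  blank <- matrix(0L, 20, 20)
  expect_warning(out <- labels_to_contours(blank, pg), "skipped")
  expect_null(out)
})

test_that("label images survive a NIfTI round trip", {
  fx <- generate_synthetic_labels_and_landmarks(seed = 5)
  path <- tempfile(fileext = ".nii")
  write_label_nifti(fx$images[[1]], path)
  back <- read_label_nifti(path)
  expect_equal(unclass(back)[, ], unclass(fx$images[[1]])[, ])
  expect_equal(attr(back, "spacing"), fx$spacing)
  unlink(path)
})
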