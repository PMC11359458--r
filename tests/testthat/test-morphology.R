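test_that("binary erosion and dilation equal their set definitions", {
  full <- binary_mask(matrix(255, 6, 6))
  er <- unclass(erode(full, square_se(3)))
  expect_true(all(er[2:5, 2:5] == 255))
  expect_true(all(er[c(1, 6), ] == 0) && all(er[, c(1, 6)] == 0))  # border strip

  single <- matrix(0, 5, 5); single[3, 3] <- 255
  expect_true(all(unclass(erode(binary_mask(single), square_se(3))) == 0))
  di <- unclass(dilate(binary_mask(single), square_se(3)))
  expect_identical(di[2:4, 2:4], matrix(255, 3, 3))
  expect_equal(sum(di == 255), 9)

  empty <- binary_mask(matrix(0, 5, 5))
  expect_true(all(unclass(dilate(empty, disk_se(2))) == 0))

  m <- rand_mask(10, 10, 4)
  off <- disk_se(2)$offsets
  expect_identical(unclass(erode(m, disk_se(2))), oracle_bin_erode(m, off))
  expect_identical(unclass(dilate(m, disk_se(2))), oracle_bin_dilate(m, off))

  expect_error(erode(m, structure(list(offsets = matrix(0, 0, 2), kind = "x"),
                                  class = "structuring_element")),
               "empty footprint")
})

test_that("morphology oracle equivalence holds across random masks and elements", {
  for (seed in c(1, 13, 77)) {
    m <- rand_mask(12, 16, seed, p = 0.35)
    for (se in list(disk_se(1), disk_se(2), square_se(3), cross_se())) {
      expect_identical(unclass(erode(m, se)), oracle_bin_erode(m, se$offsets))
      expect_identical(unclass(dilate(m, se)), oracle_bin_dilate(m, se$offsets))
    }
  }
})

test_that("duality links erosion and dilation for symmetric elements", {
  # masks with background borders so the finite domain does not interfere
  for (seed in 1:3) {
    inner <- rand_mask(8, 8, seed)
    m <- matrix(0, 12, 12)
    m[3:10, 3:10] <- unclass(inner)
    m <- binary_mask(m)
    comp <- function(x) binary_mask(255 - unclass(x))
    for (se in list(square_se(3), disk_se(1))) {
      expect_identical(unclass(erode(m, se))[3:10, 3:10],
                       unclass(comp(dilate(comp(m), se)))[3:10, 3:10])
    }
  }
})

test_that("extensivity, anti-extensivity and opening idempotence hold", {
  m <- rand_mask(14, 14, 6)
  se <- disk_se(2)
  er <- unclass(erode(m, se)) == 255
  di <- unclass(dilate(m, se)) == 255
  fg <- unclass(m) == 255
  expect_true(all(!er | fg))   # A erode B  subset of A
  expect_true(all(!fg | di))   # A subset of A dilate B
  op1 <- opening(m, se)
  expect_identical(unclass(opening(op1, se)), unclass(op1))

  single <- matrix(50, 9, 9); single[5, 5] <- 250
  opened <- opening(gray_frame(single), square_se(3))
  expect_true(all(unclass(opened) == 50))  # isolated bright pixel removed

  rect <- matrix(0, 12, 12); rect[3:10, 2:11] <- 255
  expect_identical(unclass(opening(binary_mask(rect), square_se(3))), rect)
})

test_that("grayscale morphology takes local extrema ignoring the border", {
  f <- rand_frame(10, 10, 33)
  off <- disk_se(2)$offsets
  expect_identical(unclass(erode(f, disk_se(2)))[, ], oracle_gray_erode(f, off))
  # dilation duality on the negated image gives max = -min(-x)
  neg <- 255 - unclass(f)
  expect_identical(unclass(dilate(f, disk_se(2)))[, ],
                   255 - oracle_gray_erode(neg, off))
})

test_that("the top-hat transform isolates small bright structures", {
  expect_true(all(top_hat(gray_frame(matrix(120, 8, 8)), square_se(3)) == 0))

  m <- matrix(50, 9, 9); m[4, 6] <- 200
  th <- top_hat(gray_frame(m), square_se(3))
  expect_equal(th[4, 6], 150)
  expect_equal(sum(th != 0), 1)

  f <- rand_frame(12, 12, 8)
  th2 <- top_hat(f, disk_se(2))
  expect_true(all(th2 >= 0))
  expect_equal(unclass(f)[, ] - unclass(opening(f, disk_se(2)))[, ], th2)
  # top-hat of an opening is identically zero
  expect_true(all(top_hat(opening(f, disk_se(2)), disk_se(2)) == 0))
})

test_that("the top-hat detector recovers planted colloids on synthetic frames", {
  ref <- render_reference_frame(ci_scene_config())
  mask <- tophat_detect(ref$frame, r = 2)
  dets <- extract_detections(mask, 0, "tophat")
  cc <- match_detections(dets, ref$truth, tol = 3)
  expect_equal(recall(cc), 1)
  expect_equal(cc$fp, 0L)

  # single bright pixel on a slowly varying background stays foreground
  bgm <- outer(seq(40, 80, length.out = 15), rep(1, 15))
  bgm <- round(bgm); bgm[8, 8] <- 220
  mask2 <- tophat_detect(gray_frame(bgm), r = 2)
  expect_identical(unclass(mask2)[8, 8], 255)

  expect_error(tophat_detect(gray_frame(matrix(5, 6, 6))), "degenerate")
})

test_that("the dilation detector enlarges bright spots before binarizing", {
  # a colloid-only image: dilation turns the single pixel into a disk(4)
  m <- matrix(20, 21, 21); m[11, 11] <- 250
  mask <- dilation_detect(gray_frame(m), r = 4)
  fg <- which(unclass(mask) == 255, arr.ind = TRUE)
  d2 <- (fg[, 1] - 11)^2 + (fg[, 2] - 11)^2
  expect_equal(sum(unclass(mask) == 255), nrow(disk_se(4)$offsets))
  expect_true(all(d2 <= 16))
  # fixed-threshold post-binarization is available as an override
  mask2 <- dilation_detect(gray_frame(m), r = 4, post_threshold = 200)
  expect_identical(unclass(mask2), unclass(mask))
  expect_error(dilation_detect(gray_frame(matrix(7, 5, 5))), "degenerate")
})
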