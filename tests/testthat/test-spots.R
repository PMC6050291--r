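test_that("normalized distance is the clipped axial projection", {
  g <- cell_geometry(centroid = c(10, 5), axis = c(1, 0), half_length = 10)
  expect_equal(as.numeric(normalized_distance(c(10, 5), g)), 0)
  expect_equal(as.numeric(normalized_distance(c(20, 5), g)), 1)
  expect_equal(as.numeric(normalized_distance(c(15, 5), g)), 0.5)
  expect_equal(as.numeric(normalized_distance(c(5, 8), g)), 0.5)  # axial only
  d <- normalized_distance(c(25, 5), g)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "outside"))
  # arbitrary axis orientation
  g2 <- cell_geometry(c(0, 0), axis = c(1, 1), half_length = sqrt(2))
  expect_equal(as.numeric(normalized_distance(c(1, 1), g2)), 1)
})

test_that("classify_spot uses the 0.6 threshold, boundary to the pole", {
  expect_identical(classify_spot(0.7), "CI")
  expect_identical(classify_spot(0.3), "Cro")
  expect_identical(classify_spot(0.6), "CI")
  # monotone threshold function with exactly two classes
  d <- seq(0, 1, by = 0.01)
  cls <- classify_spot(d)
  expect_identical(unique(cls), c("Cro", "CI"))
  expect_true(all(diff(cls == "CI") >= 0))
  expect_error(classify_spot(1.2), "0, 1")
})

test_that("intensity calibration fits the peak and rejects bad samples", {
  expect_error(calibrate_single_molecule_intensity(rep(500, 10)), "30")
  cal <- calibrate_single_molecule_intensity(rep(500, 40))
  expect_equal(cal$peak, 500)
  set.seed(8)
  x <- rnorm(1e4, 500, 50)
  cal2 <- calibrate_single_molecule_intensity(x)
  expect_lt(abs(cal2$peak - 500), 3 * 50 / sqrt(1e4))
  # bimodal-looking sample: sd exceeds peak
  expect_error(calibrate_single_molecule_intensity(c(rep(1, 50),
                                                     rep(1000, 10))),
               "quality")
})

test_that("intensity-to-molecule conversion rounds, floors and scales", {
  cal <- calibrate_single_molecule_intensity(rnorm(100, 500, 20))
  expect_identical(as.integer(intensity_to_molecules(cal$peak, cal)), 1L)
  expect_identical(as.integer(intensity_to_molecules(0, cal)), 0L)
  expect_identical(as.integer(intensity_to_molecules(4.6 * cal$peak, cal)), 5L)
  neg <- intensity_to_molecules(-10, cal)
  expect_identical(as.integer(neg), 0L)
  expect_true(attr(neg, "flagged"))
  # homogeneity: doubling intensity and peak leaves counts unchanged
  cal2 <- cal; cal2$peak <- 2 * cal$peak
  x <- runif(50, 0, 10 * cal$peak)
  expect_identical(as.integer(intensity_to_molecules(x, cal)),
                   as.integer(intensity_to_molecules(2 * x, cal2)))
})

test_that("cloud quantification subtracts pole spots", {
  cal <- calibrate_single_molecule_intensity(rnorm(100, 500, 20))
  p <- cal$peak
  expect_identical(as.integer(quantify_cloud(10 * p, rep(p, 4), cal)), 6L)
  expect_identical(as.integer(quantify_cloud(5 * p, rep(p, 5), cal)), 0L)
  over <- quantify_cloud(2 * p, rep(p, 3), cal)
  expect_identical(as.integer(over), 0L)
  expect_true(attr(over, "flagged"))
})

test_that("spot frames render expected geometry and ground truth", {
  empty <- simulate_spot_frame(0, 0, seed = 1)
  expect_identical(nrow(empty$truth), 0L)
  expect_lt(sd(empty$image), 15)  # background only
  expect_identical(detect_spots(empty$image), detect_spots(empty$image))
  expect_identical(nrow(detect_spots(empty$image)), 0L)
})

test_that("a single clean spot is detected within tolerance", {
  sf <- simulate_spot_frame(1, 0, seed = 5,
                            image_params = list(read_noise = 0.1,
                                                background = 20))
  det <- detect_spots(sf$image)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_px - sf$truth$x_px), 1)
  expect_lt(abs(det$y_px - sf$truth$y_px), 1)
  expect_lt(abs(det$intensity - sf$truth$intensity) / sf$truth$intensity,
            0.25)
})

test_that("detection on a 20-spot frame: recall and precision >= 0.95", {
  sf <- simulate_spot_frame(10, 10, cell_length_nm = 30000, seed = 6,
                            image_params = list(cell_radius_nm = 3000))
  det <- detect_spots(sf$image)
  dmat <- outer(seq_len(nrow(sf$truth)), seq_len(nrow(det)),
                function(i, j) sqrt((sf$truth$x_px[i] - det$x_px[j])^2 +
                                      (sf$truth$y_px[i] - det$y_px[j])^2))
  matched_truth <- apply(dmat, 1, min) < 2
  matched_det <- apply(dmat, 2, min) < 2
  expect_gte(mean(matched_truth), 0.95)
  expect_gte(mean(matched_det), 0.95)
})

test_that("d-classifier separates 1000 pole and 1000 mid spots >= 90%", {
  expect_warning(sp <- simulate_spot_frame(1000, 0, seed = 21),
                 "resolvability")
  expect_true(sp$crowded)
  sm <- suppressWarnings(simulate_spot_frame(0, 1000, seed = 22))
  dp <- normalized_distance(as.matrix(sp$truth[, c("x_px", "y_px")]),
                            sp$geometry)
  dm <- normalized_distance(as.matrix(sm$truth[, c("x_px", "y_px")]),
                            sm$geometry)
  expect_gte(mean(classify_spot(dp) == "CI"), 0.90)
  expect_gte(mean(classify_spot(dm) == "Cro"), 0.90)
})

test_that("rendered cloud intensities recover the molecule count", {
  # 50 mid molecules + 5 pole spots on a larger synthetic cell
  sf <- suppressWarnings(
    simulate_spot_frame(5, 50, cell_length_nm = 8000, seed = 9,
                        image_params = list(cell_radius_nm = 1200,
                                            read_noise = 1)))
  ip <- sf$params
  total <- sum(sf$image) - ip$background * length(sf$image)
  cal <- calibrate_single_molecule_intensity(rnorm(200, ip$photons,
                                                   ip$photons * 0.05))
  pole_sum <- sum(sf$truth$intensity[sf$truth$class == "pole"])
  n_mid <- quantify_cloud(total, pole_sum, cal)
  expect_lt(abs(as.integer(n_mid) - 50) / 50, 0.1)
})
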