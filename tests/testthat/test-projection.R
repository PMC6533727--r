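test_that("field rotation applies the direction-specific effective angle", {
  expect_equal(rotate_field_points(tibble::tibble(x = 2, y = 1), 0, "NE")[, c("x_rot", "y_rot")],
               tibble::tibble(x_rot = 2, y_rot = 1))
  # quarter turn of the stacked (y; x) rotation
  r <- rotate_field_points(tibble::tibble(x = 2, y = 1), 90, "NE")
  expect_equal(c(r$x_rot, r$y_rot), c(-1, 2))
  # SW adds 180 deg and negates coordinates: identical to plain theta
  p <- tibble::tibble(x = c(1.3, -0.4), y = c(2.0, 5.5))
  ne <- rotate_field_points(p, 33, "NE")
  sw <- rotate_field_points(p, 33, "SW")
  expect_equal(sw$x_rot, ne$x_rot, tolerance = 1e-12)
  expect_equal(sw$y_rot, ne$y_rot, tolerance = 1e-12)
})

test_that("rotation preserves Euclidean norms for all directions", {
  set.seed(42)
  for (dir in c("NE", "NW", "SE", "SW")) {
    p <- tibble::tibble(x = rnorm(20, 0, 5), y = rnorm(20, 0, 5))
    th <- runif(1, -180, 180)
    r <- rotate_field_points(p, th, dir)
    expect_equal(sqrt(r$x_rot^2 + r$y_rot^2), sqrt(p$x^2 + p$y^2),
                 tolerance = 1e-9)
  }
})

test_that("spherical transform gives latitude from drop and 4-quadrant longitude", {
  s <- cartesian_to_spherical(3, 0, 4)
  expect_equal(s$latitude_deg, asin(4 / 5) * 180 / pi, tolerance = 1e-9)
  expect_equal(s$longitude_deg, 0)
  s2 <- cartesian_to_spherical(1, 1, sqrt(2))
  expect_equal(s2$latitude_deg, 45, tolerance = 1e-9)
  expect_equal(s2$longitude_deg, 45)
  expect_equal(cartesian_to_spherical(0, 0, 1)$latitude_deg, 90)
  expect_equal(cartesian_to_spherical(-1, -1, 1e-9)$longitude_deg, -135)
  expect_error(cartesian_to_spherical(1, 1, 0), "z_eff")
})

test_that("the radial lens quadratic matches its fixed coefficients", {
  expect_identical(latitude_to_radial_fraction(0), 0.3609)
  expect_equal(latitude_to_radial_fraction(50), 0.11115, tolerance = 1e-12)
  expect_equal(latitude_to_radial_fraction(10), 0.31091, tolerance = 1e-12)
  expect_error(latitude_to_radial_fraction(-1), "within")
  expect_error(latitude_to_radial_fraction(91), "within")
})

test_that("the radial fraction decreases strictly with latitude", {
  phi <- seq(0, 90, by = 0.5)
  D <- latitude_to_radial_fraction(phi)
  expect_true(all(diff(D) < 0))
})

test_that("signed fractions follow the law-of-sines split and quadrant signs", {
  expect_equal(as.numeric(spherical_to_signed_fractions(0.2, 90)), c(-0.2, 0))
  expect_equal(as.numeric(spherical_to_signed_fractions(0.2, 0)), c(0, 0.2))
  rc <- spherical_to_signed_fractions(0.2, 45)
  expect_equal(rc$R, -0.1414214, tolerance = 1e-6)
  expect_equal(rc$C, 0.1414214, tolerance = 1e-6)
  # quadrant signs: up is negative R, right is positive C
  expect_true(spherical_to_signed_fractions(0.3, 120)$R < 0)
  expect_true(spherical_to_signed_fractions(0.3, -120)$R > 0)
  expect_true(spherical_to_signed_fractions(0.3, -45)$C > 0)
  expect_true(spherical_to_signed_fractions(0.3, 135)$C < 0)
})

test_that("magnitudes obey R^2 + C^2 = D^2 across the longitude range", {
  theta <- seq(-179, 180, by = 7)
  D <- runif(length(theta), 0, 0.5)
  rc <- spherical_to_signed_fractions(D, theta)
  expect_equal(rc$R^2 + rc$C^2, D^2, tolerance = 1e-9)
})

test_that("pixel indices scale by image size and offset by its half", {
  expect_equal(as.numeric(fractions_to_pixel_index(0, 0, 2880)), c(1440, 1440))
  expect_equal(as.numeric(fractions_to_pixel_index(0.25, -0.10, 2880)),
               c(2160, 1152))
  expect_equal(as.numeric(fractions_to_pixel_index(-0.5, 0.5, 2880)), c(0, 2880))
})

test_that("project_field emits one four-corner polygon per plot", {
  cfg <- camera_config()
  names24 <- parse_plot_names(sprintf("Cv%d_oat_1A", 1:24))
  rows <- do.call(rbind, lapply(1:24, function(i) {
    x0 <- (i - 12.5) * 0.6
    c(0.9, x0, 2.28, x0 + 0.3, 2.28, x0, 2.58, x0 + 0.3, 2.58)
  }))
  design <- parse_plot_coordinates(rows, plots = names24)
  det <- list(theta_off_deg = 25, direction = "SW")
  polys <- project_field(design, det, cfg)
  expect_equal(length(unique(polys$name)), 24)
  expect_equal(nrow(polys), 96)
  expect_true(all(is.finite(polys$row)), all(is.finite(polys$col)))
  # determinism: bit-identical on re-run
  expect_identical(polys, project_field(design, det, cfg))
})

test_that("a plot centered under the camera projects symmetrically", {
  cfg <- camera_config()
  design <- parse_plot_coordinates("0.9 -1 -1 1 -1 -1 1 1 1")
  det <- list(theta_off_deg = 45, direction = "NW")
  polys <- project_field(design, det, cfg)
  ctr <- cfg$image_size_px / 2
  # corners are symmetric about image center in pairs
  expect_equal(sort(polys$row - ctr), sort(-(polys$row - ctr)), tolerance = 1e-9)
  expect_equal(sort(polys$col - ctr), sort(-(polys$col - ctr)), tolerance = 1e-9)
})

test_that("offset-angle errors displace distant plots more than near ones", {
  cfg <- camera_config()
  design <- synth_field_design()
  d0 <- project_field(design, list(theta_off_deg = 30, direction = "SW"), cfg)
  d1 <- project_field(design, list(theta_off_deg = 31, direction = "SW"), cfg)
  disp <- sqrt((d1$row - d0$row)^2 + (d1$col - d0$col)^2)
  inner <- mean(disp[d0$position == "inner"])
  outer <- mean(disp[d0$position == "outer"])
  expect_gt(outer, inner)
})

test_that("projected polygons land on the rendered plot stripes", {
  cfg <- test_config()
  sc <- test_scene(40, "NW", cfg)
  fr <- render_panel_frame(sc, cfg, seed = 2, draw_plots = TRUE)
  det <- list(theta_off_deg = theta_off_expected(sc), direction = sc$direction)
  polys <- project_field(sc$design, det, cfg)
  S <- cfg$image_size_px
  stripe <- fr[, , 1] == 70 & fr[, , 2] == 110  # painted plot color
  for (p in unique(polys$name)[1:3]) {
    px <- polygon_pixels(polys[polys$name == p, ], S, S)
    inter <- sum(stripe[px])
    expect_gt(inter / nrow(px), 0.9)
  }
})
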