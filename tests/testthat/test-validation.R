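test_that("registration recovers a known rigid motion exactly", {
  set.seed(31)
  src <- matrix(runif(30, -50, 50), ncol = 3)
  R <- rotation_z(pi / 6)
  t <- c(5, -3, 2)
  tgt <- sweep(src %*% t(R), 2, t, "+")
  reg <- landmark_register(src, tgt)
  expect_equal(reg$rotation, R, tolerance = 1e-8)
  expect_equal(reg$translation, t, tolerance = 1e-8)
  expect_equal(det(reg$rotation), 1, tolerance = 1e-10)
  expect_lt(reg$rms_error, 1e-9)

  ident <- landmark_register(src, src)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(ident$rms_error, 1e-12)
})

test_that("rms under landmark noise sits in the expected band", {
  set.seed(42)
  rms <- replicate(100, {
    src <- matrix(runif(30, -60, 60), ncol = 3)
    tgt <- sweep(src %*% t(rotation_z(0.4)), 2, c(10, 2, -7), "+") +
      matrix(rnorm(30, 0, 0.5), ncol = 3)
    landmark_register(src, tgt)$rms_error
  })
  # rms = sigma * sqrt(chi2_{3n-6} / n), n = 10 landmarks: expectation
  # sigma * sqrt(2.4) ~ 0.77 mm, with chi-square spread around it
  expect_gt(mean(rms), 0.2)
  expect_lt(mean(rms), 1.0)
  expect_true(all(rms > 0.2 & rms < 1.5))
})

test_that("registration is invariant to a common rigid motion", {
  set.seed(33)
  src <- matrix(runif(30, -40, 40), ncol = 3)
  tgt <- src + matrix(rnorm(30, 0, 1), ncol = 3)
  base <- landmark_register(src, tgt)$rms_error
  Rc <- rotation_z(1.1)
  tc <- c(-20, 4, 9)
  moved <- landmark_register(sweep(src %*% t(Rc), 2, tc, "+"),
                             sweep(tgt %*% t(Rc), 2, tc, "+"))$rms_error
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_register(line, line + 1), "collinear")
  expect_error(landmark_register(matrix(runif(6), 2), matrix(runif(6), 2)),
               "at least 3")
  expect_error(landmark_register(matrix(runif(9), 3), matrix(runif(12), 4)),
               "equal counts")
})

test_that("similarity mode recovers a known scale when enabled", {
  set.seed(35)
  src <- matrix(runif(30, -50, 50), ncol = 3)
  tgt <- sweep(1.8 * src %*% t(rotation_z(0.3)), 2, c(1, 2, 3), "+")
  rigid <- landmark_register(src, tgt)
  expect_identical(rigid$scale, 1)
  sim <- landmark_register(src, tgt, allow_scaling = TRUE)
  expect_equal(sim$scale, 1.8, tolerance = 1e-9)
  expect_lt(sim$rms_error, 1e-9)
})

test_that("surface distance is exact for identical and concentric spheres", {
  ico <- unit_icosphere(3)
  a <- surface_mesh(ico$vertices * 30, ico$faces)
  self <- surface_distance(a, a)
  expect_equal(self$report$mad, 0)
  expect_equal(self$report$std, 0)
  expect_equal(self$report$max, 0)
  expect_identical(self$report$n_vertices, n_vertices(a))

  b <- surface_mesh(unit_icosphere(4)$vertices * 31, unit_icosphere(4)$faces)
  conc <- surface_distance(a, b)
  expect_equal(conc$report$mad, 1, tolerance = 0.02)
  expect_equal(conc$report$max, 1, tolerance = 0.02)
})

test_that("surface distance matches a brute-force oracle and is directed", {
  soup <- random_triangle_soup(40, seed = 17)
  set.seed(18)
  qv <- matrix(runif(60, -12, 12), ncol = 3)
  qm <- surface_mesh(qv, matrix(seq_len(18), ncol = 3))  # 20-vertex toy mesh
  sd_ <- surface_distance(qm, soup)
  for (i in seq_len(nrow(qv))) {
    expect_equal(sd_$distances[i], oracle_closest_point(soup, qv[i, ])$distance,
                 tolerance = 1e-9)
  }
  expect_identical(sd_$report$direction, "query_to_reference")
  # not symmetric
  rev <- surface_distance(soup, qm)
  expect_false(isTRUE(all.equal(sd_$report$mad, rev$report$mad)))
})

test_that("registered surface distance pulls a moved copy back onto itself", {
  ico <- unit_icosphere(3)
  a <- surface_mesh(ico$vertices * 25, ico$faces)
  R <- rotation_z(0.5)
  t <- c(12, -4, 6)
  b <- transform_phantom(a, R, t)
  lm_a <- a$vertices[seq(1, 601, by = 60), ]
  lm_b <- sweep(lm_a %*% t(R), 2, t, "+")
  reg <- landmark_register(lm_a, lm_b)
  sd_ <- surface_distance(a, b, transform = reg)
  expect_lt(sd_$report$mad, 1e-8)
  expect_equal(sd_$report$rms_error, reg$rms_error)
})

test_that("landmark files and report CSVs round-trip", {
  lm <- matrix(runif(30, -40, 40), ncol = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# landmarks in mm", apply(lm, 1, paste, collapse = " ")), f)
  back <- read_landmarks(f)
  expect_equal(back, lm, tolerance = 1e-7, ignore_attr = TRUE)

  rep <- surface_distance(unit_icosphere(2), unit_icosphere(2))$report
  rep$rms_error <- 0.5
  csv <- withr::local_tempfile(fileext = ".csv")
  write_distance_report(rep, csv, patient_id = "phantom-1")
  got <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(names(got), c("PatientID", "RMS-error", "N", "MAD", "STD", "MAX"))
  expect_identical(got$PatientID, "phantom-1")
  expect_equal(got$MAD, 0)
})
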