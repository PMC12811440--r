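test_that("plane-plane intersection satisfies both plane equations", {
  pz <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))   # z = 0
  px <- plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))   # x = 0
  l <- intersect_planes(pz, px)
  expect_equal(abs(l$direction), c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(plane_distance(pz, l$point)), 1e-9)
  expect_lt(abs(plane_distance(px, l$point)), 1e-9)

  set.seed(42)
  for (i in 1:20) {
    p <- plane(rnorm(3, 0, 30), rnorm(3), rnorm(3))
    q <- plane(rnorm(3, 0, 30), rnorm(3), rnorm(3))
    l <- intersect_planes(p, q)
    expect_lt(abs(plane_distance(p, l$point)), 1e-9)
    expect_lt(abs(plane_distance(q, l$point)), 1e-9)
    expect_lt(abs(sum(l$direction * p$normal)), 1e-9)
    expect_lt(abs(sum(l$direction * q$normal)), 1e-9)
  }
})

test_that("parallel planes raise a degenerate-geometry error", {
  p1 <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  p2 <- plane(c(0, 0, 5), c(1, 0, 0), c(0, 1, 0))
  expect_error(intersect_planes(p1, p2), "parallel")
  p3 <- plane(c(3, 1, 2), c(0, 1, 0), c(1, 0, 0))
  expect_error(three_plane_point(p1, p2, p3), "degenerate|independent")
})

test_that("three coordinate planes intersect at the origin", {
  px <- plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  py <- plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  pz <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(three_plane_point(px, py, pz), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the phantom's three-plane point lies inside the LV cavity", {
  ph <- make_phantom(fast_spec(), seed = 1, truth = FALSE)
  sax <- plane_from_affine(ph$sax[[1]]$affine, 5)
  ch2 <- plane_from_affine(ph$ch2[[1]]$affine, 0)
  ch4 <- plane_from_affine(ph$ch4[[1]]$affine, 0)
  pt <- three_plane_point(sax, ch2, ch4)
  # the point lies on the LV long axis: the line through the apex and the
  # centroid of the mitral landmarks (the annulus centre)
  base_ctr <- colMeans(rbind(ph$landmarks$mv_2ch, ph$landmarks$mv_4ch))
  ax <- (base_ctr - ph$apex) / sqrt(sum((base_ctr - ph$apex)^2))
  v <- pt - ph$apex
  perp <- sqrt(sum((v - sum(v * ax) * ax)^2))
  expect_lt(perp, 1e-6)
  # inside the cavity: between apex and base, on the slice plane
  expect_gt(sum(v * ax), 0)
  expect_lt(sum(v * ax), sqrt(sum((base_ctr - ph$apex)^2)) + 10)
  expect_lt(abs(plane_distance(sax, pt)), 1e-9)
})

test_that("long-axis views intersect the short-axis stack through the cavity", {
  ph <- make_phantom(fast_spec(), seed = 2, truth = FALSE)
  sax <- plane_from_affine(ph$sax[[1]]$affine, 6)
  for (vw in list(ph$ch2[[1]], ph$ch4[[1]])) {
    l <- intersect_planes(sax, plane_from_affine(vw$affine, 0))
    ctr <- three_plane_point(sax, plane_from_affine(ph$ch2[[1]]$affine, 0),
                             plane_from_affine(ph$ch4[[1]]$affine, 0))
    # the intersection line passes within a pixel of the cavity axis point
    v <- ctr - l$point
    off <- sqrt(sum((v - sum(v * l$direction) * l$direction)^2))
    expect_lt(off, 1e-6)
  }
})

test_that("normalization transform is identity for an already-normalized slice", {
  sax <- plane(c(-80, -80, 0), c(1, 0, 0), c(0, 1, 0))
  ch2 <- plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))   # x = 0, line along y
  ch4 <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))   # y = 0, line along x
  t <- normalization_transform(sax, 1, ch2, ch4, source_size = c(160, 160))
  expect_equal(t$translation, c(0, 0), tolerance = 1e-9)
  expect_equal(t$rotation_deg %% 180, 0, tolerance = 1e-9)
  expect_equal(t$scale, c(1, 1))
  expect_equal(t$centre, c(0, 0, 0), tolerance = 1e-12)
})

test_that("a slice rotated about its normal yields the opposite rotation", {
  th <- 30 * pi / 180
  sax <- plane(c(0, 0, 0), c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0))
  ch2 <- plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ch4 <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  t <- normalization_transform(sax, 1, ch2, ch4)
  expect_equal((t$rotation_deg + 30) %% 180, 0, tolerance = 1e-9)
})

test_that("pixel spacing propagates into the transform scale", {
  sax <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ch2 <- plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ch4 <- plane(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  t <- normalization_transform(sax, 2, ch2, ch4)
  expect_equal(t$scale, c(2, 2))
})

test_that("normalized frame geometry: centre pixel, 1 mm pixels, in-plane", {
  ph <- make_phantom(fast_spec(), seed = 3, truth = FALSE)
  sax <- plane_from_affine(ph$sax[[1]]$affine, 5)
  ch2 <- plane_from_affine(ph$ch2[[1]]$affine, 0)
  ch4 <- plane_from_affine(ph$ch4[[1]]$affine, 0)
  t <- normalization_transform(sax, 1.25, ch2, ch4)
  expect_equal(as.numeric(norm_frame_points(t, 80, 80)), t$centre,
               tolerance = 1e-9)
  p1 <- norm_frame_points(t, 10, 20); p2 <- norm_frame_points(t, 11, 20)
  expect_equal(sqrt(sum((p2 - p1)^2)), 1, tolerance = 1e-9)   # 1 mm pixels
  expect_lt(abs(plane_distance(sax, as.numeric(p1))), 1e-9)
  # 2ch intersection line maps to the y axis of the frame
  l2 <- intersect_planes(sax, ch2)
  expect_equal(abs(sum(t$axes[, 2] * l2$direction)), 1, tolerance = 1e-9)
})

test_that("mitral plane fit: coplanar points give zero residual, noise is bounded", {
  p2 <- rbind(c(10, 0, 5), c(-10, 0, 5))
  p4 <- rbind(c(0, 10, 5), c(0, -10, 5))
  mp <- fit_mitral_plane(p2, p4, apex_hint = c(0, 0, -50))
  expect_equal(mp$residual_rms, 0, tolerance = 1e-12)
  expect_equal(mp$normal, c(0, 0, -1), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    dz <- runif(4, -1, 1)
    mpn <- fit_mitral_plane(p2 + cbind(0, 0, dz[1:2]), p4 + cbind(0, 0, dz[3:4]),
                            apex_hint = c(0, 0, -50))
    expect_lte(mpn$residual_rms, sqrt(mean(dz^2)) + 1e-9)
  }
})

test_that("mitral plane fit recovers the phantom's plane", {
  ph <- make_phantom(fast_spec(), seed = 4, truth = FALSE)
  mp <- fit_mitral_plane(ph$landmarks$mv_2ch, ph$landmarks$mv_4ch, ph$apex)
  ang <- acos(min(1, abs(sum(mp$normal * ph$mitral_plane$normal)))) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(mp$residual_rms, 1e-6)
  # landmark points lie exactly on the phantom's mitral plane
  d <- plane_distance(ph$mitral_plane, rbind(ph$landmarks$mv_2ch, ph$landmarks$mv_4ch))
  expect_lt(max(abs(d)), 1e-9)
})

test_that("collinear landmarks raise a degenerate-geometry error", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(fit_mitral_plane(pts, rbind(c(2, 0, 0), c(3, 0, 0)),
                                apex_hint = c(0, 0, -1)), "collinear")
})

test_that("plane operations are equivariant under rigid transforms", {
  set.seed(11)
  for (i in 1:10) {
    p <- plane(rnorm(3, 0, 20), rnorm(3), rnorm(3))
    q <- plane(rnorm(3, 0, 20), rnorm(3), rnorm(3))
    r <- plane(rnorm(3, 0, 20), rnorm(3), rnorm(3))
    tf <- random_rigid()
    pt <- three_plane_point(p, q, r)
    pt2 <- three_plane_point(rigid_plane(tf, p), rigid_plane(tf, q), rigid_plane(tf, r))
    expect_equal(pt2, apply_rigid(tf, pt), tolerance = 1e-6)
    l <- intersect_planes(p, q)
    l2 <- intersect_planes(rigid_plane(tf, p), rigid_plane(tf, q))
    expect_lt(abs(plane_distance(rigid_plane(tf, p), l2$point)), 1e-8)
    expect_equal(abs(sum(l2$direction * (tf$R %*% l$direction))), 1,
                 tolerance = 1e-9)
    lm2 <- matrix(rnorm(6, 0, 10), 2); lm4 <- matrix(rnorm(6, 0, 10), 2)
    hint <- rnorm(3, 0, 40)
    m1 <- fit_mitral_plane(lm2, lm4, hint)
    m2 <- fit_mitral_plane(apply_rigid(tf, lm2), apply_rigid(tf, lm4),
                           apply_rigid(tf, hint))
    expect_equal(m2$point, apply_rigid(tf, m1$point), tolerance = 1e-6)
    expect_equal(m2$normal, as.numeric(tf$R %*% m1$normal), tolerance = 1e-6)
  }
})
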