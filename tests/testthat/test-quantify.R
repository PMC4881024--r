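# build a reverse-transformed image with uniform background `bg` and a
# 21-pixel disc of value `disc` at (cx, cy)
disc_image <- function(bg = 100, disc = 612, size = 31, cx = 16, cy = 16) {
  px <- matrix(bg, size, size)
  for (dy in -2:2) for (dx in -2:2) {
    if (dx^2 + dy^2 <= 6.25) px[cy + dy, cx + dx] <- disc
  }
  phosphor_image(px, transform_state = "reverse_transformed")
}

test_that("net intensity is disc mean minus background median, log2ed", {
  img <- disc_image(bg = 100, disc = 612)
  q <- quantify_spot(img, c(16, 16))
  expect_length(q$disc_values, 21L)
  expect_equal(q$disc_mean, 612)
  expect_equal(q$bg_median, 100)
  expect_equal(q$net, 512)
  expect_equal(q$net_log2, 9)

  # disc equal to background: net 0 -> missing, a no-contrast candidate
  q0 <- quantify_spot(disc_image(disc = 100), c(16, 16))
  expect_equal(q0$net, 0)
  expect_true(is.na(q0$net_log2))

  # background exclusions can starve the estimate
  excl <- matrix(TRUE, 31, 31)
  qe <- quantify_spot(img, c(16, 16), exclusions = excl)
  expect_true(qe$bg_failed)
})

test_that("centre refinement finds offsets and honours the 2-pixel clamp", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  tab <- new_spot_table(layout)
  tab$net_log2 <- 10
  img <- reverse_transform(render_slide(tab, layout, seed = 7))
  ctr <- attr(render_slide(tab, layout, seed = 7), "centers")
  true1 <- c(ctr$x_px[10], ctr$y_px[10])
  # exact nominal: stays
  r1 <- refine_center(img, true1)
  expect_lte(max(abs(r1 - round(true1))), 1)
  # 1 px off: comes back within 1 px of truth
  r2 <- refine_center(img, true1 + c(1, -1))
  expect_lte(max(abs(r2 - true1)), 1.6)
  # 4 px off: clamped to within 2 px of the (wrong) nominal
  nominal4 <- true1 + c(4, 0)
  r3 <- refine_center(img, nominal4)
  expect_lte(max(abs(r3 - round(nominal4))), 2)
})

test_that("saturation flags more than 3 of the 21 disc pixels", {
  mk <- function(n_sat) {
    img <- disc_image(bg = 100, disc = 612)
    hit <- 0
    for (dy in -2:2) for (dx in -2:2) {
      if (dx^2 + dy^2 <= 6.25 && hit < n_sat) {
        img$pixels[16 + dy, 16 + dx] <- 96000
        hit <- hit + 1
      }
    }
    img
  }
  enh_pos <- structure(list(pixels = matrix(1, 31, 31), pixel_pitch = 50),
                       class = "enhanced_image")
  flag_of <- function(n_sat) {
    img <- mk(n_sat)
    q <- quantify_spot(img, c(16, 16))
    flag_spot(img, enh_pos, c(16, 16), c(16, 16), q)[["saturated"]]
  }
  expect_equal(flag_of(3), 0L)
  expect_equal(flag_of(4), 1L)
})

test_that("the KS flag marks discs indistinguishable from background", {
  set.seed(30)
  px <- matrix(rnorm(31 * 31, 100, 10), 31, 31)
  img <- phosphor_image(pmax(px, 0), transform_state = "reverse_transformed")
  enh_neg <- structure(list(pixels = matrix(-1, 31, 31), pixel_pitch = 50),
                       class = "enhanced_image")
  q <- quantify_spot(img, c(16, 16))
  f <- flag_spot(img, enh_neg, c(16, 16), c(16, 16), q)
  expect_equal(f[["ks"]], 1L)          # same distribution: cannot reject
  expect_equal(f[["no_contrast"]], 1L) # enhanced all < 0

  img2 <- disc_image(bg = 100, disc = 5000)
  img2$pixels <- img2$pixels + matrix(rnorm(31 * 31, 0, 5), 31, 31)
  enh_pos <- structure(list(pixels = matrix(1, 31, 31), pixel_pitch = 50),
                       class = "enhanced_image")
  q2 <- quantify_spot(img2, c(16, 16))
  f2 <- flag_spot(img2, enh_pos, c(16, 16), c(16, 16), q2)
  expect_equal(f2[["ks"]], 0L)
  expect_equal(f2[["no_contrast"]], 0L)
})

test_that("shape flag applies the bright and weak aspect limits", {
  elongated <- function(level) {
    px <- matrix(100, 31, 31)
    for (dy in -1:1) for (dx in -5:5) px[16 + dy, 16 + dx] <- level
    phosphor_image(px, transform_state = "reverse_transformed")
  }
  enh_pos <- structure(list(pixels = matrix(1, 31, 31), pixel_pitch = 50),
                       class = "enhanced_image")
  # bright elongated object (net_log2 > 8, aspect ~ 2.8): flagged
  img_b <- elongated(3000)
  qb <- quantify_spot(img_b, c(16, 16))
  expect_gt(qb$net_log2, 8)
  expect_equal(flag_spot(img_b, enh_pos, c(16, 16), c(16, 16), qb)[["shape"]],
               1L)
  # round bright spot: not flagged
  img_r <- disc_image(bg = 100, disc = 3000)
  qr <- quantify_spot(img_r, c(16, 16))
  expect_equal(flag_spot(img_r, enh_pos, c(16, 16), c(16, 16), qr)[["shape"]],
               0L)
})

test_that("position flag fires when the object centroid drifts off-grid", {
  enh_pos <- structure(list(pixels = matrix(1, 31, 31), pixel_pitch = 50),
                       class = "enhanced_image")
  img <- disc_image(bg = 100, disc = 3000, cx = 16, cy = 16)
  q <- quantify_spot(img, c(16, 16))
  # nominal at the true centre: fine; nominal 3 px (150 um) away: flagged
  expect_equal(flag_spot(img, enh_pos, c(16, 16), c(16, 16), q)[["position"]],
               0L)
  expect_equal(flag_spot(img, enh_pos, c(16, 16), c(13, 16), q)[["position"]],
               1L)
})

test_that("overshine needs a bright neighbour with decaying bleed", {
  # bright wide Gaussian neighbour 11 px left of an empty spot position
  px <- matrix(100, 41, 41)
  for (y in 1:41) for (x in 1:41) {
    px[y, x] <- px[y, x] + 60000 * exp(-((y - 21)^2 + (x - 10)^2) / (2 * 16))
  }
  img <- phosphor_image(px, transform_state = "reverse_transformed")
  enh_pos <- structure(list(pixels = matrix(1, 41, 41), pixel_pitch = 50),
                       class = "enhanced_image")
  q <- quantify_spot(img, c(21, 21))
  nb <- tibble::tibble(x_px = 10, y_px = 21, net_log2 = 12)
  f <- flag_spot(img, enh_pos, c(21, 21), c(21, 21), q, neighbors = nb)
  expect_equal(f[["overshine"]], 1L)
  # a weak neighbour (net_log2 <= 8) never triggers it
  nb_weak <- tibble::tibble(x_px = 10, y_px = 21, net_log2 = 7)
  f2 <- flag_spot(img, enh_pos, c(21, 21), c(21, 21), q, neighbors = nb_weak)
  expect_equal(f2[["overshine"]], 0L)
})

test_that("overall equals the OR of the seven sub-flags on a whole slide", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  tab <- new_spot_table(layout)
  set.seed(31)
  tab$net_log2 <- rnorm(64, 10, 1.5)
  tab$net_log2[sample(64, 10)] <- NA   # off-spots provoke flags
  img <- render_slide(tab, layout, seed = 8,
                      artifacts = list(list(type = "stripe", row_px = 30,
                                            height_px = 5, level = 2000)))
  q <- quantify_image(img, attr(img, "bounds"), layout)
  sub <- as.matrix(q[setdiff(flag_columns(), "overall")])
  expect_equal(q$overall, as.integer(rowSums(sub) > 0))
  expect_gt(sum(q$overall), 0)
})
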