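test_that("reverse transform squares out the scanner compression", {
  img <- phosphor_image(matrix(c(0, 100, 1000, 65535), 2))
  out <- reverse_transform(img)
  expect_equal(out$pixels[1], 0)
  expect_equal(max(out$pixels), 65535^2 / 42752)
  expect_equal(max(out$pixels), 100459.3054, tolerance = 1e-8)
  expect_equal(out$transform_state, "reverse_transformed")
  # monotone order-preserving
  expect_equal(order(img$pixels), order(out$pixels))
  # double application is a state error
  expect_error(reverse_transform(out), "already")
})

test_that("the saturation level corresponds to a sub-16-bit raw value", {
  # smallest raw integer whose transform exceeds 95000, by brute-force scan
  raw <- 0:65535
  first <- raw[which(raw^2 / 42752 > 95000)[1]]
  expect_lt(first, 65535)
  expect_gt(first^2 / 42752, 95000)
  expect_lte((first - 1)^2 / 42752, 95000)
  spec <- transform_spec()
  expect_equal(spec$reverse(first, spec$TF) > 95000, TRUE)
})

test_that("forward and reverse transforms invert up to quantization", {
  set.seed(20)
  vals <- matrix(runif(400, 0, 95000), 20)
  q <- kinorm:::forward_transform_quantized(vals)
  back <- q$pixels^2 / 42752
  # raw step at level I corresponds to ~2*sqrt(I/TF) transformed units
  expect_lt(max(abs(back - vals) / (2 * sqrt(pmax(vals, 1) / 42752) + 1)), 1)
  expect_equal(q$clipped, 0)
  over <- kinorm:::forward_transform_quantized(matrix(2e5, 2, 2))
  expect_equal(over$clipped, 4)
})

test_that("enhancement suppresses flats and impulses but peaks on spots", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  flat <- phosphor_image(matrix(500, 60, 60), transform_state = "reverse_transformed")
  enh <- enhance_image(flat, layout)
  expect_true(all(enh$pixels <= 1e-6))

  # single-pixel impulse (50 um < 100 um) vanishes
  imp <- matrix(10, 60, 60); imp[30, 30] <- 5000
  enh_imp <- enhance_image(
    phosphor_image(imp, transform_state = "reverse_transformed"), layout)
  expect_lt(enh_imp$pixels[30, 30], 1e-6)

  # a matched Gaussian spot peaks at its centre
  sp <- matrix(10, 60, 60)
  sig <- (125 / 50) / sqrt(2)  # sigma matched to the 125 um radius
  for (dy in -8:8) for (dx in -8:8)
    sp[33 + dy, 27 + dx] <- sp[33 + dy, 27 + dx] +
      3000 * exp(-(dx^2 + dy^2) / (2 * (2.12)^2))
  enh_sp <- enhance_image(
    phosphor_image(sp, transform_state = "reverse_transformed"), layout)
  peak <- which(enh_sp$pixels == max(enh_sp$pixels), arr.ind = TRUE)
  expect_lte(max(abs(peak - c(33, 27))), 1)

  expect_error(enhance_image(
    phosphor_image(matrix(1, 4, 4), transform_state = "reverse_transformed"),
    layout), "smaller")
  expect_error(enhance_image(phosphor_image(matrix(1, 60, 60)), layout),
               "reverse-transformed")
})

test_that("rotation alignment recovers small rotations and clamps large ones", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  tab <- new_spot_table(layout)
  tab$net_log2 <- 10

  img0 <- render_slide(tab, layout, seed = 1)
  enh0 <- enhance_image(reverse_transform(img0), layout)
  r0 <- auto_rotate(enh0)
  expect_lte(abs(r0$angle), 0.1)

  img2 <- render_slide(tab, layout, seed = 1, rotation_deg = 2)
  enh2 <- enhance_image(reverse_transform(img2), layout)
  r2 <- auto_rotate(enh2)
  expect_equal(abs(r2$angle), 2, tolerance = 0.2)

  img5 <- render_slide(tab, layout, seed = 1, rotation_deg = 5)
  enh5 <- enhance_image(reverse_transform(img5), layout)
  expect_warning(r5 <- auto_rotate(enh5), "bound")
  expect_equal(abs(r5$angle), 3)
})

test_that("block partition counts and validates bounds", {
  layout <- array_layout()  # 3 sets of 32x32, blocks of 8
  tab <- new_spot_table(layout)
  tab$net_log2 <- 10
  img <- render_slide(tab, layout, seed = 2)
  enh <- enhance_image(reverse_transform(img), layout)
  b <- attr(img, "bounds")
  blocks <- locate_blocks(enh, b, layout)
  expect_length(blocks, 48L)  # 16 per set x 3 sets
  expect_equal(sort(unique(vapply(blocks, function(x) x$set, numeric(1)))),
               0:2)
  # 5% wider bounds rescale to the same 48 blocks
  w <- b[3] - b[1]
  b2 <- b + c(-0.025 * w, 0, 0.025 * w, 0)
  expect_length(locate_blocks(enh, b2, layout), 48L)
  # half-height bounds are a geometry error
  b3 <- b; b3[4] <- b3[2] + (b[4] - b[2]) / 2
  expect_error(locate_blocks(enh, b3, layout), "inconsistent")
})

test_that("grid fitting recovers jittered spot centres", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  tab <- new_spot_table(layout)
  set.seed(21)
  tab$net_log2 <- rnorm(64, 11, 0.5)
  img <- render_slide(tab, layout, seed = 3)
  # jitter: re-render with shifted centres by editing x_um/y_um up to 50 um
  tab_j <- tab
  tab_j$x_um <- tab_j$x_um + runif(64, -50, 50)
  tab_j$y_um <- tab_j$y_um + runif(64, -50, 50)
  img_j <- render_slide(tab_j, layout, seed = 3)
  enh <- enhance_image(reverse_transform(img_j), layout)
  blocks <- locate_blocks(enh, attr(img_j, "bounds"), layout)
  g <- fit_grid(blocks[[1]], layout)
  truth <- attr(img_j, "centers")
  m <- merge(g, truth, by = c("row", "col"))
  d_um <- sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2) * 50
  expect_gte(mean(d_um <= 100), 63 / 64)

  # half the spots dark: fit succeeds on the bright ones
  tab_h <- tab
  tab_h$net_log2[sample(64, 32)] <- NA
  img_h <- render_slide(tab_h, layout, seed = 4)
  enh_h <- enhance_image(reverse_transform(img_h), layout)
  g_h <- fit_grid(locate_blocks(enh_h, attr(img_h, "bounds"), layout)[[1]],
                  layout)
  bright <- !is.na(tab_h$net_log2)
  mh <- merge(g_h, attr(img_h, "centers")[bright, ], by = c("row", "col"))
  dh <- sqrt((mh$x_px.x - mh$x_px.y)^2 + (mh$y_px.x - mh$y_px.y)^2) * 50
  expect_gte(mean(dh <= 100), 0.95)

  # a blank block falls back to the nominal grid with a warning
  tab_b <- tab; tab_b$net_log2 <- NA
  img_b <- render_slide(tab_b, layout, seed = 5, bg_sd = 0)
  enh_b <- enhance_image(reverse_transform(img_b), layout)
  expect_warning(
    g_b <- fit_grid(locate_blocks(enh_b, attr(img_b, "bounds"), layout)[[1]],
                    layout),
    "nominal")
  expect_equal(nrow(g_b), 64L)
})

test_that("TIFF round trip preserves 16-bit pixels", {
  layout <- array_layout(n_sets = 1, set_rows = 8, set_cols = 8)
  tab <- new_spot_table(layout)
  tab$net_log2 <- 10
  img <- render_slide(tab, layout, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_phosphor_tiff(img, path)
  back <- read_phosphor_tiff(path)
  expect_equal(back$pixels, unname(img$pixels))
  expect_equal(back$transform_state, "raw")
})
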