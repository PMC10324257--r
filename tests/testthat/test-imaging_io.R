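test_that("PNG round trip preserves scaled 8-bit intensities", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(128L / 255, 10, 10), p)
  img <- load_image(p)
  expect_equal(dim(img$pixels), c(10, 10, 1))
  expect_true(all(abs(img$pixels - 128 / 255) < 1e-6))

  # extremes of the 8-bit range map to 0 and 1 exactly
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rbind(c(0, 1), c(1, 0)), p2)
  img2 <- load_image(p2)
  expect_equal(range(img2$pixels), c(0, 1))

  expect_error(load_image(file.path(tempdir(), "absent.png")),
               class = "osm_io_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(load_image(bad), class = "osm_io_error")
})

test_that("grayscale expansion replicates the channel", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(25), 5, 5), p)
  img <- load_image(p, expand_gray = TRUE)
  expect_equal(dim(img$pixels)[3], 3)
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])
})

test_that("cropping follows half-open image coordinates", {
  img <- array(runif(512 * 512 * 3), dim = c(512, 512, 3))
  out <- crop_fundus(img, fundus_crop_spec())
  expect_equal(dim(out$pixels), c(250, 300, 3))  # 300 wide x 250 tall

  expect_equal(crop_fundus(img, crop_spec(0, 0, 512, 512))$pixels, img)

  two <- array(matrix(1:4 / 4, 2, 2), dim = c(2, 2, 1))
  single <- crop_fundus(two, crop_spec(1, 1, 2, 2))
  expect_equal(dim(single$pixels), c(1, 1, 1))
  expect_equal(single$pixels[1, 1, 1], two[2, 2, 1])

  small <- array(runif(20 * 20), dim = c(20, 20, 1))
  expect_error(crop_fundus(small, crop_spec(0, 0, 30, 10)),
               "exceeds image bounds")
  expect_error(crop_spec(5, 0, 5, 10))
})

test_that("nested crops compose into a single crop", {
  img <- array(runif(60 * 80 * 1), dim = c(60, 80, 1))
  a <- crop_fundus(crop_fundus(img, crop_spec(10, 5, 70, 55)),
                   crop_spec(3, 7, 40, 30))
  b <- crop_fundus(img, crop_spec(13, 12, 50, 35))
  expect_equal(a$pixels, b$pixels)
})

test_that("resizing is bilinear, identity at matched size, clamped", {
  const <- array(0.37, dim = c(13, 9, 1))
  expect_true(all(abs(resize_image(const, 20)$pixels - 0.37) < 1e-9))

  x <- array(runif(224 * 224 * 3), dim = c(224, 224, 3))
  expect_identical(resize_image(x, 224)$pixels, x)

  two <- array(c(0, 0, 1, 1), dim = c(2, 2, 1))  # rows [[0,1],[0,1]]
  up <- resize_image(two, 4)$pixels[, , 1]
  for (i in 1:4) expect_true(all(diff(up[i, ]) >= -1e-12))
  expect_error(resize_image(two, 0))
})

test_that("channel-wise normalization matches its definition and inverts", {
  px <- array(0.5, dim = c(4, 4, 3))
  x <- normalize_image(px, norm_spec(0.5, 0.5))
  expect_true(all(x == 0))

  px[1, 1, ] <- 1; px[2, 2, ] <- 0
  x <- normalize_image(px, norm_spec(0.5, 0.5))
  expect_equal(x[1, 1, 1], 1)   # 1.0 -> +1
  expect_equal(x[1, 2, 2], -1)  # 0.0 -> -1 (tensor is C x H x W)
  expect_equal(dim(x), c(3, 4, 4))

  img <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
  est <- normalize_image(img, norm_spec(mode = "dataset-estimated"))
  for (ch in 1:3) {
    expect_lt(abs(mean(est[ch, , ])), 1e-6)
    expect_lt(abs(sd(est[ch, , ]) - 1), 1e-6)
  }
  expect_error(normalize_image(array(0.2, dim = c(4, 4, 1)),
                               norm_spec(mode = "dataset-estimated")),
               "zero sd")

  # inverse transform recovers the raster
  back <- denormalize_tensor(normalize_image(img, norm_spec(0.5, 0.5)))
  expect_lt(max(abs(back$pixels - img)), 1e-6)
})

test_that("manifests round-trip through CSV and JSON", {
  m <- manifest(sprintf("img%02d.png", 1:6), rep(c("VO", "PVD"), 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, csv)
  write_manifest(m, js)
  expect_equal(read_manifest(csv)$path, m$path)
  expect_equal(read_manifest(js)$label, m$label)
  expect_error(manifest(c("a", "a"), c("VO", "PVD")), "unique")
  expect_error(manifest(c("a", "b"), c("VO", "VO")), "two classes")
})

test_that("stratified split respects per-class floor(0.7 n) and the seed", {
  m <- manifest(sprintf("i%03d", 1:440), rep(c("VO", "PVD"), each = 220))
  sp <- stratified_split(m, 0.7, seed = 9)
  expect_equal(as.vector(table(sp$train$label)), c(154, 154))
  expect_equal(as.vector(table(sp$test$label)), c(66, 66))
  expect_equal(sort(c(sp$train$path, sp$test$path)), sort(m$path))
  expect_length(intersect(sp$train$path, sp$test$path), 0)

  sp2 <- stratified_split(m, 0.7, seed = 9)
  expect_identical(sp$train$path, sp2$train$path)
  sp3 <- stratified_split(m, 0.7, seed = 10)
  expect_false(identical(sp$train$path, sp3$train$path))

  expect_error(stratified_split(m, 1.0), "empty test")
  full <- stratified_split(m, 1.0, allow_empty_test = TRUE)
  expect_equal(nrow(full$test), 0)
  uneven <- manifest(sprintf("i%02d", 1:11), c(rep("VO", 5), rep("PVD", 6)))
  spu <- stratified_split(uneven, 0.7, seed = 1)
  frac <- table(spu$train$label) / table(uneven$label)
  expect_true(all(abs(frac - 0.7) * table(uneven$label) <= 1))
})

test_that("augmentation order, involution and determinism hold", {
  img <- ramp_image(24, 24, 3)
  hflip <- augment_spec("horizontal-flip")
  twice <- augment_image(augment_image(img, hflip, seed = 1), hflip, seed = 1)
  expect_equal(twice$pixels, img)

  ident <- augment_spec(c("random-crop", "rotation", "color-jitter"),
                        crop_scale = c(1, 1), rotation = c(0, 0),
                        brightness = c(0, 0), contrast = c(1, 1))
  expect_equal(augment_image(img, ident, seed = 3)$pixels, img)

  full <- augment_spec()
  a <- augment_image(img, full, seed = 7)
  b <- augment_image(img, full, seed = 7)
  expect_identical(a$pixels, b$pixels)
  c2 <- augment_image(img, full, seed = 8)
  expect_false(identical(a$pixels, c2$pixels))
  expect_error(augment_spec(character(0)))
})

test_that("the preprocessing chain is crop -> resize -> normalize", {
  img <- array(runif(512 * 512 * 3), dim = c(512, 512, 3))
  pre <- preprocess_spec(crop = fundus_crop_spec(), side = 64)
  x <- preprocess_image(img, pre, label = "VO")
  expect_equal(dim(x), c(3, 64, 64))
  expect_equal(attr(x, "label"), "VO")
  manual <- normalize_image(resize_image(crop_fundus(img, fundus_crop_spec()), 64),
                            norm_spec())
  expect_equal(x, manual, ignore_attr = TRUE)
})
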