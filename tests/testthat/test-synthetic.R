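test_that("vein networks are connected, reproducible, and carry junctions", {
  # single unbranched path -> one connected component
  cfg <- synth_config(n_seeds = 1L, branch_prob = 0, seed = 5L)
  net <- gen_vein_network(cfg)
  expect_equal(max(EBImage::bwlabel(net$mask)), 1)
  expect_true(all(net$mask %in% c(0L, 1L)))

  # determinism
  net2 <- gen_vein_network(cfg)
  expect_identical(net$mask, net2$mask)

  # with branching enabled a junction exists: some vein pixel has 3+
  # skeleton-like neighbors among distinct strokes; detect via a pixel
  # whose 3x3 neighborhood intersects >= 2 strokes beyond its own
  cfgb <- synth_config(branch_prob = 0.02, seed = 9L)
  netb <- gen_vein_network(cfgb)
  expect_gt(length(netb$paths), cfgb$n_seeds)   # at least one branch spawned
  # branch start point lies on the parent stroke -> connected per seed tree
  expect_lte(max(EBImage::bwlabel(netb$mask)), cfgb$n_seeds)
})

test_that("rendered veins are dark with blur-preserved mean and Gaussian-like profile", {
  cfg <- synth_config(seed = 3L)
  net <- gen_vein_network(cfg)

  # no blur: exact inverted mask
  cfg0 <- cfg; cfg0$blur_iters <- 0L
  expect_equal(render_veins(net$mask, cfg0), 1 - net$mask, ignore_attr = TRUE)

  img <- render_veins(net$mask, cfg)
  expect_true(all(img >= 0 & img <= 1))
  # centerline darker than pixels ~3 widths away
  pt <- which(net$mask == 1, arr.ind = TRUE)[200, ]
  far_col <- min(pt[2] + 15, cfg$width)
  if (net$mask[pt[1], far_col] == 0)
    expect_lt(img[pt[1], pt[2]], img[pt[1], far_col])
  # interior mean preserved by smoothing
  expect_lt(abs(mean(img[10:77, 10:202]) -
                mean((1 - net$mask)[10:77, 10:202])), 0.02)
})

test_that("background fields are smooth, bounded, and reproducible", {
  cfg <- synth_config(seed = 21L)
  bg <- gen_background(cfg)
  expect_identical(bg, gen_background(cfg))
  expect_true(all(bg > 0.25 & bg < 0.95))
  # gradient bound
  gx <- abs(diff(bg)); gy <- abs(t(diff(t(bg))))
  expect_lt(max(gx, gy), 0.02)

  # many smoothing iterations approach a constant
  cfg50 <- cfg; cfg50$bg_iters <- 50L
  expect_lt(sd(gen_background(cfg50)), 0.02)
})

test_that("composition and distortion behave as stated", {
  a <- matrix(runif(50, 0, 1), 5, 10)
  b <- matrix(runif(50, 0, 1), 5, 10)
  expect_equal(compose(a, b, 1), a)
  expect_equal(compose(a, b, 0), b)
  expect_equal(compose(a, b, 0.5), (a + b) / 2)
  expect_error(compose(a, matrix(0, 3, 3)), "dims differ")

  img <- matrix(0.5, 100, 100)
  expect_identical(distort(img, "gaussian", 0), img)

  sp <- distort(img, "salt_pepper", 0.1, seed = 4L)
  changed <- sum(sp != img)
  expect_gt(changed, 1000 - 3 * sqrt(1000 * 0.9))  # hits set to 0 or 1
  expect_lt(changed, 1000 + 3 * sqrt(1000 * 0.9))

  g <- distort(img, "gaussian", 0.05, seed = 4L)
  expect_lt(abs(sd(g) - 0.05), 0.005)

  expect_error(distort(img, "poisson", 0.1), "unknown noise kind")
})

test_that("database generation is manifest-stable with in-range vein fractions", {
  db <- gen_database(4, synth_config(), master_seed = 7L)
  expect_length(db, 4)
  fr <- vapply(db, function(s) mean(s$truth), numeric(1))
  expect_true(all(fr > 0.02 & fr < 0.40))
  for (s in db) expect_equal(dim(s$image), dim(s$truth))

  # regeneration reproduces the manifest byte for byte
  db2 <- gen_database(4, synth_config(), master_seed = 7L)
  j1 <- jsonlite::toJSON(attr(db, "manifest"), auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(attr(db2, "manifest"), auto_unbox = TRUE, digits = NA)
  expect_identical(j1, j2)

  # golden manifest fingerprint, frozen from the generator's first release
  f <- tempfile(fileext = ".json")
  writeLines(j1, f)
  expect_equal(unname(tools::md5sum(f)), GOLDEN_MANIFEST_MD5)

  # a written database round-trips through the directory loader
  dir <- tempfile("synthdb")
  gen_database(2, synth_config(), master_seed = 3L, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  loaded <- veinseg:::load_database(dir)
  expect_length(loaded, 2)
  expect_true(all(loaded[[1]]$truth %in% c(0L, 1L)))
})

test_that("noise-free samples have concave Gaussian-like vein cross profiles", {
  s <- gen_sample(synth_config(seed = 13L))
  # at a vein centerline the image is a local minimum along some direction
  rows_mid <- 20:60
  ok <- 0
  for (r in rows_mid) {
    cols <- which(s$truth[r, ] == 1)
    if (length(cols) == 0) next
    c0 <- cols[which.min(s$image[r, cols])]
    if (c0 > 8 && c0 < ncol(s$image) - 8) {
      left <- s$image[r, c0 - 8]; right <- s$image[r, c0 + 8]
      if (s$image[r, c0] < left && s$image[r, c0] < right) ok <- ok + 1
    }
  }
  expect_gt(ok / length(rows_mid), 0.5)
})
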