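# Local projection around a height-map.

make_random_stack <- function(ny = 16, nx = 16, nz = 9, seed = 1) {
  set.seed(seed)
  volume_stack(array(runif(ny * nx * nz, 0, 100), c(ny, nx, nz)))
}

test_that("delta_z = 0 reads exactly the addressed slice, offsets shift it", {
  st <- make_random_stack()
  hm5 <- matrix(5, 16, 16)
  expect_equal(project_channel(st, 1, hm5, channel_params(0, 0, "max")),
               st$data[, , 5, 1, 1])
  expect_equal(project_channel(st, 1, hm5, channel_params(2, 0, "max")),
               st$data[, , 7, 1, 1])
  expect_equal(project_channel(st, 1, hm5, channel_params(0, 0, "mean")),
               st$data[, , 5, 1, 1])
})

test_that("accumulation matches a brute-force per-pixel loop", {
  st <- make_random_stack(seed = 3)
  set.seed(4)
  hm <- matrix(sample(2:6, 256, TRUE) + runif(256, -0.3, 0.3), 16, 16)
  for (mode in c("max", "mean")) {
    out <- project_channel(st, 1, hm, channel_params(0, 1, mode))
    oracle <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) {
      zc <- floor(hm[i, j] + 0.5)
      zs <- max(1, zc - 1):min(9, zc + 1)
      v <- st$data[i, j, zs, 1, 1]
      oracle[i, j] <- if (mode == "max") max(v) else mean(v)
    }
    expect_equal(out, oracle, tolerance = 1e-12)
  }
})

test_that("accumulation windows clip at the stack boundary", {
  st <- make_random_stack(seed = 5)
  hm <- matrix(1, 16, 16)  # window 0..2 clips to 1..2
  out <- project_channel(st, 1, hm, channel_params(0, 1, "mean"))
  expect_equal(out, (st$data[, , 1, 1, 1] + st$data[, , 2, 1, 1]) / 2)
  # window entirely outside collapses to the nearest valid slice
  out2 <- project_channel(st, 1, hm, channel_params(-5, 1, "max"))
  expect_equal(out2, st$data[, , 1, 1, 1])
})

test_that("max over the full slice range reduces to the MIP", {
  st <- make_random_stack(seed = 6)
  set.seed(7)
  hm <- matrix(sample(1:9, 256, TRUE), 16, 16)
  out <- project_channel(st, 1, hm, channel_params(0, 9, "max"))
  expect_equal(out, mip(st))
})

test_that("projection ignores slices outside every accumulation window", {
  st <- make_random_stack(seed = 8)
  hm <- matrix(5, 16, 16)
  base <- project_channel(st, 1, hm, channel_params(0, 1, "max"))
  st2 <- st
  st2$data[, , 9, 1, 1] <- 1e6  # far from every window
  expect_equal(project_channel(st2, 1, hm, channel_params(0, 1, "max")), base)
})

test_that("max mode is monotone in delta_z; mean stays within slice bounds", {
  st <- make_random_stack(seed = 9)
  hm <- matrix(5, 16, 16)
  prev <- project_channel(st, 1, hm, channel_params(0, 0, "max"))
  for (dz in 1:3) {
    cur <- project_channel(st, 1, hm, channel_params(0, dz, "max"))
    expect_true(all(cur >= prev))
    prev <- cur
  }
  mn <- project_channel(st, 1, hm, channel_params(0, 2, "mean"))
  lo <- apply(st$data[, , 3:7, 1, 1], c(1, 2), min)
  hi <- apply(st$data[, , 3:7, 1, 1], c(1, 2), max)
  expect_true(all(mn >= lo - 1e-12 & mn <= hi + 1e-12))
})

test_that("mip picks the brightest slice", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 1; arr[, , 2] <- 5; arr[, , 3] <- 3
  expect_equal(mip(volume_stack(arr)), matrix(5, 4, 4))
  one <- volume_stack(array(runif(16), c(4, 4, 1)))
  expect_equal(mip(one), one$data[, , 1, 1, 1])
})

test_that("a constant channel projects to that constant for any params", {
  spec <- synthetic_preset("flat", seed = 2, ny = 48L, nx = 48L, nz = 10L)
  fx <- synthetic_fixture(spec)
  arr <- array(0, c(48, 48, 10, 2))
  arr[, , , 1] <- fx$stack$data[, , , 1, 1]
  arr[, , , 2] <- 3
  st <- volume_stack(arr)
  proj <- project_stack(st, height_map_params(filter_window = 9, binning = 1,
                                              median_window = 9),
                        list(channel_params(0, 0, "max"),
                             channel_params(1, 2, "mean")))
  expect_true(all(projection_image(proj, 2) == 3))
})

test_that("noiseless surface-only stacks project exactly to the ideal image", {
  spec <- synthetic_preset("flat", seed = 3, ny = 48L, nx = 48L, nz = 10L)
  fx <- synthetic_fixture(spec)
  img <- project_channel(fx$stack, 1, fx$hm_truth, channel_params(0, 0, "max"))
  expect_identical(img, fx$ideal_projection)
})

test_that("shape mismatches and bad indices error", {
  st <- make_random_stack()
  expect_error(project_channel(st, 1, matrix(5, 4, 4), channel_params()),
               "extent")
  expect_error(get_plane(st, 2, 1), "channel")
  expect_error(get_plane(st, 1, 99), "z index")
  expect_error(channel_params(delta_z = -1), "delta_z")
})
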