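# The fixture generator and its ground truth.

test_that("analytic surfaces and their sampled height-maps agree", {
  spec <- synthetic_preset("flat", surface_args = list(z0 = 5))
  s <- make_surface(spec)
  expect_true(all(s$hm_truth == 5 / spec$dz + 1))
  # tilted plane spans tan(theta) * extent slices, linearly
  spec2 <- synthetic_preset("plane", seed = 1,
                            surface_args = list(theta_deg = 30, z0 = 1.5))
  s2 <- make_surface(spec2)
  span <- diff(range(s2$hm_truth))
  expect_equal(span, tan(pi / 6) * (spec2$nx - 1) * spec2$dx / spec2$dz,
               tolerance = 1e-9)
  expect_equal(s2$hm_truth[1, ], s2$hm_truth[160, ])  # no y dependence
  # sphere cap rises by h
  spec3 <- synthetic_preset("sphere")
  s3 <- make_surface(spec3)
  expect_equal(diff(range(s3$hm_truth)),
               spec3$surface_args$h / spec3$dz, tolerance = 0.5)
  # sampled grid matches the closed form at pixel centres
  xs <- (seq_len(spec3$nx) - 1) * spec3$dx
  expect_equal(s3$hm_truth[3, ], s3$f(xs, rep(2 * spec3$dy, spec3$nx)) /
                 spec3$dz + 1)
})

test_that("surfaces leaving the usable z range are rejected", {
  spec <- synthetic_preset("flat", surface_args = list(z0 = 50))
  expect_error(make_surface(spec), "z range")
})

test_that("epithelium masks partition the grid and are seed-reproducible", {
  spec <- synthetic_preset("flat", seed = 23, n_cells = 25L)
  m1 <- make_epithelium_mask(spec)
  m2 <- make_epithelium_mask(spec)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$seeds, m2$seeds)
  labs <- sort(unique(as.vector(m1$mask)))
  expect_equal(labs, 0:25)
  # every label is 4-connected: component labelling of each region gives 1
  for (lab in 1:25) {
    sub <- (m1$mask == lab) * 1L
    comp <- epiproj:::label_components(sub)
    expect_equal(max(comp), 1L)
  }
})

test_that("a single cell covers the grid minus the border band", {
  spec <- synthetic_preset("flat", seed = 3, ny = 32L, nx = 32L, n_cells = 1L)
  m <- make_epithelium_mask(spec)$mask
  expect_equal(sort(unique(as.vector(m))), c(0L, 1L))
  expect_true(all(m[2:31, 2:31] == 1L))
  expect_true(all(m[c(1, 32), ] == 0L))
})

test_that("membrane-only renders put nonzero voxels exactly on the surface", {
  spec <- synthetic_preset("flat", seed = 4, ny = 48L, nx = 48L, nz = 10L,
                           fill_intensity = 0)
  fx <- synthetic_fixture(spec)
  arr <- fx$stack$data[, , , 1, 1]
  zidx <- round(fx$hm_truth)
  nz_pos <- which(arr > 0, arr.ind = TRUE)
  expect_true(all(nz_pos[, 3] == zidx[cbind(nz_pos[, 1], nz_pos[, 2])]))
  # and those (x, y) are junction-band positions
  memb <- epiproj:::dilate_chebyshev(fx$mask == 0L, 0L)
  expect_true(all(fx$mask[nz_pos[, 1:2]] == 0 |
                  arr[nz_pos] == spec$membrane_intensity))
})

test_that("stacks are bitwise reproducible for a fixed seed", {
  spec <- synthetic_preset("notum", seed = 31, ny = 64L, nx = 64L, nz = 16L,
                           n_cells = 20L,
                           surface_args = list(z0 = 6, amplitude = 3,
                                               width = 6))
  a <- render_stack(spec)$stack$data
  b <- render_stack(spec)$stack$data
  expect_identical(a, b)
})

test_that("gaussian noise adds the requested residual sd", {
  spec0 <- synthetic_preset("flat", seed = 9, background = 500)
  specN <- synthetic_preset("flat", seed = 9, background = 500,
                            noise = list(kind = "gaussian", sd = 80))
  a <- render_stack(specN)$stack$data
  b <- render_stack(spec0)$stack$data
  expect_equal(stats::sd(a - b), 80, tolerance = 0.05)
})

test_that("fat bodies corrupt the MIP but not the local projection", {
  spec <- synthetic_preset("notum", seed = 3, noise = list(kind = "none"))
  fx <- synthetic_fixture(spec)
  m <- mip(fx$stack)
  loc <- project_channel(fx$stack, 1, fx$hm_truth, channel_params(0, 1, "max"))
  expect_gt(rmse(m, fx$ideal_projection), rmse(loc, fx$ideal_projection))
  # the MIP overshoots the surface intensity where spurious layers are
  # brighter; the truth-surface projection reproduces it exactly
  expect_gt(max(m - fx$ideal_projection), 100)
  expect_equal(project_channel(fx$stack, 1, fx$hm_truth,
                               channel_params(0, 0, "max")),
               fx$ideal_projection)
})
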