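test_that("grid_spec validates its invariants", {
  expect_s3_class(grid_spec(0.5, 4), "grid_spec")
  expect_error(grid_spec(0, 4), "r must be")
  expect_error(grid_spec(1.2, 4), "r must be")
  expect_error(grid_spec(0.5, 0), "d must be")
  expect_error(grid_spec(0.5, 4, delta_x = 4), "delta_x")
  expect_error(grid_spec(0.5, 4, delta_y = -1), "delta_y")
})

test_that("generate_mask matches the hand-derived lattice examples", {
  # r = 1 removes nothing
  expect_true(all(generate_mask(grid_spec(1, 4), 8, 8) == 1))
  # near-zero keep ratio drops the whole unit
  expect_true(all(generate_mask(grid_spec(1e-9, 8), 8, 8) == 0))
  # r = 0.5, d = 4: four 2x2 zero squares, kept fraction 48/64
  m <- generate_mask(grid_spec(0.5, 4), 8, 8)
  expect_equal(mean(m), 0.75)
  for (tl in list(c(1, 1), c(1, 5), c(5, 1), c(5, 5)))
    expect_true(all(m[tl[1] + 0:1, tl[2] + 0:1] == 0))
  expect_equal(sum(m == 0), 16)
})

test_that("generate_mask rejects invalid sizes", {
  expect_error(generate_mask(grid_spec(0.5, 4), 0, 8), "height")
  expect_error(generate_mask(grid_spec(0.5, 4), 8, -1), "width")
  expect_error(generate_mask(list(), 8, 8), "grid_spec")
})

test_that("offsets translate the drop pattern", {
  m <- generate_mask(grid_spec(0.5, 4, delta_x = 1, delta_y = 2), 8, 8)
  m0 <- generate_mask(grid_spec(0.5, 4), 12, 12)
  # shifted mask equals the unshifted lattice read from offset (-2, -1),
  # i.e. rows 2+d-2.., handled via periodicity: compare by modular identity
  for (i in 1:8) for (j in 1:8)
    expect_identical(m[i, j], m0[(i - 1 - 2) %% 4 + 1, (j - 1 - 1) %% 4 + 1])
})

test_that("un-rotated masks are d-periodic and match the tiling oracle", {
  set.seed(42)
  for (rep in 1:25) {
    d <- sample(2:12, 1)
    r <- runif(1, 0.05, 1)
    dx <- sample(0:(d - 1), 1)
    dy <- sample(0:(d - 1), 1)
    h <- sample(5:30, 1)
    w <- sample(5:30, 1)
    m <- generate_mask(grid_spec(r, d, dx, dy), h, w)
    expect_identical(m, oracle_gridmask(r, d, dx, dy, h, w))
    if (h > d) expect_identical(m[1:(h - d), ], m[(d + 1):h, ])
    if (w > d) expect_identical(m[, 1:(w - d)], m[, (d + 1):w])
  }
})

test_that("exact kept fraction holds when d divides H and W with zero offset", {
  for (d in c(2, 4, 8)) for (r in c(0.25, 0.5, 0.75)) {
    m <- generate_mask(grid_spec(r, d), 32, 32)
    expect_equal(mean(m), 1 - (round((1 - r) * d) / d)^2)
  }
})

test_that("rotated masks stay binary and carry no intact-corner artefact", {
  set.seed(7)
  for (angle in c(15, 45, 90, 201.5)) {
    m <- generate_mask(grid_spec(0.4, 8, rotation_deg = angle), 48, 48)
    expect_true(all(m %in% c(0L, 1L)))
    # drop squares must reach everywhere, including all four corners' quads
    for (q in list(1:24, 25:48))
      for (p in list(1:24, 25:48))
        expect_true(any(m[q, p] == 0))
  }
  # rotation by 90 degrees preserves the kept fraction structure approximately
  m90 <- generate_mask(grid_spec(0.5, 8, rotation_deg = 90), 64, 64)
  expect_lt(abs(mean(m90) - 0.75), 0.05)
})

test_that("apply_mask is the element-wise product and leaves input intact", {
  img <- array(c(0.2, 0.6, 0.4, 0.8), c(2, 2, 1))
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  out <- apply_mask(img, m)
  expect_equal(out[, , 1], matrix(c(0.2, 0, 0, 0.8), 2, 2))
  expect_equal(img[, , 1], matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2))
  # identity and annihilator masks
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(apply_mask(rgb, matrix(1L, 8, 8)), rgb)
  expect_true(all(apply_mask(rgb, matrix(0L, 8, 8)) == 0))
  # masking is idempotent
  mm <- generate_mask(grid_spec(0.5, 4), 8, 8)
  once <- apply_mask(rgb, mm)
  expect_identical(apply_mask(once, mm), once)
  expect_error(apply_mask(rgb, matrix(1L, 4, 4)), "dimensions")
  expect_error(apply_mask(rgb, matrix(2L, 8, 8)), "0/1")
})

test_that("sample_spec respects the policy and is seed-deterministic", {
  pol <- gridmask_policy(r = 0.5, d_range = c(4, 4), rotate = FALSE)
  set.seed(1)
  sp <- sample_spec(pol)
  expect_equal(sp$d, 4L)
  expect_equal(sp$r, 0.5)
  expect_equal(sp$rotation_deg, 0)
  expect_true(sp$delta_x %in% 0:3 && sp$delta_y %in% 0:3)
  set.seed(99)
  a <- sample_spec(gridmask_policy())
  set.seed(99)
  b <- sample_spec(gridmask_policy())
  expect_identical(a, b)
})

test_that("sampled unit lengths are uniform over d_range", {
  set.seed(123)
  pol <- gridmask_policy(d_range = c(8, 32), rotate = FALSE)
  d <- replicate(10000, sample_spec(pol)$d)
  tab <- table(factor(d, levels = 8:32))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("augment_sample applies GridMask per policy", {
  set.seed(5)
  sc <- generate_scene(scene_config(), seed = 11)
  # apply_prob = 0: untouched
  out <- augment_sample(sc$image, sc$label, gridmask_policy(apply_prob = 0))
  expect_identical(out$image, sc$image)
  expect_identical(out$label, sc$label)
  # apply_prob = 1, r < 1: image loses pixels, label untouched by default
  out <- augment_sample(sc$image, sc$label,
                        gridmask_policy(r = 0.5, d_range = c(8, 16),
                                        apply_prob = 1, rotate = FALSE))
  expect_gt(sum(out$image == 0), 0)
  expect_identical(out$label, sc$label)
  # r = 1 removes nothing even when applied
  out <- augment_sample(sc$image, sc$label,
                        gridmask_policy(r = 1, apply_prob = 1))
  expect_identical(out$image, sc$image)
  # mask_labels = TRUE zeroes label pixels under the lattice
  set.seed(5)
  out <- augment_sample(sc$image, sc$label,
                        gridmask_policy(r = 0.3, d_range = c(8, 8),
                                        apply_prob = 1, rotate = FALSE,
                                        mask_labels = TRUE))
  expect_lt(sum(out$label), sum(sc$label))
  expect_error(augment_sample(sc$image, sc$label[1:10, ],
                              gridmask_policy()), "dimensions")
})
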