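test_that("three_point multiplies voxelwise, symmetrically", {
  set.seed(1)
  a <- fake_grid(array(runif(27), c(3, 3, 3)))
  ones <- fake_grid(array(1, c(3, 3, 3)))
  expect_identical(three_point(a, ones)$W, a$fluence)
  b <- fake_grid(array(runif(27), c(3, 3, 3)))
  expect_identical(three_point(a, b)$W, three_point(b, a)$W)

  expect_error(three_point(a, fake_grid(array(1, c(2, 3, 3)))), "mismatched")
  expect_error(three_point(a, fake_grid(array(1, c(3, 3, 3)),
                                        normalized = FALSE)), "normalized")
})

test_that("dynamic-range masking zeroes sub-threshold voxels monotonically", {
  m <- three_point(fake_grid(array(c(1, 1e-3, 1e-6, 0, 0, 0, 0, 0),
                                   c(2, 2, 2))),
                   fake_grid(array(1, c(2, 2, 2))))
  t5 <- threshold_map(m, 5)
  expect_equal(sort(unique(as.vector(t5$W))), c(0, 1e-3, 1))
  expect_identical(threshold_map(m, Inf)$W, m$W)
  expect_error(threshold_map(m, 0.5), "orders")

  tots <- sapply(c(2, 3, 4, 5), function(o) threshold_map(m, o)$total_sum)
  expect_true(all(diff(tots) >= 0))
  expect_lte(max(tots), m$total_sum)
})

test_that("partition sums are proportions that add up and decompose", {
  W <- array(0, c(5, 2, 1)); W[1:10] <- 1  # uniform over 10 voxels
  part <- array(0L, c(5, 2, 1)); part[1:3] <- 1L; part[4:10] <- 2L
  m <- three_point(fake_grid(W), fake_grid(array(1, dim(W))))
  pr <- partition_sums(m, partition_spec(part, c("p1", "p2")))
  expect_equal(pr$proportion, c(0.3, 0.7))
  expect_equal(sum(pr$proportion), 1)

  # tissue partition: brain equals gray + white
  h <- build_layered_sphere(15, c(scalp = 2, skull = 2, csf = 1, gray = 2))
  Wt <- array(0, dim(h$labels)); Wt[h$labels > 0L] <- runif(sum(h$labels > 0L))
  mt <- three_point(fake_grid(Wt), fake_grid(array(1, dim(Wt))))
  prt <- partition_sums(mt, h)
  expect_equal(sum(prt$proportion), 1, tolerance = 1e-12)
  expect_equal(brain_fraction(mt, h),
               sum(prt$proportion[prt$partition %in% c("gray", "white")]))

  # weight on unpartitioned voxels is an error naming the voxel count
  Wb <- Wt; Wb[1, 1, 1] <- 0.5  # air corner
  mb <- three_point(fake_grid(Wb), fake_grid(array(1, dim(Wb))))
  expect_error(partition_sums(mb, h), "1 unpartitioned")
})

test_that("proportions are invariant to the normalization constant", {
  set.seed(2)
  W <- array(runif(27), c(3, 3, 3))
  part <- array(1L + (seq_len(27) %% 2), c(3, 3, 3))
  ps <- partition_spec(part, c("a", "b"))
  m1 <- three_point(fake_grid(W), fake_grid(W + 1))
  m2 <- three_point(fake_grid(W * 7), fake_grid((W + 1) * 3))
  expect_equal(partition_sums(m1, ps)$proportion,
               partition_sums(m2, ps)$proportion, tolerance = 1e-12)
})

test_that("pair enumeration honours separation and midpoint constraints", {
  pts <- data.frame(x = c(-15, 15), y = 0, z = 0)
  p1 <- enumerate_pairs(pts, target = c(0, 0, 0))
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$separation, 30)

  p0 <- enumerate_pairs(pts, target = c(15, 0, 0))
  expect_identical(nrow(p0), 0L)

  set.seed(3)
  many <- data.frame(x = runif(20, -40, 40), y = runif(20, -40, 40), z = 0)
  a <- enumerate_pairs(many, c(0, 0, 0))
  b <- enumerate_pairs(many[rev(seq_len(20)), ], c(0, 0, 0))
  expect_identical(nrow(a), nrow(b))
  expect_equal(sort(a$separation), sort(b$separation))
})

test_that("separation bins are half-open and centred on multiples of 5", {
  pp <- data.frame(separation = c(28, 31), partition = "gray",
                   proportion = c(0.1, 0.1))
  cv <- bin_curve(pp)
  expect_identical(nrow(cv), 1L)
  expect_equal(cv$bin_center, 30)
  expect_equal(cv$n, 2L)
  expect_equal(cv$mean, 0.1)
  expect_equal(cv$se, 0)   # identical proportions

  # the upper edge 32.5 belongs to the next bin
  edge <- bin_curve(data.frame(separation = c(30, 32.5), partition = "gray",
                               proportion = c(0.1, 0.2)))
  expect_equal(edge$bin_center, c(30, 35))
  expect_true(is.na(edge$se[1]))  # single-pair bins report no SE
  expect_equal(edge$n, c(1L, 1L))
})

test_that("location aggregation averages curves with across-location SE", {
  cv <- data.frame(bin_center = 30, partition = "gray", mean = 0.1,
                   se = 0.01, n = 5L)
  same <- aggregate_locations(list(cv, cv))
  expect_equal(same$mean, 0.1)
  expect_equal(same$se, 0)

  two <- aggregate_locations(list(
    transform(cv, mean = 0.1), transform(cv, mean = 0.2)))
  expect_equal(two$mean, 0.15)
  expect_equal(two$se, 0.05)

  cvs <- list(transform(cv, mean = 0.1), transform(cv, mean = 0.2),
              transform(cv, mean = 0.3))
  expect_equal(aggregate_locations(cvs), aggregate_locations(rev(cvs)))
})

test_that("the sensitivity profile is banana-shaped on a slab", {
  slab <- build_layered_slab(c(80, 50, 35), c(scalp = 5, skull = 5, csf = 2,
                                              gray = 4))
  src <- top_source(slab, -15)
  det <- top_source(slab, +15)
  gs <- normalize_fluence(run_mc(slab, source = src,
                                 config = sim_config(1e5, 31)))
  gd <- normalize_fluence(run_mc(slab, source = det,
                                 config = sim_config(1e5, 32)))
  m <- three_point(gs, gd)
  # the peak sits under the optodes; the profile between them dips below
  # the surface (the "banana")
  peak <- arrayInd(which.max(m$W), dim(m$W))
  expect_gte(peak[1], src$i)
  expect_lte(peak[1], det$i)
  expect_gt(slab$labels[peak[1], peak[2], peak[3]], 0)  # inside tissue
  mid <- as.integer((src$i + det$i) / 2)
  mid_peak_k <- which.max(m$W[mid, as.integer(src$j), ])
  expect_gt(mid_peak_k, 4)             # several mm below the surface
  expect_lt(mid_peak_k, dim(m$W)[3] - 4)

  # masking at 5 orders of magnitude leaves the major tissue proportions
  # unchanged to better than 1% relative (the faintest partition sits at
  # the Monte Carlo noise floor at this scaled-down photon count; the
  # full-scale check accompanies the study-condition runs)
  pr_full <- partition_sums(m, slab)
  pr_m5 <- partition_sums(threshold_map(m, 5), slab)
  nz <- pr_full$proportion > 0.05
  expect_true(all(abs(pr_m5$proportion[nz] - pr_full$proportion[nz]) /
                    pr_full$proportion[nz] < 0.01))
})
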