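test_that("scattering step lengths follow the exponential distribution", {
  expect_equal(sample_step(1, exp(-1)), 1)
  expect_error(sample_step(0, 0.5), "mu_s")

  # CSF scattering (0.01/mm) gives ~100 mm free paths
  L <- nindepth:::.sample_step_cpp(1e5, 0.01, 99)
  expect_equal(mean(L), 100, tolerance = 0.02)

  L2 <- nindepth:::.sample_step_cpp(1e4, 0.7, 123)
  ks <- suppressWarnings(stats::ks.test(L2, stats::pexp, rate = 0.7))
  expect_gt(ks$p.value, 0.01)
})

test_that("Henyey-Greenstein sampling has mean cosine g", {
  expect_error(sample_scatter(1, 0.5, 0.5), "anisotropy")
  # isotropic limit: uniform cosine
  ct0 <- nindepth:::.sample_hg_cpp(1e5, 0, 7)
  ks <- suppressWarnings(stats::ks.test(ct0, stats::punif, min = -1, max = 1))
  expect_gt(ks$p.value, 0.01)

  for (g in c(0, 0.01, 0.5, 0.9)) {
    ct <- nindepth:::.sample_hg_cpp(1e6, g, 1000 + round(1000 * g))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se + 1e-12)
  }

  # the R-level sampler returns unit vectors with the sampled cosine as z
  v <- sample_scatter(0.9, 0.3, 0.6)
  expect_equal(sum(v^2), 1)
})

test_that("Fresnel reflectance matches closed forms (R and C++ agree)", {
  expect_equal(fresnel_reflectance(1, 1, 0.3), 0)
  expect_equal(fresnel_reflectance(1.4, 1.0, 1.0), (0.4 / 2.4)^2)
  # beyond the critical angle: total internal reflection
  expect_equal(fresnel_reflectance(1.4, 1.0, 0.1), 1)
  for (ci in seq(0, 1, by = 0.1))
    expect_equal(fresnel_reflectance(1.4, 1.0, ci),
                 nindepth:::.fresnel_cpp(1.4, 1.0, ci))
})

test_that("photon weight is conserved without absorption", {
  slab <- gray_block(c(40, 40, 20))
  opt <- default_optics()
  opt$mu_a[] <- 0
  cfg <- sim_config(n_photons = 2e4, seed = 11, t_max_ns = 100)
  g <- run_mc(slab, opt, top_source(slab), config = cfg)
  # with mu_a = 0 and a generous time budget every photon exits at weight 1
  expect_equal(unname(g$ledger["exit"]), 2e4)
  expect_equal(unname(g$ledger["absorbed"]), 0)
})

test_that("forced straight paths obey Beer-Lambert through the layers", {
  th <- c(scalp = 5, skull = 4, csf = 2, gray = 3)
  slab <- build_layered_slab(c(20, 20, 20), th)
  opt <- default_optics()
  opt$mu_s[2:6] <- 1e-9  # step far longer than the slab: no scattering
  src <- top_source(slab)
  det <- data.frame(x = src$x, y = src$y, z = 20)  # straight below the source
  cfg <- sim_config(n_photons = 1, seed = 3)
  g <- run_mc(slab, opt, src, detectors = det, config = cfg)
  # the photon starts at the source voxel centre, half a voxel into the
  # scalp, so the scalp path is th - h/2
  paths <- c(5 - 0.5, 4, 2, 3, 20 - sum(th))
  mu <- setNames(opt$mu_a, opt$tissue)
  expected <- exp(-sum(mu[c("scalp", "skull", "csf", "gray", "white")] * paths))
  expect_equal(unname(g$ledger["exit"]), expected, tolerance = 1e-12)

  # the detected photon's per-tissue path lengths equal the layer depths
  hist <- g$history[[1]]
  expect_identical(nrow(hist), 1L)
  expect_equal(as.numeric(hist[1, -1]), paths, tolerance = 1e-9)
})

test_that("energy ledger closes and runs are seed-deterministic", {
  slab <- build_layered_slab(c(40, 40, 30), c(scalp = 5, skull = 5, csf = 2,
                                              gray = 4))
  cfg <- sim_config(n_photons = 1e4, seed = 21)
  g1 <- run_mc(slab, source = top_source(slab), config = cfg)
  expect_equal(sum(g1$ledger), 1e4, tolerance = 1e-6)

  g2 <- run_mc(slab, source = top_source(slab), config = cfg)
  expect_identical(g1$fluence, g2$fluence)

  g3 <- run_mc(slab, source = top_source(slab),
               config = sim_config(1e4, seed = 22))
  expect_false(identical(g1$fluence, g3$fluence))

  expect_error(run_mc(slab, source = data.frame(x = 0, y = 0, z = -5,
                                                dx = 0, dy = 0, dz = 1)),
               "not inside tissue")
})

test_that("zero photons give an empty grid and empty histories", {
  slab <- gray_block(c(20, 20, 12))
  g <- run_mc(slab, source = top_source(slab),
              detectors = data.frame(x = 14.5, y = 9.5, z = 0),
              config = sim_config(0, seed = 1))
  expect_true(all(g$fluence == 0))
  expect_identical(nrow(g$history[[1]]), 0L)
})

test_that("on-axis fluence decay matches diffusion theory for gray matter", {
  slab <- gray_block(c(80, 80, 60))
  src <- top_source(slab)
  g <- run_mc(slab, source = src, config = sim_config(2e5, seed = 5))
  f <- g$fluence
  ci <- as.integer(src$i); cj <- as.integer(src$j)
  prof <- sapply(2:(dim(f)[3] - 1), function(k)
    mean(f[(ci - 2):(ci + 2), (cj - 2):(cj + 2), k]))
  depth <- (2:(dim(f)[3] - 1)) - 1.5
  sel <- depth >= 5 & depth <= 35   # beyond ~2 transport lengths, good stats
  fit <- lm(log(prof[sel] * depth[sel]) ~ depth[sel])  # point source ~ exp(-x)/x
  mu_eff <- sqrt(3 * 0.0195 * (0.0195 + 1.10 * (1 - 0.01)))
  expect_lt(abs(-coef(fit)[2] - mu_eff) / mu_eff, 0.15)
})

test_that("fluence obeys source-detector reciprocity in a homogeneous block", {
  blk <- gray_block(c(40, 40, 24))
  pa <- top_source(blk, -7)
  pb <- top_source(blk, +7)
  probe <- function(g, pt) {
    i <- as.integer(pt$i); j <- as.integer(pt$j); k <- as.integer(pt$k)
    sum(g$fluence[(i - 1):(i + 1), (j - 1):(j + 1), k:(k + 2)])
  }
  ab <- sapply(1:5, function(r) probe(run_mc(blk, source = pa,
    config = sim_config(5e4, 300 + r)), pb))
  ba <- sapply(1:5, function(r) probe(run_mc(blk, source = pb,
    config = sim_config(5e4, 400 + r)), pa))
  se <- sqrt(sd(ab)^2 / 5 + sd(ba)^2 / 5)
  expect_lt(abs(mean(ab) - mean(ba)), 3 * se)
})

test_that("detected photon counts fall with source-detector separation", {
  slab <- build_layered_slab(c(90, 60, 30), c(scalp = 5, skull = 5, csf = 2,
                                              gray = 4))
  src <- top_source(slab, -20)
  dets <- do.call(rbind, lapply(c(-10, 0, 20), function(o) {
    p <- top_source(slab, o); data.frame(x = p$x, y = p$y, z = 0)
  }))
  g <- run_mc(slab, source = src, detectors = dets,
              config = sim_config(2e5, seed = 77))
  counts <- vapply(g$history, nrow, integer(1))  # separations 10, 20, 40 mm
  expect_gt(counts[1], counts[2])
  expect_gt(counts[2], counts[3])
})

test_that("normalization is per-photon, idempotent, and scale-consistent", {
  slab <- gray_block(c(20, 20, 12))
  g <- run_mc(slab, source = top_source(slab), config = sim_config(2000, 9))
  tot <- sum(g$fluence)
  gn <- normalize_fluence(g)
  expect_equal(sum(gn$fluence), tot / 2000)
  expect_warning(gn2 <- normalize_fluence(gn), "already normalized")
  expect_identical(gn2$fluence, gn$fluence)

  # per-photon deposition is consistent across photon counts
  g2 <- normalize_fluence(run_mc(slab, source = top_source(slab),
                                 config = sim_config(2e4, 10)))
  expect_equal(sum(gn$fluence), sum(g2$fluence), tolerance = 0.05)
})
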