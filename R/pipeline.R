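md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Declarative configuration for an end-to-end sensitivity run
#'
#' Encodes the whole workflow: phantom geometry, optics, the paired
#' source-detector separations to simulate, Monte Carlo settings, masking
#' orders, shell construction and binning.
#'
#' @param phantom List: `type` ("sphere" or "slab") plus the geometry
#'   arguments of [build_layered_sphere()] / [build_layered_slab()].
#' @param optics Optical-property table.
#' @param separations Source-detector separations (mm) to simulate; each
#'   pairs the surface anchor with one partner point.
#' @param mc List: `n_photons`, `seed`, and optionally `t_max_ns`,
#'   `collection_radius_mm`.
#' @param orders Dynamic-range masking levels to report (`Inf` = none).
#' @param shells List: `n_shells`, `step_voxels`.
#' @param bin_width Separation bin width, mm.
#' @param max_fit_depth Deepest shell depth (mm) entering the exponential
#'   fits.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = list(type = "sphere", outer_radius = 80,
                                      thicknesses = c(scalp = 6.9, skull = 6.1,
                                                      csf = 2, gray = 4),
                                      voxel_size = 1),
                       optics = default_optics(),
                       separations = c(20, 30, 55),
                       mc = list(n_photons = 1e5, seed = 1),
                       orders = Inf,
                       shells = list(n_shells = 21, step_voxels = 2),
                       bin_width = 5,
                       max_fit_depth = 20) {
  structure(list(phantom = phantom, optics = optics,
                 separations = separations, mc = mc, orders = orders,
                 shells = shells, bin_width = bin_width,
                 max_fit_depth = max_fit_depth),
            class = "run_config")
}

build_phantom <- function(phantom) {
  args <- phantom[setdiff(names(phantom), "type")]
  switch(phantom$type,
         sphere = do.call(build_layered_sphere, args),
         slab = do.call(build_layered_slab, args),
         stop("unknown phantom type: ", phantom$type))
}

pipeline_stage <- function(manifest, out_dir, stage, file, md5 = NULL) {
  path <- file.path(out_dir, file)
  if (is.null(md5)) md5 <- unname(tools::md5sum(path))
  manifest$files[[file]] <- list(stage = stage, md5 = md5)
  manifest
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full phantom-to-depth-regression pipeline
#'
#' Stages, in order: phantom construction, surface-point placement, one
#' Monte Carlo simulation per unique injection point (cached on disk keyed
#' by phantom + source + MC spec, so re-runs reuse fluence grids), 3-point
#' sensitivity maps per separation, tissue- and shell-partition
#' proportions (at each masking level), separation curves, depth profiles
#' and exponential depth fits. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (also written as `manifest.json`): file list
#'   with stage provenance and md5 checksums, plus seed, config hash and
#'   package version.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("nindepth")),
                   seed = config$mc$seed,
                   config_hash = md5_of(unclass(config)),
                   files = list())

  # --- phantom -----------------------------------------------------------
  head <- build_phantom(config$phantom)
  save_label_volume(head, file.path(out_dir, "phantom.nii"))
  manifest <- pipeline_stage(manifest, out_dir, "phantom", "phantom.nii")

  # --- injection points --------------------------------------------------
  pts <- if (config$phantom$type == "sphere")
    surface_points_at_separations(head, config$separations)
  else
    slab_points_at_separations(head, config$separations)
  write_tsv(pts, file.path(out_dir, "surface_points.tsv"))
  manifest <- pipeline_stage(manifest, out_dir, "points", "surface_points.tsv")

  # --- Monte Carlo (cached) ---------------------------------------------
  mc <- config$mc
  cfg <- sim_config(n_photons = mc$n_photons,
                    seed = mc$seed,
                    t_max_ns = if (is.null(mc$t_max_ns)) 10 else mc$t_max_ns,
                    collection_radius_mm =
                      if (is.null(mc$collection_radius_mm)) 1.5
                      else mc$collection_radius_mm)
  grids <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    key <- md5_of(list(config$phantom, config$optics,
                       as.numeric(pts[p, c("x", "y", "z", "dx", "dy", "dz")]),
                       unclass(cfg)))
    cache_file <- file.path(cache_dir, paste0("fluence_", key, ".rds"))
    if (file.exists(cache_file)) {
      grids[[p]] <- readRDS(cache_file)
    } else {
      g <- normalize_fluence(run_mc(head, config$optics, pts[p, ],
                                    config = cfg))
      saveRDS(g, cache_file, version = 2)
      grids[[p]] <- g
    }
    manifest <- pipeline_stage(manifest, cache_dir, "mc",
                               file.path("cache", basename(cache_file)))
  }

  # --- sensitivity maps and partition sums ------------------------------
  shells <- compute_shells(head, config$shells$n_shells,
                           config$shells$step_voxels)
  tissue_rows <- list()
  shell_rows <- list()
  for (s in seq_along(config$separations)) {
    map <- three_point(grids[[1]], grids[[s + 1]])
    for (om in config$orders) {
      masked <- threshold_map(map, om)
      pr <- partition_sums(masked, head)
      pr$separation <- map$separation
      pr$orders <- om
      tissue_rows[[length(tissue_rows) + 1]] <- pr
      sp <- partition_sums(masked, shells)
      sp$separation <- map$separation
      sp$orders <- om
      shell_rows[[length(shell_rows) + 1]] <- sp
    }
  }
  tissue_props <- do.call(rbind, tissue_rows)
  shell_props <- do.call(rbind, shell_rows)
  write_tsv(tissue_props, file.path(out_dir, "tissue_proportions.tsv"))
  write_tsv(shell_props, file.path(out_dir, "shell_proportions.tsv"))
  manifest <- pipeline_stage(manifest, out_dir, "sensitivity",
                             "tissue_proportions.tsv")
  manifest <- pipeline_stage(manifest, out_dir, "sensitivity",
                             "shell_proportions.tsv")

  # --- curves and depth fits (unmasked level) ---------------------------
  first_orders <- config$orders[1]
  tp <- tissue_props[tissue_props$orders == first_orders, ]
  curve <- bin_curve(tp[, c("separation", "partition", "proportion")],
                     config$bin_width)
  write_tsv(curve, file.path(out_dir, "sensitivity_curve.tsv"))
  manifest <- pipeline_stage(manifest, out_dir, "curves",
                             "sensitivity_curve.tsv")

  sp <- shell_props[shell_props$orders == first_orders, ]
  profile <- depth_profile(sp[, c("separation", "partition", "proportion")],
                           shells, config$bin_width)
  write_tsv(profile, file.path(out_dir, "depth_profile.tsv"))
  manifest <- pipeline_stage(manifest, out_dir, "depth", "depth_profile.tsv")

  fits <- fit_depth_profile(profile, max_depth = config$max_fit_depth)
  fit_table <- depth_fit_table(fits)
  write_tsv(fit_table, file.path(out_dir, "depth_fits.tsv"))
  manifest <- pipeline_stage(manifest, out_dir, "depth", "depth_fits.tsv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write small demonstration fixtures
#'
#' Generates, under `out_dir`: a small layered slab phantom and a 40 mm
#' layered sphere phantom (NIfTI), the default optics table (TSV), and a
#' pair of small fluence grids computed with a fixed seed (NIfTI + JSON
#' sidecars), plus `checksums.json` with the md5 of every file.
#'
#' @param out_dir Output directory.
#' @return Invisibly, the checksum list.
#' @export
make_demo_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slab <- build_layered_slab(c(40, 40, 30), c(scalp = 5, skull = 5, csf = 2,
                                              gray = 4), voxel_size = 1)
  save_label_volume(slab, file.path(out_dir, "demo_slab.nii"))
  sphere <- build_layered_sphere(40, voxel_size = 1)
  save_label_volume(sphere, file.path(out_dir, "demo_sphere.nii"))
  write_tsv(default_optics(), file.path(out_dir, "optics.tsv"))

  cfg <- sim_config(n_photons = 5e3, seed = 42)
  for (p in 1:2) {
    g <- run_mc(slab, source = slab_surface_point(slab, if (p == 1) 0 else 15),
                config = cfg)
    save_fluence(g, file.path(out_dir, sprintf("demo_fluence_%d.nii", p)))
  }
  files <- list.files(out_dir, full.names = TRUE)
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  jsonlite::write_json(sums, file.path(out_dir, "checksums.json"),
                       auto_unbox = TRUE)
  invisible(sums)
}

# anchor at the centre of a slab's top face plus one partner per
# separation, offset along x; mirrors surface_points_at_separations
slab_points_at_separations <- function(slab, separations) {
  rows <- lapply(c(0, separations), function(s) slab_surface_point(slab, s))
  out <- do.call(rbind, rows)
  out$role <- c("anchor", as.character(separations))
  out$separation <- c(NA_real_,
                      sqrt(colSums((t(out[-1, c("x", "y", "z")]) -
                                      as.numeric(out[1, c("x", "y", "z")]))^2)))
  out
}

# surface point on the top face of a slab phantom, offset mm from the
# centre of the face along x
slab_surface_point <- function(slab, offset_mm = 0) {
  d <- dim(slab$labels)
  h <- slab$voxel_size
  i <- as.integer(round((d[1] + 1) / 2 + offset_mm / h))
  j <- as.integer(round((d[2] + 1) / 2))
  k <- 2L  # first tissue layer below the air padding
  pos <- (c(i, j, k) - 1) * h + slab$origin
  data.frame(x = pos[1], y = pos[2], z = pos[3], dx = 0, dy = 0, dz = 1,
             i = i, j = j, k = k)
}
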