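#' Monte Carlo simulation configuration
#'
#' @param n_photons Number of photons to launch.
#' @param seed Integer seed; every random draw in the transport kernel is a
#'   deterministic function of it.
#' @param t_max_ns Photon lifetime cutoff in ns (default 10); photons still
#'   in flight at the cutoff are tallied as in-flight weight. With n = 1 the
#'   cutoff corresponds to a path length of about 2998 mm.
#' @param c_mm_ns Speed of light in the medium, mm/ns.
#' @param collection_radius_mm Detector collection radius (default 1.5 mm,
#'   i.e. a 3 mm diameter aperture).
#' @param w_min Survival-weight floor triggering Russian roulette.
#' @param roulette_p Roulette survival probability.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_photons = 1e6, seed = 1L, t_max_ns = 10,
                       c_mm_ns = C_LIGHT_MM_NS, collection_radius_mm = 1.5,
                       w_min = 1e-8, roulette_p = 0.1) {
  stopifnot(n_photons >= 0, t_max_ns > 0, collection_radius_mm > 0,
            w_min > 0, roulette_p > 0, roulette_p < 1)
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 t_max_ns = t_max_ns, c_mm_ns = c_mm_ns,
                 collection_radius_mm = collection_radius_mm,
                 w_min = w_min, roulette_p = roulette_p),
            class = "sim_config")
}

#' Sample a scattering step length
#'
#' Free path between scattering events, drawn from the exponential
#' distribution with rate `mu_s`: `L = -log(u) / mu_s`.
#'
#' @param mu_s Scattering coefficient, 1/mm (> 0).
#' @param u Uniform deviate(s) in (0, 1].
#' @return Step length(s) in mm.
#' @export
sample_step <- function(mu_s, u) {
  if (mu_s <= 0) stop("mu_s must be > 0")
  -log(u) / mu_s
}

#' Sample a Henyey-Greenstein scattering deflection
#'
#' Draws the cosine of the polar deflection angle from the
#' Henyey-Greenstein phase function with anisotropy `g` (uniform on
#' \[-1, 1\] in the isotropic limit g = 0) and a uniform azimuth, returning
#' the new propagation direction relative to an old direction of (0, 0, 1).
#'
#' @param g Anisotropy, -1 < g < 1; equals the mean cosine of the sampled
#'   deflection.
#' @param u1,u2 Uniform deviates in \[0, 1).
#' @return Unit 3-vector `c(dx, dy, dz)`; `dz` is the sampled cosine.
#' @export
sample_scatter <- function(g, u1, u2) {
  if (abs(g) >= 1) stop("anisotropy g must satisfy -1 < g < 1")
  if (abs(g) < 1e-6) {
    ct <- 2 * u1 - 1
  } else {
    s <- (1 - g^2) / (1 - g + 2 * g * u1)
    ct <- (1 + g^2 - s^2) / (2 * g)
    ct <- pmin(1, pmax(-1, ct))
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * u2
  c(st * cos(phi), st * sin(phi), ct)
}

#' Unpolarized Fresnel reflectance
#'
#' Probability of internal reflection at a planar interface between media
#' of refractive indices `n1` (incident side) and `n2`, for incidence
#' cosine `cos_incident`; returns 1 beyond the critical angle and 0 for
#' matched indices. Inputs are clamped to their valid ranges.
#'
#' @param n1,n2 Refractive indices (>= 1).
#' @param cos_incident Cosine of the incidence angle, in \[0, 1\].
#' @return Reflection probability in \[0, 1\].
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  ci <- min(1, max(0, cos_incident))
  if (n1 == n2) return(0)
  st2 <- (n1 / n2)^2 * (1 - ci^2)
  if (st2 >= 1) return(1)
  ct <- sqrt(1 - st2)
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  (rs^2 + rp^2) / 2
}

mm_to_voxel_units <- function(pos_mm, head) {
  (pos_mm - head$origin) / head$voxel_size + 0.5
}

#' Run a Monte Carlo photon-transport simulation
#'
#' Launches `config$n_photons` photons at the source position along the
#' source direction and traces them voxel-by-voxel through the head model:
#' exponential scattering lengths in optical depth (so tissue boundaries
#' rescale the remaining depth), Henyey-Greenstein deflections,
#' Beer-Lambert absorption weighting per voxel segment, Fresnel
#' internal-reflection tests at tissue-air boundaries, a 10 ns lifetime
#' cutoff and Russian-roulette termination of low-weight photons. Fluence
#' is accumulated per voxel with the path-length estimator (each voxel a
#' photon crosses accrues weight x segment length), yielding the 2-point
#' Green's function of the source after normalization.
#'
#' An energy ledger (exit + absorbed + in-flight + roulette balance =
#' photons launched) is checked to 1e-6 relative tolerance on every run.
#'
#' @param head A `head_volume`.
#' @param optics Optical-property table as from [default_optics()].
#' @param source A single-row data frame with `x,y,z,dx,dy,dz` (as returned
#'   by [place_surface_points()]) or a list with `position` and `direction`.
#' @param detectors Optional matrix/data frame of detector mm positions
#'   (columns x, y, z); photons exiting within the collection radius of a
#'   detector are recorded in its history.
#' @param config A [sim_config()].
#' @return A `fluence_grid`: list with `fluence` (array, weight x mm per
#'   voxel), `n_launched`, `normalized`, `voxel_size`, `origin`, `source`,
#'   `seed`, energy `ledger`, and `history` (per detector: data frame with
#'   exit `weight` and per-tissue path lengths in mm, plus the detector
#'   position and collection radius as attributes).
#' @export
run_mc <- function(head, optics = default_optics(), source,
                   detectors = NULL, config = sim_config()) {
  stopifnot(inherits(head, "head_volume"))
  optics <- validate_optics(optics)
  if (is.data.frame(source)) {
    stopifnot(nrow(source) == 1)
    src_pos <- as.numeric(source[1, c("x", "y", "z")])
    src_dir <- as.numeric(source[1, c("dx", "dy", "dz")])
  } else {
    src_pos <- source$position
    src_dir <- source$direction
  }
  src_dir <- src_dir / sqrt(sum(src_dir^2))
  ijk <- floor((src_pos - head$origin) / head$voxel_size + 0.5) + 1
  if (any(ijk < 1) || any(ijk > dim(head$labels)) ||
      head$labels[ijk[1], ijk[2], ijk[3]] == 0L)
    stop("source position is not inside tissue")

  if (is.null(detectors)) {
    det <- matrix(numeric(0), 0, 3)
  } else {
    det <- as.matrix(as.data.frame(detectors)[, c("x", "y", "z")])
  }
  det_v <- if (nrow(det)) t(apply(det, 1, mm_to_voxel_units, head = head)) else det
  dim(det_v) <- c(nrow(det), 3)

  max_path_mm <- config$t_max_ns * config$c_mm_ns
  res <- .run_mc_cpp(as.integer(head$labels), as.integer(dim(head$labels)),
                     head$voxel_size,
                     optics$mu_a, optics$mu_s, optics$g, optics$n,
                     mm_to_voxel_units(src_pos, head), src_dir,
                     det_v, config$collection_radius_mm,
                     config$n_photons, config$seed,
                     max_path_mm, config$w_min, config$roulette_p)
  if (res$geometry_errors > 0)
    stop("malformed phantom: ", res$geometry_errors,
         " photon(s) escaped the grid without touching air")

  ledger <- c(exit = res$exit_weight, absorbed = res$absorbed_weight,
              inflight = res$inflight_weight, roulette = res$roulette_net)
  if (config$n_photons > 0) {
    rel <- abs(sum(ledger) - config$n_photons) / config$n_photons
    if (rel > 1e-6)
      stop(sprintf("energy ledger violated: relative error %.3g", rel))
  }

  hist <- lapply(seq_len(nrow(det)), function(d) {
    m <- res$history[[d]]
    df <- as.data.frame(m)
    names(df) <- c("weight", "path_scalp", "path_skull", "path_csf",
                   "path_gray", "path_white")
    attr(df, "detector") <- det[d, ]
    attr(df, "collection_radius_mm") <- config$collection_radius_mm
    df
  })

  structure(list(fluence = res$fluence, n_launched = config$n_photons,
                 normalized = FALSE, voxel_size = head$voxel_size,
                 origin = head$origin, source = src_pos, seed = config$seed,
                 ledger = ledger, history = hist),
            class = "fluence_grid")
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat(sprintf(
    "<fluence_grid> %s voxels, %g photons (seed %d)%s, total weight %.6g\n",
    paste(dim(x$fluence), collapse = " x "), x$n_launched, x$seed,
    if (x$normalized) ", normalized" else "", sum(x$fluence)))
  invisible(x)
}

#' Normalize a fluence grid to a per-photon Green's function
#'
#' Divides the accumulated weights by the number of photons launched.
#' Idempotent: normalizing twice warns and returns the input unchanged.
#'
#' @param grid A `fluence_grid`.
#' @return The normalized `fluence_grid`.
#' @export
normalize_fluence <- function(grid) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (grid$normalized) {
    warning("fluence grid is already normalized; returning unchanged")
    return(grid)
  }
  if (grid$n_launched <= 0) stop("cannot normalize a grid with no photons")
  grid$fluence <- grid$fluence / grid$n_launched
  grid$normalized <- TRUE
  grid
}

#' Save a fluence grid as NIfTI with a JSON sidecar
#'
#' The sidecar records the seed, photon count, source position and energy
#' ledger so that any saved grid can be traced to its simulation.
#'
#' @param grid A `fluence_grid`.
#' @param path Output `.nii`/`.nii.gz` path; the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `path`, invisibly.
#' @export
save_fluence <- function(grid, path) {
  img <- RNifti::asNifti(grid$fluence)
  RNifti::pixdim(img) <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- list(n_launched = grid$n_launched, seed = grid$seed,
               normalized = grid$normalized, source = grid$source,
               origin = grid$origin, ledger = as.list(grid$ledger),
               package_version = as.character(utils::packageVersion("nindepth")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
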