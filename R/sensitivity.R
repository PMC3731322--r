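#' Build a 3-point sensitivity map from two fluence grids
#'
#' The spatial sensitivity of a continuous-wave source-detector pair to a
#' local absorption change is the voxelwise product of the normalized
#' 2-point Green's functions of the source and of the detector (by
#' reciprocity). The operation is symmetric in its two arguments.
#'
#' @param src,det Normalized `fluence_grid`s on the same voxel grid.
#' @param separation Optional source-detector separation in mm; computed
#'   from the grids' source positions when available.
#' @return A `three_point_map`: list with `W` (array), `total_sum`,
#'   `separation`, `voxel_size`, `origin`.
#' @export
three_point <- function(src, det, separation = NULL) {
  stopifnot(inherits(src, "fluence_grid"), inherits(det, "fluence_grid"))
  if (!src$normalized || !det$normalized)
    stop("both fluence grids must be normalized (see normalize_fluence)")
  if (!identical(dim(src$fluence), dim(det$fluence)) ||
      !isTRUE(all.equal(src$voxel_size, det$voxel_size)))
    stop("fluence grids have mismatched geometry")
  if (is.null(separation) && !is.null(src$source) && !is.null(det$source))
    separation <- sqrt(sum((src$source - det$source)^2))
  W <- src$fluence * det$fluence
  structure(list(W = W, total_sum = sum(W), separation = separation,
                 voxel_size = src$voxel_size, origin = src$origin),
            class = "three_point_map")
}

#' @export
print.three_point_map <- function(x, ...) {
  cat(sprintf("<three_point_map> %s voxels, separation %s mm, total %.4g\n",
              paste(dim(x$W), collapse = " x "),
              if (is.null(x$separation)) "?" else signif(x$separation, 4),
              x$total_sum))
  invisible(x)
}

#' Mask a sensitivity map at a dynamic-range limit
#'
#' Zeroes voxels whose sensitivity lies more than `orders` orders of
#' magnitude below the map's peak, emulating an instrument with limited
#' dynamic range (2 orders is roughly a 40 dB instrument). `orders = Inf`
#' leaves the map untouched.
#'
#' @param map A `three_point_map`.
#' @param orders Orders of magnitude retained below peak (>= 1).
#' @return The masked `three_point_map` with `total_sum` recomputed.
#' @export
threshold_map <- function(map, orders) {
  stopifnot(inherits(map, "three_point_map"))
  if (orders < 1) stop("orders must be >= 1")
  if (is.infinite(orders)) return(map)
  peak <- max(map$W)
  map$W[map$W < peak * 10^(-orders)] <- 0
  map$total_sum <- sum(map$W)
  map
}

#' Partition specification
#'
#' Pairs an integer assignment grid with partition names. Code 0 means
#' "unassigned" (air). A `head_volume` is interpreted as the five-tissue
#' partition; a `shell_set` supplies its depth-shell partition.
#'
#' @param x A `head_volume`, `shell_set`, or integer array.
#' @param names Partition names for codes 1..max (required for raw arrays).
#' @return A `partition_spec` list with `grid` and `names`.
#' @export
partition_spec <- function(x, names = NULL) {
  if (inherits(x, "head_volume")) {
    return(structure(list(grid = x$labels,
                          names = c("scalp", "skull", "csf", "gray", "white")),
                     class = "partition_spec"))
  }
  if (inherits(x, "shell_set")) {
    return(structure(list(grid = x$partition, names = x$names),
                     class = "partition_spec"))
  }
  if (inherits(x, "partition_spec")) return(x)
  stopifnot(is.array(x), !is.null(names))
  structure(list(grid = x, names = names), class = "partition_spec")
}

#' Sensitivity proportions by partition
#'
#' Sums the 3-point weights over every voxel of each partition and divides
#' by the map total, giving the proportion of the measurement's sensitivity
#' attributable to that partition. Over an exhaustive partition the
#' proportions sum to 1.
#'
#' @param map A `three_point_map`.
#' @param partition Anything accepted by [partition_spec()].
#' @return A data frame with `partition`, `proportion`, `sum_w`, `n_voxels`.
#' @export
partition_sums <- function(map, partition) {
  stopifnot(inherits(map, "three_point_map"))
  ps <- partition_spec(partition)
  if (!identical(dim(ps$grid), dim(map$W)))
    stop("partition grid does not match the sensitivity map geometry")
  un <- ps$grid == 0L & map$W > 0
  if (any(un))
    stop("sensitivity is nonzero on ", sum(un), " unpartitioned voxel(s)")
  codes <- seq_along(ps$names)
  grid <- as.integer(ps$grid)
  sums <- vapply(codes, function(cd) sum(map$W[grid == cd]), numeric(1))
  nvox <- tabulate(grid, nbins = length(codes))
  tot <- map$total_sum
  data.frame(partition = ps$names,
             proportion = if (tot > 0) sums / tot else rep(NA_real_, length(sums)),
             sum_w = sums, n_voxels = nvox,
             stringsAsFactors = FALSE)
}

#' Enumerate source-detector pairs around a target location
#'
#' All unordered pairs of surface points separated by no more than
#' `max_separation` whose 3D midpoint lies within `midpoint_radius` of the
#' target location.
#'
#' @param points Data frame of surface points (columns `x,y,z`).
#' @param target Target mm position (length 3).
#' @param midpoint_radius Midpoint constraint radius, mm (default 10).
#' @param max_separation Maximum separation, mm (default 60).
#' @return A `pair_set` data frame with `src`, `det` (row indices into
#'   `points`), `separation` and midpoint columns `mx,my,mz`.
#' @export
enumerate_pairs <- function(points, target, midpoint_radius = 10,
                            max_separation = 60) {
  stopifnot(nrow(points) >= 2, length(target) == 3)
  P <- as.matrix(points[, c("x", "y", "z")])
  n <- nrow(P)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  dsep <- sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
  mid <- (P[a, , drop = FALSE] + P[b, , drop = FALSE]) / 2
  dmid <- sqrt(colSums((t(mid) - target)^2))
  keep <- dsep <= max_separation & dmid <= midpoint_radius
  out <- data.frame(src = a[keep], det = b[keep], separation = dsep[keep],
                    mx = mid[keep, 1], my = mid[keep, 2], mz = mid[keep, 3])
  attr(out, "target") <- target
  attr(out, "midpoint_radius") <- midpoint_radius
  attr(out, "max_separation") <- max_separation
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Bin per-pair proportions into a separation curve
#'
#' Averages partition proportions over source-detector pairs within 5 mm
#' separation bins centred at multiples of the bin width with half-open
#' edges (the 30 mm bin covers 27.5-32.5 mm). Empty bins are omitted; the
#' standard error is reported as NA for single-pair bins.
#'
#' @param pair_props Long data frame with columns `separation`, `partition`
#'   and `proportion` (one row per pair x partition).
#' @param bin_width Bin width in mm (default 5).
#' @return A `sensitivity_curve` data frame with `bin_center`, `partition`,
#'   `mean`, `se`, `n`.
#' @export
bin_curve <- function(pair_props, bin_width = 5) {
  stopifnot(all(c("separation", "partition", "proportion") %in%
                  names(pair_props)), nrow(pair_props) >= 1)
  ctr <- round(pair_props$separation / bin_width) * bin_width
  # half-open edges [c - w/2, c + w/2): push exact upper edges up a bin
  at_upper <- (pair_props$separation - (ctr + bin_width / 2)) == 0
  ctr[at_upper] <- ctr[at_upper] + bin_width
  key <- interaction(ctr, pair_props$partition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(pair_props)), key), function(ii) {
    p <- pair_props$proportion[ii]
    data.frame(bin_center = ctr[ii[1]],
               partition = pair_props$partition[ii[1]],
               mean = mean(p),
               se = if (length(p) > 1) sd(p) / sqrt(length(p)) else NA_real_,
               n = length(p), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$partition, agg$bin_center), ]
  rownames(agg) <- NULL
  class(agg) <- c("sensitivity_curve", "data.frame")
  agg
}

#' Average sensitivity curves across target locations
#'
#' Per-bin, per-partition mean of the location curves; the reported
#' standard error is the across-location SE (per-pair errors within each
#' location are deliberately dropped).
#'
#' @param curves List of `sensitivity_curve` data frames.
#' @return A `sensitivity_curve` with `n` = number of contributing
#'   locations per bin.
#' @export
aggregate_locations <- function(curves) {
  stopifnot(length(curves) >= 1)
  all <- do.call(rbind, lapply(curves, function(cv)
    cv[, c("bin_center", "partition", "mean")]))
  key <- interaction(all$bin_center, all$partition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(all)), key), function(ii) {
    m <- all$mean[ii]
    data.frame(bin_center = all$bin_center[ii[1]],
               partition = all$partition[ii[1]],
               mean = mean(m),
               se = if (length(m) > 1) sd(m) / sqrt(length(m)) else NA_real_,
               n = length(m), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$partition, agg$bin_center), ]
  rownames(agg) <- NULL
  class(agg) <- c("sensitivity_curve", "data.frame")
  agg
}

#' Brain fraction of a sensitivity map
#'
#' Proportion of the total 3-point sensitivity attributable to brain tissue
#' (gray + white matter).
#'
#' @param map A `three_point_map`.
#' @param head The `head_volume` supplying the tissue partition.
#' @return A single proportion in \[0, 1\].
#' @export
brain_fraction <- function(map, head) {
  pr <- partition_sums(map, head)
  sum(pr$proportion[pr$partition %in% c("gray", "white")])
}
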