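#' Published depth-sensitivity regression coefficients
#'
#' Reference coefficients of the exponential depth-sensitivity model
#' S(d) = a + b * c^d fitted on an adult MRI head template at
#' source-detector separations 5-65 mm, together with the printed modeled
#' sensitivities (percent) at depths 0, 5 and 10 mm below the inner skull
#' surface. Used as the worked-example input for model evaluation and for
#' the rule-of-thumb average.
#'
#' @return Data frame with columns `sep_mm`, `a`, `b`, `c`, standard
#'   errors, `adj_r2`, `n`, and `sens0_pct`, `sens5_pct`, `sens10_pct`.
#' @export
reference_depth_coefficients <- function() {
  path <- system.file("extdata", "reference_depth_coefficients.tsv",
                      package = "nindepth", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Fit the exponential depth-sensitivity model
#'
#' Least-squares fit of S(d) = a + b * c^d to per-shell sensitivity
#' proportions versus depth, via bounded Levenberg-Marquardt. Starting
#' values come from a log-linear regression of log(S - min(S) + eps) on
#' depth; bounds are a in \[-0.1, 0.1\], b in (0, 1\], c in (0.5, 0.999).
#' The fit is deterministic given its inputs.
#'
#' @param depths Depths in mm (>= 3 points).
#' @param S Sensitivity proportions (>= 0).
#' @param weights Optional per-point weights (default unweighted).
#' @return An `exp_fit`: list with `coefficients` (a, b, c), `se`, `ci`
#'   (95%), `adj_r2`, `n`, `converged`, and `diagnostics` when the
#'   optimizer fails.
#' @export
fit_exponential <- function(depths, S, weights = NULL) {
  stopifnot(length(depths) == length(S), length(S) >= 3, all(S >= -1e-12))
  d <- as.numeric(depths)
  y <- as.numeric(S)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)

  eps <- max(1e-9, 1e-3 * max(y - min(y)))
  ylog <- log(pmax(y - min(y), 0) + eps)
  ll <- lm(ylog ~ d)
  c0 <- min(0.998, max(0.51, exp(coef(ll)[2])))
  b0 <- min(1, max(1e-6, exp(coef(ll)[1])))
  start <- list(a = 0, b = b0, c = c0)

  df <- data.frame(d = d, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * c^d, data = df, start = start,
                      weights = w,
                      lower = c(a = -0.1, b = 1e-12, c = 0.5),
                      upper = c(a = 0.1, b = 1, c = 0.999),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = c(a = NA, b = NA, c = NA),
                          se = c(a = NA, b = NA, c = NA), ci = NULL,
                          adj_r2 = NA, n = length(y), converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "exp_fit"))
  }
  est <- coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  dof <- length(y) - 3
  tq <- qt(0.975, dof)
  ci <- cbind(low = est - tq * se, high = est + tq * se)
  res <- y - (est["a"] + est["b"] * est["c"]^d)
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * (y - weighted.mean(y, w))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (length(y) - 1) / dof
  structure(list(coefficients = est, se = se, ci = ci, adj_r2 = adj_r2,
                 n = length(y), converged = TRUE, diagnostics = NULL),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<exp_fit> NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  co <- x$coefficients
  cat(sprintf("<exp_fit> S(d) = %.4g + %.4g * %.4f^d  (n = %d, adj R2 = %.3f)\n",
              co["a"], co["b"], co["c"], x$n, x$adj_r2))
  invisible(x)
}

#' Evaluate the exponential depth-sensitivity model
#'
#' @param fit An `exp_fit`, or a numeric vector with named elements
#'   `a`, `b`, `c`.
#' @param depth Depth(s) in mm below the inner skull surface.
#' @return Modeled sensitivity proportion(s) a + b * c^depth.
#' @export
evaluate_model <- function(fit, depth) {
  co <- if (inherits(fit, "exp_fit")) fit$coefficients else fit
  stopifnot(all(c("a", "b", "c") %in% names(co)))
  unname(co["a"] + co["b"] * co["c"]^depth)
}

#' Rule-of-thumb depth-sensitivity formula
#'
#' Arithmetic means of the b and c coefficients over fits at typical NIRS
#' separations (20-40 mm), rendering the compact approximation
#' S(d) = b_bar * c_bar^d for sensitivity at depth d mm below the inner
#' skull surface.
#'
#' @param fits A list of `exp_fit` objects, or a data frame with columns
#'   `b` and `c` (e.g. rows of [reference_depth_coefficients()]).
#' @return List with `b_bar`, `c_bar` and `evaluate(d)`.
#' @export
rule_of_thumb <- function(fits) {
  if (is.data.frame(fits)) {
    b <- fits$b; cc <- fits$c
  } else {
    co <- vapply(fits, function(f) f$coefficients[c("b", "c")], numeric(2))
    b <- co[1, ]; cc <- co[2, ]
  }
  stopifnot(length(b) >= 1, !any(is.na(b)), !any(is.na(cc)))
  b_bar <- mean(b)
  c_bar <- mean(cc)
  list(b_bar = b_bar, c_bar = c_bar,
       evaluate = function(d) b_bar * c_bar^d)
}

#' Linear sensitivity-vs-separation slope
#'
#' Ordinary least-squares slope of the binned mean proportion against
#' source-detector separation for one partition, reported per centimetre
#' (per 10 mm) of separation.
#'
#' @param curve A `sensitivity_curve` (from [bin_curve()] or
#'   [aggregate_locations()]).
#' @param partition Partition name to regress (e.g. "gray").
#' @param separation_range Length-2 mm range, inclusive (default 20-45).
#' @return List with `slope_per_cm`, `se_per_cm`, `n_bins`.
#' @export
linear_slope <- function(curve, partition, separation_range = c(20, 45)) {
  rows <- curve[curve$partition == partition &
                  curve$bin_center >= separation_range[1] &
                  curve$bin_center <= separation_range[2], ]
  stopifnot(nrow(rows) >= 2)
  fit <- lm(mean ~ bin_center, data = rows)
  sl <- coef(fit)["bin_center"]
  se <- if (nrow(rows) > 2)
    suppressWarnings(summary(fit))$coefficients["bin_center", "Std. Error"]
  else NA_real_
  list(slope_per_cm = unname(sl) * 10, se_per_cm = se * 10,
       n_bins = nrow(rows))
}

#' Shell-resolved depth-sensitivity profile
#'
#' Bins per-pair shell proportions by source-detector separation (as in
#' [bin_curve()]) and attaches each shell's mean depth below the inner
#' skull surface, giving, per separation bin, sensitivity as a function of
#' depth ready for [fit_exponential()].
#'
#' @param pair_props Long data frame with `separation`, `partition`,
#'   `proportion` where partitions follow the `shell_set` naming
#'   (scalp, skull, shell_1, ...).
#' @param shells The `shell_set` used for the partitioning.
#' @param bin_width Separation bin width in mm.
#' @return A `depth_profile` data frame: `bin_center`, `partition`,
#'   `mean`, `se`, `n`, and `depth_mm` (NA for scalp/skull/core).
#' @export
depth_profile <- function(pair_props, shells, bin_width = 5) {
  stopifnot(inherits(shells, "shell_set"))
  curve <- bin_curve(pair_props, bin_width = bin_width)
  depth_lookup <- setNames(rep(NA_real_, length(shells$names)), shells$names)
  depth_lookup[paste0("shell_", seq_len(shells$n_shells))] <- shells$depth_mm
  curve$depth_mm <- unname(depth_lookup[curve$partition])
  class(curve) <- c("depth_profile", class(curve))
  curve
}

#' Fit the depth model at each separation of a depth profile
#'
#' @param profile A `depth_profile`.
#' @param max_depth Use shells no deeper than this (mm); the exponential
#'   regime holds through roughly the first 15-20 mm.
#' @return Named list of `exp_fit` objects, one per separation bin.
#' @export
fit_depth_profile <- function(profile, max_depth = Inf) {
  sh <- profile[!is.na(profile$depth_mm) & profile$depth_mm <= max_depth, ]
  fits <- lapply(split(sh, sh$bin_center), function(gr)
    fit_exponential(gr$depth_mm, gr$mean))
  fits[order(as.numeric(names(fits)))]
}

#' Render a regression-results table
#'
#' One row per separation with coefficients, standard errors, adjusted R2
#' and modeled percent sensitivity at depths 0, 5 and 10 mm, mirroring the
#' package's reference coefficient table layout.
#'
#' @param fits Named list of `exp_fit`s (names = separation in mm).
#' @return Data frame; percentages are rounded to 2 decimals.
#' @export
depth_fit_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    co <- f$coefficients
    data.frame(sep_mm = as.numeric(nm),
               a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
               se_a = unname(f$se["a"]), se_b = unname(f$se["b"]),
               se_c = unname(f$se["c"]),
               adj_r2 = f$adj_r2, n = f$n, converged = f$converged,
               sens0_pct = round(100 * evaluate_model(f, 0), 2),
               sens5_pct = round(100 * evaluate_model(f, 5), 2),
               sens10_pct = round(100 * evaluate_model(f, 10), 2))
  })
  do.call(rbind, rows)
}
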