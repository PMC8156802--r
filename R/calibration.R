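# Unreliable-feature calibration: fit a Gaussian kernel density estimate per
# feature on the training split, convert the tail probability threshold P_th
# into fixed lower/upper bounds via the KDE's CDF, and clamp (or replace by
# the training mean) any value outside those bounds. No rows are ever
# deleted: a frame with a calibrated feature still contributes a (soft)
# decision downstream.

#' Silverman-style kernel bandwidth
#'
#' Computes the bandwidth `rho = sigma * (4 / (3 L))^(1/5)` with `sigma` the
#' sample standard deviation and `L` the number of values. A return value of
#' 0 signals a degenerate (constant) sample for which density-based
#' calibration is skipped.
#'
#' @param values Numeric vector with at least 2 entries.
#' @return Non-negative bandwidth; 0 for a constant sample.
#' @examples
#' silverman_bandwidth(scale(rnorm(100)))  # ~ (4/300)^0.2 = 0.4217
#' @export
silverman_bandwidth <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("`values` must hold at least 2 finite numbers", call. = FALSE)
  stats::sd(values) * (4 / (3 * length(values)))^0.2
}

#' Kernel-density cumulative distribution evaluator
#'
#' Returns the CDF of a Gaussian kernel density estimate: the average of the
#' per-sample normal CDFs centered at each observation with standard
#' deviation `rho`. The evaluator is monotone non-decreasing with limits 0
#' and 1.
#'
#' @param values Numeric sample (>= 2 values).
#' @param rho Positive kernel bandwidth, e.g. from [silverman_bandwidth()].
#' @return A vectorized function `Phi(z)`.
#' @export
estimate_density_cdf <- function(values, rho) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("`values` must hold at least 2 finite numbers", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive bandwidth", call. = FALSE)
  force(values); force(rho)
  function(z) {
    vapply(as.numeric(z),
           function(zz) mean(stats::pnorm(zz, mean = values, sd = rho)),
           numeric(1))
  }
}

#' Tail bounds of one feature from its density estimate
#'
#' Solves `Phi(z_ub) = p_th` and `Phi(z_lb) = 1 - p_th` for the KDE CDF of
#' the training values by root bracketing on
#' `[min(values) - 5 rho, max(values) + 5 rho]`. Values outside
#' `[z_lb, z_ub]` are judged unreliable.
#'
#' @param values Training values of one feature.
#' @param p_th Tail probability threshold in `[0.5, 1)`; default 0.999.
#' @param rho Kernel bandwidth; defaults to [silverman_bandwidth()].
#' @return List with `z_lb`, `z_ub`, `rho`, `center` (training mean) and
#'   `p_th`.
#' @export
compute_bounds <- function(values, p_th = 0.999, rho = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(p_th) || length(p_th) != 1L || p_th < 0.5 || p_th >= 1)
    stop("`p_th` must lie in [0.5, 1)", call. = FALSE)
  if (is.null(rho)) rho <- silverman_bandwidth(values)
  if (!is.finite(rho) || rho <= 0)
    stop("degenerate sample (zero bandwidth); calibration is skipped for ",
         "constant features", call. = FALSE)
  cdf <- estimate_density_cdf(values, rho)
  lo <- min(values) - 5 * rho
  hi <- max(values) + 5 * rho
  root <- function(p) {
    stats::uniroot(function(z) cdf(z) - p, lower = lo, upper = hi,
                   tol = .Machine$double.eps^0.5)$root
  }
  z_ub <- root(p_th)
  z_lb <- root(1 - p_th)
  list(z_lb = min(z_lb, z_ub), z_ub = max(z_lb, z_ub), rho = rho,
       center = mean(values), p_th = p_th)
}

#' Fit calibration bounds for every feature column
#'
#' Fits [compute_bounds()] per feature on the pooled training matrix (one
#' density per feature, not per subject). Constant columns are flagged and
#' left unbounded (`-Inf`, `Inf`), i.e. never calibrated.
#'
#' @param features Training feature matrix (rows = frames).
#' @param p_th Tail probability threshold in `[0.5, 1)`; default 0.999.
#' @return An object of class `feature_bounds`: data frame with one row per
#'   feature (`feature`, `z_lb`, `z_ub`, `rho`, `center`) and attribute
#'   `p_th`.
#' @export
fit_feature_bounds <- function(features, p_th = 0.999) {
  x <- as.matrix(features)
  if (nrow(x) < 2L)
    stop("at least 2 training rows are required", call. = FALSE)
  nms <- colnames(x)
  if (is.null(nms)) nms <- sprintf("f%02d", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    rho <- silverman_bandwidth(x[, j])
    if (!is.finite(rho) || rho <= 0)
      return(data.frame(feature = nms[j], z_lb = -Inf, z_ub = Inf,
                        rho = NA_real_, center = mean(x[, j])))
    b <- compute_bounds(x[, j], p_th = p_th, rho = rho)
    data.frame(feature = nms[j], z_lb = b$z_lb, z_ub = b$z_ub, rho = rho,
               center = b$center)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$rho))
    warning(sum(is.na(out$rho)),
            " constant feature column(s) left uncalibrated")
  structure(out, p_th = p_th, class = c("feature_bounds", "data.frame"))
}

#' Calibrate a feature matrix against fitted bounds
#'
#' Values above `z_ub` or below `z_lb` are judged unreliable. The default
#' `"clamp"` strategy replaces them by the violated bound; `"mean"` replaces
#' them by the training mean of the feature; `"off"` returns the input
#' unchanged. No rows are deleted and the output shape equals the input
#' shape. Clamping is idempotent.
#'
#' @param features Feature matrix with the same columns as the fitted bounds.
#' @param bounds A `feature_bounds` object from [fit_feature_bounds()].
#' @param strategy One of `"clamp"` (default), `"mean"`, `"off"`.
#' @return Calibrated matrix of the same dimension.
#' @export
calibrate_features <- function(features, bounds,
                               strategy = c("clamp", "mean", "off")) {
  strategy <- match.arg(strategy)
  x <- as.matrix(features)
  if (!inherits(bounds, "feature_bounds"))
    stop("`bounds` must come from fit_feature_bounds()", call. = FALSE)
  if (ncol(x) != nrow(bounds))
    stop("feature column count (", ncol(x), ") does not match fitted bounds (",
         nrow(bounds), ")", call. = FALSE)
  if (strategy == "off") return(x)
  for (j in seq_len(ncol(x))) {
    lb <- bounds$z_lb[j]; ub <- bounds$z_ub[j]
    if (!is.finite(lb) && !is.finite(ub)) next
    if (strategy == "clamp") {
      x[, j] <- pmin(pmax(x[, j], lb), ub)
    } else {
      out_of_range <- x[, j] < lb | x[, j] > ub
      x[out_of_range, j] <- bounds$center[j]
    }
  }
  x
}

#' Serialize calibration bounds to JSON
#'
#' Writes a JSON table `{feature: {z_lb, z_ub, rho, center}}` plus the
#' threshold `p_th`; [read_feature_bounds()] restores the object.
#'
#' @param bounds A `feature_bounds` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_bounds <- function(bounds, path) {
  if (!inherits(bounds, "feature_bounds"))
    stop("`bounds` must come from fit_feature_bounds()", call. = FALSE)
  fin <- function(v) if (is.finite(v)) v else NA  # JSON has no Inf
  entries <- lapply(seq_len(nrow(bounds)), function(j)
    list(z_lb = fin(bounds$z_lb[j]), z_ub = fin(bounds$z_ub[j]),
         rho = fin(bounds$rho[j]), center = bounds$center[j]))
  names(entries) <- bounds$feature
  jsonlite::write_json(list(p_th = attr(bounds, "p_th"), bounds = entries),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_bounds
#' @export
read_feature_bounds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- obj$bounds
  out <- data.frame(feature = names(b),
                    z_lb = vapply(b, function(e) null_to(e$z_lb, -Inf), 1),
                    z_ub = vapply(b, function(e) null_to(e$z_ub, Inf), 1),
                    rho = vapply(b, function(e) null_to(e$rho, NA_real_), 1),
                    center = vapply(b, function(e) e$center, 1))
  rownames(out) <- NULL
  structure(out, p_th = obj$p_th, class = c("feature_bounds", "data.frame"))
}

null_to <- function(x, default) if (is.null(x) || is.na(x)) default else x
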