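# Decision fusion across motion frames. Per-frame classifier outputs are
# turned into fuzzy membership vectors; the reliability-weighted-sum (RWS)
# rule weighs each frame by how consistent its fuzzy decision is with the
# other frames (principal eigenvector of the inner-product consistency
# matrix) before averaging.

as_membership_matrix <- function(decisions) {
  if (is.list(decisions)) {
    len <- unique(lengths(decisions))
    if (length(len) != 1L)
      stop("all fuzzy decisions must have the same length", call. = FALSE)
    decisions <- do.call(rbind, decisions)
  }
  m <- as.matrix(decisions)
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("at least one fuzzy decision is required", call. = FALSE)
  if (!all(is.finite(m)) || any(m < 0))
    stop("memberships must be finite and nonnegative", call. = FALSE)
  m
}

#' Fuzzy membership transformation of classifier outputs
#'
#' Maps a vector of per-class classifier outputs `o` to memberships
#' `mu_i = exp(-(o_i / (mean(o) + gamma * sd(o)))^2)` with `sd` the sample
#' (n-1) standard deviation. Relative larger outputs yield larger
#' memberships; all memberships lie in `(0, 1]`. `gamma` controls the spread
#' of the memberships (default 0.5). In the degenerate case
#' `mean(o) + gamma * sd(o) == 0` the function warns and returns equal
#' memberships `exp(-1)`.
#'
#' Note the transformation is even in `o_i / (mean + gamma sd)`: outputs `+c`
#' and `-c` receive equal membership. With one-vs-rest plus/minus-one coded
#' classifiers the mean output is negative, which makes near `+1` outputs
#' large relative to the (negative) scale and near `-1` outputs small, as
#' intended.
#'
#' @param o Numeric output vector (length >= 2) or matrix (rows = frames).
#' @param gamma Spread parameter, default 0.5.
#' @return Membership vector in `(0, 1]` (or matrix for matrix input).
#' @examples
#' round(fuzzy_membership(c(-0.9, 0.2, -0.4, -0.8, -0.95)), 4)
#' @export
fuzzy_membership <- function(o, gamma = 0.5) {
  if (is.matrix(o))
    return(t(apply(o, 1, fuzzy_membership, gamma = gamma)))
  nms <- names(o)
  o <- as.numeric(o)
  if (length(o) < 2L || anyNA(o))
    stop("`o` must hold at least 2 finite outputs", call. = FALSE)
  s <- mean(o) + gamma * stats::sd(o)
  if (s == 0) {
    warning("degenerate output vector (mean + gamma * sd == 0); ",
            "returning equal memberships")
    return(stats::setNames(rep(exp(-1), length(o)), nms))
  }
  mu <- exp(-(o / s)^2)
  names(mu) <- nms
  mu
}

#' Consistency matrix of fuzzy decisions
#'
#' Pairwise agreement between fuzzy decisions, measured as the plain inner
#' product `a[t, k] = <mu^t, mu^k>` (the Dempster-Shafer consistency degree
#' reduces to this when all focal elements are singleton classes). The
#' diagonal holds the squared norms. The result is symmetric, nonnegative,
#' and positive semidefinite (it is the Gram matrix of the membership
#' vectors).
#'
#' @param decisions `T x n_class` membership matrix (rows = frames) or list
#'   of membership vectors; `T >= 2`.
#' @return Symmetric `T x T` matrix.
#' @export
consistency_matrix <- function(decisions) {
  m <- as_membership_matrix(decisions)
  if (nrow(m) < 2L)
    stop("at least 2 fuzzy decisions are required", call. = FALSE)
  tcrossprod(m)
}

#' Eigenvector reliability weights of the frames
#'
#' The unit-norm principal eigenvector `w` of the consistency matrix scores
#' each frame by its overall agreement with the other frames; for a
#' nonnegative matrix it can be oriented with all entries nonnegative
#' (Perron-Frobenius). The raw eigenvector is affinely rescaled to
#' `r_t = a + b * (w_t - min(w)) / (max(w) - min(w))`, so reliabilities span
#' exactly `[a, a + b]`. If all entries coincide (mutually identical frames)
#' every `r_t` is set to `a + b`: identical frames are maximally mutually
#' consistent.
#'
#' @param A Consistency matrix from [consistency_matrix()].
#' @param a Lower bound of the reliability range (default 0.6).
#' @param b Span of the reliability range (default 0.4).
#' @return An object of class `reliability_weights` with the raw unit-norm
#'   eigenvector `w` and normalized reliabilities `r`.
#' @export
reliability_weights <- function(A, a = 0.6, b = 0.4) {
  A <- as.matrix(A)
  if (nrow(A) == 0L) stop("empty consistency matrix", call. = FALSE)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop("`A` must be a symmetric matrix", call. = FALSE)
  if (!is.numeric(a) || !is.numeric(b) || b < 0)
    stop("invalid reliability bounds", call. = FALSE)
  if (nrow(A) == 1L) {
    w <- 1
  } else {
    e <- eigen(A, symmetric = TRUE)
    w <- e$vectors[, 1]
    if (sum(w) < 0) w <- -w  # nonnegative orientation
  }
  rng <- max(w) - min(w)
  r <- if (rng <= .Machine$double.eps^0.5 * max(1, max(abs(w)))) {
    rep(a + b, length(w))
  } else {
    a + b * (w - min(w)) / rng
  }
  structure(list(w = w, r = r, a = a, b = b), class = "reliability_weights")
}

#' @export
print.reliability_weights <- function(x, ...) {
  cat(sprintf("reliability_weights over %d frames, range [%g, %g]\n",
              length(x$r), x$a, x$a + x$b))
  print(round(x$r, 3))
  invisible(x)
}

new_global_decision <- function(membership, rule, class_list,
                                winner_index = which.max(membership),
                                reliabilities = NULL) {
  winner_index <- as.integer(unname(winner_index))
  if (is.null(class_list)) class_list <- names(membership)
  if (is.null(class_list)) class_list <- seq_along(membership)
  structure(list(membership = membership,
                 winner_index = winner_index,
                 winner = class_list[winner_index],
                 rule = rule,
                 class_list = class_list,
                 reliabilities = reliabilities),
            class = "global_decision")
}

#' @export
print.global_decision <- function(x, ...) {
  cat(sprintf("global_decision (%s rule): winner '%s'\n", x$rule, x$winner))
  print(round(x$membership, 4))
  invisible(x)
}

#' Reliability-weighted-sum fusion of per-frame fuzzy decisions
#'
#' The RWS rule: (1) build the consistency matrix of the `T` fuzzy
#' decisions, (2) take its principal eigenvector and rescale it into
#' `[a, a + b]` as per-frame reliabilities `r_t`
#' ([reliability_weights()]), (3) average
#' `mu_g = (1 / T) * sum_t r_t * mu^t`, and (4) pick the class with maximal
#' global membership (ties to the lowest class index). For a single frame
#' the reliability defaults to `a + b` and the rule reduces to the frame's
#' own arg-max.
#'
#' @param decisions `T x n_class` membership matrix (rows = frames) or list
#'   of membership vectors.
#' @param a,b Reliability lower bound and span (defaults 0.6 and 0.4).
#' @param class_list Optional class labels (defaults to column names).
#' @return A `global_decision` with elements `membership` (the global fuzzy
#'   decision), `winner`, `winner_index`, and the `reliability_weights`
#'   used.
#' @examples
#' mu <- rbind(c(0.2, 0.7, 0.1), c(0.3, 0.6, 0.2))
#' rws_fuse(mu)$winner_index  # 2
#' @export
rws_fuse <- function(decisions, a = 0.6, b = 0.4, class_list = NULL) {
  m <- as_membership_matrix(decisions)
  if (is.null(class_list)) class_list <- colnames(m)
  if (nrow(m) == 1L) {
    rel <- structure(list(w = 1, r = a + b, a = a, b = b),
                     class = "reliability_weights")
  } else {
    rel <- reliability_weights(consistency_matrix(m), a = a, b = b)
  }
  mu_g <- colSums(rel$r * m) / nrow(m)
  new_global_decision(mu_g, "rws", class_list, reliabilities = rel)
}

#' Baseline decision-fusion rules
#'
#' Combines `T` per-frame fuzzy decisions with one of five reference rules:
#' \describe{
#'   \item{`sum`}{`mu_i = (1/T) sum_t mu_i^t` — unweighted average.}
#'   \item{`product`}{`mu_i = prod_t (mu_i^t + delta)` — naive-Bayes-like
#'     product; `delta` guards against memberships near 0.}
#'   \item{`majority`}{each frame casts a hard vote for its arg-max class;
#'     the class with most votes wins. Vote ties are resolved by the larger
#'     average membership, remaining ties by the lowest class index. The
#'     reported membership vector holds the vote fractions.}
#'   \item{`belief`}{`mu_i = prod_t 1 / (1 - mu_i^t + delta)` — Dempster-style
#'     singleton belief combination.}
#'   \item{`wbelief`}{`mu_i = prod_t 1 / (1 - r_t mu_i^t + delta)` — belief
#'     combination discounted by the eigenvector reliabilities `r_t`.}
#' }
#' Product and belief scores are reported un-normalized; the winner is the
#' arg-max (ties to the lowest class index).
#'
#' @param decisions `T x n_class` membership matrix or list of membership
#'   vectors.
#' @param rule One of `"sum"`, `"product"`, `"majority"`, `"belief"`,
#'   `"wbelief"`.
#' @param delta Small positive floor for the product/belief rules (default
#'   `1e-3`).
#' @param reliabilities Optional `reliability_weights` (or numeric vector)
#'   for `"wbelief"`; computed from the consistency matrix with bounds
#'   `a`, `b` when missing.
#' @param a,b Reliability bounds used when `reliabilities` is computed here.
#' @param class_list Optional class labels.
#' @return A `global_decision`.
#' @export
baseline_fuse <- function(decisions,
                          rule = c("sum", "product", "majority", "belief",
                                   "wbelief"),
                          delta = 1e-3, reliabilities = NULL,
                          a = 0.6, b = 0.4, class_list = NULL) {
  rule <- match.arg(rule)
  m <- as_membership_matrix(decisions)
  if (is.null(class_list)) class_list <- colnames(m)
  nT <- nrow(m)
  if (rule == "sum") {
    mu <- colMeans(m)
    return(new_global_decision(mu, rule, class_list))
  }
  if (rule == "product") {
    mu <- apply(m + delta, 2, prod)
    return(new_global_decision(mu, rule, class_list))
  }
  if (rule == "belief") {
    mu <- apply(1 / (1 - m + delta), 2, prod)
    return(new_global_decision(mu, rule, class_list))
  }
  if (rule == "wbelief") {
    if (is.null(reliabilities)) {
      reliabilities <- if (nT == 1L)
        structure(list(w = 1, r = a + b, a = a, b = b),
                  class = "reliability_weights")
      else reliability_weights(consistency_matrix(m), a = a, b = b)
    }
    r <- if (inherits(reliabilities, "reliability_weights"))
      reliabilities$r else as.numeric(reliabilities)
    if (length(r) != nT)
      stop("one reliability per frame is required", call. = FALSE)
    mu <- apply(1 / (1 - r * m + delta), 2, prod)
    return(new_global_decision(mu, rule, class_list,
                               reliabilities = reliabilities))
  }
  # majority vote over per-frame hard decisions
  votes <- tabulate(apply(m, 1, which.max), nbins = ncol(m))
  top <- which(votes == max(votes))
  winner <- if (length(top) == 1L) top else {
    avg <- colMeans(m)[top]
    top[which.max(avg)]  # which.max resolves remaining ties by lowest index
  }
  mu <- votes / nT
  names(mu) <- colnames(m)
  new_global_decision(mu, rule, class_list, winner_index = winner)
}

#' Fuse per-frame decisions with any supported rule
#'
#' Thin dispatcher over [rws_fuse()] and [baseline_fuse()]; arguments that a
#' rule does not use (`delta` for RWS/sum, `a`/`b` for the unweighted
#' baselines) are ignored.
#'
#' @param decisions Membership matrix or list of membership vectors.
#' @param rule One of `"rws"`, `"sum"`, `"product"`, `"majority"`,
#'   `"belief"`, `"wbelief"`.
#' @param a,b Reliability bounds for `"rws"` and `"wbelief"`.
#' @param delta Floor constant for the product/belief rules.
#' @param class_list Optional class labels.
#' @return A `global_decision`.
#' @export
fuse_decisions <- function(decisions, rule = "rws", a = 0.6, b = 0.4,
                           delta = 1e-3, class_list = NULL) {
  if (rule == "rws")
    rws_fuse(decisions, a = a, b = b, class_list = class_list)
  else
    baseline_fuse(decisions, rule = rule, delta = delta, a = a, b = b,
                  class_list = class_list)
}
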