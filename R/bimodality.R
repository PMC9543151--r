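# Bimodality detection on per-cell phase-shift histograms: 15-min binning,
# one- and two-component Gaussian least-squares fits, chi-square/AIC model
# selection with a nested-component override, population fractions from the
# component areas, the intersection cutoff, per-cell classification, and the
# exact paired Wilcoxon signed-rank test.
#
# Component parameterization: y(x) = A / (w * sqrt(pi/2)) * exp(-2 (x - xc)^2 / w^2),
# so A is the area under the component, w its width (implied SD = w/2) and
# xc its center.

BIN_W <- 0.25  # 15-min histogram bins

#' Histogram of per-cell phase shifts with 15-min bins
#'
#' Bins span the data range on quarter-hour boundaries (half-open bins,
#' closed on the left); counts are conserved.
#'
#' @param shifts_h per-cell phase shifts in hours (>= 1 value).
#' @return an object of class `shift_histogram`: `bin_edges`, `mids`,
#'   `counts`, `n_total`, `bin_width`.
#' @export
make_histogram <- function(shifts_h) {
  if (length(shifts_h) == 0) stop("no shifts to bin")
  lo <- floor(min(shifts_h) / BIN_W) * BIN_W
  hi <- ceiling(max(shifts_h) / BIN_W) * BIN_W
  if (hi <= max(shifts_h)) hi <- hi + BIN_W  # keep bins half-open
  edges <- seq(lo, hi, by = BIN_W)
  idx <- findInterval(shifts_h, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(bin_edges = edges, mids = edges[-length(edges)] + BIN_W / 2,
                 counts = counts, n_total = length(shifts_h),
                 bin_width = BIN_W),
            class = "shift_histogram")
}

# component density at x
gauss_component <- function(x, A, w, xc) {
  A / (w * sqrt(pi / 2)) * exp(-2 * (x - xc)^2 / w^2)
}

# sum of k components; pars is c(A1, w1, xc1[, A2, w2, xc2])
gauss_mixture <- function(x, pars) {
  k <- length(pars) / 3
  y <- 0
  for (i in seq_len(k)) {
    p <- pars[(3 * i - 3) + 1:3]
    y <- y + gauss_component(x, p[1], p[2], p[3])
  }
  y
}

# expand a histogram back to pseudo-observations at bin mids
expand_hist <- function(hist) rep(hist$mids, hist$counts)

# deterministic start values for the two-component fit: quantile pairs plus
# a 1-D Lloyd (k-means style) split
bi_starts <- function(hist) {
  obs <- expand_hist(hist)
  qp <- function(a, b) unname(quantile(obs, c(a, b), type = 7))
  centers <- list(qp(0.25, 0.75), qp(0.20, 0.80), qp(0.35, 0.65),
                  qp(0.10, 0.60), qp(0.40, 0.90))
  # Lloyd iterations from the quartile centers
  cc <- qp(0.25, 0.75)
  if (diff(cc) > 0) {
    for (it in 1:20) {
      assign2 <- abs(obs - cc[1]) > abs(obs - cc[2])
      new_cc <- c(mean(obs[!assign2]), mean(obs[assign2]))
      if (any(!is.finite(new_cc)) || isTRUE(all.equal(new_cc, cc))) break
      cc <- new_cc
    }
    centers <- c(centers, list(cc))
  }
  lapply(centers, function(ctr) {
    ctr <- sort(ctr)
    mid <- mean(ctr)
    left <- obs[obs <= mid]; right <- obs[obs > mid]
    mk <- function(v, ctr_i) {
      s <- if (length(v) > 1) max(sd(v), hist$bin_width / 2) else hist$bin_width
      c(A = max(length(v), 1), w = 2 * s, xc = ctr_i)
    }
    c(mk(left, ctr[1]), mk(right, ctr[2]))
  })
}

#' Fit a one- or two-component Gaussian to a shift histogram
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt) of the sum of
#' component curves evaluated at the bin centers against the bin values
#' (count density by default, i.e. counts / bin width, so that a component's
#' area A is in cells). The one-component fit starts from moment estimates;
#' the two-component fit uses deterministic multi-start initialization
#' (quantile-pair centers plus a 1-D k-means-style split) and keeps the
#' lowest-RSS converged fit. Amplitudes must be positive and widths at least
#' one bin width.
#'
#' @param hist a [make_histogram()] result.
#' @param n_components 1 or 2.
#' @param scale fit `"density"` (counts / bin width) or raw `"counts"`.
#' @return an object of class `gaussian_model_fit`: `components` (data frame
#'   A, w, xc, ordered by xc for two components), `rss`, `chi_square`,
#'   `aic`, `n_bins`, `k_params`, `n_components`, `fitted` (at bin mids).
#' @export
fit_gaussians <- function(hist, n_components = 1, scale = c("density", "counts")) {
  scale <- match.arg(scale)
  stopifnot(n_components %in% 1:2)
  x <- hist$mids
  yobs <- if (scale == "density") hist$counts / hist$bin_width else hist$counts
  area_scale <- if (scale == "density") 1 else hist$bin_width
  k_params <- 3L * n_components
  if (sum(hist$counts > 0) < k_params)
    stop("fit error: fewer occupied bins than parameters")
  obs <- expand_hist(hist)
  n <- hist$n_total

  starts <- if (n_components == 1) {
    s <- max(sd(obs), hist$bin_width / 2)
    if (is.na(s)) s <- hist$bin_width
    list(c(A = n, w = 2 * s, xc = mean(obs)))
  } else {
    bi_starts(hist)
  }
  starts <- lapply(starts, function(st) {
    st[grep("^A", names(st))] <- st[grep("^A", names(st))] * area_scale
    st
  })
  lower <- rep(c(1e-6, hist$bin_width, min(hist$bin_edges)), n_components)
  upper <- rep(c(10 * n * area_scale + 1,
                 diff(range(hist$bin_edges)) * 2,
                 max(hist$bin_edges)), n_components)

  par_names <- paste0(c("A", "w", "xc"), rep(seq_len(n_components), each = 3))
  form <- if (n_components == 1) {
    yobs ~ gauss_component(x, A1, w1, xc1)
  } else {
    yobs ~ gauss_component(x, A1, w1, xc1) + gauss_component(x, A2, w2, xc2)
  }
  best <- NULL
  for (st in starts) {
    st <- setNames(as.list(unname(st)), par_names)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = list(yobs = yobs, x = x), start = st,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("fit error: no start converged")

  pars <- unname(coef(best$fit)[par_names])
  comp <- data.frame(A = pars[seq(1, k_params, by = 3)] / area_scale,
                     w = pars[seq(2, k_params, by = 3)],
                     xc = pars[seq(3, k_params, by = 3)])
  comp <- comp[order(comp$xc), , drop = FALSE]
  rownames(comp) <- NULL
  fitted_y <- gauss_mixture(x, pars)
  n_bins <- length(x)
  rss <- best$rss
  aic <- n_bins * log(rss / n_bins) + 2 * k_params
  # Pearson chi-square on the counts scale over occupied bins
  fit_counts <- if (scale == "density") fitted_y * hist$bin_width else fitted_y
  occ <- hist$counts > 0
  chi_sq <- sum((hist$counts[occ] - fit_counts[occ])^2 /
                  pmax(fit_counts[occ], 0.5))
  structure(list(components = comp, rss = rss, chi_square = chi_sq,
                 aic = aic, n_bins = n_bins, k_params = k_params,
                 n_components = n_components, scale = scale,
                 fitted = fitted_y, mids = x),
            class = "gaussian_model_fit")
}

#' @export
print.gaussian_model_fit <- function(x, ...) {
  cat(sprintf("<gaussian_model_fit: %d component(s), AIC %.2f, chi2 %.2f>\n",
              x$n_components, x$aic, x$chi_square))
  print(x$components)
  invisible(x)
}

# is the smaller-area component entirely within the larger one?
# containment of [xc +/- w] intervals
is_nested <- function(comp) {
  small <- which.min(comp$A)
  big <- setdiff(1:2, small)
  (comp$xc[small] - comp$w[small]) >= (comp$xc[big] - comp$w[big]) &&
    (comp$xc[small] + comp$w[small]) <= (comp$xc[big] + comp$w[big])
}

#' Select the unimodal or bimodal model
#'
#' The two-component model must fit better by both selection statistics: its
#' Pearson chi-square must not exceed the one-component model's, and its AIC
#' must be at least `delta_aic` points lower. Even then, when the
#' smaller-area component lies entirely within the other (interval
#' containment of `xc +/- w`), the one-component model is kept. The
#' chi-square condition matters in practice: the least-squares RSS of the
#' nested two-component model is never worse, but the Pearson statistic over
#' occupied bins can be, and requiring both suppresses spurious tail-shoulder
#' components.
#'
#' @param fit1,fit2 one- and two-component [fit_gaussians()] results.
#' @param delta_aic required AIC improvement (default 2).
#' @return an object of class `bimodality_result` with `selected`
#'   (`"unimodal"` or `"bimodal"`), `fit1`, `fit2`, and — when bimodal —
#'   `fractions`, `mean_shifts_h` and `cutoff_h`.
#' @export
select_model <- function(fit1, fit2, delta_aic = 2) {
  if (is.null(fit1) || is.null(fit2)) stop("selection error: missing fit")
  stopifnot(fit1$n_components == 1, fit2$n_components == 2)
  bimodal <- (fit2$aic <= fit1$aic - delta_aic) &&
    (fit2$chi_square <= fit1$chi_square) &&
    !is_nested(fit2$components)
  res <- list(selected = if (bimodal) "bimodal" else "unimodal",
              fit1 = fit1, fit2 = fit2,
              delta_aic = fit1$aic - fit2$aic)
  if (bimodal) {
    ps <- population_stats(fit2)
    res$fractions <- ps$fractions
    res$mean_shifts_h <- ps$mean_shifts_h
    res$cutoff_h <- intersection_cutoff(fit2$components[1, ],
                                        fit2$components[2, ])
  }
  structure(res, class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf("<bimodality_result: %s (delta AIC %.2f)>\n",
              x$selected, x$delta_aic))
  if (x$selected == "bimodal")
    cat(sprintf("  populations: %.1f%% at %.2f h / %.1f%% at %.2f h; cutoff %.2f h\n",
                100 * x$fractions[1], x$mean_shifts_h[1],
                100 * x$fractions[2], x$mean_shifts_h[2], x$cutoff_h))
  invisible(x)
}

#' Population fractions and mean shifts from a two-component fit
#'
#' The relative contribution of each population is its component area
#' divided by the total area; the mean shift is the component center.
#'
#' @param fit2 a two-component [fit_gaussians()] result.
#' @return list with `fractions` (sums to 1, ordered by center) and
#'   `mean_shifts_h`.
#' @export
population_stats <- function(fit2) {
  stopifnot(fit2$n_components == 2)
  A <- fit2$components$A
  list(fractions = A / sum(A), mean_shifts_h = fit2$components$xc)
}

#' Intersection cutoff between two Gaussian components
#'
#' The point between the two centers where the component curves are equal
#' (the root of the log-density difference, a quadratic in x). Used as the
#' cutoff separating the slow from the rapid population. When no root lies
#' strictly between the centers the midpoint is returned with a warning.
#'
#' @param c1,c2 one-row data frames (or lists) with `A`, `w`, `xc`;
#'   `c1$xc < c2$xc`.
#' @return cutoff location in hours.
#' @export
intersection_cutoff <- function(c1, c2) {
  if (!(c1$xc < c2$xc)) stop("components must be ordered: c1$xc < c2$xc")
  # log y1 - log y2 = 0:
  # (b - a) x^2 + 2 (a xc1 - b xc2) x + (b xc2^2 - a xc1^2 + L) = 0
  a <- 2 / c1$w^2
  b <- 2 / c2$w^2
  L <- log((c1$A * c2$w) / (c2$A * c1$w))
  qa <- b - a
  qb <- 2 * (a * c1$xc - b * c2$xc)
  qc <- b * c2$xc^2 - a * c1$xc^2 + L
  roots <- if (abs(qa) < 1e-12) {
    if (abs(qb) < 1e-12) numeric(0) else -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) numeric(0)
    else (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
  }
  roots <- roots[roots > c1$xc & roots < c2$xc]
  if (length(roots) == 0) {
    warning("no intersection between the centers; using midpoint")
    return((c1$xc + c2$xc) / 2)
  }
  roots[1]
}

#' Classify cells into slow and rapid populations by the cutoff
#'
#' Cells with a shift strictly greater than the cutoff belong to the rapid
#' (more-shifted) population; a shift exactly at the cutoff is slow (closed
#' lower side).
#'
#' @param shifts_h per-cell shifts (hours).
#' @param cutoff_h the [intersection_cutoff()].
#' @return character vector `"rapid"` / `"slow"`.
#' @export
classify_cells <- function(shifts_h, cutoff_h) {
  ifelse(shifts_h > cutoff_h, "rapid", "slow")
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact p-value comparing paired per-explant population means by
#' full enumeration of all 2^n sign assignments of the ranked absolute
#' differences (midranks for ties; zero differences dropped). The two-sided
#' p-value is the probability, under the enumeration null, of a rank sum at
#' least as far from its expectation as observed.
#'
#' @param pop1,pop2 equal-length paired vectors (hours); n between 1 and 15
#'   after dropping zero differences.
#' @return list with `p_value`, `statistic` (V, rank sum of positive
#'   differences), `n_pairs`.
#' @export
paired_population_test <- function(pop1, pop2) {
  if (length(pop1) != length(pop2)) stop("pop1 and pop2 must be paired")
  if (length(pop1) == 0) stop("no pairs")
  d <- pop2 - pop1
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p_value = 1, statistic = 0, n_pairs = 0L))
  if (n > 15) stop("exact enumeration limited to n <= 15")
  r <- rank(abs(d))           # midranks for ties
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  p <- mean(abs(V - mu) >= abs(v_obs - mu) - 1e-9)
  list(p_value = p, statistic = v_obs, n_pairs = as.integer(n))
}

#' Full bimodality analysis of a set of phase shifts
#'
#' Convenience wrapper: histogram, both fits, model selection, and per-cell
#' labels when bimodal.
#'
#' @param shifts_h per-cell phase shifts (hours).
#' @param scale passed to [fit_gaussians()].
#' @return a `bimodality_result` with an added `labels` element (per-cell
#'   population labels; all `"slow"` when unimodal) and `histogram`.
#' @export
analyze_shifts <- function(shifts_h, scale = "density") {
  hist <- make_histogram(shifts_h)
  fit1 <- fit_gaussians(hist, 1, scale = scale)
  fit2 <- fit_gaussians(hist, 2, scale = scale)
  res <- select_model(fit1, fit2)
  res$histogram <- hist
  res$labels <- if (res$selected == "bimodal")
    classify_cells(shifts_h, res$cutoff_h) else rep("slow", length(shifts_h))
  res
}
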