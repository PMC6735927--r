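# Origin-constrained Michaelis-Menten-type saturation curves of divergence
# versus Ks, and extra-sum-of-squares F-tests comparing partitions.
#
# The model is y = a * x / (b + x): zero divergence at the time of
# duplication (functional redundancy, so the curve passes through the
# origin), monotone approach to the asymptote a with half-saturation b. The
# curve accommodates the saturation of synonymous sites at high Ks that makes
# a linear divergence-time model inappropriate.

#' Fit an origin-constrained saturation curve by least squares
#'
#' Minimizes `sum((y - a*x/(b+x))^2)` over the parameter box. The problem is
#' solved by profiling: for fixed `b` the optimal asymptote has the closed
#' form `a(b) = sum(y*g)/sum(g^2)` with `g = x/(b+x)`, clamped to its bounds,
#' leaving a one-dimensional search over `b` that is multi-started on
#' log-spaced subintervals of the `b` box; the best (lowest-SSE) solution
#' wins, ties broken toward smaller `b`.
#'
#' @param x,y numeric vectors: Ks values (positive) and divergence values.
#'   Alternatively `x` may be a data frame with columns `ks` and `value`.
#' @param a_max upper bound for the asymptote: 1 for bounded measures
#'   (ED, ID), a larger value (default 10) suits an unbounded sequence
#'   divergence.
#' @param b_range bounds for the half-saturation constant.
#' @return object of class `"saturation_fit"`: list with `a`, `b`, `sse`,
#'   `n`, `dof` (`n - 2`), `converged`, `b_identified` (FALSE when the data
#'   cannot pin down `b`, e.g. all-zero divergence giving `a = 0`), and the
#'   fitting data (`x`, `y`) retained for bootstrap resampling.
#' @export
fit_saturation <- function(x, y = NULL, a_max = 1, b_range = c(1e-6, 100)) {
  if (is.data.frame(x)) { y <- x$value; x <- x$ks }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points to fit a saturation curve")
  if (any(x <= 0)) stop("ks values must be positive")

  profile_a <- function(b) {
    g <- x / (b + x)
    a <- sum(y * g) / sum(g * g)
    min(max(a, 0), a_max)
  }
  sse_at <- function(b) {
    g <- x / (b + x)
    a <- profile_a(b)
    sum((y - a * g)^2)
  }

  if (all(y == 0)) {
    fit <- list(a = 0, b = NA_real_, sse = 0, n = length(x),
                dof = length(x) - 2L, converged = TRUE, b_identified = FALSE,
                x = x, y = y)
    class(fit) <- "saturation_fit"
    return(fit)
  }

  # multi-start: one bounded 1-D minimization per log-spaced subinterval
  breaks <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = 7))
  cand_b <- breaks
  for (i in seq_len(length(breaks) - 1L)) {
    o <- stats::optimize(sse_at, lower = breaks[i], upper = breaks[i + 1],
                         tol = 1e-9)
    cand_b <- c(cand_b, o$minimum)
  }
  sse_vals <- vapply(cand_b, sse_at, numeric(1))
  best_sse <- min(sse_vals)
  # ties (flat profile) broken toward smaller b
  b_hat <- min(cand_b[sse_vals <= best_sse + 1e-12 * max(1, best_sse)])
  a_hat <- profile_a(b_hat)
  b_ident <- a_hat > 0 &&
    (sse_at(min(b_hat * 2, b_range[2])) > best_sse + 1e-12 * max(1, best_sse) ||
     sse_at(max(b_hat / 2, b_range[1])) > best_sse + 1e-12 * max(1, best_sse))
  fit <- list(a = a_hat, b = b_hat, sse = best_sse, n = length(x),
              dof = length(x) - 2L, converged = TRUE, b_identified = b_ident,
              x = x, y = y)
  class(fit) <- "saturation_fit"
  fit
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation fit y = a*x/(b+x): a = %.4f, b = %s, sse = %.4g, n = %d\n",
              x$a, ifelse(is.na(x$b), "unidentified", sprintf("%.4f", x$b)),
              x$sse, x$n))
  invisible(x)
}

#' @param object a `"saturation_fit"`.
#' @param newdata numeric vector of Ks values.
#' @param ... unused.
#' @rdname fit_saturation
#' @export
predict.saturation_fit <- function(object, newdata, ...) {
  b <- if (is.na(object$b)) 1 else object$b   # a = 0 makes b irrelevant
  object$a * newdata / (b + newdata)
}

#' Compare partitions by an extra-sum-of-squares F-test
#'
#' Fits one saturation curve per partition and a single curve to the pooled
#' data, then tests the nested null hypothesis that one curve suffices:
#' `F = ((SSE_comb - SSE_sep)/df_num) / (SSE_sep/df_den)` with `df_num =
#' 2*(k-1)` and `df_den = n_total - 2k` for `k` partitions of two parameters
#' each. The nesting inequality `SSE_comb >= SSE_sep` is asserted on every
#' comparison.
#'
#' @param partitions named list of data frames, each with columns `ks` and
#'   `value`.
#' @param a_max,b_range parameter box passed to [fit_saturation()].
#' @return object of class `"model_comparison"`: separate fits, combined
#'   fit, `f_stat`, `df_num`, `df_den`, `p_value`.
#' @export
compare_partitions <- function(partitions, a_max = 1, b_range = c(1e-6, 100)) {
  stopifnot(is.list(partitions), length(partitions) >= 2L,
            !is.null(names(partitions)))
  fits <- lapply(partitions, fit_saturation, a_max = a_max, b_range = b_range)
  pooled <- do.call(rbind, lapply(partitions, function(d)
    data.frame(ks = d$ks, value = d$value)))
  combined <- fit_saturation(pooled, a_max = a_max, b_range = b_range)
  sse_sep <- sum(vapply(fits, function(f) f$sse, numeric(1)))
  k <- length(partitions)
  n_total <- combined$n
  df_num <- 2L * (k - 1L)
  df_den <- n_total - 2L * k
  if (df_den <= 0L) stop("not enough points for the nested F-test (df_den <= 0)")
  if (combined$sse < sse_sep - 1e-8 * max(1, combined$sse))
    stop("nesting violated: combined SSE below summed separate SSEs")
  f_stat <- max(0, (combined$sse - sse_sep) / df_num) / (sse_sep / df_den)
  out <- list(partitions = names(partitions), fits = fits, combined = combined,
              sse_separate = sse_sep, f_stat = f_stat,
              df_num = df_num, df_den = df_den,
              p_value = stats::pf(f_stat, df_num, df_den, lower.tail = FALSE))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("nested F-test (%s): F(%d, %d) = %.3f, p = %.3g\n",
              paste(x$partitions, collapse = " vs "),
              x$df_num, x$df_den, x$f_stat, x$p_value))
  for (nm in x$partitions)
    cat(sprintf("  %-16s a = %.4f, b = %s, n = %d\n", nm, x$fits[[nm]]$a,
                ifelse(is.na(x$fits[[nm]]$b), "NA",
                       sprintf("%.4f", x$fits[[nm]]$b)), x$fits[[nm]]$n))
  invisible(x)
}

#' Bootstrap confidence band for a fitted saturation curve
#'
#' Nonparametric case-resampling bootstrap: the (x, y) points stored in the
#' fit are resampled with replacement and refit `n_boot` times; the band is
#' the pointwise percentile interval of the refitted curves on `x_grid`,
#' widened where necessary to contain the point-estimate curve.
#'
#' @param fit a converged [fit_saturation()] result.
#' @param level coverage level (default 0.95).
#' @param n_boot number of bootstrap resamples (default 500).
#' @param seed integer seed for reproducibility.
#' @param x_grid Ks grid (default 50 points spanning the data).
#' @return data frame `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, level = 0.95, n_boot = 500L, seed = 1L,
                            x_grid = NULL) {
  stopifnot(inherits(fit, "saturation_fit"), isTRUE(fit$converged))
  if (is.null(x_grid))
    x_grid <- seq(min(fit$x), max(fit$x), length.out = 50L)
  set.seed(seed)
  n <- fit$n
  a_max <- max(1, fit$a)  # refits share the original box height
  curves <- matrix(NA_real_, nrow = n_boot, ncol = length(x_grid))
  ok <- 0L
  for (bidx in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(fit_saturation(fit$x[idx], fit$y[idx], a_max = a_max),
                   error = function(e) NULL)
    if (is.null(bf)) next
    ok <- ok + 1L
    curves[bidx, ] <- predict(bf, x_grid)
  }
  if (ok < 50L) stop("fewer than 50 successful bootstrap refits")
  alpha <- (1 - level) / 2
  lower <- apply(curves, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(curves, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  yhat <- predict(fit, x_grid)
  data.frame(x = x_grid, fit = yhat,
             lower = pmin(lower, yhat), upper = pmax(upper, yhat))
}

#' Fit and compare saturation curves for every divergence measure
#'
#' The panel driver behind the divergence-versus-Ks figures: for each
#' requested measure it fits per-partition curves and runs the nested F-test.
#' Under the `"mode_x_ppi"` scheme, with-PPI and without-PPI duplicates are
#' compared *within* each duplication mode separately (two F-tests per
#' measure); the other schemes yield one two-partition test each.
#'
#' @param records data frame with columns `ks`, `mode`, `ppi_status` and one
#'   column per measure in `measures`.
#' @param measures character subset of `c("sd", "ed", "id")` naming columns
#'   of `records`.
#' @param scheme `"mode"`, `"ppi_status"`, or `"mode_x_ppi"`.
#' @param min_n partitions smaller than this are skipped with a report line
#'   (default 10).
#' @param b_range half-saturation bounds.
#' @return list with `fits` (tidy table: measure, comparison, partition, a,
#'   b, sse, n), `comparisons` (measure, comparison, f, df1, df2, p),
#'   `skipped` (report lines for undersized partitions), and `objects`
#'   (the underlying `model_comparison` objects, keyed measure.comparison).
#' @export
run_figure_suite <- function(records, measures = c("sd", "ed"),
                             scheme = c("mode", "ppi_status", "mode_x_ppi"),
                             min_n = 10L, b_range = c(1e-6, 100)) {
  scheme <- match.arg(scheme)
  stopifnot(all(measures %in% names(records)), "ks" %in% names(records))
  groupings <- switch(scheme,
    mode = list(all = list(filter = rep(TRUE, nrow(records)), key = records$mode,
                           levels = c("tandem", "block"))),
    ppi_status = list(all = list(filter = rep(TRUE, nrow(records)),
                                 key = records$ppi_status,
                                 levels = c("with", "without"))),
    mode_x_ppi = {
      g <- lapply(c("tandem", "block"), function(m)
        list(filter = records$mode == m, key = records$ppi_status,
             levels = c("with", "without")))
      names(g) <- c("within_tandem", "within_block")
      g
    })
  fits <- comparisons <- list()
  skipped <- character()
  objects <- list()
  for (ms in measures) {
    a_max <- if (ms == "sd") 10 else 1
    for (cmp_name in names(groupings)) {
      gr <- groupings[[cmp_name]]
      parts <- lapply(gr$levels, function(l) {
        sel <- gr$filter & gr$key == l & !is.na(records[[ms]])
        data.frame(ks = records$ks[sel], value = records[[ms]][sel])
      })
      names(parts) <- gr$levels
      small <- vapply(parts, nrow, integer(1)) < min_n
      if (any(small)) {
        skipped <- c(skipped, sprintf(
          "measure %s, comparison %s: partition(s) %s below min size %d; comparison skipped",
          ms, cmp_name, paste(gr$levels[small], collapse = "/"), min_n))
      }
      part_fits <- lapply(parts[!small], fit_saturation,
                          a_max = a_max, b_range = b_range)
      for (l in names(part_fits))
        fits[[length(fits) + 1L]] <- data.frame(
          measure = ms, comparison = cmp_name, partition = l,
          a = part_fits[[l]]$a, b = part_fits[[l]]$b, sse = part_fits[[l]]$sse,
          n = part_fits[[l]]$n, stringsAsFactors = FALSE)
      if (sum(!small) < 2L) next
      mc <- compare_partitions(parts[!small], a_max = a_max, b_range = b_range)
      objects[[paste(ms, cmp_name, sep = ".")]] <- mc
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        measure = ms, comparison = cmp_name, f = mc$f_stat,
        df1 = mc$df_num, df2 = mc$df_den, p = mc$p_value,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = if (length(fits)) do.call(rbind, fits) else NULL,
       comparisons = if (length(comparisons)) do.call(rbind, comparisons) else NULL,
       skipped = skipped, objects = objects)
}
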