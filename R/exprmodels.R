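#' Differential-expression binning and the rejected mechanistic models
#'
#' Tools to turn per-gene log2 fold changes into mCG-density-binned response
#' curves (with the zero-shift convention that the gene-weighted average over
#' densities 1-6 per 100 bp is zero), a maximum-slope estimator for those
#' curves, and two mechanistic models operated as predictors: the detachment
#' model (premature termination per bound protein, linear in the total mCG
#' count) and the condensation model (expression follows promoter
#' accessibility).
#'
#' @name exprmodels
NULL

#' Per-gene methylation coverage fractions
#'
#' For each gene, the fraction of its gene-body CG sites covered by at
#' least `min_cov` reads in the methylome.
#'
#' @param panel A `gene_panel`.
#' @param m A [methylome] with simulated read calls.
#' @param min_cov Coverage threshold (default 20).
#' @return Numeric vector, one fraction per gene (`NA` for genes without
#'   CG sites).
#' @export
gene_coverage_stats <- function(panel, m, min_cov = 20L) {
  stopifnot(inherits(panel, "gene_panel"), inherits(m, "methylome"))
  pos <- m$cg_positions
  covok <- m$coverage >= min_cov
  vapply(seq_len(nrow(panel)), function(i) {
    inside <- pos >= panel$tss[i] & pos < panel$tes[i]
    if (!any(inside)) return(NA_real_)
    mean(covok[inside])
  }, numeric(1))
}

#' Filter genes on length and methylation coverage
#'
#' A gene is kept when its body is at least `min_len` bp long and the
#' fraction of its Cs with coverage of at least `min_cov` reads is at least
#' `min_cov_frac`. Genes without CG sites (coverage fraction `NA`) pass
#' the coverage criterion vacuously.
#'
#' @param panel A `gene_panel`.
#' @param cov_frac Per-gene coverage fractions, see [gene_coverage_stats].
#' @param min_len Minimum body length in bp (default 1000).
#' @param min_cov_frac Minimum covered fraction (default 0.8).
#' @return The filtered `gene_panel`.
#' @export
filter_genes <- function(panel, cov_frac, min_len = 1000, min_cov_frac = 0.8) {
  stopifnot(inherits(panel, "gene_panel"))
  if (length(cov_frac) != nrow(panel))
    stop("cov_frac must have one entry per gene")
  keep <- panel$length >= min_len &
    (is.na(cov_frac) | cov_frac >= min_cov_frac)
  out <- panel[keep, , drop = FALSE]
  class(out) <- c("gene_panel", "data.frame")
  out
}

#' Bin Log2FC against mCG density with the zero-shift convention
#'
#' Genes are binned by gene-body mCG density; per-bin means and standard
#' errors of the mean are computed, and a single additive shift is applied
#' to all values so that the gene-weighted average Log2FC over the density
#' range `shift_range` (default 1-6 per 100 bp) is zero.
#'
#' @param rho Per-gene mCG density (per 100 bp).
#' @param log2fc Per-gene log2 fold change.
#' @param bin_width Bin width in mCG per 100 bp (default 0.25).
#' @param rho_max Upper edge of the binned range (default 8).
#' @param shift_range Density range whose gene-weighted mean is shifted to
#'   zero.
#' @return Object of class `binned_response`: a data frame with `bin_lo`,
#'   `bin_hi`, `mid`, `mean`, `sem`, `n` (only non-empty bins) and
#'   attributes `shift` and `shift_range`. The SEM of a single-gene bin is
#'   `NA`.
#' @export
bin_log2fc <- function(rho, log2fc, bin_width = 0.25, rho_max = 8,
                       shift_range = c(1, 6)) {
  if (length(rho) != length(log2fc)) stop("rho and log2fc lengths differ")
  ok <- is.finite(rho) & is.finite(log2fc)
  rho <- rho[ok]; log2fc <- log2fc[ok]
  in_range <- rho >= shift_range[1L] & rho <= shift_range[2L]
  if (!any(in_range))
    stop("no genes with rho_mCG in [", shift_range[1L], ", ", shift_range[2L],
         "]; zero shift undefined")
  shift <- mean(log2fc[in_range])
  y <- log2fc - shift
  edges <- seq(0, max(rho_max, max(rho) + bin_width), by = bin_width)
  idx <- findInterval(rho, edges, rightmost.closed = TRUE)
  rows <- lapply(sort(unique(idx)), function(b) {
    v <- y[idx == b]
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mid = (edges[b] + edges[b + 1L]) / 2,
               mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "shift") <- shift
  attr(out, "shift_range") <- shift_range
  attr(out, "bin_width") <- bin_width
  class(out) <- c("binned_response", "data.frame")
  out
}

#' @export
print.binned_response <- function(x, ...) {
  cat(sprintf("Binned Log2FC response: %d bins, %d genes, shift %.4g\n",
              nrow(x), sum(x$n), attr(x, "shift")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.binned_response <- function(x, ...) {
  graphics::plot(x$mid, x$mean, type = "b", pch = 16,
                 xlab = "mCG density (per 100 bp)", ylab = "Log2FC", ...)
  has_sem <- !is.na(x$sem)
  graphics::arrows(x$mid[has_sem], x$mean[has_sem] - x$sem[has_sem],
                   x$mid[has_sem], x$mean[has_sem] + x$sem[has_sem],
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Maximum slope of a binned response
#'
#' Fits a weighted least-squares line in every contiguous window of
#' `window_bins` bins and returns the steepest (most negative) slope, in
#' Log2FC per (mCG/100 bp). Weights are inverse squared SEMs; bins with
#' zero or undefined SEM get the largest finite weight in the window, and
#' when no bin has a usable SEM the fit is unweighted.
#'
#' @param binned A `binned_response`.
#' @param window_bins Window width in bins, at least 3 (default 5).
#' @return List with `slope`, `stderr`, `window` (density range of the
#'   winning window) and `index` (first bin of the window).
#' @export
max_slope <- function(binned, window_bins = 5L) {
  stopifnot(inherits(binned, "binned_response"))
  if (window_bins < 3L) stop("window_bins must be at least 3")
  nb <- nrow(binned)
  if (nb < window_bins) stop("fewer bins (", nb, ") than window_bins")
  best <- list(slope = Inf, stderr = NA_real_, window = c(NA, NA), index = NA)
  for (s in seq_len(nb - window_bins + 1L)) {
    i <- s:(s + window_bins - 1L)
    x <- binned$mid[i]; y <- binned$mean[i]; sem <- binned$sem[i]
    w <- 1 / sem^2
    if (all(!is.finite(w))) w <- rep(1, length(i))
    else w[!is.finite(w)] <- max(w[is.finite(w)])
    xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
    sxx <- sum(w * (x - xm)^2)
    if (sxx == 0) next
    slope <- sum(w * (x - xm) * (y - ym)) / sxx
    if (slope < best$slope)
      best <- list(slope = slope, stderr = sqrt(1 / sxx),
                   window = c(binned$bin_lo[i[1L]], binned$bin_hi[i[window_bins]]),
                   index = s)
  }
  if (!is.finite(best$slope)) stop("no window admitted a slope fit")
  best
}

#' Detachment-model Log2FC
#'
#' Premature termination at each bound site gives a survival probability
#' `(1 - lambda)^n`, hence
#' `Log2FC_X/Y = const - gamma * (M_X / M_Y - 1) * n`, with `gamma`
#' proportional to the per-site abortion probability `lambda` and `n` the
#' total mCG count of the gene.
#'
#' @param n Total gene-body mCG count (vectorized).
#' @param M_X,M_Y Relative protein levels of the two lines; `M_Y > 0`.
#' @param params List with `gamma` (>= 0) and `const`.
#' @return Log2FC value(s).
#' @export
detachment_log2fc <- function(n, M_X, M_Y, params) {
  if (M_Y <= 0)
    stop("M_Y must be positive (put the knockout on the X side)")
  if (params$gamma < 0) stop("gamma must be non-negative")
  params$const - params$gamma * (M_X / M_Y - 1) * n
}

#' Fit the detachment model to one line pair
#'
#' Least-squares fit of the linear-in-`n` model
#' `log2fc = const - gamma * (M_ratio - 1) * n` on per-gene data from a
#' single training pair with known level ratio `M_ratio = M_X / M_Y`. The
#' fitted `gamma` is reusable to predict any other pair.
#'
#' @param n Per-gene total mCG counts.
#' @param log2fc Per-gene Log2FC of the training pair.
#' @param M_ratio Level ratio of the training pair (not 1).
#' @return Object of class `detachment_fit` with `gamma`, `const` and the
#'   training ratio; see [predict.detachment_fit].
#' @export
fit_detachment <- function(n, log2fc, M_ratio) {
  if (M_ratio == 1) stop("training pair has M_X = M_Y; gamma unidentifiable")
  if (stats::var(n) == 0) stop("degenerate n range; cannot fit")
  fit <- stats::lm.fit(cbind(1, n), log2fc)
  slope <- fit$coefficients[2L]
  structure(list(gamma = as.numeric(-slope / (M_ratio - 1)),
                 const = as.numeric(fit$coefficients[1L]),
                 M_ratio_train = M_ratio),
            class = "detachment_fit")
}

#' @export
print.detachment_fit <- function(x, ...) {
  cat(sprintf("Detachment fit: gamma = %.4g, const = %.4g (trained at M ratio %g)\n",
              x$gamma, x$const, x$M_ratio_train))
  invisible(x)
}

#' @export
coef.detachment_fit <- function(object, ...)
  c(gamma = object$gamma, const = object$const)

#' @export
predict.detachment_fit <- function(object, n, M_X, M_Y = 1, const = NULL, ...) {
  detachment_log2fc(n, M_X, M_Y,
                    list(gamma = object$gamma,
                         const = if (is.null(const)) object$const else const))
}

#' Condensation-model prediction from accessibilities
#'
#' Under the condensation model the fraction of cells with a gene in the ON
#' state follows promoter openness, so the predicted Log2FC between lines X
#' and Y is `log2(a_X / a_Y)` per gene, binned by mCG density with the same
#' zero-shift convention as the expression curves. When an observed binned
#' curve is supplied, the prediction is aligned to it by a free additive
#' constant and scored by the mean squared deviation over shared bins.
#'
#' @param a_X,a_Y Per-gene accessibilities (Y strictly positive).
#' @param rho Per-gene mCG densities.
#' @param observed Optional `binned_response` to compare against.
#' @param ids Optional gene ids used in error messages.
#' @param ... Binning arguments passed to [bin_log2fc].
#' @return Object of class `condensation_fit` with the predicted
#'   `binned_response` and, when `observed` is given, `offset` and `mse`.
#' @export
condensation_predict <- function(a_X, a_Y, rho, observed = NULL, ids = NULL,
                                 ...) {
  bad <- !is.finite(a_Y) | a_Y <= 0 | !is.finite(a_X) | a_X <= 0
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("non-positive accessibility for gene(s): ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  pred <- bin_log2fc(rho, log2(a_X / a_Y), ...)
  out <- list(binned = pred)
  if (!is.null(observed)) {
    al <- align_curves(observed, pred)
    out$offset <- al$offset
    out$mse <- al$mse
  }
  structure(out, class = "condensation_fit")
}

#' @export
print.condensation_fit <- function(x, ...) {
  cat("Condensation-model prediction:", nrow(x$binned), "bins")
  if (!is.null(x$mse))
    cat(sprintf("; constant-aligned MSE vs observed = %.4g", x$mse))
  cat("\n")
  invisible(x)
}

#' Constant-aligned comparison of two binned curves
#'
#' Matches bins by midpoint, removes the mean difference (the free additive
#' constant) and returns the residual mean squared deviation.
#'
#' @param observed,predicted `binned_response` objects or data frames with
#'   `mid` and `mean` columns.
#' @return List with `offset` (added to the prediction) and `mse`.
#' @export
align_curves <- function(observed, predicted) {
  m <- merge(data.frame(mid = observed$mid, obs = observed$mean),
             data.frame(mid = predicted$mid, pred = predicted$mean),
             by = "mid")
  if (nrow(m) < 2L) stop("curves share fewer than two bins")
  offset <- mean(m$obs - m$pred)
  list(offset = offset, mse = mean((m$obs - m$pred - offset)^2), n_bins = nrow(m))
}
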