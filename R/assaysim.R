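#' In-silico ChIP-seq and ATAC-seq
#'
#' Generative models of the two assays used to measure methyl-CpG protein
#' binding: a ChIP model in which a fragment is retained if it carries at
#' least one bound protein (background fragments retained with probability
#' `p_bg`), and a Tn5 insertion model in which candidate cut sites are
#' rejected inside the 11-bp window occupied by a bound protein. Profiles
#' anchored on mCG sites are flank-normalized, combined into enrichment or
#' log-ratio footprint curves, and fitted by seeded grid search to recover
#' the generating occupancy.
#'
#' @name assaysim
NULL

# ---- counts profiles --------------------------------------------------------

#' Construct a counts profile
#'
#' A counts profile holds accumulated per-offset counts over a window
#' centred on a set of anchor features: read-overlap counts (`mode
#' "overlap"`, ChIP-style) or fragment-endpoint counts (`mode "insertion"`,
#' Tn5-style).
#'
#' @param counts Numeric vector of length `2 * radius + 1`, offsets
#'   `-radius..radius`.
#' @param radius Window radius in bp.
#' @param mode `"overlap"` or `"insertion"`.
#' @param n_anchors Number of anchors accumulated.
#' @return An object of class `counts_profile`.
#' @export
counts_profile <- function(counts, radius, mode = c("overlap", "insertion"),
                           n_anchors = NA_integer_) {
  mode <- match.arg(mode)
  counts <- as.numeric(counts)
  if (length(counts) != 2L * radius + 1L)
    stop("counts must have length 2 * radius + 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  names(counts) <- seq(-radius, radius)
  structure(list(counts = counts, radius = as.integer(radius),
                 mode = mode, n_anchors = as.integer(n_anchors)),
            class = "counts_profile")
}

#' @export
print.counts_profile <- function(x, ...) {
  cat(sprintf("Counts profile (%s): radius %d bp, %s anchors, total %g\n",
              x$mode, x$radius,
              ifelse(is.na(x$n_anchors), "?", x$n_anchors), sum(x$counts)))
  invisible(x)
}

#' @export
plot.counts_profile <- function(x, ...) {
  graphics::plot(seq(-x$radius, x$radius), x$counts, type = "l",
                 xlab = "offset from anchor (bp)", ylab = "counts", ...)
  invisible(x)
}

#' @export
`+.counts_profile` <- function(e1, e2) {
  stopifnot(inherits(e2, "counts_profile"),
            e1$radius == e2$radius, e1$mode == e2$mode)
  counts_profile(e1$counts + e2$counts, e1$radius, e1$mode,
                 n_anchors = e1$n_anchors)
}

#' Accumulate counts around anchors
#'
#' In `overlap` mode, `counts[i]` is the number of fragments whose
#' half-open interval covers base `anchor + i`, summed over anchors. In
#' `insertion` mode it is the number of insertion events at exactly
#' `anchor + i`. Anchors closer than `radius` to a sequence end are
#' skipped.
#'
#' @param x For `overlap`, a data frame or matrix with 0-based half-open
#'   `start`/`end` columns; for `insertion`, an integer vector of 0-based
#'   positions.
#' @param anchors Integer vector of 0-based anchor positions (non-empty).
#' @param radius Window radius in bp (defaults: 500 for overlap, 100 for
#'   insertion).
#' @param mode `"overlap"` or `"insertion"`.
#' @param sequence_length Length of the underlying sequence in bp.
#' @return A [counts_profile].
#' @export
profile_counts <- function(x, anchors, sequence_length,
                           mode = c("overlap", "insertion"),
                           radius = NULL) {
  mode <- match.arg(mode)
  if (is.null(radius)) radius <- if (mode == "overlap") 500L else 100L
  if (length(anchors) == 0L) stop("anchor set is empty")
  anchors <- as.integer(anchors)
  keep <- anchors - radius >= 0L & anchors + radius <= sequence_length - 1L
  anchors <- anchors[keep]
  if (length(anchors) == 0L)
    stop("no anchors remain after dropping those within radius of an end")
  if (mode == "overlap") {
    s <- pmax(0L, as.integer(x[, "start"]))
    e <- pmin(as.integer(sequence_length), as.integer(x[, "end"]))
    ok <- e > s
    vec <- cumsum(tabulate(s[ok] + 1L, sequence_length + 1L) -
                  tabulate(e[ok] + 1L, sequence_length + 1L))[seq_len(sequence_length)]
  } else {
    pos <- as.integer(x)
    pos <- pos[pos >= 0L & pos < sequence_length]
    vec <- tabulate(pos + 1L, sequence_length)
  }
  idx <- outer(anchors + 1L, seq(-radius, radius), "+")
  counts <- colSums(matrix(vec[idx], nrow = length(anchors)))
  counts_profile(counts, radius, mode, n_anchors = length(anchors))
}

#' Flank-normalize a counts profile
#'
#' Divides the counts by the mean count over the flank region, so the
#' normalized profile has flank mean exactly 1. Default flanks are the
#' standard windows for each mode: offsets \[-500, -301\] and \[301, 500\]
#' (divisor 400) for overlap profiles, and \[-50, -41\] and \[41, 50\]
#' (divisor 20) for insertion profiles.
#'
#' @param profile A [counts_profile].
#' @param flank A list of two integer ranges `c(lo, hi)` (offsets), or
#'   `NULL` for the mode default.
#' @return Named numeric vector of normalized values (names are offsets).
#' @export
normalize_flanks <- function(profile, flank = NULL) {
  stopifnot(inherits(profile, "counts_profile"))
  if (is.null(flank)) {
    flank <- if (profile$mode == "overlap")
      list(c(-500L, -301L), c(301L, 500L))
    else list(c(-50L, -41L), c(41L, 50L))
  }
  r <- profile$radius
  idx <- unlist(lapply(flank, function(fr) {
    if (fr[1L] < -r || fr[2L] > r) stop("flank range outside profile radius")
    seq(fr[1L], fr[2L]) + r + 1L
  }))
  fsum <- sum(profile$counts[idx])
  if (fsum <= 0) stop("flank counts sum to zero; cannot normalize")
  profile$counts / (fsum / length(idx))
}

#' ChIP enrichment profile
#'
#' `f[i] = Norm1(chip)[i] / Norm1(input)[i] - 1`, where `Norm1` is the
#' overlap-mode flank normalization. The flank mean of `f` is close to 0 by
#' construction.
#'
#' @param chip,input Overlap-mode [counts_profile]s of equal radius.
#' @param flank Optional flank ranges passed to [normalize_flanks].
#' @return Named numeric vector of enrichment values.
#' @export
enrichment_profile <- function(chip, input, flank = NULL) {
  stopifnot(inherits(chip, "counts_profile"), inherits(input, "counts_profile"))
  if (chip$radius != input$radius) stop("profiles must share a radius")
  nc <- normalize_flanks(chip, flank)
  ni <- normalize_flanks(input, flank)
  if (any(ni == 0)) {
    bad <- as.integer(names(ni)[ni == 0])
    stop("input profile is zero at offset(s) ", paste(utils::head(bad, 5), collapse = ", "),
         "; enrichment undefined")
  }
  nc / ni - 1
}

#' ATAC footprint profile
#'
#' Natural-log ratio of flank-normalized insertion profiles between a cell
#' line and its knockout control:
#' `f[i] = ln( Norm2(cell)[i] / Norm2(ko)[i] )`. If either profile contains
#' zero counts, a pseudo-count is added to all counts of both profiles (with
#' a warning) so the log stays finite.
#'
#' @param cell,ko Insertion-mode [counts_profile]s of equal radius.
#' @param pseudo Pseudo-count used when zeros are present (default 0.5).
#' @param flank Optional flank ranges passed to [normalize_flanks].
#' @return Named numeric vector of log-ratio values.
#' @export
footprint_profile <- function(cell, ko, pseudo = 0.5, flank = NULL) {
  stopifnot(inherits(cell, "counts_profile"), inherits(ko, "counts_profile"))
  if (cell$mode != "insertion" || ko$mode != "insertion")
    stop("footprints are defined on insertion-mode profiles")
  if (cell$radius != ko$radius) stop("profiles must share a radius")
  if (any(cell$counts == 0) || any(ko$counts == 0)) {
    warning("zero counts in footprint ratio; adding pseudo-count ", pseudo)
    cell$counts <- cell$counts + pseudo
    ko$counts <- ko$counts + pseudo
  }
  log(normalize_flanks(cell, flank) / normalize_flanks(ko, flank))
}

# ---- methylation calls and binding -----------------------------------------

#' Call methylation state from read counts
#'
#' A site is called methylated when it is methylated in 100% of the reads
#' and the coverage is at least `min_cov` (default 5); unmethylated when no
#' read reports methylation (and at least one read covers the site);
#' ambiguous otherwise (including zero coverage).
#'
#' @param coverage,meth_reads Non-negative integers (vectorized),
#'   `meth_reads <= coverage`.
#' @param min_cov Minimum coverage for a methylated call.
#' @return Character vector in `{"methylated", "unmethylated", "ambiguous"}`.
#' @export
call_methylation <- function(coverage, meth_reads, min_cov = 5L) {
  if (any(coverage < 0) || any(meth_reads < 0))
    stop("coverage and meth_reads must be non-negative")
  if (any(meth_reads > coverage)) stop("meth_reads must not exceed coverage")
  out <- rep("ambiguous", length(coverage))
  out[coverage >= min_cov & meth_reads == coverage] <- "methylated"
  out[coverage > 0 & meth_reads == 0] <- "unmethylated"
  out
}

#' Default motif affinity table
#'
#' Relative binding probabilities per motif, with mCG fixed at the maximum.
#' The mCA and unmethylated-CG entries are placeholders standing in for
#' measured relative affinities, which are not pinned down here; override
#' them when a calibrated table is available.
#'
#' @return Named numeric vector with entries `mCG`, `mCA`, `CG`.
#' @export
default_affinities <- function() c(mCG = 1.0, mCA = 0.35, CG = 0.0)

check_affinities <- function(a) {
  if (any(a < 0 | a > 1)) stop("affinities must be in [0, 1]")
  if (!"mCG" %in% names(a) || a[["mCG"]] < max(a))
    stop("affinity table must contain mCG with the maximum value")
  a
}

#' Simulate protein binding over a methylome
#'
#' Each CG site is bound independently with probability
#' `p * affinity(motif)`, where the motif is `mCG` for methylated sites and
#' `CG` otherwise.
#'
#' @param m A [methylome].
#' @param p Occupancy multiplier in \[0, 1\].
#' @param affinities Named affinity table, see [default_affinities].
#' @param seed Integer seed.
#' @return Sorted integer vector of bound 0-based positions (the C of each
#'   bound CG).
#' @export
simulate_binding <- function(m, p, affinities = default_affinities(),
                             seed = 1L) {
  stopifnot(inherits(m, "methylome"))
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  affinities <- check_affinities(affinities)
  set.seed(seed)
  pr <- p * ifelse(m$meth_state, affinities[["mCG"]], affinities[["CG"]])
  m$cg_positions[stats::runif(length(pr)) < pr]
}

# ---- ChIP library -----------------------------------------------------------

#' Parameters of the ChIP library simulator
#'
#' @param p_bg Background retention probability in \[0, 1\].
#' @param frag_mean,frag_sd,frag_min Fragment length distribution (normal,
#'   truncated below at `frag_min`).
#' @param gc_bias_strength,len_bias_strength Retention-bias strengths
#'   (heuristic exponential-tilt weights; 0 disables).
#' @return A list of class `chip_sim_params`.
#' @export
chip_sim_params <- function(p_bg = 0.8, frag_mean = 200, frag_sd = 50,
                            frag_min = 50, gc_bias_strength = 0,
                            len_bias_strength = 0) {
  if (p_bg < 0 || p_bg > 1) stop("p_bg must be in [0, 1]")
  structure(list(p_bg = p_bg, frag_mean = frag_mean, frag_sd = frag_sd,
                 frag_min = frag_min, gc_bias_strength = gc_bias_strength,
                 len_bias_strength = len_bias_strength),
            class = "chip_sim_params")
}

#' Simulate a ChIP (or input) fragment library
#'
#' Random fragments are drawn along the sequence; a fragment is retained
#' with probability 1 if it overlaps at least one bound position, and with
#' probability `p_bg` otherwise. GC and length biases, when enabled, tilt
#' the retention probability multiplicatively. An unbiased input library is
#' obtained with `bound = integer(0)` and `p_bg = 1`.
#'
#' @param sequence_length Sequence length in bp.
#' @param bound Sorted 0-based positions of bound proteins.
#' @param params A [chip_sim_params].
#' @param n_fragments Number of fragments drawn.
#' @param seed Integer seed.
#' @param sequence Optional sequence (character scalar), required when
#'   `gc_bias_strength != 0`.
#' @return Data frame with 0-based half-open `start`/`end` of retained
#'   fragments.
#' @export
simulate_chip_library <- function(sequence_length, bound, params,
                                  n_fragments, seed = 1L, sequence = NULL) {
  stopifnot(inherits(params, "chip_sim_params"))
  if (n_fragments < 1) stop("n_fragments must be at least 1")
  set.seed(seed)
  s <- sample.int(sequence_length, n_fragments, replace = TRUE) - 1L
  len <- pmax(params$frag_min,
              round(stats::rnorm(n_fragments, params$frag_mean, params$frag_sd)))
  e <- pmin(sequence_length, s + len)
  bound <- sort(as.integer(bound))
  covers <- if (length(bound))
    (findInterval(e - 1L, bound) - findInterval(s - 1L, bound)) > 0L
  else rep(FALSE, n_fragments)
  p_keep <- ifelse(covers, 1, params$p_bg)
  if (params$gc_bias_strength != 0) {
    if (is.null(sequence)) stop("sequence required for GC bias")
    gc <- cumsum(c(0L, as.integer(strsplit(sequence, "")[[1L]] %in% c("C", "G"))))
    frac <- (gc[e + 1L] - gc[s + 1L]) / pmax(1L, e - s)
    p_keep <- pmin(1, p_keep * exp(params$gc_bias_strength * (frac - mean(frac))))
  }
  if (params$len_bias_strength != 0)
    p_keep <- pmin(1, p_keep * exp(params$len_bias_strength *
                                     log((e - s) / params$frag_mean)))
  keep <- stats::runif(n_fragments) < p_keep
  data.frame(start = s[keep], end = e[keep])
}

# ---- ATAC / Tn5 -------------------------------------------------------------

#' Parameters of the Tn5 insertion simulator
#'
#' @param t Mean insertion-site density per bp (> 0).
#' @param b GC bias (default 6.0); insertion weight is
#'   `1 + (b - 1) * local GC fraction` in a 10-bp window.
#' @param footprint_bp Protected span centred on a bound mC; must be odd
#'   (default 11).
#' @return A list of class `atac_sim_params`.
#' @export
atac_sim_params <- function(t = 0.5, b = 6.0, footprint_bp = 11L) {
  if (t <= 0) stop("t must be positive")
  if (footprint_bp %% 2L != 1L) stop("footprint_bp must be odd")
  structure(list(t = t, b = b, footprint_bp = as.integer(footprint_bp)),
            class = "atac_sim_params")
}

#' Per-position Tn5 insertion weights
#'
#' `1 + (b - 1) * gc10`, where `gc10` is the GC fraction in a centred 10-bp
#' window. Precompute once and pass to [simulate_atac] when simulating many
#' libraries on the same sequence.
#'
#' @param sequence Character scalar DNA sequence.
#' @param b GC bias.
#' @return Numeric weight per position.
#' @export
tn5_weights <- function(sequence, b = 6.0) {
  if (b == 1) return(NULL)
  isgc <- as.integer(strsplit(sequence, "")[[1L]] %in% c("C", "G"))
  cs <- cumsum(c(0L, isgc))
  n <- length(isgc)
  lo <- pmax(0L, seq_len(n) - 6L)          # window [i-5, i+4], clipped
  hi <- pmin(n, seq_len(n) + 4L)
  gc10 <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  1 + (b - 1) * gc10
}

#' Simulate Tn5 insertion sites
#'
#' Candidate insertion sites are drawn with mean density `t` per bp,
#' weighted by the GC-bias factor, and rejected when they fall inside the
#' protected window (`footprint_bp`, centred on the bound mC) of any bound
#' protein.
#'
#' @param sequence_length Sequence length in bp.
#' @param bound Sorted 0-based positions of bound proteins.
#' @param params An [atac_sim_params].
#' @param seed Integer seed.
#' @param weights Optional precomputed [tn5_weights]; when `NULL` and
#'   `params$b != 1`, `sequence` must be supplied to compute them.
#' @param sequence Optional sequence used to compute weights.
#' @return Integer vector of 0-based insertion positions.
#' @export
simulate_atac <- function(sequence_length, bound, params, seed = 1L,
                          weights = NULL, sequence = NULL) {
  stopifnot(inherits(params, "atac_sim_params"))
  set.seed(seed)
  n_cand <- stats::rpois(1L, params$t * sequence_length)
  if (n_cand == 0L) return(integer(0))
  if (is.null(weights) && params$b != 1) {
    if (is.null(sequence)) stop("sequence or weights required when b != 1")
    weights <- tn5_weights(sequence, params$b)
  }
  pos <- if (is.null(weights))
    sample.int(sequence_length, n_cand, replace = TRUE) - 1L
  else
    sample.int(sequence_length, n_cand, replace = TRUE, prob = weights) - 1L
  bound <- sort(as.integer(bound))
  if (length(bound)) {
    half <- (params$footprint_bp - 1L) %/% 2L
    blocked <- (findInterval(pos + half, bound) -
                findInterval(pos - half - 1L, bound)) > 0L
    pos <- pos[!blocked]
  }
  sort(pos)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the ChIP model to an observed enrichment profile
#'
#' Re-simulates the ChIP and input libraries at every grid point
#' `(p, p_bg)` with seeds shared across grid points (common random numbers)
#' and minimizes the mean squared deviation between the simulated and
#' observed enrichment profiles. The full objective surface is returned so
#' flat directions (e.g. all small `p` fitting comparably well) stay
#' visible; a near-optimal set is reported using the replicate-to-replicate
#' spread of the objective at the minimizer as the noise floor.
#'
#' @param observed_f Observed enrichment profile (numeric, offsets
#'   `-radius..radius`).
#' @param context List with `sequence_length`, `methylome`, `params`
#'   (a [chip_sim_params] used for both libraries), `n_fragments`,
#'   `affinities`, `radius`, `seed`.
#' @param p_grid,pbg_grid Grids of candidate values.
#' @param n_rep Simulated replicates accumulated per grid point.
#' @return Object of class `chip_fit` with fields `p_hat`, `pbg_hat`,
#'   `objective` (matrix p x p_bg), `fitted`, `near_optimal`.
#' @export
fit_chip_model <- function(observed_f, context,
                           p_grid = c(0, 0.01, 0.02, 0.05, 0.1, 0.2),
                           pbg_grid = c(0.2, 0.4, 0.6, 0.8, 1),
                           n_rep = 2L) {
  if (!length(p_grid) || !length(pbg_grid)) stop("grids must be non-empty")
  ctx <- context
  anchors <- mcg_positions(ctx$methylome)
  radius <- if (is.null(ctx$radius)) 500L else ctx$radius
  seed0 <- if (is.null(ctx$seed)) 1L else ctx$seed
  aff <- if (is.null(ctx$affinities)) default_affinities() else ctx$affinities

  sim_profile <- function(p, p_bg, seeds) {
    pars <- ctx$params
    pars$p_bg <- p_bg
    prof <- NULL
    for (s in seeds) {
      b <- simulate_binding(ctx$methylome, p, aff, seed = s)
      fr <- simulate_chip_library(ctx$sequence_length, b, pars,
                                  ctx$n_fragments, seed = s + 1L)
      pc <- profile_counts(fr, anchors, ctx$sequence_length, "overlap", radius)
      prof <- if (is.null(prof)) pc else prof + pc
    }
    prof
  }
  input_for <- function(seeds) {
    pars <- ctx$params
    pars$p_bg <- 1
    prof <- NULL
    for (s in seeds) {
      fr <- simulate_chip_library(ctx$sequence_length, integer(0), pars,
                                  ctx$n_fragments, seed = s + 2L)
      pc <- profile_counts(fr, anchors, ctx$sequence_length, "overlap", radius)
      prof <- if (is.null(prof)) pc else prof + pc
    }
    prof
  }

  seeds <- seed0 + 10L * seq_len(n_rep)
  input_prof <- input_for(seeds)
  obj <- matrix(NA_real_, length(p_grid), length(pbg_grid),
                dimnames = list(p_grid, pbg_grid))
  fits <- vector("list", length(obj))
  dim(fits) <- dim(obj)
  for (i in seq_along(p_grid)) for (j in seq_along(pbg_grid)) {
    f <- enrichment_profile(sim_profile(p_grid[i], pbg_grid[j], seeds), input_prof)
    obj[i, j] <- mean((f - observed_f)^2)
    fits[[i, j]] <- f
  }
  best <- which(obj == min(obj), arr.ind = TRUE)
  best <- best[order(best[, 1L]), , drop = FALSE][1L, ]  # ties -> smaller p
  # noise floor: re-run the minimizer with independent seeds
  nf <- vapply(1:3, function(k) {
    sds <- seed0 + 1000L * k + 10L * seq_len(n_rep)
    f <- enrichment_profile(sim_profile(p_grid[best[1L]], pbg_grid[best[2L]], sds),
                            input_for(sds))
    mean((f - observed_f)^2)
  }, numeric(1))
  thr <- min(obj) + 3 * stats::sd(c(nf, obj[best[1L], best[2L]]))
  near <- which(obj <= thr, arr.ind = TRUE)
  structure(list(p_hat = p_grid[best[1L]], pbg_hat = pbg_grid[best[2L]],
                 objective = obj,
                 fitted = fits[[best[1L], best[2L]]],
                 observed = observed_f,
                 near_optimal = data.frame(p = p_grid[near[, 1L]],
                                           p_bg = pbg_grid[near[, 2L]],
                                           objective = obj[near]),
                 p_grid = p_grid, pbg_grid = pbg_grid),
            class = "chip_fit")
}

#' @export
print.chip_fit <- function(x, ...) {
  cat(sprintf("ChIP model fit: p_hat = %g, p_bg_hat = %g (MSE %.3g)\n",
              x$p_hat, x$pbg_hat, min(x$objective)))
  cat(" near-optimal grid points:", nrow(x$near_optimal), "\n")
  invisible(x)
}

#' @export
coef.chip_fit <- function(object, ...) c(p = object$p_hat, p_bg = object$pbg_hat)

#' Fit the Tn5 footprint model to an observed footprint
#'
#' Grid search over occupancy `p` and insertion density `t` with the GC
#' bias `b` held fixed. For every grid point the cell-line and control
#' libraries are re-simulated with seeds shared across the grid (common
#' random numbers), replicate counts are accumulated, and the mean squared
#' deviation between simulated and observed footprints is minimized. When
#' `refine = TRUE` and the minimizing `p` is interior, a quadratic
#' interpolation through the three neighbouring objective values gives a
#' continuous estimate `p_refined`; `p_hat` remains the grid minimizer.
#' Ties are broken toward smaller `p`. Note that flank normalization makes
#' the footprint shape nearly independent of `t`, so `t_hat` is weakly
#' identified by design.
#'
#' @param observed_f Observed footprint (numeric, offsets `-radius..radius`).
#' @param context List with `sequence_length`, `methylome`, `weights`
#'   (precomputed [tn5_weights], or `NULL`), `affinities`, `radius`
#'   (default 100), `seed`, and `footprint_bp`.
#' @param p_grid,t_grid Grids of candidate values.
#' @param b Fixed GC bias (default 6.0).
#' @param n_rep Simulated replicates accumulated per grid point.
#' @param refine Quadratically refine the minimizing `p` (default `TRUE`).
#' @return Object of class `footprint_fit` with fields `p_hat`, `t_hat`,
#'   `p_refined`, `objective`, `fitted`.
#' @export
fit_footprint <- function(observed_f, context,
                          p_grid = seq(0, 0.012, by = 0.0015),
                          t_grid = 0.5, b = 6.0, n_rep = 50L,
                          refine = TRUE) {
  if (!length(p_grid) || !length(t_grid)) stop("grids must be non-empty")
  ctx <- context
  anchors <- mcg_positions(ctx$methylome)
  radius <- if (is.null(ctx$radius)) 100L else ctx$radius
  seed0 <- if (is.null(ctx$seed)) 1L else ctx$seed
  aff <- if (is.null(ctx$affinities)) default_affinities() else ctx$affinities
  fp <- if (is.null(ctx$footprint_bp)) 11L else ctx$footprint_bp
  seeds <- seed0 + 10L * seq_len(n_rep)

  accum <- function(p, t) {
    pars <- atac_sim_params(t = t, b = b, footprint_bp = fp)
    prof <- NULL
    for (s in seeds) {
      bnd <- if (p > 0) simulate_binding(ctx$methylome, p, aff, seed = s)
             else integer(0)
      ins <- simulate_atac(ctx$sequence_length, bnd, pars, seed = s + 1L,
                           weights = ctx$weights)
      pc <- profile_counts(ins, anchors, ctx$sequence_length, "insertion", radius)
      prof <- if (is.null(prof)) pc else prof + pc
    }
    prof
  }

  obj <- matrix(NA_real_, length(p_grid), length(t_grid),
                dimnames = list(p_grid, t_grid))
  fits <- vector("list", length(obj))
  dim(fits) <- dim(obj)
  for (j in seq_along(t_grid)) {
    ko <- accum(0, t_grid[j])
    for (i in seq_along(p_grid)) {
      f <- footprint_profile(accum(p_grid[i], t_grid[j]), ko)
      obj[i, j] <- mean((f - observed_f)^2)
      fits[[i, j]] <- f
    }
  }
  best <- which(obj == min(obj), arr.ind = TRUE)
  best <- best[order(best[, 1L]), , drop = FALSE][1L, ]
  i <- best[1L]; j <- best[2L]
  p_ref <- p_grid[i]
  if (refine && i > 1L && i < length(p_grid)) {
    y <- obj[(i - 1L):(i + 1L), j]
    x <- p_grid[(i - 1L):(i + 1L)]
    denom <- (y[1L] - 2 * y[2L] + y[3L])
    if (is.finite(denom) && denom > 0)
      p_ref <- x[2L] - (x[3L] - x[1L]) / 4 * (y[3L] - y[1L]) / denom
  }
  structure(list(p_hat = p_grid[i], t_hat = t_grid[j], p_refined = p_ref,
                 objective = obj, fitted = fits[[i, j]],
                 observed = observed_f,
                 p_grid = p_grid, t_grid = t_grid),
            class = "footprint_fit")
}

#' @export
print.footprint_fit <- function(x, ...) {
  cat(sprintf("Footprint fit: p_hat = %g (refined %.4g), t_hat = %g, MSE %.3g\n",
              x$p_hat, x$p_refined, x$t_hat, min(x$objective)))
  invisible(x)
}

#' @export
coef.footprint_fit <- function(object, ...)
  c(p = object$p_refined, t = object$t_hat)

#' @export
plot.footprint_fit <- function(x, ...) {
  off <- seq_along(x$observed) - (length(x$observed) + 1L) / 2
  graphics::plot(off, x$observed, type = "l", col = "grey40",
                 xlab = "offset from mCG (bp)", ylab = "ln insertion ratio", ...)
  graphics::lines(off, x$fitted, col = "black", lwd = 2)
  invisible(x)
}

# ---- occupancy relation and accessibility ----------------------------------

#' Through-origin occupancy-vs-level relation
#'
#' Fits `p = k * M` by least squares through the origin to a panel of
#' (relative protein level, fitted occupancy) pairs.
#'
#' @param panel Data frame with columns `M` and `p_hat` (at least two
#'   distinct `M`, not all zero).
#' @return Object of class `occupancy_fit`; `coef` gives the slope `k`,
#'   `predict(fit, M)` evaluates the clipped relation.
#' @export
occupancy_relation <- function(panel) {
  M <- panel$M; p <- panel$p_hat
  if (length(unique(M)) < 2L) stop("panel needs at least two distinct M")
  if (all(M == 0)) stop("all M are zero; slope undefined")
  k <- sum(M * p) / sum(M^2)
  structure(list(k = k, panel = panel), class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Occupancy relation: p = %.4g x M (through origin, %d lines)\n",
              x$k, nrow(x$panel)))
  invisible(x)
}

#' @export
coef.occupancy_fit <- function(object, ...) c(k = object$k)

#' @export
predict.occupancy_fit <- function(object, M, ...) evaluate_occupancy(M, object$k)

#' Evaluate the linear occupancy relation
#'
#' `p = k * M`, clipped to \[0, 1\].
#'
#' @param M Relative protein level(s), >= 0.
#' @param k Through-origin slope.
#' @return Occupancy in \[0, 1\].
#' @export
evaluate_occupancy <- function(M, k) pmin(1, pmax(0, k * M))

#' Chromatin accessibility from insertion counts
#'
#' `n_bar` is the mean insertion count over the gene, peaks are positions
#' with `n_i > 4 * n_bar`, and accessibility is the sum of peak insertions
#' divided by `n_bar`.
#'
#' @param counts Non-negative integer vector of per-position insertion
#'   counts over a gene (non-empty, not all zero).
#' @return Object of class `accessibility_result` with fields `n_bar`,
#'   `peak_positions` (1-based indices) and `a`.
#' @export
accessibility <- function(counts) {
  if (!length(counts)) stop("counts vector is empty")
  if (any(counts < 0)) stop("counts must be non-negative")
  n_bar <- mean(counts)
  if (n_bar == 0) stop("all counts are zero; background undefined")
  peaks <- which(counts > 4 * n_bar)
  a <- if (length(peaks)) sum(counts[peaks]) / n_bar else 0
  structure(list(n_bar = n_bar, peak_positions = peaks, a = a),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat(sprintf("Accessibility: a = %.3g (%d peaks, background %.3g)\n",
              x$a, length(x$peak_positions), x$n_bar))
  invisible(x)
}
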