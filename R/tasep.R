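#' Open-boundary TASEP models of transcription elongation
#'
#' A gene is a chain of `L` lattice sites, each spanning 60 bp. RNA Pol II
#' particles enter at site 1 with initiation rate `alpha`, hop forward under
#' hard-core exclusion with rate `v = 1/s` (about 60 bp/s), and exit at site
#' `L` with rate `beta = 1/s`. Methyl-CpG protein binding is represented
#' either as static slow sites (hop rate `v_s` out of a slow site), as
#' dynamical obstacles that bind free mCG sites with rate `k_u * p` and
#' unbind with rate `k_u`, blocking Pol II while bound, or as slow-down
#' obstacles that reduce the hop rate to `v_s` instead of blocking.
#' Steady-state currents `J` predict transcription rates, and log2 current
#' ratios between cell lines predict differential expression.
#'
#' @name tasep
NULL

VARIANTS <- c(slow_sites = 0L, dynamical_obstacles = 1L, slowdown_obstacles = 2L)

#' TASEP configuration
#'
#' @param L Number of lattice sites (1 site = 60 bp).
#' @param alpha Initiation rate, 1/s.
#' @param beta Exit rate, 1/s (default 1).
#' @param v Hop rate on fast sites, 1/s (default 1).
#' @param v_s Hop rate on slow sites / through slow-down obstacles, 1/s
#'   (default 0.05).
#' @param k_u Obstacle unbinding rate, 1/s (default 0.04; binding rate is
#'   `k_u * p` per free mCG).
#' @param p Occupancy probability (slow sites) or relative obstacle density
#'   (dynamical variants), in \[0, 1\].
#' @param variant One of `"slow_sites"`, `"dynamical_obstacles"`,
#'   `"slowdown_obstacles"`.
#' @param special_sites Integer site indices in `1..L`: slow sites, or mCG
#'   sites for the obstacle variants.
#' @param mult Integer mCG multiplicity per special site (default 1); a
#'   site holding `m` mCGs collects obstacle-binding rate `k_u * p * m`.
#' @param seed Integer seed.
#' @param bp_per_site Site span in bp (default 60).
#' @return Object of class `tasep_config`.
#' @export
tasep_config <- function(L, alpha, beta = 1, v = 1, v_s = 0.05, k_u = 0.04,
                         p = 0, variant = c("slow_sites",
                                            "dynamical_obstacles",
                                            "slowdown_obstacles"),
                         special_sites = integer(0), mult = NULL,
                         seed = 1L, bp_per_site = 60) {
  variant <- match.arg(variant)
  if (L < 2) stop("L must be at least 2")
  if (any(c(alpha, beta, v, v_s, k_u) < 0)) stop("rates must be non-negative")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  special_sites <- as.integer(special_sites)
  if (length(special_sites) &&
      (min(special_sites) < 1L || max(special_sites) > L))
    stop("special_sites must lie in 1..L")
  if (anyDuplicated(special_sites)) stop("special_sites must be unique")
  if (is.null(mult)) mult <- rep(1L, length(special_sites))
  if (length(mult) != length(special_sites))
    stop("mult must match special_sites in length")
  structure(list(L = as.integer(L), alpha = alpha, beta = beta, v = v,
                 v_s = v_s, k_u = k_u, p = p, variant = variant,
                 special_sites = special_sites, mult = as.integer(mult),
                 seed = as.integer(seed), bp_per_site = bp_per_site),
            class = "tasep_config")
}

#' @export
print.tasep_config <- function(x, ...) {
  cat(sprintf("TASEP config (%s): L = %d sites (%g bp/site), alpha = %g, beta = %g\n",
              x$variant, x$L, x$bp_per_site, x$alpha, x$beta))
  cat(sprintf("  v = %g, v_s = %g, k_u = %g, p = %g, %d special sites\n",
              x$v, x$v_s, x$k_u, x$p, length(x$special_sites)))
  invisible(x)
}

#' Convert mCG density to per-site slow-site density and sample sites
#'
#' Slow sites are distributed with density `rho_s = p * rho_mCG` mCG per
#' 100 bp, converted to the per-site (60 bp) basis:
#' `rho_per_site = p * rho_mCG * bp_per_site / 100`. When `L` is given,
#' each site is independently declared special with that probability.
#'
#' @param rho_mCG mCG density per 100 bp, >= 0.
#' @param p Occupancy probability in \[0, 1\].
#' @param L Optional lattice length; when supplied, sites are sampled.
#' @param seed Integer seed used when sampling.
#' @param bp_per_site Site span in bp (default 60).
#' @return List with `rho_per_site` and (when `L` is given) `sites`.
#' @export
site_density <- function(rho_mCG, p, L = NULL, seed = 1L, bp_per_site = 60) {
  if (rho_mCG < 0 || p < 0) stop("inputs must be non-negative")
  rho_site <- p * rho_mCG * bp_per_site / 100
  if (rho_site > 1)
    stop("per-site slow-site density ", signif(rho_site, 3),
         " exceeds 1; infeasible")
  out <- list(rho_per_site = rho_site)
  if (!is.null(L)) {
    set.seed(seed)
    out$sites <- which(stats::runif(L) < rho_site)
  }
  out
}

#' Lay mCG sites out on a lattice with multiplicity
#'
#' Places `round(rho_mCG * bp_per_site / 100 * L)` mCGs uniformly over the
#' `L` sites; a site may hold several mCGs (its obstacle-binding rate
#' scales with the count).
#'
#' @inheritParams site_density
#' @param L Lattice length in sites.
#' @return List with integer vectors `sites` and `mult`.
#' @export
mcg_site_layout <- function(rho_mCG, L, seed = 1L, bp_per_site = 60) {
  if (rho_mCG < 0) stop("rho_mCG must be non-negative")
  n <- round(rho_mCG * bp_per_site / 100 * L)
  set.seed(seed)
  if (n == 0L) return(list(sites = integer(0), mult = integer(0)))
  tab <- tabulate(sample.int(L, n, replace = TRUE), L)
  sites <- which(tab > 0L)
  list(sites = sites, mult = tab[sites])
}

#' Run the TASEP engine
#'
#' Exact continuous-time (Gillespie) kinetic Monte Carlo. The current `J`
#' is estimated as exits per second after a burn-in period, with a standard
#' error from batch means.
#'
#' @param config A [tasep_config].
#' @param burn_in Burn-in time in s (default `10 * L / v`).
#' @param measure Measurement time in s (default `50 * L / v`).
#' @param n_batches Batches for the standard error (default 10).
#' @param max_particles Cap on simultaneous particles (0 = unlimited);
#'   `1` follows a single tagged particle.
#' @param kymo_dt Snapshot interval in s for a kymograph (`NULL` = none).
#' @param init_obstacles Initial obstacle state for the dynamic variants:
#'   `"equilibrium"` (each free mCG site starts bound with its stationary
#'   probability `p m / (1 + p m)`), `"none"`, or `"all"`.
#' @return Object of class `tasep_result` with current `J`, `J_stderr`,
#'   event counts, per-site time-averaged Pol II and obstacle densities,
#'   hop count and occupied time (their ratio is the mean particle speed in
#'   sites/s), completed obstacle residence statistics, and optional
#'   kymograph matrices (`kymo_pol`, `kymo_obs`; rows are snapshots).
#' @export
run_tasep <- function(config, burn_in = NULL, measure = NULL,
                      n_batches = 10L, max_particles = 0L, kymo_dt = NULL,
                      init_obstacles = c("equilibrium", "none", "all")) {
  stopifnot(inherits(config, "tasep_config"))
  init_obstacles <- match.arg(init_obstacles)
  if (is.null(burn_in)) burn_in <- 10 * config$L / config$v
  if (is.null(measure)) measure <- 50 * config$L / config$v
  if (burn_in <= 0 || measure <= 0) stop("burn_in and measure must be positive")
  set.seed(config$seed)
  res <- .tasep_engine(config$L, config$alpha, config$beta, config$v,
                       config$v_s, config$k_u, config$p,
                       VARIANTS[[config$variant]],
                       config$special_sites, config$mult,
                       burn_in, measure, as.integer(n_batches),
                       as.integer(max_particles),
                       if (is.null(kymo_dt)) 0 else kymo_dt,
                       switch(init_obstacles, none = 0L, equilibrium = 1L, all = 2L))
  res$config <- config
  res$burn_in <- burn_in
  res$measure <- measure
  class(res) <- "tasep_result"
  res
}

#' @export
print.tasep_result <- function(x, ...) {
  cat(sprintf("TASEP result (%s, L = %d): J = %.4g +/- %.2g /s\n",
              x$config$variant, x$config$L, x$J,
              ifelse(is.na(x$J_stderr), NaN, x$J_stderr)))
  cat(sprintf("  entries %g, exits %g, mean density %.3g\n",
              x$entries, x$exits, mean(x$density)))
  if (!is.na(x$residence_mean))
    cat(sprintf("  obstacle residence: %.3g s over %g unbinding events\n",
                x$residence_mean, x$residence_n))
  invisible(x)
}

#' @export
plot.tasep_result <- function(x, what = c("kymograph", "density"), ...) {
  what <- match.arg(what)
  if (what == "kymograph") {
    if (is.null(x$kymo_pol)) stop("run with kymo_dt set to record a kymograph")
    z <- x$kymo_pol
    if (!is.null(x$kymo_obs)) z <- z + 2L * x$kymo_obs
    graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = t(z),
                    col = c("white", "grey20", "red", "purple"),
                    xlab = "site", ylab = "snapshot (time)", ...)
  } else {
    graphics::plot(seq_along(x$density), x$density, type = "l",
                   xlab = "site", ylab = "mean Pol II density", ...)
  }
  invisible(x)
}

#' Scan the current as a function of the initiation rate
#'
#' @param config A [tasep_config] (its `alpha` is ignored).
#' @param alpha_grid Initiation rates to scan.
#' @param ... Passed to [run_tasep].
#' @return Data frame with `alpha`, `J`, `J_stderr`.
#' @export
tasep_scan <- function(config, alpha_grid, ...) {
  rows <- lapply(seq_along(alpha_grid), function(i) {
    cfg <- config
    cfg$alpha <- alpha_grid[i]
    cfg$seed <- config$seed + i
    r <- run_tasep(cfg, ...)
    data.frame(alpha = alpha_grid[i], J = r$J, J_stderr = r$J_stderr)
  })
  do.call(rbind, rows)
}

engine_layout <- function(variant, rho_mCG, p, L, seed, bp_per_site = 60) {
  if (variant == "slow_sites") {
    sd <- site_density(rho_mCG, p, L = L, seed = seed, bp_per_site = bp_per_site)
    list(sites = sd$sites, mult = rep(1L, length(sd$sites)))
  } else {
    mcg_site_layout(rho_mCG, L, seed = seed, bp_per_site = bp_per_site)
  }
}

run_current <- function(variant, rho_mCG, p, alpha, L, seed, v_s = 0.05,
                        k_u = 0.04, beta = 1, v = 1, ...) {
  lay <- engine_layout(variant, rho_mCG, p, L, seed)
  cfg <- tasep_config(L, alpha, beta = beta, v = v, v_s = v_s, k_u = k_u,
                      p = if (variant == "slow_sites") 0 else p,
                      variant = variant, special_sites = lay$sites,
                      mult = lay$mult, seed = seed + 1L)
  run_tasep(cfg, ...)$J
}

#' Predict differential expression from TASEP currents
#'
#' `Log2FC_X/Y = log2( J(alpha, rho_s_X) / J(alpha, rho_s_Y) )`, where the
#' two lines share the gene geometry (length and, for the obstacle
#' variants, the mCG layout) and differ only in occupancy/obstacle density.
#' Currents are averaged over `n_rep` replicate simulations with distinct
#' seeds; within a replicate the two lines share the random-number seed, so
#' `rho_mCG = 0` or `p_X = p_Y` gives exactly 0.
#'
#' @param alpha Initiation rate, 1/s.
#' @param rho_mCG Gene-body mCG density per 100 bp.
#' @param p_X,p_Y Occupancy (slow sites) or relative obstacle density
#'   (dynamic variants) for the two lines.
#' @param variant Engine variant, see [tasep_config].
#' @param L Lattice length in sites (default 150, about a 9-kb gene).
#' @param n_rep Replicate gene realizations averaged (default 6; the mCG
#'   layout is quenched disorder, so averaging over layouts, not longer
#'   runs, controls the Log2FC error).
#' @param seed Integer seed.
#' @param ... Further engine settings passed to [run_current] /
#'   [run_tasep] (`v_s`, `k_u`, `burn_in`, `measure`, ...).
#' @return Log2 fold change (scalar).
#' @export
predict_log2fc <- function(alpha, rho_mCG, p_X, p_Y,
                           variant = "dynamical_obstacles", L = 150L,
                           n_rep = 6L, seed = 1L, ...) {
  jx <- jy <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- seed + 1000L * r
    jx[r] <- run_current(variant, rho_mCG, p_X, alpha, L, seed = s, ...)
    jy[r] <- run_current(variant, rho_mCG, p_Y, alpha, L, seed = s, ...)
  }
  if (mean(jy) <= 0) stop("reference current is zero; Log2FC undefined")
  if (mean(jx) <= 0) stop("current is zero for the X line; Log2FC undefined")
  log2(mean(jx) / mean(jy))
}

#' Fit per-bin initiation rates to a reference Log2FC curve
#'
#' For every mCG-density bin of a reference (training) line pair, the
#' initiation rate `alpha` is chosen on a grid to minimize the squared
#' deviation between the TASEP-predicted and observed Log2FC. The fitted
#' rates are reusable, via [predict.tasep_fit], to predict any other line
#' pair without refitting. A bin is flagged non-identifiable when the
#' predicted Log2FC varies less across the grid than twice its Monte Carlo
#' error.
#'
#' @param reference Data frame with columns `rho` (bin mCG density) and
#'   `log2fc` (observed value per bin).
#' @param p_X,p_Y Densities of the training pair.
#' @param alpha_grid Candidate initiation rates.
#' @param variant Engine variant.
#' @param L Representative lattice length in sites.
#' @param n_rep Replicate gene realizations per current evaluation
#'   (default 6).
#' @param seed Integer seed.
#' @param ... Engine settings passed through.
#' @return Object of class `tasep_fit`: per-bin `alpha_hat`, objective and
#'   identifiability flag.
#' @export
fit_initiation <- function(reference, p_X, p_Y,
                           alpha_grid = c(0.01, 0.02, 0.04, 0.06, 0.1, 0.2),
                           variant = "dynamical_obstacles", L = 150L,
                           n_rep = 6L, seed = 1L, ...) {
  if (!length(alpha_grid)) stop("alpha_grid must be non-empty")
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    rho <- reference$rho[i]
    obs <- reference$log2fc[i]
    pred <- vapply(seq_along(alpha_grid), function(k) {
      predict_log2fc(alpha_grid[k], rho, p_X, p_Y, variant = variant, L = L,
                     n_rep = n_rep, seed = seed + 17L * i + k, ...)
    }, numeric(1))
    objective <- (pred - obs)^2
    best <- which.min(objective)
    # MC error of a prediction: repeat the best point once with a new seed
    pred2 <- predict_log2fc(alpha_grid[best], rho, p_X, p_Y, variant = variant,
                            L = L, n_rep = n_rep, seed = seed + 8191L + i, ...)
    mc_err <- abs(pred2 - pred[best]) / sqrt(2)
    data.frame(rho = rho, alpha_hat = alpha_grid[best],
               objective = objective[best],
               identifiable = diff(range(pred)) > 2 * mc_err)
  })
  structure(list(bins = do.call(rbind, rows), alpha_grid = alpha_grid,
                 variant = variant, L = L, n_rep = n_rep, seed = seed,
                 p_train = c(X = p_X, Y = p_Y), engine_args = list(...)),
            class = "tasep_fit")
}

#' @export
print.tasep_fit <- function(x, ...) {
  cat(sprintf("TASEP initiation-rate fit (%s): %d bins, alpha grid [%g, %g]\n",
              x$variant, nrow(x$bins), min(x$alpha_grid), max(x$alpha_grid)))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Predict Log2FC for a new line pair from fitted initiation rates
#'
#' @param object A `tasep_fit`.
#' @param p_X,p_Y Densities of the pair to predict.
#' @param seed Integer seed (default: the fit's seed plus one).
#' @param ... Ignored.
#' @return Data frame with `rho` and predicted `log2fc` per bin.
#' @export
predict.tasep_fit <- function(object, p_X, p_Y, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed + 1L
  pred <- vapply(seq_len(nrow(object$bins)), function(i) {
    do.call(predict_log2fc,
            c(list(alpha = object$bins$alpha_hat[i], rho_mCG = object$bins$rho[i],
                   p_X = p_X, p_Y = p_Y, variant = object$variant,
                   L = object$L, n_rep = object$n_rep,
                   seed = seed + 31L * i),
              object$engine_args))
  }, numeric(1))
  data.frame(rho = object$bins$rho, log2fc = pred)
}
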