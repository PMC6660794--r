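test_that("methylation calls follow the 100%-of-reads, coverage >= 5 rule", {
  expect_equal(call_methylation(5, 5), "methylated")
  expect_equal(call_methylation(4, 4), "ambiguous")
  expect_equal(call_methylation(12, 0), "unmethylated")
  expect_equal(call_methylation(c(10, 7, 0, 6), c(10, 3, 0, 0)),
               c("methylated", "ambiguous", "ambiguous", "unmethylated"))
  expect_error(call_methylation(3, 5), "exceed")
  expect_error(call_methylation(-1, 0), "non-negative")
})

test_that("binding is Bernoulli per site with motif affinity", {
  g <- fixture_methylated(length_bp = 5e5, cg_density = 2)
  m <- g$methylome
  expect_length(simulate_binding(m, 0), 0)
  expect_identical(simulate_binding(m, 1), mcg_positions(m))
  b <- simulate_binding(m, 0.3, seed = 5)
  n <- length(mcg_positions(m))
  expect_lt(abs(length(b) / n - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # unmethylated CGs have zero affinity by default
  g0 <- fixture_genome(length_bp = 5000, meth_frac = 0)
  expect_length(simulate_binding(g0$methylome, 1), 0)
  expect_error(simulate_binding(m, 1, affinities = c(mCG = 0.5, CG = 0.9)),
               "maximum")
})

test_that("ChIP library retention follows the bound/background rule", {
  params <- chip_sim_params(p_bg = 1)
  fr <- simulate_chip_library(10000, integer(0), params, 500, seed = 1)
  expect_equal(nrow(fr), 500)                      # input library: keep all
  params0 <- chip_sim_params(p_bg = 0)
  fr0 <- simulate_chip_library(10000, integer(0), params0, 500, seed = 1)
  expect_equal(nrow(fr0), 0)
  # single bound site, p_bg = 0, fixed length F: retained iff covering
  F <- 200L
  pf <- chip_sim_params(p_bg = 0, frag_mean = F, frag_sd = 0, frag_min = F)
  fr1 <- simulate_chip_library(100000, 50000L, pf, 20000, seed = 2)
  expect_true(all(fr1$start <= 50000 & fr1$end > 50000))
  frac <- nrow(fr1) / 20000
  expect_lt(abs(frac - F / 100000), 3 * sqrt((F / 1e5) * (1 - F / 1e5) / 20000))
})

test_that("profile accumulation matches hand-built examples", {
  # one anchor at 100, one fragment [98, 103): covers offsets -2..2
  p <- profile_counts(data.frame(start = 98L, end = 103L), anchors = 100L,
                      sequence_length = 300L, mode = "overlap", radius = 10L)
  expect_equal(unname(p$counts[as.character(-10:10)]),
               c(rep(0, 8), rep(1, 5), rep(0, 8)))
  # insertion mode: one endpoint at offset -7
  pi1 <- profile_counts(93L, anchors = 100L, sequence_length = 300L,
                        mode = "insertion", radius = 10L)
  expect_equal(sum(pi1$counts), 1)
  expect_equal(unname(pi1$counts["-7"]), 1)
  # additivity over anchors with identical local data
  frs <- data.frame(start = c(98L, 198L), end = c(103L, 203L))
  p2 <- profile_counts(frs, anchors = c(100L, 200L), sequence_length = 400L,
                       mode = "overlap", radius = 10L)
  expect_equal(sum(p2$counts), 2 * sum(p$counts))
  # anchors too close to an end are skipped
  p3 <- profile_counts(frs, anchors = c(5L, 100L), sequence_length = 400L,
                       mode = "overlap", radius = 10L)
  expect_equal(p3$n_anchors, 1L)
  expect_error(profile_counts(frs, integer(0), 400L), "empty")
})

test_that("flank normalization fixes the flank mean at one", {
  const <- counts_profile(rep(10, 1001), 500, "overlap")
  expect_equal(unname(normalize_flanks(const)), rep(1, 1001))
  ins <- counts_profile(rep(3, 201), 100, "insertion")
  expect_equal(unname(normalize_flanks(ins)), rep(1, 201))
  # flank mean 4, centre 2 -> centre value 0.5
  v <- rep(4, 201); v[101] <- 2
  pr <- counts_profile(v, 100, "insertion")
  nv <- normalize_flanks(pr)
  expect_equal(unname(nv["0"]), 0.5)
  fl <- c(seq(-50, -41), seq(41, 50)) + 101
  expect_equal(mean(nv[fl]), 1)
  expect_error(normalize_flanks(counts_profile(c(rep(0, 100), 5, rep(0, 100)),
                                               100, "insertion")),
               "zero")
})

test_that("enrichment and footprint profiles follow their defining ratios", {
  chip <- counts_profile(rep(7, 1001), 500, "overlap")
  expect_equal(unname(enrichment_profile(chip, chip)), rep(0, 1001))
  v <- rep(1, 1001); v[501] <- 3
  expect_equal(unname(enrichment_profile(counts_profile(v, 500, "overlap"),
                                         counts_profile(rep(1, 1001), 500,
                                                        "overlap"))["0"]),
               3 / 1 - 1, tolerance = 0.02)
  cell <- rep(1, 201); cell[101] <- 0.5
  f <- footprint_profile(counts_profile(cell * 20, 100, "insertion"),
                         counts_profile(rep(20, 201), 100, "insertion"))
  expect_equal(unname(f["0"]), log(0.5), tolerance = 0.02)
  expect_warning(
    footprint_profile(counts_profile(c(rep(5, 100), 0, rep(5, 100)), 100,
                                     "insertion"),
                      counts_profile(rep(5, 201), 100, "insertion")),
    "pseudo")
})

test_that("Tn5 insertions avoid the 11-bp footprint of bound proteins", {
  g <- fixture_methylated(length_bp = 20000, cg_density = 1)
  m <- g$methylome
  bound <- mcg_positions(m)
  params <- atac_sim_params(t = 0.3, b = 1)
  ins <- simulate_atac(20000, bound, params, seed = 8)
  off <- outer(ins, bound, "-")
  expect_false(any(abs(off) <= 5))
  # accumulated profile: exactly 11 central zero positions
  prof <- NULL
  for (s in 1:10) {
    p <- profile_counts(simulate_atac(20000, bound, params, seed = s),
                        bound, 20000, "insertion", 100L)
    prof <- if (is.null(prof)) p else prof + p
  }
  zero_run <- prof$counts == 0
  expect_true(all(zero_run[as.character(-5:5)]))
  expect_equal(sum(zero_run), 11)
})

test_that("unbound insertion counts are uniform within Poisson error", {
  ins <- simulate_atac(50000, integer(0), atac_sim_params(t = 0.4, b = 1),
                       seed = 9)
  counts <- tabulate(ins + 1L, 50000)
  expect_lt(abs(mean(counts) - 0.4), 3 * sqrt(0.4 / 50000))
  # chunked counts consistent with Poisson dispersion
  chunks <- colSums(matrix(counts, nrow = 500))
  expect_lt(abs(var(chunks) / mean(chunks) - 1), 0.25)
})

test_that("GC bias tilts insertions toward GC-rich positions", {
  g <- fixture_methylated(length_bp = 50000, cg_density = 1)
  w <- tn5_weights(g$sequence, b = 6)
  expect_length(w, 50000)
  ins <- simulate_atac(50000, integer(0), atac_sim_params(t = 0.5, b = 6),
                       seed = 10, weights = w)
  hi <- w > stats::median(w)
  counts <- tabulate(ins + 1L, 50000)
  expect_gt(mean(counts[hi]), mean(counts[!hi]))
})

test_that("accessibility implements the peak-over-background ratio", {
  r <- accessibility(c(rep(1, 9), 11))
  expect_equal(r$n_bar, 2)
  expect_equal(r$peak_positions, 10L)
  expect_equal(r$a, 5.5)
  expect_equal(accessibility(rep(4, 50))$a, 0)
  expect_equal(accessibility(10 * c(rep(1, 9), 11))$a, 5.5)  # scale invariant
  expect_error(accessibility(rep(0, 10)), "zero")
  expect_error(accessibility(integer(0)), "empty")
})

test_that("the occupancy relation is a through-origin line with clipping", {
  expect_equal(evaluate_occupancy(1, 0.0058), 0.0058)
  expect_equal(evaluate_occupancy(11, 0.0058), 0.0638)
  expect_equal(evaluate_occupancy(0, 0.7), 0)
  expect_equal(evaluate_occupancy(1000, 0.0058), 1)
  fit <- occupancy_relation(data.frame(M = c(0, 1, 4, 11),
                                       p_hat = 0.0058 * c(0, 1, 4, 11)))
  expect_equal(unname(coef(fit)), 0.0058, tolerance = 1e-12)
  expect_equal(predict(fit, 2), 0.0116)
  expect_error(occupancy_relation(data.frame(M = c(0, 0), p_hat = c(0, 0))),
               "distinct|zero")
})

test_that("footprint fitting recovers a strong generating occupancy", {
  g <- fixture_methylated(length_bp = 30000, cg_density = 2)
  m <- g$methylome
  w <- tn5_weights(g$sequence, 6)
  ctx <- list(sequence_length = 30000, methylome = m, weights = w, seed = 100)
  gen_footprint <- function(p, n_rep, seed0) {
    pars <- atac_sim_params(t = 0.4, b = 6)
    cellp <- kop <- NULL
    for (s in seed0 + seq_len(n_rep)) {
      b <- simulate_binding(m, p, seed = s)
      cp <- profile_counts(simulate_atac(30000, b, pars, s + 1, weights = w),
                           mcg_positions(m), 30000, "insertion", 100L)
      kp <- profile_counts(simulate_atac(30000, integer(0), pars, s + 2,
                                         weights = w),
                           mcg_positions(m), 30000, "insertion", 100L)
      cellp <- if (is.null(cellp)) cp else cellp + cp
      kop <- if (is.null(kop)) kp else kop + kp
    }
    footprint_profile(cellp, kop)
  }
  obs <- gen_footprint(0.3, 30, 5000)
  fit <- fit_footprint(obs, ctx, p_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                       t_grid = 0.4, n_rep = 10)
  expect_equal(fit$p_hat, 0.3)
  # null data prefer p = 0
  obs0 <- gen_footprint(0, 10, 9000)
  fit0 <- fit_footprint(obs0, ctx, p_grid = c(0, 0.1, 0.2, 0.4), t_grid = 0.4,
                        n_rep = 5)
  expect_equal(fit0$p_hat, 0)
})

test_that("fitted occupancy rises with protein level across a panel", {
  g <- fixture_methylated(length_bp = 30000, cg_density = 2)
  m <- g$methylome
  w <- tn5_weights(g$sequence, 6)
  pars <- atac_sim_params(t = 0.4, b = 6)
  anchors <- mcg_positions(m)
  depth_for <- function(p, seed0) {
    cellp <- kop <- NULL
    for (s in seed0 + 1:15) {
      b <- simulate_binding(m, p, seed = s)
      cp <- profile_counts(simulate_atac(30000, b, pars, s + 50, weights = w),
                           anchors, 30000, "insertion", 100L)
      kp <- profile_counts(simulate_atac(30000, integer(0), pars, s + 80,
                                         weights = w),
                           anchors, 30000, "insertion", 100L)
      cellp <- if (is.null(cellp)) cp else cellp + cp
      kop <- if (is.null(kop)) kp else kop + kp
    }
    footprint_profile(cellp, kop)
  }
  ctx <- list(sequence_length = 30000, methylome = m, weights = w, seed = 1)
  Ms <- c(0.5, 2, 4, 11)
  p_true <- 0.05 * Ms
  p_hat <- vapply(seq_along(Ms), function(i) {
    fit_footprint(depth_for(p_true[i], 300 * i),
                  ctx, p_grid = seq(0, 0.7, by = 0.05), t_grid = 0.4,
                  n_rep = 8, refine = TRUE)$p_refined
  }, numeric(1))
  expect_true(all(diff(p_hat) > 0))
  fit <- occupancy_relation(data.frame(M = Ms, p_hat = p_hat))
  expect_gt(coef(fit)[["k"]], 0)
  expect_equal(coef(fit)[["k"]], 0.05, tolerance = 0.2)
})

test_that("ChIP model fitting recovers generating parameters on its grid", {
  g <- fixture_methylated(length_bp = 30000, cg_density = 2)
  m <- g$methylome
  ctx <- list(sequence_length = 30000, methylome = m,
              params = chip_sim_params(p_bg = 0.5), n_fragments = 6000,
              radius = 500L, seed = 77)
  gen <- function(p, p_bg, seeds) {
    pars <- chip_sim_params(p_bg = p_bg)
    anchors <- mcg_positions(m)
    chip <- input <- NULL
    for (s in seeds) {
      b <- simulate_binding(m, p, seed = s)
      cfr <- simulate_chip_library(30000, b, pars, 6000, seed = s + 1)
      ifr <- simulate_chip_library(30000, integer(0),
                                   chip_sim_params(p_bg = 1), 6000,
                                   seed = s + 2)
      cp <- profile_counts(cfr, anchors, 30000, "overlap", 500L)
      ip <- profile_counts(ifr, anchors, 30000, "overlap", 500L)
      chip <- if (is.null(chip)) cp else chip + cp
      input <- if (is.null(input)) ip else input + ip
    }
    enrichment_profile(chip, input)
  }
  obs <- gen(0.2, 0.5, 40000 + 1:4)
  fit <- fit_chip_model(obs, ctx, p_grid = c(0, 0.05, 0.2, 0.5),
                        pbg_grid = c(0.25, 0.5, 1), n_rep = 2)
  expect_equal(fit$p_hat, 0.2)
  expect_equal(fit$pbg_hat, 0.5)
  expect_true(nrow(fit$near_optimal) >= 1)
  # null observed profile prefers p = 0
  fit0 <- fit_chip_model(rep(0, 1001), ctx, p_grid = c(0, 0.2),
                         pbg_grid = c(0.5, 1), n_rep = 1)
  expect_equal(fit0$p_hat, 0)
})

test_that("ChIP enrichment peaks at bound mCGs and is flat under the null", {
  g <- generate_genome(50000, cg_density = 0.5, meth_frac = 1, seed = 42)
  m <- g$methylome
  anchors <- mcg_positions(m)
  gen <- function(p, p_bg, seeds) {
    chip <- input <- NULL
    for (s in seeds) {
      b <- simulate_binding(m, p, seed = s)
      cfr <- simulate_chip_library(50000, b, chip_sim_params(p_bg = p_bg),
                                   20000, seed = s + 1)
      ifr <- simulate_chip_library(50000, integer(0),
                                   chip_sim_params(p_bg = 1), 20000,
                                   seed = s + 2)
      cp <- profile_counts(cfr, anchors, 50000, "overlap", 500L)
      ip <- profile_counts(ifr, anchors, 50000, "overlap", 500L)
      chip <- if (is.null(chip)) cp else chip + cp
      input <- if (is.null(input)) ip else input + ip
    }
    enrichment_profile(chip, input)
  }
  f <- gen(1, 0.1, 1:6)
  expect_gt(mean(f[as.character(-20:20)]),
            mean(f[c(1:100, 902:1001)]) + 0.2)
  # null assay (p = 0 against its own input) is statistically flat
  f0 <- gen(0, 1, 11:16)
  expect_lt(abs(mean(f0)), 3 * stats::sd(f0) / sqrt(sum(!is.na(f0))) + 0.01)
})
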