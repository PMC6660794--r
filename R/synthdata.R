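#' Synthetic genomes, methylomes and gene panels
#'
#' The generators in this file produce desk-scale stand-ins for the inputs a
#' methylome-aware transcription study needs: a random sequence with CG
#' dinucleotides placed at a controlled density, a per-CG methylation map
#' with bisulfite-style read calls, a panel of gene models spanning a grid of
#' gene-body mCG densities, and a panel of cell lines with graded levels of a
#' methyl-CpG binding protein.
#'
#' All coordinates are 0-based, half-open. An mCG is anchored at the position
#' of its C on the forward strand; methylation is treated as symmetric at CG
#' so only the forward-strand C is recorded.
#'
#' @name synthdata
NULL

#' Construct a methylome map
#'
#' A methylome map records the CG dinucleotide positions of a sequence, the
#' methylation state of each CG, and (once read calls have been simulated)
#' the per-site read coverage and methylated-read counts.
#'
#' @param sequence_length Sequence length in bp.
#' @param cg_positions Strictly increasing 0-based positions of the C of each
#'   CG dinucleotide.
#' @param meth_state Logical, `TRUE` for methylated sites.
#' @param coverage Integer per-site read coverage (`NA` until calls are
#'   simulated).
#' @param meth_reads Integer methylated-read counts, `meth_reads <= coverage`.
#' @return An object of class `methylome`.
#' @export
methylome <- function(sequence_length, cg_positions, meth_state,
                      coverage = NA_integer_, meth_reads = NA_integer_) {
  cg_positions <- as.integer(cg_positions)
  n <- length(cg_positions)
  if (n > 1L && any(diff(cg_positions) <= 0L))
    stop("cg_positions must be strictly increasing")
  if (n > 0L && (cg_positions[1L] < 0L || cg_positions[n] > sequence_length - 2L))
    stop("cg_positions out of range for sequence_length")
  meth_state <- as.logical(meth_state)
  if (length(meth_state) != n)
    stop("meth_state must have one entry per CG position")
  coverage <- rep_len(as.integer(coverage), n)
  meth_reads <- rep_len(as.integer(meth_reads), n)
  ok <- !is.na(coverage) & !is.na(meth_reads)
  if (any(coverage[ok] < 0L) || any(meth_reads[ok] < 0L))
    stop("coverage and meth_reads must be non-negative")
  if (any(meth_reads[ok] > coverage[ok]))
    stop("meth_reads must not exceed coverage")
  structure(list(sequence_length = as.integer(sequence_length),
                 cg_positions = cg_positions,
                 meth_state = meth_state,
                 coverage = coverage,
                 meth_reads = meth_reads),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  n <- length(x$cg_positions)
  cat("Methylome map:", x$sequence_length, "bp,", n, "CG sites,",
      sum(x$meth_state), "methylated\n")
  if (n > 0L && !all(is.na(x$coverage)))
    cat("  mean coverage:", round(mean(x$coverage, na.rm = TRUE), 2), "\n")
  invisible(x)
}

#' mCG positions of a methylome
#'
#' @param m A `methylome`.
#' @return Integer vector of 0-based positions of methylated CGs.
#' @export
mcg_positions <- function(m) {
  stopifnot(inherits(m, "methylome"))
  m$cg_positions[m$meth_state]
}

#' Generate a random genome with a controlled CG density
#'
#' Draws a random sequence with the requested GC content, then places the
#' requested number of CG dinucleotides at uniformly random, non-overlapping
#' positions. Background bases that happen to spell an extra CG are mutated
#' (C to T) so that the emitted methylome enumerates every CG in the
#' sequence. Each placed CG is methylated independently with probability
#' `meth_frac`.
#'
#' @param length_bp Sequence length, at least 200 bp.
#' @param gc_frac Background GC fraction in (0, 1).
#' @param cg_density Target CG dinucleotides per 100 bp.
#' @param meth_frac Per-CG methylation probability in \[0, 1\].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements `sequence` (character scalar) and
#'   `methylome` (a [methylome] with `coverage`/`meth_reads` unset).
#' @export
generate_genome <- function(length_bp, gc_frac = 0.41, cg_density = 2,
                            meth_frac = 0.8, seed = 1L) {
  if (length_bp < 200) stop("length_bp must be at least 200")
  if (gc_frac <= 0 || gc_frac >= 1) stop("gc_frac must be in (0, 1)")
  if (meth_frac < 0 || meth_frac > 1) stop("meth_frac must be in [0, 1]")
  n_cg <- round(cg_density * length_bp / 100)
  if (n_cg < 1) stop("cg_density too low: fewer than one CG requested")
  if (2L * n_cg > length_bp - 1L)
    stop("cg_density infeasible: cannot place ", n_cg,
         " non-overlapping CG dinucleotides in ", length_bp, " bp")
  set.seed(seed)
  # positions of the C (1-based for now), pairwise gaps >= 2
  pos <- sort(sample.int(length_bp - 1L - (n_cg - 1L), n_cg)) + 0:(n_cg - 1L)
  base_p <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2,
              G = gc_frac / 2, T = (1 - gc_frac) / 2)
  seq_chr <- sample(names(base_p), length_bp, replace = TRUE, prob = base_p)
  seq_chr[pos] <- "C"
  seq_chr[pos + 1L] <- "G"
  # remove accidental CGs outside the placed set
  is_c <- seq_chr == "C"
  cg_all <- which(is_c[-length_bp] & seq_chr[-1L] == "G")
  stray <- setdiff(cg_all, pos)
  if (length(stray)) seq_chr[stray] <- "T"
  meth <- stats::runif(n_cg) < meth_frac
  list(sequence = paste(seq_chr, collapse = ""),
       methylome = methylome(length_bp, pos - 1L, meth))
}

#' Generate a panel of gene models over a grid of mCG densities
#'
#' Genes are laid out end to end on a virtual contig, separated by their
#' promoter windows. Each gene is assigned a target gene-body mCG density
#' from `rho_grid` (cycled), its body length is drawn from a log-normal
#' distribution (truncated below at `min_len`), and mCG positions are placed
#' uniformly at random (pairwise gaps of at least 2 bp) inside the body.
#' `n_mcg` and `rho_mcg` are recomputed from the placed positions, so the
#' identity `rho_mcg = 100 * n_mcg / length` holds exactly.
#'
#' @param n_genes Number of genes, at least 1.
#' @param length_meanlog,length_sdlog Log-normal parameters of the body
#'   length in bp (defaults give a median near 10 kb).
#' @param rho_grid Target mCG densities (per 100 bp), recycled over genes.
#' @param min_len Minimum body length in bp (default 1000).
#' @param promoter_bp Promoter window upstream of the TSS (default 2000 bp).
#' @param seed Integer seed.
#' @return A `data.frame` of class `gene_panel` with columns `id`, `tss`,
#'   `tes`, `length`, `promoter_start`, `promoter_end`, `n_mcg`, `rho_mcg`
#'   and a list column `mcg_pos` of absolute 0-based mCG positions.
#' @export
generate_gene_panel <- function(n_genes, length_meanlog = log(10000),
                                length_sdlog = 0.5,
                                rho_grid = c(0.5, 1, 2, 4),
                                min_len = 1000, promoter_bp = 2000,
                                seed = 1L) {
  if (n_genes < 1) stop("n_genes must be at least 1")
  if (any(rho_grid < 0)) stop("rho_grid targets must be non-negative")
  set.seed(seed)
  L <- pmax(min_len, round(stats::rlnorm(n_genes, length_meanlog, length_sdlog)))
  rho_t <- rep_len(rho_grid, n_genes)
  tss <- integer(n_genes)
  cur <- 0L
  mcg_pos <- vector("list", n_genes)
  n_mcg <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    tss[i] <- cur + as.integer(promoter_bp)
    k <- round(rho_t[i] * L[i] / 100)
    if (2L * k > L[i]) stop("target rho_mCG infeasible for gene length ", L[i])
    if (k > 0L) {
      rel <- sort(sample.int(L[i] - 1L - (k - 1L), k)) + 0:(k - 1L)
      mcg_pos[[i]] <- tss[i] + rel - 1L
    } else {
      mcg_pos[[i]] <- integer(0)
    }
    n_mcg[i] <- k
    cur <- tss[i] + L[i]
  }
  out <- data.frame(id = sprintf("gene%04d", seq_len(n_genes)),
                    tss = tss, tes = tss + L, length = L,
                    promoter_start = tss - as.integer(promoter_bp),
                    promoter_end = tss,
                    n_mcg = n_mcg,
                    rho_mcg = 100 * n_mcg / L,
                    stringsAsFactors = FALSE)
  out$mcg_pos <- mcg_pos
  class(out) <- c("gene_panel", "data.frame")
  out
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", nrow(x), "genes, body length",
      min(x$length), "-", max(x$length), "bp, rho_mCG",
      round(min(x$rho_mcg), 2), "-", round(max(x$rho_mcg), 2), "per 100 bp\n")
  print.data.frame(utils::head(as.data.frame(x[setdiff(names(x), "mcg_pos")]), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more genes\n")
  invisible(x)
}

#' Simulate bisulfite-style read calls over a methylome
#'
#' Per-site coverage is drawn from a Poisson distribution with the stated
#' mean; methylated-read counts are binomial given the true state, with a
#' symmetric per-read error rate (a methylated site yields an unmethylated
#' call, and vice versa, with probability `error_rate`).
#'
#' @param m A [methylome].
#' @param mean_coverage Mean per-site coverage, > 0.
#' @param error_rate Per-read call error in \[0, 0.5).
#' @param seed Integer seed.
#' @return The methylome with `coverage` and `meth_reads` filled in.
#' @export
simulate_read_calls <- function(m, mean_coverage = 30, error_rate = 0,
                                seed = 1L) {
  stopifnot(inherits(m, "methylome"))
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  set.seed(seed)
  n <- length(m$cg_positions)
  cov <- stats::rpois(n, mean_coverage)
  pr <- ifelse(m$meth_state, 1 - error_rate, error_rate)
  m$coverage <- cov
  m$meth_reads <- stats::rbinom(n, cov, pr)
  m
}

#' Construct a cell-line panel
#'
#' Each line carries a relative protein level `M` (wild type = 1) and,
#' optionally, the fraction `p_occ` of mCG sites it occupies. `M = 0`
#' forces `p_occ = 0`.
#'
#' @param name Character line names.
#' @param M Non-negative relative protein levels; exactly one entry must be 1
#'   (the wild-type reference).
#' @param p_occ Optional occupancies in \[0, 1\].
#' @return A `data.frame` of class `cell_panel`.
#' @export
cell_panel <- function(name, M, p_occ = NULL) {
  if (any(M < 0)) stop("M must be non-negative")
  if (is.null(p_occ)) p_occ <- rep(NA_real_, length(M))
  p_occ[M == 0] <- 0
  ok <- !is.na(p_occ)
  if (any(p_occ[ok] < 0 | p_occ[ok] > 1)) stop("p_occ must be in [0, 1]")
  out <- data.frame(name = as.character(name), M = as.numeric(M),
                    p_occ = as.numeric(p_occ), stringsAsFactors = FALSE)
  class(out) <- c("cell_panel", "data.frame")
  out
}

#' Default seven-level cell-line panel
#'
#' Emulates a knockout, two knockdowns, wild type and three overexpression
#' lines (up to 11-fold), the spread of protein levels the mechanistic
#' models are discriminated over.
#'
#' @return A [cell_panel].
#' @export
default_cell_panel <- function() {
  cell_panel(name = c("KO", "KD30", "KD60", "WT", "OE2", "OE4", "OE11"),
             M = c(0, 0.3, 0.6, 1, 2, 4, 11))
}
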