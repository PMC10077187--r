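# SparCC: compositionally robust correlation inference.
#
# Marker-gene counts only carry relative information, so naive Pearson
# correlations between relative abundances are confounded by the closure.
# SparCC works from the variation matrix t_ij = var(log(x_i/x_j)), which is
# invariant to per-sample scaling, and solves a sparse linear approximation
# for latent "basis" variances w_i^2, from which correlations follow as
#   rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j).
# Strongly correlated pairs violate the sparsity assumption and are excluded
# iteratively from the basis system.

.OMEGA_EPS <- 1e-10  # floor for basis variances; keeps omegas positive

#' Log-ratio variation matrix
#'
#' @param fractions strictly positive matrix of relative abundances,
#'   OTUs x samples.
#' @return Symmetric matrix `t` with `t[i, j] = var(log(x_i / x_j))` over
#'   samples and a zero diagonal.
#' @export
log_ratio_variances <- function(fractions) {
  if (ncol(fractions) < 3L) stopf("need at least 3 samples")
  if (any(fractions <= 0)) stopf("fractions must be strictly positive")
  lg <- log(fractions)
  cv <- stats::cov(t(lg))                       # OTU x OTU covariance
  v <- diag(cv)
  t_mat <- outer(v, v, "+") - 2 * cv
  t_mat <- (t_mat + t(t_mat)) / 2
  diag(t_mat) <- 0
  t_mat[t_mat < 0] <- 0                          # numerical noise
  t_mat
}

#' Solve the SparCC basis-variance system
#'
#' Under sparsity of true correlations, summing the variation matrix over the
#' active partners of OTU i gives `t_i = (p - 2) w_i^2 + sum_j w_j^2`. With
#' all pairs active this is the linear system `M w^2 = t` with
#' `M = 1 1' + (p - 2) I`; excluding a pair removes its contribution from both
#' rows of the system.
#'
#' @param t_mat variation matrix from [log_ratio_variances()].
#' @param excluded two-column integer matrix of excluded pairs (may be
#'   `NULL`).
#' @return Vector of basis standard deviations `omega` (negative solutions
#'   floored at a small positive epsilon).
#' @export
estimate_basis_variances <- function(t_mat, excluded = NULL) {
  p <- nrow(t_mat)
  if (p < 3L) stopf("need at least 3 OTUs for the basis system")
  M <- matrix(1, p, p)
  diag(M) <- p - 1
  t_i <- rowSums(t_mat)
  if (!is.null(excluded) && NROW(excluded) > 0) {
    for (k in seq_len(NROW(excluded))) {
      i <- excluded[k, 1L]; j <- excluded[k, 2L]
      t_i[i] <- t_i[i] - t_mat[i, j]
      t_i[j] <- t_i[j] - t_mat[i, j]
      M[i, j] <- M[j, i] <- 0
      M[i, i] <- M[i, i] - 1
      M[j, j] <- M[j, j] - 1
    }
  }
  w2 <- tryCatch(solve(M, t_i), error = function(e) {
    # near-singular after heavy exclusion: minimum-norm least squares
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-10
    s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], t_i)) / s$d[pos])
  })
  w2 <- as.numeric(w2)
  w2[w2 < .OMEGA_EPS] <- .OMEGA_EPS
  sqrt(w2)
}

#' One-shot SparCC correlation estimate with iterative exclusion
#'
#' Each exclusion round removes the single strongest remaining |rho| pair
#' above `exclusion_threshold` from the basis system and re-solves, up to
#' `max_exclusion_rounds` rounds (the defaults follow the original
#' algorithm).
#'
#' @param fractions strictly positive relative abundances, OTUs x samples.
#' @param exclusion_threshold |rho| above which a pair may be excluded.
#' @param max_exclusion_rounds cap on exclusion iterations.
#' @return A `sparcc_fit` list: `rho` (symmetric, unit diagonal, clipped to
#'   \[-1, 1\]), `omega` (basis sds), `excluded_pairs`.
#' @export
estimate_correlations <- function(fractions, exclusion_threshold = 0.1,
                                  max_exclusion_rounds = 10L) {
  t_mat <- log_ratio_variances(fractions)
  p <- nrow(t_mat)
  ids <- rownames(fractions) %||% paste0("otu", seq_len(p))
  excluded <- matrix(integer(), 0L, 2L)
  rho <- NULL
  for (round in seq_len(max_exclusion_rounds + 1L)) {
    omega <- estimate_basis_variances(t_mat, excluded)
    w2 <- omega^2
    rho <- (outer(w2, w2, "+") - t_mat) / (2 * outer(omega, omega))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (round > max_exclusion_rounds) break
    cand <- abs(rho)
    diag(cand) <- 0
    cand[lower.tri(cand)] <- 0
    if (NROW(excluded) > 0) cand[excluded] <- 0
    # keep every OTU in at least 3 pairwise equations (cap p - 3 exclusions)
    n_excl <- tabulate(excluded, nbins = p)
    saturated <- which(n_excl >= p - 3L)
    if (length(saturated) > 0) {
      cand[saturated, ] <- 0
      cand[, saturated] <- 0
    }
    top <- arrayInd(which.max(cand), dim(cand))
    if (cand[top] <= exclusion_threshold) break
    excluded <- rbind(excluded, top)
  }
  dimnames(rho) <- list(ids, ids)
  names(omega) <- ids
  structure(list(rho = rho, omega = omega,
                 excluded_pairs = if (NROW(excluded) > 0)
                   data.frame(a = ids[excluded[, 1L]], b = ids[excluded[, 2L]],
                              stringsAsFactors = FALSE)
                 else data.frame(a = character(), b = character())),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  p <- nrow(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("SparCC fit: %d OTUs, %d excluded pair(s)\n", p,
              nrow(x$excluded_pairs)))
  cat(sprintf("  |rho| > 0.6: %d of %d pairs; range [%.3f, %.3f]\n",
              sum(abs(off) > 0.6), length(off), min(off), max(off)))
  invisible(x)
}

# Dirichlet-posterior fractions: one draw per sample with pseudocount 1;
# n_draws = 0 requests the posterior mean instead (used by the bootstrap).
.draw_fractions <- function(counts, random = TRUE) {
  p <- nrow(counts)
  f <- if (random) {
    matrix(stats::rgamma(length(counts), shape = counts + 1), p)
  } else {
    counts + 1
  }
  f <- sweep(f, 2L, colSums(f), "/")
  dimnames(f) <- dimnames(counts)
  f
}

#' SparCC with Dirichlet resampling (median aggregation)
#'
#' Full SparCC procedure: per draw, per-sample relative abundances are sampled
#' from a Dirichlet posterior with pseudocount 1 (so zero counts never enter a
#' log), correlations are estimated with iterative exclusion, and the
#' element-wise median over draws is returned.
#'
#' @param counts an [otu_table()] or a count matrix (OTUs x samples); both
#'   kingdoms may be pooled by row-binding their count matrices.
#' @param n_draws number of Dirichlet resamplings (>= 1).
#' @param seed integer seed or `NULL`.
#' @param exclusion_threshold,max_exclusion_rounds see
#'   [estimate_correlations()].
#' @return A `sparcc_fit` (median `rho` and `omega` across draws).
#' @export
sparcc <- function(counts, n_draws = 20L, seed = NULL,
                   exclusion_threshold = 0.1, max_exclusion_rounds = 10L) {
  m <- if (inherits(counts, "otu_table")) counts$counts else counts
  stopifnot(is_count_matrix(m))
  if (n_draws < 1L) stopf("n_draws must be >= 1")
  with_seed(seed, {
    fits <- lapply(seq_len(n_draws), function(d)
      estimate_correlations(.draw_fractions(m), exclusion_threshold,
                            max_exclusion_rounds))
    if (n_draws == 1L) return(fits[[1L]])
    rho <- apply(simplify2array(lapply(fits, `[[`, "rho")), c(1, 2),
                 stats::median)
    omega <- apply(do.call(rbind, lapply(fits, `[[`, "omega")), 2L,
                   stats::median)
    diag(rho) <- 1
    structure(list(rho = rho, omega = omega,
                   excluded_pairs = fits[[n_draws]]$excluded_pairs),
              class = "sparcc_fit")
  })
}

#' Permutation p-values for SparCC correlations
#'
#' Builds a null by permuting every OTU's counts independently across samples
#' (destroying all between-OTU association while preserving each OTU's count
#' distribution), re-estimating rho per permutation, and reporting the
#' two-sided p as the plain proportion of null `|rho|` at least as large as
#' the observed `|rho|`, per pair.
#'
#' @param counts the same counts passed to [sparcc()].
#' @param observed a `sparcc_fit`.
#' @param n_boot number of permutations (>= 20; study-style default 100).
#' @param seed integer seed or `NULL`.
#' @param exclusion_threshold,max_exclusion_rounds see
#'   [estimate_correlations()].
#' @return A `sparcc_sig` list: `p` (symmetric, `NA` diagonal), `n_boot`,
#'   `two_sided = TRUE`.
#' @export
sparcc_pvalues <- function(counts, observed, n_boot = 100L, seed = NULL,
                           exclusion_threshold = 0.1,
                           max_exclusion_rounds = 10L) {
  m <- if (inherits(counts, "otu_table")) counts$counts else counts
  stopifnot(inherits(observed, "sparcc_fit"), is_count_matrix(m))
  if (n_boot < 20L) stopf("n_boot must be >= 20")
  obs <- abs(observed$rho)
  n <- ncol(m)
  with_seed(seed, {
    exceed <- matrix(0, nrow(m), nrow(m))
    for (b in seq_len(n_boot)) {
      perm <- t(apply(m, 1L, function(r) r[sample.int(n)]))
      fit <- estimate_correlations(.draw_fractions(perm, random = FALSE),
                                   exclusion_threshold, max_exclusion_rounds)
      exceed <- exceed + (abs(fit$rho) >= obs)
    }
    p <- exceed / n_boot
    diag(p) <- NA_real_
    dimnames(p) <- dimnames(observed$rho)
    structure(list(p = p, n_boot = n_boot, two_sided = TRUE),
              class = "sparcc_sig")
  })
}

#' @export
print.sparcc_sig <- function(x, ...) {
  cat(sprintf("SparCC significance: %d permutations, %d pair(s) with p < 0.05\n",
              x$n_boot, sum(x$p[upper.tri(x$p)] < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Select significant correlation edges
#'
#' Applies the network-construction thresholds: an edge is retained when
#' `|rho| > r_threshold` (strict) and `p < p_threshold` (strict); the study
#' default is rho > 0.6 and P < 0.05.
#'
#' @param fit a `sparcc_fit` (or bare rho matrix).
#' @param sig a `sparcc_sig` (or bare p matrix) of matching shape.
#' @param r_threshold correlation magnitude threshold.
#' @param p_threshold significance threshold.
#' @return data.frame edge list: `source`, `target`, `rho`, `p`, `sign`
#'   (`"positive"`/`"negative"`), one row per unordered pair.
#' @export
significant_edges <- function(fit, sig, r_threshold = 0.6,
                              p_threshold = 0.05) {
  rho <- if (inherits(fit, "sparcc_fit")) fit$rho else fit
  p <- if (inherits(sig, "sparcc_sig")) sig$p else sig
  if (!identical(dim(rho), dim(p))) stopf("rho and p shapes differ")
  ids <- rownames(rho) %||% paste0("otu", seq_len(nrow(rho)))
  ut <- which(upper.tri(rho) & abs(rho) > r_threshold & p < p_threshold,
              arr.ind = TRUE)
  data.frame(source = ids[ut[, 1L]], target = ids[ut[, 2L]],
             rho = rho[ut], p = p[ut],
             sign = ifelse(rho[ut] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Write / read an edge list as tab-separated text
#' @param edges data.frame as from [significant_edges()].
#' @param path file path.
#' @return `path` (write) or the edge data.frame (read).
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
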