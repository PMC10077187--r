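# NODF significance against Patefield fixed-marginal null tables.

#' Patefield random contingency tables
#'
#' Uniform samples from the set of non-negative integer matrices with the
#' given row and column sums (Patefield's sequential conditional algorithm,
#' as provided by `stats::r2dtable`).
#'
#' @param row_sums,col_sums integer marginals with equal totals.
#' @param n number of tables.
#' @param seed integer seed or `NULL`.
#' @return A single matrix when `n = 1`, else a list of matrices.
#' @export
patefield_sample <- function(row_sums, col_sums, n = 1L, seed = NULL) {
  row_sums <- as.integer(round(row_sums))
  col_sums <- as.integer(round(col_sums))
  if (sum(row_sums) != sum(col_sums))
    stopf("row and column totals differ (%d vs %d)",
          sum(row_sums), sum(col_sums))
  if (sum(row_sums) <= 0) stopf("marginal totals must be positive")
  tabs <- if (length(row_sums) == 1L) {
    replicate(n, matrix(col_sums, 1L), simplify = FALSE)  # forced table
  } else if (length(col_sums) == 1L) {
    replicate(n, matrix(row_sums, ncol = 1L), simplify = FALSE)
  } else {
    with_seed(seed, stats::r2dtable(n, row_sums, col_sums))
  }
  if (n == 1L) tabs[[1L]] else tabs
}

#' Monte Carlo NODF significance
#'
#' Draws `n_rand` Patefield tables with the observed integer-scaled
#' marginals, binarizes each at > 0, and compares their NODF with the
#' observed value. P-values are the plain proportions of null matrices with
#' an index at least as high (`p_higher`) or at least as low (`p_lower`) as
#' observed.
#'
#' @param net a `bipnet` or weight matrix; weights are scaled x100 and
#'   rounded to integer interaction counts.
#' @param n_rand number of randomizations (study default 100; >= 20).
#' @param seed integer seed or `NULL`.
#' @return Object of class `nodf_null`: `observed`, `null` (vector),
#'   `p_higher`, `p_lower`, `n_rand`.
#' @export
nodf_significance <- function(net, n_rand = 100L, seed = NULL) {
  if (n_rand < 20L) stopf("n_rand must be >= 20")
  a <- round(as_incidence(net) * 100)
  if (nrow(a) < 2L || ncol(a) < 2L || sum(a) == 0)
    stopf("degenerate matrix: need >= 2 rows, >= 2 cols and positive total")
  rs <- rowSums(a); cs <- colSums(a)
  if (any(rs == 0) || any(cs == 0))
    stopf("degenerate marginals: empty row or column")
  obs <- nodf(a)
  nulls <- patefield_sample(rs, cs, n = n_rand, seed = seed)
  null_nodf <- vapply(nulls, function(m) nodf(m > 0), numeric(1))
  structure(list(observed = obs, null = null_nodf,
                 p_higher = mean(null_nodf >= obs),
                 p_lower = mean(null_nodf <= obs),
                 n_rand = n_rand),
            class = "nodf_null")
}

#' @export
print.nodf_null <- function(x, ...) {
  cat(sprintf(paste0("NODF = %.2f vs %d Patefield nulls ",
                     "(mean %.2f, sd %.2f)\n  p_higher = %.3f, ",
                     "p_lower = %.3f\n"),
              x$observed, x$n_rand, mean(x$null), stats::sd(x$null),
              x$p_higher, x$p_lower))
  invisible(x)
}
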