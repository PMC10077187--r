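# Barber bipartite modularity, weighted label propagation (LPAwb+ family),
# and z-c topological role classification.

#' Barber's bipartite modularity
#'
#' `Q = (1/m) * sum_{i,j: g(i) = g(j)} (w_ij - k_i d_j / m)` over
#' row-column pairs sharing a module, with `m` the total weight and `k`, `d`
#' the marginal weights. `Q = 0` for the one-module partition on any
#' network.
#'
#' @param net a `bipnet` or weight matrix.
#' @param partition list with integer label vectors `rows` and `cols`.
#' @return Q in \[-1, 1\].
#' @export
barber_q <- function(net, partition) {
  w <- as_incidence(net)
  r <- partition$rows; c_ <- partition$cols
  stopifnot(length(r) == nrow(w), length(c_) == ncol(w))
  m <- sum(w)
  if (m == 0) return(0)
  k <- rowSums(w); d <- colSums(w)
  q <- 0
  for (lab in unique(r)) {
    ri <- r == lab; ci <- c_ == lab
    if (!any(ci)) next
    q <- q + sum(w[ri, ci, drop = FALSE]) - sum(k[ri]) * sum(d[ci]) / m
  }
  q / m
}

# One sweep family: greedily relabel one guild to maximize its Barber-Q
# contribution given the other guild's labels; alternating sweeps increase Q
# monotonically, so the propagation terminates.
.propagate <- function(w, rows, cols) {
  m <- sum(w)
  k <- rowSums(w); d <- colSums(w)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 200L) break            # safety against tie oscillation
    changed <- FALSE
    # columns adopt the best row label
    labs <- sort(unique(rows))
    kf <- vapply(labs, function(l) sum(k[rows == l]), numeric(1))
    for (j in seq_len(ncol(w))) {
      wt <- vapply(labs, function(l) sum(w[rows == l, j]), numeric(1))
      score <- wt - kf * d[j] / m
      best <- which.max(score)
      cur <- match(cols[j], labs)
      # a dead label (no counterpart nodes) contributes 0; merge it away
      # whenever the move is Q-neutral or better
      move <- if (is.na(cur)) score[best] >= 0
              else labs[best] != cols[j] && score[best] > score[cur] + 1e-12
      if (move) {
        cols[j] <- labs[best]; changed <- TRUE
      }
    }
    # rows adopt the best column label
    labs <- sort(unique(cols))
    df <- vapply(labs, function(l) sum(d[cols == l]), numeric(1))
    for (i in seq_len(nrow(w))) {
      wt <- vapply(labs, function(l) sum(w[i, cols == l]), numeric(1))
      score <- wt - df * k[i] / m
      best <- which.max(score)
      cur <- match(rows[i], labs)
      move <- if (is.na(cur)) score[best] >= 0
              else labs[best] != rows[i] && score[best] > score[cur] + 1e-12
      if (move) {
        rows[i] <- labs[best]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(rows = rows, cols = cols)
}

.relabel <- function(part) {
  labs <- sort(unique(c(part$rows, part$cols)))
  part$rows <- match(part$rows, labs)
  part$cols <- match(part$cols, labs)
  part
}

#' Weighted label propagation for Barber modularity (LPAwb+ style)
#'
#' Starting from per-row singleton labels (or a supplied initialization),
#' rows and columns alternately adopt the label maximizing their Barber-Q
#' contribution until no improving move remains. Deterministic given the
#' initialization; `seed` only matters for a random `init`.
#'
#' @param net a `bipnet` or weight matrix.
#' @param seed integer seed or `NULL`.
#' @param init optional integer vector of initial row labels.
#' @return Object of class `module_partition`: `rows`, `cols` (labels), `Q`,
#'   `n_modules`.
#' @export
lpawb_plus <- function(net, seed = NULL, init = NULL) {
  w <- as_incidence(net)
  if (length(w) == 0L || sum(w) == 0) stopf("empty network")
  rows <- init %||% seq_len(nrow(w))
  cols <- rep(rows[1L], ncol(w))
  part <- .relabel(.propagate(w, rows, cols))
  structure(list(rows = stats::setNames(part$rows, rownames(w)),
                 cols = stats::setNames(part$cols, colnames(w)),
                 Q = barber_q(w, part),
                 n_modules = length(unique(c(part$rows, part$cols)))),
            class = "module_partition")
}

#' Multi-restart label propagation (DIRTLPAwb+ style)
#'
#' Repeats [lpawb_plus()] from varied random initial module counts and
#' returns the best-Q partition. The first restart is the deterministic
#' singleton initialization, so `n_restarts = 1` reproduces [lpawb_plus()].
#'
#' @param net a `bipnet` or weight matrix.
#' @param n_restarts number of restarts (default 10).
#' @param seed integer seed or `NULL`.
#' @return A `module_partition` (best Q over restarts).
#' @export
dirt_lpawb_plus <- function(net, n_restarts = 10L, seed = NULL) {
  w <- as_incidence(net)
  if (n_restarts < 1L) stopf("n_restarts must be >= 1")
  best <- lpawb_plus(w)
  if (n_restarts > 1L) with_seed(seed, {
    for (r in seq_len(n_restarts - 1L)) {
      kmax <- max(2L, min(nrow(w), length(unique(best$rows)) + 2L))
      k <- sample.int(kmax, 1L)
      cand <- lpawb_plus(w, init = sample.int(k, nrow(w), replace = TRUE))
      if (cand$Q > best$Q) best <- cand
    }
    best
  }) else best
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d modules, Barber Q = %.4f\n",
              x$n_modules, x$Q))
  invisible(x)
}

#' z-c topological roles
#'
#' Computes, on binary degrees, each node's within-module degree z-score
#' (`z_i = (k_i,own - mean) / sd` over its module's same-guild members;
#' modules with zero sd give z = 0) and among-module connectivity
#' `c_i = 1 - sum_t (k_it / k_i)^2`, then classifies:
#' module hub (z > 2.5, c <= 0.62), network hub (z > 2.5, c > 0.62),
#' connector (z <= 2.5, c > 0.62), peripheral (z <= 2.5, c <= 0.62).
#'
#' @param net a `bipnet` or weight matrix.
#' @param partition a `module_partition` (or list with `rows`/`cols`).
#' @param z_threshold,c_threshold role thresholds.
#' @return data.frame with columns `id`, `guild`, `module`, `degree`, `z`,
#'   `c`, `role`.
#' @export
node_roles <- function(net, partition, z_threshold = 2.5,
                       c_threshold = 0.62) {
  b <- (as_incidence(net) > 0) * 1
  r <- unname(partition$rows); cl <- unname(partition$cols)
  stopifnot(length(r) == nrow(b), length(cl) == ncol(b))
  one_guild <- function(mat, own, other, guild, ids) {
    # mat: guild x opposite incidence; own/other: labels
    k <- rowSums(mat)
    labs_all <- sort(unique(c(own, other)))
    k_by_mod <- matrix(0, nrow(mat), length(labs_all))
    for (t_ in seq_along(labs_all))
      k_by_mod[, t_] <- rowSums(mat[, other == labs_all[t_], drop = FALSE])
    k_own <- vapply(seq_along(own), function(i)
      sum(mat[i, other == own[i]]), numeric(1))
    z <- numeric(length(own))
    for (l in unique(own)) {
      members <- own == l
      mu <- mean(k_own[members]); sg <- stats::sd(k_own[members])
      z[members] <- if (is.na(sg) || sg == 0) 0 else (k_own[members] - mu) / sg
    }
    c_val <- 1 - rowSums((k_by_mod / pmax(k, 1))^2)
    c_val[k == 0] <- 0
    data.frame(id = ids, guild = guild, module = own, degree = unname(k),
               z = unname(z), c = unname(c_val), stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_guild(b, r, cl, "microeukaryote",
              rownames(b) %||% paste0("r", seq_len(nrow(b)))),
    one_guild(t(b), cl, r, "bacteria",
              colnames(b) %||% paste0("c", seq_len(ncol(b)))))
  out$role <- classify_role(out$z, out$c, z_threshold, c_threshold)
  out
}

#' Classify z-c values into topological roles
#'
#' @param z,c numeric vectors of within-module z-scores and among-module
#'   connectivities.
#' @param z_threshold,c_threshold thresholds (defaults 2.5 and 0.62).
#' @return Character vector: `"module hub"`, `"network hub"`, `"connector"`
#'   or `"peripheral"`.
#' @export
classify_role <- function(z, c, z_threshold = 2.5, c_threshold = 0.62) {
  ifelse(z > z_threshold,
         ifelse(c <= c_threshold, "module hub", "network hub"),
         ifelse(c > c_threshold, "connector", "peripheral"))
}
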