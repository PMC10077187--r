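# Network-level and node-level topology of a bipartite network.
#
# All functions accept either a `bipnet` or a bare weight/incidence matrix
# (rows = microeukaryotes, cols = bacteria). Quantitative metrics use the
# weights as given; NODF and degrees binarize at > 0.

nonempty <- function(m) {
  if (length(m) == 0L || sum(m) == 0) stopf("empty network")
  m
}

#' Connectance
#'
#' Realized fraction of all possible inter-guild links,
#' `L / (n_rows * n_cols)`.
#' @param net a `bipnet` or weight matrix.
#' @return Proportion in (0, 1].
#' @export
connectance <- function(net) {
  m <- nonempty(as_incidence(net))
  sum(m > 0) / (nrow(m) * ncol(m))
}

#' Links per species
#'
#' `L / (n_rows + n_cols)`: mean number of links per node.
#' @inheritParams connectance
#' @return Non-negative number.
#' @export
links_per_species <- function(net) {
  m <- nonempty(as_incidence(net))
  sum(m > 0) / (nrow(m) + ncol(m))
}

#' NODF nestedness
#'
#' Nestedness metric based on paired overlap and decreasing fill: for every
#' ordered row pair and column pair, the percentage overlap of the sparser
#' member within the denser one when their fills strictly decrease (0
#' otherwise), averaged over all pairs. Ranges from 0 (completely disordered)
#' to 100 (perfectly nested). Computed on the binarized incidence.
#'
#' @inheritParams connectance
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(net) {
  m <- (as_incidence(net) > 0) * 1L
  if (nrow(m) < 2L || ncol(m) < 2L)
    stopf("NODF needs at least 2 rows and 2 columns")
  if (sum(m) == 0L) stopf("all-zero matrix")
  unname(vegan::nestednodf(m, order = FALSE, weighted = FALSE)$
           statistic[["NODF"]])
}

#' Interaction (Shannon) diversity
#'
#' `H = -sum p_ij log(p_ij)` over nonzero cells, with `p_ij = w_ij / m`
#' (natural log). Invariant to weight rescaling.
#' @inheritParams connectance
#' @return H >= 0.
#' @export
interaction_shannon <- function(net) {
  w <- nonempty(as_incidence(net))
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

#' Interaction evenness
#'
#' `H / log(n_rows * n_cols)` ("product" denominator convention);
#' `denominator = "links"` divides by `log(L)` instead.
#' @inheritParams connectance
#' @param denominator `"product"` (default) or `"links"`.
#' @return Proportion in \[0, 1\].
#' @export
interaction_evenness <- function(net, denominator = c("product", "links")) {
  denominator <- match.arg(denominator)
  w <- nonempty(as_incidence(net))
  denom <- switch(denominator,
                  product = log(nrow(w) * ncol(w)),
                  links = log(sum(w > 0)))
  if (denom <= 0) stopf("evenness undefined for a single-cell network")
  interaction_shannon(w) / denom
}

#' Quantitative linkage density
#'
#' Marginal-weighted mean of the effective partner numbers
#' `LD = 1/2 * [ sum_j (w_.j/m) 2^{H_j} + sum_i (w_i./m) 2^{H_i} ]`, where
#' `H` is a node's Shannon entropy (base 2) of its interaction weights and
#' `2^H` its effective number of partners.
#' @inheritParams connectance
#' @return LD >= 0, bounded by the larger guild size.
#' @export
linkage_density <- function(net) {
  w <- nonempty(as_incidence(net))
  m <- sum(w)
  eff <- function(v) {                   # 2^shannon entropy, base 2
    p <- v[v > 0] / sum(v)
    2^(-sum(p * log2(p)))
  }
  rows <- apply(w, 1L, function(v) if (sum(v) > 0) sum(v) / m * eff(v) else 0)
  cols <- apply(w, 2L, function(v) if (sum(v) > 0) sum(v) / m * eff(v) else 0)
  (sum(rows) + sum(cols)) / 2
}

#' Bluethgen's d' specialization index
#'
#' Node-level Kullback-Leibler specialization: for node i with interaction
#' shares `p'_ij` against partner availabilities `q_j` (partner marginal
#' totals / grand total), `d_i = sum_j p'_ij log(p'_ij / q_j)`. Standardized
#' to `d' = d_i / log(m / A_i)` (`A_i` = node total, `m` = grand total),
#' whose endpoints are attained exactly: 0 when a node's shares match the
#' partner marginals, 1 when all its interactions fall on partners used by
#' nobody else. Weights are scaled to integer counts (x100, rounded) first.
#'
#' @inheritParams connectance
#' @param guild `"rows"` (microeukaryotes) or `"cols"` (bacteria).
#' @return Named vector of d' values in \[0, 1\] for that guild's nodes.
#' @export
specialization_d <- function(net, guild = c("rows", "cols")) {
  guild <- match.arg(guild)
  a <- round(nonempty(as_incidence(net)) * 100)
  if (guild == "cols") a <- t(a)
  m <- sum(a)
  q <- colSums(a) / m
  vapply(seq_len(nrow(a)), function(i) {
    ai <- sum(a[i, ])
    if (ai == 0) return(0)
    dmax <- log(m / ai)
    if (dmax <= 0 || ncol(a) < 2L) return(0)   # single possible partner
    ps <- a[i, a[i, ] > 0] / ai
    qs <- q[a[i, ] > 0]
    d <- sum(ps * log(ps / qs))
    min(max(d / dmax, 0), 1)
  }, numeric(1), USE.NAMES = FALSE) -> out
  stats::setNames(out, rownames(a))
}

#' Count perfect specialists (d' = 1)
#'
#' Number of nodes (both guilds) whose specialization index equals 1 within
#' 1e-9 — exclusive pairing partners.
#' @inheritParams connectance
#' @return Integer count.
#' @export
count_perfect_specialists <- function(net) {
  dr <- specialization_d(net, "rows")
  dc <- specialization_d(net, "cols")
  sum(c(dr, dc) >= 1 - 1e-9)
}

#' Guild clustering coefficient
#'
#' One-mode projection onto one guild (two nodes adjacent iff they share at
#' least one partner), then the mean local clustering coefficient over the
#' guild's nodes, counting nodes with fewer than two projection neighbours
#' as 0.
#' @inheritParams connectance
#' @param guild `"rows"` or `"cols"`.
#' @return Proportion in \[0, 1\].
#' @export
guild_cluster_coefficient <- function(net, guild = c("rows", "cols")) {
  guild <- match.arg(guild)
  b <- (nonempty(as_incidence(net)) > 0) * 1
  if (guild == "cols") b <- t(b)
  if (nrow(b) < 2L) stopf("guild needs at least 2 nodes")
  adj <- tcrossprod(b) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  mean(cc)
}

#' Number of compartments
#'
#' Connected components of the bipartite graph.
#' @inheritParams connectance
#' @return Integer >= 1.
#' @export
compartments <- function(net) {
  b <- nonempty(as_incidence(net)) > 0
  g <- igraph::graph_from_biadjacency_matrix(b)
  igraph::components(g)$no
}

#' Per-node degree, strength and specialization
#'
#' @inheritParams connectance
#' @return data.frame with columns `id`, `guild`, `degree`, `strength`,
#'   `dprime`.
#' @export
node_metrics <- function(net) {
  w <- nonempty(as_incidence(net))
  rbind(
    data.frame(id = rownames(w) %||% paste0("r", seq_len(nrow(w))),
               guild = "microeukaryote", degree = unname(rowSums(w > 0)),
               strength = unname(rowSums(w)),
               dprime = unname(specialization_d(w, "rows")),
               stringsAsFactors = FALSE),
    data.frame(id = colnames(w) %||% paste0("c", seq_len(ncol(w))),
               guild = "bacteria", degree = unname(colSums(w > 0)),
               strength = unname(colSums(w)),
               dprime = unname(specialization_d(w, "cols")),
               stringsAsFactors = FALSE))
}

#' Full network-level metric report
#'
#' Assembles every network-level statistic of the topology table: node and
#' link counts, links per species, connectance, NODF, linkage density,
#' interaction diversity and evenness, per-guild clustering coefficients and
#' compartment count.
#'
#' @inheritParams connectance
#' @return Object of class `network_metrics` (a JSON-serializable list).
#' @export
network_report <- function(net) {
  w <- nonempty(as_incidence(net))
  structure(list(
    n_microeukaryotes = nrow(w),
    n_bacteria = ncol(w),
    n_links = sum(w > 0),
    total_weight = sum(w),
    links_per_species = links_per_species(w),
    connectance = connectance(w),
    NODF = if (nrow(w) >= 2 && ncol(w) >= 2) nodf(w) else NA_real_,
    linkage_density = linkage_density(w),
    shannon_diversity = interaction_shannon(w),
    interaction_evenness = if (length(w) > 1L) interaction_evenness(w)
                           else NA_real_,
    cluster_coefficient_microeukaryotes =
      if (nrow(w) >= 2) guild_cluster_coefficient(w, "rows") else NA_real_,
    cluster_coefficient_bacteria =
      if (ncol(w) >= 2) guild_cluster_coefficient(w, "cols") else NA_real_,
    n_compartments = compartments(w)),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("bipartite network metrics\n")
  for (k in names(x))
    cat(sprintf("  %-36s %s\n", k,
                if (is.numeric(x[[k]])) format(round(x[[k]], 4)) else x[[k]]))
  invisible(x)
}
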