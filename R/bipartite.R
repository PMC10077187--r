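# Signed bipartite networks: microeukaryote rows vs bacterial columns.

#' Construct a bipartite network
#'
#' Rows are microeukaryote OTUs, columns bacterial OTUs; entries are
#' non-negative interaction weights (|rho| of a retained edge, 0 otherwise).
#' Isolated (all-zero) rows and columns are pruned, matching the convention
#' that a network node must carry at least one link.
#'
#' @param weights non-negative numeric matrix with unique dimnames.
#' @param sign `"positive"` or `"negative"` — which co-occurrence sign this
#'   network collects.
#' @param habitat free-text habitat label (e.g. `"water"`).
#' @param row_phylum,col_phylum optional named character vectors of phylum
#'   labels for the row/column nodes.
#' @param edges optional edge data.frame (source, target, rho, p, sign) kept
#'   for export.
#' @return Object of class `bipnet`.
#' @export
bipartite_network <- function(weights, sign = c("positive", "negative"),
                              habitat = "", row_phylum = NULL,
                              col_phylum = NULL, edges = NULL) {
  sign <- match.arg(sign)
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (nrow(weights) > 0L && is.null(rownames(weights)))
    rownames(weights) <- paste0("euk_", seq_len(nrow(weights)))
  if (ncol(weights) > 0L && is.null(colnames(weights)))
    colnames(weights) <- paste0("bact_", seq_len(ncol(weights)))
  if (anyDuplicated(rownames(weights)) || anyDuplicated(colnames(weights)))
    stopf("duplicate node ids")
  keep_r <- rowSums(weights) > 0
  keep_c <- colSums(weights) > 0
  weights <- weights[keep_r, keep_c, drop = FALSE]
  if (nrow(weights) == 0L || ncol(weights) == 0L)
    warning("network is empty after pruning isolated nodes", call. = FALSE)
  structure(list(weights = weights, sign = sign, habitat = habitat,
                 row_phylum = row_phylum, col_phylum = col_phylum,
                 edges = edges),
            class = "bipnet")
}

#' @export
print.bipnet <- function(x, ...) {
  w <- x$weights
  cat(sprintf("bipnet [%s%s]: %d microeukaryotes x %d bacteria, %d links\n",
              x$sign, if (nzchar(x$habitat)) paste0(", ", x$habitat) else "",
              nrow(w), ncol(w), sum(w > 0)))
  invisible(x)
}

# Accept a bipnet or a bare incidence/weight matrix everywhere downstream.
as_incidence <- function(x) {
  if (inherits(x, "bipnet")) x$weights
  else if (is.matrix(x)) x
  else stopf("expected a bipnet or a matrix")
}

#' Keep only inter-kingdom edges
#'
#' The whole-community correlation network contains intra- and inter-kingdom
#' edges; the bipartite analysis uses only microeukaryote-bacterium pairs.
#' Edges are reoriented so that `source` is the microeukaryote.
#'
#' @param edges edge data.frame (see [significant_edges()]).
#' @param euk_ids,bact_ids id vectors defining kingdom membership.
#' @return Edge data.frame restricted to cross-kingdom pairs.
#' @export
extract_cross_kingdom <- function(edges, euk_ids, bact_ids) {
  if (nrow(edges) == 0L) return(edges)
  side <- function(id) ifelse(id %in% euk_ids, "E",
                              ifelse(id %in% bact_ids, "B", NA))
  s <- side(edges$source); t <- side(edges$target)
  if (anyNA(s) || anyNA(t))
    stopf("edge endpoint of unknown kingdom: %s",
          c(edges$source[is.na(s)], edges$target[is.na(t)])[1L])
  cross <- s != t
  out <- edges[cross, , drop = FALSE]
  flip <- s[cross] == "B"
  tmp <- out$source[flip]
  out$source[flip] <- out$target[flip]
  out$target[flip] <- tmp
  rownames(out) <- NULL
  out
}

#' Split cross-kingdom edges into positive and negative networks
#'
#' Edge weight is |rho|; a node engaged in both signs appears in both
#' networks.
#'
#' @param edges cross-kingdom edge data.frame (source = microeukaryote).
#' @param habitat habitat label forwarded to both networks.
#' @param taxonomy optional taxonomy data.frame used to attach phylum labels.
#' @return List with elements `positive` and `negative` ([bipartite_network()]
#'   objects; an all-one-sign input yields an empty counterpart).
#' @export
split_by_sign <- function(edges, habitat = "", taxonomy = NULL) {
  if (nrow(edges) > 0 && any(edges$rho == 0))
    stopf("edges must carry nonzero rho")
  build <- function(sub, sgn) {
    euk <- unique(sub$source); bact <- unique(sub$target)
    w <- matrix(0, length(euk), length(bact), dimnames = list(euk, bact))
    if (nrow(sub) > 0) w[cbind(sub$source, sub$target)] <- abs(sub$rho)
    phy <- function(ids) {
      if (is.null(taxonomy)) return(NULL)
      v <- taxonomy$phylum[match(ids, taxonomy$otu_id)]
      v[is.na(v)] <- "unclassified"
      stats::setNames(v, ids)
    }
    bipartite_network(w, sgn, habitat, row_phylum = phy(euk),
                      col_phylum = phy(bact), edges = sub)
  }
  list(positive = suppressWarnings(
         build(edges[edges$sign == "positive", , drop = FALSE], "positive")),
       negative = suppressWarnings(
         build(edges[edges$sign == "negative", , drop = FALSE], "negative")))
}

#' Core taxa shared by the positive and negative networks
#'
#' Core taxa are nodes holding both positive and negative links with the
#' other kingdom. For each core node the positive degree `d_pos`, negative
#' degree `d_neg` and the asymmetry index `(d_pos - d_neg)/(d_pos + d_neg)`
#' (1 = purely positive, -1 = purely negative) are reported, together with
#' the share of all degrees carried by core nodes.
#'
#' @param pos,neg positive and negative [bipartite_network()]s sharing an id
#'   namespace.
#' @return Object of class `core_taxa`: data.frame `nodes` (`id`, `guild`,
#'   `phylum`, `d_pos`, `d_neg`, `asymmetry`), plus `coverage` (overall and
#'   per guild) and core node counts.
#' @export
core_taxa <- function(pos, neg) {
  stopifnot(inherits(pos, "bipnet"), inherits(neg, "bipnet"))
  deg <- function(net) {
    w <- net$weights
    c(stats::setNames(rowSums(w > 0), rownames(w)),
      stats::setNames(colSums(w > 0), colnames(w)))
  }
  guild_of <- function(net) {
    rep(c("microeukaryote", "bacteria"),
        c(nrow(net$weights), ncol(net$weights)))
  }
  dp <- deg(pos); dn <- deg(neg)
  gp <- stats::setNames(guild_of(pos), names(dp))
  gn <- stats::setNames(guild_of(neg), names(dn))
  core <- intersect(names(dp), names(dn))
  guild <- gp[core]
  phylum <- rep(NA_character_, length(core))
  all_phy <- c(pos$row_phylum, pos$col_phylum, neg$row_phylum, neg$col_phylum)
  if (!is.null(all_phy)) phylum <- unname(all_phy[core])
  d_pos <- unname(dp[core]); d_neg <- unname(dn[core])
  nodes <- data.frame(id = core, guild = unname(guild), phylum = phylum,
                      d_pos = d_pos, d_neg = d_neg,
                      asymmetry = ifelse(d_pos + d_neg > 0,
                                         (d_pos - d_neg) / (d_pos + d_neg), 0),
                      stringsAsFactors = FALSE)
  total_deg <- sum(dp) + sum(dn)
  cov_all <- if (total_deg > 0) (sum(dp[core]) + sum(dn[core])) / total_deg else 0
  cov_guild <- vapply(c("microeukaryote", "bacteria"), function(g) {
    tot <- sum(dp[gp == g]) + sum(dn[gn == g])
    in_core <- core[guild == g]
    if (tot > 0) (sum(dp[in_core]) + sum(dn[in_core])) / tot else 0
  }, numeric(1))
  structure(list(nodes = nodes,
                 n_core = c(microeukaryote = sum(guild == "microeukaryote"),
                            bacteria = sum(guild == "bacteria")),
                 coverage = c(overall = cov_all, cov_guild)),
            class = "core_taxa")
}

#' @export
print.core_taxa <- function(x, ...) {
  cat(sprintf(paste0("core taxa: %d microeukaryotes and %d bacteria with both",
                     " positive and negative links\n  degree coverage: %.0f%%",
                     " overall\n"),
              x$n_core[["microeukaryote"]], x$n_core[["bacteria"]],
              100 * x$coverage[["overall"]]))
  invisible(x)
}

#' Phylum-level node and degree percentages
#'
#' For each guild, the percentage of nodes and of degrees contributed by each
#' phylum (each column sums to 100 within a guild); nodes without taxonomy
#' are reported as `"unclassified"`.
#'
#' @param net a [bipartite_network()].
#' @param taxonomy optional taxonomy data.frame overriding the network's
#'   stored phylum labels.
#' @return data.frame with columns `guild`, `phylum`, `node_pct`,
#'   `degree_pct`.
#' @export
phylum_summary <- function(net, taxonomy = NULL) {
  stopifnot(inherits(net, "bipnet"))
  w <- net$weights
  one_guild <- function(ids, degrees, guild, stored) {
    phy <- if (!is.null(taxonomy)) taxonomy$phylum[match(ids, taxonomy$otu_id)]
           else if (!is.null(stored)) unname(stored[ids])
           else rep(NA_character_, length(ids))
    phy[is.na(phy) | phy == ""] <- "unclassified"
    node_pct <- 100 * as.numeric(table(phy)[unique(phy)]) / length(ids)
    deg_by <- tapply(degrees, phy, sum)[unique(phy)]
    data.frame(guild = guild, phylum = unique(phy), node_pct = node_pct,
               degree_pct = 100 * as.numeric(deg_by) / sum(degrees),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_guild(rownames(w), rowSums(w > 0), "microeukaryote", net$row_phylum),
    one_guild(colnames(w), colSums(w > 0), "bacteria", net$col_phylum))
  out[order(out$guild, -out$degree_pct), ]
}

#' Export a bipartite network to GraphML
#'
#' Writes a Gephi-compatible GraphML file with node attributes `guild`,
#' `phylum` and `degree`, and edge attributes `rho`, `p` and `sign`.
#'
#' @param net a [bipartite_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "bipnet"))
  g <- as_igraph(net)
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e) stopf("cannot write '%s': %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

#' Convert a bipartite network to an igraph object
#' @param net a [bipartite_network()].
#' @return An undirected igraph graph with a logical `type` vertex attribute
#'   (TRUE = bacteria).
#' @export
as_igraph <- function(net) {
  w <- net$weights
  euk <- rownames(w); bact <- colnames(w)
  idx <- which(w > 0, arr.ind = TRUE)
  sgn <- if (net$sign == "positive") 1 else -1
  rho <- sgn * w[idx]
  pval <- rep(NA_real_, nrow(idx))
  if (!is.null(net$edges) && nrow(net$edges) > 0) {
    key <- paste(net$edges$source, net$edges$target)
    hit <- match(paste(euk[idx[, 1L]], bact[idx[, 2L]]), key)
    pval <- net$edges$p[hit]
    rho <- ifelse(is.na(hit), rho, net$edges$rho[hit])
  }
  verts <- data.frame(
    name = c(euk, bact),
    type = rep(c(FALSE, TRUE), c(length(euk), length(bact))),
    guild = rep(c("microeukaryote", "bacteria"),
                c(length(euk), length(bact))),
    phylum = c(if (!is.null(net$row_phylum)) unname(net$row_phylum[euk])
               else rep(NA_character_, length(euk)),
               if (!is.null(net$col_phylum)) unname(net$col_phylum[bact])
               else rep(NA_character_, length(bact))),
    degree = c(rowSums(w > 0), colSums(w > 0)),
    stringsAsFactors = FALSE)
  verts$phylum[is.na(verts$phylum)] <- "unclassified"
  edf <- data.frame(from = euk[idx[, 1L]], to = bact[idx[, 2L]],
                    weight = w[idx], rho = rho, p = pval, sign = net$sign,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = verts)
}

#' Build a bipartite network from a saved edge list
#'
#' @param edges edge data.frame or TSV path (source = microeukaryote ids).
#' @param sign which sign to extract (`"positive"` or `"negative"`).
#' @param habitat habitat label.
#' @param taxonomy optional taxonomy data.frame.
#' @return A [bipartite_network()].
#' @export
network_from_edges <- function(edges, sign = c("positive", "negative"),
                               habitat = "", taxonomy = NULL) {
  sign <- match.arg(sign)
  if (is.character(edges)) edges <- read_edges(edges)
  split_by_sign(edges, habitat, taxonomy)[[sign]]
}
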