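# Synthetic paired-kingdom communities with known ground truth.
#
# The generator emulates the structure of a coastal-pond amplicon survey:
# 48 paired water samples, 406 microeukaryotic (18S) and 1210 bacterial (16S)
# OTUs surviving a 50% prevalence filter, log-normal basis abundances turned
# into compositional counts by multinomial resampling at the study's
# rarefaction depths, and a set of planted signed inter-kingdom associations
# on the latent (log basis abundance) scale -- the scale on which SparCC is
# meant to recover them.

# Phylum inventories with relative node frequencies taken from the water
# bipartite network's node percentages, so that synthetic phylum summaries
# resemble a real pond community.
.bact_phyla <- c(
  Proteobacteria = 34.3, Bacteroidetes = 13.5, Chloroflexi = 4.2,
  Actinobacteria = 14.0, Planctomycetes = 8.3, Cyanobacteria = 14.0,
  Verrucomicrobia = 3.7, Firmicutes = 1.2, Patescibacteria = 2.7,
  Acidobacteria = 0.2, Spirochaetes = 0.2, Epsilonbacteraeota = 0.2)
.euk_phyla <- c(
  Chlorophyta = 23.5, Ciliophora = 14.5, Fungi = 13.5, Ochrophyta = 12.5,
  Cercozoa = 8.0, Cryptophyta = 8.0, `Stramenopiles X` = 5.0,
  Dinoflagellata = 2.5, Choanoflagellida = 1.5, Apicomplexa = 1.5,
  Conosa = 1.0, Centroheliozoa = 0.5)

#' Default planted inter-kingdom association set
#'
#' Pairs eukaryote i with bacterium i on disjoint index pairs, the first
#' `n_pos` positive and the next `n_neg` negative, all at one latent
#' correlation magnitude.
#'
#' @param n_pos,n_neg numbers of positive / negative planted pairs.
#' @param magnitude latent basis correlation magnitude, in (0, 1].
#' @return data.frame with columns `euk`, `bact` (1-based indices), `sign`
#'   (`"+"`/`"-"`), `magnitude`.
#' @export
planted_edges <- function(n_pos = 24, n_neg = 16, magnitude = 0.9) {
  n <- n_pos + n_neg
  data.frame(euk = seq_len(n), bact = seq_len(n),
             sign = rep(c("+", "-"), c(n_pos, n_neg)),
             magnitude = rep_len(magnitude, n), stringsAsFactors = FALSE)
}

#' Specification of a synthetic paired-kingdom community
#'
#' Defaults emulate the water habitat of the study design: 48 samples, 406
#' microeukaryotic and 1210 bacterial OTUs (the post-filter table sizes),
#' per-sample depths of 31,781 (18S) and 49,706 (16S) reads, and 40 planted
#' signed inter-kingdom associations of magnitude 0.9 on the latent scale.
#'
#' @param n_samples number of paired samples.
#' @param n_bacteria,n_eukaryotes OTU counts per kingdom.
#' @param depth_bacteria,depth_eukaryotes sequencing depth per sample.
#' @param planted data.frame as from [planted_edges()]; may have zero rows.
#' @param log_mean_sd sd of the per-OTU basis log-mean (abundance
#'   heterogeneity across OTUs).
#' @param log_sd per-OTU sd of basis log-abundance across samples.
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 48, n_bacteria = 1210,
                           n_eukaryotes = 406, depth_bacteria = 49706,
                           depth_eukaryotes = 31781,
                           planted = planted_edges(),
                           log_mean_sd = 1, log_sd = 1, seed = 1) {
  stopifnot(n_samples >= 3, n_bacteria >= 1, n_eukaryotes >= 1,
            depth_bacteria > 0, depth_eukaryotes > 0, log_sd > 0)
  planted <- as.data.frame(planted)
  if (nrow(planted) > 0) {
    if (any(planted$magnitude <= 0 | planted$magnitude > 1))
      stopf("planted correlation magnitudes must lie in (0, 1]")
    if (anyDuplicated(planted[, c("euk", "bact")]))
      stopf("duplicate planted pair")
    if (any(planted$euk < 1 | planted$euk > n_eukaryotes) ||
        any(planted$bact < 1 | planted$bact > n_bacteria))
      stopf("planted edge references a nonexistent OTU")
    if (!all(planted$sign %in% c("+", "-")))
      stopf("planted sign must be '+' or '-'")
  }
  structure(list(n_samples = n_samples, n_bacteria = n_bacteria,
                 n_eukaryotes = n_eukaryotes,
                 depth_bacteria = depth_bacteria,
                 depth_eukaryotes = depth_eukaryotes, planted = planted,
                 log_mean_sd = log_mean_sd, log_sd = log_sd, seed = seed),
            class = "synthetic_spec")
}

#' Generate a paired-kingdom community with planted associations
#'
#' Basis log-abundances are drawn from a multivariate normal whose covariance
#' embeds the planted signed correlations; each kingdom's counts are then
#' drawn multinomially per sample at its stated depth, which reproduces the
#' compositional distortion SparCC is designed to undo.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `eukaryotes` and `bacteria` ([otu_table()]s,
#'   each carrying sampled phylum labels in `$taxonomy`) and `truth`, a list
#'   with the planted edge table (ids attached), the latent basis log
#'   abundance matrix, and the phylum assignment.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ne <- spec$n_eukaryotes; nb <- spec$n_bacteria
  p <- ne + nb
  euk_ids <- sprintf("euk_%04d", seq_len(ne))
  bact_ids <- sprintf("bact_%04d", seq_len(nb))
  ids <- c(euk_ids, bact_ids)
  samples <- sprintf("s%02d", seq_len(spec$n_samples))

  sds <- rep(spec$log_sd, p)
  Sigma <- diag(sds^2, p)
  if (nrow(spec$planted) > 0) {
    i <- spec$planted$euk
    j <- ne + spec$planted$bact
    rho <- ifelse(spec$planted$sign == "+", 1, -1) * spec$planted$magnitude
    Sigma[cbind(i, j)] <- Sigma[cbind(j, i)] <- rho * sds[i] * sds[j]
  }
  L <- tryCatch(chol(Sigma), error = function(e)
    stopf("planted covariance is not positive definite; lower the magnitudes"))

  with_seed(spec$seed, {
    mu <- stats::rnorm(p, 0, spec$log_mean_sd)
    z <- mu + crossprod(L, matrix(stats::rnorm(p * spec$n_samples), p))
    dimnames(z) <- list(ids, samples)

    draw_counts <- function(rows, depth) {
      f <- exp(z[rows, , drop = FALSE])
      f <- sweep(f, 2L, colSums(f), "/")
      cnt <- vapply(seq_len(ncol(f)),
                    function(s) stats::rmultinom(1L, depth, f[, s])[, 1L],
                    integer(length(rows)))
      dimnames(cnt) <- list(rows, samples)
      cnt
    }
    euk_counts <- draw_counts(euk_ids, spec$depth_eukaryotes)
    bact_counts <- draw_counts(bact_ids, spec$depth_bacteria)

    euk_phy <- sample(names(.euk_phyla), ne, replace = TRUE,
                      prob = .euk_phyla / sum(.euk_phyla))
    bact_phy <- sample(names(.bact_phyla), nb, replace = TRUE,
                       prob = .bact_phyla / sum(.bact_phyla))
    tax <- data.frame(
      otu_id = ids,
      kingdom = rep(c("Eukaryota", "Bacteria"), c(ne, nb)),
      phylum = c(euk_phy, bact_phy),
      class = NA_character_, order = NA_character_,
      family = NA_character_, genus = NA_character_,
      stringsAsFactors = FALSE)

    planted <- spec$planted
    if (nrow(planted) > 0) {
      planted$euk_id <- euk_ids[planted$euk]
      planted$bact_id <- bact_ids[planted$bact]
    }
    list(
      eukaryotes = otu_table(euk_counts, "microeukaryote",
                             tax[tax$kingdom == "Eukaryota", ]),
      bacteria = otu_table(bact_counts, "bacteria",
                           tax[tax$kingdom == "Bacteria", ]),
      truth = list(planted = planted, basis = z, taxonomy = tax))
  })
}

#' Perfectly nested binary incidence matrix
#'
#' Builds a prefix ("staircase") matrix whose row fills strictly decrease.
#' With the default square shape every row and column fill is distinct and
#' consecutive, so the NODF of the output is exactly 100.
#'
#' @param n_rows,n_cols matrix shape; `n_rows` must be at least 2 and at most
#'   `n_cols`.
#' @param fill target proportion of ones, or `NULL` for the maximal staircase.
#' @return Binary matrix.
#' @export
generate_nested_incidence <- function(n_rows, n_cols = n_rows, fill = NULL) {
  if (n_rows < 2L) stopf("need at least 2 rows (no row pairs otherwise)")
  if (n_rows > n_cols)
    stopf("strictly decreasing row fills need n_rows <= n_cols")
  if (is.null(fill)) {
    f <- seq(n_cols, by = -1L, length.out = n_rows)
  } else {
    if (fill <= 0 || fill > 1) stopf("fill must be in (0, 1]")
    target <- round(fill * n_rows * n_cols)
    f <- seq(n_rows, 1L)             # minimal strictly decreasing fills
    if (target < sum(f) || target > sum(seq(n_cols, by = -1L,
                                            length.out = n_rows)))
      stopf("fill %.3f infeasible for a strictly nested %dx%d matrix",
            fill, n_rows, n_cols)
    surplus <- target - sum(f)
    for (i in seq_len(n_rows)) {
      cap <- if (i == 1L) n_cols else f[i - 1L] - 1L
      add <- min(surplus, cap - f[i])
      f[i] <- f[i] + add
      surplus <- surplus - add
      if (surplus == 0L) break
    }
  }
  m <- matrix(0L, n_rows, n_cols,
              dimnames = list(paste0("r", seq_len(n_rows)),
                              paste0("c", seq_len(n_cols))))
  for (i in seq_len(n_rows)) m[i, seq_len(f[i])] <- 1L
  m
}

#' Block-diagonal modular incidence matrix
#'
#' Complete bipartite blocks on the diagonal with no inter-block links; the
#' planted module labels are attached as attributes `row_block` / `col_block`.
#'
#' @param blocks number of blocks (at least 2).
#' @param block_rows,block_cols shape of each block.
#' @return Binary matrix with planted-partition attributes.
#' @export
generate_modular_incidence <- function(blocks, block_rows = 2L,
                                       block_cols = 2L) {
  if (blocks < 2L) stopf("need at least 2 blocks")
  m <- kronecker(diag(blocks), matrix(1L, block_rows, block_cols))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("r", seq_len(nrow(m))),
                      paste0("c", seq_len(ncol(m))))
  attr(m, "row_block") <- rep(seq_len(blocks), each = block_rows)
  attr(m, "col_block") <- rep(seq_len(blocks), each = block_cols)
  m
}

#' Write a planted ground-truth edge table
#' @param truth the `truth` element of [generate_community()] output.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$planted
  cols <- c("euk_id", "bact_id", "sign", "magnitude")
  if (nrow(df) == 0) df <- data.frame(euk_id = character(), bact_id = character(),
                                      sign = character(), magnitude = numeric())
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
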