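# Shared fixtures and independent oracles, built in code.

staircase3 <- function() {
  matrix(c(1, 1, 1,
           1, 1, 0,
           1, 0, 0), 3, 3, byrow = TRUE,
         dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
}

named_matrix <- function(m, rp = "r", cp = "c") {
  dimnames(m) <- list(paste0(rp, seq_len(nrow(m))),
                      paste0(cp, seq_len(ncol(m))))
  m
}

tiny_table <- function(counts = matrix(c(3L, 0L, 1L, 5L), 2, byrow = TRUE),
                       kingdom = "bacteria") {
  dimnames(counts) <- list(paste0("otu", seq_len(nrow(counts))),
                           paste0("s", seq_len(ncol(counts))))
  otu_table(counts, kingdom)
}

# quick edge-list builder
make_edges <- function(source, target, rho, p = 0.01) {
  data.frame(source = source, target = target, rho = rho,
             p = rep_len(p, length(rho)),
             sign = ifelse(rho > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

# deterministic binary incidence with exactly L links covering every row/col
incidence_with_links <- function(nr, nc, L, seed = 1) {
  stopifnot(L >= max(nr, nc), L <= nr * nc)
  m <- matrix(0L, nr, nc)
  for (i in seq_len(max(nr, nc))) m[(i - 1) %% nr + 1, (i - 1) %% nc + 1] <- 1L
  need <- L - sum(m)
  if (need > 0) {
    free <- which(m == 0L)
    set.seed(seed)
    m[sample(free, need)] <- 1L
  }
  named_matrix(m)
}

# independent NODF oracle: explicit enumeration of row and column pairs,
# contribution 100 * overlap / smaller fill iff fills strictly decrease
nodf_oracle <- function(m) {
  m <- (m > 0) * 1L
  rf <- rowSums(m); cf <- colSums(m)
  contribs <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m))
    contribs <- c(contribs,
                  if (rf[i] > rf[j] && rf[j] > 0)
                    100 * sum(m[i, ] & m[j, ]) / rf[j] else 0)
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m))
    contribs <- c(contribs,
                  if (cf[i] > cf[j] && cf[j] > 0)
                    100 * sum(m[, i] & m[, j]) / cf[j] else 0)
  mean(contribs)
}

# independent extinction oracle: recompute survivors from scratch per step
extinction_oracle <- function(b, ord) {
  b <- (b > 0) * 1
  y <- c(1, vapply(seq_along(ord), function(k) {
    sub <- b[-ord[seq_len(k)], , drop = FALSE]
    sum(colSums(sub) > 0) / ncol(b)
  }, numeric(1)))
  y
}

# scaled-down community at the planted-recovery study conditions
recovery_community <- function() {
  spec <- synthetic_spec(n_samples = 200, n_bacteria = 60, n_eukaryotes = 30,
                         depth_bacteria = 4500, depth_eukaryotes = 4500,
                         planted = planted_edges(12, 8, 0.9), seed = 42)
  generate_community(spec)
}
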