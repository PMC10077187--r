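#' OTU count table
#'
#' Container for an OTU-by-sample matrix of non-negative integer counts from
#' one marker-gene survey: 16S rRNA gene amplicons for bacteria or the 18S V4
#' region for microeukaryotes. Rows are OTUs (97%-identity clusters used as
#' species proxies), columns are samples.
#'
#' @param counts numeric matrix of non-negative integers with unique rownames
#'   (OTU ids) and colnames (sample ids).
#' @param kingdom either `"bacteria"` or `"microeukaryote"`; tags which marker
#'   the table comes from so that inter-kingdom edges can be identified later.
#' @param taxonomy optional taxonomy table (see [read_taxonomy()]) restricted
#'   to these OTUs.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `kingdom` and `taxonomy`.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 5L), 2, byrow = TRUE,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' otu_table(m, "bacteria")
#' @export
otu_table <- function(counts, kingdom = c("bacteria", "microeukaryote"),
                      taxonomy = NULL) {
  kingdom <- match.arg(kingdom)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stopf("no OTUs: count table has zero rows")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated OTU id: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicated sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("invalid count (negative or non-integer) at OTU '%s', sample '%s'",
          rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, kingdom = kingdom, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table [%s]: %d OTUs x %d samples, %s total counts\n",
              x$kingdom, nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row of sample ids whose first field is the OTU-id column
#' (conventionally `#OTU_ID`), then one row per OTU.
#'
#' @param path file path.
#' @param kingdom `"bacteria"` or `"microeukaryote"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, kingdom = c("bacteria", "microeukaryote")) {
  kingdom <- match.arg(kingdom)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("no OTUs in '%s'", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stopf("duplicated OTU id in '%s': %s", path,
                                ids[duplicated(ids)][1L])
  m <- df[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    v <- suppressWarnings(as.numeric(m[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stopf("non-numeric count at OTU '%s', sample '%s'", ids[i], names(m)[j])
    }
    m[[j]] <- v
  }
  counts <- as.matrix(m)
  rownames(counts) <- ids
  otu_table(counts, kingdom)
}

#' Write an OTU table as tab-separated text
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#OTU_ID", colnames(x$counts)), collapse = "\t"), con)
  utils::write.table(x$counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two tab-separated columns: OTU id, then a semicolon-delimited lineage
#' (kingdom;phylum;class;order;family;genus). Lineages shorter than two ranks
#' are rejected; an empty phylum field is replaced by `"unclassified"`.
#'
#' @param path file path.
#' @return data.frame with columns `otu_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus` (missing deep ranks are `NA`).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  out <- data.frame(otu_id = as.character(df[[1L]]), stringsAsFactors = FALSE)
  lin <- as.character(df[[2L]])
  # rank count from separators, so "Bacteria;" is two ranks (empty phylum)
  nranks <- nchar(lin) - nchar(gsub(";", "", lin, fixed = TRUE)) + 1L
  if (any(nranks < 2L))
    stopf("lineage with fewer than 2 ranks for OTU '%s'",
          out$otu_id[which(nranks < 2L)[1L]])
  parts <- strsplit(lin, ";", fixed = TRUE)
  for (k in seq_along(ranks)) {
    v <- vapply(parts, function(p) if (length(p) >= k) trimws(p[k]) else NA_character_,
                character(1))
    out[[ranks[k]]] <- v
  }
  out$phylum[is.na(out$phylum) | out$phylum == ""] <- "unclassified"
  out
}

#' Write a taxonomy table
#' @param tax data.frame as returned by [read_taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family", "genus"),
                     names(tax))
  lin <- apply(as.matrix(tax[, ranks, drop = FALSE]), 1L,
               function(r) paste(r[!is.na(r)], collapse = ";"))
  utils::write.table(data.frame(tax$otu_id, lin), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep OTUs detected in at least a fraction of samples
#'
#' The study design retains only OTUs detected (count > 0) in at least half of
#' the 48 samples; the threshold is `ceiling(min_fraction * n_samples)`
#' occupied samples, so with 48 samples and the default 0.5 an OTU present in
#' 24 samples is kept and one present in 23 is dropped.
#'
#' @param x an [otu_table()].
#' @param min_fraction required fraction of samples, in (0, 1].
#' @return Filtered [otu_table()]; warns (and returns an empty table) if no
#'   OTU survives.
#' @export
prevalence_filter <- function(x, min_fraction = 0.5) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * ncol(x$counts))
  keep <- rowSums(x$counts > 0L) >= need
  if (!any(keep)) {
    warning("prevalence filter removed every OTU", call. = FALSE)
  }
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  if (!is.null(x$taxonomy))
    out$taxonomy <- x$taxonomy[x$taxonomy$otu_id %in% rownames(out$counts), ,
                               drop = FALSE]
  out
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample column to exactly `depth` reads without replacement
#' (multivariate hypergeometric), the standard rarefaction scheme. The study's
#' tables were rarefied to 31,781 (18S) and 49,706 (16S) reads per sample.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample; must not exceed any sample's total.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return Rarefied [otu_table()]; every column sums to `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  totals <- colSums(x$counts)
  low <- which(totals < depth)
  if (length(low) > 0L)
    stopf("rarefaction depth %d exceeds total (%d) of sample '%s'",
          depth, totals[low[1L]], colnames(x$counts)[low[1L]])
  with_seed(seed, {
    out <- x$counts
    p <- nrow(out)
    for (j in seq_len(ncol(out))) {
      if (totals[j] == depth) next
      pool <- rep.int(seq_len(p), out[, j])
      draw <- sample(pool, depth, replace = FALSE)
      out[, j] <- tabulate(draw, nbins = p)
    }
    y <- x
    y$counts <- out
    y
  })
}

#' Restrict two OTU tables to their shared samples
#'
#' Paired 16S and 18S tables must describe the same biological samples before
#' correlations can be pooled; both tables are subset to the shared sample ids
#' in the order they appear in `a`.
#'
#' @param a,b [otu_table()] objects.
#' @return List with elements `a` and `b`, sample-aligned.
#' @export
align_samples <- function(a, b) {
  stopifnot(inherits(a, "otu_table"), inherits(b, "otu_table"))
  shared <- intersect(colnames(a$counts), colnames(b$counts))
  if (length(shared) < 3L)
    stopf("tables share only %d sample(s); need at least 3", length(shared))
  a$counts <- a$counts[, shared, drop = FALSE]
  b$counts <- b$counts[, shared, drop = FALSE]
  list(a = a, b = b)
}
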