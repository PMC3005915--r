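#' Chromosomal distribution of age-by-disease classes
#'
#' Per chromosome: counts of the four classes Old-NonDisease, Old-Disease,
#' New-NonDisease, New-Disease; the disease proportion with its binomial
#' standard error \eqn{\sqrt{p(1-p)/n}}; mean gene length in kb with the
#' standard error of the mean; and the ranking of chromosomes by disease
#' proportion.
#'
#' @param attrs An attribute table.
#' @param chromosomes Allowed chromosome labels; any other label in the data
#'   is a validation error.
#' @return A list of class \code{chromosome_profile}: per-chromosome
#'   data.frame (ordered as \code{chromosomes}) plus the disease-proportion
#'   ranking.
#' @export
chromosome_class_distribution <- function(attrs,
                                          chromosomes = default_chromosomes()) {
  bad <- setdiff(unique(attrs$chromosome), chromosomes)
  if (length(bad))
    stop(sprintf("unknown chromosome labels: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  rows <- lapply(chromosomes, function(ch) {
    idx <- attrs$chromosome == ch
    n <- sum(idx)
    old <- attrs$age[idx] == "OLD"; dis <- attrs$disease[idx] == "DIS"
    p <- if (n > 0) mean(dis) else NA_real_
    lk <- attrs$length_kb[idx]
    data.frame(chromosome = ch, n = n,
               old_nondisease = sum(old & !dis),
               old_disease = sum(old & dis),
               new_nondisease = sum(!old & !dis),
               new_disease = sum(!old & dis),
               prop_disease = p,
               se_disease = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_,
               mean_length_kb = if (n > 0) mean(lk) else NA_real_,
               se_length_kb = if (n > 1) stats::sd(lk) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$prop_disease)
  structure(list(chromosomes = tab,
                 disease_ranking = tab$chromosome[ord][!is.na(tab$prop_disease[ord])]),
            class = "chromosome_profile")
}

#' @export
print.chromosome_profile <- function(x, ...) {
  print(x$chromosomes, row.names = FALSE, digits = 3)
  cat("disease-proportion ranking:",
      paste(utils::head(x$disease_ranking, 5), collapse = " > "), "...\n")
  invisible(x)
}

#' Chromosome-by-tissue expression count matrix
#'
#' Entry (c, t) = number of genes located on chromosome c and expressed
#' (abundance > 0) in tissue t.
#'
#' @param genes A gene table.
#' @param chromosomes Row order.
#' @return Integer matrix, chromosomes x tissues.
#' @export
chrom_tissue_matrix <- function(genes, chromosomes = default_chromosomes()) {
  cols <- tissue_columns(genes)
  A <- as.matrix(genes[, cols, drop = FALSE]) > 0
  tissues <- attr(genes, "tissues")
  if (is.null(tissues)) tissues <- sub("^tis_", "", cols)
  M <- matrix(0L, length(chromosomes), length(cols),
              dimnames = list(chromosomes, tissues))
  for (i in seq_along(chromosomes)) {
    idx <- genes$chromosome == chromosomes[i]
    if (any(idx)) M[i, ] <- as.integer(colSums(A[idx, , drop = FALSE]))
  }
  M
}

# Deterministic agglomerative clustering with an explicit tie rule: at every
# step merge the pair at minimal linkage distance, ties broken by the
# lexicographically smallest pair of smallest-original-member indices.
# Returns an hclust-compatible object (so stats and ape tooling apply).
agglomerate <- function(D, sizes, linkage) {
  n <- nrow(D)
  active <- seq_len(n)
  id <- -seq_len(n)            # hclust convention: negative = singleton
  minmem <- seq_len(n)         # smallest original row index in each cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  tied <- FALSE
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; bestd <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- D[active[i], active[j]]
      if (d < bestd - 1e-12) {
        bestd <- d; best <- c(i, j); tie_set <- 1L
      } else if (abs(d - bestd) <= 1e-12) {
        tied <- TRUE
        cand <- sort(c(minmem[active[i]], minmem[active[j]]))
        cur <- sort(c(minmem[active[best[1]]], minmem[active[best[2]]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          best <- c(i, j)
        }
      }
    }
    ai <- active[best[1]]; aj <- active[best[2]]
    pair <- sort(c(id[ai], id[aj]))
    merge[step, ] <- pair
    height[step] <- bestd
    # update linkage distances into cluster ai
    for (m in setdiff(active, c(ai, aj))) {
      dnew <- switch(linkage,
        average = (sizes[ai] * D[ai, m] + sizes[aj] * D[aj, m]) /
          (sizes[ai] + sizes[aj]),
        single = min(D[ai, m], D[aj, m]),
        complete = max(D[ai, m], D[aj, m]))
      D[ai, m] <- D[m, ai] <- dnew
    }
    sizes[ai] <- sizes[ai] + sizes[aj]
    minmem[ai] <- min(minmem[ai], minmem[aj])
    id[ai] <- step
    active <- setdiff(active, aj)
  }
  list(merge = merge, height = height, tied = tied)
}

hclust_order <- function(merge) {
  n <- nrow(merge) + 1
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  if (n == 1) return(1L)
  walk(nrow(merge))
}

#' Deterministic hierarchical clustering of a count matrix
#'
#' Agglomerative clustering of the rows of a matrix with an explicit
#' lowest-index tie-break (making the merge tree invariant to input row
#' permutation, up to relabeling). Default: average linkage (UPGMA) on
#' Euclidean distances of row-standardised values (each row z-scored, so
#' the comparison is relative, not absolute; constant rows are flagged
#' degenerate and standardised to zeros).
#'
#' @param M Numeric matrix (at least 2 rows).
#' @param linkage "average", "single" or "complete".
#' @param metric "euclidean" or "manhattan".
#' @param standardise Z-score each row first.
#' @return An object of class \code{c("diseasome_hclust", "hclust")} with
#'   the usual \code{merge}, \code{height}, \code{order}, \code{labels}
#'   fields plus \code{tied} and \code{degenerate} flags.
#' @export
cluster_rows <- function(M, linkage = c("average", "single", "complete"),
                         metric = c("euclidean", "manhattan"),
                         standardise = TRUE) {
  linkage <- match.arg(linkage); metric <- match.arg(metric)
  if (nrow(M) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  X <- M
  degenerate <- FALSE
  if (standardise) {
    s <- apply(X, 1, stats::sd)
    if (any(s == 0)) degenerate <- TRUE
    X <- (X - rowMeans(X)) / ifelse(s == 0, 1, s)
  }
  D <- as.matrix(stats::dist(X, method = metric))
  if (all(D[upper.tri(D)] == D[upper.tri(D)][1]) && nrow(D) > 2)
    degenerate <- TRUE
  agg <- agglomerate(D, sizes = rep(1L, nrow(M)), linkage = linkage)
  structure(list(merge = agg$merge, height = agg$height,
                 order = hclust_order(agg$merge),
                 labels = rownames(M),
                 method = linkage, dist.method = metric,
                 call = match.call(),
                 tied = agg$tied, degenerate = degenerate),
            class = c("diseasome_hclust", "hclust"))
}

#' Two-way clustering of the chromosome-by-tissue matrix
#'
#' Clusters chromosomes (rows) and tissues (columns) of the expression count
#' matrix, as in chromosome-tissue heat maps.
#'
#' @param M Matrix from \code{\link{chrom_tissue_matrix}}.
#' @inheritParams cluster_rows
#' @return A list with \code{row} and \code{col} trees (hclust-compatible)
#'   and the corresponding leaf orders.
#' @export
hierarchical_cluster <- function(M, linkage = "average",
                                 metric = "euclidean", standardise = TRUE) {
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  rowtree <- cluster_rows(M, linkage, metric, standardise)
  coltree <- cluster_rows(t(M), linkage, metric, standardise)
  list(row = rowtree, col = coltree,
       row_order = rowtree$labels[rowtree$order],
       col_order = coltree$labels[coltree$order])
}

#' Merge tree in Newick text form
#'
#' @param tree An hclust-compatible tree (e.g. from
#'   \code{\link{cluster_rows}}).
#' @return A single Newick string (with branch lengths from merge heights).
#' @export
as_newick <- function(tree) {
  class(tree) <- "hclust"
  ape::write.tree(ape::as.phylo(tree))
}
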