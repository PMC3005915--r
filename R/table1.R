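# The published summary contingency table of the 12,753-gene dataset,
# embedded as a fixture. Cells not printed in the original table are NA.

table1_levels <- c("OLD", "NEW", "TSP", "HKP", "EXL", "EXH", "INT", "NIN",
                   "DIS", "NDI", "TFA", "NTF", "PTM", "NPT", "REG", "NRE",
                   "SHO", "LON")

table1_dichotomies <- list(
  age = c("OLD", "NEW"), specificity = c("TSP", "HKP"),
  expression = c("EXL", "EXH"), interaction = c("INT", "NIN"),
  disease = c("DIS", "NDI"), tf = c("TFA", "NTF"), ptm = c("PTM", "NPT"),
  regulator = c("REG", "NRE"), length = c("SHO", "LON"))

#' Construct a contingency matrix object
#'
#' @param counts Symmetric numeric matrix with the attribute levels as
#'   dimnames; diagonal entries are per-level totals, off-diagonal entries
#'   joint counts. NA marks an unknown (unrecorded) pair.
#' @param dichotomies Named list mapping dichotomy name to its two level
#'   codes. Defaults to the nine standard dichotomies.
#' @param extras Named list of auxiliary scalar counts (e.g. higher-order
#'   overlaps that a pairwise matrix cannot hold).
#' @param n_total Total number of genes.
#' @return An object of class \code{contingency_matrix}.
#' @export
contingency_matrix <- function(counts, dichotomies = table1_dichotomies,
                               extras = list(), n_total = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (is.null(rownames(counts)))
    stop("counts must carry level dimnames", call. = FALSE)
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("counts must be symmetric", call. = FALSE)
  bad <- which(!is.na(counts) &
                 counts > pmin(diag(counts)[row(counts)],
                               diag(counts)[col(counts)]))
  if (length(bad))
    stop("a joint count exceeds one of its marginal totals", call. = FALSE)
  structure(list(levels = rownames(counts), counts = counts,
                 dichotomies = dichotomies, extras = extras,
                 n_total = n_total),
            class = "contingency_matrix")
}

#' @export
print.contingency_matrix <- function(x, ...) {
  cat(sprintf("Contingency matrix: %d levels, %s genes\n", length(x$levels),
              if (is.null(x$n_total)) "?" else format(x$n_total)))
  print(x$counts)
  if (length(x$extras)) {
    cat("extras:\n")
    for (nm in names(x$extras)) cat(sprintf("  %s = %s\n", nm, x$extras[[nm]]))
  }
  invisible(x)
}

#' Joint count of two attribute levels
#' @param cm A \code{contingency_matrix}.
#' @param a,b Level codes.
#' @return The stored count (NA if unrecorded).
#' @export
cm_cell <- function(cm, a, b) cm$counts[a, b]

#' Per-level total count
#' @param cm A \code{contingency_matrix}.
#' @param a Level code.
#' @export
cm_total <- function(cm, a) cm$counts[a, a]

#' The published 12,753-gene summary table
#'
#' Returns the embedded all-against-all cross-tabulation of the merged human
#' gene dataset: 18 attribute level totals on the diagonal (e.g. OLD = 8301,
#' DIS = 2522, TFA = 999) and the printed pairwise overlaps off the diagonal
#' (e.g. DIS with TFA = 262). Auxiliary scalars that the pairwise matrix
#' cannot represent are exposed in \code{$extras}: \code{tf_ptm_overlap}
#' (genes that are both TF and PTM-modified, 228), \code{dis_tf_ptm_overlap}
#' (disease genes among those, 72), and \code{tf_ptm_ps5} (those originating
#' in phylostratum 5, 30).
#'
#' Pairs the source table does not print (the REG/NRE rows carry only the
#' length split, and within-dichotomy complements) are NA.
#'
#' @return A \code{\link{contingency_matrix}}.
#' @export
load_table1_fixture <- function() {
  L <- table1_levels
  M <- matrix(NA_real_, 18, 18, dimnames = list(L, L))
  fill <- function(row, cols, vals) {
    M[row, cols] <<- vals
    M[cols, row] <<- vals
  }
  diag(M) <- c(8301, 4452, 3628, 3348, 3599, 3377, 4658, 8095,
               2522, 10231, 999, 11754, 1785, 10968, 2556, 10197,
               6382, 6371)
  fill("OLD", c("TSP", "HKP", "EXL", "EXH", "INT", "NIN", "DIS", "NDI",
                "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(2424, 2648, 2587, 2485, 3445, 4856, 1892, 6409,
         650, 7651, 1310, 6991, 3362, 4939))
  fill("NEW", c("TSP", "HKP", "EXL", "EXH", "INT", "NIN", "DIS", "NDI",
                "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(1204, 700, 1012, 892, 1213, 3239, 630, 3822,
         349, 4103, 475, 3977, 3020, 1432))
  fill("TSP", c("EXL", "EXH", "INT", "NIN", "DIS", "NDI",
                "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(2619, 1009, 1571, 2057, 879, 2749, 304, 3324, 582, 3046, 1719, 1909))
  fill("HKP", c("EXL", "EXH", "INT", "NIN", "DIS", "NDI",
                "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(980, 2368, 1783, 1565, 848, 2500, 347, 3001, 737, 2611, 1144, 2204))
  fill("EXL", c("INT", "NIN", "DIS", "NDI", "TFA", "NTF", "PTM", "NPT",
                "SHO", "LON"),
       c(1543, 2056, 830, 2769, 342, 3257, 565, 3034, 1512, 2087))
  fill("EXH", c("INT", "NIN", "DIS", "NDI", "TFA", "NTF", "PTM", "NPT",
                "SHO", "LON"),
       c(1811, 1566, 897, 2480, 309, 3068, 754, 2623, 1351, 2026))
  fill("INT", c("DIS", "NDI", "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(1524, 3134, 573, 4085, 1335, 3323, 1963, 2695))
  fill("NIN", c("DIS", "NDI", "TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(998, 7097, 426, 7669, 450, 7645, 4419, 3676))
  fill("DIS", c("TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(262, 2260, 607, 1915, 988, 1534))
  fill("NDI", c("TFA", "NTF", "PTM", "NPT", "SHO", "LON"),
       c(737, 9494, 1178, 9053, 5394, 4837))
  fill("TFA", c("PTM", "NPT", "SHO", "LON"), c(228, 771, 493, 506))
  fill("NTF", c("PTM", "NPT", "SHO", "LON"), c(1557, 10197, 5889, 5865))
  fill("PTM", c("SHO", "LON"), c(668, 1117))
  fill("NPT", c("SHO", "LON"), c(5714, 5254))
  fill("REG", c("SHO", "LON"), c(1090, 1466))
  fill("NRE", c("SHO", "LON"), c(5292, 4905))
  contingency_matrix(M, table1_dichotomies,
                     extras = list(tf_ptm_overlap = 228,
                                   dis_tf_ptm_overlap = 72,
                                   tf_ptm_ps5 = 30),
                     n_total = 12753)
}
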