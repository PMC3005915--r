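# level code -> attribute_table column, for cross-tabulation
dichotomy_columns <- c(age = "age", specificity = "specificity",
                       expression = "expression_level",
                       interaction = "interaction", disease = "disease",
                       tf = "tf", ptm = "ptm", regulator = "regulator",
                       length = "length_class")

#' Cross-tabulate all attribute levels against each other
#'
#' Builds the all-against-all contingency matrix over the 18 attribute level
#' codes: diagonal entries are per-level totals, off-diagonal entries the
#' number of genes jointly in both levels. Genes with MISSING tissue status
#' are excluded from any total or cell involving a tissue-based level
#' (TSP/HKP/EXL/EXH) but counted everywhere else; complementary levels of
#' one dichotomy therefore need not sum to the table size for the
#' tissue-based dichotomies. Within-dichotomy complement pairs are 0 by
#' construction. Higher-order overlaps needed for the regulator
#' inclusion-exclusion arithmetic are stored in \code{$extras}.
#'
#' @param attrs An attribute table from \code{\link{derive_attributes}}.
#' @return A \code{\link{contingency_matrix}}.
#' @export
build_contingency <- function(attrs) {
  L <- table1_levels
  ind <- level_indicators(attrs)
  M <- crossprod(ind)                      # counts of joint membership
  M <- M[L, L]
  tf_ptm <- sum(attrs$tf == "TFA" & attrs$ptm == "PTM")
  dis_tf_ptm <- sum(attrs$tf == "TFA" & attrs$ptm == "PTM" &
                      attrs$disease == "DIS")
  tf_ptm_ps5 <- sum(attrs$tf == "TFA" & attrs$ptm == "PTM" &
                      attrs$phylostratum == 5L)
  contingency_matrix(M, table1_dichotomies,
                     extras = list(tf_ptm_overlap = tf_ptm,
                                   dis_tf_ptm_overlap = dis_tf_ptm,
                                   tf_ptm_ps5 = tf_ptm_ps5),
                     n_total = nrow(attrs))
}

# 0/1 membership matrix, genes x 18 level codes (MISSING rows are 0 for the
# tissue-based levels)
level_indicators <- function(attrs) {
  out <- matrix(0, nrow(attrs), length(table1_levels),
                dimnames = list(attrs$gene_id, table1_levels))
  for (lv in table1_levels) {
    d <- names(which(vapply(table1_dichotomies, function(x) lv %in% x,
                            logical(1))))
    out[, lv] <- as.numeric(attrs[[dichotomy_columns[[d]]]] == lv)
  }
  out
}

#' Unpooled two-proportion z-test
#'
#' Two-tailed z-test for the difference between two independent proportions
#' with the unpooled (unequal group variances) standard error
#' \eqn{\sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}. No continuity correction.
#' Alongside the test, the fold change \eqn{p_1/p_2} and the odds ratio are
#' reported, plus the informal "2 percent guide" flag (both groups above
#' 1,000 records and the proportions more than 2 percentage points apart) --
#' a reporting heuristic only, never the decision rule.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return An object of class \code{prop_ztest} with fields \code{k1, n1,
#'   k2, n2, p1, p2, diff, z, p_value, fold, odds_ratio, guide_2pct}.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  if (n1 < 1 || n2 < 1) stop("group sizes must be at least 1", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0) {
    z <- 0; p <- 1
    if (p1 != p2) { z <- sign(p1 - p2) * Inf; p <- 0 }
  } else {
    z <- (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  fold <- if (p2 > 0) p1 / p2 else NA_real_
  or <- if (k2 > 0 && k1 < n1) (k1 / (n1 - k1)) / (k2 / (n2 - k2)) else NA_real_
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
                 diff = p1 - p2, z = z, p_value = p, fold = fold,
                 odds_ratio = or,
                 guide_2pct = n1 > 1000 && n2 > 1000 && abs(p1 - p2) > 0.02),
            class = "prop_ztest")
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat(sprintf("two-proportion z-test (unpooled): %d/%d (%.3f) vs %d/%d (%.3f)\n",
              x$k1, x$n1, x$p1, x$k2, x$n2, x$p2))
  cat(sprintf("  z = %.4f, two-tailed p = %.4g, fold = %.3f, OR = %.3f\n",
              x$z, x$p_value, x$fold, x$odds_ratio))
  invisible(x)
}

#' Regulator count by inclusion-exclusion
#'
#' Size of the union of the TF and PTM gene sets:
#' \code{tfa + ptm - overlap}.
#'
#' @param tfa_count,ptm_count Sizes of the TF and PTM sets.
#' @param overlap_count Genes in both sets.
#' @return The regulator (union) count.
#' @export
regulator_union <- function(tfa_count, ptm_count, overlap_count) {
  if (any(c(tfa_count, ptm_count, overlap_count) < 0) ||
      overlap_count > min(tfa_count, ptm_count))
    stop("overlap must be non-negative and no larger than either set",
         call. = FALSE)
  tfa_count + ptm_count - overlap_count
}

#' Scan every level-vs-dichotomy enrichment
#'
#' For each target level T and each dichotomy (A vs its complement) from a
#' different attribute, compares P(T | A) with P(T | complement of A) by the
#' unpooled two-proportion z-test. Denominators are reconstructed from the
#' matrix itself as cell(A,T) + cell(A, complement of T), so genes missing
#' the target attribute never inflate a denominator. Comparisons whose cells
#' are unrecorded (NA, as in the published fixture) or whose denominators
#' are zero are returned flagged \code{evaluable = FALSE}, not dropped.
#'
#' @param cm A \code{\link{contingency_matrix}}.
#' @param alpha Two-tailed significance level used for the \code{significant}
#'   flag (default 0.05, raw p-values).
#' @param bh If TRUE, add Benjamini-Hochberg adjusted p-values and flag on
#'   those instead.
#' @return A data.frame with one row per (target level, conditioning
#'   dichotomy) pair: counts, proportions, z, p, fold, odds ratio, the
#'   2-percent-guide flag and the significance flag.
#' @export
enrichment_scan <- function(cm, alpha = 0.05, bh = FALSE) {
  res <- list()
  for (target_d in names(cm$dichotomies)) {
    for (T in cm$dichotomies[[target_d]]) {
      Tc <- setdiff(cm$dichotomies[[target_d]], T)
      for (cond_d in setdiff(names(cm$dichotomies), target_d)) {
        A <- cm$dichotomies[[cond_d]][1]; B <- cm$dichotomies[[cond_d]][2]
        k1 <- cm_cell(cm, T, A); n1 <- k1 + cm_cell(cm, Tc, A)
        k2 <- cm_cell(cm, T, B); n2 <- k2 + cm_cell(cm, Tc, B)
        row <- data.frame(target = T, group1 = A, group2 = B,
                          k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                          p1 = NA_real_, p2 = NA_real_, z = NA_real_,
                          p_value = NA_real_, fold = NA_real_,
                          odds_ratio = NA_real_, guide_2pct = NA,
                          evaluable = FALSE, stringsAsFactors = FALSE)
        if (!anyNA(c(k1, n1, k2, n2)) && n1 > 0 && n2 > 0) {
          zt <- two_proportion_ztest(k1, n1, k2, n2)
          row[c("p1", "p2", "z", "p_value", "fold", "odds_ratio")] <-
            zt[c("p1", "p2", "z", "p_value", "fold", "odds_ratio")]
          row$guide_2pct <- zt$guide_2pct
          row$evaluable <- TRUE
        }
        res[[length(res) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, res)
  if (bh) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  } else {
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}

#' Disease enrichment among regulators, by inclusion-exclusion
#'
#' Reconstructs the regulator union from the TF and PTM totals and their
#' overlap, the disease-regulator joint count from the DIS-TFA and DIS-PTM
#' cells and the three-way overlap, and compares P(DIS | REG) with
#' P(DIS | NRE) by the unpooled z-test. This is the arithmetic needed when,
#' as in the published summary table, regulator rows are only partially
#' printed.
#'
#' @param cm A \code{\link{contingency_matrix}} whose extras include
#'   \code{tf_ptm_overlap} and \code{dis_tf_ptm_overlap}.
#' @return A \code{prop_ztest} comparing disease proportions among
#'   regulators vs non-regulators.
#' @export
regulator_disease_comparison <- function(cm) {
  n_total <- cm$n_total
  n_reg <- regulator_union(cm_total(cm, "TFA"), cm_total(cm, "PTM"),
                           cm$extras$tf_ptm_overlap)
  k_reg <- regulator_union(cm_cell(cm, "DIS", "TFA"),
                           cm_cell(cm, "DIS", "PTM"),
                           cm$extras$dis_tf_ptm_overlap)
  k_nre <- cm_total(cm, "DIS") - k_reg
  n_nre <- n_total - n_reg
  two_proportion_ztest(k_reg, n_reg, k_nre, n_nre)
}

#' Worked percentages from a summary contingency matrix
#'
#' Computes the headline percentages derivable from the cross-tabulation and
#' its auxiliary overlap constants: disease proportion among regulators and
#' non-regulators (inclusion-exclusion), the genome-wide TF and disease
#' proportions, the disease proportion among genes that are both TF and
#' PTM-modified, the phylostratum-5 share of that TF-and-PTM set, and the
#' total gene count recovered from complementary dichotomy totals.
#'
#' @param cm A \code{\link{contingency_matrix}} (e.g.
#'   \code{\link{load_table1_fixture}()}).
#' @return Named list of percentages (0-100 scale) and counts.
#' @export
crosstab_summary <- function(cm) {
  rd <- regulator_disease_comparison(cm)
  total_age <- cm_total(cm, "OLD") + cm_total(cm, "NEW")
  total_dis <- cm_total(cm, "DIS") + cm_total(cm, "NDI")
  total_tf <- cm_total(cm, "TFA") + cm_total(cm, "NTF")
  list(
    dis_given_reg_pct = 100 * rd$p1,
    dis_given_nre_pct = 100 * rd$p2,
    dis_reg_vs_nre_p_value = rd$p_value,
    tfa_overall_pct = 100 * cm_total(cm, "TFA") / total_tf,
    dis_overall_pct = 100 * cm_total(cm, "DIS") / total_dis,
    dis_given_tf_and_ptm_pct =
      100 * cm$extras$dis_tf_ptm_overlap / cm$extras$tf_ptm_overlap,
    ps5_given_tf_and_ptm_pct =
      if (is.null(cm$extras$tf_ptm_ps5)) NA_real_ else
        100 * cm$extras$tf_ptm_ps5 / cm$extras$tf_ptm_overlap,
    total_genes_from_age = total_age,
    total_genes_from_disease = total_dis,
    regulator_total = regulator_union(cm_total(cm, "TFA"),
                                      cm_total(cm, "PTM"),
                                      cm$extras$tf_ptm_overlap))
}
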