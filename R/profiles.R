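#' Per-phylostratum regulator profile with genome-wide confidence band
#'
#' For each phylostratum 1..19, the proportion of transcription factors and
#' of PTM-carrying genes among the genes originating there, set against the
#' genome-wide proportions with a 95 percent normal-approximation band
#' \eqn{p \pm z_{\alpha/2}\sqrt{p(1-p)/N}} (N = all genes), as drawn in
#' flat-line stratum profile figures. Strata are flagged over- or
#' under-represented by comparing the stratum proportion to the genome-wide
#' estimate; the default test uses the exact null standard error of that
#' difference, \eqn{\sqrt{\hat p(1-\hat p)(1/n_s - 1/N)}}, which calibrates
#' the flag rate to the nominal level under a uniform-rate null. Setting
#' \code{flag_method = "band"} instead flags strata whose proportion leaves
#' the displayed genome-wide band (a much more liberal rule, kept for
#' figure-faithful output). A Wilson band is available via
#' \code{ci_method}.
#'
#' @param attrs An attribute table.
#' @param conf_level Band/test coverage (default 0.95).
#' @param flag_method "stratum_se" (default) or "band".
#' @param ci_method "normal" (default) or "wilson" for the genome-wide band.
#' @return A list of class \code{stratum_profile}: per-stratum data.frame
#'   (\code{stratum, n, tf_count, tf_prop, tf_flag, ptm_count, ptm_prop,
#'   ptm_flag}; empty strata carry NA proportions) and genome-wide
#'   \code{tf_prop, ptm_prop} with band bounds.
#' @export
stratum_regulator_profile <- function(attrs, conf_level = 0.95,
                                      flag_method = c("stratum_se", "band"),
                                      ci_method = c("normal", "wilson")) {
  flag_method <- match.arg(flag_method)
  ci_method <- match.arg(ci_method)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  N <- nrow(attrs)
  band <- function(k) {
    p <- k / N
    if (ci_method == "normal") {
      h <- zq * sqrt(p * (1 - p) / N)
      c(p = p, low = p - h, high = p + h)
    } else {
      z2 <- zq^2
      centre <- (p + z2 / (2 * N)) / (1 + z2 / N)
      h <- zq * sqrt(p * (1 - p) / N + z2 / (4 * N^2)) / (1 + z2 / N)
      c(p = p, low = centre - h, high = centre + h)
    }
  }
  is_tf <- attrs$tf == "TFA"
  is_ptm <- attrs$ptm == "PTM"
  g_tf <- band(sum(is_tf)); g_ptm <- band(sum(is_ptm))

  flag_one <- function(k, n, gl) {
    # gl = c(p, low, high) genome-wide
    if (n == 0) return(NA_character_)
    ps <- k / n
    if (flag_method == "band") {
      if (ps > gl["high"]) return("over")
      if (ps < gl["low"]) return("under")
      return("none")
    }
    se <- sqrt(gl["p"] * (1 - gl["p"]) * (1 / n - 1 / N))
    if (se == 0) return("none")
    z <- (ps - gl["p"]) / se
    if (z > zq) "over" else if (z < -zq) "under" else "none"
  }

  rows <- lapply(1:19, function(s) {
    idx <- attrs$phylostratum == s
    n <- sum(idx)
    ktf <- sum(is_tf & idx); kptm <- sum(is_ptm & idx)
    data.frame(stratum = s, n = n,
               tf_count = ktf,
               tf_prop = if (n > 0) ktf / n else NA_real_,
               tf_flag = flag_one(ktf, n, g_tf),
               ptm_count = kptm,
               ptm_prop = if (n > 0) kptm / n else NA_real_,
               ptm_flag = flag_one(kptm, n, g_ptm),
               stringsAsFactors = FALSE)
  })
  structure(list(strata = do.call(rbind, rows),
                 genome = data.frame(attribute = c("tf", "ptm"),
                                     prop = c(g_tf["p"], g_ptm["p"]),
                                     band_low = c(g_tf["low"], g_ptm["low"]),
                                     band_high = c(g_tf["high"], g_ptm["high"]),
                                     stringsAsFactors = FALSE),
                 n_total = N, conf_level = conf_level,
                 flag_method = flag_method, ci_method = ci_method),
            class = "stratum_profile")
}

#' @export
print.stratum_profile <- function(x, ...) {
  cat(sprintf("Regulator profile over 19 phylostrata (N = %d, %.0f%% band, flags: %s)\n",
              x$n_total, 100 * x$conf_level, x$flag_method))
  print(x$strata, row.names = FALSE, digits = 3)
  print(x$genome, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-tissue attribute profiles
#'
#' For each tissue: the number and fraction of (expressed) genes expressed
#' there, and among those genes the proportion old, the proportion
#' disease-associated, the mean relative breadth (mean breadth divided by
#' the tissue count -- the share of other tissues where the tissue's genes
#' are also expressed), and the proportion of regulators. Tissues with no
#' expressed gene yield NA entries. Per-statistic extreme tissues are
#' reported.
#'
#' @param genes A gene table.
#' @param attrs The matching attribute table.
#' @return A list of class \code{tissue_profile}: per-tissue data.frame and
#'   an \code{extremes} data.frame (max/min tissue per statistic).
#' @export
tissue_profiles <- function(genes, attrs) {
  cols <- tissue_columns(genes)
  if (!any(attrs$breadth > 0))
    stop("no expressed genes in the table", call. = FALSE)
  tissues <- attr(genes, "tissues")
  if (is.null(tissues)) tissues <- sub("^tis_", "", cols)
  A <- as.matrix(genes[, cols, drop = FALSE]) > 0
  n_expressed_genes <- sum(attrs$breadth > 0)
  old <- attrs$age == "OLD"
  dis <- attrs$disease == "DIS"
  reg <- attrs$regulator == "REG"
  br <- attrs$breadth
  nt <- length(cols)
  rows <- lapply(seq_len(nt), function(k) {
    idx <- A[, k]
    n <- sum(idx)
    if (n == 0)
      return(data.frame(tissue = tissues[k], n_genes = 0L,
                        frac_expressed = 0, prop_old = NA_real_,
                        prop_disease = NA_real_, mean_rel_breadth = NA_real_,
                        prop_regulator = NA_real_, stringsAsFactors = FALSE))
    data.frame(tissue = tissues[k], n_genes = n,
               frac_expressed = n / n_expressed_genes,
               prop_old = mean(old[idx]),
               prop_disease = mean(dis[idx]),
               mean_rel_breadth = mean(br[idx]) / nt,
               prop_regulator = mean(reg[idx]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ext <- do.call(rbind, lapply(
    c("prop_old", "prop_disease", "mean_rel_breadth", "prop_regulator"),
    function(stat) {
      v <- tab[[stat]]
      data.frame(statistic = stat,
                 max_tissue = tab$tissue[which.max(v)],
                 max_value = max(v, na.rm = TRUE),
                 min_tissue = tab$tissue[which.min(v)],
                 min_value = min(v, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  structure(list(tissues = tab, extremes = ext,
                 breadth_reading = "mean breadth of expressed genes / n_tissues"),
            class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  print(x$tissues, row.names = FALSE, digits = 3)
  cat("extremes:\n")
  print(x$extremes, row.names = FALSE, digits = 3)
  invisible(x)
}
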