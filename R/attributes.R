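#' Expression breadth of each gene
#'
#' Number of tissues in which a gene is expressed, i.e. tissues with
#' abundance strictly greater than zero. Genes with an all-zero abundance
#' vector (no expression data) have breadth 0.
#'
#' @param genes A gene table with \code{tis_*} abundance columns.
#' @return Integer vector, one count per gene, in \code{[0, n_tissues]}.
#' @export
breadth <- function(genes) {
  cols <- tissue_columns(genes)
  if (!length(cols)) stop("gene table has no tissue columns", call. = FALSE)
  as.integer(rowSums(as.matrix(genes[, cols, drop = FALSE]) > 0))
}

#' Default dichotomisation thresholds
#'
#' @param age_ps_max Highest phylostratum still counted as OLD (default 2:
#'   genes originating up to eukaryotes, before fungi).
#' @param hk_min_tissues Minimum breadth for the housekeeping class; genes
#'   expressed in fewer tissues are tissue-specific (default 14 of 32).
#' @param long_min_kb Length cut in kb; genes of exactly this length are
#'   classed short (default 24).
#' @param expression_summary How to summarise a gene's abundance across its
#'   expressed tissues before the high/low median split: \code{"max"}
#'   (default) or \code{"mean"}.
#' @return A named list of thresholds.
#' @export
attribute_thresholds <- function(age_ps_max = 2, hk_min_tissues = 14,
                                 long_min_kb = 24,
                                 expression_summary = c("max", "mean")) {
  list(age_ps_max = age_ps_max, hk_min_tissues = hk_min_tissues,
       long_min_kb = long_min_kb,
       expression_summary = match.arg(expression_summary))
}

#' Derive the nine binary gene dichotomies
#'
#' Converts a raw gene table plus an interaction edge list into the standard
#' attribute codes: age (OLD = phylostratum 1-2 / NEW), tissue specificity
#' (TSP = expressed in fewer than \code{hk_min_tissues} tissues / HKP;
#' MISSING when the gene has no expression data), expression level (EXL/EXH,
#' a median split of the per-gene summary abundance over expressed genes;
#' MISSING likewise), interaction status (INT = appears in at least one
#' edge / NIN), disease (DIS/NDI), transcription factor (TFA/NTF),
#' post-translational modification (PTM = at least one PTM / NPT),
#' regulator (REG = TF and/or PTM / NRE), and length (SHO = up to
#' \code{long_min_kb} kb / LON).
#'
#' @param genes A gene table.
#' @param interactions An \code{\link{interaction_set}} (or NULL for no
#'   network: every gene is then NIN).
#' @param thresholds See \code{\link{attribute_thresholds}}.
#' @return A \code{data.frame} (class \code{attribute_table}) with one factor
#'   column per dichotomy plus carried-through \code{phylostratum},
#'   \code{breadth}, \code{chromosome}, \code{length_kb} and \code{gene_id}.
#' @export
derive_attributes <- function(genes, interactions = NULL,
                              thresholds = attribute_thresholds()) {
  if (anyDuplicated(genes$gene_id))
    stop(sprintf("duplicate gene ids: %s",
                 paste(utils::head(unique(genes$gene_id[duplicated(genes$gene_id)]), 10),
                       collapse = ", ")), call. = FALSE)
  if (!is.null(interactions)) {
    bad <- setdiff(unique(c(interactions$from, interactions$to)),
                   genes$gene_id)
    if (length(bad))
      stop(sprintf("edges reference genes absent from the table: %s",
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
  }
  n <- nrow(genes)
  br <- breadth(genes)
  expressed <- br > 0L

  age <- factor(ifelse(genes$phylostratum <= thresholds$age_ps_max,
                       "OLD", "NEW"), levels = c("OLD", "NEW"))
  specificity <- factor(ifelse(!expressed, "MISSING",
                        ifelse(br < thresholds$hk_min_tissues, "TSP", "HKP")),
                        levels = c("TSP", "HKP", "MISSING"))

  cols <- tissue_columns(genes)
  A <- as.matrix(genes[, cols, drop = FALSE])
  summ <- rep(NA_real_, n)
  if (any(expressed)) {
    if (thresholds$expression_summary == "max") {
      summ[expressed] <- apply(A[expressed, , drop = FALSE], 1, max)
    } else {
      summ[expressed] <- rowSums(A[expressed, , drop = FALSE]) / br[expressed]
    }
  }
  med <- stats::median(summ[expressed])
  expression_level <- factor(ifelse(!expressed, "MISSING",
                             ifelse(summ <= med, "EXL", "EXH")),
                             levels = c("EXL", "EXH", "MISSING"))

  in_net <- if (is.null(interactions)) rep(FALSE, n) else
    genes$gene_id %in% c(interactions$from, interactions$to)
  interaction <- factor(ifelse(in_net, "INT", "NIN"), levels = c("INT", "NIN"))
  disease <- factor(ifelse(genes$disease, "DIS", "NDI"),
                    levels = c("DIS", "NDI"))
  tf <- factor(ifelse(genes$tf, "TFA", "NTF"), levels = c("TFA", "NTF"))
  ptm <- factor(ifelse(genes$ptm_count > 0, "PTM", "NPT"),
                levels = c("PTM", "NPT"))
  regulator <- factor(ifelse(genes$tf | genes$ptm_count > 0, "REG", "NRE"),
                      levels = c("REG", "NRE"))
  length_class <- factor(ifelse(genes$length_kb <= thresholds$long_min_kb,
                                "SHO", "LON"), levels = c("SHO", "LON"))

  out <- data.frame(gene_id = genes$gene_id, age = age,
                    specificity = specificity,
                    expression_level = expression_level,
                    interaction = interaction, disease = disease,
                    tf = tf, ptm = ptm, regulator = regulator,
                    length_class = length_class,
                    phylostratum = genes$phylostratum, breadth = br,
                    chromosome = genes$chromosome,
                    length_kb = genes$length_kb,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("attribute_table", "data.frame")
  out
}
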