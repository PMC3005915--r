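#' Default tissue panel
#'
#' The 32 tissues of the MPSS expression atlas used throughout the package,
#' in their conventional order (pancreas first, lung last).
#'
#' @return Character vector of length 32.
#' @export
default_tissues <- function() {
  c("Pancreas", "Kidney", "Pituitary_gland", "Cerebellum", "Fetal_brain",
    "Adrenal_gland", "Amygdala", "Heart", "Brain_caudate_nucleus",
    "Peripheral_blood_lymphocytes", "Thalamus", "Spinal_cord", "Uterus",
    "Brain_corpus_callosum", "Placenta", "Colon", "Stomach", "Monocytes",
    "Hypothalamus", "Prostate", "Bladder", "Salivary_gland", "Thyroid",
    "Small_intestine", "Trachea", "Retina", "Mammary_gland", "Thymus",
    "Bone_marrow", "Testis", "Spleen", "Lung")
}

#' Default chromosome labels
#' @return Character vector: "1".."22", "X", "Y".
#' @export
default_chromosomes <- function() c(as.character(1:22), "X", "Y")

# Default phylostratum weights: ~65.1% of genes originate in ps1-ps2 (the
# "old" class), ~2% in ps3, a metazoan bump at ps5, and a thin decaying tail.
default_stratum_weights <- function() {
  w <- c(0.545, 0.106,                        # ps1, ps2 -> old fraction 0.651
         0.020, 0.024, 0.060, 0.030, 0.025,   # ps3..ps7 (metazoa bump at ps5)
         0.022, 0.020, 0.018, 0.030, 0.015,   # ps8..ps12 (vertebrata at ps11)
         0.013, 0.012, 0.012, 0.012, 0.012, 0.012, 0.012)
  w / sum(w)
}

#' Configuration for the synthetic diseasome generator
#'
#' Builds a validated configuration object describing the joint distribution
#' of per-gene attributes (phylostratum of origin, tissue expression, length,
#' chromosome, disease / transcription-factor / PTM status) and of the
#' gene-gene interaction network. Defaults emulate the statistical structure
#' of the merged human dataset the analysis is designed for: 12,753 genes of
#' which ~65% are old (phylostrata 1-2), ~45% lack tissue-expression data,
#' disease probability raised by age, tissue-specificity and regulator
#' status, TF/PTM rates elevated at phylostrata 3/5/11, old genes longer and
#' better connected, and mild age-assortative interaction mixing.
#'
#' @param n_genes Number of genes to simulate.
#' @param stratum_weights 19 non-negative weights summing to 1; probability a
#'   gene originates in phylostratum 1..19.
#' @param n_tissues Number of tissues in the expression panel.
#' @param tissue_names Tissue labels (length \code{n_tissues}).
#' @param unexpressed_fraction Fraction of genes with no expression data at
#'   all (breadth 0; such genes carry no specificity/expression-level label).
#' @param breadth_params List with elements \code{old} and \code{new}, each
#'   \code{c(shape1, shape2)} of the Beta mixing distribution of a
#'   beta-binomial on \code{n_tissues - 1}; breadth = 1 + that draw, so every
#'   expressed gene is expressed somewhere.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for the
#'   abundance assigned to each expressed (gene, tissue) pair.
#' @param tissue_weights Optional per-tissue selection weights (default
#'   uniform).
#' @param tissue_old_bias Optional named numeric vector of multiplicative
#'   tissue-selection weights applied to old genes only (plants per-tissue
#'   age structure; e.g. \code{c(Pancreas = 2)}).
#' @param disease_log_odds Named vector \code{c(intercept, old, tsp, reg)} of
#'   logistic coefficients for per-gene disease probability. \code{tsp} is
#'   the effect of being tissue-specific (breadth in 1..13); unexpressed
#'   genes get neither the TSP nor the implicit HKP contribution.
#' @param disease_breadth_slope Additive per-tissue slope on the
#'   \emph{probability} scale: disease probability gains
#'   \code{slope * (breadth - mean breadth)} (clipped to (0,1)). Default 0.
#'   A linear-probability term, useful when an exactly linear mediation
#'   pathway through expression breadth is wanted.
#' @param disease_chrom_boost Optional named vector of per-chromosome
#'   log-odds increments to disease probability (e.g. \code{c(X = log(2))}).
#' @param tf_rate_by_stratum,ptm_rate_by_stratum Length-19 vectors of
#'   per-stratum TF / PTM probabilities.
#' @param tf_ptm_overlap_boost Log-odds increment of carrying a PTM given the
#'   gene is a TF (positive values create the observed TF/PTM overlap).
#' @param ptm_count_mean Mean of the Poisson excess over 1 for the PTM count
#'   of PTM-positive genes.
#' @param length_params List with \code{old} and \code{new} elements, each
#'   \code{c(meanlog, sdlog)} of the log-normal gene length in kb.
#' @param chromosomes Chromosome labels.
#' @param chromosome_weights Optional per-chromosome assignment weights
#'   (default uniform).
#' @param degree_effects Named vector \code{c(old, reg)} of multiplicative
#'   effects on a gene's expected degree.
#' @param degree_dispersion Log-normal sd of the per-gene connectivity
#'   propensity (heavy-tailed degrees; 0 = homogeneous).
#' @param n_edges Number of interactions to draw.
#' @param age_homophily Mixing parameter in [0,1]: probability an edge is
#'   forced within an age class (0 = proportionate degree-weighted mixing,
#'   1 = only within-class edges).
#' @param seed Integer seed governing all randomness of the generator.
#'
#' @return An object of class \code{generator_config} (a validated list).
#' @seealso [generate_gene_table()], [generate_interactions()]
#' @export
generator_config <- function(n_genes = 12753,
                             stratum_weights = default_stratum_weights(),
                             n_tissues = 32,
                             tissue_names = default_tissues(),
                             unexpressed_fraction = 1 - 6976 / 12753,
                             breadth_params = list(old = c(1.2, 1.2),
                                                   new = c(0.85, 1.6)),
                             abundance_meanlog = 2,
                             abundance_sdlog = 1,
                             tissue_weights = NULL,
                             tissue_old_bias = NULL,
                             disease_log_odds = c(intercept = stats::qlogis(0.13),
                                                  old = 0.45, tsp = 0.25,
                                                  reg = 0.75),
                             disease_breadth_slope = 0,
                             disease_chrom_boost = NULL,
                             tf_rate_by_stratum = {
                               r <- rep(0.065, 19); r[3] <- 0.286; r[5] <- 0.15; r
                             },
                             ptm_rate_by_stratum = {
                               r <- rep(0.125, 19); r[5] <- 0.25; r[11] <- 0.25; r
                             },
                             tf_ptm_overlap_boost = 0.6,
                             ptm_count_mean = 1,
                             length_params = list(old = c(meanlog = log(30), sdlog = 1.2),
                                                  new = c(meanlog = log(13), sdlog = 1.2)),
                             chromosomes = default_chromosomes(),
                             chromosome_weights = NULL,
                             degree_effects = c(old = 1.5, reg = 1.4),
                             degree_dispersion = 1,
                             n_edges = 55606,
                             age_homophily = 0.3,
                             seed = 1L) {
  cfg <- list(n_genes = n_genes, stratum_weights = stratum_weights,
              n_tissues = n_tissues, tissue_names = tissue_names,
              unexpressed_fraction = unexpressed_fraction,
              breadth_params = breadth_params,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              tissue_weights = tissue_weights,
              tissue_old_bias = tissue_old_bias,
              disease_log_odds = disease_log_odds,
              disease_breadth_slope = disease_breadth_slope,
              disease_chrom_boost = disease_chrom_boost,
              tf_rate_by_stratum = tf_rate_by_stratum,
              ptm_rate_by_stratum = ptm_rate_by_stratum,
              tf_ptm_overlap_boost = tf_ptm_overlap_boost,
              ptm_count_mean = ptm_count_mean,
              length_params = length_params,
              chromosomes = chromosomes,
              chromosome_weights = chromosome_weights,
              degree_effects = degree_effects,
              degree_dispersion = degree_dispersion,
              n_edges = n_edges, age_homophily = age_homophily,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_generator_config <- function(cfg) {
  if (length(cfg$n_genes) != 1 || is.na(cfg$n_genes) || cfg$n_genes < 0)
    config_error("n_genes", "must be a single non-negative count")
  w <- cfg$stratum_weights
  if (length(w) != 19 || any(!is.finite(w)) || any(w < 0))
    config_error("stratum_weights", "must be 19 finite non-negative values")
  if (abs(sum(w) - 1) > 1e-9)
    config_error("stratum_weights", "must sum to 1 (within 1e-9)")
  if (cfg$n_tissues < 1)
    config_error("n_tissues", "must be at least 1")
  if (length(cfg$tissue_names) != cfg$n_tissues)
    config_error("tissue_names", "must have length n_tissues")
  for (f in c("unexpressed_fraction", "age_homophily")) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      config_error(f, "must be a probability in [0,1]")
  }
  for (f in c("tf_rate_by_stratum", "ptm_rate_by_stratum")) {
    v <- cfg[[f]]
    if (length(v) != 19 || any(!is.finite(v)) || any(v < 0 | v > 1))
      config_error(f, "must be 19 probabilities in [0,1]")
  }
  if (any(cfg$degree_effects <= 0))
    config_error("degree_effects", "multipliers must be positive")
  if (cfg$n_edges < 0)
    config_error("n_edges", "must be non-negative")
  if (!is.null(cfg$chromosome_weights) &&
      length(cfg$chromosome_weights) != length(cfg$chromosomes))
    config_error("chromosome_weights", "must match chromosomes in length")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic diseasome generator configuration\n")
  cat(sprintf("  genes: %d   tissues: %d   edges: %d   seed: %d\n",
              x$n_genes, x$n_tissues, x$n_edges, x$seed))
  cat(sprintf("  old fraction (ps1-2 weight): %.3f   unexpressed: %.3f   homophily: %.2f\n",
              sum(x$stratum_weights[1:2]), x$unexpressed_fraction,
              x$age_homophily))
  invisible(x)
}

#' Simulate a per-gene attribute table
#'
#' Draws \code{n_genes} genes with phylostratum of origin, per-tissue MPSS-like
#' abundances, gene length, chromosome, and disease / TF / PTM status, under
#' the generative model described in \code{\link{generator_config}}. The
#' sampling order is: stratum, expression breadth and tissue abundances,
#' TF then PTM (with overlap boost), length, chromosome, and finally disease
#' status as a logistic function of the gene's own OLD / TSP / REG indicators
#' (plus optional breadth slope and chromosome boosts).
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{data.frame} (class \code{gene_table}) with columns
#'   \code{gene_id}, \code{phylostratum}, one \code{tis_<name>} abundance
#'   column per tissue, \code{length_kb}, \code{chromosome}, \code{disease},
#'   \code{tf}, \code{ptm_count}. The tissue display names are kept in the
#'   \code{"tissues"} attribute.
#' @export
generate_gene_table <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  nt <- config$n_tissues
  tis_cols <- paste0("tis_", config$tissue_names)

  if (n == 0) {
    tab <- data.frame(gene_id = character(0), phylostratum = integer(0),
                      stringsAsFactors = FALSE)
    for (cc in tis_cols) tab[[cc]] <- numeric(0)
    tab$length_kb <- numeric(0)
    tab$chromosome <- character(0)
    tab$disease <- logical(0)
    tab$tf <- logical(0)
    tab$ptm_count <- integer(0)
    return(as_gene_table(tab, config$tissue_names))
  }

  ps <- sample.int(19L, n, replace = TRUE, prob = config$stratum_weights)
  old <- ps <= 2L

  # expression: breadth first (beta-binomial, age-dependent), then tissues
  expressed <- stats::runif(n) >= config$unexpressed_fraction
  bp <- config$breadth_params
  sh <- matrix(0, n, 2)
  sh[old, 1] <- bp$old[1];  sh[old, 2] <- bp$old[2]
  sh[!old, 1] <- bp$new[1]; sh[!old, 2] <- bp$new[2]
  pmix <- stats::rbeta(n, sh[, 1], sh[, 2])
  breadth <- ifelse(expressed, 1L + stats::rbinom(n, nt - 1L, pmix), 0L)

  w_base <- config$tissue_weights
  if (is.null(w_base)) w_base <- rep(1, nt)
  w_old <- w_base
  if (!is.null(config$tissue_old_bias)) {
    idx <- match(names(config$tissue_old_bias), config$tissue_names)
    if (anyNA(idx))
      config_error("tissue_old_bias", "names must be tissue names")
    w_old[idx] <- w_old[idx] * config$tissue_old_bias
  }
  abund <- matrix(0, n, nt)
  for (i in which(breadth > 0L)) {
    w <- if (old[i]) w_old else w_base
    sel <- sample.int(nt, breadth[i], prob = w)
    abund[i, sel] <- stats::rlnorm(breadth[i], config$abundance_meanlog,
                                   config$abundance_sdlog)
  }

  tf <- stats::runif(n) < config$tf_rate_by_stratum[ps]
  ptm_eta <- stats::qlogis(pmin(pmax(config$ptm_rate_by_stratum[ps], 1e-12),
                                1 - 1e-12)) +
    config$tf_ptm_overlap_boost * tf
  ptm <- stats::runif(n) < stats::plogis(ptm_eta)
  ptm_count <- ifelse(ptm, 1L + stats::rpois(n, config$ptm_count_mean), 0L)

  lp <- config$length_params
  length_kb <- numeric(n)
  length_kb[old] <- stats::rlnorm(sum(old), lp$old[1], lp$old[2])
  length_kb[!old] <- stats::rlnorm(sum(!old), lp$new[1], lp$new[2])

  chrom <- sample(config$chromosomes, n, replace = TRUE,
                  prob = config$chromosome_weights)

  tsp <- expressed & breadth < 14L
  reg <- tf | ptm
  b <- config$disease_log_odds
  eta <- b[["intercept"]] + b[["old"]] * old + b[["tsp"]] * tsp +
    b[["reg"]] * reg
  if (!is.null(config$disease_chrom_boost)) {
    idx <- match(chrom, names(config$disease_chrom_boost))
    eta <- eta + ifelse(is.na(idx), 0, config$disease_chrom_boost[idx])
  }
  pdis <- stats::plogis(eta)
  if (config$disease_breadth_slope != 0) {
    pdis <- pdis + config$disease_breadth_slope * (breadth - mean(breadth))
    pdis <- pmin(pmax(pdis, 1e-6), 1 - 1e-6)
  }
  disease <- stats::runif(n) < pdis

  tab <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                    phylostratum = ps, stringsAsFactors = FALSE)
  for (k in seq_len(nt)) tab[[tis_cols[k]]] <- abund[, k]
  tab$length_kb <- length_kb
  tab$chromosome <- chrom
  tab$disease <- disease
  tab$tf <- tf
  tab$ptm_count <- ptm_count
  as_gene_table(tab, config$tissue_names)
}

as_gene_table <- function(tab, tissues) {
  attr(tab, "tissues") <- tissues
  class(tab) <- c("gene_table", "data.frame")
  tab
}

#' Tissue abundance columns of a gene table
#' @param genes A gene table.
#' @return Character vector of the \code{tis_*} column names.
#' @export
tissue_columns <- function(genes) {
  grep("^tis_", names(genes), value = TRUE)
}

#' Construct a validated interaction set
#'
#' @param edges Two-column data.frame (or matrix) of gene-id pairs. Edges are
#'   undirected: pairs are canonicalised, self-loops and duplicates rejected.
#' @param gene_ids Optional vector of known gene ids for referential checks.
#' @return A \code{data.frame} of class \code{interaction_set} with columns
#'   \code{from}, \code{to} (with \code{from < to} lexicographically).
#' @export
interaction_set <- function(edges, gene_ids = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list must have two columns", call. = FALSE)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
  from <- pmin(a, b); to <- pmax(a, b)
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edges are not allowed", call. = FALSE)
  if (!is.null(gene_ids)) {
    bad <- setdiff(unique(c(from, to)), gene_ids)
    if (length(bad))
      stop(sprintf("edges reference unknown gene ids: %s",
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
  }
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Simulate an interaction network over a gene table
#'
#' Draws \code{n_edges} undirected simple edges by a degree-weighted
#' (Chung-Lu style) configuration scheme. Each gene carries a connectivity
#' propensity \code{exp(N(0, degree_dispersion)) * old_mult^OLD * reg_mult^REG};
#' a fraction \code{age_homophily} of edges is forced within an age class
#' (class chosen proportionally to its squared stub mass), the rest mix
#' proportionately. Self-loops and duplicate edges are rejected and redrawn.
#'
#' @param genes A gene table from \code{\link{generate_gene_table}}.
#' @param config The same \code{\link{generator_config}} (its seed, offset by
#'   one, governs edge randomness so table and network are jointly
#'   reproducible).
#' @return An \code{\link{interaction_set}}.
#' @export
generate_interactions <- function(genes, config) {
  validate_generator_config(config)
  m <- as.integer(config$n_edges)
  n <- nrow(genes)
  if (anyDuplicated(genes$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  if (m == 0L)
    return(interaction_set(data.frame(from = character(0), to = character(0))))
  if (n < 2)
    stop("cannot generate interactions: need at least 2 genes for a positive edge count",
         call. = FALSE)
  if (m > n * (n - 1) / 2)
    stop("requested more edges than distinct gene pairs exist", call. = FALSE)
  set.seed(config$seed + 1L)

  old <- genes$phylostratum <= 2L
  reg <- genes$tf | genes$ptm_count > 0L
  w <- exp(stats::rnorm(n, 0, config$degree_dispersion)) *
    config$degree_effects[["old"]]^old * config$degree_effects[["reg"]]^reg

  n_hom <- stats::rbinom(1, m, config$age_homophily)
  w_old_mass <- sum(w[old]); w_new_mass <- sum(w[!old])
  idx_old <- which(old); idx_new <- which(!old)

  draw_batch <- function(k_prop, k_hom) {
    i <- integer(0); j <- integer(0)
    if (k_prop > 0) {
      i <- sample.int(n, k_prop, replace = TRUE, prob = w)
      j <- sample.int(n, k_prop, replace = TRUE, prob = w)
    }
    if (k_hom > 0) {
      p_old_class <- w_old_mass^2 / (w_old_mass^2 + w_new_mass^2)
      in_old <- stats::runif(k_hom) < p_old_class
      k_o <- sum(in_old); k_n <- k_hom - k_o
      if (k_o > 0 && length(idx_old) >= 2) {
        i <- c(i, sample(idx_old, k_o, replace = TRUE, prob = w[idx_old]))
        j <- c(j, sample(idx_old, k_o, replace = TRUE, prob = w[idx_old]))
      } else if (k_o > 0) {
        stop("cannot place within-class edges: old class has < 2 genes",
             call. = FALSE)
      }
      if (k_n > 0 && length(idx_new) >= 2) {
        i <- c(i, sample(idx_new, k_n, replace = TRUE, prob = w[idx_new]))
        j <- c(j, sample(idx_new, k_n, replace = TRUE, prob = w[idx_new]))
      } else if (k_n > 0) {
        stop("cannot place within-class edges: new class has < 2 genes",
             call. = FALSE)
      }
    }
    cbind(pmin(i, j), pmax(i, j))
  }

  frac_hom <- if (m > 0) n_hom / m else 0
  acc <- matrix(integer(0), 0, 2)
  seen <- character(0)
  for (attempt in 1:80) {
    need <- m - nrow(acc)
    if (need <= 0) break
    k <- ceiling(need * 1.25)
    kh <- round(k * frac_hom)
    batch <- draw_batch(k - kh, kh)
    batch <- batch[batch[, 1] != batch[, 2], , drop = FALSE]
    key <- paste(batch[, 1], batch[, 2])
    keep <- !duplicated(key) & !(key %in% seen)
    batch <- batch[keep, , drop = FALSE]
    if (nrow(batch) > need) batch <- batch[seq_len(need), , drop = FALSE]
    seen <- c(seen, paste(batch[, 1], batch[, 2]))
    acc <- rbind(acc, batch)
  }
  if (nrow(acc) < m)
    stop(sprintf("could not place %d unique edges (placed %d); the weight structure is too concentrated",
                 m, nrow(acc)), call. = FALSE)
  interaction_set(data.frame(from = genes$gene_id[acc[, 1]],
                             to = genes$gene_id[acc[, 2]],
                             stringsAsFactors = FALSE))
}
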