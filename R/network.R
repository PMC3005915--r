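#' Per-gene connection counts
#'
#' Degree of every gene in the interaction network; genes absent from all
#' edges get degree 0. The graph is handled through igraph.
#'
#' @param interactions An \code{\link{interaction_set}}.
#' @param attrs An attribute table (supplies the gene universe; every edge
#'   endpoint must be present in it).
#' @return Named integer vector of degrees, one per gene, in table order.
#' @export
degrees <- function(interactions, attrs) {
  bad <- setdiff(unique(c(interactions$from, interactions$to)), attrs$gene_id)
  if (length(bad))
    stop(sprintf("edges reference unknown genes: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  g <- igraph::graph_from_data_frame(interactions, directed = FALSE,
                                     vertices = attrs$gene_id)
  d <- igraph::degree(g)
  d[attrs$gene_id]
}

#' Least-squares means of connectivity across attribute factors
#'
#' Fits a linear model of per-gene degree on the crossed attribute factors
#' (default: age, regulator, specificity, disease; additive main effects,
#' optionally with all two-way interactions) and reports, for each factor
#' level, the least-squares mean: the model prediction averaged over an
#' equally-weighted grid of the other factors' levels. Each within-factor
#' contrast is tested by a two-sided t-test on the model's residual degrees
#' of freedom. By default only interacting genes (INT) enter, and genes with
#' MISSING tissue status are dropped when specificity is among the factors.
#'
#' @param deg Named degree vector as from \code{\link{degrees}}.
#' @param attrs The attribute table.
#' @param factors Attribute columns to cross.
#' @param interacting_only Restrict to genes with at least one edge.
#' @param two_way Include all two-way factor interactions.
#' @param log1p_response Model \code{log1p(degree)} instead of the raw count.
#' @return A list of class \code{lsmeans_result} with data.frames
#'   \code{means} (factor, level, lsmean, se, n) and \code{contrasts}
#'   (factor, level pair, difference, t, df, p_value), plus the fitted lm.
#' @export
lsmeans_connectivity <- function(deg, attrs,
                                 factors = c("age", "regulator",
                                             "specificity", "disease"),
                                 interacting_only = TRUE,
                                 two_way = FALSE,
                                 log1p_response = FALSE) {
  dat <- as.data.frame(attrs)[, factors, drop = FALSE]
  dat$.degree <- as.numeric(deg)
  keep <- rep(TRUE, nrow(dat))
  if (interacting_only) keep <- keep & dat$.degree > 0
  for (f in factors) {
    if (is.factor(dat[[f]]) && "MISSING" %in% levels(dat[[f]]))
      keep <- keep & dat[[f]] != "MISSING"
  }
  dat <- dat[keep, , drop = FALSE]
  for (f in factors) dat[[f]] <- droplevels(factor(dat[[f]]))
  short <- vapply(dat[factors], function(x) nlevels(x) < 2, logical(1))
  if (any(short))
    stop(sprintf("factor(s) with fewer than 2 observed levels: %s",
                 paste(factors[short], collapse = ", ")), call. = FALSE)
  if (log1p_response) dat$.degree <- log1p(dat$.degree)
  rhs <- paste(factors, collapse = if (two_way) " * " else " + ")
  if (two_way && length(factors) > 2)
    rhs <- paste0("(", paste(factors, collapse = " + "), ")^2")
  fit <- stats::lm(stats::as.formula(paste(".degree ~", rhs)), data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop(paste("inestimable least-squares means: empty design cells leave",
               "coefficients", paste(names(beta)[is.na(beta)], collapse = ", "),
               "aliased"), call. = FALSE)
  V <- stats::vcov(fit)
  grid <- expand.grid(lapply(dat[factors], levels), KEEP.OUT.ATTRS = FALSE)
  Xg <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)

  lsvec <- function(f, lev) colMeans(Xg[grid[[f]] == lev, , drop = FALSE])
  means <- list(); contrasts <- list()
  for (f in factors) {
    for (lev in levels(dat[[f]])) {
      a <- lsvec(f, lev)
      means[[length(means) + 1L]] <-
        data.frame(factor = f, level = lev,
                   lsmean = drop(a %*% beta),
                   se = sqrt(drop(t(a) %*% V %*% a)),
                   n = sum(dat[[f]] == lev), stringsAsFactors = FALSE)
    }
    lv <- levels(dat[[f]])
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      a <- lsvec(f, lv[i]) - lsvec(f, lv[j])
      est <- drop(a %*% beta)
      se <- sqrt(drop(t(a) %*% V %*% a))
      tval <- est / se
      contrasts[[length(contrasts) + 1L]] <-
        data.frame(factor = f, level1 = lv[i], level2 = lv[j],
                   difference = est, t = tval, df = fit$df.residual,
                   p_value = 2 * stats::pt(-abs(tval), fit$df.residual),
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(means = do.call(rbind, means),
                 contrasts = do.call(rbind, contrasts),
                 model = fit, n = nrow(dat),
                 response = if (log1p_response) "log1p(degree)" else "degree"),
            class = "lsmeans_result")
}

#' @export
print.lsmeans_result <- function(x, ...) {
  cat(sprintf("Least-squares means of %s (n = %d genes)\n", x$response, x$n))
  print(x$means, row.names = FALSE)
  cat("contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Age-class mixing of the interaction network
#'
#' Observed fractions of old-old, old-new and new-new edges, their expected
#' fractions under degree-weighted proportionate mixing (products of the
#' age-class stub fractions), the within-class excess, and a permutation
#' p-value obtained by shuffling age labels over genes (expectations are
#' recomputed for every shuffle, so the test is exact for the label
#' assignment null given the graph).
#'
#' @param interactions An \code{\link{interaction_set}}.
#' @param attrs The attribute table.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation stream.
#' @return A list of class \code{mixing_result}: \code{observed},
#'   \code{expected} (each a named vector over oldold/oldnew/newnew),
#'   \code{excess_within}, \code{p_value} (one-sided, for positive
#'   within-class excess), \code{degenerate} flag.
#' @export
age_mixing <- function(interactions, attrs, n_perm = 1000, seed = 1L) {
  if (nrow(interactions) < 1) stop("need at least one edge", call. = FALSE)
  old <- stats::setNames(attrs$age == "OLD", attrs$gene_id)
  ia <- old[interactions$from]; ib <- old[interactions$to]
  if (anyNA(ia) || anyNA(ib))
    stop("edges reference genes absent from the attribute table",
         call. = FALSE)
  deg <- degrees(interactions, attrs)

  mix_stats <- function(is_old) {
    a <- is_old[interactions$from]; b <- is_old[interactions$to]
    obs <- c(oldold = mean(a & b), oldnew = mean(xor(a, b)),
             newnew = mean(!a & !b))
    s_old <- sum(deg[is_old[attrs$gene_id]]) / sum(deg)
    exp <- c(oldold = s_old^2, oldnew = 2 * s_old * (1 - s_old),
             newnew = (1 - s_old)^2)
    list(obs = obs, exp = exp,
         excess = (obs["oldold"] + obs["newnew"]) -
           (exp["oldold"] + exp["newnew"]))
  }
  base <- mix_stats(old)
  degenerate <- all(ia & ib) || all(!ia & !ib)

  set.seed(seed)
  perm_excess <- replicate(n_perm, {
    shuffled <- stats::setNames(sample(unname(old)), names(old))
    mix_stats(shuffled)$excess
  })
  p <- (1 + sum(perm_excess >= base$excess)) / (n_perm + 1)
  structure(list(observed = base$obs, expected = base$exp,
                 excess_within = unname(base$excess), p_value = p,
                 perm_excess = perm_excess, n_perm = n_perm,
                 degenerate = degenerate), class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  m <- rbind(observed = x$observed, expected = x$expected)
  print(round(m, 4))
  cat(sprintf("within-class excess = %.4f, permutation p = %.4g (%d shuffles)%s\n",
              x$excess_within, x$p_value, x$n_perm,
              if (x$degenerate) " [degenerate: single age class]" else ""))
  invisible(x)
}

#' Mean phylostratum of interaction partners, by age class
#'
#' For each interacting gene, the mean phylostratum of its partners; class
#' summaries (mean over OLD genes and over NEW genes) with a percentile
#' bootstrap interval obtained by resampling genes within class.
#'
#' @param interactions An \code{\link{interaction_set}}.
#' @param genes A gene table (phylostrata).
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param conf_level Interval coverage.
#' @return Data.frame with one row per age class: n genes, mean partner
#'   stratum, bootstrap CI bounds.
#' @export
partner_stratum_profile <- function(interactions, genes, n_boot = 1000,
                                    seed = 1L, conf_level = 0.95) {
  if (nrow(interactions) < 1) stop("need at least one edge", call. = FALSE)
  ps <- stats::setNames(genes$phylostratum, genes$gene_id)
  if (anyNA(ps[interactions$from]) || anyNA(ps[interactions$to]))
    stop("edges reference genes absent from the gene table", call. = FALSE)
  ends <- data.frame(gene = c(interactions$from, interactions$to),
                     partner = c(interactions$to, interactions$from),
                     stringsAsFactors = FALSE)
  per_gene <- tapply(ps[ends$partner], ends$gene, mean)
  cls <- ifelse(ps[names(per_gene)] <= 2, "OLD", "NEW")
  alpha <- (1 - conf_level) / 2
  set.seed(seed)
  out <- lapply(c("OLD", "NEW"), function(cl) {
    v <- per_gene[cls == cl]
    if (!length(v))
      return(data.frame(class = cl, n = 0L, mean_partner_stratum = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    boots <- replicate(n_boot, mean(sample(v, replace = TRUE)))
    data.frame(class = cl, n = length(v), mean_partner_stratum = mean(v),
               ci_low = unname(stats::quantile(boots, alpha)),
               ci_high = unname(stats::quantile(boots, 1 - alpha)))
  })
  do.call(rbind, out)
}

#' Within- versus between-class edge density
#'
#' Cohesion of a gene class: within-class density = within-class edges over
#' all within-class pairs; between-class density = cross edges over all
#' cross pairs (class members vs all other genes); their ratio.
#'
#' @param interactions An \code{\link{interaction_set}}.
#' @param attrs The attribute table.
#' @param class_label One of the 18 level codes (e.g. "NEW").
#' @return A list: class size, densities, ratio, and the raw edge counts; or
#'   a not-evaluable marker when the class has fewer than 2 members.
#' @export
cohesion <- function(interactions, attrs, class_label) {
  d <- names(which(vapply(table1_dichotomies, function(x) class_label %in% x,
                          logical(1))))
  if (!length(d))
    stop(sprintf("unknown class label '%s'", class_label), call. = FALSE)
  members <- attrs$gene_id[attrs[[dichotomy_columns[[d]]]] == class_label]
  n_in <- length(members); n_out <- nrow(attrs) - n_in
  if (n_in < 2)
    return(list(class = class_label, n = n_in, evaluable = FALSE))
  a_in <- interactions$from %in% members
  b_in <- interactions$to %in% members
  e_within <- sum(a_in & b_in)
  e_between <- sum(xor(a_in, b_in))
  within_density <- e_within / choose(n_in, 2)
  between_density <- if (n_out > 0) e_between / (n_in * n_out) else NA_real_
  list(class = class_label, n = n_in, evaluable = TRUE,
       within_edges = e_within, between_edges = e_between,
       within_density = within_density, between_density = between_density,
       ratio = if (!is.na(between_density) && between_density > 0)
         within_density / between_density else NA_real_,
       definition = "within-class edge density")
}
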