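#' Pearson correlation with a t-based two-tailed p-value
#'
#' Standard product-moment correlation; for 0/1-coded dichotomies this is
#' the point-biserial / phi coefficient as a special case. Significance from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A list of class \code{correlation_result}: \code{r}, \code{n},
#'   \code{p_value}, \code{conditioned_on} (NA here), \code{evaluable}
#'   (FALSE when either input has zero variance).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(correlation_result(NA_real_, n, NA_real_, evaluable = FALSE))
  r <- stats::cor(x, y)
  correlation_result(r, n, cor_pvalue(r, df = n - 2))
}

cor_pvalue <- function(r, df) {
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

correlation_result <- function(r, n, p, conditioned_on = NA_character_,
                               evaluable = TRUE) {
  structure(list(r = r, n = n, p_value = p, conditioned_on = conditioned_on,
                 evaluable = evaluable), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cond <- if (is.na(x$conditioned_on)) "" else
    sprintf(" | %s", x$conditioned_on)
  cat(sprintf("r%s = %.4f (n = %d, two-tailed p = %.4g)\n", cond, x$r, x$n,
              x$p_value))
  invisible(x)
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear contribution of a
#' single conditioning variable z:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' with significance from a t statistic on \eqn{n-3} degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length (at least 4).
#' @param conditioned_on Label recorded in the result.
#' @return A \code{correlation_result}.
#' @export
partial_cor <- function(x, y, z, conditioned_on = "z") {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    return(correlation_result(NA_real_, n, NA_real_, conditioned_on,
                              evaluable = FALSE))
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  num <- rxy - rxz * ryz
  if (den2 < 1e-12) {
    # a variable collinear with z: its residual variance is zero. The
    # numerator then vanishes identically (fully explained) and the partial
    # correlation is 0; anything else is genuinely degenerate conditioning.
    if (abs(num) < 1e-8)
      return(correlation_result(0, n, 1, conditioned_on))
    stop("degenerate conditioning: a variable is collinear with z",
         call. = FALSE)
  }
  r <- num / sqrt(den2)
  r <- min(max(r, -1), 1)
  correlation_result(r, n, cor_pvalue(r, df = n - 3), conditioned_on)
}

# numeric codings used by correlation_matrix; dichotomies coded 0/1 with the
# "marked" level (OLD, DIS, REG, INT, TFA, PTM, HKP, EXH) as 1
attribute_codings <- function(attrs, var) {
  switch(var,
    age = as.numeric(attrs$age == "OLD"),
    disease = as.numeric(attrs$disease == "DIS"),
    regulator = as.numeric(attrs$regulator == "REG"),
    interaction = as.numeric(attrs$interaction == "INT"),
    tf = as.numeric(attrs$tf == "TFA"),
    ptm = as.numeric(attrs$ptm == "PTM"),
    specificity = ifelse(attrs$specificity == "MISSING", NA_real_,
                         as.numeric(attrs$specificity == "HKP")),
    expression_level = ifelse(attrs$expression_level == "MISSING", NA_real_,
                              as.numeric(attrs$expression_level == "EXH")),
    breadth = ifelse(attrs$breadth == 0, NA_real_,
                     as.numeric(attrs$breadth)),
    length_kb = attrs$length_kb,
    stop(sprintf("unknown correlation variable '%s'", var), call. = FALSE))
}

#' Correlation matrix over attribute codings
#'
#' Pairwise Pearson correlations (optionally partial, conditional on one
#' variable such as expression breadth) among selected gene attributes.
#' Dichotomies are coded 0/1; breadth and length enter as numeric. Genes
#' lacking tissue data are dropped listwise whenever any selected or
#' conditioning variable involves expression (breadth, specificity,
#' expression level), matching the reduced denominators of tissue-based
#' tabulations.
#'
#' @param attrs An attribute table.
#' @param vars Variables to correlate; any of \code{age, disease, breadth,
#'   length_kb, regulator, interaction, tf, ptm, specificity,
#'   expression_level}.
#' @param conditioning Optional single variable name to condition every pair
#'   on (must not itself be in \code{vars}).
#' @return A list with matrices \code{r} and \code{p_value}, the common
#'   \code{n}, and \code{conditioning}.
#' @export
correlation_matrix <- function(attrs,
                               vars = c("age", "disease", "breadth",
                                        "length_kb", "regulator",
                                        "interaction"),
                               conditioning = NULL) {
  if (!is.null(conditioning)) {
    if (conditioning %in% vars)
      stop("conditioning variable must not be among the correlated variables",
           call. = FALSE)
  }
  tissue_vars <- c("breadth", "specificity", "expression_level")
  X <- sapply(vars, function(v) attribute_codings(attrs, v))
  zvec <- if (is.null(conditioning)) NULL else
    attribute_codings(attrs, conditioning)
  involved <- c(vars, conditioning)
  if (any(involved %in% tissue_vars)) {
    keep <- attrs$breadth > 0
    X <- X[keep, , drop = FALSE]
    if (!is.null(zvec)) zvec <- zvec[keep]
  }
  keep <- stats::complete.cases(X)
  if (!is.null(zvec)) keep <- keep & !is.na(zvec)
  X <- X[keep, , drop = FALSE]
  if (!is.null(zvec)) zvec <- zvec[keep]
  k <- length(vars)
  R <- diag(1, k); P <- matrix(NA_real_, k, k)
  dimnames(R) <- dimnames(P) <- list(vars, vars)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    res <- if (is.null(zvec)) pearson_cor(X[, i], X[, j]) else
      partial_cor(X[, i], X[, j], zvec, conditioned_on = conditioning)
    R[i, j] <- R[j, i] <- res$r
    P[i, j] <- P[j, i] <- res$p_value
  }
  list(r = R, p_value = P, n = nrow(X),
       conditioning = if (is.null(conditioning)) NA_character_ else conditioning)
}
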