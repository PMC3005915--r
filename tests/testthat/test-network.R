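degrees_brute <- function(e, ids) {
  sapply(ids, function(g) sum(e$from == g) + sum(e$to == g))
}

test_that("degrees match hand-built and brute-force counts", {
  g <- tiny_gene_table(rep(1, 6), matrix(1, 6, 4))
  tri <- edge_df("g001", "g002", "g002", "g003", "g001", "g003")
  a <- derive_attributes(g, tri)
  expect_equal(unname(degrees(tri, a)[1:3]), c(2, 2, 2))
  star <- edge_df("g001", "g002", "g001", "g003", "g001", "g004",
                  "g001", "g005", "g001", "g006")
  a2 <- derive_attributes(g, star)
  d <- degrees(star, a2)
  expect_equal(unname(d["g001"]), 5)
  expect_equal(unname(d[paste0("g00", 2:6)]), rep(1, 5))
  # genes in no edge have degree 0 and class NIN
  expect_equal(unname(degrees(tri, a)[4:6]), c(0, 0, 0))
  expect_true(all(a$interaction[4:6] == "NIN"))

  cfg <- small_config(seed = 19)
  gg <- generate_gene_table(cfg)
  ee <- generate_interactions(gg, cfg)
  aa <- derive_attributes(gg, ee)
  expect_equal(unname(degrees(ee, aa)),
               unname(degrees_brute(ee, gg$gene_id)))
  expect_equal(sum(degrees(ee, aa)), 2 * nrow(ee))
  expect_error(degrees(edge_df("g001", "nope"), a), "nope")
})

test_that("least-squares means collapse to raw group means under balance", {
  # perfectly balanced 2x2: adjustment changes nothing
  dat <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  dat <- dat[rep(1:4, each = 10), ]
  set.seed(5)
  dat$y <- 2 + (dat$A == "a2") * 3 + (dat$B == "b2") * 1 + rnorm(40, 0, 0.5)
  attrs <- data.frame(age = dat$A, regulator = dat$B)
  l <- lsmeans_connectivity(setNames(dat$y, NULL), attrs,
                            factors = c("age", "regulator"),
                            interacting_only = FALSE)
  raw <- tapply(dat$y, dat$A, mean)
  got <- l$means[l$means$factor == "age", ]
  expect_equal(got$lsmean[got$level == "a1"], unname(raw["a1"]),
               tolerance = 1e-10)
  expect_equal(got$lsmean[got$level == "a2"], unname(raw["a2"]),
               tolerance = 1e-10)
})

test_that("unbalanced two-way LS means equal equally-weighted cell means", {
  # hand-computable unbalanced 2x2 with interaction: LS mean of level a is
  # the plain average of its two cell means (saturated model)
  cells <- list(c(10, 12), c(20), c(5, 5, 5, 7), c(30, 34))
  A <- rep(c("a", "a", "b", "b"), lengths(cells))
  B <- rep(c("x", "y", "x", "y"), lengths(cells))
  y <- unlist(cells)
  attrs <- data.frame(age = A, disease = B)
  l <- lsmeans_connectivity(y, attrs, factors = c("age", "disease"),
                            interacting_only = FALSE, two_way = TRUE)
  cm <- tapply(y, list(A, B), mean)
  expect_equal(l$means$lsmean[l$means$factor == "age" & l$means$level == "a"],
               mean(cm["a", ]), tolerance = 1e-10)
  expect_equal(l$means$lsmean[l$means$factor == "age" & l$means$level == "b"],
               mean(cm["b", ]), tolerance = 1e-10)
  con <- l$contrasts[l$contrasts$factor == "age", ]
  expect_equal(con$difference, mean(cm["a", ]) - mean(cm["b", ]),
               tolerance = 1e-10)
})

test_that("the LS-means engine agrees with emmeans on a random unbalanced design", {
  skip_if_not_installed("emmeans")
  set.seed(6)
  n <- 300
  attrs <- data.frame(age = sample(c("OLD", "NEW"), n, TRUE, c(0.7, 0.3)),
                      regulator = sample(c("REG", "NRE"), n, TRUE, c(0.2, 0.8)),
                      disease = sample(c("DIS", "NDI"), n, TRUE, c(0.3, 0.7)))
  y <- 5 + 2 * (attrs$age == "OLD") + 1.2 * (attrs$regulator == "REG") +
    rnorm(n)
  l <- lsmeans_connectivity(y, attrs,
                            factors = c("age", "regulator", "disease"),
                            interacting_only = FALSE)
  fit <- lm(y ~ age + regulator + disease, data = attrs)
  em <- as.data.frame(emmeans::emmeans(fit, "age"))
  for (lev in em$age) {
    mine <- l$means[l$means$factor == "age" & l$means$level == lev, ]
    expect_equal(mine$lsmean, em$emmean[em$age == lev], tolerance = 1e-8)
    expect_equal(mine$se, em$SE[em$age == lev], tolerance = 1e-8)
  }
})

test_that("empty design cells yield an explicit inestimability error", {
  attrs <- data.frame(age = c("OLD", "OLD", "NEW", "NEW"),
                      regulator = c("REG", "REG", "NRE", "NRE"))
  y <- c(1, 2, 3, 4)
  expect_error(lsmeans_connectivity(y, attrs, factors = c("age", "regulator"),
                                    interacting_only = FALSE),
               "inestimable|aliased")
})

test_that("mixing fractions are well-formed and degenerate networks flagged", {
  g <- tiny_gene_table(rep(1, 4), matrix(1, 4, 4))
  e <- edge_df("g001", "g002", "g003", "g004")
  a <- derive_attributes(g, e)
  m <- age_mixing(e, a, n_perm = 20, seed = 1)
  expect_equal(unname(m$observed["oldold"]), 1)
  expect_true(m$degenerate)
  expect_equal(sum(m$observed), 1)
  expect_equal(sum(m$expected), 1)
})

test_that("random age labels on a fixed graph show no mixing excess", {
  cfg <- small_config(seed = 23, n_genes = 800, n_edges = 3000,
                      age_homophily = 0, degree_effects = c(old = 1, reg = 1))
  g <- generate_gene_table(cfg)
  # break any residual age-degree coupling by randomising strata afterwards
  set.seed(77)
  g$phylostratum <- sample(g$phylostratum)
  e <- generate_interactions(g, cfg)
  a <- derive_attributes(g, e)
  m <- age_mixing(e, a, n_perm = 300, seed = 2)
  perm_se <- sd(m$perm_excess)
  expect_lt(abs(m$excess_within), 3 * perm_se + 1e-8)
})

test_that("planted homophily produces detectable within-class excess", {
  cfg <- generator_config(n_genes = 4000, n_edges = 16000, seed = 25,
                          age_homophily = 0.8)
  g <- generate_gene_table(cfg)
  e <- generate_interactions(g, cfg)
  a <- derive_attributes(g, e)
  m <- age_mixing(e, a, n_perm = 199, seed = 3)
  expect_gt(m$observed["oldold"] - m$expected["oldold"], 0)
  expect_gt(m$observed["newnew"] - m$expected["newnew"], 0)
  expect_lt(m$p_value, 0.05)
})

test_that("permutation p-values are uniform under the label-shuffle null", {
  set.seed(41)
  pvals <- replicate(60, {
    cfg <- small_config(seed = sample.int(1e6, 1), n_genes = 150,
                        n_edges = 400, age_homophily = 0,
                        degree_effects = c(old = 1, reg = 1))
    g <- generate_gene_table(cfg)
    g$phylostratum <- sample(g$phylostratum)
    e <- generate_interactions(g, cfg)
    a <- derive_attributes(g, e)
    age_mixing(e, a, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partner phylostratum profiles reflect forced and planted structure", {
  # every NEW gene linked only to deep-stratum (ps >= 10) genes
  g <- tiny_gene_table(c(1, 2, 12, 15, 11), matrix(1, 5, 4))
  e <- edge_df("g003", "g004", "g003", "g005", "g001", "g002")
  p <- partner_stratum_profile(e, g, n_boot = 50, seed = 1)
  expect_gte(p$mean_partner_stratum[p$class == "NEW"], 10)
  expect_lt(p$mean_partner_stratum[p$class == "OLD"], 3)

  cfg <- generator_config(n_genes = 3000, n_edges = 9000, seed = 27,
                          age_homophily = 0.8)
  gg <- generate_gene_table(cfg)
  ee <- generate_interactions(gg, cfg)
  pp <- partner_stratum_profile(ee, gg, n_boot = 100, seed = 4)
  expect_gt(pp$mean_partner_stratum[pp$class == "NEW"],
            pp$mean_partner_stratum[pp$class == "OLD"])
})

test_that("under random mixing class partner means sit at the degree-weighted global mean", {
  cfg <- generator_config(n_genes = 3000, n_edges = 12000, seed = 29,
                          age_homophily = 0,
                          degree_effects = c(old = 1, reg = 1))
  g <- generate_gene_table(cfg)
  g$phylostratum <- sample(g$phylostratum)   # decouple strata from degree
  e <- generate_interactions(g, cfg)
  a <- derive_attributes(g, e)
  d <- degrees(e, a)
  global <- sum(d * g$phylostratum) / sum(d)
  p <- partner_stratum_profile(e, g, n_boot = 400, seed = 5)
  for (i in seq_len(nrow(p)))
    expect_true(p$ci_low[i] <= global && global <= p$ci_high[i])
})

test_that("cohesion equals exhaustive pair enumeration and handles extremes", {
  g <- tiny_gene_table(c(1, 1, 1, 3), matrix(1, 4, 4))
  # complete graph on the OLD class, nothing else
  e <- edge_df("g001", "g002", "g001", "g003", "g002", "g003")
  a <- derive_attributes(g, e)
  co <- cohesion(e, a, "OLD")
  expect_equal(co$within_density, 1)
  expect_equal(co$between_density, 0)

  set.seed(8)
  g50 <- tiny_gene_table(sample(1:19, 50, TRUE), matrix(1, 50, 4))
  pairs <- t(combn(g50$gene_id, 2))
  keep <- runif(nrow(pairs)) < 0.1
  e50 <- interaction_set(data.frame(from = pairs[keep, 1],
                                    to = pairs[keep, 2]))
  a50 <- derive_attributes(g50, e50)
  co50 <- cohesion(e50, a50, "NEW")
  members <- a50$gene_id[a50$age == "NEW"]
  w <- 0; b <- 0
  for (i in seq_len(nrow(e50))) {
    inn <- c(e50$from[i] %in% members, e50$to[i] %in% members)
    if (all(inn)) w <- w + 1 else if (any(inn)) b <- b + 1
  }
  expect_equal(co50$within_edges, w)
  expect_equal(co50$between_edges, b)
  expect_equal(co50$within_density, w / choose(length(members), 2))

  tiny <- derive_attributes(tiny_gene_table(c(1, 3, 3), matrix(1, 3, 4)),
                            NULL)
  empty <- interaction_set(data.frame(from = character(0),
                                      to = character(0)))
  expect_false(cohesion(empty, tiny, "OLD")$evaluable)   # class of size 1
  expect_equal(cohesion(empty, tiny, "NEW")$within_density, 0)
})
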