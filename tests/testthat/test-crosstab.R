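test_that("joint membership fills both the cell and the diagonal", {
  g <- tiny_gene_table(c(1, 2), matrix(1, 2, 4), disease = c(TRUE, TRUE))
  a <- derive_attributes(g, NULL)
  cm <- build_contingency(a)
  expect_equal(cm_cell(cm, "OLD", "DIS"), 2)
  expect_equal(cm_total(cm, "OLD"), 2)
  expect_equal(cm_total(cm, "NEW"), 0)
})

test_that("an empty table gives an all-zero matrix", {
  g <- generate_gene_table(generator_config(n_genes = 0, n_edges = 0))
  cm <- build_contingency(derive_attributes(g, NULL))
  expect_true(all(cm$counts == 0))
})

test_that("every contingency cell equals a brute-force double-loop recount", {
  cfg <- generator_config(n_genes = 5000, seed = 17, n_edges = 6000)
  g <- generate_gene_table(cfg)
  e <- generate_interactions(g, cfg)
  a <- derive_attributes(g, e)
  cm <- build_contingency(a)
  cols <- c(OLD = "age", NEW = "age", TSP = "specificity",
            HKP = "specificity", EXL = "expression_level",
            EXH = "expression_level", INT = "interaction",
            NIN = "interaction", DIS = "disease", NDI = "disease",
            TFA = "tf", NTF = "tf", PTM = "ptm", NPT = "ptm",
            REG = "regulator", NRE = "regulator", SHO = "length_class",
            LON = "length_class")
  lv <- names(cols)
  for (i in seq_along(lv)) for (j in i:length(lv)) {
    brute <- sum(a[[cols[lv[i]]]] == lv[i] & a[[cols[lv[j]]]] == lv[j])
    expect_equal(unname(cm_cell(cm, lv[i], lv[j])), brute)
  }
  expect_equal(cm$extras$tf_ptm_overlap,
               sum(a$tf == "TFA" & a$ptm == "PTM"))
})

test_that("MISSING genes are excluded from tissue-based cells only", {
  ab <- rbind(matrix(1, 3, 8), matrix(0, 2, 8))  # 2 genes unexpressed
  g <- tiny_gene_table(c(1, 1, 3, 1, 3), abund = ab,
                       disease = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  a <- derive_attributes(g, NULL)
  cm <- build_contingency(a)
  expect_equal(cm_total(cm, "DIS"), 5)
  expect_equal(cm_cell(cm, "DIS", "TSP") + cm_cell(cm, "DIS", "HKP"), 3)
})

test_that("the unpooled z-test matches its closed form and degenerates safely", {
  expect_equal(two_proportion_ztest(50, 100, 50, 100)$z, 0)
  expect_equal(two_proportion_ztest(50, 100, 50, 100)$p_value, 1)
  zt <- two_proportion_ztest(30, 100, 10, 80)
  p1 <- 0.3; p2 <- 0.125
  se <- sqrt(p1 * (1 - p1) / 100 + p2 * (1 - p2) / 80)
  expect_equal(zt$z, (p1 - p2) / se)
  expect_equal(zt$p_value, 2 * pnorm(-abs(zt$z)))
  expect_equal(zt$fold, p1 / p2)
  expect_equal(zt$odds_ratio, (30 / 70) / (10 / 70))
  # swapping the groups negates z and preserves p
  sw <- two_proportion_ztest(10, 80, 30, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_value, zt$p_value)
  # all-success in both groups: zero SE with equal proportions
  expect_equal(two_proportion_ztest(5, 5, 7, 7)$p_value, 1)
  expect_error(two_proportion_ztest(5, 3, 1, 10), "0 <= k <= n")
  expect_error(two_proportion_ztest(-1, 3, 1, 10), "0 <= k <= n")
})

test_that("the p-value shrinks monotonically with n for fixed unequal proportions", {
  ns <- c(100, 400, 1600, 6400)
  ps <- sapply(ns, function(n)
    two_proportion_ztest(round(0.3 * n), n, round(0.25 * n), n)$p_value)
  expect_true(all(diff(ps) < 0))
})

test_that("the z-test p-value is calibrated against a binomial resampling oracle", {
  # simulate both groups at the pooled proportion; the two-tailed rejection
  # frequency at the observed |z| estimates the p-value
  k1 <- 262; n1 <- 999; k2 <- 607; n2 <- 1785
  zt <- two_proportion_ztest(k1, n1, k2, n2)
  pool <- (k1 + k2) / (n1 + n2)
  set.seed(31)
  B <- 1e5
  s1 <- rbinom(B, n1, pool) / n1
  s2 <- rbinom(B, n2, pool) / n2
  zsim <- (s1 - s2) / sqrt(s1 * (1 - s1) / n1 + s2 * (1 - s2) / n2)
  phat <- mean(abs(zsim) >= abs(zt$z))
  mc_se <- sqrt(max(phat, zt$p_value) * (1 - min(phat, zt$p_value)) / B)
  expect_lt(abs(phat - zt$p_value), 4 * mc_se + 1e-4)
})

test_that("regulator union equals the explicit set-union size", {
  expect_equal(regulator_union(999, 1785, 228), 2556)
  expect_equal(regulator_union(0, 0, 0), 0)
  set.seed(12)
  for (i in 1:25) {
    n <- 200
    tf_set <- sample(n, sample(0:80, 1))
    ptm_set <- sample(n, sample(0:80, 1))
    ov <- length(intersect(tf_set, ptm_set))
    expect_equal(regulator_union(length(tf_set), length(ptm_set), ov),
                 length(union(tf_set, ptm_set)))
  }
  expect_error(regulator_union(5, 4, 5), "overlap")
})

test_that("the enrichment scan reports unevaluable pairs instead of dropping them", {
  cm <- load_table1_fixture()
  sc <- enrichment_scan(cm)
  # REG/NRE disease cells are unprinted in the fixture: flagged, present
  reg_rows <- sc[sc$group1 == "REG" & sc$target %in% c("DIS", "NDI"), ]
  expect_gt(nrow(reg_rows), 0)
  expect_true(all(!reg_rows$evaluable))
  # but the printed REG/NRE length split is evaluable
  reg_len <- sc[sc$group1 == "REG" & sc$target == "SHO", ]
  expect_true(all(reg_len$evaluable))
  # an evaluable worked case: P(DIS | OLD) vs P(DIS | NEW)
  row <- sc[sc$target == "DIS" & sc$group1 == "OLD", ]
  expect_equal(row$k1 / row$n1, 1892 / 8301)
  expect_equal(row$k2 / row$n2, 630 / 4452)
  expect_true(row$significant)
  # BH switch adds adjusted p-values
  scb <- enrichment_scan(cm, bh = TRUE)
  expect_true("p_adjusted" %in% names(scb))
  expect_true(all(scb$p_adjusted >= scb$p_value - 1e-15, na.rm = TRUE))
})

test_that("tissue-based denominators come from the matrix, not the table size", {
  cm <- load_table1_fixture()
  sc <- enrichment_scan(cm)
  row <- sc[sc$target == "TSP" & sc$group1 == "OLD", ]
  expect_equal(row$n1, 2424 + 2648)   # expressed old genes only
  expect_equal(row$n2, 1204 + 700)
})
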