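test_that("disease proportion and its standard error follow the hand formula", {
  g <- tiny_gene_table(rep(1, 10), matrix(1, 10, 4),
                       disease = c(rep(TRUE, 3), rep(FALSE, 7)),
                       chromosome = rep("7", 10))
  cp <- chromosome_class_distribution(derive_attributes(g, NULL))
  row <- cp$chromosomes[cp$chromosomes$chromosome == "7", ]
  expect_equal(row$prop_disease, 0.3)
  expect_equal(row$se_disease, sqrt(0.3 * 0.7 / 10))
  expect_equal(row$mean_length_kb, 10)
})

test_that("a homogeneous class populates only its own cell and totals conserve", {
  g <- tiny_gene_table(c(1, 1, 2), matrix(1, 3, 4),
                       chromosome = c("1", "2", "1"))
  cp <- chromosome_class_distribution(derive_attributes(g, NULL))
  tab <- cp$chromosomes
  expect_equal(sum(tab$old_nondisease), 3)
  expect_equal(sum(tab$old_disease) + sum(tab$new_nondisease) +
                 sum(tab$new_disease), 0)
  expect_equal(tab$n, rowSums(tab[, c("old_nondisease", "old_disease",
                                      "new_nondisease", "new_disease")]))
})

test_that("doubled disease odds on X push it above the autosomes", {
  cfg <- generator_config(n_genes = 20000, n_edges = 0, seed = 44,
                          disease_chrom_boost = c(X = log(2.5)))
  cp <- chromosome_class_distribution(
    derive_attributes(generate_gene_table(cfg), NULL))
  tab <- cp$chromosomes
  autosomes <- tab$prop_disease[!tab$chromosome %in% c("X", "Y")]
  expect_gt(tab$prop_disease[tab$chromosome == "X"], max(autosomes))
  expect_equal(cp$disease_ranking[1], "X")
})

test_that("unknown chromosome labels are a validation error listing offenders", {
  g <- tiny_gene_table(1, matrix(1, 1, 4), chromosome = "chrMT")
  expect_error(chromosome_class_distribution(derive_attributes(g, NULL)),
               "chrMT")
})

test_that("the chromosome-by-tissue matrix counts exactly", {
  ab <- rbind(c(2, 5, 0), c(0, 0, 0))
  g <- tiny_gene_table(c(1, 1), ab, chromosome = c("1", "2"))
  M <- chrom_tissue_matrix(g)
  expect_equal(unname(M["1", ]), c(1L, 1L, 0L))
  expect_equal(sum(M["2", ]), 0L)     # all-zero gene contributes nothing

  set.seed(9)
  n <- 200
  ab2 <- matrix(rlnorm(n * 6), n, 6)
  ab2[runif(length(ab2)) < 0.5] <- 0
  chrom <- sample(default_chromosomes(), n, TRUE)
  g2 <- tiny_gene_table(rep(1, n), ab2, chromosome = chrom)
  M2 <- chrom_tissue_matrix(g2)
  for (ch in default_chromosomes()) {
    idx <- chrom == ch
    expect_equal(unname(M2[ch, ]),
                 as.integer(colSums(ab2[idx, , drop = FALSE] > 0)))
  }
})

# independent agglomeration oracle: recompute linkage from member lists at
# every step (no distance-update recursion)
cluster_oracle <- function(D, linkage = "average") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  id <- -seq_len(n)
  merges <- list(); heights <- numeric(0)
  linkdist <- function(a, b) {
    d <- D[clusters[[a]], clusters[[b]], drop = FALSE]
    switch(linkage, average = mean(d), single = min(d), complete = max(d))
  }
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- linkdist(i, j)
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    merges[[step]] <- sort(c(id[best[1]], id[best[2]]))
    heights[step] <- bestd
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    id[best[1]] <- step
    clusters[[best[2]]] <- NULL
    id <- id[-best[2]]
  }
  list(merge = do.call(rbind, merges), height = heights)
}

test_that("identical rows merge first at height zero", {
  M <- rbind(a = c(1, 2, 3), b = c(9, 1, 4), c = c(1, 2, 3), d = c(5, 5, 5))
  tree <- cluster_rows(M, standardise = FALSE)
  expect_equal(sort(tree$merge[1, ]), c(-3, -1))
  expect_equal(tree$height[1], 0)
})

test_that("the merge tree matches a brute-force linkage oracle", {
  M <- rbind(r1 = c(0, 1, 2), r2 = c(10, 9, 8), r3 = c(0.5, 1.5, 2.5),
             r4 = c(9, 9, 9))
  tree <- cluster_rows(M, standardise = FALSE)
  oracle <- cluster_oracle(as.matrix(dist(M)))
  expect_equal(tree$height, oracle$height)
  expect_equal(tree$merge, oracle$merge)
  # UPGMA distance-update recursion vs direct recomputation on random data
  set.seed(10)
  for (i in 1:5) {
    R <- matrix(rnorm(7 * 4), 7, 4)
    t2 <- cluster_rows(R, standardise = FALSE)
    o2 <- cluster_oracle(as.matrix(dist(R)))
    expect_equal(t2$height, o2$height, tolerance = 1e-10)
  }
})

test_that("clustering agrees with hclust and is permutation invariant off ties", {
  set.seed(11)
  M <- matrix(rnorm(9 * 5), 9, 5, dimnames = list(paste0("r", 1:9), NULL))
  own <- cluster_rows(M, standardise = FALSE)
  ref <- hclust(dist(M), method = "average")
  expect_equal(own$height, ref$height, tolerance = 1e-12)
  key <- function(tr) {
    leaves <- function(node) {
      if (node < 0) return(tr$labels[-node])
      sort(c(leaves(tr$merge[node, 1]), leaves(tr$merge[node, 2])))
    }
    sort(sapply(seq_len(nrow(tr$merge)),
                function(s) paste(leaves(s), collapse = "+")))
  }
  expect_equal(key(own), key(ref))

  perm <- sample(9)
  own_p <- cluster_rows(M[perm, ], standardise = FALSE)
  expect_equal(key(own_p), key(own))
})

test_that("constant matrices cluster under the tie rule and are flagged", {
  M <- matrix(1, 4, 3, dimnames = list(letters[1:4], NULL))
  tree <- cluster_rows(M, standardise = TRUE)
  expect_true(tree$degenerate)
  expect_equal(nrow(tree$merge), 3)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))   # lowest-index merge first
})

test_that("two-way clustering returns consistent leaf orders and Newick text", {
  cfg <- small_config(seed = 45, n_edges = 0)
  g <- generate_gene_table(cfg)
  M <- chrom_tissue_matrix(g)
  hc <- hierarchical_cluster(M)
  expect_setequal(hc$row_order, rownames(M))
  expect_setequal(hc$col_order, colnames(M))
  nw <- as_newick(hc$row)
  expect_match(nw, "^\\(")
  expect_equal(length(ape::read.tree(text = nw)$tip.label), nrow(M))
})
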