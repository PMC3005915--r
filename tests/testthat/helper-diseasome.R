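# Small in-code fixture builders shared across tests.

# A gene table built by hand: `abund` is a genes x tissues matrix.
tiny_gene_table <- function(ps, abund, length_kb = NULL, chromosome = NULL,
                            disease = NULL, tf = NULL, ptm_count = NULL,
                            tissues = NULL) {
  n <- length(ps)
  abund <- as.matrix(abund)
  stopifnot(nrow(abund) == n)
  if (is.null(tissues)) tissues <- paste0("T", seq_len(ncol(abund)))
  tab <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                    phylostratum = as.integer(ps), stringsAsFactors = FALSE)
  for (k in seq_along(tissues)) tab[[paste0("tis_", tissues[k])]] <- abund[, k]
  tab$length_kb <- if (is.null(length_kb)) rep(10, n) else length_kb
  tab$chromosome <- if (is.null(chromosome)) rep("1", n) else chromosome
  tab$disease <- if (is.null(disease)) rep(FALSE, n) else disease
  tab$tf <- if (is.null(tf)) rep(FALSE, n) else tf
  tab$ptm_count <- if (is.null(ptm_count)) rep(0L, n) else
    as.integer(ptm_count)
  diseasome:::as_gene_table(tab, tissues)
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  interaction_set(data.frame(from = m[, 1], to = m[, 2],
                             stringsAsFactors = FALSE))
}

# Default-structured generator scaled down for unit tests.
small_config <- function(n_genes = 500, n_edges = 1200, seed = 1, ...) {
  generator_config(n_genes = n_genes, n_edges = n_edges, seed = seed, ...)
}
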