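# TSV readers/writers with a '#'-prefixed metadata header recording the
# tool version, seed and every in-force choice the source data do not fix.

metadata_header <- function(seed = NA, extra = character(0)) {
  ver <- tryCatch(as.character(utils::packageVersion("diseasome")),
                  error = function(e) "dev")
  c(sprintf("# diseasome_version: %s", ver),
    sprintf("# seed: %s", seed),
    sprintf("# written: %s", "deterministic-output"),
    extra)
}

write_tsv_with_header <- function(df, path, seed = NA, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a gene table as TSV
#'
#' One row per gene, one abundance column per tissue; a metadata comment
#' header precedes the data. Write-then-read round-trips the in-memory
#' table.
#'
#' @param genes A gene table.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @return The path (write) or a \code{gene_table} (read).
#' @export
write_gene_table <- function(genes, path, seed = NA) {
  write_tsv_with_header(as.data.frame(genes), path, seed = seed)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_skip_comments(path)
  required <- c("gene_id", "phylostratum", "length_kb", "chromosome",
                "disease", "tf", "ptm_count")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("malformed gene table %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop(sprintf("duplicate gene id(s) in %s: %s", path,
                 paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 10),
                       collapse = ", ")), call. = FALSE)
  tis <- grep("^tis_", names(df), value = TRUE)
  for (cc in tis) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))
      stop(sprintf("non-numeric abundance in %s column %s (data line %d)",
                   path, cc, bad[1]), call. = FALSE)
    }
  }
  df$disease <- as.logical(df$disease)
  df$tf <- as.logical(df$tf)
  df$chromosome <- as.character(df$chromosome)
  as_gene_table(df, sub("^tis_", "", tis))
}

#' Write / read an interaction edge list as two-column TSV
#'
#' @param interactions An \code{\link{interaction_set}}.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @param gene_ids Optional known gene ids for referential validation on
#'   read.
#' @return The path (write) or an \code{interaction_set} (read).
#' @export
write_edges <- function(interactions, path, seed = NA) {
  write_tsv_with_header(as.data.frame(interactions), path, seed = seed)
}

#' @rdname write_edges
#' @export
read_edges <- function(path, gene_ids = NULL) {
  df <- read_tsv_skip_comments(path)
  if (ncol(df) < 2)
    stop(sprintf("malformed edge list %s: expected two columns", path),
         call. = FALSE)
  interaction_set(df[, 1:2], gene_ids = gene_ids)
}

#' Write an attribute table as TSV
#'
#' Columns use the standard level codes (OLD/NEW, TSP/HKP/MISSING, ...).
#' @param attrs An attribute table.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @export
write_attribute_table <- function(attrs, path, seed = NA) {
  th <- attr(attrs, "thresholds")
  extra <- if (is.null(th)) character(0) else
    c(sprintf("# age_ps_max: %s", th$age_ps_max),
      sprintf("# hk_min_tissues: %s", th$hk_min_tissues),
      sprintf("# long_min_kb: %s", th$long_min_kb),
      sprintf("# expression_summary: %s (median split; cutoff not fixed by the source data)",
              th$expression_summary))
  write_tsv_with_header(as.data.frame(attrs), path, seed = seed, extra = extra)
}

#' Serialise a contingency matrix as an upper-triangular TSV
#'
#' @param cm A \code{\link{contingency_matrix}}.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @export
write_contingency <- function(cm, path, seed = NA) {
  M <- cm$counts
  M[lower.tri(M)] <- NA
  df <- data.frame(level = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  extra <- sprintf("# extras: %s",
                   paste(sprintf("%s=%s", names(cm$extras),
                                 unlist(cm$extras)), collapse = ", "))
  write_tsv_with_header(df, path, seed = seed, extra = extra)
}

#' Run the whole diseasome analysis pipeline
#'
#' Executes simulate (or ingest) -> derive -> cross-tabulate and enrichment
#' scan -> correlations (raw and conditioned on breadth) -> network
#' connectivity (LS means, age mixing, partner strata, cohesion) -> stratum
#' and tissue profiles -> chromosome maps and two-way clustering, and
#' writes every artifact as TSV/JSON into \code{out_dir} together with a
#' human-readable summary. Identical seeds and inputs give byte-identical
#' bundles.
#'
#' @param generator A \code{\link{generator_config}}, or NULL when reading
#'   from files.
#' @param gene_table_path,edges_path Input TSVs (exactly one of generator /
#'   paths must be supplied).
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param thresholds Dichotomisation thresholds.
#' @param alpha Significance level for the enrichment scan.
#' @param bh Use Benjamini-Hochberg adjusted p-values in the scan.
#' @param n_perm Label permutations for the mixing test.
#' @param linkage,metric Clustering options.
#' @param seed Seed for permutation/bootstrap randomness (the generator uses
#'   its own configured seed).
#' @return The report bundle (a named list of all results), invisibly when
#'   written to disk.
#' @export
run_pipeline <- function(generator = NULL, gene_table_path = NULL,
                         edges_path = NULL, out_dir = NULL,
                         thresholds = attribute_thresholds(),
                         alpha = 0.05, bh = FALSE, n_perm = 1000,
                         linkage = "average", metric = "euclidean",
                         seed = 1L) {
  from_files <- !is.null(gene_table_path) || !is.null(edges_path)
  if (is.null(generator) == !from_files)
    stop("supply exactly one of: a generator config, or gene table + edge list paths",
         call. = FALSE)
  if (!is.null(generator)) {
    genes <- generate_gene_table(generator)
    edges <- generate_interactions(genes, generator)
  } else {
    genes <- read_gene_table(gene_table_path)
    edges <- read_edges(edges_path, gene_ids = genes$gene_id)
  }
  attrs <- derive_attributes(genes, edges, thresholds)
  cm <- build_contingency(attrs)
  scan <- enrichment_scan(cm, alpha = alpha, bh = bh)
  summary_pcts <- crosstab_summary(cm)
  cors <- correlation_matrix(attrs)
  pcors <- correlation_matrix(attrs, vars = c("age", "disease", "length_kb",
                                              "regulator", "interaction"),
                              conditioning = "breadth")
  deg <- degrees(edges, attrs)
  lsm <- lsmeans_connectivity(deg, attrs)
  mixing <- age_mixing(edges, attrs, n_perm = n_perm, seed = seed)
  partners <- partner_stratum_profile(edges, genes, seed = seed)
  coh <- list(NEW = cohesion(edges, attrs, "NEW"),
              OLD = cohesion(edges, attrs, "OLD"))
  strata <- stratum_regulator_profile(attrs)
  tissues <- tissue_profiles(genes, attrs)
  chrom <- chromosome_class_distribution(attrs,
                                         chromosomes = unique(c(default_chromosomes(),
                                                                genes$chromosome)))
  ctm <- chrom_tissue_matrix(genes,
                             chromosomes = intersect(c(default_chromosomes(),
                                                       unique(genes$chromosome)),
                                                     unique(genes$chromosome)))
  clust <- hierarchical_cluster(ctm, linkage = linkage, metric = metric)

  bundle <- list(genes = genes, edges = edges, attrs = attrs,
                 contingency = cm, enrichment = scan,
                 summary = summary_pcts, correlations = cors,
                 partial_correlations = pcors, degrees = deg,
                 lsmeans = lsm, mixing = mixing, partners = partners,
                 cohesion = coh, strata = strata, tissues = tissues,
                 chromosomes = chrom, chrom_tissue = ctm,
                 clustering = clust, seed = seed)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, seed = seed, linkage = linkage,
                 metric = metric)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, dir, seed, linkage, metric) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_table(bundle$genes, p("gene_table.tsv"), seed = seed)
  write_edges(bundle$edges, p("edges.tsv"), seed = seed)
  write_attribute_table(bundle$attrs, p("attributes.tsv"), seed = seed)
  write_contingency(bundle$contingency, p("contingency.tsv"), seed = seed)
  write_tsv_with_header(bundle$enrichment, p("enrichment.tsv"), seed = seed)
  jsonlite::write_json(bundle$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  cor_df <- function(cc) data.frame(variable = rownames(cc$r), cc$r,
                                    check.names = FALSE)
  write_tsv_with_header(cor_df(bundle$correlations), p("correlations.tsv"),
                        seed = seed)
  write_tsv_with_header(cor_df(bundle$partial_correlations),
                        p("partial_correlations.tsv"), seed = seed,
                        extra = "# conditioning: breadth")
  write_tsv_with_header(bundle$lsmeans$means, p("lsmeans.tsv"), seed = seed)
  write_tsv_with_header(bundle$lsmeans$contrasts, p("lsmeans_contrasts.tsv"),
                        seed = seed)
  jsonlite::write_json(list(observed = as.list(bundle$mixing$observed),
                            expected = as.list(bundle$mixing$expected),
                            excess_within = bundle$mixing$excess_within,
                            p_value = bundle$mixing$p_value),
                       p("mixing.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_with_header(bundle$partners, p("partner_strata.tsv"), seed = seed)
  write_tsv_with_header(bundle$strata$strata, p("stratum_profile.tsv"),
                        seed = seed,
                        extra = sprintf("# flag_method: %s",
                                        bundle$strata$flag_method))
  write_tsv_with_header(bundle$tissues$tissues, p("tissue_profiles.tsv"),
                        seed = seed,
                        extra = sprintf("# breadth_reading: %s",
                                        bundle$tissues$breadth_reading))
  write_tsv_with_header(bundle$chromosomes$chromosomes,
                        p("chromosome_profile.tsv"), seed = seed)
  write_tsv_with_header(data.frame(chromosome = rownames(bundle$chrom_tissue),
                                   bundle$chrom_tissue, check.names = FALSE),
                        p("chrom_tissue_matrix.tsv"), seed = seed)
  writeLines(c(metadata_header(seed,
                               extra = c(sprintf("# linkage: %s", linkage),
                                         sprintf("# metric: %s", metric))),
               as_newick(bundle$clustering$row),
               as_newick(bundle$clustering$col)),
             p("cluster_trees.nwk"))
  writeLines(pipeline_summary_text(bundle), p("summary.txt"))
  invisible(dir)
}

# Table-2-style plain-language summary of the significant enrichments
pipeline_summary_text <- function(bundle) {
  sc <- bundle$enrichment
  sc <- sc[sc$evaluable & sc$significant & !is.na(sc$p1) & sc$p1 > sc$p2, ]
  lines <- c("Diseasome cross-comparison summary",
             sprintf("genes: %d, edges: %d", nrow(bundle$attrs),
                     nrow(bundle$edges)),
             "")
  s <- bundle$summary
  lines <- c(lines, sprintf(
    "Disease genes among regulators: %.1f%% vs %.1f%% among non-regulators.",
    s$dis_given_reg_pct, s$dis_given_nre_pct))
  grp <- split(sc, sc$group1)
  for (g in names(grp)) {
    rows <- grp[[g]]
    lines <- c(lines, sprintf(
      "When compared to %s genes, a higher proportion of %s genes are: %s.",
      rows$group2[1], g,
      paste(sprintf("%s (+%.0f pp)", rows$target, 100 * (rows$p1 - rows$p2)),
            collapse = ", ")))
  }
  lines
}
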