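# Hypergeometric over-representation analysis of DEG sets.
#
# The background is the set of genes carrying at least one annotation in
# the tested category (the standard over-representation convention; the
# "Ref" column counts term-annotated genes, not the whole transcriptome).
# GO terms are treated as flat sets -- no DAG propagation.

#' Load a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `category` and an
#'   optional `description`; duplicate rows are dropped.
#' @return a `data.table` keyed by category/term_id.
#' @export
load_annotation <- function(path) {
  check(file.exists(path), "file error: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  for (col in c("gene_id", "term_id", "category")) {
    check(col %in% names(dt),
          "format error: annotation is missing column '%s'", col)
  }
  keep <- intersect(c("gene_id", "term_id", "category", "description"),
                    names(dt))
  dt <- unique(dt[, keep, with = FALSE])
  data.table::setkeyv(dt, c("category", "term_id"))
  dt[]
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a random
#' size-`n` draw from a background of `N` genes, `K` of which carry the
#' term, contains at least `k` term genes. Vectorized.
#'
#' @param k observed overlap (DEGs annotated to the term).
#' @param K term size in the background.
#' @param n query-set size (annotated DEGs).
#' @param N background size (annotated genes).
#' @return upper-tail probabilities.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  check(all(args == floor(args)) && all(args >= 0),
        "domain error: arguments must be non-negative integers")
  k <- args[, 1]; K <- args[, 2]; n <- args[, 3]; N <- args[, 4]
  check(all(K <= N) && all(n <= N),
        "domain error: K and n must not exceed N")
  check(all(k <= pmin(K, n)), "domain error: k exceeds min(K, n)")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Term enrichment of a DEG set
#'
#' For every term in the category: `dif` = DEGs annotated to the term,
#' `ref` = background genes annotated to the term, tested against the
#' annotated background with the upper-tail hypergeometric probability.
#' Raw `p_value <= p_threshold` marks significance (the conventional
#' filter for this analysis); BH-adjusted p-values across the category's
#' terms are reported alongside but not used for filtering.
#'
#' @param deg_genes character vector of DEG gene ids.
#' @param annotation annotation `data.table` from [load_annotation()] or
#'   [generate_annotation()].
#' @param category which annotation category to test (e.g. "KEGG").
#' @param p_threshold raw-p significance filter (default 0.05).
#' @return a `data.table` (term_id, description?, dif, ref, p_value,
#'   adjusted_p, significant) sorted by p ascending, ties by term_id, with
#'   attributes `n_query` and `n_background`.
#' @export
enrich <- function(deg_genes, annotation, category,
                   p_threshold = 0.05) {
  annotation <- data.table::as.data.table(annotation)
  sel <- annotation[["category"]] == category # plain vector: avoids
  ann <- annotation[which(sel), ]             # column-name capture in i
  check(nrow(ann) > 0L,
        "input error: empty annotated background for category '%s'",
        category)
  background <- unique(ann$gene_id)
  N <- length(background)
  deg_in_bg <- unique(intersect(deg_genes, background))
  n <- length(deg_in_bg)
  per_term <- ann[, list(
    ref = data.table::uniqueN(gene_id),
    dif = sum(unique(gene_id) %in% deg_in_bg),
    description = if ("description" %in% names(ann))
      description[1] else NA_character_
  ), by = "term_id"]
  per_term$p_value <- hypergeom_upper_tail(per_term$dif, per_term$ref,
                                           n, N)
  per_term$adjusted_p <- benjamini_hochberg(per_term$p_value)
  per_term$significant <- per_term$p_value <= p_threshold
  data.table::setorder(per_term, p_value, term_id)
  data.table::setcolorder(per_term, c("term_id", "description", "dif",
                                      "ref", "p_value", "adjusted_p",
                                      "significant"))
  data.table::setattr(per_term, "n_query", n)
  data.table::setattr(per_term, "n_background", N)
  data.table::setattr(per_term, "category", category)
  per_term[]
}

#' Write an enrichment table as TSV (Pathway ID, description, Dif, Ref,
#' P-value, adjusted p)
#' @param table an [enrich()] result.
#' @param path output TSV path.
#' @export
write_enrichment_tsv <- function(table, path) {
  out <- data.table::data.table(
    `Pathway ID` = table$term_id,
    `Pathway description` = table$description,
    Dif = table$dif, Ref = table$ref,
    `P-value` = table$p_value, adjusted_p = table$adjusted_p)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
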