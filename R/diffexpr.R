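# Two-library differential expression for tag counts.
#
# With one DGE library per condition there are no replicates, so
# differential expression is assessed with the classical exact
# conditional test for comparing a count between two libraries of known
# sizes (Audic & Claverie's SAGE statistic): conditional on x tags in
# library A (size n1), the count y in library B (size n2) follows
#
#   P(Y = y | x) = r^y (x+y)! / ( x! y! (1+r)^(x+y+1) ),  r = n2/n1,
#
# which is the negative binomial NB(size = x + 1, prob = 1/(1+r)). Tail
# probabilities are therefore computed with stats::pnbinom (log-space
# incomplete beta internally), and the two-sided p-value is twice the
# smaller tail, capped at 1.

#' TPM normalization of mapped tag counts
#'
#' TPM here is transcripts per million clean tags: per-gene unambiguous
#' tag count scaled by `1e6 / clean_total`. Genes of the reference absent
#' from the mapped counts get count 0 and TPM 0.
#'
#' @param result a [map_tags()] result (or a `data.table` with columns
#'   gene_id, count plus a `gene_ids` argument).
#' @param clean_total the library's clean tag total (N); must be > 0.
#' @param gene_ids gene universe; defaults to the mapping result's
#'   reference genes.
#' @param library_id label; defaults to the mapping result's.
#' @return an `expression_profile`: a `data.table` (gene_id, count, tpm)
#'   with attributes `library_id` and `clean_total`.
#' @export
compute_tpm <- function(result, clean_total, gene_ids = NULL,
                        library_id = NULL) {
  if (inherits(result, "mapping_result")) {
    if (is.null(gene_ids)) gene_ids <- result$reference_genes
    if (is.null(library_id)) library_id <- result$library_id
    counts <- result$gene_counts
  } else {
    counts <- data.table::as.data.table(result)
    check(all(c("gene_id", "count") %in% names(counts)),
          "need columns gene_id and count")
    if (is.null(gene_ids)) gene_ids <- counts$gene_id
    if (is.null(library_id)) library_id <- "lib"
  }
  check(length(clean_total) == 1L && is.finite(clean_total) &&
          clean_total > 0, "normalization error: clean_total must be > 0")
  prof <- data.table::data.table(gene_id = gene_ids)
  prof <- counts[prof, on = "gene_id"]
  prof[is.na(prof$count), "count"] <- 0
  prof$tpm <- prof$count / clean_total * 1e6
  data.table::setattr(prof, "library_id", library_id)
  data.table::setattr(prof, "clean_total", as.numeric(clean_total))
  data.table::setattr(prof, "class",
                      c("expression_profile", class(prof)))
  prof[]
}

#' Exact two-library test for a tag count
#'
#' Two-sided p-value for observing counts `x` (library of size `n1`) and
#' `y` (library of size `n2`) of the same tag/gene under the null of equal
#' relative abundance. Vectorized over `x`, `y`.
#'
#' @param x,y non-negative tag counts in libraries A and B.
#' @param n1,n2 positive clean-tag totals of libraries A and B.
#' @return two-sided p-values in \[0, 1\].
#' @export
#' @examples
#' exact_count_pvalue(0, 5, 1e6, 1e6) # 2 * 2^-5 = 0.0625
exact_count_pvalue <- function(x, y, n1, n2) {
  check(all(x >= 0) && all(y >= 0) && all(x == floor(x)) &&
          all(y == floor(y)), "domain error: counts must be >= 0 integers")
  check(all(n1 > 0) && all(n2 > 0),
        "domain error: library sizes must be > 0")
  r <- n2 / n1
  prob <- 1 / (1 + r)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = prob,
                          lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH: sorted p-values are scaled by m/rank and a running minimum
#' is taken from the largest rank down; output order matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return BH-adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  check(all(p_values >= 0 & p_values <= 1, na.rm = FALSE) &&
          !anyNA(p_values), "domain error: p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  adj[order(o)]
}

#' Call differentially expressed genes between two profiles
#'
#' Genes with zero counts in both libraries are excluded from testing; BH
#' adjustment runs across exactly the tested set. For the log2 ratio, a
#' zero TPM is floored at the TPM of a single tag (1e6 / clean_total of
#' that library) so ratios stay finite and depth-aware. A gene is called
#' up when `fdr < fdr_threshold` and `log2_ratio >= lfc_threshold`, down
#' symmetrically, otherwise ns.
#'
#' @param profile_a,profile_b [compute_tpm()] profiles over the same gene
#'   universe (A = control, B = treated; the ratio is B over A).
#' @param fdr_threshold FDR cutoff (default 0.001).
#' @param lfc_threshold |log2 ratio| cutoff (default 1).
#' @return a `deg_table`: `data.table` (gene_id, count_a, count_b, tpm_a,
#'   tpm_b, log2_ratio, p_value, fdr, status) over tested genes, with
#'   threshold and library-size attributes.
#' @export
call_degs <- function(profile_a, profile_b, fdr_threshold = 0.001,
                      lfc_threshold = 1) {
  check(inherits(profile_a, "expression_profile") &&
          inherits(profile_b, "expression_profile"),
        "profiles must come from compute_tpm()")
  check(nrow(profile_a) == nrow(profile_b) &&
          all(profile_a$gene_id == profile_b$gene_id),
        "input error: profiles have mismatched gene universes")
  n1 <- attr(profile_a, "clean_total")
  n2 <- attr(profile_b, "clean_total")
  tested <- profile_a$count > 0 | profile_b$count > 0
  dt <- data.table::data.table(
    gene_id = profile_a$gene_id[tested],
    count_a = profile_a$count[tested],
    count_b = profile_b$count[tested],
    tpm_a = profile_a$tpm[tested],
    tpm_b = profile_b$tpm[tested])
  floor_a <- 1e6 / n1
  floor_b <- 1e6 / n2
  dt$log2_ratio <- log2(pmax(dt$tpm_b, floor_b) / pmax(dt$tpm_a, floor_a))
  dt$p_value <- exact_count_pvalue(dt$count_a, dt$count_b, n1, n2)
  dt$fdr <- benjamini_hochberg(dt$p_value)
  dt$status <- ifelse(
    dt$fdr < fdr_threshold & dt$log2_ratio >= lfc_threshold, "up",
    ifelse(dt$fdr < fdr_threshold & dt$log2_ratio <= -lfc_threshold,
           "down", "ns"))
  data.table::setattr(dt, "fdr_threshold", fdr_threshold)
  data.table::setattr(dt, "lfc_threshold", lfc_threshold)
  data.table::setattr(dt, "clean_total_a", n1)
  data.table::setattr(dt, "clean_total_b", n2)
  data.table::setattr(dt, "library_a", attr(profile_a, "library_id"))
  data.table::setattr(dt, "library_b", attr(profile_b, "library_id"))
  data.table::setattr(dt, "class", c("deg_table", class(dt)))
  dt[]
}

#' Summarize a DEG table
#'
#' Counts and percentages (1 decimal, half-up) of up- and down-regulated
#' genes among DEGs, and the |log2 ratio| histogram in bins \[1,2), \[2,3),
#' \[3,4), \[4,12), >= 12 plus the aggregate \[1,4) share.
#'
#' @param table a `deg_table` from [call_degs()] (or any data.frame with
#'   `status` and `log2_ratio`).
#' @return list with n_deg, n_up, n_down, pct_up, pct_down, `bins`
#'   (named counts), `bin_pct`, `pct_1_4`, and `empty` flag.
#' @export
summarize_degs <- function(table) {
  check(all(c("status", "log2_ratio") %in% names(table)),
        "need columns status and log2_ratio")
  deg <- table[table$status != "ns", , drop = FALSE]
  n_deg <- nrow(deg)
  if (n_deg == 0L) {
    z <- stats::setNames(rep(0L, 5L),
                         c("[1,2)", "[2,3)", "[3,4)", "[4,12)", ">=12"))
    return(list(n_deg = 0L, n_up = 0L, n_down = 0L, pct_up = 0.0,
                pct_down = 0.0, bins = z,
                bin_pct = stats::setNames(rep(0.0, 5L), names(z)),
                pct_1_4 = 0.0, empty = TRUE))
  }
  n_up <- sum(deg$status == "up")
  n_down <- sum(deg$status == "down")
  alr <- abs(deg$log2_ratio)
  breaks <- c(1, 2, 3, 4, 12, Inf)
  bins <- base::table(cut(alr, breaks, right = FALSE,
                          labels = c("[1,2)", "[2,3)", "[3,4)", "[4,12)",
                                     ">=12")))
  bins <- stats::setNames(as.integer(bins), names(bins))
  list(n_deg = n_deg, n_up = n_up, n_down = n_down,
       pct_up = pct(n_up, n_deg, 1L),
       pct_down = pct(n_down, n_deg, 1L),
       bins = bins,
       bin_pct = stats::setNames(pct(as.numeric(bins), n_deg, 1L),
                                 names(bins)),
       pct_1_4 = pct(sum(alr >= 1 & alr < 4), n_deg, 1L),
       empty = FALSE)
}

#' Pearson correlation between two expression profiles
#'
#' Computed over `log2(tpm + 1)` for genes detected (count > 0) in at
#' least one of the two libraries.
#'
#' @param profile_a,profile_b [compute_tpm()] profiles over the same gene
#'   universe.
#' @return Pearson r.
#' @export
pearson_correlation <- function(profile_a, profile_b) {
  check(nrow(profile_a) == nrow(profile_b) &&
          all(profile_a$gene_id == profile_b$gene_id),
        "input error: profiles have mismatched gene universes")
  keep <- profile_a$count > 0 | profile_b$count > 0
  check(sum(keep) >= 2L,
        "undefined correlation: fewer than 2 detected genes")
  a <- log2(profile_a$tpm[keep] + 1)
  b <- log2(profile_b$tpm[keep] + 1)
  check(stats::sd(a) > 0 && stats::sd(b) > 0,
        "undefined correlation: zero variance")
  stats::cor(a, b)
}

#' Write a DEG table as TSV
#' @param table a `deg_table`.
#' @param path output TSV path.
#' @export
write_deg_table_tsv <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path, sep = "\t")
  invisible(path)
}
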