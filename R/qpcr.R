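# Relative quantification by 2^-ddCt and concordance with DGE calls.

#' Construct a qPCR record
#'
#' One gene in one condition: replicate Ct values for the target gene and
#' for the reference (normalizer, e.g. beta-actin) gene.
#'
#' @param gene_id gene label.
#' @param condition condition label.
#' @param ct_target numeric replicate Ct values for the target.
#' @param ct_reference numeric replicate Ct values for the normalizer.
#' @return an object of class `qpcr_record`.
#' @export
qpcr_record <- function(gene_id, condition, ct_target, ct_reference) {
  check(length(ct_target) >= 1L && length(ct_reference) >= 1L,
        "input error: empty Ct replicate list")
  check(all(ct_target > 0 & ct_target < 50) &&
          all(ct_reference > 0 & ct_reference < 50),
        "Ct values must lie in (0, 50)")
  structure(list(gene_id = gene_id, condition = condition,
                 ct_target = as.numeric(ct_target),
                 ct_reference = as.numeric(ct_reference)),
            class = "qpcr_record")
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicates are averaged on the Ct scale, then
#' dCt = mean(Ct_target) - mean(Ct_reference) per condition,
#' ddCt = dCt_treated - dCt_control, and the fold change is 2^-ddCt.
#' No primer-efficiency correction is applied.
#'
#' @param treated,control [qpcr_record()]s for the same gene.
#' @return fold change (treated relative to control).
#' @export
#' @examples
#' t <- qpcr_record("g", "T", c(20, 20, 20), c(15, 15, 15))
#' c <- qpcr_record("g", "C", c(22, 22, 22), c(15, 15, 15))
#' ddct_fold_change(t, c) # ddCt = -2 -> fold 4
ddct_fold_change <- function(treated, control) {
  stopifnot(inherits(treated, "qpcr_record"),
            inherits(control, "qpcr_record"))
  check(identical(treated$gene_id, control$gene_id),
        "input error: records are for different genes")
  dct_t <- mean(treated$ct_target) - mean(treated$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  2^-(dct_t - dct_c)
}

#' Read a Ct table
#'
#' @param path TSV with columns gene_id, condition, replicate, ct_target,
#'   ct_reference.
#' @return a `data.table` of the parsed rows.
#' @export
read_ct_table <- function(path) {
  check(file.exists(path), "file error: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t")
  for (col in c("gene_id", "condition", "replicate", "ct_target",
                "ct_reference")) {
    check(col %in% names(dt),
          "format error: Ct table is missing column '%s'", col)
  }
  dt
}

#' Fold changes for every gene in a Ct table
#'
#' @param ct a `data.table` from [read_ct_table()].
#' @param treated,control the two condition labels to compare.
#' @return named numeric vector gene id -> 2^-ddCt fold change.
#' @export
ddct_table <- function(ct, treated, control) {
  genes <- sort(unique(ct$gene_id))
  folds <- vapply(genes, function(g) {
    sub <- ct[ct$gene_id == g, ]
    tr <- sub[sub$condition == treated, ]
    co <- sub[sub$condition == control, ]
    check(nrow(tr) > 0L && nrow(co) > 0L,
          "input error: gene %s lacks one of the conditions", g)
    ddct_fold_change(
      qpcr_record(g, treated, tr$ct_target, tr$ct_reference),
      qpcr_record(g, control, co$ct_target, co$ct_reference))
  }, 0.0)
  folds
}

#' Direction-of-change concordance between qPCR and DGE
#'
#' A shared gene is concordant when the sign of its log2 qPCR fold change
#' equals the sign of its DGE log2 ratio; a zero on either side counts as
#' non-concordant (conservative boundary rule).
#'
#' @param qpcr_folds named numeric vector gene id -> 2^-ddCt fold change.
#' @param deg_table a `deg_table` from [call_degs()] (needs gene_id and
#'   log2_ratio).
#' @return list with `concordant`, `total` and per-gene `flags`
#'   (`data.table` gene_id, qpcr_log2, dge_log2, concordant).
#' @export
concordance <- function(qpcr_folds, deg_table) {
  shared <- intersect(names(qpcr_folds), deg_table$gene_id)
  check(length(shared) > 0L, "input error: no shared genes")
  dge <- deg_table$log2_ratio[match(shared, deg_table$gene_id)]
  qp <- log2(qpcr_folds[shared])
  flags <- data.table::data.table(
    gene_id = shared, qpcr_log2 = unname(qp), dge_log2 = dge,
    concordant = sign(qp) == sign(dge) & sign(qp) != 0)
  list(concordant = sum(flags$concordant), total = length(shared),
       flags = flags)
}
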