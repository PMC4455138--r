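# Exact-match tag index and mapping.
#
# De novo transcriptome contigs have unknown orientation, so by default
# every CATG + 17 nt window on both the given sequence and its reverse
# complement is indexed. Mapping is exact (no mismatches); a clean tag
# matching windows in more than one gene is "ambiguous" and excluded from
# gene counts, matching the convention that only unambiguous tags
# quantify genes.

#' Build an exact-match tag index from a reference transcriptome
#'
#' Enumerates, for every gene, each anchor (`CATG`) occurrence followed by
#' at least `tag_length - 4` nt, on the sense strand and (by default) the
#' reverse complement. Windows containing non-ACGT characters are skipped
#' with a warning.
#'
#' @param transcriptome named [Biostrings::DNAStringSet] or named
#'   character vector of gene sequences.
#' @param tag_length tag length (anchor + downstream; default 21).
#' @param anchor restriction anchor sequence (default "CATG" for NlaIII).
#' @param both_strands index the reverse complement too (default TRUE);
#'   set FALSE for an oriented (sense-only) reference.
#' @return an object of class `tag_index` with fields `entries` (a
#'   `data.table` tag / gene_id / strand / offset, offsets 0-based on the
#'   scanned strand), `genes`, `reference_size`, `tag_length`,
#'   `both_strands`.
#' @export
build_tag_index <- function(transcriptome, tag_length = 21L,
                            anchor = "CATG", both_strands = TRUE) {
  seqs <- ref_as_character(transcriptome)
  strands <- if (both_strands) c("+", "-") else "+"
  pieces <- vector("list", length(strands))
  skipped <- 0L
  for (si in seq_along(strands)) {
    s <- if (strands[si] == "+") seqs else revcomp_safe(seqs)
    lens <- nchar(s)
    hits <- gregexpr(anchor, s, fixed = TRUE)
    n_hits <- vapply(hits, function(h) sum(h > 0L), 0L)
    gene <- rep(names(s), n_hits)
    pos <- unlist(lapply(hits, function(h) h[h > 0L]), use.names = FALSE)
    len <- rep(lens, n_hits)
    ok <- pos + tag_length - 1L <= len
    gene <- gene[ok]; pos <- pos[ok]
    tags <- substr(rep(unname(s), n_hits)[ok], pos, pos + tag_length - 1L)
    bad <- grepl("[^ACGT]", tags)
    skipped <- skipped + sum(bad)
    pieces[[si]] <- data.table::data.table(tag = tags[!bad],
                                           gene_id = gene[!bad],
                                           strand = strands[si],
                                           offset = pos[!bad] - 1L)
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d window(s) with non-ACGT characters",
                    skipped))
  }
  entries <- data.table::rbindlist(pieces)
  data.table::setkeyv(entries, "tag")
  structure(list(entries = entries, genes = names(seqs),
                 reference_size = length(seqs),
                 tag_length = as.integer(tag_length),
                 anchor = anchor, both_strands = both_strands),
            class = "tag_index")
}

# reverse complement preserving non-ACGT characters (complemented via
# IUPAC where possible); plain-character fallback for odd alphabets
revcomp_safe <- function(x) {
  out <- tryCatch(revcomp(x), error = function(e) NULL)
  if (!is.null(out)) {
    names(out) <- names(x)
    return(out)
  }
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "")[[1]])
    comp <- REVCOMP_MAP[chars]
    comp[is.na(comp)] <- chars[is.na(comp)]
    paste(comp, collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf(
    "tag_index: %s windows, %s distinct tags over %d genes (%s)\n",
    format(nrow(x$entries), big.mark = ","),
    format(data.table::uniqueN(x$entries$tag), big.mark = ","),
    x$reference_size,
    if (x$both_strands) "both strands" else "sense only"))
  invisible(x)
}

#' Map clean tags against a tag index
#'
#' Each distinct clean tag is classified: absent from the index ->
#' unmapped; matching exactly one gene -> unambiguous (its copies count
#' toward that gene, multiple positions within one gene included);
#' matching more than one gene -> ambiguous, excluded from gene counts.
#'
#' @param lib a [tag_library()].
#' @param index a [build_tag_index()] result.
#' @return an object of class `mapping_result`: `gene_counts`
#'   (`data.table` gene_id / count over unambiguous tags),
#'   `distinct_unambiguous`, `distinct_ambiguous`, `distinct_unmapped`,
#'   `distinct_mapped` (unambiguous + ambiguous), `genes_all`,
#'   `genes_unambiguous`, `reference_genes`, `library_id`.
#' @export
map_tags <- function(lib, index) {
  stopifnot(inherits(lib, "tag_library"), inherits(index, "tag_index"))
  tags <- lib$tag_counts
  if (nrow(tags) == 0L) {
    return(structure(list(
      library_id = lib$library_id,
      gene_counts = data.table::data.table(gene_id = character(0),
                                           count = numeric(0)),
      distinct_unambiguous = 0L, distinct_ambiguous = 0L,
      distinct_unmapped = 0L, distinct_mapped = 0L,
      genes_all = 0L, genes_unambiguous = 0L,
      mapped_copies = 0,
      reference_genes = index$genes,
      reference_size = index$reference_size), class = "mapping_result"))
  }
  tag_gene <- unique(index$entries[, c("tag", "gene_id")])
  hit <- tag_gene[tags, on = "tag", allow.cartesian = TRUE]
  # per distinct tag: how many distinct genes it touches (0 = unmapped)
  per_tag <- hit[, list(n_genes = sum(!is.na(gene_id))), by = "tag"]
  n_unmapped <- sum(per_tag$n_genes == 0L)
  n_unamb <- sum(per_tag$n_genes == 1L)
  n_amb <- sum(per_tag$n_genes > 1L)
  mapped_hits <- hit[!is.na(gene_id)]
  genes_all <- data.table::uniqueN(mapped_hits$gene_id)
  unamb_tags <- per_tag$tag[per_tag$n_genes == 1L]
  unamb <- mapped_hits[mapped_hits$tag %in% unamb_tags, ]
  gene_counts <- unamb[, list(count = sum(count)), by = "gene_id"]
  data.table::setorder(gene_counts, gene_id)
  structure(list(library_id = lib$library_id,
                 gene_counts = gene_counts,
                 distinct_unambiguous = n_unamb,
                 distinct_ambiguous = n_amb,
                 distinct_unmapped = n_unmapped,
                 distinct_mapped = n_unamb + n_amb,
                 genes_all = genes_all,
                 genes_unambiguous = data.table::uniqueN(unamb$gene_id),
                 mapped_copies = sum(gene_counts$count),
                 reference_genes = index$genes,
                 reference_size = index$reference_size),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf(paste0(
    "mapping_result '%s': %d unambiguous / %d ambiguous / %d unmapped ",
    "distinct tags; %d of %d genes hit\n"),
    x$library_id, x$distinct_unambiguous, x$distinct_ambiguous,
    x$distinct_unmapped, x$genes_all, x$reference_size))
  invisible(x)
}

#' Table-1-style mapping percentages
#'
#' Percentages are rounded half-up to 2 decimals, matching the formatting
#' of printed DGE library-statistics tables.
#'
#' @param result a [map_tags()] result.
#' @param lib the [tag_library()] the result was produced from.
#' @param index the [build_tag_index()] used.
#' @return list with `pct_distinct_mapped_of_clean` (mapped distinct tags,
#'   ambiguous included, as % of clean distinct tags), `pct_genes_all` and
#'   `pct_genes_unambiguous` (as % of reference genes).
#' @export
mapping_statistics <- function(result, lib, index) {
  stopifnot(inherits(result, "mapping_result"),
            inherits(lib, "tag_library"), inherits(index, "tag_index"))
  check(index$reference_size > 0,
        "undefined percentage: reference_size is 0")
  n_distinct <- nrow(lib$tag_counts)
  list(
    pct_distinct_mapped_of_clean =
      if (n_distinct == 0L) 0 else
        pct(result$distinct_mapped, n_distinct, 2L),
    pct_genes_all = pct(result$genes_all, index$reference_size, 2L),
    pct_genes_unambiguous =
      pct(result$genes_unambiguous, index$reference_size, 2L))
}

#' Serialize a tag index as TSV (tag, gene_id, strand, offset)
#' @param index a `tag_index`.
#' @param path output TSV path.
#' @export
write_tag_index_tsv <- function(index, path) {
  stopifnot(inherits(index, "tag_index"))
  data.table::fwrite(index$entries, path, sep = "\t")
  invisible(path)
}
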