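# End-to-end orchestration: clean -> index -> map -> diffexp -> enrich,
# with library-statistics reporting and a recompute-and-diff verifier.
# Every number in the reports is re-derivable from the serialized
# intermediate files; the manifest records inputs, thresholds and seeds
# (no timestamps, so a rerun is byte-identical).

#' Specify a within-species comparison
#'
#' @param name comparison label, e.g. "MT_vs_MC".
#' @param library_treated,library_control library ids; both must map
#'   against the same species reference.
#' @param reference_id the species reference both libraries map against.
#' @return a `comparison_spec` list.
#' @export
comparison_spec <- function(name, library_treated, library_control,
                            reference_id) {
  structure(list(name = name, library_treated = library_treated,
                 library_control = library_control,
                 reference_id = reference_id),
            class = "comparison_spec")
}

#' Table-1-style library statistics report
#'
#' Formats per-library statistics in the conventional DGE
#' sequencing-statistics layout: raw totals, clean totals, distinct-tag
#' mapping counts with "% of clean tag", and all/unambiguous tag-mapped
#' gene counts with "% of reference genes". Percentages are rounded
#' half-up to 2 decimals and suffixed with "%".
#'
#' @param stats a list of per-library records, each a list with fields
#'   `library_id`, `raw_total`, `raw_distinct`, `clean_total`,
#'   `clean_distinct`, `distinct_mapped`, `genes_all`,
#'   `genes_unambiguous`, `reference_size`.
#' @return a data.frame with columns Category, Parameter, then one column
#'   per library.
#' @export
table1_report <- function(stats) {
  layout <- data.frame(
    Category = c("Raw tag", "", "Clean tag", "",
                 "All tags mapping to gene", "",
                 "All tag-mapped genes", "",
                 "Unambiguous tag-mapped genes", ""),
    Parameter = c("Total no. of tags", "No. of distinct tags",
                  "Total number", "Distinct Tag number",
                  "No. of distinct tags", "Distinct Tag % of clean tag",
                  "No. of genes", "% of reference genes",
                  "No. of genes", "% of reference genes"),
    stringsAsFactors = FALSE)
  if (length(stats) == 0L) return(layout)
  fmt_pct <- function(x) sprintf("%.2f%%", x)
  for (s in stats) {
    col <- c(format(c(s$raw_total, s$raw_distinct, s$clean_total,
                      s$clean_distinct, s$distinct_mapped),
                    scientific = FALSE, trim = TRUE),
             fmt_pct(pct(s$distinct_mapped, s$clean_distinct, 2L)),
             format(s$genes_all, scientific = FALSE, trim = TRUE),
             fmt_pct(pct(s$genes_all, s$reference_size, 2L)),
             format(s$genes_unambiguous, scientific = FALSE, trim = TRUE),
             fmt_pct(pct(s$genes_unambiguous, s$reference_size, 2L)))
    # interleave: the percentage rows sit after their count rows
    col <- col[c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)]
    layout[[s$library_id]] <- col
  }
  layout
}

# assemble a table1_report() record from pipeline objects
table1_stats <- function(lib, raw_distinct, result, index) {
  list(library_id = lib$library_id,
       raw_total = lib$raw_total,
       raw_distinct = raw_distinct,
       clean_total = lib$clean_total,
       clean_distinct = nrow(lib$tag_counts),
       distinct_mapped = result$distinct_mapped,
       genes_all = result$genes_all,
       genes_unambiguous = result$genes_unambiguous,
       reference_size = index$reference_size)
}

#' Run the full DGE analysis pipeline
#'
#' @param config a list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{references}{named list reference_id -> FASTA path (or
#'       DNAStringSet).}
#'     \item{libraries}{named list library_id -> list(path = FASTQ or
#'       tag-count TSV, reference = reference_id, raw_total = optional for
#'       TSV input). In-memory `tag_reads`/`tag_library` objects are also
#'       accepted in place of `path`.}
#'     \item{comparisons}{list of lists (name, treated, control,
#'       reference) or [comparison_spec()]s.}
#'     \item{annotations}{optional named list reference_id -> annotation
#'       TSV path or table.}
#'     \item{adaptor, quality_threshold, fdr_threshold, lfc_threshold,
#'       enrich_p_threshold, both_strands, tag_length}{optional scalars.}
#'   }
#' @param outdir optional output directory; when given, all tables are
#'   written as TSV plus a JSON manifest, and the bundle is byte-identical
#'   across reruns with the same inputs.
#' @return a list with `libraries` (tag_library), `mappings`,
#'   `profiles`, `table1` (data.frame), `comparisons` (per comparison:
#'   deg_table, summary, pearson_r, enrichment tables) and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  defaults <- list(adaptor = NULL, quality_threshold = 10,
                   fdr_threshold = 0.001, lfc_threshold = 1,
                   enrich_p_threshold = 0.05, both_strands = TRUE,
                   tag_length = 21L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  check(!is.null(config$references) && length(config$references) > 0L,
        "configuration error: no references given")
  check(!is.null(config$libraries) && length(config$libraries) > 0L,
        "configuration error: no libraries given")

  indexes <- lapply(config$references, function(ref) {
    if (is.character(ref) && length(ref) == 1L && is.null(names(ref))) {
      check(file.exists(ref), "file error: no such file: %s", ref)
      ref <- Biostrings::readDNAStringSet(ref)
    }
    build_tag_index(ref, tag_length = config$tag_length,
                    both_strands = config$both_strands)
  })

  libs <- list(); mappings <- list(); profiles <- list(); stats <- list()
  for (id in names(config$libraries)) {
    spec <- config$libraries[[id]]
    ref_id <- spec$reference
    check(!is.null(ref_id) && ref_id %in% names(indexes),
          "configuration error: library %s references unknown '%s'",
          id, ref_id)
    raw_distinct <- NA_real_
    src <- if (!is.null(spec$path)) spec$path else spec$reads
    if (inherits(src, "tag_library")) {
      lib <- src
      lib$library_id <- id
    } else if (inherits(src, "tag_reads") ||
               (is.character(src) && grepl("\\.(fq|fastq)$", src,
                                           ignore.case = TRUE))) {
      if (is.character(src)) {
        check(file.exists(src), "file error: no such file: %s", src)
        src <- read_tag_fastq(src)
      }
      raw_distinct <- length(unique(src$reads))
      lib <- extract_clean_tags(src, adaptor = config$adaptor,
                                quality_threshold =
                                  config$quality_threshold,
                                library_id = id,
                                tag_length = config$tag_length)
    } else if (is.character(src)) {
      lib <- read_tag_counts_tsv(src, library_id = id,
                                 raw_total = spec$raw_total,
                                 tag_length = config$tag_length)
    } else {
      stop(sprintf("configuration error: library %s has no input", id),
           call. = FALSE)
    }
    res <- map_tags(lib, indexes[[ref_id]])
    libs[[id]] <- lib
    mappings[[id]] <- res
    profiles[[id]] <- compute_tpm(res, lib$clean_total)
    stats[[id]] <- table1_stats(lib, raw_distinct, res, indexes[[ref_id]])
  }
  table1 <- table1_report(stats)

  comparisons <- list()
  for (cmp in config$comparisons %||% list()) {
    if (!inherits(cmp, "comparison_spec")) {
      cmp <- comparison_spec(cmp$name, cmp$treated, cmp$control,
                             cmp$reference)
    }
    ref_t <- config$libraries[[cmp$library_treated]]$reference
    ref_c <- config$libraries[[cmp$library_control]]$reference
    check(identical(ref_t, ref_c) && identical(ref_t, cmp$reference_id),
          paste0("configuration error: comparison %s crosses references",
                 " (%s vs %s)"), cmp$name, ref_t, ref_c)
    pa <- profiles[[cmp$library_control]]
    pb <- profiles[[cmp$library_treated]]
    degs <- call_degs(pa, pb, fdr_threshold = config$fdr_threshold,
                      lfc_threshold = config$lfc_threshold)
    out <- list(spec = cmp, deg_table = degs,
                summary = summarize_degs(degs),
                pearson_r = pearson_correlation(pa, pb))
    ann <- config$annotations[[cmp$reference_id]]
    if (!is.null(ann)) {
      if (is.character(ann)) ann <- load_annotation(ann)
      deg_genes <- degs$gene_id[degs$status != "ns"]
      out$enrichment <- lapply(
        stats::setNames(nm = sort(unique(ann$category))),
        function(cat) enrich(deg_genes, ann, cat,
                             p_threshold = config$enrich_p_threshold))
    }
    comparisons[[cmp$name]] <- out
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tagdge")),
    thresholds = config[c("quality_threshold", "fdr_threshold",
                          "lfc_threshold", "enrich_p_threshold")],
    tag_length = config$tag_length,
    both_strands = config$both_strands,
    adaptor = config$adaptor %||% NA,
    references = lapply(config$references, function(r)
      if (is.character(r)) r else "<in-memory>"),
    libraries = lapply(config$libraries, function(s)
      list(reference = s$reference,
           path = if (is.character(s$path %||% s$reads))
             s$path else "<in-memory>")))
  bundle <- list(libraries = libs, mappings = mappings,
                 profiles = profiles, stats = stats, table1 = table1,
                 comparisons = comparisons, manifest = manifest)
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle to a directory
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @export
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (id in names(bundle$libraries)) {
    write_tag_counts_tsv(bundle$libraries[[id]],
                         p(sprintf("tags_%s.tsv", id)))
    data.table::fwrite(bundle$mappings[[id]]$gene_counts,
                       p(sprintf("gene_counts_%s.tsv", id)), sep = "\t")
    data.table::fwrite(
      data.table::as.data.table(bundle$profiles[[id]]),
      p(sprintf("tpm_%s.tsv", id)), sep = "\t")
  }
  jsonlite::write_json(bundle$stats, p("library_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(bundle$table1, p("table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[nm]]
    write_deg_table_tsv(cmp$deg_table, p(sprintf("degs_%s.tsv", nm)))
    jsonlite::write_json(
      c(cmp$summary[c("n_deg", "n_up", "n_down", "pct_up", "pct_down",
                      "pct_1_4", "empty")],
        list(bins = as.list(cmp$summary$bins),
             bin_pct = as.list(cmp$summary$bin_pct),
             pearson_r = cmp$pearson_r)),
      p(sprintf("deg_summary_%s.json", nm)), auto_unbox = TRUE,
      digits = NA)
    for (cat in names(cmp$enrichment %||% list())) {
      write_enrichment_tsv(cmp$enrichment[[cat]],
                           p(sprintf("enrichment_%s_%s.tsv", nm, cat)))
    }
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

read_pipeline_config <- function(path) {
  check(file.exists(path), "file error: no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("configuration error: config must be .yaml/.yml/.json",
         call. = FALSE)
  }
}

#' Verify a written report bundle
#'
#' Recomputes the Table-1 percentages and DEG-summary percentages from the
#' serialized per-library statistics and DEG tables and diffs them against
#' the written reports. Catches any drift between intermediates and
#' reports (there is no hidden state).
#'
#' @param outdir a directory written by [run_pipeline()].
#' @return TRUE invisibly if everything matches; otherwise stops with the
#'   first mismatch.
#' @export
verify_run <- function(outdir) {
  stats <- jsonlite::read_json(file.path(outdir, "library_stats.json"),
                               simplifyVector = FALSE)
  stats <- lapply(stats, function(s) {
    num <- setdiff(names(s), "library_id")
    s[num] <- lapply(s[num], function(v)
      if (is.null(v)) NA_real_ else as.numeric(v))
    s
  })
  table1 <- utils::read.table(file.path(outdir, "table1.tsv"),
                              sep = "\t", header = TRUE,
                              check.names = FALSE,
                              colClasses = "character",
                              na.strings = character(0))
  recomputed <- table1_report(stats)
  check(identical(as.matrix(recomputed), as.matrix(table1)),
        "verification failed: table1.tsv does not match recomputation")
  deg_files <- list.files(outdir, pattern = "^degs_.*\\.tsv$")
  for (f in deg_files) {
    nm <- sub("^degs_(.*)\\.tsv$", "\\1", f)
    degs <- data.table::fread(file.path(outdir, f), sep = "\t")
    s <- summarize_degs(degs)
    written <- jsonlite::read_json(
      file.path(outdir, sprintf("deg_summary_%s.json", nm)),
      simplifyVector = TRUE)
    for (fld in c("n_deg", "n_up", "n_down", "pct_up", "pct_down",
                  "pct_1_4")) {
      check(isTRUE(all.equal(as.numeric(s[[fld]]),
                             as.numeric(written[[fld]]))),
            "verification failed: %s / %s", nm, fld)
    }
  }
  invisible(TRUE)
}
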