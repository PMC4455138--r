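# Clean-tag extraction and library statistics.

#' Construct a tag library
#'
#' A `tag_library` holds one sequencing library's distinct clean 21-nt
#' tags with copy counts plus raw/clean read totals (the library sizes N1,
#' N2 used by the differential test). The constructor enforces the
#' conservation invariant sum(counts) == clean_total <= raw_total and the
#' tag alphabet/length.
#'
#' @param tag_counts a `data.table`/data.frame with columns `tag`, `count`,
#'   or a named integer vector.
#' @param library_id label for the library.
#' @param raw_total number of raw reads the library started from.
#' @param tag_length expected tag length (default 21).
#' @return an object of class `tag_library`.
#' @export
tag_library <- function(tag_counts, library_id = "lib",
                        raw_total = NULL, tag_length = 21L) {
  if (is.numeric(tag_counts) && !is.null(names(tag_counts))) {
    tag_counts <- data.table::data.table(tag = names(tag_counts),
                                         count = as.numeric(tag_counts))
  }
  tag_counts <- data.table::as.data.table(tag_counts)
  check(all(c("tag", "count") %in% names(tag_counts)),
        "tag_counts needs columns 'tag' and 'count'")
  tag_counts <- tag_counts[, list(count = sum(count)), by = "tag"]
  data.table::setorder(tag_counts, tag)
  if (nrow(tag_counts)) {
    check(all(nchar(tag_counts$tag) == tag_length),
          "tag(s) with length != %d", tag_length)
    check(all(grepl("^[ACGT]+$", tag_counts$tag)),
          "tag(s) outside the ACGT alphabet")
    check(all(tag_counts$count >= 1), "non-positive tag count")
  }
  clean_total <- sum(tag_counts$count)
  if (is.null(raw_total)) raw_total <- clean_total
  check(clean_total <= raw_total,
        "clean_total (%d) exceeds raw_total (%d)", clean_total, raw_total)
  structure(list(library_id = library_id,
                 raw_total = as.numeric(raw_total),
                 clean_total = as.numeric(clean_total),
                 tag_counts = tag_counts,
                 tag_length = as.integer(tag_length)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %s raw, %s clean, %s distinct tags\n",
              x$library_id, format(x$raw_total, big.mark = ","),
              format(x$clean_total, big.mark = ","),
              format(nrow(x$tag_counts), big.mark = ",")))
  invisible(x)
}

#' Extract clean tags from raw reads
#'
#' Cleaning removes (i) reads equal to or containing the adaptor artifact
#' (reads longer than the tag are first trimmed at the adaptor and then
#' truncated to `tag_length`; reads left shorter than a tag are dropped),
#' (ii) reads with any base below `quality_threshold` (Phred) and (iii)
#' reads containing an ambiguous base. Survivors are aggregated into
#' distinct-tag counts.
#'
#' @param reads a `tag_reads` object, a FASTQ path, or a character vector
#'   of reads (then `qualities` may be given in parallel).
#' @param adaptor adaptor artifact sequence to remove (`NULL` to skip).
#' @param quality_threshold minimum per-base Phred score (default 10).
#' @param library_id label for the resulting library.
#' @param qualities optional character vector of Phred+33 quality strings,
#'   parallel to `reads` when `reads` is a character vector.
#' @param min_copies drop distinct tags with fewer copies (default 1, i.e.
#'   no copy-number filter).
#' @param tag_length tag length (default 21).
#' @return a [tag_library()].
#' @export
extract_clean_tags <- function(reads, adaptor = NULL,
                               quality_threshold = 10, library_id = "lib",
                               qualities = NULL, min_copies = 1L,
                               tag_length = 21L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fq|fastq)$", reads, ignore.case = TRUE)) {
    reads <- read_tag_fastq(reads)
  }
  if (inherits(reads, "tag_reads")) {
    qualities <- reads$qualities
    if (is.null(adaptor) && !is.na(reads$adaptor)) adaptor <- reads$adaptor
    reads <- reads$reads
  }
  check(is.character(reads), "reads must be character, tag_reads or FASTQ")
  raw_total <- length(reads)
  if (raw_total == 0L) {
    return(tag_library(data.table::data.table(tag = character(0),
                                              count = numeric(0)),
                       library_id, raw_total = 0, tag_length = tag_length))
  }
  reads <- toupper(reads)
  keep <- rep(TRUE, raw_total)
  if (!is.null(adaptor) && !is.na(adaptor) && nzchar(adaptor)) {
    if (nchar(adaptor) == tag_length && all(nchar(reads) == tag_length)) {
      # equal lengths: containment reduces to equality
      hit <- ifelse(reads == adaptor, 1L, -1L)
    } else {
      hit <- regexpr(adaptor, reads, fixed = TRUE)
    }
    has_adaptor <- hit > 0L
    # adaptor read-through on long reads: keep the insert before the
    # adaptor if it is still a full tag, otherwise drop the read
    long <- has_adaptor & nchar(reads) > tag_length & hit > tag_length
    if (any(long)) {
      reads[long] <- substr(reads[long], 1L, hit[long] - 1L)
      has_adaptor[long] <- FALSE
    }
    keep <- keep & !has_adaptor
  }
  keep <- keep & nchar(reads) >= tag_length
  reads <- substr(reads, 1L, tag_length)
  keep <- keep & !grepl("[^ACGT]", reads)
  if (!is.null(qualities)) {
    check(length(qualities) == raw_total,
          "qualities length != number of reads")
    keep <- keep & min_phred(substr(qualities, 1L, tag_length),
                             tag_length) >= quality_threshold
  }
  surv <- reads[keep]
  if (length(surv) == 0L) {
    return(tag_library(data.table::data.table(tag = character(0),
                                              count = numeric(0)),
                       library_id, raw_total = raw_total,
                       tag_length = tag_length))
  }
  counts <- data.table::data.table(tag = surv)
  counts <- counts[, list(count = as.numeric(.N)), by = "tag"]
  if (min_copies > 1L) counts <- counts[counts$count >= min_copies, ]
  tag_library(counts, library_id, raw_total = raw_total,
              tag_length = tag_length)
}

# minimum Phred score per read; deduplicates identical quality strings
# (simulated libraries have very few distinct ones) and uses a rowwise
# pmin sweep instead of a per-read loop
min_phred <- function(qualities, width = NULL) {
  if (!length(qualities)) return(numeric(0))
  uq <- unique(qualities)
  lens <- nchar(uq)
  if (!is.null(width) && all(lens == width)) {
    m <- matrix(utf8ToInt(paste(uq, collapse = "")) - 33L, nrow = width)
    mins <- m[1L, ]
    for (i in seq_len(width)[-1L]) mins <- pmin(mins, m[i, ])
  } else {
    mins <- vapply(uq, function(q) min(utf8ToInt(q)) - 33L, 0L,
                   USE.NAMES = FALSE)
  }
  mins[match(qualities, uq)]
}

#' Summarize a tag library
#'
#' @param lib a [tag_library()].
#' @return list with `library_id`, `raw_total`, `clean_total` and
#'   `distinct_tags` (the Table-1-style library statistics).
#' @export
library_summary <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  list(library_id = lib$library_id,
       raw_total = lib$raw_total,
       clean_total = lib$clean_total,
       distinct_tags = nrow(lib$tag_counts))
}

#' Read a pre-counted tag table (TSV: tag, count)
#' @param path TSV file with columns `tag` and `count` (header optional if
#'   exactly two columns).
#' @param library_id label for the library.
#' @param raw_total raw read total if known; defaults to the clean total.
#' @param tag_length tag length (default 21).
#' @return a [tag_library()].
#' @export
read_tag_counts_tsv <- function(path, library_id = "lib",
                                raw_total = NULL, tag_length = 21L) {
  check(file.exists(path), "file error: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("tag", "count") %in% names(dt))) {
    check(ncol(dt) == 2L,
          "format error: %s must have columns 'tag' and 'count'", path)
    data.table::setnames(dt, c("tag", "count"))
  }
  tag_library(dt, library_id, raw_total = raw_total,
              tag_length = tag_length)
}

#' Write a tag library as TSV (tag, count) plus a JSON totals summary
#' @param lib a [tag_library()].
#' @param path output TSV path; the summary is written next to it as
#'   `<path>.summary.json`.
#' @export
write_tag_counts_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  data.table::fwrite(lib$tag_counts, path, sep = "\t")
  jsonlite::write_json(library_summary(lib),
                       paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
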