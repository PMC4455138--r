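# Synthetic DGE study generator.
#
# Emulates the sampling process behind an NlaIII tag-profiling experiment:
# a reference transcriptome in which every gene carries at least one
# CATG + 17 nt tag site, a planted ground truth of differential expression,
# and raw 21-nt tag libraries with substitution errors, adaptor artifacts
# and low-quality reads. Everything is deterministic given (config, seed).

#' Simulation configuration for a synthetic DGE library
#'
#' Bundles and validates all generator parameters. Defaults describe the
#' study scale the pipeline targets: a reference of thousands of genes,
#' ~6 million raw tags per library, log-normal baseline expression
#' (sd 1.5 on the log2 scale), planted log2 fold changes drawn uniformly
#' from +/-\[1, 4\], 1% per-base substitution error, and small fractions of
#' adaptor and low-quality reads. Tests and examples scale `n_genes` and
#' `library_depth` down.
#'
#' @param n_genes number of genes in the reference (>= 1).
#' @param gene_length_range integer length-2 vector, min/max gene length in
#'   nt; the minimum must be >= 25 so every gene can hold a CATG + 17 nt
#'   tag site.
#' @param de_fraction fraction of genes planted as differentially
#'   expressed.
#' @param frac_up fraction of DE genes that are up-regulated in condition
#'   "B" relative to "A".
#' @param lfc_magnitude_range range of |log2 fold change| for DE genes.
#' @param baseline_meanlog2,baseline_sdlog2 parameters of the log-normal
#'   baseline-abundance law, on the log2 scale.
#' @param library_depth number of raw reads per simulated library.
#' @param error_rate per-base substitution probability (i.i.d.; no indels).
#' @param adaptor_fraction fraction of raw reads replaced by the adaptor
#'   artifact sequence.
#' @param low_quality_fraction fraction of raw reads flagged low quality
#'   (written with quality '#'); removed during cleaning.
#' @param adaptor the 21-nt adaptor artifact sequence.
#' @param tag_length tag length in nt (CATG + 17 = 21 for NlaIII DGE).
#' @param seed integer base seed; all generator randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       gene_length_range = c(200L, 1500L),
                       de_fraction = 0.05,
                       frac_up = 0.5,
                       lfc_magnitude_range = c(1, 4),
                       baseline_meanlog2 = 0,
                       baseline_sdlog2 = 1.5,
                       library_depth = 6e6,
                       error_rate = 0.01,
                       adaptor_fraction = 0.02,
                       low_quality_fraction = 0.01,
                       adaptor = "TCGTATGCCGTCTTCTGCTTG",
                       tag_length = 21L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              de_fraction = de_fraction, frac_up = frac_up,
              lfc_magnitude_range = as.numeric(lfc_magnitude_range),
              baseline_meanlog2 = baseline_meanlog2,
              baseline_sdlog2 = baseline_sdlog2,
              library_depth = as.numeric(library_depth),
              error_rate = error_rate,
              adaptor_fraction = adaptor_fraction,
              low_quality_fraction = low_quality_fraction,
              adaptor = toupper(adaptor),
              tag_length = as.integer(tag_length),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check(is_count1(cfg$n_genes) && cfg$n_genes >= 1L,
        "configuration error: n_genes must be a positive integer")
  check(length(cfg$gene_length_range) == 2L &&
          all(is.finite(cfg$gene_length_range)) &&
          cfg$gene_length_range[1] <= cfg$gene_length_range[2],
        "configuration error: gene_length_range must be an increasing pair")
  check(cfg$gene_length_range[1] >= 25L,
        "configuration error: minimum gene length must be >= 25 nt")
  for (f in c("de_fraction", "frac_up", "error_rate", "adaptor_fraction",
              "low_quality_fraction")) {
    check(length(cfg[[f]]) == 1L && cfg[[f]] >= 0 && cfg[[f]] <= 1,
          "configuration error: %s must lie in [0, 1]", f)
  }
  check(cfg$library_depth >= 0, "configuration error: library_depth < 0")
  check(length(cfg$lfc_magnitude_range) == 2L &&
          all(cfg$lfc_magnitude_range > 0) &&
          cfg$lfc_magnitude_range[1] <= cfg$lfc_magnitude_range[2],
        "configuration error: lfc_magnitude_range must be positive pair")
  check(cfg$tag_length >= 5L, "configuration error: tag_length too short")
  check(nchar(cfg$adaptor) == cfg$tag_length &&
          grepl("^[ACGT]+$", cfg$adaptor),
        "configuration error: adaptor must be a %d-nt ACGT sequence",
        cfg$tag_length)
  check(is_count1(abs(cfg$seed)), "configuration error: bad seed")
  invisible(cfg)
}

# Derived per-operation seeds: a single seeded generator per call, no
# global state leaks (withr restores .Random.seed).
op_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

#' Generate a synthetic reference transcriptome
#'
#' Draws `n_genes` random ACGT sequences with lengths uniform in
#' `gene_length_range` and plants one CATG anchor with >= 17 nt of
#' downstream sequence in each gene, so every gene is guaranteed a tag
#' site. Additional CATG sites arise by chance, as in real transcripts.
#'
#' @param config a [sim_config()].
#' @return a named [Biostrings::DNAStringSet] (gene_0001, gene_0002, ...).
#' @export
generate_transcriptome <- function(config) {
  validate_sim_config(config)
  tl <- config$tag_length
  withr::with_seed(op_seed(config, 101L), {
    # sample.int avoids base::sample's 1:x surprise when min == max
    span <- config$gene_length_range[2] - config$gene_length_range[1] + 1L
    lens <- config$gene_length_range[1] - 1L +
      sample.int(span, config$n_genes, replace = TRUE)
    total <- sum(lens)
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    big <- paste(bases, collapse = "")
    ends <- cumsum(lens)
    seqs <- substring(big, ends - lens + 1L, ends)
    # plant the anchor at a position leaving >= tag_length - 4 nt downstream
    anchor_pos <- 1L + floor(stats::runif(config$n_genes) * (lens - tl + 1L))
    substr(seqs, anchor_pos, anchor_pos + 3L) <- "CATG"
  })
  names(seqs) <- sprintf("gene_%05d", seq_len(config$n_genes))
  Biostrings::DNAStringSet(seqs)
}

#' Canonical tag of each gene
#'
#' The canonical NlaIII tag is the CATG + 17 nt window at the 3'-most CATG
#' site of the sense strand that still has 17 nt downstream -- the classic
#' DGE chemistry cuts at the 3'-most site. Used by the read sampler; the
#' mapper itself accepts any indexed window.
#'
#' @param transcriptome named DNAStringSet or character vector.
#' @param tag_length tag length (default 21).
#' @return named character vector gene id -> canonical tag; NA for genes
#'   without a usable site.
#' @export
canonical_tags <- function(transcriptome, tag_length = 21L) {
  seqs <- ref_as_character(transcriptome)
  lens <- nchar(seqs)
  hits <- gregexpr("CATG", seqs, fixed = TRUE)
  pos <- vapply(seq_along(seqs), function(i) {
    p <- hits[[i]]
    p <- p[p > 0 & p + tag_length - 1L <= lens[i]]
    if (length(p)) max(p) else NA_integer_
  }, integer(1))
  tags <- ifelse(is.na(pos), NA_character_,
                 substr(seqs, pos, pos + tag_length - 1L))
  names(tags) <- names(seqs)
  tags
}

#' Generate planted ground truth of differential expression
#'
#' `round(n_genes * de_fraction)` genes are flagged DE; a fraction
#' `frac_up` of them get positive log2 fold changes with magnitudes drawn
#' uniformly from `lfc_magnitude_range`; everything else has log2_fc = 0.
#' Baseline abundances follow the configured log-normal law (log2 scale).
#'
#' @param config a [sim_config()].
#' @return a `data.table` with columns gene_id, baseline_abundance,
#'   log2_fc, is_de.
#' @export
generate_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  n_de <- as.integer(round(n * config$de_fraction))
  n_up <- as.integer(round(n_de * config$frac_up))
  withr::with_seed(op_seed(config, 211L), {
    baseline <- 2^stats::rnorm(n, config$baseline_meanlog2,
                               config$baseline_sdlog2)
    de_idx <- sample.int(n, n_de)
    mag <- stats::runif(n_de, config$lfc_magnitude_range[1],
                        config$lfc_magnitude_range[2])
    sgn <- rep(c(1, -1), c(n_up, n_de - n_up))
  })
  lfc <- numeric(n)
  lfc[de_idx] <- mag * sgn
  data.table::data.table(gene_id = sprintf("gene_%05d", seq_len(n)),
                         baseline_abundance = baseline,
                         log2_fc = lfc,
                         is_de = seq_len(n) %in% de_idx)
}

#' Sample a raw tag library
#'
#' Draws `library_depth` raw 21-nt reads. Informative reads are canonical
#' gene tags drawn multinomially with probabilities proportional to
#' `baseline_abundance * 2^log2_fc` (the fold change applies in condition
#' "B" only); `adaptor_fraction` of reads are replaced by the adaptor
#' artifact; i.i.d. per-base substitution errors are applied at
#' `error_rate`; `low_quality_fraction` of reads are flagged low quality.
#'
#' @param truth ground-truth table from [generate_truth()].
#' @param transcriptome reference from [generate_transcriptome()].
#' @param condition "A" (control) or "B" (treated).
#' @param config a [sim_config()].
#' @param seed optional explicit seed overriding the one derived from
#'   `config$seed` and `condition`; use to draw replicate libraries from
#'   the same truth.
#' @return a list of class `tag_reads`: `reads` and `qualities` character
#'   vectors of length `library_depth` plus metadata fields.
#' @export
sample_tag_library <- function(truth, transcriptome,
                               condition = c("A", "B"), config,
                               seed = NULL) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  seqs <- ref_as_character(transcriptome)
  check(all(truth$gene_id %in% names(seqs)),
        "generation error: truth gene(s) missing from transcriptome")
  tags <- canonical_tags(seqs[truth$gene_id], config$tag_length)
  if (anyNA(tags)) {
    stop("generation error: gene(s) without a tag site: ",
         paste(utils::head(names(tags)[is.na(tags)], 3L), collapse = ", "))
  }
  depth <- as.integer(config$library_depth)
  tl <- config$tag_length
  if (is.null(seed)) {
    seed <- op_seed(config, 307L + 7L * (condition == "B"))
  }
  if (depth == 0L) {
    return(structure(list(reads = character(0), qualities = character(0),
                          condition = condition, raw_total = 0L,
                          tag_length = tl, adaptor = config$adaptor),
                     class = "tag_reads"))
  }
  probs <- truth$baseline_abundance
  if (condition == "B") probs <- probs * 2^truth$log2_fc
  probs <- probs / sum(probs)
  withr::with_seed(seed, {
    n_adaptor <- stats::rbinom(1L, depth, config$adaptor_fraction)
    gene_counts <- as.vector(stats::rmultinom(1L, depth - n_adaptor, probs))
    reads <- c(rep(unname(tags), gene_counts),
               rep(config$adaptor, n_adaptor))
    reads <- apply_substitutions(reads, tl, config$error_rate)
    lowq <- stats::rbinom(depth, 1L, config$low_quality_fraction) == 1L
  })
  qualities <- rep(strrep("I", tl), depth)
  qualities[lowq] <- strrep("#", tl)
  structure(list(reads = reads, qualities = qualities,
                 condition = condition, raw_total = depth,
                 tag_length = tl, adaptor = config$adaptor),
            class = "tag_reads")
}

# i.i.d. per-base substitutions: per read the error count is
# Binomial(tag_length, rate); affected reads are mutated at uniformly
# chosen positions, each to one of the three other bases. The common
# single-error case is fully vectorized.
apply_substitutions <- function(reads, tag_length, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  n_err <- stats::rbinom(length(reads), tag_length, rate)
  aff <- which(n_err > 0L)
  if (!length(aff)) return(reads)
  k <- n_err[aff]
  ints <- matrix(utf8ToInt(paste(reads[aff], collapse = "")),
                 nrow = tag_length)
  base_ints <- utf8ToInt("ACGT")
  mutate_at <- function(lin, n_mut) {
    cur <- match(ints[lin], base_ints)
    shift <- sample.int(3L, n_mut, replace = TRUE)
    ints[lin] <<- base_ints[((cur - 1L + shift) %% 4L) + 1L]
  }
  one <- which(k == 1L)
  if (length(one)) {
    pos <- sample.int(tag_length, length(one), replace = TRUE)
    mutate_at((one - 1L) * tag_length + pos, length(one))
  }
  for (i in which(k >= 2L)) {
    pos <- sample.int(tag_length, k[i])
    mutate_at((i - 1L) * tag_length + pos, k[i])
  }
  s <- intToUtf8(as.vector(ints))
  n <- length(aff)
  reads[aff] <- substring(s, seq.int(1L, by = tag_length, length.out = n),
                          seq.int(tag_length, by = tag_length,
                                  length.out = n))
  reads
}

#' Generate a gene-to-term annotation table
#'
#' Each gene joins each term independently with probability `base_prob`;
#' for terms listed in `planted_terms`, the odds of membership for DE
#' genes are multiplied by `odds_multiplier`, so enrichment recovery is
#' testable. With `odds_multiplier = 1` membership is independent of DE
#' status.
#'
#' @param truth ground-truth table from [generate_truth()].
#' @param n_terms number of terms to generate.
#' @param planted_terms character vector of term ids (subset of the
#'   generated universe `term_001` ... ) to enrich with DE genes.
#' @param seed integer seed.
#' @param odds_multiplier odds multiplier for DE-gene membership in
#'   planted terms.
#' @param base_prob background membership probability per (gene, term).
#' @param categories categories cycled across terms (e.g. "GO", "KEGG").
#' @return a `data.table` with columns gene_id, term_id, category.
#' @export
generate_annotation <- function(truth, n_terms, planted_terms = character(),
                                seed = 1L, odds_multiplier = 10,
                                base_prob = 0.05,
                                categories = c("GO", "KEGG")) {
  check(is_count1(n_terms), "n_terms must be a non-negative integer")
  term_ids <- sprintf("term_%03d", seq_len(n_terms))
  check(all(planted_terms %in% term_ids),
        "planted_terms outside the term universe")
  if (n_terms == 0L) {
    return(data.table::data.table(gene_id = character(0),
                                  term_id = character(0),
                                  category = character(0)))
  }
  cat_of <- rep_len(categories, n_terms)
  odds0 <- base_prob / (1 - base_prob)
  p_planted_de <- odds0 * odds_multiplier / (1 + odds0 * odds_multiplier)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_terms), function(t) {
      p <- rep(base_prob, nrow(truth))
      if (term_ids[t] %in% planted_terms) p[truth$is_de] <- p_planted_de
      member <- stats::runif(nrow(truth)) < p
      if (!any(member)) return(NULL)
      data.table::data.table(gene_id = truth$gene_id[member],
                             term_id = term_ids[t],
                             category = cat_of[t])
    })
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, category, term_id, gene_id)
  out[]
}

#' Write a reference transcriptome to FASTA
#' @param transcriptome DNAStringSet or named character vector.
#' @param path output file.
#' @export
write_reference_fasta <- function(transcriptome, path) {
  if (!methods::is(transcriptome, "DNAStringSet")) {
    transcriptome <- Biostrings::DNAStringSet(ref_as_character(transcriptome))
  }
  Biostrings::writeXStringSet(transcriptome, path)
  invisible(path)
}

#' Write a raw tag library to FASTQ
#' @param tag_reads a `tag_reads` object from [sample_tag_library()].
#' @param path output file.
#' @export
write_tag_fastq <- function(tag_reads, path) {
  stopifnot(inherits(tag_reads, "tag_reads"))
  if (length(tag_reads$reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(tag_reads$reads)
  names(dna) <- sprintf("read_%07d", seq_along(tag_reads$reads))
  qual <- Biostrings::PhredQuality(tag_reads$qualities)
  # muffle Biostrings' cosmetic note about dropped metadata columns
  withCallingHandlers(
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Read a raw tag library from FASTQ
#' @param path FASTQ file of tag reads.
#' @return a `tag_reads` object.
#' @export
read_tag_fastq <- function(path) {
  check(file.exists(path), "file error: no such file: %s", path)
  qs <- withCallingHandlers(
    tryCatch(Biostrings::readQualityScaledDNAStringSet(path),
             error = function(e) {
               stop(sprintf("format error reading FASTQ %s: %s",
                            path, conditionMessage(e)), call. = FALSE)
             }),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(reads = unname(as.character(qs)),
                 qualities = unname(as.character(Biostrings::quality(qs))),
                 condition = NA_character_,
                 raw_total = length(qs),
                 tag_length = if (length(qs)) nchar(as.character(qs)[1])
                   else 21L,
                 adaptor = NA_character_),
            class = "tag_reads")
}

#' Simulate a full two-species, two-treatment study
#'
#' Builds the four-library design the pipeline targets: two species, each
#' with its own reference transcriptome and ground truth, and one library
#' per (species, host) treatment -- `MC`/`MT` for the first species and
#' `AC`/`AT` for the second. The first species' truth is up-biased
#' (frac_up = 0.8) and the second down-biased (frac_up = 0.17), mirroring
#' the asymmetric regulation the pipeline is designed to summarize.
#'
#' @param config a [sim_config()]; `frac_up` is overridden per species as
#'   described above.
#' @param frac_up_species length-2 numeric, frac_up for the two species.
#' @return list with `references`, `truths`, `configs` (per species) and
#'   `libraries` (tag_reads keyed MC, MT, AC, AT).
#' @export
simulate_study <- function(config, frac_up_species = c(0.8, 0.17)) {
  species <- c("M", "A")
  refs <- list(); truths <- list(); libs <- list(); cfgs <- list()
  for (i in 1:2) {
    cfg <- config
    cfg$frac_up <- frac_up_species[i]
    cfg$seed <- config$seed + 50000L * i
    cfg <- do.call(sim_config, cfg[setdiff(names(cfg), NULL)])
    ref <- generate_transcriptome(cfg)
    truth <- generate_truth(cfg)
    refs[[species[i]]] <- ref
    truths[[species[i]]] <- truth
    cfgs[[species[i]]] <- cfg
    libs[[paste0(species[i], "C")]] <-
      sample_tag_library(truth, ref, "A", cfg)
    libs[[paste0(species[i], "T")]] <-
      sample_tag_library(truth, ref, "B", cfg)
  }
  list(references = refs, truths = truths, configs = cfgs,
       libraries = libs)
}
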