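# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Brute-force two-sided tail summation of the exact two-library count
# statistic: P(Y = j | x) = r^j (x+j)! / (x! j! (1+r)^(x+j+1)), summed
# term by term in log space. Truncated far into the geometric tail.
ac_pvalue_bruteforce <- function(x, y, n1, n2, tail_extra = 4000L) {
  r <- n2 / n1
  j <- 0:(x + y + tail_extra)
  logp <- j * log(r) + lgamma(x + j + 1) - lgamma(x + 1) -
    lgamma(j + 1) - (x + j + 1) * log1p(r)
  pj <- exp(logp)
  min(1, 2 * min(sum(pj[j <= y]), sum(pj[j >= y])))
}

# Exact rational enumeration of the hypergeometric upper tail.
hyper_upper_enum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive exact-match scan: search a CATG-anchored tag against every gene
# sequence and its reverse complement; returns the distinct genes hit.
naive_scan_genes <- function(tag, seqs) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  hit <- grepl(tag, seqs, fixed = TRUE) | grepl(tag, rc, fixed = TRUE)
  names(seqs)[hit]
}

# Random DNA of a given length, from the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A valid random 21-nt tag (CATG + 17 random nt).
random_tag <- function() paste0("CATG", random_dna(17))

# Small in-memory study used by several tests; ... overrides defaults.
tiny_config <- function(...) {
  defaults <- list(n_genes = 120L, gene_length_range = c(100L, 400L),
                   de_fraction = 0.1, frac_up = 0.5, library_depth = 2e4,
                   error_rate = 0.005, adaptor_fraction = 0.02,
                   low_quality_fraction = 0.01, seed = 404L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
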