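# Shared fixtures and an independent brute-force diplotype oracle.

bundle <- load_reference_bundle()

# Brute-force oracle: enumerate every ordered allele pair for the gene and
# keep those whose combined defining-variant multiset exactly matches the
# variant alleles observed at the gene's defining rsIDs (sites absent from
# `calls` count as homozygous reference). Independent of the package's
# matcher: plain loops, no shared helpers.
oracle_diplotypes <- function(calls, gene, bundle) {
  al <- bundle$alleles[bundle$alleles$gene == gene, ]
  keys <- character(0)
  for (v in al$variants) {
    if (length(v) > 0) keys <- c(keys, paste(names(v), v, sep = "="))
  }
  keys <- unique(keys)
  observed <- integer(length(keys))
  names(observed) <- keys
  for (key in keys) {
    kv <- strsplit(key, "=", fixed = TRUE)[[1]]
    pair <- calls[[kv[1]]]
    if (!is.null(pair)) observed[key] <- sum(pair == kv[2])
  }
  hits <- character(0)
  for (i in seq_len(nrow(al))) {
    for (j in seq_len(nrow(al))) {
      combined <- c(al$variants[[i]], al$variants[[j]])
      ok <- TRUE
      for (key in keys) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        n_pair <- sum(names(combined) == kv[1] & combined == kv[2])
        if (n_pair != observed[key]) { ok <- FALSE; break }
      }
      if (ok) {
        a <- sort(c(al$star_allele[i], al$star_allele[j]))
        hits <- c(hits, paste(a, collapse = "|"))
      }
    }
  }
  unique(hits)
}

# Random call set for one gene: each defining rsID is hom-ref, het, hom-alt,
# absent, or (rarely) an explicit missing call.
random_gene_calls <- function(gene, bundle, allow_missing = TRUE) {
  al <- bundle$alleles[bundle$alleles$gene == gene, ]
  variants <- unlist(al$variants)
  rsids <- unique(names(variants))
  calls <- list()
  for (rs in rsids) {
    alt <- unname(variants[names(variants) == rs][1])
    ref <- paste0("ref_", rs)
    state <- sample(c("homref", "het", "homalt", "absent",
                      if (allow_missing) "missing"),
                    1, prob = c(0.35, 0.25, 0.15, 0.15,
                                if (allow_missing) 0.10))
    pair <- switch(state,
                   homref = c(ref, ref),
                   het = c(ref, alt),
                   homalt = c(alt, alt),
                   absent = NULL,
                   missing = c("missing", "missing"))
    if (!is.null(pair)) calls[[rs]] <- pair
  }
  calls
}

make_diplotype <- function(gene, a1, a2) {
  tibble::tibble(gene = gene, allele_1 = a1, allele_2 = a2,
                 diplotype = paste(a1, a2, sep = "/"),
                 determinate = TRUE, ambiguity_note = "")
}
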