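# Shared fixtures: all corpora are generated in code at test time.

# Wrap a named count vector into the codon_counts container (for oracle
# tests that need exact counts without going through a sequence).
make_counts <- function(...) {
  given <- c(...)
  counts <- stats::setNames(integer(64), codon_universe())
  counts[names(given)] <- as.integer(given)
  structure(list(counts = counts, total = sum(counts)),
            class = "codon_counts")
}

# Small corpus with clear class signal, for pipeline tests.
tiny_corpus <- function(n_species = 2, genes_per_species = 120, seed = 101,
                        ...) {
  generate_corpus(synthetic_config(n_species = n_species,
                                   genes_per_species = genes_per_species,
                                   seed = seed, ...))
}

# Compact network configuration keeping unit tests fast; the architecture
# defaults themselves are exercised in the classifier tests.
fast_mlp_config <- function(max_epochs = 30L, patience = 5L, ...) {
  mlp_config(hidden_dims = c(32L, 16L), dropout_rate = 0.2,
             max_epochs = max_epochs, patience = patience,
             batch_size = 64L, ...)
}

# Independent AUC oracle: exhaustive pairwise concordance over all
# positive/negative score pairs, ties counted half.
pairwise_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  grid <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(grid)
}

# Write a FASTA file from a named character vector of sequences.
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  path
}
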