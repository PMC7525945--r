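# Sequence-derived features: codon usage, GC content, gene/protein length,
# relative synonymous codon usage (RSCU), codon adaptation index (CAI) and
# amino-acid composition. Together these form the fixed 89-value feature
# vector used by the classifier.

#' Count in-frame codons of a coding sequence
#'
#' Codons are read as non-overlapping triplets starting at position 0 (the
#' sequence is assumed to be the coding strand in frame). A trailing
#' incomplete triplet is discarded; any triplet containing a non-ACGT
#' character (IUPAC ambiguity codes, gaps) is skipped and does not contribute
#' to the total.
#'
#' @param dna Character scalar, the DNA sequence (case-insensitive).
#' @param id Optional record identifier used in error messages.
#' @return A `codon_counts` object: list with `counts` (named integer vector
#'   over the 64 codons) and `total` (sum of counts).
#' @export
count_codons <- function(dna, id = NULL) {
  who <- if (is.null(id)) "sequence" else sprintf("record '%s'", id)
  if (!is.character(dna) || length(dna) != 1 || is.na(dna) || !nzchar(dna)) {
    stop_invalid_input("%s: empty or missing DNA sequence", who)
  }
  dna <- toupper(dna)
  n <- floor(nchar(dna) / 3)
  counts <- stats::setNames(integer(64), codon_universe())
  if (n > 0) {
    cods <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
    idx <- match(cods, codon_universe())      # ambiguous triplets -> NA
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) {
      counts <- counts + tabulate(idx, nbins = 64)
    }
  }
  total <- sum(counts)
  if (total == 0) {
    stop_invalid_input("%s: no complete unambiguous codon found", who)
  }
  structure(list(counts = counts, total = total), class = "codon_counts")
}

#' Normalized codon frequencies
#'
#' Each gene's raw codon counts are normalized by that gene's total number of
#' complete codons, yielding a per-gene distribution over the 64 codons in
#' lexicographic order.
#'
#' @param counts A `codon_counts` object.
#' @return Named numeric vector of length 64 summing to 1.
#' @export
codon_frequencies <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$total < 1) {
    stop_invalid_input("codon frequencies undefined: total codon count is 0")
  }
  counts$counts / counts$total
}

#' GC content of a DNA sequence
#'
#' Fraction of G and C among the unambiguous A/C/G/T characters; ambiguity
#' letters are excluded from both numerator and denominator.
#'
#' @param dna Character scalar.
#' @param id Optional record identifier used in error messages.
#' @return Numeric scalar in \[0, 1\].
#' @export
gc_content <- function(dna, id = NULL) {
  who <- if (is.null(id)) "sequence" else sprintf("record '%s'", id)
  if (!is.character(dna) || length(dna) != 1 || is.na(dna) || !nzchar(dna)) {
    stop_invalid_input("%s: empty or missing DNA sequence", who)
  }
  s <- strsplit(toupper(dna), "", fixed = TRUE)[[1]]
  acgt <- s[s %in% DNA_BASES]
  if (length(acgt) == 0) {
    stop_invalid_input("%s: no unambiguous A/C/G/T base", who)
  }
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon i in a synonymous family of degeneracy n with family total
#' S = sum of the family's counts, RSCU_i = X_i / (S / n): the observed count
#' relative to the count expected if all synonymous codons were used equally.
#' A family with S = 0 gets RSCU 0 for all its codons. Stop codons form their
#' own family under the chosen code.
#'
#' @param counts A `codon_counts` object.
#' @param code NCBI genetic-code table id (default "11", bacterial).
#' @return An `rscu_table`: list with `rscu` (named numeric over 64 codons)
#'   and `code`.
#' @export
rscu <- function(counts, code = "11") {
  stopifnot(inherits(counts, "codon_counts"))
  fams <- codon_families(code)
  vals <- stats::setNames(numeric(64), codon_universe())
  for (cods in fams) {
    x <- counts$counts[cods]
    s <- sum(x)
    if (s > 0) {
      vals[cods] <- x / (s / length(cods))
    }
  }
  structure(list(rscu = vals, code = as.character(code)), class = "rscu_table")
}

#' Maximum RSCU over degenerate sense families
#'
#' The single-value RSCU feature: the maximum RSCU across codons belonging to
#' degenerate (n >= 2) amino-acid families, excluding methionine, tryptophan
#' and the stop family. An all-zero table returns 0.
#'
#' @param table An `rscu_table`.
#' @return Numeric scalar.
#' @export
rscu_max <- function(table) {
  stopifnot(inherits(table, "rscu_table"))
  map <- genetic_code_map(table$code)
  deg <- codon_degeneracy(table$code)
  keep <- deg >= 2 & !(unname(map) %in% c("M", "W", "*"))
  max(table$rscu[names(deg)[keep]], 0)
}

#' Relative adaptedness of each codon against a reference
#'
#' Within each degenerate amino-acid family of the reference counts, the
#' family's most frequent codon has adaptedness r = 1 and every other codon
#' has r = X_i / X_max, i.e. its count relative to the family maximum
#' (equivalently RSCU_i / RSCU_max within the family). A codon unobserved in
#' an observed family receives the pseudo-value 0.5 / X_max so that CAI never
#' collapses to exactly zero. Methionine, tryptophan and stop codons are not
#' scored, and families with no observation in the reference are dropped.
#'
#' @param reference A `codon_counts` object (the reference set).
#' @param code NCBI genetic-code table id.
#' @param source Free-text description of where the reference counts come
#'   from, stored with the table.
#' @return An `adaptedness_table`: list with `r` (named numeric over scored
#'   codons, values in (0, 1\]), `excluded` (codons without a score) and
#'   `source` (description of the reference).
#' @export
relative_adaptedness <- function(reference, code = "11",
                                 source = "user-supplied reference counts") {
  stopifnot(inherits(reference, "codon_counts"))
  if (reference$total == 0) {
    stop_invalid_input("relative adaptedness: reference has zero total count")
  }
  map <- genetic_code_map(code)
  fams <- codon_families(code)
  fams <- fams[setdiff(names(fams), c("M", "W", "*"))]
  r <- numeric(0)
  for (cods in fams) {
    x <- reference$counts[cods]
    xmax <- max(x)
    if (xmax == 0) next                      # family unobserved: not scored
    ri <- x / xmax
    ri[x == 0] <- 0.5 / xmax
    r <- c(r, ri)
  }
  excluded <- setdiff(codon_universe(), names(r))
  structure(list(r = r, excluded = excluded, source = source,
                 code = as.character(code)),
            class = "adaptedness_table")
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptedness values over the gene's codon
#' occurrences (each occurrence contributes once), skipping codons without a
#' score in the table (methionine, tryptophan, stop codons, unobserved
#' families). Computed in log space for numerical stability. The range is
#' (0, 1]; 1 is attained exactly when the gene uses only family-maximal
#' codons of the reference.
#'
#' @param gene A `codon_counts` object for the gene.
#' @param table An `adaptedness_table`.
#' @param id Optional record identifier used in error messages.
#' @return Numeric scalar in (0, 1].
#' @export
cai <- function(gene, table, id = NULL) {
  stopifnot(inherits(gene, "codon_counts"),
            inherits(table, "adaptedness_table"))
  who <- if (is.null(id)) "gene" else sprintf("record '%s'", id)
  x <- gene$counts[names(table$r)]
  l <- sum(x)
  if (l == 0) {
    stop_invalid_input(
      "%s: CAI undefined, every codon is excluded (Met/Trp/stop or unscored)",
      who)
  }
  exp(sum(x * log(table$r)) / l)
}

#' Amino-acid frequencies of a protein sequence
#'
#' Frequency of each of the 20 standard amino acids among counted residues,
#' in one-letter alphabetical order A..Y. A single trailing "*" (stop) is
#' ignored; non-standard letters (B, J, O, U, X, Z, ...) are skipped and
#' excluded from the denominator.
#'
#' @param protein Character scalar (case-insensitive).
#' @param id Optional record identifier used in error messages.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_frequencies <- function(protein, id = NULL) {
  who <- if (is.null(id)) "protein" else sprintf("record '%s'", id)
  if (!is.character(protein) || length(protein) != 1 || is.na(protein) ||
      !nzchar(protein)) {
    stop_invalid_input("%s: empty or missing protein sequence", who)
  }
  protein <- sub("\\*$", "", toupper(protein))
  s <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- match(s, amino_acid_universe())
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    stop_invalid_input("%s: no standard amino-acid residue", who)
  }
  stats::setNames(tabulate(idx, nbins = 20) / length(idx),
                  amino_acid_universe())
}

# Number of standard residues (the protein-length feature): trailing stop and
# non-standard letters excluded, consistent with aa_frequencies().
protein_length <- function(protein) {
  s <- strsplit(sub("\\*$", "", toupper(protein)), "", fixed = TRUE)[[1]]
  sum(s %in% amino_acid_universe())
}

#' Fixed layout of the 89-value feature vector
#'
#' 64 codon frequencies (codons lexicographic AAA..TTT), GC content, gene
#' length (nucleotides), CAI, RSCU max, 20 amino-acid frequencies (A..Y),
#' protein length (standard residues).
#'
#' @return Character vector of the 89 feature names, in order.
#' @export
feature_layout <- function() {
  c(paste0("codon_", codon_universe()),
    "gc_content", "gene_length", "cai", "rscu_max",
    paste0("aa_", amino_acid_universe()),
    "protein_length")
}

#' Build the 89-value feature vector for one gene/protein pair
#'
#' @param dna Character scalar, coding DNA sequence.
#' @param protein Character scalar, the corresponding protein sequence.
#' @param table Optional `adaptedness_table` used by CAI. The default
#'   (`NULL`) is self-referential: the table is built from the gene's own
#'   codon counts, matching the definition of relative adaptedness via the
#'   gene's codon counts; a pooled per-species reference may be supplied
#'   instead.
#' @param id Optional record identifier used in error messages.
#' @param code NCBI genetic-code table id.
#' @return Named numeric vector of length 89 in `feature_layout()` order.
#' @export
build_feature_vector <- function(dna, protein, table = NULL, id = NULL,
                                 code = "11") {
  counts <- count_codons(dna, id = id)
  if (is.null(table)) {
    table <- relative_adaptedness(counts, code = code,
                                  source = "self (the gene's own counts)")
  }
  v <- c(codon_frequencies(counts),
         gc_content(dna, id = id),
         nchar(dna),
         cai(counts, table, id = id),
         rscu_max(rscu(counts, code = code)),
         aa_frequencies(protein, id = id),
         protein_length(protein))
  stats::setNames(v, feature_layout())
}

#' Feature matrix for a corpus of gene records
#'
#' @param records A corpus data frame with columns `gene_id`, `species`,
#'   `dna`, `protein` (see [read_labeled_fasta_pair()]).
#' @param reference `"self"` (default): the CAI adaptedness table is built
#'   per gene from its own counts. `"species"`: one pooled reference table
#'   per species, built from the summed codon counts of all its genes.
#' @param code NCBI genetic-code table id.
#' @return Numeric matrix, one row per record (rownames = gene_id), 89
#'   columns named by `feature_layout()`.
#' @export
feature_matrix <- function(records, reference = c("self", "species"),
                           code = "11") {
  reference <- match.arg(reference)
  validate_corpus(records)
  tables <- NULL
  if (reference == "species") {
    tables <- lapply(split(records$dna, records$species), function(seqs) {
      pooled <- stats::setNames(integer(64), codon_universe())
      for (s in seqs) {
        pooled <- pooled + count_codons(s)$counts
      }
      relative_adaptedness(
        structure(list(counts = pooled, total = sum(pooled)),
                  class = "codon_counts"),
        code = code, source = "pooled species reference")
    })
  }
  out <- matrix(NA_real_, nrow = nrow(records), ncol = 89,
                dimnames = list(records$gene_id, feature_layout()))
  for (i in seq_len(nrow(records))) {
    tab <- if (is.null(tables)) NULL else tables[[records$species[i]]]
    out[i, ] <- build_feature_vector(records$dna[i], records$protein[i],
                                     table = tab, id = records$gene_id[i],
                                     code = code)
  }
  out
}

#' Write a corpus feature table as delimited text
#'
#' One row per gene: identifier, species, label, then the 89 feature columns
#' with the fixed layout names.
#'
#' @param features Matrix from [feature_matrix()].
#' @param records The corpus data frame the features were computed from.
#' @param path Output path (tab-separated).
#' @export
write_feature_table <- function(features, records, path) {
  stopifnot(nrow(features) == nrow(records))
  df <- data.frame(gene_id = records$gene_id,
                   species = records$species,
                   essential = records$essential,
                   features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
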