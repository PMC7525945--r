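# Codon universe and genetic-code helpers shared by the feature extractors
# and the synthetic-sequence generator.

DNA_BASES <- c("A", "C", "G", "T")

#' The 64 canonical codons in lexicographic order (AAA..TTT)
#'
#' This fixed ordering defines the layout of the codon-frequency block of the
#' feature vector.
#'
#' @return Character vector of length 64.
#' @export
codon_universe <- function() {
  paste0(rep(DNA_BASES, each = 16),
         rep(rep(DNA_BASES, each = 4), times = 4),
         rep(DNA_BASES, times = 16))
}

#' The 20 standard amino acids in one-letter alphabetical order (A..Y)
#'
#' @return Character vector of length 20.
#' @export
amino_acid_universe <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Codon -> amino-acid map for an NCBI translation-table id, reordered to the
# lexicographic codon universe. Stop codons map to "*". Default is table 11
# (bacterial, archaeal and plant plastid), whose codon assignments coincide
# with the standard code.
genetic_code_map <- local({
  cache <- new.env(parent = emptyenv())
  function(code = "11") {
    code <- as.character(code)
    if (!is.null(cache[[code]])) {
      return(cache[[code]])
    }
    gc <- tryCatch(Biostrings::getGeneticCode(code),
                   error = function(e) NULL)
    if (is.null(gc)) {
      stop_config("unknown genetic-code id '%s'", code)
    }
    gc <- gc[codon_universe()]
    attr(gc, "alt_init_codons") <- NULL
    cache[[code]] <- gc
    gc
  }
})

# Synonymous families: a named list mapping each amino acid (and "*" for the
# stop family) to its codons, in codon-universe order.
codon_families <- function(code = "11") {
  map <- genetic_code_map(code)
  split(names(map), factor(unname(map)))
}

# Degeneracy n of the family each codon belongs to, named by codon.
codon_degeneracy <- function(code = "11") {
  map <- genetic_code_map(code)
  fam_size <- table(unname(map))
  stats::setNames(as.integer(fam_size[unname(map)]), names(map))
}

# Translate an in-frame coding sequence (character scalar) to its protein,
# dropping a single terminal stop if present. Used by the synthetic generator.
translate_cds <- function(dna, code = "11") {
  map <- genetic_code_map(code)
  n <- floor(nchar(dna) / 3)
  cods <- substring(toupper(dna), 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(map[cods])
  if (anyNA(aa)) {
    stop_invalid_input("cannot translate: ambiguous codon in '%s...'",
                       substr(dna, 1, 12))
  }
  if (length(aa) > 0 && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste0(aa, collapse = "")
}
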