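# Reading DEG-style paired DNA/protein FASTA files and orthology cluster
# tables into a validated corpus data frame (one row per gene).

corpus_columns <- c("gene_id", "species", "dna", "protein", "essential",
                    "cluster_id")

# Check the corpus contract: required columns, unique non-empty gene ids,
# non-empty sequences.
validate_corpus <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("gene_id", "species", "dna", "protein") %in% names(records))) {
    stop_invalid_input(
      "corpus must be a data frame with columns gene_id, species, dna, protein")
  }
  if (anyDuplicated(records$gene_id)) {
    dup <- records$gene_id[duplicated(records$gene_id)][1]
    stop_invalid_input("duplicate gene identifier '%s' in corpus", dup)
  }
  empty <- !nzchar(records$dna) | !nzchar(records$protein)
  if (any(empty)) {
    stop_invalid_input("record '%s' has an empty sequence",
                       records$gene_id[which(empty)[1]])
  }
  invisible(records)
}

fasta_ids <- function(x, id_pattern = NULL) {
  nm <- names(x)
  if (is.null(id_pattern)) {
    sub("\\s.*$", "", nm)
  } else {
    m <- regmatches(nm, regexpr(id_pattern, nm))
    if (length(m) != length(nm)) {
      stop_invalid_input("id pattern '%s' failed to match every FASTA header",
                         id_pattern)
    }
    m
  }
}

#' Read a paired DNA/protein FASTA file into labeled gene records
#'
#' Records are matched across the two files by identifier: by default the
#' first whitespace-delimited token of each FASTA header, or the match of
#' `id_pattern` if given. One record is returned per identifier present in
#' both files, in DNA-file order; identifiers present in only one file are
#' reported with a warning and skipped.
#'
#' @param dna_path Path to the DNA (nucleotide) FASTA.
#' @param protein_path Path to the protein FASTA.
#' @param species Species accession attached to every record.
#' @param essential Logical label attached to every record.
#' @param id_pattern Optional regular expression; its match on the header is
#'   used as the identifier instead of the first token.
#' @return A corpus data frame with columns gene_id, species, dna, protein,
#'   essential, cluster_id (NA until [attach_clusters()]).
#' @export
read_labeled_fasta_pair <- function(dna_path, protein_path, species,
                                    essential, id_pattern = NULL) {
  dna_set <- tryCatch(Biostrings::readDNAStringSet(dna_path),
                      error = function(e) {
                        stop_io("cannot read DNA FASTA '%s': %s",
                                dna_path, conditionMessage(e))
                      })
  aa_set <- tryCatch(Biostrings::readAAStringSet(protein_path),
                     error = function(e) {
                       stop_io("cannot read protein FASTA '%s': %s",
                               protein_path, conditionMessage(e))
                     })
  dna_ids <- fasta_ids(dna_set, id_pattern)
  aa_ids <- fasta_ids(aa_set, id_pattern)
  for (ids in list(dna = dna_ids, protein = aa_ids)) {
    if (anyDuplicated(ids)) {
      stop_invalid_input("duplicated identifier '%s' in FASTA input",
                         ids[duplicated(ids)][1])
    }
  }
  common <- dna_ids[dna_ids %in% aa_ids]
  orphans <- c(setdiff(dna_ids, aa_ids), setdiff(aa_ids, dna_ids))
  if (length(orphans) > 0) {
    warning(sprintf("%d unpaired record(s) skipped: %s",
                    length(orphans),
                    paste(utils::head(orphans, 5), collapse = ", ")),
            call. = FALSE)
  }
  if (length(common) == 0) {
    stop_invalid_input("no DNA/protein record pair shares an identifier")
  }
  records <- data.frame(
    gene_id = common,
    species = as.character(species),
    dna = as.character(dna_set)[match(common, dna_ids)],
    protein = as.character(aa_set)[match(common, aa_ids)],
    essential = isTRUE(essential),
    cluster_id = NA_character_,
    stringsAsFactors = FALSE)
  validate_corpus(records)
}

#' Write gene records back to a DNA/protein FASTA pair
#'
#' @param records Corpus data frame.
#' @param dna_path,protein_path Output paths.
#' @export
write_labeled_fasta_pair <- function(records, dna_path, protein_path) {
  validate_corpus(records)
  dna <- Biostrings::DNAStringSet(stats::setNames(records$dna,
                                                  records$gene_id))
  aa <- Biostrings::AAStringSet(stats::setNames(records$protein,
                                                records$gene_id))
  Biostrings::writeXStringSet(dna, dna_path)
  Biostrings::writeXStringSet(aa, protein_path)
  invisible(c(dna_path, protein_path))
}

#' Read a gene-to-cluster membership table
#'
#' Two-column delimited text (gene_id, cluster_id) as produced by an external
#' orthology clustering tool; blank lines and lines starting with `#` are
#' ignored. Genes absent from the file are treated downstream as singleton
#' clusters.
#'
#' @param path Path to the table.
#' @return Named character vector mapping gene_id to cluster_id (possibly
#'   empty).
#' @export
read_cluster_map <- function(path) {
  if (!file.exists(path)) {
    stop_io("cluster map '%s' does not exist", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(lines, "[\t ,]+")
  bad <- vapply(parts, length, 1L) < 2
  if (any(bad)) {
    stop_invalid_input("cluster map line %d has fewer than two columns",
                       which(bad)[1])
  }
  gene <- vapply(parts, `[[`, "", 1)
  clust <- vapply(parts, `[[`, "", 2)
  by_gene <- split(clust, gene)
  conflict <- vapply(by_gene, function(x) length(unique(x)) > 1, TRUE)
  if (any(conflict)) {
    stop_invalid_input("gene '%s' is mapped to more than one cluster",
                       names(by_gene)[conflict][1])
  }
  keep <- !duplicated(gene)
  stats::setNames(clust[keep], gene[keep])
}

#' Attach cluster assignments to a corpus
#'
#' Each record's cluster_id is set from the map; genes absent from the map
#' get a unique singleton cluster id derived from their gene id.
#'
#' @param records Corpus data frame.
#' @param map Named character vector from [read_cluster_map()].
#' @return The corpus with `cluster_id` filled for every record.
#' @export
attach_clusters <- function(records, map) {
  validate_corpus(records)
  cl <- unname(map[records$gene_id])
  singleton <- is.na(cl)
  cl[singleton] <- paste0("singleton:", records$gene_id[singleton])
  records$cluster_id <- cl
  records
}
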