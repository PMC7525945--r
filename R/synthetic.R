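# Synthetic labeled corpora with the statistical structure the predictor
# assumes: class-conditional codon-usage bias, a GC-content offset between
# classes (non-essential higher by default), class-specific length
# distributions, exact in-frame translations, and cross-species orthologous
# gene families sharing a cluster id. The generator makes the whole pipeline
# -- including the homology data-leak experiment -- testable without any
# curated essentiality database.

STOP_CODONS <- c("TAA", "TAG", "TGA")
# E. coli-like stop-codon usage
STOP_WEIGHTS <- c(0.61, 0.09, 0.30)

#' Configuration of the synthetic corpus generator
#'
#' Defaults describe a corpus of 3 bacterial species with 2000 genes each,
#' a 20% essential fraction, a clear class-conditional codon-usage contrast,
#' slightly higher GC in non-essential genes, slightly longer essential
#' genes, 30% of genes in multi-species orthologous families, and 5%
#' per-base divergence within a family.
#'
#' @param n_species Number of species.
#' @param genes_per_species Genes per species.
#' @param essential_fraction Expected fraction of essential genes, in (0,1).
#' @param codon_bias_strength Concentration of the class-conditional tilt of
#'   codon usage (0 = identical class distributions).
#' @param gc_shift Difference in codon GC weighting between classes;
#'   positive values give non-essential genes higher GC content.
#' @param length_log_mean,length_log_sd Named numeric vectors (`essential`,
#'   `nonessential`): log-normal parameters of gene length in codons
#'   (including start and stop); sampled lengths are floored at 30 codons.
#' @param ortholog_family_rate Fraction of genes belonging to multi-species
#'   orthologous families, in \[0,1\].
#' @param mutation_rate Per-base substitution rate within a family, in
#'   \[0,1); substitutions are biased toward third codon positions and never
#'   create internal stops or destroy the start/stop codons.
#' @param label_noise Probability that a cluster unit (a whole family, or a
#'   singleton gene) carries the label opposite to the class its sequences
#'   were generated from. Non-zero values make within-family labels
#'   consistent but between-family labels unpredictable from sequence alone,
#'   which is what exposes the homology data leak.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_species = 3L,
                             genes_per_species = 2000L,
                             essential_fraction = 0.2,
                             codon_bias_strength = 0.5,
                             gc_shift = 0.3,
                             length_log_mean = c(essential = log(320),
                                                 nonessential = log(280)),
                             length_log_sd = c(essential = 0.35,
                                               nonessential = 0.35),
                             ortholog_family_rate = 0.3,
                             mutation_rate = 0.05,
                             label_noise = 0,
                             seed = 1L) {
  if (n_species < 1 || genes_per_species < 1) {
    stop_config("n_species and genes_per_species must be positive")
  }
  if (essential_fraction <= 0 || essential_fraction >= 1) {
    stop_config("essential_fraction must be in (0, 1)")
  }
  if (codon_bias_strength < 0 || ortholog_family_rate < 0 ||
      ortholog_family_rate > 1 || mutation_rate < 0 || mutation_rate >= 1 ||
      label_noise < 0 || label_noise >= 1) {
    stop_config("a rate parameter is outside its valid range")
  }
  for (nm in c("essential", "nonessential")) {
    if (!nm %in% names(length_log_mean) || !nm %in% names(length_log_sd)) {
      stop_config("length parameters must be named 'essential'/'nonessential'")
    }
  }
  structure(list(n_species = as.integer(n_species),
                 genes_per_species = as.integer(genes_per_species),
                 essential_fraction = essential_fraction,
                 codon_bias_strength = codon_bias_strength,
                 gc_shift = gc_shift,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 ortholog_family_rate = ortholog_family_rate,
                 mutation_rate = mutation_rate,
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset configuration for the homology data-leak experiment
#'
#' A smaller balanced corpus dominated by multi-species families with very
#' low within-family divergence and family-level label noise: random
#' splitting lets the classifier memorize family identity across the
#' train/test boundary, while cluster-aware splitting removes that shortcut.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_leak_config <- function(...) {
  defaults <- list(n_species = 4L, genes_per_species = 600L,
                   essential_fraction = 0.5, codon_bias_strength = 0.25,
                   gc_shift = 0.15, ortholog_family_rate = 0.6,
                   mutation_rate = 0.02, label_noise = 0.25, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

sense_codons <- function(code = "11") {
  setdiff(codon_universe(), names(which(genetic_code_map(code) == "*")))
}

codon_gc_fraction <- function(codons) {
  vapply(strsplit(codons, ""), function(s) mean(s %in% c("G", "C")),
         numeric(1))
}

#' Class-conditional codon-usage distributions
#'
#' A base distribution over the 61 sense codons is drawn once from a
#' symmetric Dirichlet; the essential-class distribution is tilted away from
#' it with concentration `codon_bias_strength`, and `gc_shift` reweights
#' GC-rich codons in opposite directions for the two classes (non-essential
#' higher GC for positive shifts). Both distributions are deterministic
#' given the configuration seed.
#'
#' @param config A `synthetic_config`.
#' @return List with named probability vectors `essential` and
#'   `nonessential` over the 61 sense codons, each summing to 1.
#' @export
sample_class_codon_distributions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cods <- sense_codons()
  with_local_seed(stage_seed(config$seed, "class-distributions"), {
    base <- stats::rgamma(length(cods), shape = 5)
    base <- base / sum(base)
    tilt <- stats::rnorm(length(cods))
    gcf <- codon_gc_fraction(cods)
    ess <- base * exp(config$codon_bias_strength * tilt -
                        config$gc_shift * gcf / 2)
    non <- base * exp(config$gc_shift * gcf / 2)
    list(essential = stats::setNames(ess / sum(ess), cods),
         nonessential = stats::setNames(non / sum(non), cods))
  })
}

#' Generate one synthetic gene
#'
#' The gene starts with ATG, continues with `length - 2` sense codons drawn
#' from the class distribution, and ends with a stop codon; the protein is
#' the exact bacterial-code translation of the sense codons.
#'
#' @param distribution Named probability vector over sense codons.
#' @param length Total gene length in codons (including start and stop),
#'   at least 2.
#' @param seed Integer seed; the gene is deterministic given the seed.
#' @return List with `dna` and `protein` character scalars.
#' @export
generate_gene <- function(distribution, length, seed) {
  if (length < 2) {
    stop_invalid_input("gene length must be at least 2 codons")
  }
  with_local_seed(seed, {
    body <- if (length > 2) {
      sample(names(distribution), length - 2, replace = TRUE,
             prob = distribution)
    } else {
      character(0)
    }
    stop_codon <- sample(STOP_CODONS, 1, prob = STOP_WEIGHTS)
    dna <- paste0(c("ATG", body, stop_codon), collapse = "")
    list(dna = dna, protein = translate_cds(dna))
  })
}

# Substitute bases at `rate` per site on average, biased toward third codon
# positions (where most substitutions are synonymous). The start codon is
# untouched; a mutation creating an internal stop or destroying the terminal
# stop is reverted.
mutate_dna <- function(dna, rate) {
  if (rate == 0) return(dna)
  s <- strsplit(dna, "")[[1]]
  n <- length(s)
  pos_in_codon <- ((seq_len(n) - 1) %% 3) + 1
  weight <- c(0.25, 0.25, 2.5)[pos_in_codon]   # mean 1 => average rate kept
  mutable <- seq_len(n) > 3                    # keep the start codon
  hit <- which(mutable & stats::runif(n) < rate * weight)
  if (length(hit) == 0) return(dna)
  orig <- s
  for (i in hit) {
    s[i] <- sample(setdiff(DNA_BASES, s[i]), 1)
  }
  # revert codons that gained an internal stop or lost the terminal stop
  n_cod <- n / 3
  for (ci in unique(ceiling(hit / 3))) {
    rng <- (3 * ci - 2):(3 * ci)
    codon <- paste0(s[rng], collapse = "")
    bad <- if (ci == n_cod) !(codon %in% STOP_CODONS) else codon %in% STOP_CODONS
    if (bad) s[rng] <- orig[rng]
  }
  paste0(s, collapse = "")
}

sample_gene_length <- function(config, essential, n = 1) {
  cls <- if (essential) "essential" else "nonessential"
  pmax(30, round(stats::rlnorm(n, config$length_log_mean[[cls]],
                               config$length_log_sd[[cls]])))
}

#' Generate a labeled multi-species corpus with orthologous families
#'
#' Family genes descend from a generated ancestor copied into at least two
#' species with per-base substitution at `mutation_rate`; all members share
#' the family's label and cluster id. The remaining genes are independent
#' singletons. With `label_noise > 0`, whole cluster units carry a flipped
#' label with that probability (see [synthetic_config()]).
#'
#' @param config A `synthetic_config`.
#' @return List with `records` (corpus data frame, cluster_id filled) and
#'   `cluster_map` (named character vector covering the family genes, as an
#'   external clustering tool would report).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  total <- config$n_species * config$genes_per_species
  if (total < 1) stop_invalid_input("configuration implies an empty corpus")
  dists <- sample_class_codon_distributions(config)
  species <- sprintf("SYN_%04d", seq_len(config$n_species))
  capacity <- stats::setNames(rep(config$genes_per_species, config$n_species),
                              species)
  rows <- vector("list", total)
  row_i <- 0L
  add_record <- function(sp, dna, protein, essential, cluster) {
    row_i <<- row_i + 1L
    capacity[sp] <<- capacity[sp] - 1L
    rows[[row_i]] <<- data.frame(
      gene_id = sprintf("%s_g%05d", sp, config$genes_per_species - capacity[sp]),
      species = sp, dna = dna, protein = protein,
      essential = essential, cluster_id = cluster,
      stringsAsFactors = FALSE)
  }
  with_local_seed(stage_seed(config$seed, "corpus"), {
    target_family_genes <- round(config$ortholog_family_rate * total)
    fam_i <- 0L
    allocated <- 0L
    while (allocated < target_family_genes && sum(capacity > 0) >= 2) {
      open <- names(capacity)[capacity > 0]
      k <- if (length(open) == 2) 2L else sample(2:length(open), 1)
      members <- sample(open, k)
      fam_i <- fam_i + 1L
      fam_id <- sprintf("FAM%05d", fam_i)
      seq_class <- stats::runif(1) < config$essential_fraction
      label <- if (stats::runif(1) < config$label_noise) !seq_class else seq_class
      len <- sample_gene_length(config, seq_class)
      ancestor <- generate_gene(
        dists[[if (seq_class) "essential" else "nonessential"]], len,
        seed = sample.int(.Machine$integer.max, 1))
      for (sp in members) {
        dna <- mutate_dna(ancestor$dna, config$mutation_rate)
        add_record(sp, dna, translate_cds(dna), label, fam_id)
      }
      allocated <- allocated + k
    }
    for (sp in species) {
      while (capacity[sp] > 0) {
        seq_class <- stats::runif(1) < config$essential_fraction
        label <- if (stats::runif(1) < config$label_noise) !seq_class else seq_class
        len <- sample_gene_length(config, seq_class)
        g <- generate_gene(
          dists[[if (seq_class) "essential" else "nonessential"]], len,
          seed = sample.int(.Machine$integer.max, 1))
        add_record(sp, g$dna, g$protein, label, NA_character_)
      }
    }
  })
  records <- do.call(rbind, rows)
  singleton <- is.na(records$cluster_id)
  records$cluster_id[singleton] <-
    paste0("singleton:", records$gene_id[singleton])
  fam_rows <- !singleton
  cluster_map <- stats::setNames(records$cluster_id[fam_rows],
                                 records$gene_id[fam_rows])
  validate_corpus(records)
  list(records = records, cluster_map = cluster_map)
}

#' Write a synthetic corpus in the standard input formats
#'
#' One DNA and one protein FASTA per species and class (e.g.
#' `SYN_0001_essential.fna` / `.faa`), the cluster table `clusters.tsv`
#' covering family genes, and `provenance.json` recording the full
#' configuration and seed.
#'
#' @param corpus List from [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @param config The `synthetic_config` used (stored as provenance).
#' @return The directory, invisibly.
#' @export
write_corpus <- function(corpus, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- corpus$records
  for (sp in unique(records$species)) {
    for (cls in c(TRUE, FALSE)) {
      sub <- records[records$species == sp & records$essential == cls, ,
                     drop = FALSE]
      if (nrow(sub) == 0) next
      stem <- sprintf("%s_%s", sp, if (cls) "essential" else "nonessential")
      write_labeled_fasta_pair(sub,
                               file.path(dir, paste0(stem, ".fna")),
                               file.path(dir, paste0(stem, ".faa")))
    }
  }
  utils::write.table(
    data.frame(gene_id = names(corpus$cluster_map),
               cluster_id = unname(corpus$cluster_map)),
    file.path(dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir Directory containing per-species/class FASTA pairs and
#'   optionally `clusters.tsv`.
#' @return Corpus data frame with cluster assignments attached.
#' @export
read_corpus <- function(dir) {
  fna <- list.files(dir, pattern = "\\.fna$", full.names = TRUE)
  if (length(fna) == 0) {
    stop_io("no DNA FASTA (*.fna) found in '%s'", dir)
  }
  parts <- lapply(fna, function(f) {
    stem <- sub("\\.fna$", "", basename(f))
    essential <- grepl("_essential$", stem)
    sp <- sub("_(non)?essential$", "", stem)
    read_labeled_fasta_pair(f, sub("\\.fna$", ".faa", f),
                            species = sp, essential = essential)
  })
  records <- do.call(rbind, parts)
  cluster_file <- file.path(dir, "clusters.tsv")
  map <- if (file.exists(cluster_file)) read_cluster_map(cluster_file)
         else stats::setNames(character(0), character(0))
  attach_clusters(records, map)
}
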