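# The synthetic corpus generator: class-conditional distributions, gene
# construction, orthologous families and corpus round-trips.

test_that("class codon distributions are valid, seeded and shift with bias", {
  cfg <- synthetic_config(seed = 12)
  d <- sample_class_codon_distributions(cfg)
  expect_length(d$essential, 61)
  expect_equal(sum(d$essential), 1, tolerance = 1e-9)
  expect_equal(sum(d$nonessential), 1, tolerance = 1e-9)
  expect_identical(d, sample_class_codon_distributions(cfg))

  # null effect: no bias and no GC shift collapse the two classes
  null <- sample_class_codon_distributions(
    synthetic_config(codon_bias_strength = 0, gc_shift = 0, seed = 12))
  expect_equal(null$essential, null$nonessential)

  # total-variation distance grows monotonically with the bias strength
  tv <- vapply(c(0, 0.2, 0.5, 1, 2), function(s) {
    d <- sample_class_codon_distributions(
      synthetic_config(codon_bias_strength = s, gc_shift = 0, seed = 12))
    sum(abs(d$essential - d$nonessential)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) > 0))

  # positive gc_shift gives non-essential genes the higher expected GC
  gcfrac <- essnet:::codon_gc_fraction(names(d$essential))
  expect_gt(sum(d$nonessential * gcfrac), sum(d$essential * gcfrac))
})

test_that("generated genes are well-formed coding sequences", {
  d <- sample_class_codon_distributions(synthetic_config(seed = 3))
  g <- generate_gene(d$essential, length = 50, seed = 9)
  expect_equal(nchar(g$dna), 150)
  expect_true(startsWith(g$dna, "ATG"))
  expect_true(substr(g$dna, 148, 150) %in% c("TAA", "TAG", "TGA"))
  expect_equal(essnet:::translate_cds(g$dna), g$protein)
  expect_equal(nchar(g$protein), 49)

  expect_identical(g, generate_gene(d$essential, 50, seed = 9))
  tiny <- generate_gene(d$essential, length = 2, seed = 1)
  expect_equal(tiny$protein, "M")
  expect_equal(nchar(tiny$dna), 6)
  expect_error(generate_gene(d$essential, 1, 1),
               class = "essnet_invalid_input")
})

test_that("corpora respect counts, labels and family structure", {
  cfg <- synthetic_config(n_species = 3, genes_per_species = 100,
                          ortholog_family_rate = 0.4, mutation_rate = 0.05,
                          seed = 21)
  corp <- generate_corpus(cfg)
  rec <- corp$records
  expect_equal(nrow(rec), 300)
  expect_equal(as.integer(table(rec$species)), rep(100L, 3))
  expect_true(all(nchar(rec$dna) %% 3 == 0))
  # every record passes the feature preconditions
  feats <- feature_matrix(rec[sample(nrow(rec), 50), ])
  expect_false(anyNA(feats))

  # family members share the cluster id and the label, and stay similar
  fams <- split(seq_len(nrow(rec)), rec$cluster_id)
  fams <- fams[lengths(fams) >= 2]
  expect_gt(length(fams), 5)
  for (idx in fams[1:5]) {
    expect_length(unique(rec$essential[idx]), 1)
    expect_length(unique(rec$species[idx]), length(idx))
    a <- strsplit(rec$dna[idx[1]], "")[[1]]
    b <- strsplit(rec$dna[idx[2]], "")[[1]]
    expect_gte(mean(a == b), 1 - 4 * cfg$mutation_rate)
  }

  # rate 0: no families at all
  solo <- generate_corpus(synthetic_config(n_species = 3,
                                           genes_per_species = 40,
                                           ortholog_family_rate = 0,
                                           seed = 5))
  expect_equal(length(unique(solo$records$cluster_id)), 120)
  expect_length(solo$cluster_map, 0)

  # mutation rate 0: family members are identical copies
  clone <- generate_corpus(synthetic_config(n_species = 3,
                                            genes_per_species = 40,
                                            ortholog_family_rate = 0.5,
                                            mutation_rate = 0, seed = 5))
  cfams <- split(clone$records$dna, clone$records$cluster_id)
  cfams <- cfams[lengths(cfams) >= 2]
  expect_true(all(vapply(cfams, function(d) length(unique(d)) == 1, TRUE)))
})

test_that("the empirical essential fraction matches the configuration", {
  cfg <- synthetic_config(n_species = 2, genes_per_species = 600, seed = 77)
  rec <- generate_corpus(cfg)$records
  p <- cfg$essential_fraction
  se <- sqrt(p * (1 - p) / nrow(rec))
  # cluster units inflate the variance; allow for the design effect
  expect_lt(abs(mean(rec$essential) - p), 3 * 2 * se)
})

test_that("a corpus round-trips through the on-disk formats", {
  cfg <- synthetic_config(n_species = 2, genes_per_species = 40,
                          ortholog_family_rate = 0.4, seed = 13)
  corp <- generate_corpus(cfg)
  dir <- tempfile("corpus_")
  write_corpus(corp, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "clusters.tsv")))
  expect_true(file.exists(file.path(dir, "provenance.json")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 13)

  back <- read_corpus(dir)
  ord <- match(corp$records$gene_id, back$gene_id)
  expect_false(anyNA(ord))
  back <- back[ord, ]
  for (col in c("gene_id", "species", "dna", "protein", "essential",
                "cluster_id")) {
    expect_equal(back[[col]], corp$records[[col]], ignore_attr = TRUE)
  }
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(essential_fraction = 0),
               class = "essnet_config_error")
  expect_error(synthetic_config(mutation_rate = 1),
               class = "essnet_config_error")
  expect_error(synthetic_config(ortholog_family_rate = 1.2),
               class = "essnet_config_error")
  expect_error(synthetic_config(length_log_mean = c(a = 1, b = 2)),
               class = "essnet_config_error")
  leak <- synthetic_leak_config(seed = 4)
  expect_s3_class(leak, "synthetic_config")
  expect_gt(leak$label_noise, 0)
})
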