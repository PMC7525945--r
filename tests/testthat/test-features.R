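# Codon counting, GC content, RSCU, relative adaptedness, CAI and the
# 89-value feature vector.

test_that("codon counting reads in-frame triplets and tolerates dirty input", {
  cc <- count_codons("ATGAAATGA")
  expect_equal(cc$total, 3)
  expect_equal(cc$counts[["ATG"]], 1)
  expect_equal(cc$counts[["AAA"]], 1)
  expect_equal(cc$counts[["TGA"]], 1)

  # trailing incomplete triplet discarded
  cc <- count_codons("ATGAAAT")
  expect_equal(cc$total, 2)
  expect_equal(unname(cc$counts[c("ATG", "AAA")]), c(1, 1))

  # ambiguous triplet skipped, not counted in the total
  cc <- count_codons("ATGNNNAAA")
  expect_equal(cc$total, 2)
  expect_equal(unname(cc$counts[c("ATG", "AAA")]), c(1, 1))

  # lower case accepted
  expect_equal(count_codons("atgaaa")$total, 2)

  expect_error(count_codons(""), class = "essnet_invalid_input")
  expect_error(count_codons("NNNNNN", id = "gX"), regexp = "gX",
               class = "essnet_invalid_input")
  expect_error(count_codons("AT"), class = "essnet_invalid_input")
})

test_that("codon frequencies normalize per gene and sum to one", {
  f <- codon_frequencies(make_counts(ATG = 1, AAA = 1, TGA = 2))
  expect_equal(f[["ATG"]], 0.25)
  expect_equal(f[["AAA"]], 0.25)
  expect_equal(f[["TGA"]], 0.5)
  expect_equal(sum(f), 1)

  f <- codon_frequencies(make_counts(AAA = 5))
  expect_equal(f[["AAA"]], 1)
  expect_equal(sum(f != 0), 1)

  expect_error(codon_frequencies(make_counts()),
               class = "essnet_invalid_input")

  # property: frequencies of random genes are non-negative and sum to 1
  withr::with_seed(5, {
    for (i in 1:20) {
      g <- paste0(sample(c("A", "C", "G", "T"), 3 * sample(10:80, 1),
                         replace = TRUE), collapse = "")
      f <- codon_frequencies(count_codons(g))
      expect_true(all(f >= 0))
      expect_equal(sum(f), 1, tolerance = 1e-9)
    }
  })
})

test_that("GC content excludes ambiguity codes from both terms", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGN"), 1 / 3)
  expect_error(gc_content("NNN"), class = "essnet_invalid_input")
})

test_that("RSCU compares observed with expected uniform synonymous usage", {
  # 2-fold lysine family AAA/AAG with counts (3, 1)
  tab <- rscu(make_counts(AAA = 3, AAG = 1))
  expect_equal(tab$rscu[["AAA"]], 1.5)
  expect_equal(tab$rscu[["AAG"]], 0.5)
  # unobserved families are all zero
  expect_equal(tab$rscu[["GGG"]], 0)

  # uniform usage in every family gives RSCU exactly 1
  uni <- rscu(make_counts(stats::setNames(rep(1, 64), codon_universe())))
  expect_true(all(uni$rscu == 1))

  expect_error(rscu(make_counts(AAA = 1), code = "no-such-code"),
               class = "essnet_config_error")
})

test_that("mean RSCU within every observed family is 1 for random counts", {
  fams <- essnet:::codon_families("11")
  withr::with_seed(42, {
    for (i in 1:25) {
      counts <- stats::setNames(rpois(64, lambda = sample(1:8, 1)),
                                codon_universe())
      tab <- rscu(make_counts(counts))
      for (cods in fams) {
        if (sum(counts[cods]) > 0) {
          expect_equal(mean(tab$rscu[cods]), 1, tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("maximum RSCU is taken over degenerate non-stop families", {
  counts <- make_counts(AAA = 3, AAG = 1)      # RSCU 1.5 / 0.5
  expect_equal(rscu_max(rscu(counts)), 1.5)

  # single-codon families (Met, Trp) and stop codons never contribute,
  # even when heavily used
  counts <- make_counts(ATG = 50, TGG = 50, TAA = 50, AAA = 2, AAG = 2)
  expect_equal(rscu_max(rscu(counts)), 1)      # only the uniform Lys family

  uni <- rscu(make_counts(stats::setNames(rep(2, 64), codon_universe())))
  expect_equal(rscu_max(uni), 1)

  zero <- structure(list(rscu = stats::setNames(numeric(64),
                                                codon_universe()),
                         code = "11"),
                    class = "rscu_table")
  expect_equal(rscu_max(zero), 0)
})

test_that("relative adaptedness is per-family with a pseudo-count for zeros", {
  tab <- relative_adaptedness(make_counts(AAA = 3, AAG = 1))
  expect_equal(tab$r[["AAA"]], 1)
  expect_equal(tab$r[["AAG"]], 1 / 3)
  # unobserved codon in an observed family with X_max = 4
  tab <- relative_adaptedness(make_counts(GGA = 4, GGC = 2))
  expect_equal(tab$r[["GGG"]], 0.125)
  expect_equal(tab$r[["GGT"]], 0.125)
  # Met/Trp/stop codons are excluded, unobserved families dropped
  expect_true(all(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% tab$excluded))
  expect_false("AAA" %in% names(tab$r))

  expect_error(relative_adaptedness(make_counts()),
               class = "essnet_invalid_input")
})

test_that("adaptedness values lie in (0,1] and every observed family attains 1", {
  fams <- essnet:::codon_families("11")
  fams <- fams[setdiff(names(fams), c("M", "W", "*"))]
  withr::with_seed(7, {
    for (i in 1:20) {
      counts <- stats::setNames(rpois(64, 3), codon_universe())
      if (sum(counts) == 0) next
      tab <- relative_adaptedness(make_counts(counts))
      expect_true(all(tab$r > 0 & tab$r <= 1))
      for (cods in fams) {
        if (max(counts[cods]) > 0) {
          expect_equal(max(tab$r[cods]), 1, tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("CAI is the geometric mean of adaptedness over scored codons", {
  # reference: AAA used 4x, AAG once -> r = 1 and 0.25
  tab <- relative_adaptedness(make_counts(AAA = 4, AAG = 1))
  gene <- make_counts(AAA = 1, AAG = 1)
  expect_equal(cai(gene, tab), sqrt(1 * 0.25))

  # a gene using only family-maximal codons attains exactly 1
  expect_identical(cai(make_counts(AAA = 10), tab), 1)

  # Met + stop only: every codon excluded
  expect_error(cai(count_codons("ATGTGA"), tab),
               class = "essnet_invalid_input")

  # duplication invariance: doubling all counts keeps the geometric mean
  g1 <- count_codons("ATGAAAGGAAAGTTTCCC")
  g2 <- count_codons(paste0("ATGAAAGGAAAGTTTCCC", "ATGAAAGGAAAGTTTCCC"))
  ref <- relative_adaptedness(make_counts(AAA = 5, AAG = 2, GGA = 3,
                                          TTT = 1, CCC = 2))
  expect_equal(cai(g2, ref), cai(g1, ref))
})

test_that("self-referential CAI is 1 iff the gene uses only family-maximal codons", {
  # every used family has a single codon -> all r = 1
  mono <- count_codons("AAAAAAGGATTT")
  expect_equal(cai(mono, relative_adaptedness(mono)), 1)
  # two synonymous codons used unevenly -> CAI < 1
  mixed <- count_codons("AAAAAAAAG")
  expect_lt(cai(mixed, relative_adaptedness(mixed)), 1)
})

test_that("amino-acid frequencies cover the 20 standard residues", {
  f <- aa_frequencies("MK")
  expect_equal(f[["M"]], 0.5)
  expect_equal(f[["K"]], 0.5)
  expect_equal(sum(f), 1)
  expect_equal(names(f), amino_acid_universe())

  expect_equal(aa_frequencies("AAAA")[["A"]], 1)
  expect_equal(aa_frequencies("MK*"), aa_frequencies("MK"))  # trailing stop
  f <- aa_frequencies("MXXK")                                # X skipped
  expect_equal(f[["M"]], 0.5)
  expect_error(aa_frequencies("XXXX"), class = "essnet_invalid_input")
})

test_that("the feature vector has the fixed 89-value layout", {
  v <- build_feature_vector("ATGAAAAAATGA", "MKK", id = "g1")
  expect_length(v, 89)
  expect_identical(names(v), feature_layout())
  expect_equal(sum(startsWith(names(v), "codon_")), 64)
  expect_equal(sum(startsWith(names(v), "aa_")), 20)
  expect_equal(v[["gene_length"]], 12)
  expect_equal(v[["protein_length"]], 3)
  expect_equal(v[["gc_content"]], 2 / 12)   # G in ATG and TGA, no C
  expect_equal(sum(v[startsWith(names(v), "codon_")]), 1, tolerance = 1e-9)
  expect_equal(sum(v[startsWith(names(v), "aa_")]), 1, tolerance = 1e-9)

  # determinism: identical input gives identical output
  expect_identical(v, build_feature_vector("ATGAAAAAATGA", "MKK", id = "g1"))

  # errors carry the record identifier
  expect_error(build_feature_vector("NNN", "MKK", id = "bad_gene"),
               regexp = "bad_gene")
})

test_that("feature_matrix supports self and pooled species references", {
  corp <- tiny_corpus(genes_per_species = 30)
  f_self <- feature_matrix(corp$records)
  f_spec <- feature_matrix(corp$records, reference = "species")
  expect_identical(dim(f_self), c(60L, 89L))
  expect_identical(rownames(f_self), corp$records$gene_id)
  # only the CAI column depends on the reference choice
  same <- setdiff(colnames(f_self), "cai")
  expect_equal(f_self[, same], f_spec[, same])
  expect_gt(sd(f_self[, "cai"] - f_spec[, "cai"]), 0)
  expect_true(all(f_self[, "cai"] > 0 & f_self[, "cai"] <= 1))
})
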