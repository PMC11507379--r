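test_that("the mitochondrial generator is seeded and validated", {
  a <- make_mito(16727, seed = 1)
  b <- make_mito(16727, seed = 1)
  expect_identical(a$seq, b$seq)
  expect_false(identical(make_mito(16727, seed = 2)$seq, a$seq))
  expect_error(make_mito(999), ">= 1000")
  # GC fraction within 3 sd of 0.5 for a uniform-random sequence
  gc <- sum(strsplit(a$seq, "")[[1]] %in% c("G", "C")) / a$width
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / a$width))
})

test_that("sequence mutation is seeded and matches its stated rates", {
  s <- random_dna_str(10000, 151)
  expect_identical(mutate_sequence(s, 0, 0, seed = 1)$seq, s)
  m1 <- mutate_sequence(s, 0.1, 0.002, seed = 5)
  m2 <- mutate_sequence(s, 0.1, 0.002, seed = 5)
  expect_identical(m1$seq, m2$seq)
  # realized substitution rate within a 99% binomial band of the request
  ci <- binom_ci99(0.1, 10000)
  expect_gte(m1$realized_divergence, ci[1])
  expect_lte(m1$realized_divergence, ci[2])
  # global identity oracle: align a mutated (substitution-only) copy and
  # compare with 1 - realized divergence
  mo <- mutate_sequence(substr(s, 1, 2000), 0.1, 0, seed = 9)
  orc <- sw_oracle(mo$seq, substr(s, 1, 2000))
  expect_lt(abs(orc$pid / 100 - (1 - mo$realized_divergence)), 0.01)
})

test_that("planted assemblies are internally consistent with their truth", {
  mito <- fx_mito()
  spec <- plant_spec(n_numts = 8, len_range = c(200L, 1500L),
                     sub_range = c(0, 0), indel_rate = 0,
                     strand_plus_prob = 1, origin_spanning_fraction = 0.5,
                     fragmented_fraction = 0)
  fx <- build_assembly(spec, mito, seed = 11)
  expect_equal(nrow(fx$truth), 8L)
  expect_equal(sum(fx$truth$origin_spanning), 4L)
  mito2 <- strrep(mito$seq, 2)
  seqs <- stats::setNames(fx$assembly$seq, fx$assembly$name)
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    planted <- substr(seqs[[tr$seqname]], tr$start + 1L, tr$end)
    source <- substr(mito2, tr$mito_start + 1L, tr$mito_start + tr$mito_len)
    expect_identical(planted, source)
    if (tr$origin_spanning) expect_match(tr$mito_interval, ",")
  }
  # reproducibility
  fx2 <- build_assembly(spec, mito, seed = 11)
  expect_identical(fx2$assembly$seq, fx$assembly$seq)
  expect_identical(fx2$truth, fx$truth)
})

test_that("fragmented Numts annotate as one locus with two HSPs", {
  mito <- fx_mito()
  spec <- plant_spec(n_numts = 5, len_range = c(1000L, 2000L),
                     sub_range = c(0, 0.05), indel_rate = 0,
                     origin_spanning_fraction = 0,
                     fragmented_fraction = 1, disruptor_len = 500L)
  fx <- build_assembly(spec, mito, seed = 13)
  expect_true(all(fx$truth$fragmented))
  ann <- annotate_numts(fx$assembly, fx$mito)
  expect_equal(nrow(ann$loci), 5L)
  expect_true(all(ann$loci$n_hsps == 2L))
  res <- match_truth_to_loci(fx$truth, ann$loci)
  expect_equal(res$n_unique, 5L)
  expect_lte(res$max_err, 25L)
})

test_that("dimorphic pairs excise exactly the requested loci", {
  mito <- fx_mito()
  spec <- plant_spec(n_numts = 6, len_range = c(300L, 800L),
                     sub_range = c(0, 0.05), indel_rate = 0,
                     fragmented_fraction = 0, origin_spanning_fraction = 0)
  fx <- build_assembly(spec, mito, seed = 17)
  pair <- derive_dimorphic_pair(fx$assembly, fx$truth,
                                absent_ids = c("planted_001", "planted_002"),
                                large_sv_ids = "planted_003")
  expect_equal(nrow(pair$indels), 3L)
  clean <- pair$indels[pair$indels$numt_id == "planted_001", ]
  tr1 <- fx$truth[fx$truth$numt_id == "planted_001", ]
  expect_equal(c(clean$start, clean$end), c(tr1$start, tr1$end))
  big <- pair$indels[pair$indels$numt_id == "planted_003", ]
  tr3 <- fx$truth[fx$truth$numt_id == "planted_003", ]
  expect_gt(big$length_bp, (tr3$end - tr3$start) + 1000L)
  expect_equal(sum(!pair$truth$present_in_other), 3L)
  # sequence bookkeeping: assembly B lost exactly the excised bases
  lost <- sum(pair$indels$length_bp[pair$indels$seqname == "chr1"])
  a_len <- fx$assembly$width[fx$assembly$name == "chr1"]
  b_len <- pair$assembly$width[pair$assembly$name == "chr1"]
  expect_equal(a_len - b_len, lost)
  # empty excision lists leave the assembly untouched
  none <- derive_dimorphic_pair(fx$assembly, fx$truth, character())
  expect_identical(none$assembly$seq, fx$assembly$seq)
  expect_equal(nrow(none$indels), 0L)
  expect_error(derive_dimorphic_pair(fx$assembly, fx$truth, "nope"),
               "unknown")
})

test_that("the population VCF generator honours fractions and frequencies", {
  mito <- fx_mito()
  fx <- make_population_vcf(mito, n_variants = 6L, n_samples = 10L,
                            partial_fraction = 1, seed = 19,
                            n_decoys = 0L, n_deletions = 0L,
                            freq_range = c(0.999, 0.9999),
                            missing_rate = 0)
  sv <- read_sv_vcf(fx$vcf)
  expect_true(all(is.na(sv$insertions$seq_full)))
  expect_true(all(!is.na(sv$insertions$seq_left)))
  # allele frequency ~1 and no missingness: every sample carries all 6
  expect_true(all(fx$expected_counts$n_numts == 6L))
  # determinism
  fx2 <- make_population_vcf(mito, n_variants = 6L, n_samples = 10L,
                             partial_fraction = 1, seed = 19,
                             n_decoys = 0L, n_deletions = 0L,
                             freq_range = c(0.999, 0.9999),
                             missing_rate = 0)
  expect_identical(fx2$truth, fx$truth)
  expect_identical(fx2$expected_counts, fx$expected_counts)
})

test_that("simulate_numts presets are reproducible and write artifacts", {
  d <- withr::local_tempdir()
  fx <- simulate_numts("basic", seed = 7, dir = d)
  expect_true(file.exists(file.path(d, "assembly.fa")))
  expect_true(file.exists(file.path(d, "mito.fa")))
  expect_true(file.exists(file.path(d, "truth.tsv")))
  back <- read_fasta(file.path(d, "assembly.fa"))
  expect_identical(back$name, fx$assembly$name)
  expect_true(all(back$seq == fx$assembly$seq))
  fx2 <- simulate_numts("basic", seed = 7)
  expect_identical(fx2$assembly$seq, fx$assembly$seq)
  expect_identical(fx2$truth, fx$truth)
})
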