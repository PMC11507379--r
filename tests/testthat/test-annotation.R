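test_that("role-stratified summaries tabulate HSP statistics correctly", {
  roles <- c(chr1 = "chromosome", chrUn_x = "unplaced")
  h1 <- tibble::tibble(
    seqname = "chr1", start = 100L, end = 200L, strand = "+",
    mito_start = 0L, mito_len = 100L, mito_interval = "0-100",
    pident = 99, aligned_bp = 100L, evalue = 1e-9, score = 200,
    L = 16727L
  )
  loci <- merge_hsps(h1)
  s <- summarize_assembly(loci, roles)
  chrom <- s[s$role == "chromosome", ]
  expect_equal(unlist(chrom[, c("hsp_count", "total_size_bp",
                                "max_length_bp", "median_length_bp",
                                "merged_locus_count")], use.names = FALSE),
               c(1, 100, 100, 100, 1))
  expect_equal(s$hsp_count[s$role == "unplaced"], 0L)

  # even-count median is the midpoint
  h2 <- dplyr::bind_rows(h1, dplyr::mutate(h1, start = 9000L, end = 9200L,
                                           mito_start = 5000L,
                                           mito_len = 200L,
                                           aligned_bp = 200L))
  s2 <- summarize_assembly(merge_hsps(h2), roles)
  expect_equal(s2$median_length_bp[s2$role == "chromosome"], 150)
  expect_equal(s2$merged_locus_count[s2$role == "chromosome"], 2L)
})

test_that("coverage_profile counts per-base coverage and conserves totals", {
  L <- 1000L
  h <- tibble::tibble(seqname = "chr1", start = 0L, end = 100L,
                      strand = "+", mito_start = 0L, mito_len = 100L,
                      mito_interval = "0-100", pident = 100,
                      aligned_bp = 100L, evalue = 0, score = 200, L = L)
  cov <- coverage_profile(h, L)
  expect_equal(sum(cov), 100L)
  expect_equal(cov[1:100], rep(1L, 100))
  expect_equal(cov[101:1000], rep(0L, 900))

  # origin-spanning HSP covers both ends
  h$mito_start <- L - 50L
  cov <- coverage_profile(h, L)
  expect_equal(sum(cov), 100L)
  expect_equal(cov[1:50], rep(1L, 50))
  expect_equal(cov[(L - 49):L], rep(1L, 50))
  expect_equal(sum(cov[51:(L - 50)]), 0L)
})

test_that("refinement against the doubled reference recomputes circular HSPs", {
  m <- fx_mito()
  L <- m$width
  # exact origin-spanning 600 bp segment inside a locus extract
  seg <- paste0(substr(m$seq, L - 299, L), substr(m$seq, 1, 300))
  assembly <- seq_record("chr1", paste0(random_dna_str(3000, 71), seg,
                                        random_dna_str(3000, 72)))
  loci <- tibble::tibble(locus_id = "numt_0001", seqname = "chr1",
                         start = 3000L, end = 3600L, strand = "+",
                         n_hsps = 1L, total_aligned_bp = 600L,
                         mean_identity = 100, mito_intervals = "",
                         unconfirmed = FALSE, members = list(tibble::tibble()))
  ref <- refine_loci(loci, assembly, m)
  expect_equal(ref$n_hsps, 1L)
  expect_equal(ref$total_aligned_bp, 600L)
  expect_true(grepl(",", ref$mito_intervals))
  expect_false(ref$unconfirmed)
  mem <- ref$members[[1]]
  expect_equal(mem$start, 3000L)
  expect_equal(mem$end, 3600L)

  # a diverged planted copy: single HSP, identity near its realized value
  seg2 <- substr(m$seq, 7001, 8000)
  mut <- mutate_sequence(seg2, 0.05, 0, seed = 73)
  assembly2 <- seq_record("chr1", paste0(random_dna_str(2000, 74), mut$seq,
                                         random_dna_str(2000, 75)))
  loci2 <- loci
  loci2$start <- 2000L; loci2$end <- 2000L + nchar(mut$seq)
  ref2 <- refine_loci(loci2, assembly2, m)
  expect_equal(ref2$n_hsps, 1L)
  ci <- 100 * binom_ci99(0.95, 1000)
  expect_gte(ref2$mean_identity, ci[1])
  expect_lte(ref2$mean_identity, ci[2])
  oracle <- sw_oracle(mut$seq, seg2)
  expect_lt(abs(ref2$mean_identity - oracle$pid), 1.5)

  # pure random locus is flagged unconfirmed and keeps no members
  loci3 <- loci
  assembly3 <- seq_record("chr1", random_dna_str(8000, 76))
  ref3 <- refine_loci(loci3, assembly3, m)
  expect_true(ref3$unconfirmed)
  expect_equal(ref3$n_hsps, 0L)
})

test_that("locus lists unify within the coordinate tolerance", {
  a <- tibble::tibble(seqname = "chr1", start = 100L, end = 500L)
  b <- tibble::tibble(seqname = "chr1", start = 105L, end = 505L)
  u <- unify_numt_lists(list(x = a, y = b))
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 100L)
  expect_equal(u$end, 505L)
  expect_equal(u$sources, "x,y")

  b2 <- tibble::tibble(seqname = "chr1", start = 111L, end = 500L)
  expect_equal(nrow(unify_numt_lists(list(x = a, y = b2))), 2L)

  # different sequence never unifies
  b3 <- tibble::tibble(seqname = "chr2", start = 100L, end = 500L)
  expect_equal(nrow(unify_numt_lists(list(x = a, y = b3))), 2L)
})

test_that("unification is independent of source order", {
  withr::with_seed(88, {
    mk <- function(n) tibble::tibble(
      seqname = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(0:5000, n), end = 0L
    ) |> dplyr::mutate(end = start + sample(100:1000, n, replace = TRUE))
    srcs <- list(a = mk(15), b = mk(15), c = mk(15))
    u1 <- unify_numt_lists(srcs)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      u2 <- unify_numt_lists(srcs[perm])
      expect_equal(u2[, c("seqname", "start", "end", "n_loci", "sources")],
                   u1[, c("seqname", "start", "end", "n_loci", "sources")])
    }
  })
})

test_that("genomic context classification follows exon > intron > intergenic", {
  genes <- tibble::tibble(seqname = "chr1",
                          start = c(1000L, 9000L), end = c(5000L, 12000L))
  exons <- tibble::tibble(seqname = "chr1",
                          start = c(1000L, 4500L), end = c(1200L, 5000L))
  cpg <- tibble::tibble(seqname = "chr1", start = 1100L, end = 1300L)
  regions <- tibble::tibble(
    seqname = "chr1",
    start = c(2000L, 6000L, 1150L, 9500L),
    end = c(2500L, 6500L, 1400L, 9800L)
  )
  out <- classify_genomic_context(regions, genes, exons, cpg)
  expect_equal(out$context, c("intronic", "intergenic", "exonic", "intronic"))
  expect_equal(out$cpg_flag, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("annotation objects expose tidy, glance and autoplot views", {
  fx <- fx_basic()
  td <- tidy(fx$ann)
  expect_s3_class(td, "tbl_df")
  expect_false("members" %in% names(td))
  expect_equal(nrow(td), nrow(fx$ann$loci))
  gl <- glance(fx$ann)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_loci, nrow(fx$ann$loci))
  expect_equal(gl$total_aligned_bp, sum(fx$ann$hsps$aligned_bp))
  p <- autoplot(fx$ann)
  expect_s3_class(p, "ggplot")
})
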