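iv <- function(seqname, start, end) {
  tibble::tibble(seqname = seqname, start = as.integer(start),
                 end = as.integer(end))
}

test_that("overlap_fraction is the asymmetric covered fraction of a", {
  expect_equal(overlap_fraction(iv("chr1", 0, 100), iv("chr1", 5, 100)), 0.95)
  expect_equal(overlap_fraction(iv("chr1", 0, 100), iv("chr1", 200, 300)), 0)
  expect_equal(overlap_fraction(iv("chr1", 0, 100), iv("chr1", 0, 100)), 1)
  expect_equal(overlap_fraction(iv("chr1", 0, 100), iv("chr2", 0, 100)), 0)
  # asymmetry
  expect_equal(overlap_fraction(iv("chr1", 0, 1000), iv("chr1", 0, 100)), 0.1)
  expect_equal(overlap_fraction(iv("chr1", 0, 100), iv("chr1", 0, 1000)), 1)
})

test_that("absence calls follow the 90% coverage and 1000 bp large-SV rules", {
  hsps <- dplyr::bind_rows(
    iv("chr1", 1000, 1195),   # 195 bp fully inside a 210 bp deletion
    iv("chr1", 5000, 5300),   # 300 bp inside a 5000 bp deletion
    iv("chr1", 9000, 9300)    # 300 bp, deletion covers 260 bp only
  )
  dels <- dplyr::bind_rows(
    iv("chr1", 990, 1200),
    iv("chr1", 3000, 8000),
    iv("chr1", 9040, 9300)
  )
  dels$kind <- "deletion"; dels$length_bp <- dels$end - dels$start
  dels$assembly <- "asmB"
  calls <- call_absence(hsps, dels)
  expect_equal(calls$class, c("absent_clean", "absent_large_sv", "fixed"))
  expect_equal(calls$n_support, c(1L, 1L, 0L))
  # every HSP receives exactly one class
  expect_equal(nrow(calls), nrow(hsps))
})

test_that("absence calling agrees with a brute-force interval scan", {
  withr::with_seed(202, {
    for (rep in 1:10) {
      nh <- 40; nd <- 30
      hs <- iv(sample(c("chr1", "chr2"), nh, TRUE),
               s <- sample(0:50000, nh), s + sample(100:2000, nh, TRUE))
      dl <- iv(sample(c("chr1", "chr2"), nd, TRUE),
               s2 <- sample(0:50000, nd), s2 + sample(100:6000, nd, TRUE))
      dl$kind <- "deletion"; dl$length_bp <- dl$end - dl$start
      dl$assembly <- "other"
      calls <- call_absence(hs, dl)
      # oracle: O(n*m) scan with independent arithmetic
      for (i in seq_len(nh)) {
        hlen <- hs$end[i] - hs$start[i]
        best_frac <- 0; best_len <- NA
        for (j in seq_len(nd)) {
          if (hs$seqname[i] != dl$seqname[j]) next
          ov <- min(hs$end[i], dl$end[j]) - max(hs$start[i], dl$start[j])
          frac <- max(0, ov) / hlen
          if (frac > best_frac ||
              (frac == best_frac && !is.na(best_len) &&
                 abs(dl$length_bp[j] - hlen) < abs(best_len - hlen))) {
            best_frac <- frac; best_len <- dl$length_bp[j]
          }
        }
        want <- if (best_frac >= 0.90) {
          if (best_len > hlen + 1000) "absent_large_sv" else "absent_clean"
        } else "fixed"
        expect_equal(calls$class[i], want)
      }
    }
  })
})

test_that("clean synthetic excisions are recovered exactly", {
  fx <- fx_dimorph()
  calls <- fx$calls
  # partition: every HSP classified once
  expect_equal(nrow(calls), nrow(fx$ann$hsps))
  expect_equal(sum(table(calls$class)), nrow(calls))
  expect_equal(sum(calls$class == "absent_clean"), 10L)
  expect_equal(sum(calls$class == "absent_large_sv"), 5L)
  expect_equal(sum(calls$class == "fixed"),
               nrow(calls) - 15L)
  # each call matches the planted truth at its locus
  tr <- fx$truth
  truth_class <- ifelse(tr$numt_id %in% fx$absent_ids, "absent_clean",
                 ifelse(tr$numt_id %in% fx$large_sv_ids, "absent_large_sv",
                        "fixed"))
  for (i in seq_len(nrow(tr))) {
    sel <- calls$seqname == tr$seqname[i] &
      calls$start < tr$end[i] & calls$end > tr$start[i]
    expect_true(all(calls$class[sel] == truth_class[i]))
  }
})

test_that("novel insertions are classified by mitochondrial content", {
  m <- fx_mito()
  ins <- tibble::tibble(
    id = c("i1", "i2", "i3"),
    seq = c(substr(m$seq, 1001, 1400),                       # exact 400 bp
            paste0(random_dna_str(2200, 91),                 # 5 kb, 600 bp core
                   substr(m$seq, 6001, 6600),
                   random_dna_str(2200, 92)),
            random_dna_str(400, 93))                         # random
  )
  calls <- call_novel_insertions(ins, m)
  expect_equal(nrow(calls), 2L)  # the random insertion is dropped
  expect_equal(calls$class[calls$id == "i1"], "inserted_clean")
  expect_equal(calls$class[calls$id == "i2"], "inserted_large_sv")
  # missing sequences are dropped with a message
  ins$seq[1] <- NA
  expect_message(calls2 <- call_novel_insertions(ins, m), "without sequence")
  expect_false("i1" %in% calls2$id)
})

test_that("Welch's test matches the closed-form statistic and df", {
  welch_oracle <- function(x, y) {
    v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
  }
  cases <- withr::with_seed(303, list(
    list(x = c(80, 81, 82, 83), y = c(95, 96, 97, 98)),
    list(x = c(90, 91, 92), y = c(90, 91, 92)),
    list(x = c(88.2, 93.5, 99.1, 85.0, 91.3), y = c(97.4, 98.8, 96.1)),
    list(x = rnorm(20, 90, 4), y = rnorm(7, 95, 1))
  ))
  for (cs in cases) {
    res <- compare_identity_groups(list(a = cs$x, b = cs$y))
    orc <- welch_oracle(cs$x, cs$y)
    expect_equal(res$t, orc$t, tolerance = 1e-10)
    expect_equal(res$df, orc$df, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  res <- compare_identity_groups(list(a = c(90, 91, 92), b = c(90, 91, 92)))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$stars, "ns")
})

test_that("identity-group comparison excludes tiny groups and makes all pairs", {
  df <- withr::with_seed(404, tibble::tibble(
    group = rep(c("fixed", "absent_clean", "absent_large_sv", "tiny"),
                c(10, 8, 5, 1)),
    identity = c(rnorm(10, 88, 3), rnorm(8, 97, 1), rnorm(5, 96, 1.5), 90)
  ))
  expect_warning(res <- compare_identity_groups(df), "tiny")
  expect_equal(nrow(res), 3L)  # 3 remaining groups -> 3 pairs
  expect_true(all(res$stars %in% c("ns", "*", "**", "***", "****")))
})
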