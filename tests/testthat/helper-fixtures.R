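# Shared fixtures, built once per test run and cached across test files.
.fx_env <- new.env(parent = emptyenv())

fx_cached <- function(name, fun) {
  if (!exists(name, envir = .fx_env)) {
    assign(name, fun(), envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

fx_mito <- function() fx_cached("mito", function() make_mito(seed = 1L))

fx_basic <- function() {
  fx_cached("basic", function() {
    fx <- simulate_numts("basic", seed = 42L)
    fx$ann <- annotate_numts(fx$assembly, fx$mito)
    fx
  })
}

fx_dimorph <- function() {
  fx_cached("dimorph", function() {
    fx <- simulate_numts("dimorph", seed = 42L)
    fx$ann <- annotate_numts(fx$assembly, fx$mito)
    fx$calls <- call_absence(fx$ann$hsps, fx$indels)
    fx
  })
}

fx_population <- function() {
  fx_cached("population", function() {
    fx <- simulate_numts("population", seed = 42L)
    fx$sv <- read_sv_vcf(fx$vcf)
    fx$queries <- assemble_insertion_query(fx$sv$insertions)
    fx$scan <- scan_insertions_for_numts(fx$queries, fx$mito)
    fx
  })
}

fx_outgroup <- function() {
  fx_cached("outgroup", function() {
    fx <- simulate_numts("outgroup", seed = 42L)
    fx$ann <- annotate_numts(fx$assembly, fx$mito)
    fx$calls <- call_outgroup_presence(fx$ann$loci, fx$assembly,
                                       fx$outgroup, fx$mito)
    fx
  })
}

# match each truth row to the annotated loci overlapping it; returns a list
# with the number recovered by exactly one locus and the max boundary error
match_truth_to_loci <- function(truth, loci) {
  n_unique <- 0L
  max_err <- 0L
  for (i in seq_len(nrow(truth))) {
    sel <- which(loci$seqname == truth$seqname[i] &
                   loci$start < truth$end[i] & loci$end > truth$start[i])
    if (length(sel) == 1L) {
      n_unique <- n_unique + 1L
      max_err <- max(max_err,
                     abs(loci$start[sel] - truth$start[i]),
                     abs(loci$end[sel] - truth$end[i]))
    }
  }
  list(n_unique = n_unique, max_err = max_err)
}

# independent Smith-Waterman oracle (exhaustive local DP via Biostrings)
# under the package's scoring scheme; returns percent identity over the
# alignment (gaps included) and the aligned length
sw_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  list(pid = Biostrings::pid(aln, type = "PID1"),
       score = Biostrings::score(aln),
       nchar = Biostrings::nchar(aln))
}

# 99% binomial CI for an observed identity proportion at alignment length n
binom_ci99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - 2.576 * se, p + 2.576 * se)
}

random_dna_str <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# independent closure oracle: pairwise predicate recomputed from scratch,
# components taken with igraph
merge_oracle_partition <- function(h, max_gap = 2000L) {
  n <- nrow(h)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (h$seqname[i] != h$seqname[j] || h$strand[i] != h$strand[j]) next
      nuc_gap <- max(0, max(h$start[i], h$start[j]) -
                       min(h$end[i], h$end[j]))
      if (nuc_gap > max_gap) next
      L <- h$L[i]
      a <- c(h$mito_start[i], h$mito_len[i])
      b <- c(h$mito_start[j], h$mito_len[j])
      pts_a <- (a[1] + seq_len(a[2]) - 1) %% L
      pts_b <- (b[1] + seq_len(b[2]) - 1) %% L
      if (length(intersect(pts_a, pts_b)) > 0) {
        adj[i, j] <- TRUE
        next
      }
      d_fwd <- (b[1] - (a[1] + a[2])) %% L
      d_bwd <- (a[1] - (b[1] + b[2])) %% L
      gap <- min(d_fwd, d_bwd)
      if (gap > max_gap) next
      dir <- if (d_fwd < d_bwd) 1 else if (d_bwd < d_fwd) -1 else 0
      first_nuc <- if (h$start[i] <= h$start[j]) i else j
      want <- if (h$strand[i] == "+") 1 else -1
      if (first_nuc == j) want <- -want
      if (dir == 0 || dir == want) adj[i, j] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  igraph::components(g)$membership
}


# construct a synthetic HSP row
mk_hsp <- function(seqname, start, end, strand, mito_start, mito_len,
                   pident = 95, L = 16727L) {
  tibble::tibble(
    seqname = seqname, start = as.integer(start), end = as.integer(end),
    strand = strand, mito_start = as.integer(mito_start),
    mito_len = as.integer(mito_len),
    mito_interval = mito_interval_string(mito_start, mito_len, L),
    pident = pident, aligned_bp = as.integer(mito_len),
    evalue = 1e-10, score = as.integer(2 * mito_len), L = as.integer(L)
  )
}

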