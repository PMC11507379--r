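#' Local-alignment parameters for Numt discovery
#'
#' The scoring scheme follows the convention used for Numt annotation:
#' +2 for a match, -3 for a mismatch, -5 for opening and -2 for extending a
#' gap, retaining only high-scoring pairs (HSPs) with an e-value below
#' 0.001.
#'
#' @param match,mismatch Match reward and mismatch penalty (mismatch and
#'   gap scores are negative).
#' @param gap_open,gap_extend Gap opening/extension scores.
#' @param evalue_max Maximum e-value for a reported HSP.
#' @param backend `"blastn"` invokes the external NCBI blastn executable
#'   with exactly these scores; `"builtin"` uses the package's own
#'   seed-and-extend aligner (no external binaries required).
#' @param word_size Seed length for the builtin aligner (and blastn `-word_size`).
#' @param xdrop X-drop threshold for builtin ungapped extension.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L,
                             gap_open = -5L, gap_extend = -2L,
                             evalue_max = 1e-3,
                             backend = c("blastn", "builtin"),
                             word_size = 11L, xdrop = 40L) {
  backend <- match.arg(backend)
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            evalue_max > 0, word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_max = evalue_max, backend = backend,
                 word_size = as.integer(word_size), xdrop = as.integer(xdrop)),
            class = "alignment_params")
}

empty_hsp_tbl <- function() {
  tibble(seqname = character(), start = integer(), end = integer(),
         strand = character(), mito_start = integer(), mito_len = integer(),
         mito_interval = character(), pident = numeric(),
         aligned_bp = integer(), evalue = numeric(), score = numeric(),
         L = integer())
}

#' Discover high-scoring pairs between subject sequences and a query
#'
#' Runs a local-alignment search of `query` (typically the mitochondrial
#' reference) against each subject sequence. With `circular = TRUE` the
#' query is doubled internally so that alignments crossing the origin of
#' the circle are found as single HSPs; doubled coordinates are reduced
#' back onto the circle and mirror hits (start in the second copy) are
#' deduplicated.
#'
#' @param subject Sequence record table (one or more nuclear sequences,
#'   merged-locus extracts, or insertion queries).
#' @param query One-row record: the mitochondrial reference (not doubled),
#'   or an arbitrary query with `circular = FALSE`.
#' @param params [alignment_params()].
#' @param circular Treat `query` as a circular sequence (double it and wrap
#'   coordinates).
#' @return Tibble of HSPs: `seqname`, `start`, `end` (0-based half-open on
#'   the subject), `strand` (query strand relative to subject), `mito_start`,
#'   `mito_len` (circular query coordinates), `mito_interval` (comma-pair
#'   rendering), `pident`, `aligned_bp` (aligned query bp), `evalue`,
#'   `score`, `L` (circle length; query length when not circular).
#' @export
discover_hsps <- function(subject, query, params = alignment_params(),
                          circular = TRUE) {
  stopifnot(nrow(query) == 1L, nrow(subject) >= 1L)
  L <- query$width
  q <- if (circular) double_reference(query) else query
  hits <- switch(params$backend,
    blastn = blastn_hsps(subject, q, params),
    builtin = builtin_hsps(subject, q, params)
  )
  if (nrow(hits) == 0L) return(empty_hsp_tbl())
  if (circular) {
    drop <- hits$q_len > L
    if (any(drop)) {
      warning(sum(drop), " HSP(s) longer than the circle dropped")
      hits <- hits[!drop, , drop = FALSE]
    }
    if (nrow(hits) == 0L) return(empty_hsp_tbl())
    hits$q_start <- ifelse(hits$q_start >= L, hits$q_start - L, hits$q_start)
  }
  out <- tibble(
    seqname = hits$seqname,
    start = as.integer(hits$s_start), end = as.integer(hits$s_end),
    strand = hits$strand,
    mito_start = as.integer(hits$q_start), mito_len = as.integer(hits$q_len),
    mito_interval = mito_interval_string(hits$q_start, hits$q_len, L),
    pident = hits$pident, aligned_bp = as.integer(hits$q_len),
    evalue = hits$evalue, score = hits$score, L = as.integer(L)
  )
  out <- dplyr::distinct(out, .data$seqname, .data$start, .data$end,
                         .data$strand, .data$mito_start, .data$mito_len,
                         .keep_all = TRUE)
  if (circular) out <- drop_wrapped_contained(out)
  arrange(out, .data$seqname, .data$start, .data$end)
}

# The doubled reference reports, next to an origin-spanning HSP, the
# sub-alignments of its two arcs against the first and second query copy.
# Drop any HSP whose nuclear interval and circular mito arc are both
# contained in a longer HSP on the same sequence and strand.
drop_wrapped_contained <- function(h) {
  if (nrow(h) <= 1L) return(h)
  h <- h[order(-h$aligned_bp, h$start), , drop = FALSE]
  L <- h$L[1L]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h) - 1L)) {
    if (!keep[i]) next
    j <- (i + 1L):nrow(h)
    cont <- keep[j] &
      h$seqname[j] == h$seqname[i] & h$strand[j] == h$strand[i] &
      h$start[j] >= h$start[i] & h$end[j] <= h$end[i] &
      ((h$mito_start[j] - h$mito_start[i]) %% L) + h$mito_len[j] <=
        h$mito_len[i]
    keep[j][cont] <- FALSE
  }
  h[keep, , drop = FALSE]
}

# ---- external blastn backend -----------------------------------------------

blastn_hsps <- function(subject, query, params) {
  exe <- Sys.which("blastn")
  if (!nzchar(exe)) {
    stop("alignment backend 'blastn' requires the blastn executable on PATH; ",
         "not found (use backend = \"builtin\" for the internal aligner)")
  }
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  write_fasta(query, qf)
  write_fasta(subject, sf)
  args <- c("-task", "blastn",
            "-query", qf, "-subject", sf,
            "-reward", params$match, "-penalty", params$mismatch,
            "-gapopen", -params$gap_open, "-gapextend", -params$gap_extend,
            "-evalue", format(params$evalue_max, scientific = FALSE),
            "-word_size", params$word_size,
            "-dust", "no", "-soft_masking", "false",
            "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue score"))
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("blastn failed (exit ", status, "): ", paste(out, collapse = "\n"))
  }
  out <- out[nzchar(out)]
  if (length(out) == 0L) {
    return(tibble(seqname = character(), s_start = integer(),
                  s_end = integer(), strand = character(),
                  q_start = integer(), q_len = integer(), pident = numeric(),
                  evalue = numeric(), score = numeric(), q_len2 = integer()))
  }
  f <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qseqid", "sseqid", "pident", "length",
                                       "mismatch", "gapopen", "qstart", "qend",
                                       "sstart", "send", "evalue", "score"))
  tibble(
    seqname = f$sseqid,
    s_start = pmin(f$sstart, f$send) - 1L,
    s_end = pmax(f$sstart, f$send),
    strand = ifelse(f$send >= f$sstart, "+", "-"),
    q_start = f$qstart - 1L,
    q_len = f$qend - f$qstart + 1L,
    pident = f$pident,
    evalue = f$evalue,
    score = f$score
  )
}

# ---- builtin seed-and-extend backend ---------------------------------------

# Karlin-Altschul lambda for a match/mismatch scheme under uniform base
# composition; K is fixed at 0.21 (the e-values of the builtin backend are
# approximate by design).
ka_lambda <- function(match, mismatch) {
  uniroot(function(l) 0.25 * exp(match * l) + 0.75 * exp(mismatch * l) - 1,
          c(1e-9, 10), tol = 1e-12)$root
}

encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L  # A
  code[v == 67L] <- 1L  # C
  code[v == 71L] <- 2L  # G
  code[v == 84L] <- 3L  # T
  code
}

kmer_codes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  acc <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) {
    acc <- acc * 4 + code[(1L + j):(n - k + 1L + j)]
  }
  acc
}

builtin_hsps <- function(subject, query, params) {
  lambda <- ka_lambda(params$match, params$mismatch)
  K <- 0.21
  q_fwd <- encode_dna(query$seq)
  q_rev <- rev(3L - q_fwd)
  nq <- length(q_fwd)
  res <- vector("list", 2L * nrow(subject))
  for (i in seq_len(nrow(subject))) {
    s_code <- encode_dna(subject$seq[i])
    ns <- length(s_code)
    search_space <- as.numeric(ns) * nq
    for (strand in c("+", "-")) {
      q_code <- if (strand == "+") q_fwd else q_rev
      h <- seed_extend_one(s_code, q_code, params)
      if (nrow(h) == 0L) next
      h$evalue <- K * search_space * exp(-lambda * h$score)
      h <- h[h$evalue <= params$evalue_max, , drop = FALSE]
      if (nrow(h) == 0L) next
      if (strand == "-") {
        qs <- nq - h$q_end
        h$q_end <- nq - h$q_start
        h$q_start <- qs
      }
      res[[2L * (i - 1L) + (strand == "-") + 1L]] <- tibble(
        seqname = subject$name[i],
        s_start = h$s_start, s_end = h$s_end, strand = strand,
        q_start = h$q_start, q_len = h$q_end - h$q_start,
        pident = 100 * h$matches / h$aln_len,
        evalue = h$evalue, score = h$score
      )
    }
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(seqname = character(), s_start = integer(),
                  s_end = integer(), strand = character(),
                  q_start = integer(), q_len = integer(), pident = numeric(),
                  evalue = numeric(), score = numeric()))
  }
  out
}

# Ungapped seed-and-extend on encoded sequences (one strand), followed by
# collinear chaining that applies the gap penalties. Coordinates in the
# returned data frame are 0-based half-open.
seed_extend_one <- function(s_code, q_code, params) {
  empty <- data.frame(s_start = integer(), s_end = integer(),
                      q_start = integer(), q_end = integer(),
                      matches = integer(), aln_len = integer(),
                      score = numeric())
  k <- params$word_size
  sk <- kmer_codes(s_code, k); qk <- kmer_codes(q_code, k)
  if (length(sk) == 0L || length(qk) == 0L) return(empty)
  s_ok <- which(!is.na(sk)); q_ok <- which(!is.na(qk))
  if (length(s_ok) == 0L || length(q_ok) == 0L) return(empty)
  seeds <- inner_join(
    tibble(spos = s_ok, code = sk[s_ok]),
    tibble(qpos = q_ok, code = qk[q_ok]),
    by = "code", relationship = "many-to-many"
  )
  if (nrow(seeds) == 0L) return(empty)
  seeds$diag <- seeds$spos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$spos), ]
  new_cluster <- c(TRUE, diff(seeds$diag) != 0 | diff(seeds$spos) > 32L)
  cl <- cumsum(new_cluster)
  cl_start <- tapply(seeds$spos, cl, min)
  cl_end <- tapply(seeds$spos, cl, max) + k - 1L
  cl_diag <- tapply(seeds$diag, cl, function(x) x[1])

  ns <- length(s_code); nq <- length(q_code)
  match_s <- params$match; mism_s <- params$mismatch
  xdrop <- params$xdrop
  win <- 20000L
  rows <- vector("list", length(cl_start))
  for (j in seq_along(cl_start)) {
    d <- cl_diag[[j]]
    lo <- max(1L, 1L + d, cl_start[[j]] - win)
    hi <- min(ns, nq + d, cl_end[[j]] + win)
    sidx <- lo:hi
    cmp <- s_code[sidx] == q_code[sidx - d]
    cmp[is.na(cmp)] <- FALSE
    steps <- ifelse(cmp, match_s, mism_s)
    anchor_l <- cl_start[[j]] - lo + 1L
    anchor_r <- cl_end[[j]] - lo + 1L
    # extend right with X-drop
    r_end <- anchor_r
    if (anchor_r < length(steps)) {
      v <- cumsum(steps[(anchor_r + 1L):length(steps)])
      bad <- which(cummax(v) - v > xdrop)
      lim <- if (length(bad)) bad[1L] else length(v)
      best <- which.max(v[seq_len(lim)])
      if (v[best] > 0) r_end <- anchor_r + best
    }
    # extend left with X-drop
    l_start <- anchor_l
    if (anchor_l > 1L) {
      v <- cumsum(steps[(anchor_l - 1L):1L])
      bad <- which(cummax(v) - v > xdrop)
      lim <- if (length(bad)) bad[1L] else length(v)
      best <- which.max(v[seq_len(lim)])
      if (v[best] > 0) l_start <- anchor_l - best
    }
    # trim to the maximal-scoring subsegment (proper local alignment on
    # this diagonal)
    seg <- l_start:r_end
    cs <- cumsum(steps[seg])
    lo_run <- cummin(c(0, cs[-length(cs)]))
    gain <- cs - lo_run
    b <- which.max(gain)
    a <- which(c(0, cs[-length(cs)]) == lo_run[b])
    a <- a[a <= b][1L]
    seg <- seg[a:b]
    score <- gain[b]
    if (score <= 0) next
    m <- sum(cmp[seg])
    rows[[j]] <- c(s_start = lo + seg[1L] - 2L,
                   s_end = lo + seg[length(seg)] - 1L,
                   matches = m, aln_len = length(seg), score = score,
                   diag = d)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  h <- as.data.frame(do.call(rbind, rows))
  h$q_start <- h$s_start - h$diag
  h$q_end <- h$s_end - h$diag
  h <- h[, c("s_start", "s_end", "q_start", "q_end",
             "matches", "aln_len", "score")]
  h <- unique(h)
  h <- drop_contained(h)
  chain_hsps(h, params)
}

# remove HSPs whose subject and query intervals are both contained in a
# higher-scoring HSP
drop_contained <- function(h) {
  h <- h[order(-h$score, h$s_start), ]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      j <- (i + 1L):nrow(h)
      cont <- keep[j] &
        h$s_start[j] >= h$s_start[i] & h$s_end[j] <= h$s_end[i] &
        h$q_start[j] >= h$q_start[i] & h$q_end[j] <= h$q_end[i]
      keep[j][cont] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

# greedy chaining of collinear ungapped HSPs separated by a small gap;
# the gap open/extend penalties are charged here
chain_hsps <- function(h, params, max_shift = 30L, max_gap = 50L) {
  if (nrow(h) <= 1L) return(h)
  repeat {
    h <- h[order(h$q_start, h$s_start), ]
    n <- nrow(h)
    merged <- FALSE
    i <- 1L
    while (i < n) {
      a <- h[i, ]; b <- h[i + 1L, ]
      gap_s <- b$s_start - a$s_end
      gap_q <- b$q_start - a$q_end
      shift <- (b$s_start - b$q_start) - (a$s_start - a$q_start)
      if (gap_s >= 0 && gap_q >= 0 && gap_s <= max_gap && gap_q <= max_gap &&
          abs(shift) <= max_shift) {
        indel <- abs(shift)
        both <- min(gap_s, gap_q)
        pen <- (-params$mismatch) * both +
          if (indel > 0) (-params$gap_open) + (-params$gap_extend) * indel else 0
        sc <- a$score + b$score - pen
        if (sc > max(a$score, b$score)) {
          h$s_end[i] <- b$s_end; h$q_end[i] <- b$q_end
          h$matches[i] <- a$matches + b$matches
          h$aln_len[i] <- a$aln_len + b$aln_len + both + indel
          h$score[i] <- sc
          h <- h[-(i + 1L), , drop = FALSE]
          n <- n - 1L
          merged <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  h
}
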