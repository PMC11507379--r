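#' Parameters for flank-anchored outgroup presence testing
#'
#' @param flank_bp Flanking sequence extracted on each side of a locus.
#' @param min_flank_alignment Minimum aligned bp required within each
#'   flank for a hit to anchor the orthologous position.
#' @param min_numt_coverage Minimum aligned fraction of the Numt interval.
#' @return List of class `outgroup_params`.
#' @export
outgroup_params <- function(flank_bp = 10000L, min_flank_alignment = 2000L,
                            min_numt_coverage = 0.80) {
  stopifnot(min_flank_alignment <= flank_bp,
            min_numt_coverage > 0, min_numt_coverage <= 1)
  structure(list(flank_bp = as.integer(flank_bp),
                 min_flank_alignment = as.integer(min_flank_alignment),
                 min_numt_coverage = min_numt_coverage),
            class = "outgroup_params")
}

#' Extract a Numt locus with flanking sequence
#'
#' Extracts the locus plus `flank_bp` of sequence on each side (clipped at
#' contig bounds, with clipping flagged) and records where the Numt sits
#' inside the extract.
#'
#' @param assembly Sequence record table.
#' @param locus One-row locus tibble (`locus_id`, `seqname`, `start`,
#'   `end`).
#' @param params [outgroup_params()].
#' @return One-row tibble: `name`, `seq`, `width`, `seqname`, `ext_start`,
#'   `ext_end`, `numt_start`, `numt_end` (Numt interval inside the
#'   extract), `left_clipped`, `right_clipped`.
#' @export
extract_locus_with_flanks <- function(assembly, locus,
                                      params = outgroup_params()) {
  stopifnot(nrow(locus) == 1L)
  i <- match(locus$seqname, assembly$name)
  if (is.na(i)) stop("locus sequence '", locus$seqname,
                     "' absent from the assembly")
  w <- assembly$width[i]
  ext_start <- max(0L, locus$start - params$flank_bp)
  ext_end <- min(w, locus$end + params$flank_bp)
  rec <- seq_record(paste0(locus$locus_id, "_flank"),
                    substr(assembly$seq[i], ext_start + 1L, ext_end),
                    role = "unplaced")
  rec$seqname <- locus$seqname
  rec$ext_start <- ext_start
  rec$ext_end <- ext_end
  rec$numt_start <- locus$start - ext_start
  rec$numt_end <- locus$end - ext_start
  rec$left_clipped <- (locus$start - ext_start) < params$flank_bp
  rec$right_clipped <- (ext_end - locus$end) < params$flank_bp
  rec
}

#' Filter outgroup hits by flank and Numt coverage
#'
#' A hit is a chained alignment of the flanked extract against an outgroup
#' assembly, supplied as one row per alignment block. A hit is retained
#' when its blocks align at least `min_flank_alignment` bp within the left
#' flank region and within the right flank region, and cover at least
#' `min_numt_coverage` of the Numt interval. All thresholds are inclusive.
#'
#' @param blocks Tibble of alignment blocks: `hit_id`, `target`,
#'   `q_start`, `q_end` (0-based half-open on the extract), `t_start`,
#'   `t_end` (on the outgroup target).
#' @param extract One-row tibble from [extract_locus_with_flanks()].
#' @param params [outgroup_params()].
#' @return Candidate tibble: `hit_id`, `target`, `t_start`, `t_end`,
#'   `left_aligned`, `right_aligned`, `numt_covered_frac`,
#'   `total_aligned`.
#' @export
filter_outgroup_hits <- function(blocks, extract,
                                 params = outgroup_params()) {
  empty <- tibble(hit_id = character(), target = character(),
                  t_start = integer(), t_end = integer(),
                  left_aligned = integer(), right_aligned = integer(),
                  numt_covered_frac = numeric(), total_aligned = integer())
  if (nrow(blocks) == 0L) return(empty)
  numt_len <- extract$numt_end - extract$numt_start
  out <- lapply(split(blocks, blocks$hit_id), function(b) {
    ir <- IRanges::reduce(IRanges::IRanges(start = b$q_start + 1L,
                                           end = b$q_end))
    covered <- function(lo, hi) { # aligned bases within [lo, hi) on extract
      if (hi <= lo) return(0L)
      sum(IRanges::width(IRanges::restrict(ir, start = lo + 1L, end = hi)))
    }
    left <- covered(0L, extract$numt_start)
    right <- covered(extract$numt_end, extract$width)
    numt_cov <- covered(extract$numt_start, extract$numt_end) / numt_len
    tibble(hit_id = b$hit_id[1L], target = b$target[1L],
           t_start = min(b$t_start), t_end = max(b$t_end),
           left_aligned = left, right_aligned = right,
           numt_covered_frac = numt_cov,
           total_aligned = sum(IRanges::width(ir)))
  })
  out <- bind_rows(out)
  out <- out[out$left_aligned >= params$min_flank_alignment &
               out$right_aligned >= params$min_flank_alignment &
               out$numt_covered_frac >= params$min_numt_coverage, ,
             drop = FALSE]
  arrange(out, dplyr::desc(.data$total_aligned))
}

#' Confirm a candidate orthologous locus against the mitochondrial genome
#'
#' @param candidate One-row sequence record extracted from the outgroup
#'   over a candidate interval.
#' @param mito One-row mitochondrial record.
#' @param params [alignment_params()].
#' @return `"present"` when at least one HSP passes the e-value threshold,
#'   else `"absent"` (the flanks align but the Numt is gone).
#' @export
confirm_candidate <- function(candidate, mito, params = alignment_params()) {
  h <- discover_hsps(candidate, mito, params, circular = TRUE)
  if (nrow(h) > 0L) "present" else "absent"
}

# group HSPs of one extract-vs-outgroup search into chained hits: same
# target, same strand, target positions within max_join of each other, and
# collinear (query order must follow target order for the strand, so a
# paralogous hit elsewhere in the query never joins a flank chain)
chain_outgroup_hits <- function(hsps, max_join = 25000L, slop = 100L) {
  if (nrow(hsps) == 0L) {
    return(tibble(hit_id = character(), target = character(),
                  q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer()))
  }
  h <- arrange(hsps, .data$seqname, .data$strand, .data$start)
  n <- nrow(h)
  qs <- h$mito_start; qe <- h$mito_start + h$mito_len
  collinear <- if (n > 1L) {
    ifelse(h$strand[-1L] == "+",
           qs[-1L] >= qe[-n] - slop,   # '+': query advances with target
           qe[-1L] <= qs[-n] + slop)   # '-': query retreats with target
  } else logical(0)
  brk <- c(TRUE, h$seqname[-1L] != h$seqname[-n] |
             h$strand[-1L] != h$strand[-n] |
             (h$start[-1L] - h$end[-n]) > max_join |
             !collinear)
  h$hit_id <- paste0("hit_", cumsum(brk))
  tibble(hit_id = h$hit_id, target = h$seqname,
         q_start = h$mito_start, q_end = h$mito_start + h$mito_len,
         t_start = h$start, t_end = h$end)
}

#' Test presence of Numt loci in an outgroup assembly
#'
#' For each locus: extract the locus with flanks from the reference
#' assembly, align the extract against the outgroup, chain and filter hits
#' by flank anchoring and Numt coverage, then confirm the best candidate
#' by querying its outgroup sequence against the mitochondrial genome.
#' When no hit passes the Numt-coverage filter but a hit still anchors
#' both flanks, the orthologous position is resolved with the Numt
#' missing; such loci are confirmed the same way and normally come out
#' `absent`. Loci with no flank-anchored hit at all are `unresolved`.
#'
#' @param loci Locus tibble.
#' @param assembly Reference assembly record table.
#' @param outgroup Outgroup assembly record table.
#' @param mito One-row mitochondrial record.
#' @param params [outgroup_params()].
#' @param aln_params [alignment_params()] used for both the flank search
#'   and the confirmation query.
#' @return Tibble: `locus_id`, `status` (`present`/`absent`/`unresolved`),
#'   `target`, `t_start`, `t_end`, `n_candidates`.
#' @export
call_outgroup_presence <- function(loci, assembly, outgroup, mito,
                                   params = outgroup_params(),
                                   aln_params = alignment_params()) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    extract <- extract_locus_with_flanks(assembly, locus, params)
    hs <- discover_hsps(outgroup, extract[, c("name", "seq", "width", "role")],
                        aln_params, circular = FALSE)
    blocks <- chain_outgroup_hits(hs)
    cand <- filter_outgroup_hits(blocks, extract, params)
    if (nrow(cand) == 0L) {
      # fall back to hits anchoring both flanks without Numt coverage:
      # the orthologous position is located, the Numt sequence is not
      flank_only <- params
      flank_only$min_numt_coverage <- 0
      cand <- filter_outgroup_hits(blocks, extract, flank_only)
    }
    if (nrow(cand) == 0L) {
      return(tibble(locus_id = locus$locus_id, status = "unresolved",
                    target = NA_character_, t_start = NA_integer_,
                    t_end = NA_integer_, n_candidates = 0L))
    }
    best <- cand[1L, ]
    j <- match(best$target, outgroup$name)
    cand_rec <- seq_record(paste0(locus$locus_id, "_candidate"),
                           substr(outgroup$seq[j], best$t_start + 1L,
                                  best$t_end),
                           role = "unplaced")
    status <- confirm_candidate(cand_rec, mito, aln_params)
    tibble(locus_id = locus$locus_id, status = status,
           target = best$target, t_start = best$t_start,
           t_end = best$t_end, n_candidates = nrow(cand))
  })
  bind_rows(out)
}
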