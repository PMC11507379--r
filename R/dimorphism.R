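#' Parameters for inter-assembly presence-absence calling
#'
#' @param min_hsp_overlap_fraction Minimum fraction of a Numt HSP that a
#'   deletion variant must cover for the Numt to be called absent.
#' @param large_sv_margin A supporting variant more than this many bp
#'   longer than the Numt HSP is classified as a large structural variant.
#' @return List of class `dimorphism_params`.
#' @export
dimorphism_params <- function(min_hsp_overlap_fraction = 0.90,
                              large_sv_margin = 1000L) {
  stopifnot(min_hsp_overlap_fraction > 0, min_hsp_overlap_fraction <= 1,
            large_sv_margin >= 0)
  structure(list(min_hsp_overlap_fraction = min_hsp_overlap_fraction,
                 large_sv_margin = as.integer(large_sv_margin)),
            class = "dimorphism_params")
}

#' Fraction of interval a covered by interval b
#'
#' Asymmetric by design: returns `|a intersect b| / |a|`, 0 when the
#' intervals are on different sequences. Vectorised over rows.
#'
#' @param a,b Tibbles/data frames with `seqname`, `start`, `end` (0-based
#'   half-open); recycled to a common length.
#' @return Numeric vector in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  inter <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  inter[a$seqname != b$seqname] <- 0L
  inter / (a$end - a$start)
}

#' Call Numt absence from inter-assembly deletion variants
#'
#' Each Numt HSP is intersected with deletion variants (reference sequence
#' present, other assembly lacking). An HSP at least
#' `min_hsp_overlap_fraction` covered by a single deletion is called
#' absent; `absent_large_sv` when the best supporting variant is more than
#' `large_sv_margin` bp longer than the HSP, otherwise `absent_clean`.
#' HSPs with no qualifying variant are `fixed`. Qualifying variants from
#' every assembly are retained as support; the variant with the largest
#' overlap fraction (ties: smallest length difference) determines the
#' class.
#'
#' @param hsps HSP tibble (needs `seqname`, `start`, `end`; an `hsp_id`
#'   column is created from the coordinates when absent).
#' @param indels Variant tibble with `seqname`, `start`, `end`, `kind`
#'   (`"deletion"` rows are used), `length_bp`, `assembly`.
#' @param params [dimorphism_params()].
#' @return Calls tibble: `hsp_id`, `seqname`, `start`, `end`, `class`,
#'   `n_support`, `assemblies`, plus a `support` list-column of qualifying
#'   variants with their overlap fractions.
#' @export
call_absence <- function(hsps, indels, params = dimorphism_params()) {
  hsps <- as_tibble(hsps)
  if (!"hsp_id" %in% names(hsps)) {
    hsps$hsp_id <- paste0(hsps$seqname, ":", hsps$start, "-", hsps$end)
  }
  dels <- as_tibble(indels)
  if ("kind" %in% names(dels)) dels <- dels[dels$kind == "deletion", ]
  if (!"length_bp" %in% names(dels)) dels$length_bp <- dels$end - dels$start
  if (!"assembly" %in% names(dels)) dels$assembly <- "other"
  calls <- lapply(seq_len(nrow(hsps)), function(i) {
    h <- hsps[i, ]
    hlen <- h$end - h$start
    cand <- dels[dels$seqname == h$seqname, , drop = FALSE]
    if (nrow(cand)) {
      cand$frac <- overlap_fraction(h[, c("seqname", "start", "end")],
                                    cand[, c("seqname", "start", "end")])
      cand <- cand[cand$frac >= params$min_hsp_overlap_fraction, , drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      return(tibble(hsp_id = h$hsp_id, seqname = h$seqname,
                    start = h$start, end = h$end, class = "fixed",
                    n_support = 0L, assemblies = "",
                    support = list(cand)))
    }
    cand <- cand[order(-cand$frac, abs(cand$length_bp - hlen)), ]
    best <- cand[1L, ]
    cls <- if (best$length_bp > hlen + params$large_sv_margin) {
      "absent_large_sv"
    } else {
      "absent_clean"
    }
    tibble(hsp_id = h$hsp_id, seqname = h$seqname,
           start = h$start, end = h$end, class = cls,
           n_support = nrow(cand),
           assemblies = paste(sort(unique(cand$assembly)), collapse = ","),
           support = list(cand))
  })
  bind_rows(calls)
}

#' Call novel Numt insertions from inter-assembly insertion variants
#'
#' Inserted sequences are scanned against the doubled mitochondrial
#' reference. Any insertion with at least one retained HSP is a Numt
#' insertion: `inserted_large_sv` when the insertion is more than
#' `large_sv_margin` bp longer than its aligned mitochondrial bp (a large
#' variant that merely contains a Numt), otherwise `inserted_clean`.
#' Insertions with no hit are dropped; insertions without sequence are
#' dropped with a message.
#'
#' @param insertions Tibble with `id`, `seq` (inserted sequence; may be
#'   `NA`), and optionally `seqname`, `pos`, `assembly`.
#' @param mito One-row mitochondrial record.
#' @param params [alignment_params()].
#' @param dim_params [dimorphism_params()].
#' @return Calls tibble: `id`, `class`, `insertion_len`, `covered_bp`
#'   (union of HSP footprints on the insertion), `n_hsps`,
#'   `best_identity`.
#' @export
call_novel_insertions <- function(insertions, mito,
                                  params = alignment_params(),
                                  dim_params = dimorphism_params()) {
  ins <- as_tibble(insertions)
  no_seq <- is.na(ins$seq) | !nzchar(ins$seq)
  if (any(no_seq)) {
    message(sum(no_seq), " insertion(s) without sequence dropped")
    ins <- ins[!no_seq, , drop = FALSE]
  }
  if (nrow(ins) == 0L) {
    return(tibble(id = character(), class = character(),
                  insertion_len = integer(), covered_bp = integer(),
                  n_hsps = integer(), best_identity = numeric()))
  }
  queries <- seq_record(ins$id, ins$seq, role = "unplaced")
  hits <- discover_hsps(queries, mito, params, circular = TRUE)
  calls <- lapply(seq_len(nrow(ins)), function(i) {
    h <- hits[hits$seqname == ins$id[i], , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = h$start + 1L, end = h$end))))
    ilen <- nchar(ins$seq[i])
    cls <- if (ilen > sum(h$aligned_bp) + dim_params$large_sv_margin) {
      "inserted_large_sv"
    } else {
      "inserted_clean"
    }
    tibble(id = ins$id[i], class = cls, insertion_len = ilen,
           covered_bp = cov, n_hsps = nrow(h), best_identity = max(h$pident))
  })
  bind_rows(calls)
}

#' Pairwise Welch's unequal-variances t-tests of identity groups
#'
#' Compares percent-identity distributions between Numt classes (for
#' example fixed vs absent) with Welch's t-test, reporting the t statistic,
#' Welch-Satterthwaite degrees of freedom, the two-sided p-value and a
#' significance star label. Groups with fewer than two observations are
#' excluded with a warning.
#'
#' @param groups Either a data frame with columns `group` and `identity`,
#'   or a named list of numeric vectors.
#' @return Tibble with one row per group pair: `group1`, `group2`, `n1`,
#'   `n2`, `mean1`, `mean2`, `t`, `df`, `p`, `stars`.
#' @export
compare_identity_groups <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$identity, groups$group)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  nms <- names(groups)
  if (length(groups) < 2L) {
    return(tibble(group1 = character(), group2 = character(),
                  n1 = integer(), n2 = integer(), mean1 = numeric(),
                  mean2 = numeric(), t = numeric(), df = numeric(),
                  p = numeric(), stars = character()))
  }
  pairs <- utils::combn(seq_along(groups), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    tt <- stats::t.test(groups[[i]], groups[[j]], var.equal = FALSE)
    tibble(group1 = nms[i], group2 = nms[j],
           n1 = length(groups[[i]]), n2 = length(groups[[j]]),
           mean1 = mean(groups[[i]]), mean2 = mean(groups[[j]]),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, stars = p_stars(tt$p.value))
  })
  bind_rows(out)
}

p_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
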