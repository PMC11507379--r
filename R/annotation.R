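#' Parameters of the dual-coordinate HSP merging rule
#'
#' Two HSPs belong to the same Numt locus when they lie within
#' `max_gap_nuclear` bp of each other in the nuclear genome **and** within
#' `max_gap_mito` bp (minimal circular distance) in the mitochondrial
#' genome, with consistent orientation. Gaps are nearest-end distances;
#' overlapping intervals count as gap 0.
#'
#' @param max_gap_nuclear,max_gap_mito Maximum gaps in bp.
#' @param require_same_strand Only merge HSPs on the same strand.
#' @return List of class `merge_params`.
#' @export
merge_params <- function(max_gap_nuclear = 2000L, max_gap_mito = 2000L,
                         require_same_strand = TRUE) {
  stopifnot(max_gap_nuclear >= 0, max_gap_mito >= 0)
  structure(list(max_gap_nuclear = as.integer(max_gap_nuclear),
                 max_gap_mito = as.integer(max_gap_mito),
                 require_same_strand = isTRUE(require_same_strand)),
            class = "merge_params")
}

# can HSP rows a and b (plain lists with the hsp columns) be merged
# directly?
merge_compatible <- function(a, b, params) {
  if (a$strand != b$strand && params$require_same_strand) return(FALSE)
  if (b$start < a$start) { tmp <- a; a <- b; b <- tmp }
  nuc_gap <- max(0L, b$start - a$end)
  if (nuc_gap > params$max_gap_nuclear) return(FALSE)
  cg <- circ_gap(a$mito_start, a$mito_len, b$mito_start, b$mito_len, a$L)
  if (cg$gap > params$max_gap_mito) return(FALSE)
  # orientation consistency: on '+' the downstream nuclear HSP must follow
  # on the circle; on '-' it must precede. Overlaps always qualify.
  if (cg$dir == 0L) return(TRUE)
  if (a$strand == "+") cg$dir >= 0L else cg$dir <= 0L
}

hsp_row <- function(hsps, i) {
  list(start = hsps$start[i], end = hsps$end[i], strand = hsps$strand[i],
       mito_start = hsps$mito_start[i], mito_len = hsps$mito_len[i],
       L = hsps$L[i])
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge Numt HSPs into Numt loci
#'
#' Computes the transitive closure of the pairwise merge relation defined
#' by [merge_params()] and returns one row per merged locus (the unit
#' counted as a Numt).
#'
#' @param hsps HSP tibble from [discover_hsps()].
#' @param params [merge_params()].
#' @return Tibble of loci: `locus_id`, `seqname`, `start`, `end` (nuclear
#'   span), `strand`, `n_hsps`, `total_aligned_bp`, `mean_identity`
#'   (aligned-length-weighted), `mito_intervals`, `unconfirmed`, and a
#'   `members` list-column holding each locus's HSP rows in nuclear order.
#' @export
merge_hsps <- function(hsps, params = merge_params()) {
  if (nrow(hsps) == 0L) return(empty_locus_tbl())
  n <- nrow(hsps)
  parent <- seq_len(n)
  grp <- if (params$require_same_strand) {
    paste(hsps$seqname, hsps$strand)
  } else {
    hsps$seqname
  }
  for (g in split(seq_len(n), grp)) {
    if (length(g) < 2L) next
    rows <- lapply(g, function(i) hsp_row(hsps, i))
    for (ii in seq_along(g)[-1L]) {
      for (jj in seq_len(ii - 1L)) {
        if (merge_compatible(rows[[ii]], rows[[jj]], params)) {
          ri <- uf_find(parent, g[[ii]]); rj <- uf_find(parent, g[[jj]])
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  loci <- lapply(split(seq_len(n), comp), function(idx) {
    members <- arrange(hsps[idx, , drop = FALSE], .data$start, .data$end)
    locus_from_members(members)
  })
  out <- bind_rows(loci)
  out <- arrange(out, .data$seqname, .data$start, .data$end)
  out$locus_id <- sprintf("numt_%04d", seq_len(nrow(out)))
  select(out, "locus_id", dplyr::everything())
}

locus_from_members <- function(members) {
  tibble(
    seqname = members$seqname[1L],
    start = min(members$start), end = max(members$end),
    strand = names(sort(table(members$strand), decreasing = TRUE))[1L],
    n_hsps = nrow(members),
    total_aligned_bp = sum(members$aligned_bp),
    mean_identity = stats::weighted.mean(members$pident, members$aligned_bp),
    mito_intervals = paste(members$mito_interval, collapse = ";"),
    unconfirmed = FALSE,
    members = list(members)
  )
}

empty_locus_tbl <- function() {
  tibble(locus_id = character(), seqname = character(), start = integer(),
         end = integer(), strand = character(), n_hsps = integer(),
         total_aligned_bp = integer(), mean_identity = numeric(),
         mito_intervals = character(), unconfirmed = logical(),
         members = list())
}

#' Refine merged loci against the doubled mitochondrial reference
#'
#' The sequence of each merged locus is extracted from the assembly and
#' searched with the doubled mitochondrial query, recomputing HSP lengths
#' and identities relative to the circular genome. The refined HSPs replace
#' each locus's member list; loci with no HSP on refinement are flagged
#' `unconfirmed` and retained with empty members.
#'
#' @param loci Locus tibble from [merge_hsps()].
#' @param assembly Sequence record table the loci were annotated on.
#' @param mito One-row mitochondrial record (not doubled).
#' @param params [alignment_params()].
#' @return Locus tibble with refined members and statistics.
#' @export
refine_loci <- function(loci, assembly, mito, params = alignment_params()) {
  if (nrow(loci) == 0L) return(loci)
  missing <- setdiff(unique(loci$seqname), assembly$name)
  if (length(missing)) {
    stop("loci reference sequences absent from the assembly: ",
         paste(missing, collapse = ", "))
  }
  seqs <- setNames(assembly$seq, assembly$name)
  extracts <- seq_record(
    loci$locus_id,
    substr(seqs[loci$seqname], loci$start + 1L, loci$end),
    role = "unplaced"
  )
  hits <- discover_hsps(extracts, mito, params, circular = TRUE)
  refined <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    h <- hits[hits$seqname == lc$locus_id, , drop = FALSE]
    if (nrow(h) == 0L) {
      lc$unconfirmed <- TRUE
      lc$members <- list(empty_hsp_tbl())
      lc$n_hsps <- 0L
      return(lc)
    }
    h$seqname <- lc$seqname
    h$start <- h$start + lc$start
    h$end <- h$end + lc$start
    h <- arrange(h, .data$start, .data$end)
    new <- locus_from_members(h)
    new$locus_id <- lc$locus_id
    select(new, "locus_id", dplyr::everything())
  })
  out <- bind_rows(refined)
  arrange(out, .data$seqname, .data$start, .data$end)
}

#' Annotate Numts in a genome assembly
#'
#' End-to-end annotation: HSP discovery against the (doubled) mitochondrial
#' reference, dual-coordinate merging into loci, per-locus refinement, and
#' role-stratified summary statistics.
#'
#' @param assembly Sequence record table (see [read_fasta()]).
#' @param mito One-row mitochondrial record.
#' @param params [alignment_params()].
#' @param merge [merge_params()].
#' @param refine Refine merged loci against the doubled reference.
#' @return Object of class `numt_annotation`: list with `hsps` (final HSP
#'   tibble), `loci`, `summary` (role-stratified), `mito_name`, `L`, and the
#'   parameter objects. Supports [tidy()], [glance()] and [autoplot()].
#' @export
annotate_numts <- function(assembly, mito, params = alignment_params(),
                           merge = merge_params(), refine = TRUE) {
  hsps <- discover_hsps(assembly, mito, params, circular = TRUE)
  loci <- merge_hsps(hsps, merge)
  if (refine && nrow(loci) > 0L) {
    loci <- refine_loci(loci, assembly, mito, params)
  }
  final_hsps <- locus_member_hsps(loci)
  roles <- setNames(assembly$role, assembly$name)
  structure(
    list(hsps = final_hsps, loci = loci,
         summary = summarize_assembly(loci, roles),
         mito_name = mito$name, L = mito$width,
         params = params, merge = merge),
    class = "numt_annotation"
  )
}

locus_member_hsps <- function(loci) {
  if (nrow(loci) == 0L) return(empty_hsp_tbl())
  mem <- loci[!loci$unconfirmed, , drop = FALSE]
  out <- bind_rows(setNames(mem$members, mem$locus_id), .id = "locus_id")
  as_tibble(out)
}

#' Role-stratified assembly summary
#'
#' Tabulates, separately for assembled chromosomes and unplaced contigs:
#' the HSP count, the total, maximum and median aligned mitochondrial bp
#' per HSP, and the merged locus count. Unconfirmed loci are excluded.
#'
#' @param loci Locus tibble from [merge_hsps()] / [refine_loci()].
#' @param roles Named character vector mapping sequence name to role.
#' @return Tibble with one row per role.
#' @export
summarize_assembly <- function(loci, roles) {
  hsps <- locus_member_hsps(loci)
  conf <- loci[!loci$unconfirmed, , drop = FALSE]
  out <- lapply(c("chromosome", "unplaced"), function(r) {
    sel <- hsps[roles[hsps$seqname] == r, , drop = FALSE]
    tibble(
      role = r,
      hsp_count = nrow(sel),
      total_size_bp = sum(sel$aligned_bp),
      max_length_bp = if (nrow(sel)) max(sel$aligned_bp) else 0L,
      median_length_bp = if (nrow(sel)) median(sel$aligned_bp) else NA_real_,
      merged_locus_count = sum(roles[conf$seqname] == r)
    )
  })
  bind_rows(out)
}

#' Per-base Numt coverage along the mitochondrial circle
#'
#' @param hsps HSP tibble with circular coordinates (`mito_start`,
#'   `mito_len`).
#' @param L Circle length.
#' @return Integer vector of length `L`; position `i` (1-based vector index
#'   for circle position `i - 1`) holds the number of HSPs covering it. The
#'   vector sum equals the total aligned mitochondrial bp exactly.
#' @export
coverage_profile <- function(hsps, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(hsps))) {
    seg <- circ_segments(hsps$mito_start[i], hsps$mito_len[i], L)
    for (r in seq_len(nrow(seg))) {
      idx <- (seg[r, "start"] + 1L):seg[r, "end"]
      cov[idx] <- cov[idx] + 1L
    }
  }
  cov
}

#' Unify Numt locus lists from multiple sources
#'
#' Loci whose start and end coordinates each differ by at most `tolerance`
#' bp are considered the same region (transitive closure); the unified
#' region spans the union and records which sources contributed. The result
#' is independent of source order.
#'
#' @param sources Named list of locus tibbles (columns `seqname`, `start`,
#'   `end`; a `locus_id` column is carried through when present).
#' @param tolerance Maximum per-endpoint coordinate difference in bp.
#' @return Tibble of unified regions: `seqname`, `start`, `end`, `n_loci`,
#'   `n_sources`, `sources` (comma-collapsed, sorted).
#' @export
unify_numt_lists <- function(sources, tolerance = 10L) {
  stopifnot(is.list(sources))
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  all <- bind_rows(lapply(sources, function(x) {
    select(as_tibble(x), "seqname", "start", "end")
  }), .id = "source")
  if (nrow(all) == 0L) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  n_loci = integer(), n_sources = integer(),
                  sources = character()))
  }
  all <- arrange(all, .data$seqname, .data$start, .data$end, .data$source)
  n <- nrow(all)
  parent <- seq_len(n)
  for (g in split(seq_len(n), all$seqname)) {
    if (length(g) < 2L) next
    for (ii in seq_along(g)[-1L]) {
      for (jj in seq_len(ii - 1L)) {
        i <- g[[ii]]; j <- g[[jj]]
        if (abs(all$start[i] - all$start[j]) <= tolerance &&
            abs(all$end[i] - all$end[j]) <= tolerance) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  out <- bind_rows(lapply(split(seq_len(n), comp), function(idx) {
    tibble(seqname = all$seqname[idx[1L]],
           start = min(all$start[idx]), end = max(all$end[idx]),
           n_loci = length(idx),
           n_sources = length(unique(all$source[idx])),
           sources = paste(sort(unique(all$source[idx])), collapse = ","))
  }))
  arrange(out, .data$seqname, .data$start, .data$end)
}

tbl_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$seqname,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Classify the genomic context of Numt regions
#'
#' A region overlapping any exon is `exonic`; otherwise a region
#' overlapping a gene body is `intronic`; otherwise `intergenic`. A region
#' is CpG-flagged when it overlaps a CpG island by at least 1 bp.
#'
#' @param regions Tibble with `seqname`, `start`, `end` (0-based half-open).
#' @param genes Gene-body intervals (same columns).
#' @param exons Exon intervals; when `NULL`, no region is called exonic.
#' @param cpg CpG-island intervals; when `NULL`, `cpg_flag` is `FALSE`.
#' @return `regions` with added `context` and `cpg_flag` columns.
#' @export
classify_genomic_context <- function(regions, genes, exons = NULL, cpg = NULL) {
  gr <- tbl_to_gr(regions)
  hit <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0L) return(rep(FALSE, nrow(regions)))
    IRanges::overlapsAny(gr, tbl_to_gr(tbl))
  }
  in_exon <- hit(exons)
  in_gene <- hit(genes)
  regions$context <- ifelse(in_exon, "exonic",
                            ifelse(in_gene, "intronic", "intergenic"))
  regions$cpg_flag <- hit(cpg)
  regions
}
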