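#' Parameters for population-scale Numt polymorphism scanning
#'
#' @param reciprocal_overlap Minimum reciprocal overlap fraction between a
#'   Numt locus and a deletion structural variant.
#' @param partial_join_n Number of `N` characters joining the left and
#'   right fragments of a partially assembled insertion.
#' @return List of class `population_params`.
#' @export
population_params <- function(reciprocal_overlap = 0.90,
                              partial_join_n = 10L) {
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1,
            partial_join_n >= 0)
  structure(list(reciprocal_overlap = reciprocal_overlap,
                 partial_join_n = as.integer(partial_join_n)),
            class = "population_params")
}

#' Reciprocal-overlap intersection of Numt loci with deletion variants
#'
#' Reports a (locus, deletion) pair when each interval covers at least
#' `reciprocal_overlap` of the other; the relation is symmetric.
#'
#' @param loci Locus tibble (`locus_id`/`id`, `seqname`, `start`, `end`).
#' @param dels Deletion tibble (`id`, `seqname`, `start`, `end`).
#' @param params [population_params()].
#' @return Tibble: `locus_id`, `deletion_id`, `frac_locus`,
#'   `frac_deletion`.
#' @export
reciprocal_overlap_deletions <- function(loci, dels,
                                         params = population_params()) {
  loci <- as_tibble(loci); dels <- as_tibble(dels)
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- if ("id" %in% names(loci)) loci$id else
      paste0(loci$seqname, ":", loci$start, "-", loci$end)
  }
  if (!"id" %in% names(dels)) {
    dels$id <- paste0(dels$seqname, ":", dels$start, "-", dels$end)
  }
  empty <- tibble(locus_id = character(), deletion_id = character(),
                  frac_locus = numeric(), frac_deletion = numeric())
  if (nrow(loci) == 0L || nrow(dels) == 0L) return(empty)
  ov <- GenomicRanges::findOverlaps(tbl_to_gr(loci), tbl_to_gr(dels))
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- pmin(loci$end[qi], dels$end[si]) - pmax(loci$start[qi], dels$start[si])
  fl <- inter / (loci$end[qi] - loci$start[qi])
  fd <- inter / (dels$end[si] - dels$start[si])
  keep <- fl >= params$reciprocal_overlap & fd >= params$reciprocal_overlap
  tibble(locus_id = loci$locus_id[qi][keep],
         deletion_id = dels$id[si][keep],
         frac_locus = fl[keep], frac_deletion = fd[keep])
}

#' Assemble insertion query sequences
#'
#' A completely assembled insertion is used as-is; a partial insertion is
#' rebuilt as left fragment, a run of `N`s, then right fragment (a missing
#' side contributes the empty string). Query names are
#' `chromosome:position` (1-based).
#'
#' @param ins Insertion tibble with `seqname`, `pos` (1-based), and
#'   `seq_full`, `seq_left`, `seq_right` columns (NA when absent).
#' @param params [population_params()].
#' @return Sequence record table with a logical `partial` column.
#' @export
assemble_insertion_query <- function(ins, params = population_params()) {
  ins <- as_tibble(ins)
  blank <- function(x) ifelse(is.na(x), "", x)
  has_full <- !is.na(ins$seq_full) & nzchar(blank(ins$seq_full))
  has_part <- nzchar(blank(ins$seq_left)) | nzchar(blank(ins$seq_right))
  if (any(!has_full & !has_part)) {
    stop("insertion(s) with no sequence at all: ",
         paste(head(which(!has_full & !has_part)), collapse = ", "))
  }
  joined <- paste0(blank(ins$seq_left),
                   strrep("N", params$partial_join_n),
                   blank(ins$seq_right))
  rec <- seq_record(paste0(ins$seqname, ":", ins$pos),
                    ifelse(has_full, ins$seq_full, joined),
                    role = "unplaced")
  rec$partial <- !has_full
  rec$left_len <- ifelse(has_full, NA_integer_, nchar(blank(ins$seq_left)))
  rec
}

#' Scan insertion queries for mitochondrial origin
#'
#' Each query is searched against the doubled mitochondrial reference;
#' queries with at least one retained HSP are classified as Numt
#' insertions. No coverage floor is applied here (unlike the
#' inter-assembly dimorphism rules): any HSP at the e-value threshold
#' qualifies. Queries are split at runs of `N` (the partial-insertion
#' join) and the fragments scanned separately, so no reported HSP ever
#' spans an N join; fragment hits are mapped back to joined-query
#' coordinates.
#'
#' @param queries Record table from [assemble_insertion_query()].
#' @param mito One-row mitochondrial record.
#' @param params [alignment_params()].
#' @return Tibble: `query`, `is_numt`, `n_hsps`, `best_identity`,
#'   `partial`, plus a `hits` list-column of the per-query HSPs (HSP
#'   `start`/`end` are positions on the insertion sequence).
#' @export
scan_insertions_for_numts <- function(queries, mito,
                                      params = alignment_params()) {
  # split at N runs (>= 5) so hits cannot cross a partial-sequence join
  frags <- lapply(seq_len(nrow(queries)), function(i) {
    s <- queries$seq[i]
    gaps <- gregexpr("N{5,}", s)[[1]]
    if (gaps[1] == -1L) {
      return(tibble(name = queries$name[i], seq = s, offset = 0L))
    }
    gap_start <- as.integer(gaps)
    gap_end <- gap_start + attr(gaps, "match.length") - 1L
    starts <- c(1L, gap_end + 1L)
    ends <- c(gap_start - 1L, nchar(s))
    keep <- ends >= starts
    tibble(name = queries$name[i],
           seq = substring(s, starts[keep], ends[keep]),
           offset = starts[keep] - 1L)
  })
  frags <- bind_rows(frags)
  frags <- frags[nchar(frags$seq) > 0L, , drop = FALSE]
  frag_rec <- seq_record(paste0(frags$name, "|", frags$offset), frags$seq,
                         role = "unplaced")
  hits <- discover_hsps(frag_rec, mito, params, circular = TRUE)
  if (nrow(hits)) {
    split_pos <- regexpr("\\|[0-9]+$", hits$seqname)
    offset <- as.integer(substring(hits$seqname, split_pos + 1L))
    hits$seqname <- substring(hits$seqname, 1L, split_pos - 1L)
    hits$start <- hits$start + offset
    hits$end <- hits$end + offset
  }
  partial <- if ("partial" %in% names(queries)) queries$partial else
    rep(FALSE, nrow(queries))
  out <- lapply(seq_len(nrow(queries)), function(i) {
    h <- hits[hits$seqname == queries$name[i], , drop = FALSE]
    tibble(query = queries$name[i], is_numt = nrow(h) > 0L,
           n_hsps = nrow(h),
           best_identity = if (nrow(h)) max(h$pident) else NA_real_,
           partial = partial[i], hits = list(h))
  })
  bind_rows(out)
}

#' Count Numt insertions present per sample
#'
#' A Numt variant is counted as present in a sample when its genotype
#' carries at least one alternate allele; missing genotypes do not count.
#'
#' @param numt_ids IDs of variants classified as Numt insertions.
#' @param genotypes Long tibble (`id`, `sample`, `dosage` with `NA` for
#'   missing) or a variants-by-samples dosage matrix with variant IDs as
#'   row names.
#' @param categories Optional tibble (`sample`, `category`); samples
#'   without a category are labelled `"Mixed/Other"` with a warning.
#' @return Tibble: `sample`, `category` (if provided), `n_numts`.
#' @export
per_sample_counts <- function(numt_ids, genotypes, categories = NULL) {
  if (is.matrix(genotypes)) {
    genotypes <- tibble(
      id = rep(rownames(genotypes), ncol(genotypes)),
      sample = rep(colnames(genotypes), each = nrow(genotypes)),
      dosage = as.vector(genotypes)
    )
  }
  g <- genotypes[genotypes$id %in% numt_ids, , drop = FALSE]
  counts <- g |>
    group_by(.data$sample) |>
    summarise(n_numts = sum(!is.na(.data$dosage) & .data$dosage >= 1L),
              .groups = "drop")
  if (!is.null(categories)) {
    counts <- left_join(counts, as_tibble(categories), by = "sample")
    if (anyNA(counts$category)) {
      warning(sum(is.na(counts$category)),
              " sample(s) without category assigned to Mixed/Other")
      counts$category[is.na(counts$category)] <- "Mixed/Other"
    }
    counts <- select(counts, "sample", "category", "n_numts")
  }
  arrange(counts, .data$sample)
}

#' Summarise per-sample Numt counts by sample category
#'
#' @param counts Tibble from [per_sample_counts()] with a `category`
#'   column.
#' @return Tibble: `category`, `n_samples`, `median_numts`, `min_numts`,
#'   `max_numts`.
#' @export
summarize_by_category <- function(counts) {
  counts |>
    group_by(.data$category) |>
    summarise(n_samples = n(),
              median_numts = median(.data$n_numts),
              min_numts = min(.data$n_numts),
              max_numts = max(.data$n_numts),
              .groups = "drop") |>
    arrange(.data$category)
}
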