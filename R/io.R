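#' Write merged Numt loci as BED6
#'
#' Coordinates are 0-based half-open. The name field carries the
#' mitochondrial interval (comma pair for origin-spanning loci), the score
#' is `round(10 x mean percent identity)` capped at 1000, and the strand
#' column comes from the locus strand.
#'
#' @param loci Locus tibble (from [merge_hsps()] or a `numt_annotation`).
#' @param path Output path.
#' @param seq_lengths Optional named vector of sequence lengths; when
#'   supplied, intervals exceeding them raise an error naming the locus.
#' @return `path`, invisibly. An empty locus table writes an empty,
#'   header-free file.
#' @export
write_numt_bed <- function(loci, path, seq_lengths = NULL) {
  if (inherits(loci, "numt_annotation")) loci <- loci$loci
  bad <- loci$start < 0 | loci$end <= loci$start
  if (!is.null(seq_lengths)) {
    bad <- bad | loci$end > seq_lengths[loci$seqname]
  }
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("unresolvable BED coordinates for: ",
         paste(loci$locus_id[bad | is.na(bad)], collapse = ", "))
  }
  if (nrow(loci) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- tibble(
    chrom = loci$seqname,
    start = loci$start,
    end = loci$end,
    name = loci$mito_intervals,
    score = pmin(1000L, as.integer(round(10 * loci$mean_identity))),
    strand = loci$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval tibble
#'
#' Thin wrapper over `rtracklayer::import` returning the package's
#' 0-based half-open interval convention.
#'
#' @param path Path to a BED file.
#' @return Tibble: `seqname`, `start`, `end`, plus `name`, `score`,
#'   `strand` when present.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_bed requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) out <- dplyr::bind_cols(out, as_tibble(md))
  if (length(gr)) out$strand <- as.character(GenomicRanges::strand(gr))
  out
}

#' Read a structural-variant VCF with insertion sequences and genotypes
#'
#' Partitions records by `SVTYPE` into insertions and deletions.
#' Insertion sequences are taken from the ALT allele when it is a
#' nucleotide string (REF base followed by the inserted sequence);
#' partially assembled insertions carry left/right fragments in INFO keys
#' (default `LSEQ`/`RSEQ`). Genotypes are decoded to alternate-allele
#' counts; any genotype containing `.` is missing. Records without an
#' `SVTYPE` are skipped with a warning count.
#'
#' @param path Path to a VCF file.
#' @param lseq_key,rseq_key INFO keys holding the partial insertion
#'   sequences.
#' @return List: `insertions` (tibble `id`, `seqname`, `pos`, `length_bp`,
#'   `seq_full`, `seq_left`, `seq_right`), `deletions` (tibble `id`,
#'   `seqname`, `start`, `end`, `length_bp`), `genotypes` (long tibble
#'   `id`, `sample`, `dosage`), `samples`, `n_skipped`.
#' @export
read_sv_vcf <- function(path, lseq_key = "LSEQ", rseq_key = "RSEQ") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "SVLEN")))
  vend <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  lseq <- vcfR::extract.info(vcf, lseq_key)
  rseq <- vcfR::extract.info(vcf, rseq_key)
  pos <- as.integer(fix$POS)
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", pos)[is.na(id) | id == "."]

  skipped <- is.na(svtype)
  if (any(skipped)) {
    warning(sum(skipped), " record(s) without SVTYPE skipped")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  dosage_one <- function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  dos <- apply(gt, c(1, 2), dosage_one)
  gid <- rep(id, length(samples))
  gsample <- rep(samples, each = length(id))
  genotypes <- tibble(id = gid, sample = gsample, dosage = as.vector(dos))
  genotypes <- genotypes[rep(!skipped, length(samples)), , drop = FALSE]

  is_ins <- !skipped & svtype == "INS"
  is_del <- !skipped & svtype == "DEL"

  alt_seq <- ifelse(grepl("^[ACGTNacgtn]+$", fix$ALT) & nchar(fix$ALT) > 1L,
                    toupper(substr(fix$ALT, 2L, nchar(fix$ALT))),
                    NA_character_)
  insertions <- tibble(
    id = id[is_ins], seqname = fix$CHROM[is_ins], pos = pos[is_ins],
    length_bp = abs(svlen[is_ins]),
    seq_full = alt_seq[is_ins],
    seq_left = lseq[is_ins], seq_right = rseq[is_ins]
  )
  both <- !is.na(insertions$seq_full) &
    (!is.na(insertions$seq_left) | !is.na(insertions$seq_right))
  if (any(both)) {
    warning(sum(both), " insertion(s) with both full and partial sequence; ",
            "partials ignored")
    insertions$seq_left[both] <- NA_character_
    insertions$seq_right[both] <- NA_character_
  }
  del_end <- ifelse(!is.na(vend[is_del]), vend[is_del],
                    pos[is_del] + abs(svlen[is_del]))
  deletions <- tibble(
    id = id[is_del], seqname = fix$CHROM[is_del],
    start = pos[is_del], end = as.integer(del_end),
    length_bp = as.integer(del_end) - pos[is_del]
  )
  list(insertions = insertions, deletions = deletions,
       genotypes = genotypes, samples = samples,
       n_skipped = sum(skipped))
}

#' Write the per-locus TSV report
#'
#' Human-readable coordinates are printed 1-based inclusive
#' (`start1 = start + 1`); the underlying tables remain 0-based half-open.
#'
#' @param loci Locus tibble or `numt_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_report <- function(loci, path) {
  if (inherits(loci, "numt_annotation")) loci <- loci$loci
  rep <- tibble(
    locus_id = loci$locus_id, chrom = loci$seqname,
    start1 = loci$start + 1L, end1 = loci$end,
    strand = loci$strand, n_hsps = loci$n_hsps,
    total_aligned_bp = loci$total_aligned_bp,
    mean_identity = round(loci$mean_identity, 2),
    mito_intervals = loci$mito_intervals,
    unconfirmed = loci$unconfirmed
  )
  readr::write_tsv(rep, path)
  invisible(path)
}
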