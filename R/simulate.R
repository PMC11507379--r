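#' Generate a random circular mitochondrial reference
#'
#' Uniform-random ACGT sequence; the default length matches the scale of a
#' canid mitochondrial genome.
#'
#' @param L Sequence length (at least 1000).
#' @param seed Integer seed; the output is bit-reproducible.
#' @param name Record name.
#' @return One-row sequence record table.
#' @export
make_mito <- function(L = 16727L, seed = 1L, name = "mito_synthetic") {
  if (L < 1000L) stop("mitochondrial length must be >= 1000 (got ", L, ")")
  withr::with_seed(seed, {
    seq_record(name, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""),
               role = "unplaced")
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence with substitutions and short indels
#'
#' Per-site substitution to a uniformly chosen alternative base, plus
#' insertion/deletion events at `indel_rate` per site with
#' geometric-distributed lengths (mean 3). Deterministic for a fixed seed.
#'
#' @param seq DNA string.
#' @param sub_rate Substitution rate per site in `[0, 1)`.
#' @param indel_rate Indel event rate per site in `[0, 1)`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return List: `seq` (mutated sequence), `n_sub`, `n_indel`,
#'   `realized_divergence` (substituted fraction of the original sites).
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  run <- function() {
    bases <- c("A", "C", "G", "T")
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(x)
    sub_idx <- which(stats::runif(n) < sub_rate)
    for (i in sub_idx) {
      x[i] <- sample(setdiff(bases, x[i]), 1L)
    }
    pieces <- as.list(x)
    indel_idx <- which(stats::runif(n) < indel_rate)
    for (i in indel_idx) {
      len <- stats::rgeom(1L, 1 / 3) + 1L
      if (stats::runif(1) < 0.5) {
        pieces[[i]] <- paste0(x[i], random_dna(len)) # insertion after site
      } else {
        drop <- i:min(n, i + len - 1L)
        for (j in drop) pieces[[j]] <- ""
      }
    }
    list(seq = paste(unlist(pieces), collapse = ""),
         n_sub = length(sub_idx), n_indel = length(indel_idx),
         realized_divergence = length(sub_idx) / n)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Specification of planted Numts for the synthetic assembly generator
#'
#' @param n_numts Number of Numts to plant.
#' @param len_range Min/max planted segment length (>= 50 bp).
#' @param sub_range Min/max per-Numt substitution rate.
#' @param indel_rate Per-site small-indel rate applied to each Numt.
#' @param strand_plus_prob Probability a Numt is planted on the + strand.
#' @param origin_spanning_fraction Fraction of Numts whose source segment
#'   crosses the origin of the circle.
#' @param fragmented_fraction Fraction of Numts split mid-sequence by a
#'   disruptor insertion (mimicking a transposon landing in the Numt).
#' @param disruptor_len Length of the disruptor sequence.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(n_numts = 50L, len_range = c(100L, 5000L),
                       sub_range = c(0, 0.15), indel_rate = 0.001,
                       strand_plus_prob = 0.5,
                       origin_spanning_fraction = 0.2,
                       fragmented_fraction = 0.1,
                       disruptor_len = 500L) {
  stopifnot(len_range[1] >= 50L, sub_range[1] >= 0, sub_range[2] < 1,
            indel_rate >= 0, indel_rate < 1,
            origin_spanning_fraction >= 0, origin_spanning_fraction <= 1,
            fragmented_fraction >= 0, fragmented_fraction <= 1,
            disruptor_len < 2000L)
  structure(list(n_numts = as.integer(n_numts),
                 len_range = as.integer(len_range), sub_range = sub_range,
                 indel_rate = indel_rate,
                 strand_plus_prob = strand_plus_prob,
                 origin_spanning_fraction = origin_spanning_fraction,
                 fragmented_fraction = fragmented_fraction,
                 disruptor_len = as.integer(disruptor_len)),
            class = "plant_spec")
}

default_scaffolds <- function() {
  c(chr1 = 200000L, chr2 = 200000L, chr3 = 200000L, chr4 = 200000L,
    chr5 = 200000L, chrUn_test = 50000L)
}

#' Build a synthetic assembly with planted Numts and ground truth
#'
#' Random nuclear scaffolds receive mutated copies of mitochondrial
#' segments at non-overlapping positions (minimum spacing 6 kb, 11 kb edge
#' margins so flank extraction never runs off a contig). Origin-spanning
#' source segments wrap around the circle; fragmented Numts are split by a
#' random disruptor sequence. The emitted truth table gives each planted
#' Numt's final nuclear interval, circular source interval, strand,
#' realized divergence and fragmentation status.
#'
#' @param spec [plant_spec()].
#' @param mito One-row mitochondrial record from [make_mito()].
#' @param seed Integer seed.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param min_sep Minimum spacing between planted Numts in bp (keep above
#'   twice the flank size when the fixture feeds outgroup testing, so that
#'   no flank contains a neighbouring Numt).
#' @param margin Minimum distance of a planted Numt from a scaffold edge.
#' @return List: `assembly` (record table), `truth` (tibble), `mito`.
#' @export
build_assembly <- function(spec, mito, seed = 1L,
                           scaffold_lengths = default_scaffolds(),
                           min_sep = 6000L, margin = 11000L) {
  L <- mito$width
  mito2 <- strrep(mito$seq, 2L)
  withr::with_seed(seed, {
    scaff <- vapply(scaffold_lengths, random_dna, character(1))
    n <- spec$n_numts
    n_origin <- round(spec$origin_spanning_fraction * n)
    n_frag <- round(spec$fragmented_fraction * n)
    origin_ids <- sample(n, n_origin)
    frag_ids <- sample(setdiff(seq_len(n), origin_ids), n_frag)

    lens <- sample(spec$len_range[1]:spec$len_range[2], n, replace = TRUE)
    subs <- stats::runif(n, spec$sub_range[1], spec$sub_range[2])
    strands <- ifelse(stats::runif(n) < spec$strand_plus_prob, "+", "-")

    placements <- plan_placements(scaffold_lengths, n, margin, min_sep)

    inserts <- character(n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- lens[i]
      src_start <- if (i %in% origin_ids) {
        sample((L - len + 1L):(L - 1L), 1L)
      } else {
        sample(0:(L - len), 1L)
      }
      segment <- substr(mito2, src_start + 1L, src_start + len)
      mut <- mutate_sequence(segment, subs[i], spec$indel_rate)
      body <- mut$seq
      if (strands[i] == "-") body <- revcomp(body)
      fragmented <- i %in% frag_ids
      if (fragmented) {
        mid <- nchar(body) %/% 2L
        body <- paste0(substr(body, 1L, mid), random_dna(spec$disruptor_len),
                       substr(body, mid + 1L, nchar(body)))
      }
      inserts[i] <- body
      truth_rows[[i]] <- tibble(
        numt_id = sprintf("planted_%03d", i),
        seqname = placements$seqname[i],
        base_pos = placements$pos[i],
        insert_len = nchar(body),
        strand = strands[i],
        mito_start = src_start, mito_len = len,
        mito_interval = mito_interval_string(src_start %% L, len, L),
        sub_rate = subs[i],
        realized_divergence = mut$realized_divergence,
        origin_spanning = i %in% origin_ids,
        fragmented = fragmented
      )
    }
    truth <- bind_rows(truth_rows)
    # apply insertions scaffold by scaffold, descending base position, and
    # compute final coordinates (earlier insertions shift later ones right)
    truth$start <- NA_integer_; truth$end <- NA_integer_
    for (sc in unique(truth$seqname)) {
      idx <- which(truth$seqname == sc)
      idx <- idx[order(truth$base_pos[idx])]
      shift <- 0L
      for (i in idx) {
        truth$start[i] <- truth$base_pos[i] + shift
        truth$end[i] <- truth$start[i] + truth$insert_len[i]
        shift <- shift + truth$insert_len[i]
      }
      s <- scaff[[sc]]
      for (i in rev(idx)) {
        p <- truth$base_pos[i]
        s <- paste0(substr(s, 1L, p), inserts[i],
                    substr(s, p + 1L, nchar(s)))
      }
      scaff[[sc]] <- s
    }
    assembly <- seq_record(names(scaff), unname(scaff))
    truth <- select(truth, -"base_pos")
    list(assembly = assembly, truth = truth, mito = mito)
  })
}

# random non-overlapping insertion positions with edge margins and a
# minimum pairwise separation, in base-scaffold coordinates
plan_placements <- function(scaffold_lengths, n, margin, min_sep) {
  avail <- scaffold_lengths - 2L * margin
  avail[avail < 0L] <- 0L
  seqname <- character(n); pos <- integer(n)
  placed <- lapply(names(scaffold_lengths), function(x) integer(0))
  names(placed) <- names(scaffold_lengths)
  for (i in seq_len(n)) {
    for (attempt in 1:2000) {
      sc <- sample(names(scaffold_lengths), 1L, prob = avail)
      p <- sample(margin:(scaffold_lengths[[sc]] - margin), 1L)
      if (all(abs(placed[[sc]] - p) >= min_sep)) {
        placed[[sc]] <- c(placed[[sc]], p)
        seqname[i] <- sc; pos[i] <- p
        break
      }
      if (attempt == 2000) stop("insufficient scaffold space to place Numt ", i)
    }
  }
  tibble(seqname = seqname, pos = pos)
}

#' Derive a dimorphic assembly pair with truth-level deletion variants
#'
#' Produces a second assembly in which the listed planted Numts are
#' excised: cleanly (`absent_ids`, the deletion exactly spans the Numt) or
#' as part of a larger structural variant (`large_sv_ids`, the deletion
#' extends 2 kb into each flank). Emits the deletion variants an
#' assembly-alignment caller would report, in reference coordinates.
#'
#' @param assembly Reference assembly record table from [build_assembly()].
#' @param truth Truth tibble from [build_assembly()].
#' @param absent_ids,large_sv_ids Character vectors of `numt_id`s.
#' @param label Label of the derived assembly.
#' @return List: `assembly` (second assembly), `indels` (deletion variant
#'   tibble: `seqname`, `start`, `end`, `kind`, `length_bp`, `assembly`,
#'   `numt_id`), `truth` (with a `present_in_other` column).
#' @export
derive_dimorphic_pair <- function(assembly, truth, absent_ids,
                                  large_sv_ids = character(),
                                  label = "assembly_B") {
  bad <- setdiff(c(absent_ids, large_sv_ids), truth$numt_id)
  if (length(bad)) stop("unknown numt_id(s): ", paste(bad, collapse = ", "))
  if (length(intersect(absent_ids, large_sv_ids))) {
    stop("absent_ids and large_sv_ids overlap")
  }
  sel <- truth[truth$numt_id %in% c(absent_ids, large_sv_ids), , drop = FALSE]
  sel$del_start <- ifelse(sel$numt_id %in% large_sv_ids,
                          sel$start - 2000L, sel$start)
  sel$del_end <- ifelse(sel$numt_id %in% large_sv_ids,
                        sel$end + 2000L, sel$end)
  # refuse overlapping excisions
  for (sc in unique(sel$seqname)) {
    s <- sel[sel$seqname == sc, ]
    s <- s[order(s$del_start), ]
    if (nrow(s) > 1L && any(s$del_start[-1L] < s$del_end[-nrow(s)])) {
      stop("overlapping excisions on ", sc)
    }
  }
  seqs <- setNames(assembly$seq, assembly$name)
  for (sc in unique(sel$seqname)) {
    s <- sel[sel$seqname == sc, ]
    s <- s[order(-s$del_start), ]
    for (i in seq_len(nrow(s))) {
      seqs[[sc]] <- paste0(substr(seqs[[sc]], 1L, s$del_start[i]),
                           substr(seqs[[sc]], s$del_end[i] + 1L,
                                  nchar(seqs[[sc]])))
    }
  }
  indels <- tibble(seqname = sel$seqname, start = sel$del_start,
                   end = sel$del_end, kind = "deletion",
                   length_bp = sel$del_end - sel$del_start,
                   assembly = label, numt_id = sel$numt_id)
  truth$present_in_other <- !(truth$numt_id %in% c(absent_ids, large_sv_ids))
  list(assembly = seq_record(names(seqs), unname(seqs)),
       indels = arrange(indels, .data$seqname, .data$start),
       truth = truth)
}

#' Generate a genotyped structural-variant call set with planted Numt
#' insertions
#'
#' Emits insertion records whose sequences are mutated mitochondrial
#' segments (a configurable fraction origin-spanning), a configurable
#' fraction represented only by left/right partial sequences (the first
#' and last 150 bp), plus non-mitochondrial decoy insertions and a few
#' deletion records. Genotypes are drawn binomially per sample at
#' per-variant allele frequencies; a small fraction is set to missing.
#' The expected per-sample Numt counts are tabulated from the drawn
#' genotypes.
#'
#' @param mito One-row mitochondrial record.
#' @param n_variants Number of Numt insertion variants.
#' @param n_samples Number of samples.
#' @param partial_fraction Fraction of Numt insertions emitted as
#'   left/right partials.
#' @param seed Integer seed.
#' @param dir Output directory (created); VCF and category TSV are written
#'   here.
#' @param n_decoys Number of random (non-Numt) insertion variants.
#' @param n_deletions Number of deletion records.
#' @param len_range,sub_range Length and substitution-rate ranges of the
#'   planted insertion sequences.
#' @param origin_fraction Fraction of Numt insertions drawn across the
#'   origin of the circle.
#' @param freq_range Range of per-variant alternate allele frequencies.
#' @param missing_rate Per-genotype missing probability.
#' @param category_probs Named probabilities of sample categories.
#' @return List: `vcf` (path), `categories_tsv` (path), `categories`
#'   (tibble), `expected_counts` (tibble `sample`, `n_numts`), `truth`
#'   (per-variant tibble with `id`, `is_numt`, `partial`), `genotypes`
#'   (long tibble of drawn dosages), `dir`.
#' @export
make_population_vcf <- function(mito, n_variants = 20L, n_samples = 100L,
                                partial_fraction = 0.5, seed = 1L,
                                dir = tempfile("popvcf"),
                                n_decoys = 3L, n_deletions = 2L,
                                len_range = c(300L, 4000L),
                                sub_range = c(0, 0.05),
                                origin_fraction = 0.2,
                                freq_range = c(0.1, 0.9),
                                missing_rate = 0.02,
                                category_probs = c("Breed Dog" = 0.70,
                                                   "Village Dog" = 0.20,
                                                   "Wolf" = 0.08,
                                                   "Mixed/Other" = 0.02)) {
  L <- mito$width
  mito2 <- strrep(mito$seq, 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    categories <- tibble(
      sample = samples,
      category = sample(names(category_probs), n_samples, replace = TRUE,
                        prob = category_probs)
    )
    n_total <- n_variants + n_decoys
    pos <- sort(sample(10000:90000000, n_total + n_deletions))
    is_numt <- c(rep(TRUE, n_variants), rep(FALSE, n_decoys))
    n_partial <- round(partial_fraction * n_variants)
    partial <- c(seq_len(n_variants) %in% sample(n_variants, n_partial),
                 rep(FALSE, n_decoys))
    n_origin <- round(origin_fraction * n_variants)
    origin <- c(seq_len(n_variants) %in% sample(n_variants, n_origin),
                rep(FALSE, n_decoys))
    lens <- sample(len_range[1]:len_range[2], n_total, replace = TRUE)
    seqs <- character(n_total)
    for (i in seq_len(n_total)) {
      if (is_numt[i]) {
        src <- if (origin[i]) sample((L - lens[i] + 1L):(L - 1L), 1L)
               else sample(0:(L - lens[i]), 1L)
        seg <- substr(mito2, src + 1L, src + lens[i])
        seqs[i] <- mutate_sequence(seg, stats::runif(1, sub_range[1],
                                                     sub_range[2]))$seq
      } else {
        seqs[i] <- random_dna(lens[i])
      }
    }
    freqs <- stats::runif(n_total, freq_range[1], freq_range[2])
    ids <- paste0("chr1:", pos[seq_len(n_total)])
    dosage <- matrix(stats::rbinom(n_total * n_samples, 2L, rep(freqs, n_samples)),
                     nrow = n_total, dimnames = list(ids, samples))
    miss <- matrix(stats::runif(n_total * n_samples) < missing_rate,
                   nrow = n_total)
    dosage[miss] <- NA_integer_

    gt_str <- matrix("", nrow = n_total, ncol = n_samples)
    gt_str[!is.na(dosage) & dosage == 0L] <- "0/0"
    gt_str[!is.na(dosage) & dosage == 1L] <- "0/1"
    gt_str[!is.na(dosage) & dosage == 2L] <- "1/1"
    gt_str[is.na(dosage)] <- "./."

    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=numtkit_synthetic",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
      "##INFO=<ID=LSEQ,Number=1,Type=String,Description=\"Left partial insertion sequence\">",
      "##INFO=<ID=RSEQ,Number=1,Type=String,Description=\"Right partial insertion sequence\">",
      "##ALT=<ID=INS,Description=\"Insertion\">",
      "##ALT=<ID=DEL,Description=\"Deletion\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t")
    )
    for (i in seq_len(n_total)) {
      ref <- sample(c("A", "C", "G", "T"), 1L)
      if (partial[i]) {
        alt <- "<INS>"
        info <- paste0("SVTYPE=INS;SVLEN=", lens[i],
                       ";LSEQ=", substr(seqs[i], 1L, 150L),
                       ";RSEQ=", substr(seqs[i], nchar(seqs[i]) - 149L,
                                        nchar(seqs[i])))
      } else {
        alt <- paste0(ref, seqs[i])
        info <- paste0("SVTYPE=INS;SVLEN=", lens[i])
      }
      lines <- c(lines, paste(c("chr1", pos[i], ids[i], ref, alt, ".",
                                "PASS", info, "GT", gt_str[i, ]),
                              collapse = "\t"))
    }
    for (j in seq_len(n_deletions)) {
      p <- pos[n_total + j]
      dlen <- sample(500:5000, 1L)
      gts <- paste(sample(c("0/0", "0/1", "1/1"), n_samples, replace = TRUE),
                   collapse = "\t")
      lines <- c(lines,
                 paste(c("chr2", p, paste0("chr2:", p), "N", "<DEL>", ".",
                         "PASS",
                         paste0("SVTYPE=DEL;SVLEN=-", dlen, ";END=", p + dlen),
                         "GT", strsplit(gts, "\t")[[1]]),
                       collapse = "\t"))
    }
    vcf_path <- file.path(dir, "population_svs.vcf")
    writeLines(lines, vcf_path)
    cat_path <- file.path(dir, "sample_categories.tsv")
    readr::write_tsv(categories, cat_path)

    numt_dos <- dosage[is_numt, , drop = FALSE]
    expected <- tibble(
      sample = samples,
      n_numts = as.integer(colSums(!is.na(numt_dos) & numt_dos >= 1L))
    )
    genotypes <- tibble(
      id = rep(ids, n_samples),
      sample = rep(samples, each = n_total),
      dosage = as.vector(dosage)
    )
    list(vcf = vcf_path, categories_tsv = cat_path, categories = categories,
         expected_counts = expected,
         truth = tibble(id = ids, pos = pos[seq_len(n_total)],
                        length_bp = lens, is_numt = is_numt,
                        partial = partial, origin_spanning = origin,
                        seq = seqs),
         genotypes = genotypes, dir = dir)
  })
}

#' Generate a complete synthetic study fixture
#'
#' One call per scenario: `"basic"` plants 50 Numts (100--5000 bp,
#' 0--15% divergence, 20% origin-spanning, 10% fragmented) in a six-
#' scaffold assembly; `"dimorph"` additionally derives a second assembly
#' with 10 clean and 5 large-SV excisions; `"population"` emits a
#' genotyped SV VCF with 20 Numt insertions (50% partial) for 100 samples;
#' `"outgroup"` builds a diverged outgroup assembly with 5 of 12 Numts
#' excised.
#'
#' @param preset One of `"basic"`, `"dimorph"`, `"population"`,
#'   `"outgroup"`.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, FASTA/VCF/TSV artifacts are
#'   written there.
#' @return A list of fixture objects; contents depend on the preset (all
#'   include the generating `mito` record and a ground-truth table).
#' @export
simulate_numts <- function(preset = c("basic", "dimorph", "population",
                                      "outgroup"),
                           seed = 42L, dir = NULL) {
  preset <- match.arg(preset)
  mito <- make_mito(seed = seed)
  out <- switch(preset,
    basic = {
      fx <- build_assembly(plant_spec(), mito, seed = seed + 1L)
      c(fx, list(preset = preset))
    },
    dimorph = {
      spec <- plant_spec(n_numts = 50L, len_range = c(200L, 3000L),
                         sub_range = c(0, 0.10), indel_rate = 0,
                         fragmented_fraction = 0)
      fx <- build_assembly(spec, mito, seed = seed + 1L)
      ids <- withr::with_seed(seed + 2L, sample(fx$truth$numt_id, 15L))
      pair <- derive_dimorphic_pair(fx$assembly, fx$truth,
                                    absent_ids = ids[1:10],
                                    large_sv_ids = ids[11:15])
      list(assembly = fx$assembly, truth = pair$truth,
           assembly_b = pair$assembly, indels = pair$indels,
           absent_ids = ids[1:10], large_sv_ids = ids[11:15],
           mito = mito, preset = preset)
    },
    population = {
      fx <- make_population_vcf(mito, seed = seed + 1L,
                                dir = if (is.null(dir)) tempfile("popvcf")
                                      else dir)
      c(fx, list(mito = mito, preset = preset))
    },
    outgroup = {
      spec <- plant_spec(n_numts = 12L, len_range = c(500L, 3000L),
                         sub_range = c(0, 0.08), indel_rate = 0,
                         origin_spanning_fraction = 0.1,
                         fragmented_fraction = 0)
      fx <- build_assembly(spec, mito, seed = seed + 1L, min_sep = 25000L)
      excised <- withr::with_seed(seed + 2L, sample(fx$truth$numt_id, 5L))
      pair <- derive_dimorphic_pair(fx$assembly, fx$truth,
                                    absent_ids = excised,
                                    label = "outgroup_synthetic")
      og <- pair$assembly
      og$seq <- withr::with_seed(seed + 3L, vapply(og$seq, function(s) {
        mutate_sequence(s, 0.005, 0)$seq
      }, character(1), USE.NAMES = FALSE))
      og <- seq_record(og$name, og$seq)
      list(assembly = fx$assembly, truth = pair$truth, outgroup = og,
           excised_ids = excised, mito = mito, preset = preset)
    }
  )
  if (!is.null(dir) && preset != "population") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(mito, file.path(dir, "mito.fa"))
    write_fasta(out$assembly, file.path(dir, "assembly.fa"))
    readr::write_tsv(select(out$truth, -dplyr::any_of("seq")),
                     file.path(dir, "truth.tsv"))
    if (!is.null(out$assembly_b)) {
      write_fasta(out$assembly_b, file.path(dir, "assembly_b.fa"))
      readr::write_tsv(out$indels, file.path(dir, "indels.tsv"))
    }
    if (!is.null(out$outgroup)) {
      write_fasta(out$outgroup, file.path(dir, "outgroup.fa"))
    }
    out$dir <- dir
  }
  out
}
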