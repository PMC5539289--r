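# Readers/writers and coordinate conventions.
#
# All genomic coordinates are 1-based inclusive in memory (the VCF
# convention); BED output converts to 0-based half-open on disk.
# Chromosome names are compared after stripping any "chr" prefix.

#' Construct a table of somatic SNVs
#'
#' Validates and assembles single-nucleotide variant records. Only simple
#' substitutions are admitted; the reference and alternative base must
#' differ.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based genomic positions.
#' @param ref_base,alt_base Single nucleotides in `A,C,G,T`.
#' @param patient_id Sample identifiers.
#' @return A tibble with columns `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `patient_id`, sorted by `(chrom, pos)`.
#' @export
#' @examples
#' snv_table("chr1", 100, "C", "T", "P1")
snv_table <- function(chrom, pos, ref_base, alt_base, patient_id) {
  tbl <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_base = toupper(as.character(ref_base)),
    alt_base = toupper(as.character(alt_base)),
    patient_id = as.character(patient_id)
  )
  bad <- !(tbl$ref_base %in% DNA_BASES) | !(tbl$alt_base %in% DNA_BASES)
  if (any(bad)) {
    stop("non-SNV or ambiguous alleles at rows: ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  if (any(tbl$ref_base == tbl$alt_base)) {
    stop("ref_base equals alt_base at rows: ",
         paste(head(which(tbl$ref_base == tbl$alt_base), 5L), collapse = ", "))
  }
  if (any(tbl$pos < 1L)) stop("positions must be >= 1")
  dplyr::arrange(tbl, .data$chrom, .data$pos, .data$patient_id)
}

#' Read somatic SNVs from per-patient VCF files
#'
#' Reads one VCF per patient and keeps biallelic single-nucleotide
#' substitutions only. Indels and multi-allelic records are skipped with a
#' message reporting the per-file count.
#'
#' @param vcf_paths Character vector of VCF paths; names are used as patient
#'   identifiers (unnamed paths fall back to the file name without
#'   extension).
#' @return SNV tibble as produced by [snv_table()], sorted by
#'   `(chrom, pos)`.
#' @export
read_snvs <- function(vcf_paths) {
  ids <- names(vcf_paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(vcf_paths))
  ids <- ifelse(is.na(ids) | ids == "",
                sub("\\.vcf(\\.gz)?$", "", basename(vcf_paths)), ids)
  per_file <- purrr::map2(unname(vcf_paths), ids, function(path, id) {
    vcf <- tryCatch(
      vcfR::read.vcfR(path, verbose = FALSE),
      error = function(e) stop("failed to parse VCF '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) {
      return(snv_table(character(), integer(), character(), character(),
                       character()))
    }
    is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      toupper(fix$REF) %in% DNA_BASES & toupper(fix$ALT) %in% DNA_BASES
    n_skip <- sum(!is_snv)
    if (n_skip > 0L) {
      message("read_snvs: skipped ", n_skip, " non-SNV record(s) in ",
              basename(path))
    }
    fix <- fix[is_snv, , drop = FALSE]
    snv_table(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT, id)
  })
  dplyr::arrange(dplyr::bind_rows(per_file), .data$chrom, .data$pos,
                 .data$patient_id)
}

#' Read transcription start site annotation
#'
#' Accepts either a tab-separated TSS table with columns `gene_id`,
#' `chrom`, `tss`, `strand` (and optionally `gene_name`), or a GTF/GFF file
#' (requires the rtracklayer package), in which case one record per
#' transcript is produced so genes may carry several TSSs.
#'
#' @param path Path to the annotation file.
#' @return Tibble with columns `gene_id`, `gene_name`, `chrom`, `tss`,
#'   `strand`.
#' @export
read_tss <- function(path) {
  if (grepl("\\.g[tf]f[23]?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF/GFF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    keep <- if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr[gr$type %in% c("transcript", "mRNA", "gene")]
    } else {
      gr
    }
    md <- S4Vectors::mcols(keep)
    strand <- as.character(BiocGenerics::strand(keep))
    tss <- ifelse(strand == "-", BiocGenerics::end(keep),
                  BiocGenerics::start(keep))
    tbl <- tibble::tibble(
      gene_id = as.character(md$gene_id %||% md$ID),
      gene_name = as.character(md$gene_name %||% md$gene_id %||% md$ID),
      chrom = as.character(GenomicRanges::seqnames(keep)),
      tss = as.integer(tss),
      strand = ifelse(strand %in% c("+", "-"), strand, "+")
    )
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(tbl))) {
      stop("TSS table must have columns: ", paste(need, collapse = ", "))
    }
    if (!"gene_name" %in% names(tbl)) tbl$gene_name <- tbl$gene_id
    tbl <- dplyr::select(tbl, "gene_id", "gene_name", "chrom", "tss",
                         "strand")
    tbl$tss <- as.integer(tbl$tss)
  }
  if (any(tbl$tss < 1L)) stop("TSS positions must be >= 1")
  if (!all(tbl$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  dplyr::distinct(tbl)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file path (plain or gzip).
#' @return A named `Biostrings::DNAStringSet`; names are truncated at the
#'   first whitespace.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Look up a genome entry by chromosome name, tolerant of a "chr" prefix.
genome_chrom <- function(genome, chrom) {
  idx <- match(norm_chrom(chrom), norm_chrom(names(genome)))
  if (is.na(idx)) stop("chromosome '", chrom, "' not found in genome")
  genome[[idx]]
}

#' Extract a genomic interval as a character sequence
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval; must lie within the
#'   chromosome.
#' @return Uppercase DNA string.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  chr <- genome_chrom(genome, chrom)
  if (start < 1L || end > length(chr) || start > end) {
    stop("interval [", start, ",", end, "] out of bounds for chromosome '",
         chrom, "' (length ", length(chr), ")")
  }
  toupper(as.character(Biostrings::subseq(chr, start, end)))
}

#' Check SNV reference-base consistency against a genome
#'
#' Verifies that each record's `ref_base` matches the genome base at `pos`;
#' any mismatch is an error listing the offending positions.
#'
#' @param snvs SNV tibble.
#' @param genome `DNAStringSet`.
#' @return `snvs`, invisibly, when all records are consistent.
#' @export
check_snv_reference <- function(snvs, genome) {
  by_chrom <- split(seq_len(nrow(snvs)), snvs$chrom)
  for (chrom in names(by_chrom)) {
    idx <- by_chrom[[chrom]]
    chr <- genome_chrom(genome, chrom)
    bases <- toupper(as.character(
      Biostrings::extractAt(chr, IRanges::IRanges(snvs$pos[idx], width = 1L))
    ))
    bad <- bases != snvs$ref_base[idx]
    if (any(bad)) {
      stop("reference mismatch at ", chrom, ":",
           paste(head(snvs$pos[idx][bad], 5L), collapse = ","),
           " (VCF says ", paste(head(snvs$ref_base[idx][bad], 5L),
                                collapse = ","),
           ", genome says ", paste(head(bases[bad], 5L), collapse = ","), ")")
    }
  }
  invisible(snvs)
}

#' Promoter windows around transcription start sites
#'
#' The window is symmetric around the TSS regardless of strand and is
#' clipped at chromosome bounds when lengths are supplied.
#'
#' @param tss TSS tibble from [read_tss()].
#' @param half_width Half-width in bp (default 1000, i.e. TSS +/- 1 kb).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   clipping and bounds checking.
#' @return `tss` with added `start` and `end` columns (1-based inclusive).
#' @export
promoter_windows <- function(tss, half_width = 1000, chrom_lengths = NULL) {
  stopifnot(half_width >= 0)
  out <- dplyr::mutate(tss,
    start = pmax(1L, .data$tss - as.integer(half_width)),
    end = .data$tss + as.integer(half_width)
  )
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[match(norm_chrom(out$chrom),
                                      norm_chrom(names(chrom_lengths)))])
    if (any(is.na(len))) stop("chromosome length missing for some TSSs")
    if (any(out$tss > len)) {
      stop("TSS beyond chromosome end for gene(s): ",
           paste(head(out$gene_id[out$tss > len], 5L), collapse = ", "))
    }
    out$end <- pmin(out$end, as.integer(len))
  }
  out
}

#' Read a JASPAR-style PWM collection
#'
#' Parses matrices in JASPAR text format: a `>pwm_id tf_name` header
#' followed by four rows (A, C, G, T across positions), with or without the
#' `A [ ... ]` decoration. Count matrices are regularized with a
#' pseudocount of 1 per cell, probability matrices with 0.001, and both are
#' renormalized so every position sums to one.
#'
#' @param path PWM file path.
#' @param default_tier Source tier recorded when the header does not carry a
#'   third `known`/`other` token.
#' @return Tibble with columns `tf_name`, `pwm_id`, `source_tier` and a
#'   list-column `probs` of L x 4 probability matrices (columns A,C,G,T).
#' @export
read_pwms <- function(path, default_tier = "known") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' headers found in PWM file: ", path)
  bounds <- c(headers, length(lines) + 1L)
  recs <- purrr::map(seq_along(headers), function(i) {
    head_toks <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]]
    pwm_id <- head_toks[1]
    tf_name <- if (length(head_toks) >= 2) head_toks[2] else pwm_id
    tier <- if (length(head_toks) >= 3 &&
                head_toks[3] %in% c("known", "other")) {
      head_toks[3]
    } else {
      default_tier
    }
    body <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- purrr::map(body, function(l) {
      l2 <- gsub("^\\s*[ACGTacgt]\\s*[:|]?", "", l)
      l2 <- gsub("\\[|\\]", " ", l2)
      as.numeric(strsplit(trimws(l2), "\\s+")[[1]])
    })
    if (length(rows) != 4L) {
      stop("PWM '", pwm_id, "': expected 4 base rows, got ", length(rows))
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L || any(is.na(unlist(rows)))) {
      stop("PWM '", pwm_id, "': ragged or non-numeric matrix")
    }
    mat <- t(do.call(rbind, rows))  # L x 4, columns A,C,G,T
    colnames(mat) <- DNA_BASES
    pwm(tf_name, pwm_id, mat, source_tier = tier)
  })
  dplyr::bind_rows(recs)
}

#' Construct a single PWM record
#'
#' @param tf_name Transcription factor name.
#' @param pwm_id Matrix identifier.
#' @param mat L x 4 matrix of counts or probabilities (columns A,C,G,T).
#' @param source_tier `"known"` or `"other"`.
#' @param pseudocount_counts,pseudocount_probs Regularization added per cell
#'   before renormalization, for count and probability input respectively.
#' @return One-row tibble matching the [read_pwms()] layout.
#' @export
pwm <- function(tf_name, pwm_id, mat, source_tier = "known",
                pseudocount_counts = 1, pseudocount_probs = 0.001) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM '", pwm_id, "': matrix must have 4 columns")
  if (nrow(mat) < 1L) stop("PWM '", pwm_id, "': empty matrix")
  if (any(mat < 0) || any(!is.finite(mat))) {
    stop("PWM '", pwm_id, "': negative or non-finite entries")
  }
  if (any(rowSums(mat) == 0)) {
    stop("PWM '", pwm_id, "': position with all-zero row")
  }
  is_counts <- max(mat) > 1 + 1e-6
  if (is_counts) {
    mat <- mat + pseudocount_counts
  } else if (any(mat == 0)) {
    # only regularize probability matrices that actually contain zeros,
    # so already-positive matrices pass through unchanged
    mat <- mat + pseudocount_probs
  }
  mat <- mat / rowSums(mat)
  colnames(mat) <- DNA_BASES
  rownames(mat) <- NULL
  tibble::tibble(
    tf_name = as.character(tf_name),
    pwm_id = as.character(pwm_id),
    source_tier = source_tier,
    probs = list(mat)
  )
}

#' Write a PWM collection in JASPAR text format
#'
#' @param pwms PWM tibble from [read_pwms()] or [pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  lines <- purrr::pmap(pwms, function(tf_name, pwm_id, source_tier, probs,
                                      ...) {
    c(paste0(">", pwm_id, " ", tf_name, " ", source_tier),
      vapply(1:4, function(b) {
        paste0(DNA_BASES[b], " [ ",
               paste(formatC(probs[, b], format = "f", digits = 6),
                     collapse = " "), " ]")
      }, character(1)))
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Read a gene expression table with tumor/normal groups
#'
#' @param path TSV with a `gene_id` column followed by one numeric column
#'   per sample (RPKM or similar non-negative values).
#' @param sample_groups Named character vector, two-column data frame
#'   (`sample`, `group`), or path to a two-column TSV, mapping every sample
#'   column to `"tumor"` or `"normal"`.
#' @return An `expression_table` object.
#' @export
read_expression <- function(path, sample_groups) {
  if (is.character(sample_groups) && length(sample_groups) == 1 &&
      file.exists(sample_groups)) {
    g <- readr::read_tsv(sample_groups, show_col_types = FALSE,
                         progress = FALSE)
    sample_groups <- setNames(g$group, g$sample)
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(tbl)) stop("expression table needs a gene_id column")
  mat <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  rownames(mat) <- tbl$gene_id
  expression_table(mat, sample_groups)
}

#' Construct an expression table
#'
#' @param values Gene x sample numeric matrix of non-negative expression
#'   values, with gene identifiers as row names.
#' @param sample_groups Named character vector (`sample -> group`) or a
#'   data frame with columns `sample` and `group`; groups must be `"tumor"`
#'   or `"normal"`.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, sample_groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene row names")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (is.data.frame(sample_groups)) {
    sample_groups <- setNames(as.character(sample_groups$group),
                              sample_groups$sample)
  }
  if (!all(colnames(values) %in% names(sample_groups))) {
    stop("every sample column needs a group assignment")
  }
  groups <- sample_groups[colnames(values)]
  if (!all(groups %in% c("tumor", "normal"))) {
    stop("groups must be 'tumor' or 'normal'")
  }
  structure(list(values = values, groups = groups),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$groups == "tumor"), " tumor, ",
      sum(x$groups == "normal"), " normal)\n", sep = "")
  invisible(x)
}

# Expression vector for one gene and one group; errors when absent.
expr_values <- function(expr, gene_id, group) {
  if (!gene_id %in% rownames(expr$values)) {
    stop("gene '", gene_id, "' absent from expression table")
  }
  unname(expr$values[gene_id, expr$groups == group])
}

#' Write mutation blocks as a BED track
#'
#' Converts the in-memory 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param blocks Block tibble with `chrom`, `start`, `end`, `block_id`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- tibble::tibble(
    chrom = blocks$chrom,
    start = blocks$start - 1L,
    end = blocks$end,
    name = blocks$block_id
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED track of mutation blocks
#'
#' @param path BED path written by [write_blocks_bed()].
#' @return Tibble with 1-based inclusive `start`/`end`.
#' @export
read_blocks_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    chrom = as.character(bed$chrom),
    start = as.integer(bed$start) + 1L,
    end = as.integer(bed$end),
    block_id = as.character(bed$name)
  )
}
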