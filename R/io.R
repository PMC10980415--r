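# Readers and writers: FASTA, GFF3, SAM and the package TSV dialects.
# Output files carry a commented metadata header (tool version, config hash,
# seed); readers skip comment lines.

#' Read a FASTA file
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a `DNAStringSet`; names are record ids up to the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet`, `DNAString` or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (methods::is(seqs, "DNAString")) {
    seqs <- Biostrings::DNAStringSet(stats::setNames(list(seqs), "seq1"))
  }
  if (is.character(seqs)) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(stats::setNames(toupper(seqs), nm))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read the single genome sequence from a FASTA file
#'
#' @param path path to a FASTA file; the first record is used (a message is
#'   emitted if there are several).
#' @return a `DNAString`.
#' @export
read_genome <- function(path) {
  x <- read_fasta(path)
  if (length(x) > 1L) message("using first of ", length(x), " FASTA records")
  x[[1L]]
}

metadata_lines <- function(seed = NULL, config = NULL) {
  # no timestamp: outputs of a seeded run are byte-identical across runs
  c(paste0("# pprcleave ", package_version_string()),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", config_hash(config)))
}

#' Write a data frame as TSV with a metadata header
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed,config optional seed and configuration object recorded in the
#'   commented header (the config is recorded as a content hash).
#' @return the path, invisibly.
#' @export
write_tsv_meta <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_lines(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a package-dialect TSV (comment lines ignored)
#'
#' @param path path to the file.
#' @return a data frame.
#' @export
read_tsv_meta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

require_columns <- function(df, cols, what, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop_input(what, " file ", path, " is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read transcript models from the TSV fallback dialect
#'
#' Columns: `gene`, `strand`, `cds_start`, `cds_end`, `utr5_len`, `utr3_len`
#' (CDS coordinates written 5' to 3', so reverse-strand genes have
#' `cds_start > cds_end`).
#'
#' @param path path to the TSV file.
#' @return a named list of [transcript_model()] objects.
#' @export
read_transcript_models_tsv <- function(path) {
  df <- require_columns(read_tsv_meta(path),
                        c("gene", "strand", "cds_start", "cds_end",
                          "utr5_len", "utr3_len"),
                        "transcript model", path)
  models <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(df$gene[i], df$strand[i], df$cds_start[i], df$cds_end[i],
                     utr5 = df$utr5_len[i], utr3 = df$utr3_len[i])
  })
  stats::setNames(models, df$gene)
}

#' Write synthetic annotation as GFF3
#'
#' Emits gene, CDS, five_prime_UTR, three_prime_UTR and intron features;
#' trans-spliced introns carry the attribute `splicing=trans`.
#'
#' @param models a named list of [transcript_model()] objects.
#' @param path output path.
#' @param seqname sequence name used in column 1 (default `"synthetic_mito"`).
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path, seqname = "synthetic_mito") {
  feats <- list()
  add <- function(type, lo, hi, strand, attrs) {
    feats[[length(feats) + 1L]] <<- GenomicRanges::GRanges(
      seqnames = seqname, ranges = IRanges::IRanges(lo, hi), strand = strand,
      type = type, ID = attrs$ID, gene_id = attrs$gene,
      phase = if (type == "CDS") 0L else NA_integer_,
      splicing = attrs$splicing %||% NA_character_)
  }
  for (m in models) {
    span <- range(m$tx_start, m$tx_end)
    cds <- range(m$cds_start, m$cds_end)
    add("gene", span[1L], span[2L], m$strand, list(ID = m$gene, gene = m$gene))
    add("CDS", cds[1L], cds[2L], m$strand,
        list(ID = paste0(m$gene, ".cds"), gene = m$gene))
    u5 <- sort(c(m$tx_start, m$cds_start - (if (m$strand == "+") 1L else -1L)))
    if (m$utr5 > 0L) add("five_prime_UTR", u5[1L], u5[2L], m$strand,
                         list(ID = paste0(m$gene, ".utr5"), gene = m$gene))
    u3 <- sort(c(m$cds_end + (if (m$strand == "+") 1L else -1L), m$tx_end))
    if (m$utr3 > 0L) add("three_prime_UTR", u3[1L], u3[2L], m$strand,
                         list(ID = paste0(m$gene, ".utr3"), gene = m$gene))
    if (!is.null(m$introns)) {
      for (i in seq_len(nrow(m$introns))) {
        add("intron", min(m$introns$start[i], m$introns$end[i]),
            max(m$introns$start[i], m$introns$end[i]), m$strand,
            list(ID = m$introns$id[i], gene = m$gene,
                 splicing = if (m$introns$trans[i]) "trans" else "cis"))
      }
    }
  }
  gr <- do.call(c, feats)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Understands the feature vocabulary written by [write_gff3()]: `gene`,
#' `CDS`, `five_prime_UTR`, `three_prime_UTR`, `intron` grouped by the
#' `gene_id` attribute; intron features may flag `splicing=trans`. Other
#' feature types are ignored with a warning.
#'
#' @param path path to the GFF3 file.
#' @return a named list of [transcript_model()] objects.
#' @export
read_transcript_models_gff3 <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  known <- c("gene", "CDS", "five_prime_UTR", "three_prime_UTR", "intron")
  types <- as.character(gr$type)
  if (any(!types %in% known)) {
    warning("ignoring unknown GFF3 feature type(s): ",
            paste(unique(types[!types %in% known]), collapse = ", "))
    gr <- gr[types %in% known]
    types <- as.character(gr$type)
  }
  gene_ids <- as.character(gr$gene_id)
  models <- list()
  for (g in unique(gene_ids[types == "gene"])) {
    sub <- gr[gene_ids == g]
    st <- as.character(GenomicRanges::strand(sub))[1L]
    cds <- sub[as.character(sub$type) == "CDS"]
    if (length(cds) != 1L) stop_input("gene ", g, " needs exactly one CDS")
    lo <- GenomicRanges::start(cds)
    hi <- GenomicRanges::end(cds)
    u5 <- sub[as.character(sub$type) == "five_prime_UTR"]
    u3 <- sub[as.character(sub$type) == "three_prime_UTR"]
    ints <- sub[as.character(sub$type) == "intron"]
    introns <- if (length(ints) > 0L) {
      data.frame(start = GenomicRanges::start(ints),
                 end = GenomicRanges::end(ints),
                 trans = !is.na(ints$splicing) & ints$splicing == "trans",
                 id = as.character(ints$ID), stringsAsFactors = FALSE)
    } else NULL
    models[[g]] <- transcript_model(
      g, st,
      cds_start = if (st == "+") lo else hi,
      cds_end = if (st == "+") hi else lo,
      utr5 = if (length(u5) > 0L) sum(GenomicRanges::width(u5)) else 0L,
      utr3 = if (length(u3) > 0L) sum(GenomicRanges::width(u3)) else 0L,
      introns = introns)
  }
  models
}

#' Read per-position 5'-end count tables
#'
#' The package TSV dialect has columns `strand`, `position`, `replicate`,
#' `genotype`, `count`; positions absent from the file have count 0.
#'
#' @param path path to the TSV file.
#' @param genome_length genome length (number of profile positions).
#' @param strand strand to extract.
#' @return a named list of [end_profile()] objects, one per genotype.
#' @export
read_end_counts_tsv <- function(path, genome_length, strand) {
  strand <- normalize_strand(strand)
  df <- require_columns(read_tsv_meta(path),
                        c("strand", "position", "replicate", "genotype",
                          "count"), "end-count", path)
  df <- df[vapply(df$strand, function(s) normalize_strand(s), character(1)) ==
             strand, , drop = FALSE]
  out <- list()
  for (g in unique(df$genotype)) {
    sub <- df[df$genotype == g, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    counts <- vapply(reps, function(r) {
      rr <- sub[sub$replicate == r, , drop = FALSE]
      if (any(rr$position < 1L | rr$position > genome_length)) {
        stop_input("end-count file ", path, " has positions outside 1..",
                   genome_length)
      }
      v <- numeric(genome_length)
      v[rr$position] <- rr$count
      v
    }, numeric(genome_length))
    colnames(counts) <- paste0(g, "_rep", reps)
    out[[g]] <- end_profile(counts, strand, genotype = g)
  }
  out
}

#' Write 5'-end profiles to the package TSV dialect
#'
#' Zero positions are omitted to keep files small.
#'
#' @param profiles a named list of [end_profile()] objects (names are
#'   genotypes) or a single profile.
#' @param path output path.
#' @param seed,config forwarded to the metadata header.
#' @return the path, invisibly.
#' @export
write_end_counts_tsv <- function(profiles, path, seed = NULL, config = NULL) {
  if (inherits(profiles, "end_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$genotype)
  }
  rows <- list()
  for (g in names(profiles)) {
    p <- profiles[[g]]
    for (j in seq_len(ncol(p$counts))) {
      nz <- which(p$counts[, j] > 0)
      if (length(nz) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = p$strand, position = nz, replicate = j, genotype = g,
        count = p$counts[nz, j], stringsAsFactors = FALSE)
    }
  }
  write_tsv_meta(do.call(rbind, rows), path, seed = seed, config = config)
}

#' Read intron junction evidence from TSV
#'
#' Required columns: `intron`, `genotype`, `replicate`, `spliced`,
#' `unspliced`.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_intron_evidence <- function(path) {
  require_columns(read_tsv_meta(path),
                  c("intron", "genotype", "replicate", "spliced", "unspliced"),
                  "intron evidence", path)
}

#' Read editing-site evidence from TSV
#'
#' Required columns: `site`, `coord`, `genotype`, `replicate`, `edited`,
#' `unedited`.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_editing_evidence <- function(path) {
  require_columns(read_tsv_meta(path),
                  c("site", "coord", "genotype", "replicate", "edited",
                    "unedited"), "editing evidence", path)
}

#' Read alignment 5'/3' coordinates from a SAM or BAM file
#'
#' Uses Rsamtools/GenomicAlignments; SAM input is converted on the fly.
#' Returns the per-read fields [count_ends()] consumes.
#'
#' @param path path to a SAM or BAM file.
#' @return a data frame with columns `strand`, `start`, `end`.
#' @export
read_sam_ends <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(bam)
  data.frame(strand = as.character(BiocGenerics::strand(aln)),
             start = BiocGenerics::start(aln),
             end = BiocGenerics::end(aln),
             stringsAsFactors = FALSE)
}

# Minimal SAM writer used by the simulator: one read per counted 5' end,
# plain matches only.
write_end_sam <- function(counts, strand, genome, path,
                          read_length = 30L, seqname = "synthetic_mito") {
  glen <- length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", seqname, "\tLN:", glen)), con)
  nz <- which(counts > 0)
  gchars <- as.character(genome)
  id <- 0L
  for (p in nz) {
    if (strand == "+") {
      s <- p; e <- min(p + read_length - 1L, glen); flag <- 0L
    } else {
      e <- p; s <- max(p - read_length + 1L, 1L); flag <- 16L
    }
    len <- e - s + 1L
    seq <- substr(gchars, s, e)
    n <- counts[p]
    lines <- paste0("r", id + seq_len(n), "\t", flag, "\t", seqname, "\t", s,
                    "\t60\t", len, "M\t*\t0\t0\t", seq, "\t*")
    writeLines(lines, con)
    id <- id + n
  }
  invisible(path)
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes `genome.fasta`, `annotation.gff3`, `truth.json`,
#' `end_counts.tsv`, `introns.tsv`, `editing.tsv` and `clones.fasta`; the
#' outputs of this function are valid inputs to every analysis function in
#' the package.
#'
#' @param truth a [simulate_genome()] result.
#' @param dir output directory (created if needed).
#' @param depth junction/pileup depth for the evidence tables (default 200).
#' @return the directory path, invisibly.
#' @export
write_synthetic_data <- function(truth, dir, depth = 200L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- truth$config
  write_fasta(Biostrings::DNAStringSet(
    stats::setNames(list(truth$genome), "synthetic_mito")),
    file.path(dir, "genome.fasta"))
  write_gff3(truth$models, file.path(dir, "annotation.gff3"))
  ends <- simulate_end_counts(truth)
  write_end_counts_tsv(list(wt = ends$wt, mutant = ends$mutant),
                       file.path(dir, "end_counts.tsv"),
                       seed = cfg$seed, config = cfg)
  ev <- simulate_junctions_and_editing(truth, depth = depth)
  write_tsv_meta(ev$introns, file.path(dir, "introns.tsv"),
                 seed = cfg$seed, config = cfg)
  write_tsv_meta(ev$editing, file.path(dir, "editing.tsv"),
                 seed = cfg$seed, config = cfg)
  cl <- simulate_clones(truth)
  write_fasta(cl$clones, file.path(dir, "clones.fasta"))
  truth_json <- list(
    seed = cfg$seed,
    site = truth$site[c("start", "end", "strand", "mismatches")],
    boundary = truth$boundary,
    cleaved_fraction = cfg$cleaved_fraction,
    splicing = truth$splicing,
    editing = truth$editing,
    clone_ends = cl$ends)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
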