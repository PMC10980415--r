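# Transcript models, strand-aware coordinate conversion, mismatch-tolerant
# site scanning and cleavage fragment-size prediction.

normalize_strand <- function(strand) {
  s <- tolower(as.character(strand))
  if (s %in% c("+", "forward", "fwd", "plus")) return("+")
  if (s %in% c("-", "reverse", "rev", "minus")) return("-")
  stop_input("strand must be one of '+', '-', 'forward', 'reverse'")
}

#' Construct a strand-aware transcript model
#'
#' Coordinates are 1-based inclusive genome coordinates (GenBank convention)
#' and the CDS interval is written 5' to 3', so a reverse-strand gene has
#' `cds_start > cds_end`. UTR lengths extend the transcript beyond the CDS on
#' the appropriate sides.
#'
#' @param gene gene identifier.
#' @param strand `"+"`/`"forward"` or `"-"`/`"reverse"`.
#' @param cds_start genome coordinate of the first CDS base (the 5' end).
#' @param cds_end genome coordinate of the last CDS base (the 3' end).
#' @param utr5,utr3 lengths of the 5' and 3' UTRs in nucleotides.
#' @param introns optional data frame with columns `start`, `end` (genome
#'   coordinates, any order) and logical `trans` marking trans-spliced
#'   introns; intervals must lie within the gene span.
#' @return an object of class `transcript_model`.
#' @examples
#' # a reverse-strand gene: CDS runs 5'->3' from 68621 down to 67098
#' atp1 <- transcript_model("atp1", "-", 68621, 67098, utr5 = 363, utr3 = 157)
#' cds_to_genome(atp1, 1330)
#' @export
transcript_model <- function(gene, strand, cds_start, cds_end,
                             utr5 = 0L, utr3 = 0L, introns = NULL) {
  strand <- normalize_strand(strand)
  for (v in c("cds_start", "cds_end", "utr5", "utr3")) {
    assert_scalar_number(get(v), v)
  }
  if (utr5 < 0 || utr3 < 0) stop_input("UTR lengths must be non-negative")
  if (strand == "+" && cds_start > cds_end) {
    stop_input("forward-strand CDS must have cds_start <= cds_end")
  }
  if (strand == "-" && cds_start < cds_end) {
    stop_input("reverse-strand CDS is written 5'->3' and must have cds_start >= cds_end")
  }
  cds_len <- abs(cds_start - cds_end) + 1L
  dirn <- if (strand == "+") 1L else -1L
  tx_start <- cds_start - dirn * utr5   # genome coordinate of transcript 5' base
  tx_end <- cds_end + dirn * utr3       # genome coordinate of transcript 3' base
  if (min(tx_start, tx_end) < 1L) {
    stop_input("transcript extends below genome coordinate 1")
  }
  if (!is.null(introns)) {
    if (!is.data.frame(introns) || !all(c("start", "end") %in% names(introns))) {
      stop_input("introns must be a data frame with columns start, end")
    }
    if (is.null(introns$trans)) introns$trans <- FALSE
    lo <- pmin(introns$start, introns$end)
    hi <- pmax(introns$start, introns$end)
    span <- range(tx_start, tx_end)
    if (any(lo < span[1L] | hi > span[2L])) {
      stop_input("intron interval(s) outside the gene span")
    }
    if (is.null(introns$id)) {
      introns$id <- paste0(gene, ".i", seq_len(nrow(introns)))
    }
  }
  structure(
    list(gene = as.character(gene), strand = strand,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         cds_length = as.integer(cds_len),
         utr5 = as.integer(utr5), utr3 = as.integer(utr3),
         tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
         tx_length = as.integer(cds_len + utr5 + utr3),
         introns = introns),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model '", x$gene, "' (", x$strand, " strand)\n", sep = "")
  cat("  CDS ", x$cds_start, "..", x$cds_end, " (", x$cds_length, " nt), UTR5 ",
      x$utr5, " nt, UTR3 ", x$utr3, " nt, transcript ", x$tx_length, " nt\n",
      sep = "")
  if (!is.null(x$introns) && nrow(x$introns) > 0L) {
    cat("  introns:", paste0(x$introns$id, "[", x$introns$start, "..",
                             x$introns$end,
                             ifelse(x$introns$trans, ",trans", ""), "]",
                             collapse = " "), "\n")
  }
  invisible(x)
}

#' Map a CDS position to its genome coordinate
#'
#' @param model a [transcript_model()].
#' @param cds_pos 1-based position(s) within the CDS (1 = first base of the
#'   start codon).
#' @return genome coordinate(s), 1-based inclusive.
#' @examples
#' atp1 <- transcript_model("atp1", "-", 68621, 67098, utr5 = 363, utr3 = 157)
#' cds_to_genome(atp1, c(1, 1330, 1524))  # 68621 67292 67098
#' @export
cds_to_genome <- function(model, cds_pos) {
  stopifnot(inherits(model, "transcript_model"))
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L) || any(cds_pos > model$cds_length)) {
    stop_input("cds_pos must lie in 1..", model$cds_length)
  }
  if (model$strand == "+") model$cds_start + cds_pos - 1L
  else model$cds_start - cds_pos + 1L
}

#' Map a genome coordinate to its CDS position
#'
#' Exact inverse of [cds_to_genome()]; the coordinate must fall within the
#' CDS interval.
#'
#' @param model a [transcript_model()].
#' @param coord genome coordinate(s), 1-based inclusive.
#' @return 1-based CDS position(s).
#' @export
genome_to_cds <- function(model, coord) {
  stopifnot(inherits(model, "transcript_model"))
  coord <- as.integer(coord)
  pos <- if (model$strand == "+") coord - model$cds_start + 1L
         else model$cds_start - coord + 1L
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > model$cds_length)) {
    stop_input("coordinate outside the CDS interval ",
               model$cds_start, "..", model$cds_end)
  }
  pos
}

# Transcript-frame position (1 = transcript 5' base, includes UTRs).
genome_to_tx <- function(model, coord) {
  coord <- as.integer(coord)
  pos <- if (model$strand == "+") coord - model$tx_start + 1L
         else model$tx_start - coord + 1L
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > model$tx_length)) {
    stop_input("coordinate outside the transcript span")
  }
  pos
}

#' Scan a genome for near-matches to a query pattern
#'
#' Reports every window whose Hamming distance to the query is at most
#' `max_mismatch`, with IUPAC-degenerate query symbols matching their base
#' sets (the classic fuzznuc-style search). Overlapping hits are all
#' reported. U and T are interchangeable on input.
#'
#' @param genome genome sequence (character string, `DNAString` or a
#'   single-sequence `DNAStringSet`).
#' @param query query pattern; plain bases plus IUPAC degeneracy codes.
#' @param max_mismatch maximum number of mismatching positions (>= 0).
#' @param both_strands also scan the reverse strand (default `TRUE`). Reverse
#'   hits are reported as forward-genome intervals with `strand == "-"`; the
#'   `match` column always gives the hit in query orientation.
#' @param circular treat the genome as circular, allowing windows that wrap
#'   past the end (reported with `end < start`). Default `FALSE`.
#' @param model optional [transcript_model()]; hits falling entirely within
#'   its CDS on its strand gain `cds_start`/`cds_end` columns.
#' @return a data frame of class `site_hit_table` with columns `start`,
#'   `end`, `strand`, `mismatches`, `match`, sorted by (mismatches,
#'   coordinate).
#' @export
fuzzy_scan <- function(genome, query, max_mismatch = 0L, both_strands = TRUE,
                       circular = FALSE, model = NULL) {
  subject <- as_dna_string(genome, "genome")
  if (!grepl("^[ACGT]*$", as.character(subject))) {
    stop_input("genome may contain only A, C, G, T/U")
  }
  pattern <- as_dna_string(query, "query")
  qlen <- length(pattern)
  glen <- length(subject)
  assert_scalar_number(max_mismatch, "max_mismatch")
  if (max_mismatch < 0L) stop_input("max_mismatch must be >= 0")
  if (qlen > glen) stop_input("query longer than genome")

  scan_subject <- subject
  if (circular && qlen > 1L) {
    scan_subject <- Biostrings::xscat(
      subject, Biostrings::subseq(subject, 1L, qlen - 1L))
  }

  one_strand <- function(pat, strand) {
    hits <- Biostrings::matchPattern(
      pat, scan_subject, max.mismatch = max_mismatch, with.indels = FALSE,
      fixed = c(pattern = FALSE, subject = TRUE))
    starts <- BiocGenerics::start(hits)
    starts <- starts[starts >= 1L & starts <= glen]  # dedupe wrapped copies
    if (length(starts) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0),
                        match = character(0), stringsAsFactors = FALSE))
    }
    nedit <- Biostrings::neditStartingAt(
      pat, scan_subject, starting.at = starts, with.indels = FALSE,
      fixed = c(pattern = FALSE, subject = TRUE))
    seqs <- vapply(starts, function(s) {
      as.character(Biostrings::subseq(scan_subject, s, s + qlen - 1L))
    }, character(1))
    if (strand == "-") {
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    }
    ends <- starts + qlen - 1L
    ends <- ifelse(ends > glen, ends - glen, ends)  # wrap (circular only)
    data.frame(start = starts, end = as.integer(ends), strand = strand,
               mismatches = as.integer(nedit), match = seqs,
               stringsAsFactors = FALSE)
  }

  out <- one_strand(pattern, "+")
  if (isTRUE(both_strands)) {
    out <- rbind(out, one_strand(Biostrings::reverseComplement(pattern), "-"))
  }
  out <- out[order(out$mismatches, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL

  if (!is.null(model) && nrow(out) > 0L) {
    out$cds_start <- NA_integer_
    out$cds_end <- NA_integer_
    cds_rng <- range(model$cds_start, model$cds_end)
    inside <- out$strand == model$strand &
      pmin(out$start, out$end) >= cds_rng[1L] &
      pmax(out$start, out$end) <= cds_rng[2L]
    if (any(inside)) {
      # CDS-relative interval written 5'->3' on the gene's strand
      five <- if (model$strand == "+") out$start[inside] else out$end[inside]
      three <- if (model$strand == "+") out$end[inside] else out$start[inside]
      out$cds_start[inside] <- genome_to_cds(model, five)
      out$cds_end[inside] <- genome_to_cds(model, three)
    }
  }
  class(out) <- c("site_hit_table", "data.frame")
  out
}

#' Predict cleavage fragment sizes
#'
#' Given a cleavage point after a CDS position, returns the lengths of the
#' 5' fragment (5' UTR plus CDS up to the cut) and the 3' fragment (rest of
#' the CDS plus 3' UTR). The two always sum to the transcript length; these
#' are the sizes a northern blot of a cleaved transcript would show.
#'
#' @param model a [transcript_model()].
#' @param cleavage_after 1-based CDS position after which the transcript is
#'   cut (`1 <= cleavage_after < cds_length`).
#' @return named numeric vector `c(frag5, frag3)`.
#' @export
predict_fragments <- function(model, cleavage_after) {
  stopifnot(inherits(model, "transcript_model"))
  assert_scalar_number(cleavage_after, "cleavage_after")
  if (cleavage_after < 1L || cleavage_after >= model$cds_length) {
    stop_input("cleavage_after must lie in 1..", model$cds_length - 1L)
  }
  frag5 <- model$utr5 + cleavage_after
  frag3 <- (model$cds_length - cleavage_after) + model$utr3
  c(frag5 = frag5, frag3 = frag3)
}

#' Locate a probe relative to a binding site on the transcript
#'
#' Orders two genome-coordinate intervals in the transcript frame
#' (strand-corrected 5' to 3') and reports whether the probe lies upstream
#' of, downstream of, or overlapping the binding site.
#'
#' @param model a [transcript_model()].
#' @param probe,site genome-coordinate intervals as length-2 vectors (order
#'   irrelevant); both must lie within the transcript span.
#' @return `"upstream_5prime"`, `"downstream_3prime"` or `"overlapping"`.
#' @export
probe_side <- function(model, probe, site) {
  stopifnot(inherits(model, "transcript_model"))
  as_tx_interval <- function(iv, name) {
    if (length(iv) != 2L || any(is.na(iv))) {
      stop_input(name, " must be a length-2 coordinate interval")
    }
    span <- range(model$tx_start, model$tx_end)
    if (max(iv) < span[1L] || min(iv) > span[2L]) {
      stop_input(name, " interval is disjoint from the transcript span")
    }
    sort(genome_to_tx(model, iv))
  }
  p <- as_tx_interval(probe, "probe")
  s <- as_tx_interval(site, "site")
  if (p[2L] < s[1L]) "upstream_5prime"
  else if (p[1L] > s[2L]) "downstream_3prime"
  else "overlapping"
}
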