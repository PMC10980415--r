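# Transcript end mapping from circularized RT-PCR (cRT-PCR) clones and
# consensus cleavage-boundary calling.
#
# A cRT-PCR clone reads across the 3'-5' junction created by circularizing a
# transcript (fragment): its prefix is the reference up to the fragment's 3'
# end, its suffix the reference from the fragment's 5' end onward, both in
# transcript orientation.

# Gene-strand view of the genome: sequence read 5'->3' on the gene's strand,
# with a mapping between strand indices and genome coordinates.
strand_view <- function(genome, strand) {
  g <- as_dna_string(genome, "genome")
  if (strand == "-") g <- Biostrings::reverseComplement(g)
  list(seq = g, strand = strand, glen = length(g))
}

strand_index_to_coord <- function(view, idx) {
  if (view$strand == "+") as.integer(idx) else view$glen - as.integer(idx) + 1L
}

# Canonical member of a junction shift family on strand indices: while the
# base just past the 3' end equals the base at the 5' end the two splits give
# identical clone sequences; shift to maximal e3.
canonicalize_junction <- function(view, e3, s5) {
  letters_ <- strsplit(as.character(view$seq), "")[[1L]]
  while (e3 + 1L <= view$glen && s5 + 1L <= view$glen &&
         letters_[e3 + 1L] == letters_[s5]) {
    e3 <- e3 + 1L
    s5 <- s5 + 1L
  }
  c(e3 = e3, s5 = s5)
}

#' Locate the circularization junction in a single cRT-PCR clone
#'
#' Splits the clone at the unique position where the prefix maps exactly and
#' contiguously to the reference (ending at the transcript fragment's 3' end)
#' and the suffix maps exactly and contiguously (starting at the fragment's
#' 5' end), with both anchors at least `min_anchor` nucleotides. Exact-match
#' anchoring is used rather than alignment: cRT-PCR products are near-exact
#' copies of the reference.
#'
#' @param clone_seq clone sequence in transcript orientation.
#' @param genome genome sequence.
#' @param model a [transcript_model()] giving the gene's strand.
#' @param min_anchor minimum exact-match length on each side of the junction
#'   (default 15 nt).
#' @return a list of class `clone_end_pair`: `end3` and `end5` (genome
#'   coordinates of the mapped 3' and 5' transcript ends), `anchor3`,
#'   `anchor5` (matched lengths on each side).
#' @section Errors: clones with no consistent split, or with several equally
#'   supported splits, raise an error of class `pprcleave_ambiguous_clone`;
#'   [map_clone_ends()] catches these and reports them as excluded.
#' @export
locate_junction <- function(clone_seq, genome, model, min_anchor = 15L) {
  stopifnot(inherits(model, "transcript_model"))
  view <- strand_view(genome, model$strand)
  clone <- as_dna_string(clone_seq, "clone_seq")
  n <- length(clone)
  if (n < 2L * min_anchor) {
    stop(errorCondition(
      paste0("clone shorter than twice the minimum anchor (", min_anchor, " nt)"),
      class = c("pprcleave_ambiguous_clone", "error")))
  }
  candidates <- list()
  for (k in seq.int(min_anchor, n - min_anchor)) {
    prefix <- Biostrings::subseq(clone, 1L, k)
    suffix <- Biostrings::subseq(clone, k + 1L, n)
    pm <- Biostrings::matchPattern(prefix, view$seq)
    if (length(pm) == 0L) next
    sm <- Biostrings::matchPattern(suffix, view$seq)
    if (length(sm) == 0L) next
    for (e in BiocGenerics::end(pm)) {
      for (s in BiocGenerics::start(sm)) {
        # skip splits that just cut a contiguously mapping block
        if (s == e + 1L) next
        candidates[[length(candidates) + 1L]] <-
          list(e3 = e, s5 = s, k = k)
      }
    }
  }
  if (length(candidates) == 0L) {
    stop(errorCondition("no consistent junction split found",
                        class = c("pprcleave_ambiguous_clone", "error")))
  }
  pairs <- unique(t(vapply(candidates, function(cc) c(cc$e3, cc$s5),
                           integer(2))))
  # Splits shifted by a common offset d -> (e3+d, s5+d) produce the identical
  # clone sequence and are indistinguishable in principle; collapse such a
  # shift family to its canonical member (maximal e3, i.e. maximal 3'-fragment
  # extension). Anything else is a genuine ambiguity.
  d <- pairs[, 1L] - pairs[1L, 1L]
  is_family <- all(pairs[, 2L] - pairs[1L, 2L] == d)
  if (!is_family) {
    stop(errorCondition(
      paste0("ambiguous clone: ", nrow(pairs), " equally supported splits"),
      class = c("pprcleave_ambiguous_clone", "error")))
  }
  pick <- which.max(pairs[, 1L])
  e3 <- pairs[pick, 1L]
  s5 <- pairs[pick, 2L]
  k <- max(vapply(candidates, function(cc) {
    if (cc$e3 == e3 && cc$s5 == s5) cc$k else NA_integer_
  }, integer(1)), na.rm = TRUE)
  structure(
    list(end3 = strand_index_to_coord(view, e3),
         end5 = strand_index_to_coord(view, s5),
         anchor3 = k, anchor5 = n - k),
    class = "clone_end_pair"
  )
}

#' Map transcript ends for a set of cRT-PCR clones
#'
#' Runs [locate_junction()] over every clone; clones that fail anchoring are
#' excluded and counted, never silently dropped.
#'
#' @param clones a named `DNAStringSet` (e.g. from [read_fasta()]) or a named
#'   character vector of clone sequences.
#' @param genome genome sequence.
#' @param model a [transcript_model()].
#' @param min_anchor minimum exact anchor length per side (default 15 nt).
#' @return a data frame with one row per clone: `clone`, `end3`, `end5`,
#'   `anchor3`, `anchor5`, `status` (`"ok"`, or the failure reason).
#' @export
map_clone_ends <- function(clones, genome, model, min_anchor = 15L) {
  if (is.character(clones)) {
    clones <- Biostrings::DNAStringSet(chartr("uU", "tT", toupper(clones)))
  }
  nm <- names(clones) %||% paste0("clone_", seq_along(clones))
  if (is.null(names(clones))) names(clones) <- nm
  rows <- lapply(seq_along(clones), function(i) {
    res <- tryCatch(
      locate_junction(clones[[i]], genome, model, min_anchor),
      pprcleave_ambiguous_clone = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      data.frame(clone = nm[i], end3 = NA_integer_, end5 = NA_integer_,
                 anchor3 = NA_integer_, anchor5 = NA_integer_,
                 status = res, stringsAsFactors = FALSE)
    } else {
      data.frame(clone = nm[i], end3 = res$end3, end5 = res$end5,
                 anchor3 = res$anchor3, anchor5 = res$anchor5,
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  n_bad <- sum(out$status != "ok")
  if (n_bad > 0L) {
    message(n_bad, " of ", nrow(out), " clone(s) excluded (ambiguous/unmapped)")
  }
  out
}

#' Call a consensus cleavage boundary from mapped clone ends
#'
#' The boundary is reported as the adjacent coordinate pair flanking the cut
#' in transcript frame ("cleavage between bases x and y"): the most-supported
#' 5' end of the downstream fragment, together with its transcript-upstream
#' neighbour. Support is the number of clones whose 5' end equals the
#' boundary's 5' side. Ties are broken toward the coordinate nearest the 3'
#' edge of the binding site when one is supplied; otherwise the call is
#' flagged multi-modal.
#'
#' @param pairs a data frame with columns `end5`, `end3` (genome
#'   coordinates), e.g. the `status == "ok"` rows of [map_clone_ends()], or a
#'   list of `clone_end_pair` objects.
#' @param model a [transcript_model()] (supplies the strand).
#' @param site_3prime optional genome coordinate of the binding site's 3'
#'   edge, used only to break ties between equally supported 5' ends.
#' @return an object of class `cleavage_call` with elements `boundary`
#'   (named vector `upstream`/`downstream`: last base of the 5' fragment and
#'   first base of the 3' fragment in transcript frame), `support`,
#'   `n_clones`, `span` (min..max over all observed ends), `multimodal` and
#'   `modes`.
#' @export
call_consensus <- function(pairs, model, site_3prime = NULL) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(end3 = p$end3, end5 = p$end5)
    }))
  }
  pairs <- pairs[!is.na(pairs$end5) & !is.na(pairs$end3), , drop = FALSE]
  if (nrow(pairs) == 0L) stop_input("no valid clone end pairs supplied")
  tab <- table(pairs$end5)
  best <- max(tab)
  modes <- as.integer(names(tab)[tab == best])
  multimodal <- length(modes) > 1L
  if (multimodal && !is.null(site_3prime)) {
    modes <- modes[order(abs(modes - site_3prime))]
    multimodal <- FALSE
  }
  m <- modes[1L]
  dirn <- if (model$strand == "+") 1L else -1L
  boundary <- c(upstream = m - dirn, downstream = m)
  structure(
    list(boundary = boundary,
         support = as.integer(best),
         n_clones = nrow(pairs),
         span = range(c(pairs$end5, pairs$end3)),
         multimodal = multimodal,
         modes = modes),
    class = "cleavage_call"
  )
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat("Cleavage call: between bases ",
      min(x$boundary), " and ", max(x$boundary), "\n", sep = "")
  cat("  support ", x$support, "/", x$n_clones, " clones; observed ends span ",
      x$span[1L], "..", x$span[2L], "\n", sep = "")
  if (x$multimodal) {
    cat("  NOTE: multi-modal (", paste(x$modes, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}
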