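# PPR scaffolds, the PPR code, binding prediction and scaffold redesign.

#' Construct a PPR protein scaffold
#'
#' A scaffold is an ordered list of PPR motifs, each carrying the two
#' specifying residues that determine its base preference under the PPR code.
#' Motifs are indexed 1..n from the N terminus; during binding prediction
#' motif i faces base i of the target with the N-terminal motif opposite the
#' 5' base.
#'
#' @param name scaffold identifier.
#' @param motifs a data frame with columns `index` (consecutive integers from
#'   1), `res1`, `res2` (one-letter amino-acid symbols, `"X"` for unknown) and
#'   optionally `class` (motif class label such as `"P"`, `"L"`, `"S"`;
#'   defaults to `"P"`).
#' @return an object of class `ppr_protein`.
#' @seealso [read_motif_table()], [predict_binding()], [redesign()]
#' @export
ppr_protein <- function(name, motifs) {
  if (!is.data.frame(motifs)) stop_input("motifs must be a data frame")
  required <- c("index", "res1", "res2")
  missing_cols <- setdiff(required, names(motifs))
  if (length(missing_cols) > 0L) {
    stop_input("motif table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  motifs <- motifs[order(motifs$index), , drop = FALSE]
  n <- nrow(motifs)
  if (n < 1L) stop_input("a scaffold needs at least one motif")
  if (!identical(as.integer(motifs$index), seq_len(n))) {
    stop_input("motif indices must be consecutive integers starting at 1")
  }
  motifs$res1 <- toupper(as.character(motifs$res1))
  motifs$res2 <- toupper(as.character(motifs$res2))
  bad <- setdiff(unique(c(motifs$res1, motifs$res2)), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop_input("invalid amino-acid symbol(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(motifs$class)) motifs$class <- "P"
  rownames(motifs) <- NULL
  structure(
    list(name = as.character(name),
         motifs = motifs[, c("index", "res1", "res2", "class")]),
    class = "ppr_protein"
  )
}

#' @export
print.ppr_protein <- function(x, ...) {
  cat("PPR scaffold '", x$name, "': ", nrow(x$motifs), " motifs\n", sep = "")
  cat(" specifying residues:",
      paste0(x$motifs$res1, x$motifs$res2, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.ppr_protein <- function(x) nrow(x$motifs)

#' Read a PPR motif table
#'
#' Reads a scaffold from a TSV file with columns `name`, `index`, `class`,
#' `res1`, `res2` (one row per motif). Scaffolds arrive pre-annotated: the
#' choice of which two residues are "specifying" is a property of this table,
#' not inferred from protein sequence.
#'
#' @param path path to the TSV file.
#' @return a [ppr_protein()] object.
#' @export
read_motif_table <- function(path) {
  df <- read_tsv_meta(path)
  required <- c("name", "index", "class", "res1", "res2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_input("motif table ", path, " is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  nm <- unique(df$name)
  if (length(nm) != 1L) stop_input("motif table must describe a single scaffold")
  ppr_protein(nm, df[, c("index", "res1", "res2", "class")])
}

#' Construct a PPR code table
#'
#' The PPR code maps a pair of specifying residues to a preference over the
#' four RNA bases, graded as `perfect`, `partial`, `neutral` or `mismatch`.
#' Residue pairs absent from the table classify as `neutral` for every base
#' (the non-committal class).
#'
#' @param entries a named list; names are two-letter residue pairs (e.g.
#'   `"TD"`), values are named character vectors giving the match class for
#'   each of `A`, `C`, `G`, `U`.
#' @return an object of class `ppr_code`.
#' @seealso [default_ppr_code()], [read_ppr_code()]
#' @export
ppr_code <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    stop_input("code entries must be a named list keyed by residue pair")
  }
  names(entries) <- toupper(names(entries))
  for (pair in names(entries)) {
    if (nchar(pair) != 2L ||
        !all(strsplit(pair, "")[[1L]] %in% AA_ALPHABET)) {
      stop_input("invalid residue pair key: ", pair)
    }
    e <- entries[[pair]]
    e <- vapply(e, as.character, character(1))
    names(e) <- toupper(chartr("T", "U", names(e)))
    if (!setequal(names(e), RNA_BASES)) {
      stop_input("code entry for ", pair, " must cover all four bases A,C,G,U")
    }
    bad <- setdiff(unique(e), MATCH_CLASSES)
    if (length(bad) > 0L) {
      stop_input("invalid match class in entry ", pair, ": ",
                 paste(bad, collapse = ", "))
    }
    entries[[pair]] <- e[RNA_BASES]
  }
  structure(list(entries = entries), class = "ppr_code")
}

#' @export
print.ppr_code <- function(x, ...) {
  cat("PPR code table:", length(x$entries), "residue pairs\n")
  for (pair in names(x$entries)) {
    e <- x$entries[[pair]]
    cat(" ", pair, ": ", paste(names(e), substr(e, 1, 4), sep = "=",
                               collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a PPR code table from a YAML file
#'
#' The file maps two-letter residue pairs to per-base match classes, e.g.
#' `TD: {A: partial, C: mismatch, G: perfect, U: mismatch}`.
#'
#' @param path path to the YAML file.
#' @return a [ppr_code()] object.
#' @export
read_ppr_code <- function(path) {
  ppr_code(yaml::read_yaml(path))
}

#' Default PPR code table
#'
#' A documented default assembled from the published PPR-code literature for
#' the canonical specifying-residue combinations (positions often numbered 5
#' and 35 of the 35-amino-acid repeat). It covers the common P-class pairs;
#' pairs not listed classify as neutral. Analyses whose conclusions depend on
#' the code should pass an explicit table.
#'
#' @return a [ppr_code()] object.
#' @export
default_ppr_code <- function() {
  read_ppr_code(system.file("extdata", "ppr_code_default.yml",
                            package = "pprcleave", mustWork = TRUE))
}

#' Classify a single motif-base pairing under the PPR code
#'
#' @param residues the motif's specifying residues, as a length-2 character
#'   vector (e.g. `c("T","D")`) or a two-letter string (`"TD"`).
#' @param base a single RNA base, one of `A`, `C`, `G`, `U` (`T` accepted).
#' @param code a [ppr_code()] table.
#' @return one of `"perfect"`, `"partial"`, `"neutral"`, `"mismatch"`.
#'   Residue pairs absent from the table return `"neutral"`.
#' @export
classify_pair <- function(residues, base, code) {
  if (!inherits(code, "ppr_code")) stop_input("code must be a ppr_code object")
  pair <- toupper(paste(residues, collapse = ""))
  if (nchar(pair) != 2L) stop_input("residues must give exactly two symbols")
  base <- as_rna_chars(base, "base")
  if (length(base) != 1L) stop_input("base must be a single RNA base")
  e <- code$entries[[pair]]
  if (is.null(e)) return("neutral")
  unname(e[[base]])
}

#' Default score weights for binding predictions
#'
#' @return named numeric vector of per-class weights.
#' @export
default_match_weights <- function() {
  c(perfect = 2, partial = 1, neutral = 0, mismatch = -2)
}

#' Predict PPR-protein binding to an RNA target
#'
#' Aligns motif i of the scaffold with base i of the target (N-terminal motif
#' opposite the 5' base) and classifies every pairing under the PPR code.
#'
#' @param protein a [ppr_protein()] scaffold.
#' @param target RNA sequence, same length as the scaffold (T is read as U).
#' @param code a [ppr_code()] table.
#' @param weights per-class score weights; see [default_match_weights()].
#' @return an object of class `binding_prediction` with elements
#'   `per_position` (data frame: index, residues, base, class), `counts`
#'   (tally per match class, summing to the motif count) and `score`
#'   (weighted sum).
#' @export
predict_binding <- function(protein, target, code,
                            weights = default_match_weights()) {
  if (!inherits(protein, "ppr_protein")) {
    stop_input("protein must be a ppr_protein object")
  }
  bases <- as_rna_chars(target, "target")
  n <- length(protein)
  if (length(bases) != n) {
    stop_input("target length (", length(bases),
               ") must equal motif count (", n, ")")
  }
  if (!all(MATCH_CLASSES %in% names(weights))) {
    stop_input("weights must name all four match classes")
  }
  cls <- vapply(seq_len(n), function(i) {
    classify_pair(c(protein$motifs$res1[i], protein$motifs$res2[i]),
                  bases[i], code)
  }, character(1))
  counts <- vapply(MATCH_CLASSES, function(k) sum(cls == k), integer(1))
  structure(
    list(
      protein = protein$name,
      target = paste(bases, collapse = ""),
      per_position = data.frame(
        index = seq_len(n),
        res1 = protein$motifs$res1,
        res2 = protein$motifs$res2,
        base = bases,
        class = cls,
        stringsAsFactors = FALSE
      ),
      counts = counts,
      score = sum(weights[cls])
    ),
    class = "binding_prediction"
  )
}

#' @export
print.binding_prediction <- function(x, ...) {
  cat("Binding prediction: ", x$protein, " vs 5'-", x$target, "-3'\n", sep = "")
  cat(" classes:", paste(substr(x$per_position$class, 1, 1), collapse = ""), "\n")
  cat(" counts: ", paste(names(x$counts), x$counts, sep = "=", collapse = " "),
      "\n score:  ", x$score, "\n", sep = "")
  invisible(x)
}

# First residue pair in the code classified perfect for `base`, or NA.
perfect_pair_for_base <- function(base, code) {
  for (pair in names(code$entries)) {
    if (code$entries[[pair]][[base]] == "perfect") return(pair)
  }
  NA_character_
}

#' Retarget a PPR scaffold to a new RNA sequence
#'
#' Computes the minimal set of specifying-residue substitutions that removes
#' all offending match classes against `new_target`. In the default mode only
#' motifs classified `mismatch` are modified; in strict mode every motif not
#' classified `perfect` is modified. Replacement pairs are taken from the
#' code table (the first pair classified `perfect` for the opposing base, in
#' table order, so the result is deterministic).
#'
#' @param protein a [ppr_protein()] scaffold.
#' @param new_target RNA sequence of the same length as the scaffold.
#' @param code a [ppr_code()] table.
#' @param strict if `FALSE` (default) only mismatched motifs are changed; if
#'   `TRUE` every motif whose class is not perfect is changed.
#' @param weights score weights forwarded to [predict_binding()].
#' @return an object of class `redesign_plan` with elements `changes`
#'   (data frame: index, old/new residue pairs), `protein` (the modified
#'   [ppr_protein()]), `predicted_pre` and `predicted_post` (binding
#'   predictions before and after modification; `predicted_post` contains no
#'   mismatches).
#' @export
redesign <- function(protein, new_target, code, strict = FALSE,
                     weights = default_match_weights()) {
  pre <- predict_binding(protein, new_target, code, weights)
  fix_classes <- if (strict) c("mismatch", "partial", "neutral") else "mismatch"
  to_fix <- which(pre$per_position$class %in% fix_classes)
  motifs <- protein$motifs
  changes <- data.frame(
    index = integer(0), old_res1 = character(0), old_res2 = character(0),
    new_res1 = character(0), new_res2 = character(0),
    stringsAsFactors = FALSE
  )
  for (i in to_fix) {
    base <- pre$per_position$base[i]
    pair <- perfect_pair_for_base(base, code)
    if (is.na(pair)) {
      stop(errorCondition(
        paste0("design infeasible: no residue pair in the code is a perfect ",
               "match for base ", base, " (motif ", i, ")"),
        class = c("pprcleave_design_infeasible", "error")
      ))
    }
    res <- strsplit(pair, "")[[1L]]
    changes <- rbind(changes, data.frame(
      index = i, old_res1 = motifs$res1[i], old_res2 = motifs$res2[i],
      new_res1 = res[1L], new_res2 = res[2L], stringsAsFactors = FALSE
    ))
    motifs$res1[i] <- res[1L]
    motifs$res2[i] <- res[2L]
  }
  new_protein <- if (nrow(changes) == 0L) protein else {
    ppr_protein(paste0(protein$name, "-redesigned"), motifs)
  }
  post <- predict_binding(new_protein, new_target, code, weights)
  if (post$counts[["mismatch"]] != 0L) {
    stop(errorCondition(
      "design infeasible: mismatches remain after substitution",
      class = c("pprcleave_design_infeasible", "error")
    ))
  }
  structure(
    list(changes = changes, protein = new_protein,
         predicted_pre = pre, predicted_post = post, strict = strict),
    class = "redesign_plan"
  )
}

#' @export
print.redesign_plan <- function(x, ...) {
  cat("Redesign plan (", if (x$strict) "strict" else "mismatch-only", "): ",
      nrow(x$changes), " change(s)\n", sep = "")
  if (nrow(x$changes) > 0L) {
    with(x$changes, cat(paste0(
      "  motif ", index, ": ", old_res1, old_res2, " -> ", new_res1, new_res2,
      collapse = "\n"), "\n"))
  }
  cat(" post-redesign counts: ",
      paste(names(x$predicted_post$counts), x$predicted_post$counts,
            sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}
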