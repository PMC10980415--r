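# Internal helpers shared across modules.

MATCH_CLASSES <- c("perfect", "partial", "neutral", "mismatch")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
RNA_BASES <- c("A", "C", "G", "U")

# IUPAC nucleotide codes as base sets (DNA alphabet; U folded into T on input)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pprcleave_input_error", "error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(name, " must be a single non-missing number")
  }
}

is_odd <- function(x) x %% 2L == 1L

# Canonical DNA form of a sequence given as character/RNA/DNA; U -> T.
as_dna_string <- function(x, name = "sequence") {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "RNAString")) return(Biostrings::DNAString(x))
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L) stop_input(name, " must be a single sequence")
    return(as_dna_string(x[[1L]], name))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_input(name, " must be a single character string or DNAString")
  }
  s <- chartr("uU", "tT", x)
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", toupper(s))
  if (!ok) stop_input(name, " contains invalid nucleotide symbols")
  Biostrings::DNAString(toupper(s))
}

# Canonical RNA character vector (one letter per element); T -> U.
as_rna_chars <- function(x, name = "target") {
  if (methods::is(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) < 1L) {
    stop_input(name, " must be a character string")
  }
  if (length(x) == 1L) x <- strsplit(x, "")[[1L]]
  x <- toupper(chartr("Tt", "Uu", paste(x, collapse = "")))
  x <- strsplit(x, "")[[1L]]
  bad <- setdiff(unique(x), RNA_BASES)
  if (length(bad) > 0L) {
    stop_input(name, " contains invalid RNA base symbol(s): ",
               paste(bad, collapse = ", "))
  }
  x
}

# Centered moving average with shrinking (partial) windows at the edges, so
# every position keeps a defined value.
running_mean <- function(x, k) {
  stopifnot(is_odd(k), k >= 1L)
  if (k == 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Short content hash for output metadata headers (base tools only).
config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

package_version_string <- function() {
  as.character(utils::packageVersion("pprcleave"))
}
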