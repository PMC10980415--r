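# Independent brute-force oracles and tiny fixtures used across tests.
# The oracles deliberately share no code with the package implementation.

# --- small explicit PPR code tables (tests never depend on the shipped
#     default's biology) ---

toy_code <- function() {
  ppr_code(list(
    TD = c(A = "partial", C = "mismatch", G = "perfect", U = "mismatch"),
    TN = c(A = "perfect", C = "mismatch", G = "partial", U = "mismatch"),
    ND = c(A = "mismatch", C = "partial", G = "mismatch", U = "perfect"),
    NS = c(A = "mismatch", C = "perfect", G = "mismatch", U = "partial")
  ))
}

# scaffold of n motifs drawn from the toy code's pairs (plus an unknown pair)
random_toy_scaffold <- function(n, include_unknown = FALSE) {
  pool <- c("TD", "TN", "ND", "NS", if (include_unknown) "QQ")
  pairs <- sample(pool, n, replace = TRUE)
  ppr_protein("toy", data.frame(
    index = seq_len(n),
    res1 = substr(pairs, 1, 1),
    res2 = substr(pairs, 2, 2)))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# brute-force per-position scan: classes of scaffold vs target, computed by
# direct table lookup without predict_binding
brute_classes <- function(protein, target, code) {
  bases <- strsplit(target, "")[[1]]
  vapply(seq_along(bases), function(i) {
    pair <- paste0(protein$motifs$res1[i], protein$motifs$res2[i])
    e <- code$entries[[pair]]
    if (is.null(e)) "neutral" else unname(e[[bases[i]]])
  }, character(1))
}

# --- brute-force fuzzy-site oracle (all-window Hamming with IUPAC sets) ---

iupac_oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_complement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

oracle_revcomp <- function(q) {
  paste(rev(iupac_complement[strsplit(q, "")[[1]]]), collapse = "")
}

# all windows of `genome` within max_mismatch of `query` (one orientation)
oracle_scan_one <- function(genome, query, max_mismatch) {
  g <- strsplit(genome, "")[[1]]
  q <- strsplit(query, "")[[1]]
  n <- length(g); k <- length(q)
  if (k > n) return(data.frame(start = integer(0), mismatches = integer(0)))
  nwin <- n - k + 1
  mm <- integer(nwin)
  for (j in seq_len(k)) {
    ok <- g[seq.int(j, j + nwin - 1)] %in% iupac_oracle_sets[[q[j]]]
    mm <- mm + !ok
  }
  hit <- which(mm <= max_mismatch)
  data.frame(start = hit, mismatches = mm[hit])
}

oracle_scan <- function(genome, query, max_mismatch, both_strands = TRUE) {
  fwd <- oracle_scan_one(genome, query, max_mismatch)
  fwd$strand <- rep("+", nrow(fwd))
  if (!both_strands) return(fwd)
  rev <- oracle_scan_one(genome, oracle_revcomp(query), max_mismatch)
  rev$strand <- rep("-", nrow(rev))
  rbind(fwd, rev)
}

random_genome_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# --- toy transcript models for coordinate tests ---

toy_models <- function() {
  list(
    fwd = transcript_model("fwd", "+", 101, 160, utr5 = 10, utr3 = 5),
    rev = transcript_model("rev", "-", 260, 201, utr5 = 7, utr3 = 12),
    bare_fwd = transcript_model("b1", "+", 11, 40),
    bare_rev = transcript_model("b2", "-", 90, 61)
  )
}

# textbook equal-variance two-sample t computed from first principles
oracle_t_equal_var <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
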