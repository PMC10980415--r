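# Synthetic organelle transcriptome with recorded ground truth.
#
# The generator emulates the data shapes the analysis modules consume:
# stranded replicate 5'-end count profiles with a planted cleavage site,
# intron junction evidence (including a trans-spliced intron), binomial
# editing pileups, and circularized-clone reads. Every stochastic draw is
# governed by the config seed.

#' Configuration for the synthetic organelle transcriptome
#'
#' Defaults describe a 10-kb toy mitogenome with three genes (one
#' reverse-strand gene carrying the planted binding site and cleavage
#' boundary, one gene with a cis intron, one with a trans-spliced intron),
#' a 16-motif scaffold, a binding site differing from the scaffold's perfect
#' target at 5 positions, a cleaved fraction of 0.5 in the knockdown with
#' 3 replicates per genotype, and negative-binomial replicate overdispersion
#' of 0.1.
#'
#' @param genome_length genome length in nucleotides (default 10000).
#' @param seed integer seed governing every stochastic draw.
#' @param perfect_target the scaffold's ideal 16-nt RNA target.
#' @param site_mismatches Hamming distance between the planted site and the
#'   perfect target (default 5).
#' @param cleaved_fraction fraction of the target transcript cleaved in the
#'   knockdown genotype (default 0.5).
#' @param replicates replicates per genotype (default 3).
#' @param depth mean background 5'-end count per transcript position for a
#'   gene of unit abundance (default 20).
#' @param peak_scale height of natural 5'-end peaks (transcript starts,
#'   trans-spliced half-intron start) and of the full cleavage point mass,
#'   as a multiple of the gene's background depth (default 50).
#' @param dispersion negative-binomial dispersion of replicate noise
#'   (variance = mu + dispersion * mu^2); 0 disables noise entirely
#'   (default 0.1).
#' @param splicing_wt,splicing_mut per-genotype spliced fractions applied to
#'   every intron (defaults 0.9 and 0.7).
#' @param n_editing_sites number of C-to-U editing sites (default 10).
#' @param editing_shift multiplicative drop of mutant editing rates relative
#'   to wild type (default 0.9).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 10000L,
                       seed = 1L,
                       perfect_target = "GAAUCCGUAUGGCAUC",
                       site_mismatches = 5L,
                       cleaved_fraction = 0.5,
                       replicates = 3L,
                       depth = 20,
                       peak_scale = 50,
                       dispersion = 0.1,
                       splicing_wt = 0.9,
                       splicing_mut = 0.7,
                       n_editing_sites = 10L,
                       editing_shift = 0.9) {
  cfg <- list(genome_length = as.integer(genome_length),
              seed = as.integer(seed),
              perfect_target = toupper(perfect_target),
              site_mismatches = as.integer(site_mismatches),
              cleaved_fraction = cleaved_fraction,
              replicates = as.integer(replicates),
              depth = depth, peak_scale = peak_scale,
              dispersion = dispersion,
              splicing_wt = splicing_wt, splicing_mut = splicing_mut,
              n_editing_sites = as.integer(n_editing_sites),
              editing_shift = editing_shift)
  if (cfg$genome_length < 9000L) {
    stop_input("genome_length must be at least 9000 for the fixed gene layout")
  }
  if (cfg$cleaved_fraction < 0 || cfg$cleaved_fraction > 1) {
    stop_input("cleaved_fraction must lie in [0, 1]")
  }
  if (cfg$site_mismatches < 0 ||
      cfg$site_mismatches > nchar(cfg$perfect_target)) {
    stop_input("site_mismatches must lie in 0..target length")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Build a scaffold whose every motif is a perfect match for `target` under
# `code` (first perfect pair in table order per base).
scaffold_for_target <- function(target, code, name = "scaffold") {
  bases <- as_rna_chars(target, "target")
  pairs <- vapply(bases, function(b) {
    p <- perfect_pair_for_base(b, code)
    if (is.na(p)) stop_input("code has no perfect pair for base ", b)
    p
  }, character(1))
  ppr_protein(name, data.frame(
    index = seq_along(bases),
    res1 = substr(pairs, 1, 1),
    res2 = substr(pairs, 2, 2),
    class = "P", stringsAsFactors = FALSE))
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Deterministic for a given config seed. The planted binding site sits in
#' the CDS of the reverse-strand gene and differs from the scaffold's
#' perfect target at exactly `site_mismatches` positions; the cleavage
#' boundary lies downstream (transcript 3') of the site. The genome is
#' locally adjusted so that the planted junction is its own canonical
#' shift-family representative (see [locate_junction()]).
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_truth` with elements `genome`
#'   (`DNAString`), `models` (named list of [transcript_model()]),
#'   `scaffold`, `code`, `site`, `boundary`, `abundance`, `natural_peaks`,
#'   `splicing`, `editing`, and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  models <- list(
    nadA = transcript_model("nadA", "+", 1501L, 2500L, utr5 = 100L, utr3 = 80L,
                            introns = data.frame(start = 1901L, end = 2100L,
                                                 trans = FALSE)),
    atpB = transcript_model("atpB", "-", 6200L, 5001L, utr5 = 150L,
                            utr3 = 120L),
    nadC = transcript_model("nadC", "+", 8001L, 8800L, utr5 = 60L, utr3 = 60L,
                            introns = data.frame(start = 8301L, end = 8500L,
                                                 trans = TRUE))
  )
  abundance <- c(nadA = 1.0, atpB = 1.5, nadC = 0.8)

  code <- default_ppr_code()
  scaffold <- scaffold_for_target(config$perfect_target, code,
                                  name = "synthetic-scaffold")
  qlen <- nchar(config$perfect_target)

  # plant the binding site at CDS positions 801..(800+qlen) of atpB
  site_cds <- c(801L, 800L + qlen)
  site_bases <- as_rna_chars(config$perfect_target)
  if (config$site_mismatches > 0L) {
    flip <- sample(qlen, config$site_mismatches)
    for (i in flip) {
      site_bases[i] <- sample(setdiff(RNA_BASES, site_bases[i]), 1L)
    }
  }
  site_rna <- paste(site_bases, collapse = "")
  site_dna <- chartr("U", "T", site_rna)
  # genome carries the reverse complement on the forward strand
  site_coords <- cds_to_genome(models$atpB, seq.int(site_cds[1L], site_cds[2L]))
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site_dna))), "")[[1L]]
  genome[seq(min(site_coords), max(site_coords))] <- rc

  # cleavage boundary: downstream fragment starts at CDS position 860
  boundary_cds <- 860L
  boundary_downstream <- cds_to_genome(models$atpB, boundary_cds)
  boundary_upstream <- cds_to_genome(models$atpB, boundary_cds - 1L)

  # Make the planted cRT-PCR junction stable under shift-family
  # canonicalization: the bases at and just past the transcript 3' end (gene
  # strand) must all differ from the base at the boundary's 5' side, so that
  # clones anchored at the boundary never shift away (and near-miss clones
  # can only shift toward it). Four positions cover the clone 3'-end jitter.
  tx3 <- models$atpB$tx_end                       # genome coord of 3' base
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  strand_base <- function(coord) comp[[genome[coord]]]  # "-" strand base
  bb <- strand_base(boundary_downstream)
  # short constant run just downstream of the cut: jittered near-boundary
  # ends then never merge with one another under canonicalization
  for (cc in boundary_downstream - 1:3) genome[cc] <- comp[[bb]]
  for (cc in tx3 - 0:3) {
    if (strand_base(cc) == bb) {
      repl <- sample(setdiff(c("A", "C", "G", "T"), bb), 1L)  # strand base
      genome[cc] <- comp[[repl]]
    }
  }

  # natural 5'-end peaks: transcript starts + trans-spliced half-intron start
  natural_peaks <- data.frame(
    gene = c("nadA", "atpB", "nadC", "nadC"),
    coord = c(models$nadA$tx_start, models$atpB$tx_start,
              models$nadC$tx_start, 8401L),
    strand = c("+", "-", "+", "+"),
    kind = c("tss", "tss", "tss", "trans_half_start"),
    stringsAsFactors = FALSE
  )

  introns <- data.frame(
    intron = c("nadA.i1", "nadC.i1"),
    gene = c("nadA", "nadC"),
    trans = c(FALSE, TRUE),
    wt = config$splicing_wt,
    mutant = config$splicing_mut,
    stringsAsFactors = FALSE
  )

  # editing sites: genome positions whose gene-strand base is C, inside CDSs
  site_pool <- do.call(rbind, lapply(models, function(m) {
    coords <- cds_to_genome(m, seq_len(m$cds_length))
    strand_bases <- if (m$strand == "+") genome[coords] else comp[genome[coords]]
    data.frame(gene = m$gene, coord = coords, strand = m$strand,
               is_c = strand_bases == "C", stringsAsFactors = FALSE)
  }))
  site_pool <- site_pool[site_pool$is_c, , drop = FALSE]
  # keep editing sites clear of the planted binding site
  site_pool <- site_pool[!(site_pool$coord >= min(site_coords) &
                             site_pool$coord <= max(site_coords)), ]
  pick <- sort(sample(nrow(site_pool), config$n_editing_sites))
  editing <- site_pool[pick, c("gene", "coord", "strand")]
  editing$site <- paste0("ed", seq_len(nrow(editing)))
  editing$rate_wt <- round(stats::runif(nrow(editing), 0.5, 0.95), 3)
  editing$rate_mutant <- round(editing$rate_wt * config$editing_shift, 3)
  rownames(editing) <- NULL

  structure(
    list(genome = Biostrings::DNAString(paste(genome, collapse = "")),
         models = models,
         scaffold = scaffold,
         code = code,
         perfect_target = config$perfect_target,
         site = list(start = min(site_coords), end = max(site_coords),
                     strand = "-", mismatches = config$site_mismatches,
                     cds_start = site_cds[1L], cds_end = site_cds[2L],
                     rna = site_rna),
         boundary = list(genome_upstream = boundary_upstream,
                         genome_downstream = boundary_downstream,
                         cds_pos = boundary_cds, strand = "-"),
         abundance = abundance,
         natural_peaks = natural_peaks,
         splicing = introns,
         editing = editing,
         config = config),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic organelle transcriptome (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  genome ", length(x$genome), " nt, ", length(x$models), " genes\n",
      sep = "")
  cat("  binding site ", x$site$start, "..", x$site$end, " (-) with ",
      x$site$mismatches, " mismatch(es); cleavage between ",
      x$boundary$genome_downstream, " and ", x$boundary$genome_upstream,
      "\n", sep = "")
  invisible(x)
}

# NB draw with mean mu and dispersion phi (var = mu + phi mu^2);
# phi = 0 is the deterministic limit.
rnb <- function(n, mu, phi) {
  if (phi == 0) return(round(mu))
  stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# Expected per-position 5'-end mean on `strand` for one genotype.
expected_end_means <- function(truth, strand, genotype) {
  cfg <- truth$config
  L <- cfg$genome_length
  mu <- rep(0.1, L)  # low off-transcript noise floor
  for (m in truth$models) {
    if (m$strand != strand) next
    span <- range(m$tx_start, m$tx_end)
    mu[span[1L]:span[2L]] <- cfg$depth * truth$abundance[[m$gene]]
  }
  pk <- truth$natural_peaks[truth$natural_peaks$strand == strand, ,
                            drop = FALSE]
  for (i in seq_len(nrow(pk))) {
    g <- pk$gene[i]
    h <- cfg$peak_scale * cfg$depth * truth$abundance[[g]]
    if (pk$kind[i] == "trans_half_start") {
      frac <- truth$splicing[truth$splicing$trans, genotype][1L]
      h <- h * (1 + (1 - frac))  # unspliced precursor adds to the half start
    }
    mu[pk$coord[i]] <- mu[pk$coord[i]] + h
  }
  if (genotype == "mutant" && truth$boundary$strand == strand) {
    gene_depth <- cfg$depth * truth$abundance[["atpB"]]
    mu[truth$boundary$genome_downstream] <-
      mu[truth$boundary$genome_downstream] +
      cfg$cleaved_fraction * cfg$peak_scale * gene_depth
  }
  mu
}

#' Simulate replicate 5'-end count profiles
#'
#' Background 5'-end counts are proportional to transcript abundance with
#' negative-binomial replicate noise; natural peaks mark transcript starts
#' and the trans-spliced half-intron start; knockdown replicates add a point
#' mass of cleaved-fraction x gene depth at the boundary's downstream 5'
#' side.
#'
#' @param truth a [simulate_genome()] result.
#' @param strand strand to profile (default `"-"`, where the planted gene
#'   lies).
#' @param replicates replicates per genotype (defaults to the config value).
#' @param sam_dir if non-`NULL`, also write one SAM file per replicate and
#'   genotype into this directory (reads of length 30 whose 5' termini
#'   reproduce the counts exactly).
#' @param seed optional seed for this draw (recorded draws default to the
#'   current RNG state).
#' @return a list with `wt` and `mutant` ([end_profile()] objects),
#'   `expected` (list of per-position expected means), `sam_files` (or
#'   `NULL`) and `truth`.
#' @export
simulate_end_counts <- function(truth, strand = "-", replicates = NULL,
                                sam_dir = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  strand <- normalize_strand(strand)
  cfg <- truth$config
  replicates <- replicates %||% cfg$replicates
  L <- cfg$genome_length
  profiles <- list()
  expected <- list()
  sam_files <- if (is.null(sam_dir)) NULL else character(0)
  for (genotype in c("wt", "mutant")) {
    mu <- expected_end_means(truth, strand, genotype)
    counts <- vapply(seq_len(replicates), function(r) {
      rnb(L, mu, cfg$dispersion)
    }, numeric(L))
    colnames(counts) <- paste0(genotype, "_rep", seq_len(replicates))
    profiles[[genotype]] <- end_profile(counts, strand, genotype = genotype)
    expected[[genotype]] <- mu
    if (!is.null(sam_dir)) {
      for (r in seq_len(replicates)) {
        f <- file.path(sam_dir, paste0(genotype, "_rep", r, ".sam"))
        write_end_sam(counts[, r], strand, truth$genome, f)
        sam_files <- c(sam_files, f)
      }
    }
  }
  list(wt = profiles$wt, mutant = profiles$mutant, expected = expected,
       sam_files = sam_files, truth = truth)
}

#' Simulate intron junction and editing-site evidence
#'
#' Binomial draws at the planted per-genotype spliced fractions and editing
#' rates, per replicate.
#'
#' @param truth a [simulate_genome()] result.
#' @param depth junction/pileup read depth per replicate (default 200).
#' @param replicates replicates per genotype (defaults to the config value).
#' @param seed optional seed for this draw.
#' @return a list with `introns` (data frame: intron, trans, genotype,
#'   replicate, spliced, unspliced) and `editing` (data frame: site, coord,
#'   strand, genotype, replicate, edited, unedited).
#' @export
simulate_junctions_and_editing <- function(truth, depth = 200L,
                                           replicates = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  replicates <- replicates %||% cfg$replicates
  grid <- expand.grid(genotype = c("wt", "mutant"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  introns <- do.call(rbind, lapply(seq_len(nrow(truth$splicing)), function(i) {
    tr <- truth$splicing[i, ]
    spliced <- stats::rbinom(nrow(grid), depth,
                             ifelse(grid$genotype == "wt", tr$wt, tr$mutant))
    data.frame(intron = tr$intron, trans = tr$trans,
               genotype = grid$genotype, replicate = grid$replicate,
               spliced = spliced, unspliced = depth - spliced,
               stringsAsFactors = FALSE)
  }))
  editing <- do.call(rbind, lapply(seq_len(nrow(truth$editing)), function(i) {
    ed <- truth$editing[i, ]
    rate <- ifelse(grid$genotype == "wt", ed$rate_wt, ed$rate_mutant)
    edited <- stats::rbinom(nrow(grid), depth, rate)
    data.frame(site = ed$site, coord = ed$coord, strand = ed$strand,
               genotype = grid$genotype, replicate = grid$replicate,
               edited = edited, unedited = depth - edited,
               stringsAsFactors = FALSE)
  }))
  list(introns = introns, editing = editing)
}

#' Simulate circularized RT-PCR clones of the cleaved 3' fragment
#'
#' Each clone concatenates reference sequence up to a 3' end with reference
#' sequence from a 5' end onward, both on the gene's strand. 5' ends are
#' drawn around the planted boundary with a jitter distribution whose mode
#' is the boundary itself; 3' ends sit at the transcript 3' terminus with
#' occasional +/-1 jitter. Drawn ends are recorded after canonicalization of
#' the junction shift family, i.e. as the ends any exact mapper can recover.
#'
#' @param truth a [simulate_genome()] result.
#' @param n number of clones (default 36).
#' @param jitter5 named numeric vector of offset probabilities for the 5'
#'   end (names are transcript-frame offsets; positive = downstream).
#'   The default places 42% of clones exactly at the boundary.
#' @param jitter3 offset probabilities for the 3' end, same format
#'   (default: 80% exactly at the transcript terminus). Set either jitter to
#'   `c("0" = 1)` for noise-free clones.
#' @param arm_range range of arm lengths flanking the junction (default
#'   40..80 nt).
#' @param seed optional seed for this draw.
#' @return a list with `clones` (a named `DNAStringSet`) and `ends` (data
#'   frame of the recorded true end coordinates per clone).
#' @export
simulate_clones <- function(truth, n = 36L,
                            jitter5 = c("-3" = 0.03, "-2" = 0.07,
                                        "-1" = 0.12, "0" = 0.42, "1" = 0.18,
                                        "2" = 0.12, "3" = 0.06),
                            jitter3 = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                            arm_range = c(40L, 80L), seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (n < 1L) stop_input("n must be >= 1")
  model <- truth$models$atpB
  view <- strand_view(truth$genome, model$strand)
  letters_ <- strsplit(as.character(view$seq), "")[[1L]]
  coord_to_index <- function(coord) {
    if (model$strand == "+") coord else view$glen - coord + 1L
  }
  b5_idx <- coord_to_index(truth$boundary$genome_downstream)
  tx3_idx <- coord_to_index(model$tx_end)
  off5 <- as.integer(names(jitter5))
  off3 <- as.integer(names(jitter3))
  ends <- data.frame(clone = paste0("clone_", seq_len(n)),
                     end5 = NA_integer_, end3 = NA_integer_,
                     stringsAsFactors = FALSE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s5 <- b5_idx + off5[sample.int(length(off5), 1L, prob = jitter5)]
    e3 <- tx3_idx + off3[sample.int(length(off3), 1L, prob = jitter3)]
    can <- canonicalize_junction(view, e3, s5)
    a <- sample(seq.int(arm_range[1L], arm_range[2L]), 1L)
    b <- sample(seq.int(arm_range[1L], arm_range[2L]), 1L)
    seqs[i] <- paste0(
      paste(letters_[(can[["e3"]] - a + 1L):can[["e3"]]], collapse = ""),
      paste(letters_[can[["s5"]]:(can[["s5"]] + b - 1L)], collapse = ""))
    ends$end3[i] <- strand_index_to_coord(view, can[["e3"]])
    ends$end5[i] <- strand_index_to_coord(view, can[["s5"]])
  }
  clones <- Biostrings::DNAStringSet(seqs)
  names(clones) <- ends$clone
  list(clones = clones, ends = ends)
}
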