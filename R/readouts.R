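# Molecular and physiological readouts: splicing efficiency, C-to-U editing
# rates, adenylate energy charge, amino-acid family aggregation and the flux
# control coefficient.

#' Intron splicing efficiency from junction-spanning evidence
#'
#' Efficiency is defined as spliced / (spliced + unspliced) junction evidence
#' per replicate. Trans-spliced introns are handled identically once their
#' two half-junctions have been reduced to spliced/unspliced tallies.
#'
#' @param spliced,unspliced non-negative per-replicate junction read counts
#'   (same length).
#' @return numeric vector of efficiencies in `[0, 1]`; replicates with zero
#'   total coverage are returned as `NA` with a warning.
#' @export
splicing_efficiency <- function(spliced, unspliced) {
  if (length(spliced) != length(unspliced)) {
    stop_input("spliced and unspliced must have the same length")
  }
  if (any(spliced < 0, na.rm = TRUE) || any(unspliced < 0, na.rm = TRUE)) {
    stop_input("counts must be non-negative")
  }
  total <- spliced + unspliced
  eff <- ifelse(total > 0, spliced / total, NA_real_)
  if (anyNA(eff)) {
    warning(sum(is.na(eff)), " replicate(s) with zero junction coverage ",
            "returned as NA")
  }
  eff
}

#' One-tailed comparison of splicing efficiencies between genotypes
#'
#' Equal-variance two-sample t test on per-replicate efficiencies, one-tailed
#' in the direction "`b` less spliced than `a`" (e.g. `a` = wild type, `b` =
#' knockdown). When both efficiency vectors are constant and equal, the test
#' statistic is 0 and the one-tailed p-value is 0.5.
#'
#' @param eff_a,eff_b numeric vectors of per-replicate efficiencies (>= 2
#'   finite values each).
#' @return a list with `t` (statistic, positive when `b` < `a`), `p`
#'   (one-tailed p-value) and `df`.
#' @export
compare_splicing <- function(eff_a, eff_b) {
  eff_a <- eff_a[is.finite(eff_a)]
  eff_b <- eff_b[is.finite(eff_b)]
  if (length(eff_a) < 2L || length(eff_b) < 2L) {
    stop_input("at least two finite replicate efficiencies per genotype")
  }
  df <- length(eff_a) + length(eff_b) - 2L
  if (stats::sd(eff_a) == 0 && stats::sd(eff_b) == 0) {
    d <- mean(eff_a) - mean(eff_b)
    t <- if (d == 0) 0 else sign(d) * Inf
  } else {
    t <- unname(stats::t.test(eff_a, eff_b, var.equal = TRUE,
                              alternative = "greater")$statistic)
  }
  list(t = t, p = stats::pt(t, df, lower.tail = FALSE), df = df)
}

#' Per-intron splicing comparison over an evidence table
#'
#' @param evidence data frame with columns `intron`, `genotype`, `replicate`,
#'   `spliced`, `unspliced` (e.g. from [simulate_junctions_and_editing()] or
#'   [read_intron_evidence()]).
#' @param ref,alt genotype labels; the one-tailed alternative is `alt` less
#'   spliced than `ref`.
#' @return a data frame with one row per intron: mean efficiencies, `t`, `p`.
#' @export
compare_splicing_table <- function(evidence, ref, alt) {
  required <- c("intron", "genotype", "replicate", "spliced", "unspliced")
  missing_cols <- setdiff(required, names(evidence))
  if (length(missing_cols) > 0L) {
    stop_input("intron evidence is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  introns <- sort(unique(evidence$intron))
  rows <- lapply(introns, function(id) {
    ev <- evidence[evidence$intron == id, , drop = FALSE]
    ea <- with(ev[ev$genotype == ref, ], splicing_efficiency(spliced, unspliced))
    eb <- with(ev[ev$genotype == alt, ], splicing_efficiency(spliced, unspliced))
    cmp <- compare_splicing(ea, eb)
    data.frame(intron = id, eff_ref = mean(ea, na.rm = TRUE),
               eff_alt = mean(eb, na.rm = TRUE), t = cmp$t, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' C-to-U editing rate
#'
#' @param edited,unedited non-negative per-replicate read counts at an
#'   editing site (edited = U/T reads, unedited = C reads).
#' @return numeric vector of rates in `[0, 1]`; zero-coverage replicates are
#'   `NA` with a warning.
#' @export
editing_rate <- function(edited, unedited) {
  splicing_efficiency(edited, unedited)
}

#' Relative editing rate between genotypes
#'
#' @param rates_mutant,rates_wt per-replicate editing rates at a site.
#' @return `mean(rates_mutant) / mean(rates_wt)`.
#' @export
relative_editing_rate <- function(rates_mutant, rates_wt) {
  mw <- mean(rates_wt, na.rm = TRUE)
  if (!is.finite(mw) || mw == 0) stop_input("wild-type mean rate must be > 0")
  mean(rates_mutant, na.rm = TRUE) / mw
}

#' Adenylate energy charge
#'
#' `(ATP + 0.5 * ADP) / (ATP + ADP + AMP)`, a bounded index of cellular
#' energy status (1 = all ATP, 0 = all AMP). Invariant to rescaling all three
#' pools by a common factor.
#'
#' @param atp,adp,amp pool concentrations in a common arbitrary unit, all
#'   >= 0 and not all zero.
#' @return energy charge in `[0, 1]`.
#' @export
energy_charge <- function(atp, adp, amp) {
  for (v in c("atp", "adp", "amp")) assert_scalar_number(get(v), v)
  if (atp < 0 || adp < 0 || amp < 0) stop_input("pools must be non-negative")
  total <- atp + adp + amp
  if (total == 0) stop_input("all adenylate pools are zero")
  (atp + 0.5 * adp) / total
}

#' ATP/ADP ratio
#'
#' @param atp,adp pool concentrations; `adp` must be > 0.
#' @return `atp / adp`.
#' @export
atp_adp_ratio <- function(atp, adp) {
  assert_scalar_number(atp, "atp")
  assert_scalar_number(adp, "adp")
  if (adp <= 0) stop_input("adp must be > 0")
  atp / adp
}

#' Aggregate amino-acid concentrations into synthesis-pathway families
#'
#' @param concentrations named numeric vector of amino-acid concentrations.
#' @param families named list mapping family name to the amino acids it
#'   contains; the families must partition the measured amino acids.
#' @return a list with `totals` (per-family sums), `fractions` (per-family
#'   share of the total, summing to 1) and `gly_ser_ratio` (when both Gly and
#'   Ser are measured, else `NA`).
#' @export
family_totals <- function(concentrations, families) {
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    stop_input("concentrations must be a named vector")
  }
  map <- unlist(lapply(names(families), function(f) {
    stats::setNames(rep(f, length(families[[f]])), families[[f]])
  }))
  if (anyDuplicated(names(map))) {
    stop_input("families must not overlap: ",
               paste(names(map)[duplicated(names(map))], collapse = ", "))
  }
  missing_aa <- setdiff(names(concentrations), names(map))
  if (length(missing_aa) > 0L) {
    stop_input("amino acid(s) missing from the family map: ",
               paste(missing_aa, collapse = ", "))
  }
  fam <- map[names(concentrations)]
  totals <- tapply(concentrations, fam, sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  has_gs <- all(c("Gly", "Ser") %in% names(concentrations))
  list(totals = totals,
       fractions = totals / sum(totals),
       gly_ser_ratio = if (has_gs) {
         unname(concentrations[["Gly"]] / concentrations[["Ser"]])
       } else NA_real_)
}

#' Flux control coefficient from a knockdown
#'
#' Estimates the control coefficient of an enzyme on a pathway flux from a
#' single knockdown as `ln(flux fraction remaining) / ln(enzyme fraction
#' remaining)` (the log-ratio finite-difference form of the scaled
#' sensitivity d ln J / d ln E). A value near 1 means proportional control,
#' near 0 no control.
#'
#' @param flux_fraction_remaining,enzyme_fraction_remaining fractions of the
#'   wild-type flux and enzyme abundance remaining in the knockdown, both in
#'   `(0, 1]`; the enzyme fraction must be < 1 unless the flux fraction is
#'   also 1.
#' @return the estimated control coefficient.
#' @export
control_coefficient <- function(flux_fraction_remaining,
                                enzyme_fraction_remaining) {
  assert_scalar_number(flux_fraction_remaining, "flux_fraction_remaining")
  assert_scalar_number(enzyme_fraction_remaining, "enzyme_fraction_remaining")
  if (flux_fraction_remaining <= 0 || flux_fraction_remaining > 1 ||
      enzyme_fraction_remaining <= 0 || enzyme_fraction_remaining > 1) {
    stop_input("fractions must lie in (0, 1]")
  }
  if (enzyme_fraction_remaining == 1) {
    if (flux_fraction_remaining == 1) return(1.0)
    stop_input("enzyme fraction of 1 is no perturbation; coefficient undefined")
  }
  log(flux_fraction_remaining) / log(enzyme_fraction_remaining)
}
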