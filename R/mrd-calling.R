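## Consensus-and-polishing MRD caller: single-strand consensus (SSCS) from
## UMI read families, duplex consensus (DCS) from transposed-UMI SSCS pairs,
## background-error polishing by one-sided exact binomial test, tissue
## mutation thresholds and the tumor-informed ctDNA positivity rule.
##
## Read families arrive as long tables, one row per read:
##   contig, pos (1-based), umiA, umiB, orientation ("AB"/"BA"),
##   read_idx, allele.
## A family is the set of rows sharing (contig, pos, umiA, umiB, orientation).

#' @import data.table
NULL

utils::globalVariables(c(
  ".", "allele", "contig", "pos", "umiA", "umiB", "orientation", "n_reads",
  "support", "level", "key_lo", "key_hi", "n_strands", "single_strand",
  "mutant", "depth", "n_duplex", "vaf", "rate", "polish_p", "pass",
  "hotspot", "cosmic_count", "N", "alt", "ref", "max_support", "n_samples",
  "mean_vaf", "patient", "day", "family_size", "read_idx", "detected"
))

#' Build single-strand consensus reads (SSCS)
#'
#' Groups reads by (contig, pos, UMI pair, strand orientation) and emits one
#' consensus read per family supported by at least two reads; the consensus
#' base is the within-family majority, ties are masked as "N", and singleton
#' families are dropped.
#'
#' @param families data.frame of reads with columns \code{contig},
#'   \code{pos}, \code{umiA}, \code{umiB}, \code{orientation},
#'   \code{read_idx}, \code{allele}; an optional \code{family_id} column is
#'   checked for structural consistency (a family must not span positions).
#' @param min_reads minimum reads per family (default 2).
#' @return data.frame of SSCS reads: family keys plus \code{level} ("SSCS"),
#'   \code{allele}, \code{support}.
#' @export
build_sscs <- function(families, min_reads = 2) {
  dt <- as.data.table(families)
  req <- c("contig", "pos", "umiA", "umiB", "orientation", "allele")
  if (!all(req %in% names(dt)))
    stop("missing read-family columns: ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  if ("family_id" %in% names(dt)) {
    bad <- dt[, uniqueN(paste(contig, pos, umiA, umiB, orientation)),
              by = "family_id"][V1 > 1]
    if (nrow(bad) > 0)
      stop("structural error: family/ies spanning multiple positions or UMI ",
           "pairs: ", paste(head(bad$family_id), collapse = ", "))
  }
  keys <- c("contig", "pos", "umiA", "umiB", "orientation")
  cnt <- dt[, .N, by = c(keys, "allele")]
  cnt[, support := sum(N), by = keys]
  cnt <- cnt[support >= min_reads]
  ## majority vote; ties mask the base
  cons <- cnt[, {
    top <- max(N)
    winners <- allele[N == top]
    .(allele = if (length(winners) > 1) "N" else winners,
      support = support[1])
  }, by = keys]
  cons[, level := "SSCS"]
  setDF(cons)
  cons
}

#' Build duplex consensus reads (DCS)
#'
#' Merges SSCS pairs with transposed UMI pairs (umiA/umiB swapped) at the
#' same mapping position into one duplex consensus whenever possible; loci
#' where the two strands disagree are masked as "N". Unpartnered SSCS are
#' retained and flagged single-strand. More than two SSCS claiming one
#' duplex is a structural error.
#'
#' @param sscs output of [build_sscs()].
#' @return data.frame of consensus reads with \code{level} ("DCS" or
#'   "SSCS"), \code{allele}, \code{support} (total reads across strands),
#'   \code{n_strands} and \code{single_strand}.
#' @export
build_dcs <- function(sscs) {
  dt <- as.data.table(sscs)
  if (nrow(dt) == 0 || any(dt$level != "SSCS"))
    stopifnot(all(dt$level == "SSCS"))
  dt[, key_lo := pmin(umiA, umiB)]
  dt[, key_hi := pmax(umiA, umiB)]
  keys <- c("contig", "pos", "key_lo", "key_hi")
  sizes <- dt[, .N, by = keys]
  if (any(sizes$N > 2))
    stop("structural error: more than two SSCS claim the same duplex")
  out <- dt[, {
    if (.N == 2) {
      .(umiA = umiA[1], umiB = umiB[1], orientation = orientation[1],
        level = "DCS",
        allele = if (allele[1] == allele[2]) allele[1] else "N",
        support = sum(support), n_strands = 2L, single_strand = FALSE)
    } else {
      .(umiA = umiA[1], umiB = umiB[1], orientation = orientation[1],
        level = "SSCS", allele = allele[1],
        support = support[1], n_strands = 1L, single_strand = TRUE)
    }
  }, by = keys]
  out[, c("key_lo", "key_hi") := NULL]
  setDF(out)
  out
}

#' Tally consensus reads into per-position variant candidates
#'
#' Counts unique consensus reads (DCS and unpartnered SSCS each count once)
#' per position and emits one candidate per non-reference allele with its
#' consensus depth, mutant read count, duplex-confirmed mutant count and
#' VAF. Masked bases ("N") contribute to depth but never to a candidate.
#'
#' @param consensus output of [build_dcs()] (or [build_sscs()]).
#' @param ref_alleles data.frame with \code{contig}, \code{pos}, \code{ref}.
#' @return data.frame of candidates: \code{contig}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{mutant}, \code{n_duplex}, \code{vaf}.
#' @export
consensus_candidates <- function(consensus, ref_alleles) {
  dt <- as.data.table(consensus)
  if (!"level" %in% names(dt)) dt[, level := "SSCS"]
  rf <- as.data.table(ref_alleles)
  dt <- merge(dt, rf[, .(contig, pos, ref)], by = c("contig", "pos"))
  dep <- dt[, .(depth = .N), by = .(contig, pos, ref)]
  muts <- dt[allele != ref & allele != "N",
             .(mutant = .N, n_duplex = sum(level == "DCS")),
             by = .(contig, pos, ref, allele)]
  setnames(muts, "allele", "alt")
  out <- merge(muts, dep, by = c("contig", "pos", "ref"))
  out[, vaf := mutant / depth]
  setDF(out)
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

#' Build a background error database from mutation-free samples
#'
#' Pools variant candidates tallied from plasma of individuals without
#' tumors and estimates, per (position, substitution), the background error
#' allele fraction and the largest distinct-supporting-read count observed.
#' Cells never observed in error get the floor rate.
#'
#' @param candidate_list list of [consensus_candidates()] tables, one per
#'   background sample.
#' @param depth_list list of per-position depth tables (\code{contig},
#'   \code{pos}, \code{depth}), matching \code{candidate_list}.
#' @param rate_floor minimum rate for any cell (default 1e-6).
#' @return data.frame: \code{contig}, \code{pos}, \code{ref}, \code{alt},
#'   \code{rate}, \code{max_support}, \code{n_samples}.
#' @export
build_background_db <- function(candidate_list, depth_list,
                                rate_floor = 1e-6) {
  stopifnot(length(candidate_list) == length(depth_list))
  cand <- rbindlist(lapply(candidate_list, as.data.table))
  deps <- rbindlist(lapply(depth_list, as.data.table))
  totdep <- deps[, .(total_depth = sum(depth)), by = .(contig, pos)]
  if (nrow(cand) == 0) return(data.frame())
  agg <- cand[, .(total_mutant = sum(mutant), max_support = max(mutant),
                  n_samples = .N),
              by = .(contig, pos, ref, alt)]
  agg <- merge(agg, totdep, by = c("contig", "pos"))
  agg[, rate := pmax(total_mutant / total_depth, rate_floor)]
  out <- agg[, .(contig, pos, ref, alt, rate, max_support, n_samples)]
  setDF(out)
  out
}

#' Polish variant candidates against the background error database
#'
#' One-sided exact binomial test of (mutant consensus reads, consensus
#' depth) against the database error rate for the candidate's position and
#' substitution. A candidate is retained when the tail probability is at or
#' below \code{alpha} and its distinct supporting reads meet the minimum of
#' one duplex-confirmed read or two SSCS reads. Candidates at positions
#' absent from the database are tested against the floor rate with a
#' warning.
#'
#' @param candidates [consensus_candidates()] table.
#' @param db [build_background_db()] table.
#' @param alpha one-sided significance level (default 0.01).
#' @param rate_floor rate for (position, substitution) cells missing from
#'   the database.
#' @return the candidates with \code{rate}, \code{polish_p} and logical
#'   \code{pass} columns added.
#' @export
polish_variants <- function(candidates, db, alpha = 0.01, rate_floor = 1e-6) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0) {
    cand[, c("rate", "polish_p", "pass") := list(numeric(), numeric(), logical())]
    return(setDF(cand))
  }
  dbt <- as.data.table(db)
  if (nrow(dbt) > 0) {
    cand <- merge(cand, dbt[, .(contig, pos, ref, alt, rate)],
                  by = c("contig", "pos", "ref", "alt"), all.x = TRUE)
  } else cand[, rate := NA_real_]
  n_missing <- sum(is.na(cand$rate))
  if (n_missing > 0) {
    warning(n_missing, " candidate(s) at positions absent from the ",
            "background database; floor rate ", rate_floor, " applied")
    cand[is.na(rate), rate := rate_floor]
  }
  cand[, polish_p := pbinom(mutant - 1, depth, rate, lower.tail = FALSE)]
  cand[, pass := mutant >= 1 & polish_p <= alpha & (n_duplex >= 1 | mutant >= 2)]
  setDF(cand)
  cand
}

#' Tissue somatic mutation thresholds for the tumor profile
#'
#' Retains tissue variants by the tumor-informed tracking rule: hotspot
#' mutations (20 or more COSMIC cancer cases) need VAF of at least 1\% and
#' at least 5 supporting reads; all other mutations need VAF of at least
#' 2\% and at least 6 supporting reads. Variants present in the matched
#' normal (germline / clonal hematopoiesis) are subtracted first.
#'
#' @param tissue_variants data.frame with \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}, \code{vaf}, \code{support} and optionally
#'   \code{cosmic_count}.
#' @param patient patient identifier stored on the profile.
#' @param matched_normal optional data.frame of variants (\code{contig},
#'   \code{pos}, \code{ref}, \code{alt}) to subtract.
#' @return object of class \code{tumor_profile}: list with \code{patient}
#'   and the retained \code{mutations} (with \code{hotspot} flag).
#' @export
call_tissue_mutations <- function(tissue_variants, patient = NA_character_,
                                  matched_normal = NULL) {
  tv <- as.data.table(tissue_variants)
  if (!"cosmic_count" %in% names(tv)) {
    message("no COSMIC annotation supplied; all variants treated as non-hotspot")
    tv[, cosmic_count := 0L]
  }
  if (anyNA(tv$cosmic_count)) {
    message(sum(is.na(tv$cosmic_count)),
            " variant(s) without COSMIC annotation treated as non-hotspot")
    tv[is.na(cosmic_count), cosmic_count := 0L]
  }
  if (!is.null(matched_normal) && nrow(matched_normal) > 0) {
    mn <- as.data.table(matched_normal)
    tv <- tv[!mn, on = c("contig", "pos", "ref", "alt")]
  }
  tv[, hotspot := cosmic_count >= 20]
  keep <- tv[(hotspot & vaf >= 0.01 & support >= 5) |
               (!hotspot & vaf >= 0.02 & support >= 6)]
  setDF(keep)
  structure(list(patient = patient, mutations = keep),
            class = "tumor_profile")
}

#' Tumor-informed ctDNA positivity for one plasma sample
#'
#' A sample is ctDNA positive when at least one tumor-profile mutation is
#' present in plasma with a minimum of one unique consensus mutant read and
#' passes the polishing criteria. \code{mean_vaf} averages the VAF over the
#' tracked mutation set used for calling -- by default over all profile
#' mutations, counting undetected ones as zero (set
#' \code{mean_mode = "detected"} to average over detected mutations only);
#' \code{max_vaf} is the maximum over detected mutations (0 when negative).
#'
#' @param plasma_calls polished candidates ([polish_variants()] output).
#' @param profile a [call_tissue_mutations()] tumor profile.
#' @param day draw day relative to surgery (carried through).
#' @param mean_mode "tracked" (default) or "detected".
#' @return object of class \code{plasma_call_result}: \code{patient},
#'   \code{day}, \code{positive}, \code{mean_vaf}, \code{max_vaf},
#'   \code{detected} (data.frame), \code{n_tracked}, \code{unevaluable}.
#' @export
assess_ctdna_positivity <- function(plasma_calls, profile, day = NA_real_,
                                    mean_mode = c("tracked", "detected")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(inherits(profile, "tumor_profile"))
  if (nrow(profile$mutations) == 0) {
    warning("empty tumor profile for patient ", profile$patient,
            ": sample unevaluable (excluded from MRD analysis)")
    return(structure(list(patient = profile$patient, day = day,
                          positive = NA, mean_vaf = NA_real_,
                          max_vaf = NA_real_,
                          detected = data.frame(), n_tracked = 0L,
                          unevaluable = TRUE),
                     class = "plasma_call_result"))
  }
  prof <- as.data.table(profile$mutations)[, .(contig, pos, ref, alt)]
  calls <- as.data.table(plasma_calls)
  if (nrow(calls) > 0) {
    m <- merge(prof, calls, by = c("contig", "pos", "ref", "alt"),
               all.x = TRUE)
  } else {
    m <- copy(prof)
    m[, c("mutant", "vaf", "pass") := list(0L, 0, FALSE)]
  }
  m[is.na(mutant), mutant := 0L]
  m[is.na(vaf), vaf := 0]
  m[is.na(pass), pass := FALSE]
  m[, detected := mutant >= 1 & pass]
  m[detected == FALSE, vaf := 0]  # undetected tracked mutations count as 0
  positive <- any(m$detected)
  mean_vaf <- if (mean_mode == "tracked") mean(m$vaf)
              else if (positive) mean(m$vaf[m$detected]) else 0
  max_vaf <- if (positive) max(m$vaf[m$detected]) else 0
  setDF(m)
  structure(list(patient = profile$patient, day = day, positive = positive,
                 mean_vaf = mean_vaf, max_vaf = max_vaf,
                 detected = m[m$detected, , drop = FALSE],
                 n_tracked = nrow(prof), unevaluable = FALSE),
            class = "plasma_call_result")
}

#' Log ctDNA level transform
#'
#' \eqn{\ln(\mathrm{mean\,VAF} + 10^{-6}) - \ln 10^{-6}}: the longitudinal
#' response used by the joint model. Zero VAF maps to exactly 0.
#'
#' @param mean_vaf VAF as a fraction in [0, 1].
#' @return non-negative log ctDNA level.
#' @export
log_ctdna_level <- function(mean_vaf) {
  if (any(mean_vaf < 0, na.rm = TRUE)) stop("mean_vaf must be non-negative")
  if (any(mean_vaf > 1, na.rm = TRUE)) stop("mean_vaf is a fraction in [0, 1]")
  log1p(mean_vaf * 1e6)
}

#' Inverse of the log ctDNA level transform
#'
#' @param level log ctDNA level (non-negative).
#' @return mean VAF fraction.
#' @export
mean_vaf_from_level <- function(level) expm1(level) * 1e-6

#' Full MRD call for one plasma sample
#'
#' Convenience wrapper: read families to SSCS to DCS to candidates,
#' polishing against the background database, then the tumor-informed
#' positivity rule.
#'
#' @param families read-family table (see [build_sscs()]).
#' @param profile [call_tissue_mutations()] tumor profile.
#' @param db background error database.
#' @param ref_alleles per-position reference alleles.
#' @param alpha polishing significance level.
#' @param day draw day relative to surgery.
#' @return a \code{plasma_call_result}.
#' @export
mrd_call_sample <- function(families, profile, db, ref_alleles,
                            alpha = 0.01, day = NA_real_) {
  cons <- build_dcs(build_sscs(families))
  cand <- consensus_candidates(cons, ref_alleles)
  polished <- polish_variants(cand, db, alpha = alpha)
  assess_ctdna_positivity(polished, profile, day = day)
}

#' @export
print.plasma_call_result <- function(x, ...) {
  cat("plasma MRD call: patient", x$patient, "day", x$day, "\n")
  if (isTRUE(x$unevaluable)) cat("  unevaluable (empty tumor profile)\n")
  else cat("  positive:", x$positive, " mean VAF:", signif(x$mean_vaf, 4),
           " max VAF:", signif(x$max_vaf, 4), "\n")
  invisible(x)
}
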