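test_that("SSCS construction: support threshold, majority vote, ties", {
  # family of two identical reads -> one SSCS
  f <- fam_rows(pos = 100, umiA = "a1", umiB = "b1", orientation = "AB",
                alleles = c("T", "T"))
  s <- build_sscs(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$allele, "T")
  expect_equal(s$support, 2)
  # singleton family -> dropped
  f1 <- fam_rows(pos = 100, umiA = "a2", umiB = "b2", orientation = "AB",
                 alleles = "T")
  expect_equal(nrow(build_sscs(rbind(f, f1))), 1)
  # family of five with one substitution -> majority base wins
  f5 <- fam_rows(pos = 7, umiA = "a3", umiB = "b3", orientation = "AB",
                 alleles = c("A", "A", "T", "A", "A"))
  expect_equal(build_sscs(f5)$allele, "A")
  # 2 vs 2 tie -> masked as N
  ftie <- fam_rows(pos = 7, umiA = "a4", umiB = "b4", orientation = "AB",
                   alleles = c("A", "A", "T", "T"))
  expect_equal(build_sscs(ftie)$allele, "N")
  # a family_id spanning two positions is a structural error
  bad <- rbind(cbind(fam_rows(pos = 1, umiA = "x", umiB = "y",
                              orientation = "AB", alleles = c("A", "A")),
                     family_id = 1),
               cbind(fam_rows(pos = 2, umiA = "x", umiB = "y",
                              orientation = "AB", alleles = c("A", "A")),
                     family_id = 1))
  expect_error(build_sscs(bad), "structural error")
})

test_that("DCS merging: transposed UMI pairs only, masking, errors", {
  mk_sscs <- function(umiA, umiB, orientation, allele, pos = 50)
    build_sscs(fam_rows(pos = pos, umiA = umiA, umiB = umiB,
                        orientation = orientation,
                        alleles = rep(allele, 3)))
  a <- mk_sscs("u1", "u2", "AB", "T")
  b <- mk_sscs("u2", "u1", "BA", "T")
  d <- build_dcs(rbind(a, b))
  expect_equal(nrow(d), 1)
  expect_equal(d$level, "DCS")
  expect_equal(d$allele, "T")
  expect_equal(d$n_strands, 2L)
  # merging is symmetric in input order
  d2 <- build_dcs(rbind(b, a))
  expect_equal(d$allele, d2$allele)
  expect_equal(d$level, d2$level)
  # unpartnered SSCS retained and flagged single-strand
  c1 <- mk_sscs("u5", "u6", "AB", "G")
  d3 <- build_dcs(rbind(a, b, c1))
  expect_equal(sort(d3$level), c("DCS", "SSCS"))
  expect_true(d3$single_strand[d3$level == "SSCS"])
  # strand disagreement -> locus masked as N
  e1 <- mk_sscs("u7", "u8", "AB", "T")
  e2 <- mk_sscs("u8", "u7", "BA", "C")
  d4 <- build_dcs(rbind(e1, e2))
  expect_equal(d4$allele, "N")
  expect_equal(d4$level, "DCS")
  # more than two SSCS claiming one duplex -> structural error
  tri <- rbind(mk_sscs("u9", "u9b", "AB", "T"),
               mk_sscs("u9b", "u9", "BA", "T"),
               mk_sscs("u9", "u9b", "AB", "T"))
  tri$orientation[3] <- "BA"   # force a third distinct SSCS on the duplex
  expect_error(build_dcs(tri), "structural error")
  # DCS count <= SSCS count / 2 + unpartnered count
  expect_lte(sum(d3$level == "DCS"), 3 / 2)
})

test_that("polishing: exact binomial against the background db", {
  cand <- data.frame(contig = "chr1", pos = c(1, 2, 3), ref = "A",
                     alt = "T", depth = c(30000, 30000, 10000),
                     mutant = c(0, 30, 100), n_duplex = c(0, 5, 10))
  cand$vaf <- cand$mutant / cand$depth
  db <- rbind(db_row(1), db_row(2), db_row(3, rate = 0.01))
  out <- polish_variants(cand, db, alpha = 0.01)
  # zero mutant reads -> never retained
  expect_false(out$pass[out$pos == 1])
  expect_equal(out$polish_p[out$pos == 1], 1)
  # 30 / 30000 against rate 1e-5: binomial tail far below alpha (oracle)
  p_oracle <- 1 - pbinom(29, 30000, 1e-5)
  expect_equal(out$polish_p[out$pos == 2], p_oracle)
  expect_lt(p_oracle, 1e-10)
  expect_true(out$pass[out$pos == 2])
  # mutant fraction equal to the db rate -> tail ~ 0.5, rejected
  expect_gt(out$polish_p[out$pos == 3], 0.4)
  expect_false(out$pass[out$pos == 3])
  # missing db entry -> floor rate with warning
  cand2 <- data.frame(contig = "chr1", pos = 99, ref = "A", alt = "G",
                      depth = 20000, mutant = 4, n_duplex = 2, vaf = 2e-4)
  expect_warning(out2 <- polish_variants(cand2, db, alpha = 0.01),
                 "absent from")
  expect_equal(out2$rate, 1e-6)
  expect_true(out2$pass)
  # supporting-read rule: a single non-duplex mutant read never passes
  cand3 <- data.frame(contig = "chr1", pos = 1, ref = "A", alt = "T",
                      depth = 30000, mutant = 1, n_duplex = 0, vaf = 1/30000)
  expect_false(polish_variants(cand3, db, alpha = 0.01)$pass)
})

test_that("tissue mutation thresholds follow the tracking rule", {
  tv <- data.frame(
    contig = "chr17", pos = c(1, 2, 3, 4, 5),
    ref = "C", alt = "T",
    vaf = c(0.012, 0.015, 0, 0.025, 0.012),
    support = c(6, 6, 10, 7, 4),
    cosmic_count = c(25, 3, 50, 0, 30))
  prof <- call_tissue_mutations(tv, patient = "P1")
  # hotspot at VAF 1.2% with 6 reads -> retained
  expect_true(1 %in% prof$mutations$pos)
  # non-hotspot at VAF 1.5% -> rejected (below 2%)
  expect_false(2 %in% prof$mutations$pos)
  # zero VAF -> rejected
  expect_false(3 %in% prof$mutations$pos)
  # non-hotspot at 2.5% with 7 reads -> retained
  expect_true(4 %in% prof$mutations$pos)
  # hotspot with only 4 supporting reads -> rejected
  expect_false(5 %in% prof$mutations$pos)
  # matched-normal subtraction removes germline/CH variants
  prof2 <- call_tissue_mutations(tv, patient = "P1",
                                 matched_normal = data.frame(
                                   contig = "chr17", pos = 1, ref = "C",
                                   alt = "T"))
  expect_false(1 %in% prof2$mutations$pos)
  # missing COSMIC annotation -> treated as non-hotspot (logged)
  expect_message(p3 <- call_tissue_mutations(tv[, names(tv) != "cosmic_count"],
                                             patient = "P1"),
                 "non-hotspot")
  expect_false(1 %in% p3$mutations$pos)  # 1.2% fails the 2% non-hotspot bar
})

test_that("positivity rule and per-sample VAF summaries", {
  prof <- call_tissue_mutations(data.frame(
    contig = "chr1", pos = c(10, 20), ref = "A", alt = "T",
    vaf = c(0.05, 0.08), support = c(10, 12), cosmic_count = c(30, 0)),
    patient = "P7")
  mkcall <- function(pos, mutant, depth, pass) data.frame(
    contig = "chr1", pos = pos, ref = "A", alt = "T", depth = depth,
    mutant = mutant, n_duplex = mutant, vaf = mutant / depth,
    rate = 1e-6, polish_p = ifelse(pass, 1e-9, 0.5), pass = pass)
  # one profile mutation with a single passing consensus read -> positive
  r <- assess_ctdna_positivity(mkcall(10, 1, 10000, TRUE), prof, day = 14)
  expect_true(r$positive)
  expect_equal(r$mean_vaf, (1 / 10000 + 0) / 2)  # tracked mode: zeros count
  expect_equal(r$max_vaf, 1 / 10000)
  # nothing detected -> negative, mean over tracked set with zeros
  r0 <- assess_ctdna_positivity(mkcall(10, 0, 10000, FALSE), prof)
  expect_false(r0$positive)
  expect_equal(r0$mean_vaf, 0)
  expect_equal(r0$max_vaf, 0)
  # two detected at 0.2% and 0.4% -> mean 0.3%, max 0.4%
  r2 <- assess_ctdna_positivity(
    rbind(mkcall(10, 20, 10000, TRUE), mkcall(20, 40, 10000, TRUE)), prof)
  expect_equal(r2$mean_vaf, 0.003)
  expect_equal(r2$max_vaf, 0.004)
  # detected-only averaging mode
  r3 <- assess_ctdna_positivity(mkcall(10, 20, 10000, TRUE), prof,
                                mean_mode = "detected")
  expect_equal(r3$mean_vaf, 0.002)
  # order of input variants is irrelevant
  r4 <- assess_ctdna_positivity(
    rbind(mkcall(20, 40, 10000, TRUE), mkcall(10, 20, 10000, TRUE)), prof)
  expect_equal(r4$mean_vaf, r2$mean_vaf)
  # a failed-polish call never drives positivity
  r5 <- assess_ctdna_positivity(mkcall(10, 5, 10000, FALSE), prof)
  expect_false(r5$positive)
  # empty tumor profile -> unevaluable with warning
  empty <- call_tissue_mutations(data.frame(
    contig = "chr1", pos = 1, ref = "A", alt = "T", vaf = 0, support = 0,
    cosmic_count = 0), patient = "P0")
  expect_warning(ru <- assess_ctdna_positivity(mkcall(10, 1, 100, TRUE),
                                               empty), "unevaluable")
  expect_true(ru$unevaluable)
  expect_true(is.na(ru$positive))
})

test_that("log ctDNA level transform and its inverse", {
  expect_equal(log_ctdna_level(0), 0)
  expect_equal(log_ctdna_level(1e-6), log(2))
  # 0.34% as a fraction: ln((0.0034 + 1e-6)/1e-6)
  expect_equal(log_ctdna_level(0.0034), log(0.003401) - log(1e-6))
  expect_equal(log_ctdna_level(0.0034), 8.132, tolerance = 1e-3)
  expect_error(log_ctdna_level(-0.1), "non-negative")
  v <- c(0, 1e-6, 1e-4, 0.05)
  expect_equal(mean_vaf_from_level(log_ctdna_level(v)), v, tolerance = 1e-12)
})

test_that("read-family simulator: error-free, binomial sampling, errors", {
  # error_rate = 0: every read carries its family's true allele
  rf <- simulate_read_families(truth_vaf = 0.3, depth = 200,
                               error_rate = 0, seed = 1)
  cons <- build_dcs(build_sscs(rf$reads))
  expect_true(all(cons$allele %in% c("A", "T")))
  expect_true(all(rf$reads$allele %in% c("A", "T")))
  # truth 0.5 at depth 10000: family-level fraction within 3 binomial SD
  rf2 <- simulate_read_families(truth_vaf = 0.5, depth = 10000,
                                error_rate = 0, duplex_prob = 0,
                                reads_per_family = list(dist = "fixed",
                                                        mean = 2),
                                seed = 2)
  frac <- mean(rf2$reads$allele[!duplicated(paste(rf2$reads$umiA,
                                                  rf2$reads$umiB))] == "T")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # truth 0: per-read mismatch rate within 3 SD of the error rate
  rf3 <- simulate_read_families(truth_vaf = 0, depth = 20000,
                                error_rate = 1e-3,
                                reads_per_family = list(dist = "fixed",
                                                        mean = 2),
                                duplex_prob = 0, seed = 3)
  nr <- nrow(rf3$reads)
  mm <- mean(rf3$reads$allele != "A")
  expect_lt(abs(mm - 1e-3), 3 * sqrt(1e-3 / nr))
  # parameter validation
  expect_error(simulate_read_families(1.5, 10), "truth_vaf")
  expect_error(simulate_read_families(0.1, 10, error_rate = 0.5),
               "error_rate")
})

test_that("end-to-end sample call detects a spiked variant", {
  # background db from clean plasma
  bg <- simulate_read_families(truth_vaf = rep(0, 30), depth = 400,
                               error_rate = 1e-3, seed = 10)
  cons_bg <- build_dcs(build_sscs(bg$reads))
  cand_bg <- consensus_candidates(cons_bg, bg$ref_alleles)
  dep_bg <- aggregate(list(depth = cons_bg$pos), by = list(
    contig = cons_bg$contig, pos = cons_bg$pos), FUN = length)
  db <- build_background_db(list(cand_bg), list(dep_bg))
  prof <- call_tissue_mutations(data.frame(
    contig = "chr1", pos = 5, ref = "A", alt = "T", vaf = 0.2,
    support = 50, cosmic_count = 100), patient = "P9")
  # plasma with the tracked mutation at VAF 1%
  pl <- simulate_read_families(truth_vaf = c(rep(0, 4), 0.01, rep(0, 25)),
                               depth = 2000, error_rate = 1e-3, seed = 11)
  res <- mrd_call_sample(pl$reads, prof, db, pl$ref_alleles, day = 91)
  expect_true(res$positive)
  expect_gt(res$mean_vaf, 0.003)
  expect_lt(res$mean_vaf, 0.03)
})
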