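test_that("PWM construction validates and normalizes", {
  m <- matrix(c(8, 1, 1, 0), 1, 4)
  p <- pwm("toy", m)
  expect_equal(rowSums(p$matrix), 1, tolerance = 1e-9)
  expect_true(all(p$matrix > 0))  # pseudocount removed the zero
  p4 <- pwm("t2", matrix(1, 4, 6))  # 4 x L orientation accepted
  expect_equal(p4$length, 6)
  expect_error(pwm("bad", matrix(-1, 1, 4)), "invalid")
})

test_that("the bundled example PFM parses with correct shapes", {
  pfm <- system.file("extdata", "example_motifs.pfm", package = "dimorphnet")
  pwms <- read_jaspar_pfm(pfm)
  expect_named(pwms, c("MOTIF_A", "MOTIF_B", "MOTIF_C"))
  expect_equal(vapply(pwms, function(p) p$length, numeric(1)),
               c(MOTIF_A = 8, MOTIF_B = 9, MOTIF_C = 7))
  expect_identical(pwm_consensus(pwms$MOTIF_A), "AGTACGGA")
})

test_that("JASPAR PFM round-trips through text", {
  pwms <- generate_promoter_fixtures(seq_config(genes = 2, n_pwms = 2,
                                                seed = 1))$pwms
  path <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(pwms, path)
  back <- read_jaspar_pfm(path)
  expect_named(back, names(pwms))
  # the reader re-applies the pseudocount, so agreement is approximate
  expect_lt(max(abs(back$PWM1$matrix - pwms$PWM1$matrix)), 5e-3)
})

test_that("PWM scoring matches the log-likelihood-ratio formula", {
  # background-equal PWM scores 0 everywhere
  flat <- pwm("flat", matrix(0.25, 3, 4), pseudocount = 0)
  expect_equal(score_pwm_match("ACG", flat), 0)
  # hand evaluation: log2(0.8 / 0.25)
  p1 <- pwm("one", matrix(c(0.8, 0.0667, 0.0666, 0.0667), 1, 4),
            pseudocount = 0)
  expect_equal(score_pwm_match("A", p1), log2(0.8 / 0.25), tolerance = 1e-9)
  # N contributes 0
  p3 <- pwm("three", rbind(c(0.8, 0.0667, 0.0666, 0.0667),
                           c(0.25, 0.25, 0.25, 0.25),
                           c(0.8, 0.0667, 0.0666, 0.0667)), pseudocount = 0)
  expect_equal(score_pwm_match("NNN", p3), 0)
  expect_equal(score_pwm_match("ANA", p3), 2 * log2(0.8 / 0.25),
               tolerance = 1e-9)
  expect_error(score_pwm_match("AC", p3), "length")
  expect_error(score_pwm_match("", p3), "empty")
})

test_that("empirical null calibration behaves at the degenerate and rich ends", {
  flat <- pwm("flat", matrix(0.25, 4, 4), pseudocount = 0)
  thr <- suppressWarnings(
    calibrate_empirical_null(flat, c(0.25, 0.25, 0.25, 0.25),
                             n_samples = 1e5, seed = 1))
  expect_equal(as.numeric(thr), 0)
  rich <- pwm("rich", {
    m <- matrix(0.01, 8, 4)
    m[, 1] <- 0.97
    m
  })
  thr2 <- suppressWarnings(
    calibrate_empirical_null(rich, c(0.25, 0.25, 0.25, 0.25),
                             n_samples = 2e5, seed = 2))
  consensus_score <- score_pwm_match(strrep("A", 8), rich)
  expect_gt(consensus_score, as.numeric(thr2))
  # oracle: direct quantile of the stored null sample
  ns <- attr(thr2, "null_scores_sorted")
  expect_equal(as.numeric(thr2), unname(ns[ceiling((1 - 1e-5) * length(ns))]))
  expect_error(calibrate_empirical_null(rich, c(0.25, 0.25, 0.25, 0.25),
                                        n_samples = 1e4), "too small")
  expect_warning(calibrate_empirical_null(rich, c(0.25, 0.25, 0.25, 0.25),
                                          n_samples = 1e5, seed = 1), "1e6")
})

test_that("default calibration draws one million null windows", {
  rich <- pwm("rich", {
    m <- matrix(0.01, 6, 4)
    m[, 2] <- 0.97
    m
  })
  thr <- calibrate_empirical_null(rich, c(0.25, 0.25, 0.25, 0.25), seed = 3)
  expect_equal(attr(thr, "n_samples"), 1e6)
  expect_length(attr(thr, "null_scores_sorted"), 1e6)
})

test_that("scanning recovers exactly the planted consensus sites", {
  fx <- generate_promoter_fixtures(seq_config(genes = 10, n_pwms = 3,
                                              planted_sites = 5, seed = 7))
  sites <- suppressWarnings(
    scan_promoters(fx$promoters, fx$tss, fx$pwms, p_cutoff = 1e-5,
                   n_null = 2e5, seed = 8))
  planted_keys <- with(fx$planted_sites, paste(gene, tf, offset, strand))
  found_keys <- with(sites, paste(gene, tf, offset, strand))
  expect_true(all(planted_keys %in% found_keys))
  # no more than Poisson-plausible false calls on top of the planted ones
  expect_lte(nrow(sites) - nrow(fx$planted_sites), 6)
  expect_true(all(sites$offset >= -750))
  expect_true(all(sites$offset <= 250 - 10))
})

test_that("an empty PWM set yields an empty site list", {
  fx <- generate_promoter_fixtures(seq_config(genes = 3, seed = 1))
  sites <- scan_promoters(fx$promoters, fx$tss, list())
  expect_equal(nrow(sites), 0)
})

test_that("sites outside the [-750, +250) window are not reported", {
  rich <- pwm("rich", {
    m <- matrix(0.01, 10, 4)
    m[, 1] <- 0.97
    m
  })
  # 1400 nt record with the TSS at position 751: consensus planted at +260
  # (outside the window) and another at +100 (inside)
  s <- strrep("C", 1400)
  substr(s, 751 + 260, 751 + 269) <- strrep("A", 10)
  substr(s, 751 + 100, 751 + 109) <- strrep("A", 10)
  thr <- c(rich = 15)  # below the consensus score of ~ 10 * log2(0.97/0.25)
  sites <- scan_promoters(c(gene1 = s),
                          data.frame(gene = "gene1", tss_pos = 751,
                                     strand = "+"),
                          list(rich), p_cutoff = 1e-5,
                          background = c(0.25, 0.25, 0.25, 0.25),
                          thresholds = thr)
  expect_equal(sites$offset, 100)
})

test_that("strand symmetry: scanning the reverse complement finds the same edges", {
  fx <- generate_promoter_fixtures(seq_config(genes = 6, n_pwms = 2,
                                              planted_sites = 4, seed = 13))
  bg <- c(0.25, 0.25, 0.25, 0.25)
  fwd <- suppressWarnings(
    scan_promoters(fx$promoters, fx$tss, fx$pwms, background = bg,
                   n_null = 1e5, seed = 5))
  rc <- Biostrings::reverseComplement(fx$promoters)
  names(rc) <- names(fx$promoters)
  tss_rc <- data.frame(gene = fx$tss$gene,
                       tss_pos = Biostrings::width(fx$promoters) -
                         fx$tss$tss_pos + 1L,
                       strand = "-")
  rev <- suppressWarnings(
    scan_promoters(rc, tss_rc, fx$pwms, background = bg,
                   n_null = 1e5, seed = 5))
  key <- function(s) sort(unique(paste(s$gene, s$tf)))
  expect_identical(key(fwd), key(rev))
  # offsets agree too: the window is reflected with the record
  expect_identical(
    fwd[order(fwd$gene, fwd$tf, fwd$offset), c("gene", "tf", "offset")],
    rev[order(rev$gene, rev$tf, rev$offset), c("gene", "tf", "offset")])
})

test_that("lowering the p cutoff never adds sites", {
  fx <- generate_promoter_fixtures(seq_config(genes = 8, n_pwms = 2,
                                              planted_sites = 4, seed = 21))
  loose <- suppressWarnings(
    scan_promoters(fx$promoters, fx$tss, fx$pwms, p_cutoff = 1e-3,
                   n_null = 1e5, seed = 6))
  strict <- suppressWarnings(
    scan_promoters(fx$promoters, fx$tss, fx$pwms, p_cutoff = 1e-5,
                   n_null = 1e5, seed = 6))
  key <- function(s) paste(s$gene, s$tf, s$offset, s$strand)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("pure-background scanning false-calls at roughly the cutoff rate", {
  # 50 promoters x ~2 x 992 windows ~ 1e5 windows at p = 1e-5: expect ~1
  # false site; assert within a generous Poisson envelope
  fx <- generate_promoter_fixtures(seq_config(genes = 50, n_pwms = 1,
                                              planted_sites = 0, seed = 31))
  sites <- suppressWarnings(
    scan_promoters(fx$promoters, fx$tss, fx$pwms, p_cutoff = 1e-5,
                   background = c(0.25, 0.25, 0.25, 0.25),
                   n_null = 2e5, seed = 9))
  n_windows <- 50 * 2 * (1000 - 10 + 1)
  expect_lte(nrow(sites), stats::qpois(0.999, 3 * 1e-5 * n_windows))
})

test_that("motif prior assembly collapses sites to binary edges", {
  sites <- data.frame(gene = c("g1", "g1", "g1", "g3"),
                      tf = c("t1", "t1", "t1", "t2"),
                      offset = c(-10, 5, 40, 0),
                      strand = c("+", "-", "+", "+"))
  adj <- build_motif_prior(sites, c("t1", "t2"), c("g1", "g2", "g3"))
  expect_identical(unname(adj), rbind(c(1L, 0L, 0L), c(0L, 0L, 1L)))
  empty <- build_motif_prior(sites[0, ], c("t1", "t2"), c("g1", "g2"))
  expect_true(all(empty == 0))
  expect_error(build_motif_prior(sites, c("t1", "t1"), "g1"), "duplicate")
})
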