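# Build a fully specified penalty table where every mismatch penalty is a
# known constant, so CFD products can be computed by hand.
constant_cfd_tables <- function(value = 0.5) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(position = 1:20, rna_base = bases, dna_base = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$rna_base != grid$dna_base, ]
  grid$penalty <- value
  pam2 <- as.vector(outer(bases, bases, paste0))
  cfd_tables(grid, data.frame(pam2 = pam2,
                              factor = ifelse(pam2 == "GG", 1.0, 0.25),
                              stringsAsFactors = FALSE))
}

test_that("CFD table validation enforces completeness and ranges", {
  t <- constant_cfd_tables()
  expect_s3_class(t, "cfd_tables")
  bad <- t$mismatch
  expect_error(cfd_tables(bad[-1, ], t$pam_factors), "incomplete")
  bad2 <- t$mismatch
  bad2$penalty[1] <- 1.5
  expect_error(cfd_tables(bad2, t$pam_factors), "0, 1")
  expect_error(cfd_tables(t$mismatch, t$pam_factors[-1, ]), "16 2-mers")
  # a listed matched pair must carry penalty 1.0
  withmatch <- rbind(t$mismatch,
                     data.frame(position = 1, rna_base = "A", dna_base = "A",
                                penalty = 0.9))
  expect_error(cfd_tables(withmatch, t$pam_factors), "matched")
})

test_that("CFD tables round-trip through TSV and normalise U to T", {
  t <- synthetic_cfd_tables(5)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cfd_tables(t, f1, f2)
  t2 <- read_cfd_tables(f1, f2)
  expect_equal(t2$lookup, t$lookup)
  u <- t$mismatch
  u$rna_base <- chartr("T", "U", u$rna_base)
  t3 <- cfd_tables(u, t$pam_factors)
  expect_equal(t3$lookup, t$lookup)
})

test_that("a planted exact copy is recovered as the 0-mismatch self-hit", {
  sim <- simulate_genome(31, contig_length = 1500L, n_planted = 1L,
                         pam = "NGN")
  spacer <- sim$truth$protospacer[1]
  hits <- find_offtargets(sim$genome, spacer, "SpG", max_mismatches = 0)
  self <- hits[hits$n_mismatches == 0, ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$start, sim$truth$start[1])
  expect_equal(self$strand, sim$truth$strand[1])
})

test_that("off-target search equals the exhaustive scan oracle", {
  specs <- list(list(pam = "SpCas9", pat = "NGG"),
                list(pam = "SpG", pat = "NGN"),
                list(pam = "SpRY", pat = "NRN"))
  set.seed(123)
  for (i in 1:6) {
    g <- random_genome(300 + i, length = 800L)
    spacer <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = "")
    v <- specs[[(i %% 3) + 1]]
    mm <- i %% 5
    for (seed_mode in c(FALSE, TRUE)) {
      got <- find_offtargets(g, spacer, v$pam, max_mismatches = mm,
                             seed_restricted = seed_mode, seed_length = 12)
      want <- oracle_offtargets(g, spacer, v$pat, mm,
                                seed_restricted = seed_mode, seed_length = 12)
      expect_identical(site_key(got), site_key(want))
      expect_equal(got$n_mismatches,
                   want$n_mismatches[match(site_key(got), site_key(want))])
    }
  }
})

test_that("seed restriction tolerates only PAM-distal mismatches", {
  spacer <- strrep("A", 20)
  # protospacer mismatching at PAM-proximal position 3 (5'->3' position 18)
  near <- paste0(strrep("A", 17), "C", "AA")
  far <- paste0("C", strrep("A", 19))  # PAM-proximal position 20
  g <- genome_from_seqs(c(
    c1 = paste0("TTTTTT", near, "TGG", "TTTTTT"),
    c2 = paste0("TTTTTT", far, "TGG", "TTTTTT")))
  strict <- find_offtargets(g, spacer, "SpCas9", max_mismatches = 2,
                            seed_restricted = TRUE, seed_length = 12)
  expect_equal(unique(strict$contig), "c2")
  loose <- find_offtargets(g, spacer, "SpCas9", max_mismatches = 2,
                           seed_restricted = FALSE)
  expect_setequal(unique(loose$contig), c("c1", "c2"))
  # seed_only marks hits whose mismatches all sit inside the seed
  near_hit <- loose[loose$contig == "c1", ]
  expect_true(near_hit$seed_only)
  expect_equal(near_hit$mismatch_positions, "3")
})

test_that("CFD is the product of mismatch penalties times the PAM factor", {
  tabs <- constant_cfd_tables(0.5)
  spacer <- strrep("A", 20)
  hits <- data.frame(
    protospacer = c(strrep("A", 20),                       # 0 mismatches
                    paste0("C", strrep("A", 19)),          # 1 mismatch
                    paste0("CC", strrep("A", 18))),        # 2 mismatches
    pam = c("TGA", "TGA", "TGA"), stringsAsFactors = FALSE)
  cfd <- cfd_score(spacer, hits, tabs, "SpG")
  expect_equal(cfd, c(1.0, 0.5, 0.25))   # matching SpG PAM contributes 1.0

  # distinct per-position penalties multiply: 0.5 * 0.4
  two <- tabs$mismatch
  two$penalty[two$position == 20 & two$rna_base == "A" & two$dna_base == "C"] <- 0.4
  tabs2 <- cfd_tables(two, tabs$pam_factors)
  expect_equal(cfd_score(spacer, hits[3, ], tabs2, "SpG"), 0.4 * 0.5)
})

test_that("wild-type NGG scoring uses the empirical PAM 2-mer factor", {
  tabs <- constant_cfd_tables(0.5)
  spacer <- strrep("A", 20)
  hit_gg <- data.frame(protospacer = spacer, pam = "TGG",
                       stringsAsFactors = FALSE)
  hit_ag <- data.frame(protospacer = spacer, pam = "TAG",
                       stringsAsFactors = FALSE)
  expect_equal(cfd_score(spacer, hit_gg, tabs, "SpCas9"), 1.0)
  expect_equal(cfd_score(spacer, hit_ag, tabs, "SpCas9"), 0.25)
})

test_that("CFD never increases as mismatches accumulate", {
  tabs <- synthetic_cfd_tables(2)
  spacer <- strrep("A", 20)
  proto <- spacer
  prev <- Inf
  for (k in 1:5) {
    substr(proto, k, k) <- "G"
    cfd <- cfd_score(spacer, data.frame(protospacer = proto, pam = "TGA",
                                        stringsAsFactors = FALSE),
                     tabs, "SpG")
    expect_lte(cfd, prev)
    expect_gte(cfd, 0)
    prev <- cfd
  }
})

test_that("variant-PAM hit sets are nested by pattern permissiveness", {
  g <- random_genome(77, length = 1000L)
  spacer <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  k_ngg <- site_key(find_offtargets(g, spacer, "SpCas9", max_mismatches = 3))
  k_ngn <- site_key(find_offtargets(g, spacer, "SpG", max_mismatches = 3))
  k_nrn <- site_key(find_offtargets(g, spacer, "SpRY", max_mismatches = 3))
  expect_true(all(k_ngg %in% k_ngn))
  # NGN and NRN intersect in NGN-with-purine... both contain all NGG hits
  expect_true(all(k_ngg %in% k_nrn))
})

test_that("the off-target report counts, sorts and excludes the on-target", {
  sim <- simulate_genome(55, contig_length = 2000L, n_planted = 1L,
                         pam = "NGN")
  spacer <- sim$truth$protospacer[1]
  tabs <- synthetic_cfd_tables(3)
  hits <- find_offtargets(sim$genome, spacer, "SpG", max_mismatches = 4)
  rep <- offtarget_report(hits, tabs, "SpG")
  expect_equal(sum(rep$counts_by_mismatch), nrow(rep$hits))
  expect_true(all(diff(rep$hits$cfd) <= 1e-12))
  ord <- order(-rep$hits$cfd, rep$hits$contig, rep$hits$start,
               rep$hits$strand)
  expect_equal(ord, seq_len(nrow(rep$hits)))
  expect_equal(rep$n_offtargets, nrow(rep$hits) - 1L)
  if (rep$n_offtargets == 0) {
    expect_equal(rep$max_offtarget_cfd, 0)
  } else {
    expect_lt(rep$max_offtarget_cfd, 1 + 1e-12)
  }

  only_self <- find_offtargets(sim$genome, spacer, "SpG", max_mismatches = 0)
  rep0 <- offtarget_report(only_self, tabs, "SpG")
  expect_equal(rep0$n_offtargets, 0L)
  expect_equal(rep0$max_offtarget_cfd, 0)
})

test_that("spacers with invalid characters are rejected", {
  g <- random_genome(1, length = 100L)
  expect_error(find_offtargets(g, paste0(strrep("A", 19), "N"), "SpG"),
               "A, C, G, T")
  expect_error(find_offtargets(g, "ACGT", "SpG"), "length")
})
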