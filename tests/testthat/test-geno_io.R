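test_that("EIGENSTRAT reader maps digits, detects ploidy and round-trips", {
  snps <- snp_table(2)
  samples <- sample_table(3)

  # diploid fixture: rows are SNPs, one digit per individual
  prefix <- write_tiny_eigenstrat(c("019", "202"), snps, samples)
  x <- read_eigenstrat(paste0(prefix, ".geno"), paste0(prefix, ".snp"),
                       paste0(prefix, ".ind"))
  expect_equal(x$ploidy_mode, "diploid_mlg")
  expect_equal(x$calls, matrix(c(0L, 2L, 1L, 0L, NA, 2L), nrow = 3,
                               byrow = TRUE))
  expect_equal(x$samples$sample_id, paste0("ind", 1:3))

  # pseudo-haploid fixture: only {0,2,9} present, remapped to {0,1,NA}
  prefix2 <- write_tiny_eigenstrat(c("029", "200"), snps, samples)
  y <- read_eigenstrat(paste0(prefix2, ".geno"), paste0(prefix2, ".snp"),
                       paste0(prefix2, ".ind"))
  expect_equal(y$ploidy_mode, "pseudo_haploid")
  expect_equal(y$calls, matrix(c(0L, 1L, 1L, 0L, NA, 0L), nrow = 3,
                               byrow = TRUE))

  # write -> read is value-identical, missing preserved
  dir <- withr::local_tempdir()
  write_eigenstrat(x, file.path(dir, "rt"))
  x2 <- read_eigenstrat(file.path(dir, "rt.geno"), file.path(dir, "rt.snp"),
                        file.path(dir, "rt.ind"))
  expect_identical(x2$calls, x$calls)
  expect_equal(x2$ploidy_mode, x$ploidy_mode)
  write_eigenstrat(y, file.path(dir, "rtp"))
  y2 <- read_eigenstrat(file.path(dir, "rtp.geno"), file.path(dir, "rtp.snp"),
                        file.path(dir, "rtp.ind"))
  expect_identical(y2$calls, y$calls)
})

test_that("EIGENSTRAT reader rejects malformed input with located errors", {
  snps <- snp_table(2)
  samples <- sample_table(3)
  prefix <- write_tiny_eigenstrat(c("019", "202", "000"), snps, samples)
  expect_error(read_eigenstrat(paste0(prefix, ".geno"), paste0(prefix, ".snp"),
                               paste0(prefix, ".ind")), "format error")
  prefix2 <- write_tiny_eigenstrat(c("019", "2x2"), snps, samples)
  expect_error(read_eigenstrat(paste0(prefix2, ".geno"), paste0(prefix2, ".snp"),
                               paste0(prefix2, ".ind")),
               "row 2, column 2")
})

test_that("VCF reader keeps biallelic SNPs, maps GT and flags malformed GT", {
  gts <- rbind(c("0/0", "0/1", "1/1"),
               c("0/1", "./.", "0|1"),
               c("1/1", "0/0", "0/0"))
  path <- write_tiny_vcf(rep("chr1", 3), c(100, 200, 300),
                         c("A", "C", "G"), c("T", "T", "A,T")[c(1, 2, 3)], gts)
  expect_message(x <- read_vcf_biallelic(path), "skipped 1")
  expect_equal(x$ploidy_mode, "diploid_mlg")
  expect_equal(ncol(x$calls), 2)             # multi-allelic record dropped
  expect_equal(x$calls[, 1], c(0L, 1L, 2L))  # ALT-allele counts
  expect_equal(x$calls[, 2], c(1L, NA, 1L))  # ./. -> NA, phased accepted
  expect_equal(x$snps$allele_ref, c("T", "T"))  # counted allele = ALT

  bad <- write_tiny_vcf("chr1", 100, "A", "T",
                        matrix(c("0/2", "0/0"), nrow = 1))
  expect_error(read_vcf_biallelic(bad), "malformed GT")
})

test_that("panel ascertainment intersects, errors on disjoint and is idempotent", {
  x <- make_acm(rand_calls(4, 10))
  panel <- x$snps[c(2, 5, 7, 9), c("chromosome", "physical_pos")]
  a <- ascertain_to_panel(x, panel)
  expect_equal(ncol(a$calls), 4)
  expect_equal(a$snps$physical_pos, x$snps$physical_pos[c(2, 5, 7, 9)])
  expect_equal(a$calls, x$calls[, c(2, 5, 7, 9)])
  # idempotent
  expect_identical(ascertain_to_panel(a, panel)$calls, a$calls)
  # panel superset of matrix: unchanged
  sup <- data.frame(chromosome = "chr1", physical_pos = seq(1000, 50000, 500))
  expect_identical(ascertain_to_panel(x, sup)$calls, x$calls)
  # disjoint
  dis <- data.frame(chromosome = "chr2", physical_pos = c(1, 2))
  expect_error(ascertain_to_panel(x, dis), "panel")
})

test_that("recombination map reads, validates and looks up by interval", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.txt")
  writeLines(c("chr1 1000 1.5", "chr1 5000 0.2", "chr1 9000 3.0"), path)
  m <- read_recombination_map(path)
  expect_equal(nrow(m$map), 3)
  # before first point -> first rate; inside intervals -> left point's rate
  expect_equal(recomb_rate_at(m, "chr1", c(10, 1000, 2500, 5000, 7000, 12000)),
               c(1.5, 1.5, 1.5, 0.2, 0.2, 3.0))
  expect_true(is.na(recomb_rate_at(m, "chrX", 100)))

  writeLines(c("chr1 1000 1.5", "chr1 900 0.2"), path)
  expect_error(read_recombination_map(path), "non-monotone")
  writeLines(c("chr1 1000 -1"), path)
  expect_error(read_recombination_map(path), "negative")
})

test_that("scan outputs use BED half-open coordinates and round-trip scores", {
  tr <- synthetic_track(c(0.1, 0.9, 0.95, 0.2, 0.8))
  tr$focal_pos <- c(500L, 1000L, 3000L, 4000L, 5000L)
  pk <- data.frame(chromosome = "chr1", idx_first = 102L, idx_last = 103L,
                   bp_first = 1000L, bp_last = 5000L, n_windows = 2L,
                   representative_g12 = 0.95)
  dir <- withr::local_tempdir()
  paths <- write_scan_outputs(tr, pk, file.path(dir, "out"))
  bed <- read.table(paths[2], sep = "\t")
  expect_equal(unname(unlist(bed[1, 1:3])), c("chr1", "999", "5000"))
  back <- read_scan_scores(paths[1])
  expect_equal(back$g12, tr$g12, tolerance = 1e-6)
  expect_equal(back$focal_pos, tr$focal_pos)

  # empty peak list -> header-only summary, empty BED
  paths2 <- write_scan_outputs(tr, call_peaks(tr, 2), file.path(dir, "none"))
  expect_equal(length(readLines(paths2[2])), 0)
  expect_equal(nrow(read.table(paths2[3], header = TRUE, sep = "\t")), 0)
})

test_that("allele_call_matrix validates domains and dimensions", {
  expect_error(make_acm(matrix(3L, 2, 2)), "outside")
  expect_error(allele_call_matrix(matrix(0L, 2, 2), snp_table(2),
                                  sample_table(3)), "rows")
  m <- matrix(0:1, 2, 2)
  expect_error(allele_call_matrix(m, snp_table(2),
                                  data.frame(sample_id = c("a", "a"),
                                             group_label = "x"),
                                  "diploid_mlg"), "duplicate")
  snps <- snp_table(2)
  snps$physical_pos <- c(2000L, 1000L)
  expect_error(allele_call_matrix(m, snps, sample_table(2), "diploid_mlg"),
               "increasing")
})
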