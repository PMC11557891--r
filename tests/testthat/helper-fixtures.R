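# Shared fixture builders: everything is generated in code at test time.

# A minimal SNP table with evenly spaced positions.
snp_table <- function(s, chr = "chr1", start = 1000L, step = 1000L,
                      ref = "G", alt = "A") {
  pos <- start + step * (seq_len(s) - 1L)
  data.frame(snp_id = paste0(chr, "_", pos), chromosome = chr,
             genetic_pos = pos * 1e-8, physical_pos = pos,
             allele_ref = rep_len(ref, s), allele_alt = rep_len(alt, s),
             stringsAsFactors = FALSE)
}

sample_table <- function(n, group = "N") {
  data.frame(sample_id = paste0("ind", seq_len(n)),
             group_label = rep_len(group, n), stringsAsFactors = FALSE)
}

make_acm <- function(calls, ploidy = "diploid_mlg", chr = "chr1", ...) {
  calls <- as.matrix(calls)
  allele_call_matrix(calls, snp_table(ncol(calls), chr = chr, ...),
                     sample_table(nrow(calls)), ploidy)
}

# Random genotype matrix for clustering oracles.
rand_calls <- function(n, s, vals = 0:2, miss_prob = 0) {
  m <- matrix(sample(vals, n * s, replace = TRUE), nrow = n)
  if (miss_prob > 0) m[runif(n * s) < miss_prob] <- NA_integer_
  storage.mode(m) <- "integer"
  m
}

# Sort-based oracle for zero-missingness clustering: unique-row multiset counts.
unique_row_freqs <- function(m) {
  key <- apply(m, 1, paste, collapse = ",")
  sort(as.vector(table(key)), decreasing = TRUE) / nrow(m)
}

# Write a small ASCII EIGENSTRAT triplet; returns the path prefix.
write_tiny_eigenstrat <- function(geno_lines, snps, samples,
                                  dir = withr::local_tempdir(.local_envir = parent.frame())) {
  prefix <- file.path(dir, "fix")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  write.table(snps, paste0(prefix, ".snp"), quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(samples$sample_id, "U", samples$group_label),
              paste0(prefix, ".ind"), quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  prefix
}

# Write a tiny VCF; gts is a variants x samples character matrix of GT values.
write_tiny_vcf <- function(chrom, pos, ref, alt, gts,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fix.vcf")
  ns <- ncol(gts)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(chrom)[1], ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("s", seq_len(ns))), collapse = "\t"))
  rec <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, rec), path)
  path
}

# A deterministic synthetic scan track for peak/QC tests.
synthetic_track <- function(g12, chr = "chr1", mean_missing = NULL,
                            mean_recomb = NULL, focal0 = 101L) {
  n <- length(g12)
  data.frame(chromosome = chr, focal_index = focal0 + seq_len(n) - 1L,
             focal_pos = 1000L * (focal0 + seq_len(n) - 1L),
             win_start_idx = seq_len(n), win_end_idx = seq_len(n) + 200L,
             win_start_bp = 1000L * seq_len(n),
             win_end_bp = 1000L * (seq_len(n) + 200L),
             g12 = g12,
             mean_missing = if (is.null(mean_missing)) rep(0.5, n) else mean_missing,
             mean_recomb = if (is.null(mean_recomb)) rep(1, n) else mean_recomb,
             mask_recomb = FALSE, mask_missing = FALSE, mask_crosspop = FALSE,
             masked = FALSE, stringsAsFactors = FALSE)
}

# Maximal-run oracle for peak calling.
run_merge_oracle <- function(g12, threshold, masked = rep(FALSE, length(g12))) {
  above <- !masked & g12 > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(lo = starts[keep], hi = ends[keep],
             rep = vapply(keep, function(k) max(g12[starts[k]:ends[k]]), 0))
}
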