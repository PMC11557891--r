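# Readers/writers for the population-genetics formats the scan touches, and
# the in-memory genotype container shared by all modules.

#' Construct an allele-call matrix
#'
#' The central genotype container: an individuals x sites integer matrix of
#' allele calls plus SNP and sample metadata.  Calls count copies of
#' `allele_ref`, the *counted allele* of each SNP (the first allele column of
#' an EIGENSTRAT `.snp` file, or the ALT allele of a VCF record); `allele_alt`
#' is the other allele.  Diploid multi-locus-genotype (MLG) matrices use
#' values 0/1/2, pseudo-haploid matrices 0/1; `NA` encodes a missing call.
#'
#' @param calls integer matrix, individuals in rows, sites in columns.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `genetic_pos`
#'   (morgans), `physical_pos` (1-based bp), `allele_ref`, `allele_alt`.
#'   Must be sorted by (chromosome, physical_pos) without duplicate positions
#'   within a chromosome.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `group_label`.
#' @param ploidy_mode `"diploid_mlg"` or `"pseudo_haploid"`.
#' @return An object of class `AlleleCallMatrix`.
#' @export
allele_call_matrix <- function(calls, snps, samples,
                               ploidy_mode = c("diploid_mlg", "pseudo_haploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples), " entries")
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but snps has ", nrow(snps), " records")
  vmax <- if (ploidy_mode == "diploid_mlg") 2L else 1L
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > vmax))
    stop("calls outside {0..", vmax, ", NA} for ploidy mode ", ploidy_mode)
  validate_snp_table(snps)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table")
  structure(list(calls = calls, snps = snps, samples = samples,
                 ploidy_mode = ploidy_mode),
            class = "AlleleCallMatrix")
}

validate_snp_table <- function(snps) {
  need <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
            "allele_ref", "allele_alt")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snps table lacks columns: ", paste(miss, collapse = ", "))
  if (any(snps$physical_pos <= 0)) stop("physical_pos must be positive (1-based)")
  same <- !is.na(snps$allele_ref) & !is.na(snps$allele_alt) &
    snps$allele_ref == snps$allele_alt
  if (any(same)) stop("allele_ref equals allele_alt at SNP ", which(same)[1])
  for (chr in unique(snps$chromosome)) {
    p <- snps$physical_pos[snps$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", chr)
  }
  invisible(snps)
}

#' @export
print.AlleleCallMatrix <- function(x, ...) {
  cat("AlleleCallMatrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "sites (", x$ploidy_mode, ")\n")
  cat("  chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$calls)),
      sprintf("(%.1f%%)", 100 * mean(is.na(x$calls))), "\n")
  invisible(x)
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads ASCII EIGENSTRAT `.geno`/`.snp`/`.ind` files.  Each `.geno` row is a
#' SNP, one digit per individual: the count of the first (`allele_ref`) allele,
#' with `9` for missing.  Files containing only `{0,2,9}` are treated as
#' pseudo-haploid and remapped to `{0,1,NA}`; otherwise the matrix is diploid
#' MLG.
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @return An [allele_call_matrix()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  geno <- readLines(geno_path)
  geno <- geno[nzchar(geno)]
  snp <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snp) < 6)
    stop(".snp file must have 6 columns (id, chromosome, genetic pos, physical pos, alleles)")
  names(snp)[1:6] <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
                       "allele_ref", "allele_alt")
  snp <- snp[, 1:6]
  snp$chromosome <- as.character(snp$chromosome)
  ind <- read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(ind[[1]]),
                        group_label = as.character(ind[[ncol(ind)]]),
                        stringsAsFactors = FALSE)

  if (length(geno) != nrow(snp))
    stop("format error: .geno has ", length(geno), " rows but .snp has ",
         nrow(snp), " lines (first mismatch at line ",
         min(length(geno), nrow(snp)) + 1, ")")
  widths <- nchar(geno)
  if (any(widths != nrow(samples))) {
    off <- which(widths != nrow(samples))[1]
    stop("format error: .geno line ", off, " has ", widths[off],
         " characters but .ind has ", nrow(samples), " lines")
  }

  mat <- matrix(NA_integer_, nrow = nrow(samples), ncol = length(geno))
  for (j in seq_along(geno)) {
    ch <- strsplit(geno[j], "", fixed = TRUE)[[1]]
    bad <- !ch %in% c("0", "1", "2", "9")
    if (any(bad)) {
      col <- which(bad)[1]
      stop("parse error: invalid genotype character '", ch[col],
           "' at .geno row ", j, ", column ", col)
    }
    v <- as.integer(ch)
    v[v == 9L] <- NA_integer_
    mat[, j] <- v
  }

  seen <- unique(mat[!is.na(mat)])
  pseudo <- !any(seen == 1L)
  if (pseudo) {
    mat[mat == 2L] <- 1L
    mode <- "pseudo_haploid"
  } else {
    mode <- "diploid_mlg"
  }
  allele_call_matrix(mat, snp, samples, mode)
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Inverse of [read_eigenstrat()]: pseudo-haploid calls are encoded `{0,2,9}`,
#' diploid MLG calls `{0,1,2,9}`.
#'
#' @param x an [allele_call_matrix()].
#' @param prefix output path prefix; writes `<prefix>.geno/.snp/.ind`.
#' @return The three file paths, invisibly.
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  m <- x$calls
  if (x$ploidy_mode == "pseudo_haploid") m[m == 1L] <- 2L
  m[is.na(m)] <- 9L
  lines <- apply(m, 2, paste, collapse = "")
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(lines, paths[1])
  write.table(x$snps, paths[2], quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  write.table(data.frame(x$samples$sample_id, "U", x$samples$group_label),
              paths[3], quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(paths)
}

#' Read biallelic SNPs from a VCF
#'
#' Keeps biallelic SNP records only (single-nucleotide REF and ALT);
#' multi-allelic or non-SNP records are skipped with a message reporting the
#' count.  GT values are mapped to ALT-allele counts (`0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, `./. -> NA`; `|`-phased genotypes are accepted), so
#' `allele_ref` of the result is the VCF ALT allele.
#'
#' @param vcf_path path to a VCF file (uncompressed or gzipped).
#' @return An [allele_call_matrix()] with `ploidy_mode = "diploid_mlg"`.
#' @export
read_vcf_biallelic <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nuc <- c("A", "C", "G", "T")
  ok <- fix[, "REF"] %in% nuc & fix[, "ALT"] %in% nuc
  nskip <- sum(!ok)
  if (nskip > 0)
    message("skipped ", nskip, " non-biallelic-SNP record(s)")
  if (!any(ok)) stop("no biallelic SNP records in ", vcf_path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]

  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L, "1/0" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  flat <- as.vector(gt)
  calls <- rep(NA_integer_, length(flat))
  known <- flat %in% names(map)
  missing_gt <- is.na(flat) | flat %in% c("./.", ".|.", ".")
  if (any(!known & !missing_gt)) {
    off <- which(!known & !missing_gt)[1]
    stop("parse error: malformed GT '", flat[off], "' at record ",
         (off - 1) %% nrow(gt) + 1)
  }
  calls[known] <- map[flat[known]]
  calls <- matrix(calls, nrow = nrow(gt))

  snps <- data.frame(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chromosome = as.character(fix[, "CHROM"]),
    genetic_pos = 0,
    physical_pos = as.integer(fix[, "POS"]),
    allele_ref = as.character(fix[, "ALT"]),   # counted allele
    allele_alt = as.character(fix[, "REF"]),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), group_label = "unknown",
                        stringsAsFactors = FALSE)
  allele_call_matrix(t(calls), snps, samples, "diploid_mlg")
}

#' Restrict a genotype matrix to a SNP panel
#'
#' Emulates capture-array ascertainment: keeps the sites present in both the
#' matrix and the panel (keyed by chromosome and physical position), in matrix
#' order, with the sample set unchanged.
#'
#' @param x an [allele_call_matrix()].
#' @param panel data.frame with columns `chromosome` and `physical_pos`.
#' @return The ascertained [allele_call_matrix()].
#' @export
ascertain_to_panel <- function(x, panel) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  key_m <- paste(x$snps$chromosome, x$snps$physical_pos)
  key_p <- paste(as.character(panel$chromosome), panel$physical_pos)
  keep <- key_m %in% key_p
  if (!any(keep))
    stop("no matrix site is on the panel; the scan would be undefined")
  allele_call_matrix(x$calls[, keep, drop = FALSE],
                     x$snps[keep, , drop = FALSE],
                     x$samples, x$ploidy_mode)
}

#' Read a recombination map
#'
#' Whitespace-delimited text with columns chromosome, position (1-based bp)
#' and rate (cM/Mb or events/bp; the scan only uses relative rates).
#' Positions must be strictly increasing within a chromosome and rates
#' non-negative.
#'
#' @param path path to the map file.
#' @return An object of class `RecombinationMap`.
#' @export
read_recombination_map <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("recombination map needs 3 columns: chromosome, position, rate")
  names(d)[1:3] <- c("chromosome", "position", "rate")
  d$chromosome <- as.character(d$chromosome)
  if (any(d$rate < 0)) stop("negative recombination rate at line ", which(d$rate < 0)[1])
  for (chr in unique(d$chromosome)) {
    p <- d$position[d$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("format error: non-monotone positions on chromosome ", chr)
  }
  structure(list(map = d[, 1:3]), class = "RecombinationMap")
}

#' Look up recombination rates at SNP positions
#'
#' A SNP takes the rate of the map interval containing it (the rate attached
#' to the nearest map point at or before the SNP); positions before the first
#' map point take the first rate.
#'
#' @param map a [read_recombination_map()] result.
#' @param chromosome chromosome of the query positions.
#' @param positions vector of 1-based bp positions.
#' @return Numeric vector of rates (NA for chromosomes absent from the map).
#' @export
recomb_rate_at <- function(map, chromosome, positions) {
  stopifnot(inherits(map, "RecombinationMap"))
  d <- map$map[map$map$chromosome == as.character(chromosome), ]
  if (nrow(d) == 0) return(rep(NA_real_, length(positions)))
  i <- findInterval(positions, d$position)
  i[i == 0] <- 1L
  d$rate[i]
}

#' Write scan outputs
#'
#' Writes the per-window score track as tab-delimited text, the peaks as BED
#' (0-based, half-open) and a tab-delimited peak summary with the
#' representative (maximum) G12 per peak.
#'
#' @param track a `ScanTrack` data.frame from [scan_g12()].
#' @param peaks a peak data.frame from [call_peaks()] (may have zero rows).
#' @param out_prefix output path prefix.
#' @return Paths of the three files, invisibly.
#' @export
write_scan_outputs <- function(track, peaks, out_prefix) {
  score_path <- paste0(out_prefix, "_scores.tsv")
  bed_path <- paste0(out_prefix, "_peaks.bed")
  peak_path <- paste0(out_prefix, "_peaks.tsv")
  write.table(track, score_path, quote = FALSE, row.names = FALSE, sep = "\t")
  bed <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    name = character(0), score = numeric(0))
  if (nrow(peaks) > 0) {
    bed <- data.frame(chrom = peaks$chromosome,
                      start = peaks$bp_first - 1L,   # 1-based inclusive -> BED
                      end = peaks$bp_last,
                      name = paste0("peak", seq_len(nrow(peaks))),
                      score = peaks$representative_g12)
  }
  write.table(bed, bed_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  write.table(peaks, peak_path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(c(score_path, bed_path, peak_path))
}

#' Read back a written score track
#'
#' @param path a `<prefix>_scores.tsv` written by [write_scan_outputs()].
#' @return The score track data.frame.
#' @export
read_scan_scores <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
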