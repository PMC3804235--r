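SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

#' Run configuration
#'
#' Bundles the thresholds used along the pipeline: pooled SNP calling filters
#' (minimum per-pool read coverage, minimum reads supporting the minor allele,
#' minimum overall minor-allele frequency), the empirical outlier rule (Fst
#' tail fraction and q-value ceiling), the association permutation count and
#' the coalescent replicate count. Defaults are the values used throughout the
#' analysis: coverage >= 10, minor allele on >= 2 reads, overall minor-allele
#' frequency >= 1%, the 1% Fst tail combined with q < 0.005, 1000 permutations
#' and 1000 coalescent replicates.
#'
#' @param seed integer seed recorded in outputs and used by stochastic steps.
#' @param min_coverage minimum read coverage per pool for a retained SNP.
#' @param min_supporting_reads minimum reads carrying the minor allele
#'   (summed over pools).
#' @param min_maf minimum overall minor-allele frequency, in (0, 1).
#' @param fst_tail_fraction upper tail of the empirical Fst distribution
#'   declared "extreme", in (0, 1).
#' @param q_max q-value ceiling an outlier must also satisfy.
#' @param n_permutations permutations for association multiple-testing
#'   adjustment.
#' @param n_coalescent_reps neutral coalescent replicates for corrected
#'   significance.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       min_coverage = 10L,
                       min_supporting_reads = 2L,
                       min_maf = 0.01,
                       fst_tail_fraction = 0.01,
                       q_max = 0.005,
                       n_permutations = 1000L,
                       n_coalescent_reps = 1000L) {
  stopifnot(min_maf > 0, min_maf < 1,
            fst_tail_fraction > 0, fst_tail_fraction < 1,
            q_max > 0, q_max <= 1,
            min_coverage >= 1, min_supporting_reads >= 0)
  structure(list(seed = as.integer(seed),
                 min_coverage = as.integer(min_coverage),
                 min_supporting_reads = as.integer(min_supporting_reads),
                 min_maf = min_maf,
                 fst_tail_fraction = fst_tail_fraction,
                 q_max = q_max,
                 n_permutations = as.integer(n_permutations),
                 n_coalescent_reps = as.integer(n_coalescent_reps)),
            class = "run_config")
}

#' Read a run configuration from a flat YAML key/value file
#'
#' Unknown keys are rejected so a typo cannot silently fall back to a default.
#'
#' @param path path to a YAML file with any subset of the `run_config()` keys.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Audit header recording seed and thresholds
#'
#' Every table the pipeline writes starts with these comment lines so a result
#' file is traceable to the run that produced it.
#'
#' @param cfg a `run_config`.
#' @return character vector of `#`-prefixed lines.
#' @export
audit_header <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  c(sprintf("# btiscan %s", as.character(utils::packageVersion("btiscan"))),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# min_coverage: %d  min_supporting_reads: %d  min_maf: %g",
            cfg$min_coverage, cfg$min_supporting_reads, cfg$min_maf),
    sprintf("# fst_tail_fraction: %g  q_max: %g", cfg$fst_tail_fraction, cfg$q_max))
}

#' Write a result table with its audit header
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param cfg a `run_config` whose audit header is prepended.
#' @export
write_result_table <- function(x, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(audit_header(cfg), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sync (pooled read counts) ----------------------------------------------

new_sync <- function(sites, counts) {
  stopifnot(is.data.frame(sites), length(dim(counts)) == 3L,
            dim(counts)[1] == nrow(sites), dim(counts)[3] == 6L)
  dimnames(counts)[[3]] <- SYNC_ALLELES
  structure(list(sites = sites, counts = counts), class = "sync")
}

#' Read a sync file of pooled allele read counts
#'
#' The sync format (as popularised by PoPoolation2) holds one genomic site per
#' line: sequence name, 1-based position, reference base, then one
#' colon-separated count 6-tuple `A:T:C:G:N:del` per pool.
#'
#' @param path path to a sync text file.
#' @return an object of class `sync`: `$sites` is a data.frame with `chrom`,
#'   `pos`, `ref`; `$counts` is an integer array of dimension
#'   sites x pools x 6 alleles.
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty sync file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("sync parse error at line ", which(nf < 4L)[1],
         ": expected chrom, pos, ref and at least one count tuple")
  n_pools <- nf[1] - 3L
  if (any(nf != nf[1]))
    stop("inconsistent pool count at line ", which(nf != nf[1])[1],
         " (expected ", n_pools, " pools)")
  n <- length(lines)
  counts <- array(NA_integer_, dim = c(n, n_pools, 6L))
  for (p in seq_len(n_pools)) {
    tup <- strsplit(vapply(fields, `[[`, "", p + 3L), ":", fixed = TRUE)
    bad <- which(lengths(tup) != 6L)
    if (length(bad) > 0L)
      stop("sync parse error at line ", bad[1], ": count tuple for pool ", p,
           " does not have 6 fields")
    vals <- suppressWarnings(as.integer(unlist(tup)))
    if (anyNA(vals))
      stop("sync parse error: non-integer count (pool ", p, ")")
    counts[, p, ] <- matrix(vals, nrow = n, ncol = 6L, byrow = TRUE)
  }
  if (any(counts < 0L)) stop("negative read count in sync file")
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos) || any(pos < 1L))
    stop("sync parse error: positions must be integers >= 1")
  sites <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                      pos = pos,
                      ref = vapply(fields, `[[`, "", 3L),
                      stringsAsFactors = FALSE)
  new_sync(sites, counts)
}

#' Write pooled counts to a sync file
#'
#' @param sync a `sync` object.
#' @param path output path.
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync"))
  n_pools <- dim(sync$counts)[2]
  tuples <- vapply(seq_len(n_pools), function(p)
    apply(sync$counts[, p, , drop = FALSE], 1L,
          function(v) paste(v, collapse = ":")),
    character(nrow(sync$sites)))
  tuples <- matrix(tuples, nrow = nrow(sync$sites))
  lines <- paste(sync$sites$chrom, sync$sites$pos, sync$sites$ref,
                 apply(tuples, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sync <- function(x, ...) {
  cat("sync: ", nrow(x$sites), " sites x ", dim(x$counts)[2], " pools\n", sep = "")
  invisible(x)
}

# ---- haplotype alignments ---------------------------------------------------

#' Construct a haplotype alignment
#'
#' @param seqs named character vector of equal-length sequences over
#'   `A,C,G,T,N,-` (case-insensitive), or a character matrix (rows =
#'   haplotypes).
#' @param label strain/locus label.
#' @return object of class `hap_alignment` with elements `seq` (character
#'   matrix n x L), `n`, `L`, `label`.
#' @export
hap_alignment <- function(seqs, label = "") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (length(seqs) == 0L) stop("empty alignment")
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L)
      stop("ragged alignment: sequences have differing lengths")
    m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) == 0L) stop("empty alignment")
  ok <- m %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) stop("alignment contains characters outside A,C,G,T,N,-")
  if (is.null(rownames(m))) rownames(m) <- paste0("hap", seq_len(nrow(m)))
  structure(list(seq = m, n = nrow(m), L = ncol(m), label = label),
            class = "hap_alignment")
}

#' Read a FASTA alignment of phased haplotypes
#'
#' All records must have the same length; gaps (`-`) and `N` are allowed and
#' are excluded site-wise from every statistic downstream.
#'
#' @param path FASTA file.
#' @param label strain/locus label attached to the alignment.
#' @return a `hap_alignment`.
#' @export
read_fasta_alignment <- function(path, label = "") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  if (length(unique(Biostrings::width(ss))) != 1L)
    stop("ragged alignment in ", path, ": sequences have differing lengths")
  seqs <- as.character(ss)
  hap_alignment(seqs, label = label)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln a `hap_alignment`.
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln$seq)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment", if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
      ": ", x$n, " haplotypes x ", x$L, " sites\n", sep = "")
  invisible(x)
}

# ---- genotype tables --------------------------------------------------------

#' Construct a genotype matrix container
#'
#' @param geno integer matrix individuals x SNPs with values in `{0,1,2,NA}`
#'   (dosage of the counted allele).
#' @param pop population label per individual.
#' @param phenotype numeric phenotype per individual (a population-level value
#'   such as the LC95 is assigned to every member of the population).
#' @param qc optional per-SNP QC data.frame with columns `snp`, `GC50`,
#'   `GenTrain`, `CR` and optionally `allele` (the counted allele).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, pop, phenotype = NULL, qc = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be in {0, 1, 2, NA}")
  storage.mode(geno) <- "integer"
  if (length(pop) != nrow(geno)) stop("one population label per individual required")
  if (is.null(colnames(geno))) colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  if (anyDuplicated(colnames(geno))) stop("duplicated SNP names")
  if (!is.null(phenotype) && length(phenotype) != nrow(geno))
    stop("one phenotype per individual required")
  if (!is.null(qc)) {
    need <- c("snp", "GC50", "GenTrain", "CR")
    if (!all(need %in% names(qc))) stop("QC table needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(qc$snp)) stop("duplicated SNP names in QC table")
  }
  structure(list(geno = geno, pop = as.character(pop),
                 phenotype = phenotype, qc = qc),
            class = "genotype_matrix")
}

#' Read a genotype table (plus optional per-SNP QC table)
#'
#' The genotype file is tab-separated with header: `id`, `population`,
#' `phenotype`, then one column per SNP holding codes `{0,1,2}` or the
#' missing token. The QC file, if given, is tab-separated with columns
#' `snp`, `GC50`, `GenTrain`, `CR` (and optionally `allele`).
#'
#' @param path genotype TSV.
#' @param qc_path optional QC TSV.
#' @param na_token string encoding a missing genotype (default `"NA"`).
#' @return a `genotype_matrix`.
#' @export
read_genotype_table <- function(path, qc_path = NULL, na_token = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = na_token, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "population", "phenotype")
  if (!all(need %in% names(tab)))
    stop("genotype table needs leading columns: ", paste(need, collapse = ", "))
  snp_cols <- setdiff(names(tab), need)
  if (length(snp_cols) == 0L) stop("no SNP columns found")
  geno <- as.matrix(tab[, snp_cols, drop = FALSE])
  bad <- !(geno %in% c(0, 1, 2, NA))
  if (any(bad)) stop("invalid genotype code(s): ",
                     paste(unique(geno[bad]), collapse = ", "))
  rownames(geno) <- tab$id
  qc <- if (!is.null(qc_path))
    utils::read.table(qc_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
  genotype_matrix(geno, pop = tab$population, phenotype = tab$phenotype, qc = qc)
}

#' Write a genotype matrix (and QC table) to TSV
#'
#' @param gm a `genotype_matrix`.
#' @param path genotype TSV path.
#' @param qc_path optional path for the QC table.
#' @param na_token token for missing genotypes.
#' @export
write_genotype_table <- function(gm, path, qc_path = NULL, na_token = "NA") {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- rownames(gm$geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(gm$geno)))
  out <- data.frame(id = ids, population = gm$pop,
                    phenotype = if (is.null(gm$phenotype)) NA else gm$phenotype,
                    gm$geno, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na_token)
  if (!is.null(qc_path) && !is.null(gm$qc))
    utils::write.table(gm$qc, qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " SNPs, ", length(unique(x$pop)), " population(s)\n", sep = "")
  invisible(x)
}

# ---- VCF output -------------------------------------------------------------

#' Write a scanned SNP table as a minimal VCF 4.2 file
#'
#' INFO carries `FST`, `FISHER_P`, `QVAL` and the `OUTLIER` flag; per-pool
#' minor-allele frequencies are emitted as the `AF` FORMAT field of two
#' pseudo-samples `pool1` and `pool2`.
#'
#' @param snps SNP data.frame as produced by [scan_pools()] (needs `chrom`,
#'   `pos`, `major`, `minor`, `freq1`, `freq2`, `fst`, `fisher_p`, `qvalue`,
#'   `outlier`), sorted by chrom then pos.
#' @param path output path.
#' @export
write_vcf <- function(snps, path) {
  need <- c("chrom", "pos", "major", "minor", "freq1", "freq2",
            "fst", "fisher_p", "qvalue", "outlier")
  stopifnot(all(need %in% names(snps)))
  o <- order(snps$chrom, snps$pos)
  if (!identical(o, seq_len(nrow(snps))))
    stop("SNPs must be sorted by (chrom, pos) before VCF export")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=btiscan",
    '##INFO=<ID=FST,Number=1,Type=Float,Description="Pairwise pooled Fst">',
    '##INFO=<ID=FISHER_P,Number=1,Type=Float,Description="Two-sided Fisher exact P for read-count allele frequency difference">',
    '##INFO=<ID=QVAL,Number=1,Type=Float,Description="Storey q-value">',
    '##INFO=<ID=OUTLIER,Number=0,Type=Flag,Description="Empirical Fst-tail outlier with q below threshold">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Minor allele frequency from read counts">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "pool1", "pool2", sep = "\t"))
  info <- sprintf("FST=%.6g;FISHER_P=%.6g;QVAL=%.6g", snps$fst,
                  snps$fisher_p, snps$qvalue)
  info <- ifelse(snps$outlier, paste0(info, ";OUTLIER"), info)
  body <- paste(snps$chrom, snps$pos, ".", snps$major, snps$minor, ".",
                "PASS", info, "AF",
                sprintf("%.6g", snps$freq1), sprintf("%.6g", snps$freq2),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
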