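# File formats: plain genotype matrices, VCF genotypes, per-sample value
# tables, BED-like region lists, and experiment-result tables.

#' Read a genotype matrix from a plain TSV
#'
#' Expected layout: first column `sample_id`, remaining column names are the
#' physical SNV positions, entries are dosages 0/1/2 (`NA` allowed).
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric genotype entries")
  pos <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(pos)) stop("malformed header: column names must be positions")
  genotype_matrix(m, pos, ids)
}

#' Write a genotype matrix as a plain TSV
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, G$counts, check.names = FALSE)
  colnames(df) <- c("sample_id", format(G$positions, scientific = FALSE,
                                        trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Keeps biallelic SNV records only (multi-allelic sites are dropped with a
#' message) and orients dosages to the minor allele: the ALT count is used
#' when ALT is the minor allele in the sample, otherwise the REF count.
#'
#' @param path VCF path (plain or bgzipped; parsed with the vcfR package).
#' @return A [genotype_matrix()] with a `chrom` attribute (per-SNV
#'   chromosome labels).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_dropped <- sum(!biallelic)
  if (n_dropped > 0) {
    message(sprintf("dropped %d multi-allelic site(s)", n_dropped))
  }
  if (!any(biallelic)) stop("no biallelic sites in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a != "0")
  })
  # minor-allele orientation from sample frequency
  for (j in seq_len(nrow(dos))) {
    f <- mean(dos[j, ], na.rm = TRUE) / 2
    if (is.finite(f) && f > 0.5) dos[j, ] <- 2 - dos[j, ]
  }
  pos <- as.numeric(fix[biallelic, "POS"])
  G <- genotype_matrix(t(dos), pos, colnames(dos))
  ord <- order(pos)
  attr(G, "chrom") <- fix[biallelic, "CHROM"][ord]
  G
}

#' Read a per-sample value table (expression or phenotype)
#'
#' Two tab-separated columns with header `sample_id` and `value`.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_value_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(df))) {
    stop("malformed header: need columns sample_id and value")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs")
  if (!is.numeric(df$value)) stop("non-numeric values")
  stats::setNames(df$value, as.character(df$sample_id))
}

#' Read a BED-like region file
#'
#' Columns chrom, start, end and optionally name (0-based half-open input);
#' coordinates are converted to the scan's 1-based inclusive convention, so a
#' record `chr1 100 200` covers positions 101..200, i.e. (100, 200].
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed_regions <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  nm <- if (ncol(df) >= 4) as.character(df[[4]]) else rep(NA_character_,
                                                          nrow(df))
  fallback <- sprintf("region_%d", seq_len(nrow(df)))
  nm <- ifelse(is.na(nm) | nm == "", fallback, nm)
  out <- data.frame(
    chrom = as.character(df[[1]]),
    start = as.numeric(df[[2]]) + 1,
    end = as.numeric(df[[3]]),
    name = nm
  )
  if (any(out$end < out$start)) stop("malformed BED record: end < start")
  out
}

#' Write an experiment-result table
#'
#' TSV with a one-line schema header comment; read back with
#' [read_experiment_result()].
#'
#' @param x An `experiment_result` from [run_type1_table()] or
#'   [run_power_curve()].
#' @param path Output path.
#' @export
write_experiment_result <- function(x, path) {
  stopifnot(inherits(x, "experiment_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# iutest experiment_result schema=1", con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment-result table written by [write_experiment_result()]
#'
#' @param path File path.
#' @return An `experiment_result` data frame.
#' @export
read_experiment_result <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# iutest experiment_result")) {
    stop("not an iutest experiment_result file")
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  experiment_result(df)
}
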