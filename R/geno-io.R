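#' Read a genotype matrix from TSV or VCF
#'
#' Two on-disk representations are supported. The TSV dialect has one row
#' per individual with columns `id`, `species`, `tree`, `caste`, then one
#' two-character genotype column per locus (`AA`, `AB`, `BB`, `--` for
#' missing). VCF input is restricted to biallelic SNP records and the `GT`
#' field; phasing separators are ignored and half-calls (e.g. `0/.`) are
#' treated as missing. Multi-allelic records are skipped with a warning
#' reporting how many were dropped.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension when
#'   omitted.
#' @param info optional data frame (`id`, `species`, `tree`, `caste`) with
#'   sample labels for VCF input, which cannot carry them itself.
#' @return a [geno_matrix].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf"), info = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path, info)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  meta_cols <- c("id", "species", "tree", "caste")
  if (!all(meta_cols %in% names(df))) {
    stop_arg("TSV genotype file must start with columns id, species, tree, caste")
  }
  if (nrow(df) == 0L) stop_arg("genotype file contains no individuals")
  loci <- setdiff(names(df), meta_cols)
  if (length(loci) == 0L) stop_arg("genotype file contains no locus columns")
  calls <- strings_to_calls(as.matrix(df[, loci, drop = FALSE]))
  geno_matrix(calls, info = df[, meta_cols], loci = loci)
}

read_genotypes_vcf <- function(path, info = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(ref) != 1L | (nchar(alt) != 1L & !grepl(",", alt))
  if (any(multi)) {
    warning(sum(multi), " non-biallelic-SNP record(s) skipped", call. = FALSE)
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop_arg("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[keep, "CHROM"], ":", fix[keep, "POS"]
  )[is.na(ids) | ids == "."]
  # GT strings -> alt-allele counts; any half-call or '.' is missing
  clean <- gsub("\\|", "/", gt)
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), ids))
  full <- grepl("^[01]/[01]$", clean)
  counts <- (substr(clean, 1, 1) == "1") + (substr(clean, 3, 3) == "1")
  counts[!full] <- NA_integer_
  calls[] <- t(counts)
  if (!is.null(info)) {
    info <- as.data.frame(info, stringsAsFactors = FALSE)
    m <- match(rownames(calls), info$id)
    if (anyNA(m)) stop_arg("sample info is missing ids present in the VCF")
    info <- info[m, , drop = FALSE]
  }
  geno_matrix(calls, info = info, loci = ids)
}

#' Write a genotype matrix to TSV or VCF
#'
#' The TSV dialect round-trips losslessly through [read_genotypes()].
#' VCF output writes one biallelic SNP record per locus (REF `A`, ALT `C`
#' placeholder bases, unphased `GT`, missing as `./.`); individual labels
#' are not representable in VCF and are dropped.
#'
#' @param g a [geno_matrix].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(g, "geno_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- cbind(g$info, as.data.frame(calls_to_strings(g$calls),
                                      stringsAsFactors = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=antcolonykin",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", g$info$id), collapse = "\t")
    ), con)
    gt_str <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(g$calls))) {
      col <- g$calls[, j]
      gts <- ifelse(is.na(col), "./.", gt_str[col + 1L])
      writeLines(paste(c("syn", j, g$loci[j], "A", "C", ".", "PASS", ".",
                         "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}
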