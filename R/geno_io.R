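#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds an n x m gene-content (allele dosage) matrix in
#' \{0, 1, 2, NA\}, sample and marker identifiers, optional marker map
#' (chromosome, position) and the per-marker allele frequency of the counted
#' allele, computed as `mean(dosage)/2` over non-missing entries.
#'
#' @param dosage numeric matrix, samples in rows, markers in columns, values
#'   in \{0, 1, 2\} or `NA` for missing calls.
#' @param samples character vector of unique sample IDs (defaults to rownames).
#' @param markers character vector of unique marker IDs (defaults to colnames).
#' @param map optional tibble with columns `marker`, `chrom`, `pos`.
#' @return an object of class `genotype_matrix` with elements `dosage`,
#'   `samples`, `markers`, `map`, `freq`.
#' @export
genotype_matrix <- function(dosage, samples = rownames(dosage),
                            markers = colnames(dosage), map = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(dosage)))
  samples <- as.character(samples); markers <- as.character(markers)
  if (nrow(dosage) < 1L || ncol(dosage) < 1L)
    stop("genotype matrix must have at least one sample and one marker")
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  if (anyDuplicated(markers)) stop("marker IDs must be unique")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA; found: ",
         paste(unique(dosage[bad]), collapse = ", "))
  dimnames(dosage) <- list(samples, markers)
  structure(
    list(dosage = dosage, samples = samples, markers = markers,
         map = map, freq = allele_freq(dosage)),
    class = "genotype_matrix")
}

allele_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      length(x$markers), " markers\n", sep = "")
  cat("  missing calls: ", sum(is.na(x$dosage)), "\n", sep = "")
  cat("  allele freq range: [",
      sprintf("%.3f", min(x$freq)), ", ", sprintf("%.3f", max(x$freq)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from standard formats
#'
#' Reads gene-content (0/1/2) genotypes from a VCF (GT field, biallelic
#' records only; multiallelic records are skipped with a warning), a PLINK
#' text `.ped`/`.map` pair, or a plain dosage TSV (tab-separated, first row
#' marker IDs, first column sample IDs, missing coded `NA`).  Dosage counts
#' the VCF ALT allele, the PLINK minor allele, or the TSV value as stored.
#'
#' @param path file path; for `plink_text`, the `.ped` file (the `.map` is
#'   found by extension substitution) or the common prefix.
#' @param format one of `"dosage_tsv"`, `"vcf"`, `"plink_text"`; default
#'   guessed from the file extension.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("guess", "dosage_tsv", "vcf", "plink_text")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.ped$", path)) "plink_text"
      else "dosage_tsv"
  }
  if (!file.exists(path) && format != "plink_text")
    stop("file not found: ", path)
  switch(format,
    dosage_tsv = read_dosage_tsv(path),
    vcf = read_vcf_genotypes(path),
    plink_text = read_plink_text(path))
}

read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("dosage TSV needs a sample-ID column and >= 1 marker: ", path)
  samples <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(samples, colnames(mat))))
  bad <- which(!is.na(mat) & mat != "NA" & (is.na(num) | !(num %in% c(0, 1, 2))))
  if (length(bad)) {
    rowi <- (bad[1L] - 1L) %% nrow(mat) + 1L
    stop("parse error in ", path, " at data line ", rowi + 1L,
         ": value '", mat[bad[1L]], "' is not a dosage in {0,1,2} or NA")
  }
  genotype_matrix(num, samples = samples, markers = colnames(mat))
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    warning(sum(multi), " multiallelic/invalid VCF record(s) skipped")
  keep <- which(!multi)
  if (!length(keep)) stop("no usable biallelic markers in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # count ALT alleles in the GT string, phased or unphased
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(s, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- t(apply(gt, 1L, count_alt))
  if (ncol(gt) == 1L) dos <- t(dos)
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  map <- tibble::tibble(marker = ids,
                        chrom = fix[keep, "CHROM"],
                        pos = suppressWarnings(as.numeric(fix[keep, "POS"])))
  genotype_matrix(t(dos), samples = colnames(gt), markers = ids, map = map)
}

read_plink_text <- function(path) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  colnames(map)[1:4] <- c("chrom", "marker", "cm", "pos")[seq_len(min(4, ncol(map)))]
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("parse error: ", ped_path, " has ", ncol(ped),
         " columns; expected ", 6L + 2L * m, " for ", m, " markers")
  samples <- ped[[2L]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  dos <- matrix(NA_real_, nrow(ped), m, dimnames = list(samples, map$marker))
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    al[al %in% c("0", "-9", "N")] <- NA
    alleles <- sort(unique(al[!is.na(al)]))
    if (length(alleles) > 2L)
      stop("parse error: marker ", map$marker[j], " has >2 alleles")
    counts <- table(factor(al, levels = alleles))
    # counted allele = minor allele (ties: first alphabetically)
    minor <- alleles[which.min(counts)]
    dos[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
  }
  genotype_matrix(dos, samples = samples, markers = map$marker,
                  map = tibble::tibble(marker = map$marker, chrom = map$chrom,
                                       pos = suppressWarnings(as.numeric(map$pos))))
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of `read_genotypes(..., format = "dosage_tsv")`: tab-separated,
#' first row marker IDs, first column sample IDs, missing coded `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(sample_id = g$samples, g$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-class labels
#'
#' Expects a CSV with header `sample_id,class`.
#'
#' @param path CSV file path.
#' @return tibble with columns `sample_id`, `class` (`class` a factor whose
#'   levels follow first appearance).
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("labels CSV must have header sample_id,class: ", path)
  tibble::tibble(sample_id = df$sample_id,
                 class = factor(df$class, levels = unique(df$class)))
}

#' Read a pedigree table
#'
#' Expects a CSV with header `id,sire,dam`; unknown parents coded `0`,
#' empty, or `NA`.
#'
#' @param path CSV file path.
#' @return tibble with columns `id`, `sire`, `dam` (`NA` for unknown parents).
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("id", "sire", "dam") %in% names(df)))
    stop("pedigree CSV must have header id,sire,dam: ", path)
  clean <- function(x) { x[x %in% c("0", "")] <- NA; x }
  ped <- tibble::tibble(id = df$id, sire = clean(df$sire), dam = clean(df$dam))
  if (anyDuplicated(ped$id)) stop("pedigree IDs must be unique")
  ped
}

# align a labels tibble to the samples of a genotype matrix; errors on
# labelled samples absent from g, drops unlabelled samples from g
align_labels <- function(g, labels) {
  labels <- tibble::as_tibble(labels)
  missing <- setdiff(labels$sample_id, g$samples)
  if (length(missing))
    stop("labelled sample(s) not in genotype matrix: ",
         paste(head(missing, 5), collapse = ", "))
  idx <- match(labels$sample_id, g$samples)
  cls <- labels$class
  if (!is.factor(cls)) cls <- factor(cls, levels = unique(cls))
  cls <- droplevels(cls)
  if (nlevels(cls) < 2L) stop("need at least 2 classes")
  list(idx = idx, class = cls)
}

#' Quality-control filter for a genotype matrix
#'
#' Removes markers with minor allele frequency strictly below `maf_min`
#' (computed on non-missing calls; markers exactly at the threshold are kept)
#' or genotyping call rate below `geno_rate_min`, then mean-imputes the
#' remaining missing dosages to `2 * freq` per marker.  Mean imputation is
#' frequency-preserving and contributes exactly zero to centered marker
#' covariates downstream.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param geno_rate_min minimum per-marker call rate (default 0.90).
#' @param autosomes_only if `TRUE` and `g$map$chrom` is present, drop markers
#'   on X/Y/MT chromosomes.
#' @return the filtered `genotype_matrix`, with a tibble QC report in
#'   attribute `"qc_report"` (columns `marker`, `maf`, `call_rate`,
#'   `removed`, `reason`).
#' @export
qc_filter <- function(g, maf_min = 0.05, geno_rate_min = 0.90,
                      autosomes_only = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 1 || geno_rate_min < 0 || geno_rate_min > 1)
    stop("thresholds must be in [0, 1]")
  call_rate <- colMeans(!is.na(g$dosage))
  maf <- pmin(g$freq, 1 - g$freq)
  reason <- rep(NA_character_, length(g$markers))
  reason[call_rate < geno_rate_min] <- "call_rate"
  low_maf <- is.na(maf) | maf < maf_min
  reason[low_maf & is.na(reason)] <- "maf"
  sex_chrom <- rep(FALSE, length(g$markers))
  if (autosomes_only && !is.null(g$map) && "chrom" %in% names(g$map)) {
    sex_chrom <- toupper(g$map$chrom[match(g$markers, g$map$marker)]) %in%
      c("X", "Y", "MT", "M", "23", "24", "25", "26")
    reason[sex_chrom & is.na(reason)] <- "sex_chromosome"
  }
  removed <- !is.na(reason)
  report <- tibble::tibble(marker = g$markers, maf = unname(maf),
                           call_rate = unname(call_rate),
                           removed = removed, reason = reason)
  if (all(removed)) stop("all markers removed by QC")
  keep <- which(!removed)
  dos <- g$dosage[, keep, drop = FALSE]
  # mean-impute remaining missing calls to 2*freq (frequency-preserving)
  if (anyNA(dos)) {
    f <- allele_freq(dos)
    na_idx <- which(is.na(dos), arr.ind = TRUE)
    dos[na_idx] <- 2 * f[na_idx[, 2L]]
  }
  out <- g
  out$dosage <- dos
  out$markers <- g$markers[keep]
  out$freq <- colMeans(dos) / 2
  if (!is.null(out$map)) out$map <- out$map[out$map$marker %in% out$markers, ]
  attr(out, "qc_report") <- report
  out
}

#' Scan for opposing allele fixation between classes
#'
#' A marker shows opposing fixation when some class is fixed for one allele
#' (within-class frequency 0) and another class is fixed for the alternative
#' allele (frequency 1), computed over non-missing calls.  Such markers would
#' individually suffice to separate the two classes.
#'
#' @param g a [genotype_matrix()].
#' @param labels tibble with `sample_id`, `class` covering samples of `g`.
#' @return tibble of reported markers with columns `marker`, `class_fixed_0`,
#'   `class_fixed_1`; zero rows when no marker is oppositely fixed.
#' @export
scan_opposing_fixation <- function(g, labels) {
  al <- align_labels(g, labels)
  dos <- g$dosage[al$idx, , drop = FALSE]
  freq_by_class <- vapply(levels(al$class), function(k) {
    allele_freq(dos[al$class == k, , drop = FALSE])
  }, numeric(ncol(dos)))
  if (is.null(dim(freq_by_class)))
    freq_by_class <- matrix(freq_by_class, nrow = 1,
                            dimnames = list(NULL, levels(al$class)))
  at0 <- freq_by_class == 0
  at1 <- freq_by_class == 1
  hit <- which(rowSums(at0, na.rm = TRUE) > 0 & rowSums(at1, na.rm = TRUE) > 0)
  tibble::tibble(
    marker = unname(g$markers[hit]),
    class_fixed_0 = vapply(hit, function(i)
      paste(colnames(freq_by_class)[which(at0[i, ])], collapse = ";"),
      character(1), USE.NAMES = FALSE),
    class_fixed_1 = vapply(hit, function(i)
      paste(colnames(freq_by_class)[which(at1[i, ])], collapse = ";"),
      character(1), USE.NAMES = FALSE))
}

# subset a genotype matrix by sample index or ID, recomputing frequencies
subset_samples <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$samples)
  out <- g
  out$dosage <- g$dosage[idx, , drop = FALSE]
  out$samples <- g$samples[idx]
  out$freq <- allele_freq(out$dosage)
  attr(out, "qc_report") <- NULL
  out
}
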