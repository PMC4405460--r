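#' Construct a genotype dataset in code
#'
#' A genotype dataset holds a diploid dosage matrix (individuals in rows,
#' SNPs in columns; entries 0, 1, 2 or `NA` for missing) together with a
#' SNP table carrying chromosome, physical position and genetic-map (cM)
#' position, and a sample table carrying population labels.
#'
#' @param dosage Numeric matrix, individuals x SNPs, entries in
#'   `{0, 1, 2, NA}`; rownames are individual ids.
#' @param snps Data frame with columns `id`, `chromosome`, `pos_bp`,
#'   `pos_cM` (one row per column of `dosage`; `pos_cM` may be `NA` if no
#'   map is attached yet).
#' @param samples Data frame with columns `sample_id`, `population_id`
#'   (one row per row of `dosage`).
#' @return A `geno_dataset` object.
#' @export
geno_dataset <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(snps) != ncol(dosage)) {
    stop("snps table and dosage matrix disagree on SNP count")
  }
  if (nrow(samples) != nrow(dosage)) {
    stop("samples table and dosage matrix disagree on individual count")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2))) {
    bad <- which(!(dosage %in% c(0, 1, 2)) & !is.na(dosage), arr.ind = TRUE)[1, ]
    stop(sprintf("dosage value outside {0,1,2,NA} at individual %d, SNP %d",
                 bad[1], bad[2]))
  }
  snps <- data.frame(id = as.character(snps$id),
                     chromosome = as.character(snps$chromosome),
                     pos_bp = as.numeric(snps$pos_bp),
                     pos_cM = if ("pos_cM" %in% names(snps))
                       as.numeric(snps$pos_cM) else NA_real_,
                     stringsAsFactors = FALSE)
  # map positions must be non-decreasing within a chromosome
  for (chr in unique(snps$chromosome)) {
    cm <- snps$pos_cM[snps$chromosome == chr]
    cm <- cm[!is.na(cm)]
    if (length(cm) > 1 && any(diff(cm) < 0)) {
      stop(sprintf("genetic positions decrease within chromosome %s", chr))
    }
  }
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        population_id = as.character(samples$population_id),
                        stringsAsFactors = FALSE)
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  tab <- table(x$samples$population_id)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  n_cm <- sum(!is.na(x$snps$pos_cM))
  cat("SNPs with cM positions:", n_cm, "of", nrow(x$snps), "\n")
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset by population
#'
#' @param geno A `geno_dataset`.
#' @param populations Character vector of population ids to keep.
#' @return A `geno_dataset` restricted to those individuals.
#' @export
subset_populations <- function(geno, populations) {
  keep <- geno$samples$population_id %in% populations
  if (!any(keep)) stop("no individuals in requested populations")
  geno_dataset(geno$dosage[keep, , drop = FALSE], geno$snps,
               geno$samples[keep, , drop = FALSE])
}

#' Read a genetic map
#'
#' Accepts a PLINK-style `.map` file (columns chromosome, id, cM, bp,
#' whitespace-delimited, no header) or a tab-delimited file with header
#' columns `chromosome`, `cM`, `bp`. The map defines, per chromosome, a
#' monotone piecewise-linear bp-to-cM interpolation.
#'
#' @param path Path to the map file.
#' @return A `genetic_map`: a data frame with columns `chromosome`, `cM`,
#'   `bp`, sorted by chromosome and bp.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("chromosome", first, fixed = TRUE)) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    df <- df[, c("chromosome", "cM", "bp")]
  } else {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("PLINK .map needs 4 columns: chrom, id, cM, bp")
    df <- data.frame(chromosome = as.character(df[[1]]),
                     cM = as.numeric(df[[3]]), bp = as.numeric(df[[4]]),
                     stringsAsFactors = FALSE)
  }
  df$chromosome <- as.character(df$chromosome)
  df <- df[order(df$chromosome, df$bp), , drop = FALSE]
  for (chr in unique(df$chromosome)) {
    cm <- df$cM[df$chromosome == chr]
    if (any(diff(cm) < 0)) {
      stop(sprintf("genetic map not non-decreasing on chromosome %s", chr))
    }
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Interpolate cM positions from a genetic map
#'
#' Linear interpolation between map anchors; positions outside the anchor
#' range are extrapolated from the nearest anchor pair (constant beyond a
#' single-anchor chromosome).
#'
#' @param map A `genetic_map`.
#' @param chromosome Chromosome labels of the query positions.
#' @param bp Physical positions (bp).
#' @return Numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chromosome, bp) {
  chromosome <- as.character(chromosome)
  out <- rep(NA_real_, length(bp))
  for (chr in unique(chromosome)) {
    sel <- chromosome == chr
    anchors <- map[map$chromosome == chr, , drop = FALSE]
    if (nrow(anchors) == 0) {
      stop(sprintf("no genetic-map anchors for chromosome %s", chr))
    }
    if (nrow(anchors) == 1) {
      out[sel] <- anchors$cM[1]
    } else {
      out[sel] <- stats::approx(anchors$bp, anchors$cM, xout = bp[sel],
                                method = "linear", rule = 2, ties = "ordered")$y
    }
  }
  out
}

#' Read genotypes from VCF or a dosage matrix
#'
#' VCF input keeps biallelic SNP records only (multi-allelic records are
#' skipped with a message); genotypes are read from the GT field, with
#' "./." as missing. Matrix input is a tab-delimited individuals x SNPs
#' dosage table (first column `sample_id`, remaining columns named by SNP
#' id, sentinel -1 for missing) with a sidecar SNP table (`id`,
#' `chromosome`, `pos_bp`, optional `pos_cM`).
#'
#' @param path Path to the VCF (plain text) or dosage matrix file.
#' @param format `"vcf"` or `"matrix"`.
#' @param sample_map Named vector or two-column data frame mapping sample
#'   id to population id.
#' @param map Optional `genetic_map`; when given, cM positions are attached
#'   by linear interpolation.
#' @param snp_table For `format = "matrix"`, path to (or data frame of)
#'   the sidecar SNP table.
#' @return A `geno_dataset`.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix"),
                           sample_map, map = NULL, snp_table = NULL) {
  format <- match.arg(format)
  smap <- as_sample_map(sample_map)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
      nchar(ref) == 1 & nchar(alt) == 1
    n_skip <- sum(!biallelic)
    if (n_skip > 0) {
      message(n_skip, " non-biallelic-SNP record(s) skipped")
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    fix <- fix[biallelic, , drop = FALSE]
    alleles <- function(x) {
      a <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
      vapply(a, function(v) {
        if (length(v) != 2 || any(v == ".")) return(NA_real_)
        sum(as.numeric(v))
      }, numeric(1))
    }
    dos <- apply(gt, 2, alleles)
    dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
    dosage <- t(dos)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    snps <- data.frame(id = ids, chromosome = fix[, "CHROM"],
                       pos_bp = as.numeric(fix[, "POS"]), pos_cM = NA_real_,
                       stringsAsFactors = FALSE)
  } else {
    mat <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    sample_id <- as.character(mat[[1]])
    dosage <- as.matrix(mat[, -1, drop = FALSE])
    storage.mode(dosage) <- "double"
    bad <- which(!(dosage %in% c(0, 1, 2, -1)) & !is.na(dosage),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("invalid dosage %g at row %d, column %d",
                   dosage[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
    }
    dosage[dosage == -1] <- NA_real_
    rownames(dosage) <- sample_id
    if (is.null(snp_table)) stop("matrix format requires snp_table")
    snps <- if (is.data.frame(snp_table)) snp_table else
      utils::read.delim(snp_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    snps <- snps[match(colnames(dosage), snps$id), , drop = FALSE]
    if (anyNA(snps$id)) stop("snp_table missing ids present in the matrix")
    if (!"pos_cM" %in% names(snps)) snps$pos_cM <- NA_real_
  }
  if (!is.null(map)) {
    snps$pos_cM <- interpolate_cM(map, snps$chromosome, snps$pos_bp)
  }
  unknown <- setdiff(rownames(dosage), names(smap))
  if (length(unknown) > 0) {
    stop("sample(s) missing from sample_map: ", paste(unknown, collapse = ", "))
  }
  samples <- data.frame(sample_id = rownames(dosage),
                        population_id = unname(smap[rownames(dosage)]),
                        stringsAsFactors = FALSE)
  geno_dataset(dosage, snps, samples)
}
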