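#' Construct an IBD segment table in code
#'
#' Canonicalizes the sample pair to lexicographic order (swapping the
#' population labels along with the samples) and validates segment
#' coordinates. Segment coordinates are genetic-map positions in cM on a
#' per-chromosome scale; intervals are half-open `[start_cM, end_cM)`.
#'
#' @param sample_a,sample_b Individual ids.
#' @param population_a,population_b Population ids of the two samples.
#' @param chromosome Chromosome labels.
#' @param start_cM,end_cM Genetic-map coordinates of the segment (cM).
#' @return An `ibd_segments` data frame with an additional `length_cM`
#'   column equal to `end_cM - start_cM`.
#' @export
ibd_segments <- function(sample_a, sample_b, population_a, population_b,
                         chromosome, start_cM, end_cM) {
  n <- length(sample_a)
  df <- data.frame(sample_a = as.character(sample_a),
                   sample_b = as.character(sample_b),
                   population_a = as.character(population_a),
                   population_b = as.character(population_b),
                   chromosome = as.character(chromosome),
                   start_cM = as.numeric(start_cM),
                   end_cM = as.numeric(end_cM),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    bad <- which(df$end_cM <= df$start_cM)
    if (length(bad) > 0) {
      stop(sprintf("segment with end_cM <= start_cM at row %d", bad[1]))
    }
    same <- which(df$sample_a == df$sample_b)
    if (length(same) > 0) {
      stop(sprintf("segment between a sample and itself at row %d", same[1]))
    }
    swap <- df$sample_a > df$sample_b
    if (any(swap)) {
      tmp <- df$sample_a[swap]
      df$sample_a[swap] <- df$sample_b[swap]
      df$sample_b[swap] <- tmp
      tmp <- df$population_a[swap]
      df$population_a[swap] <- df$population_b[swap]
      df$population_b[swap] <- tmp
    }
  }
  df$length_cM <- df$end_cM - df$start_cM
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Read post-processed IBD segments
#'
#' Reads a tab-delimited segment table of the shape produced by fastIBD
#' post-processing (one row per detected IBD segment between a pair of
#' individuals), attaches population labels from a sample-to-population
#' mapping, and canonicalizes pair order. Segments whose samples both fall
#' outside the population table are dropped with a message.
#'
#' @param path Tab-delimited file with header columns `sample_a`,
#'   `sample_b`, `chromosome`, `start_cM`, `end_cM`.
#' @param pop_table A `pop_table`; segments are kept only when both
#'   populations appear in it.
#' @param sample_map Either a named character vector mapping individual id
#'   to population id, or a two-column data frame `(sample_id,
#'   population_id)`.
#' @return An `ibd_segments` data frame.
#' @export
read_ibd_segments <- function(path, pop_table, sample_map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_a", "sample_b", "chromosome", "start_cM", "end_cM")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  map <- as_sample_map(sample_map)
  bad <- which(as.numeric(df$end_cM) <= as.numeric(df$start_cM))
  if (length(bad) > 0) {
    stop(sprintf("end_cM <= start_cM at row %d", bad[1]))
  }
  unknown <- setdiff(unique(c(df$sample_a, df$sample_b)), names(map))
  if (length(unknown) > 0) {
    stop("sample(s) missing from sample_map: ",
         paste(unknown, collapse = ", "))
  }
  pa <- unname(map[df$sample_a])
  pb <- unname(map[df$sample_b])
  keep <- pa %in% pop_table$population_id & pb %in% pop_table$population_id
  if (any(!keep)) {
    message(sum(!keep), " segment(s) dropped: population not in table")
  }
  df <- df[keep, , drop = FALSE]
  ibd_segments(df$sample_a, df$sample_b, pa[keep], pb[keep],
               df$chromosome, df$start_cM, df$end_cM)
}

as_sample_map <- function(sample_map) {
  if (is.data.frame(sample_map)) {
    if (ncol(sample_map) < 2) stop("sample_map needs two columns")
    map <- as.character(sample_map[[2]])
    names(map) <- as.character(sample_map[[1]])
  } else {
    map <- as.character(sample_map)
    names(map) <- names(sample_map)
  }
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("sample_map must be named by sample id")
  }
  map
}

#' Read a sample-to-population mapping file
#'
#' @param path Tab-delimited two-column file with header `sample_id`,
#'   `population_id`.
#' @return Named character vector mapping sample id to population id.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  as_sample_map(df)
}

#' Write a result table as TSV
#'
#' Tab-delimited, header row, UTF-8, "." decimal separator, no quoting.
#' Numeric columns are rendered with 15 significant digits so that a
#' read-back reproduces the values to well beyond 10 significant digits.
#' An empty table writes a header-only file.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      # %.15g keeps round-trips exact to >10 significant digits and prints
      # 0 as "0", never blank
      out[[j]] <- sprintf("%.15g", out[[j]])
    }
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
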