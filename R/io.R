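#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample IDs and a first
#' column of gene IDs (the genes-as-rows convention), or the transpose with
#' `orientation = "samples_rows"`. Rows with any missing value are dropped
#' and the count logged; duplicate IDs or non-numeric cells are hard errors.
#'
#' @param path TSV file path.
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @return validated expression matrix (genes x samples) with an attribute
#'   `"dropped_genes"` listing genes removed for missing data.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stop("expression TSV needs an ID column plus data columns")
  ids <- as.character(dt[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate row IDs in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      col[col == ""] <- NA
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in %s at row '%s', column '%s'",
                     path, ids[bad[1]], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  has_na <- apply(m, 1, anyNA)
  if (any(has_na)) {
    log_msg("read_expression: dropped %d gene(s) with missing data", sum(has_na))
  }
  dropped <- rownames(m)[has_na]
  m <- m[!has_na, , drop = FALSE]
  validate_expression_matrix(m)
  attr(m, "dropped_genes") <- dropped
  m
}

#' Write an expression matrix to TSV
#'
#' @param x expression matrix (genes x samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read gene-level annotation from a GTF file
#'
#' Parses a GENCODE-style GTF via \pkg{rtracklayer} and returns one record
#' per `gene_id`. Lengths are the 1-based inclusive span of the gene
#' feature (`end - start + 1`); when a file carries no explicit `gene`
#' features the span is taken over all features of each gene. Records
#' without a `gene_type` attribute get `biotype = "unknown"`.
#'
#' @param path GTF file path.
#' @return `data.frame` with columns `gene_id`, `biotype`, `chrom`,
#'   `start`, `end`, `length_bp`, `is_coding`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  if (!any(body)) {
    warning("GTF file ", path, " has no feature lines")
    return(data.frame(gene_id = character(), biotype = character(),
                      chrom = character(), start = integer(), end = integer(),
                      length_bp = integer(), is_coding = logical(),
                      stringsAsFactors = FALSE))
  }
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield < 9)) {
    stop("malformed GTF line ", which(body)[which(nfield < 9)[1]],
         " in ", path, " (fewer than 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(md)) stop("GTF lacks gene_id attributes: ", path)
  df <- data.frame(
    gene_id = as.character(md$gene_id),
    biotype = if ("gene_type" %in% names(md)) as.character(md$gene_type) else NA_character_,
    type = if ("type" %in% names(md)) as.character(md$type) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  pick <- function(d) {
    g <- d[d$type %in% "gene", , drop = FALSE]
    if (nrow(g) == 0) {
      g <- d[1, , drop = FALSE]
      g$start <- min(d$start); g$end <- max(d$end)
    } else {
      g <- g[1, , drop = FALSE]
    }
    g
  }
  parts <- lapply(split(df, df$gene_id), pick)
  out <- do.call(rbind, parts)
  out$biotype[is.na(out$biotype) | out$biotype == ""] <- "unknown"
  out$biotype <- canonical_biotype(out$biotype)
  out$length_bp <- out$end - out$start + 1L
  out$is_coding <- out$biotype == "protein_coding"
  out$type <- NULL
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Read subtype labels from TSV
#'
#' Two-column TSV `sample_id`, `subtype`; empty or `"UNLABELED"` entries are
#' treated as unlabeled (`NA`).
#'
#' @param path TSV path.
#' @return named character vector, sample IDs as names, `NA` for unlabeled.
#' @export
read_labels <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(df) < 2) stop("labels TSV needs sample_id and subtype columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", path)
  lab <- df[[2]]
  lab[lab %in% c("", "NA", "UNLABELED")] <- NA
  setNames(lab, ids)
}

#' Read a clinical table from TSV
#'
#' Expects `sample_id` plus any of: `os_time`, `os_event`, `rfs_time`,
#' `rfs_event`, `age`, `race`, `treatment`, `stage`, `histology`, `er`,
#' `pr`, `her2`. Empty strings are missing values. Times must be
#' non-negative and event flags 0/1.
#'
#' @param path TSV path.
#' @return `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) stop("clinical TSV needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in ", path)
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  for (tc in intersect(c("os_time", "rfs_time"), names(df))) {
    if (any(df[[tc]] < 0, na.rm = TRUE)) stop(tc, " must be >= 0")
  }
  for (ec in intersect(c("os_event", "rfs_event"), names(df))) {
    if (!all(df[[ec]] %in% c(0, 1, NA))) stop(ec, " must be 0/1")
  }
  invisible(df)
}

#' Write a clinical table to TSV
#' @param clinical data.frame as from [read_clinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}

#' Write a gene-selection report to TSV
#'
#' Serializes a [recursive_select()] result as one row per selected gene:
#' `gene_id`, `iteration` (2 for the final signature, 1 for genes only in
#' the iteration-1 pool), `subtype_attribution` (semicolon-joined) and
#' `weight_magnitude` (largest absolute one-vs-rest weight). The file
#' round-trips losslessly through [read_selection_report()].
#'
#' @param result `selection_result` object (or a compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  df <- if (is.data.frame(result)) result else selection_report_frame(result)
  stopifnot(all(c("gene_id", "iteration", "subtype_attribution",
                  "weight_magnitude") %in% names(df)))
  out <- df
  out$weight_magnitude <- formatC(out$weight_magnitude, format = "g",
                                  digits = 15)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a gene-selection report written by [write_selection_report()]
#' @param path TSV path.
#' @return `data.frame` with the report columns.
#' @export
read_selection_report <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c(1, 3)))
  df$gene_id <- as.character(df$gene_id)
  df$iteration <- as.integer(df$iteration)
  df$subtype_attribution <- as.character(df$subtype_attribution)
  df$weight_magnitude <- as.numeric(df$weight_magnitude)
  df
}

# flatten a selection_result into the report table
selection_report_frame <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  genes <- union(result$iteration2_genes, result$iteration1_genes)
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(), iteration = integer(),
                      subtype_attribution = character(),
                      weight_magnitude = numeric(), stringsAsFactors = FALSE))
  }
  iter <- ifelse(genes %in% result$iteration2_genes, 2L, 1L)
  attr_str <- vapply(genes, function(g) {
    a <- result$attribution[[g]]
    if (is.null(a)) "" else paste(a, collapse = ";")
  }, "")
  wmag <- vapply(genes, function(g) {
    w <- result$weights[g]
    if (is.na(w)) 0 else unname(w)
  }, 0)
  df <- data.frame(gene_id = genes, iteration = iter,
                   subtype_attribution = attr_str, weight_magnitude = wmag,
                   stringsAsFactors = FALSE)
  df[order(-df$iteration, df$gene_id), ]
}
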