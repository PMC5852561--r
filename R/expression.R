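#' Validate an expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix with genes
#' as rows and samples as columns, unique non-empty `rownames` (gene IDs) and
#' `colnames` (sample IDs), and all values finite and non-negative.
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix")
  }
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g) > 0) {
    stop("duplicate gene IDs: ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s) > 0) {
    stop("duplicate sample IDs: ", paste(unique(dup_s), collapse = ", "))
  }
  if (any(!is.finite(x))) stop("expression values must all be finite")
  if (any(x < 0)) stop("expression values must be non-negative")
  invisible(x)
}

#' Scale every gene to a maximum of one
#'
#' Divides each gene (row) by its maximum value, the per-gene normalization
#' used before SVM training so that all features live on a common \[0, 1\]
#' scale. Genes whose maximum is not strictly positive cannot be scaled;
#' drop constant genes first (see [drop_constant_genes()]).
#'
#' @param x expression matrix (genes x samples).
#' @return matrix of the same shape with `max(row) == 1` for every gene.
#' @examples
#' m <- matrix(c(2, 4, 8), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
#' max_normalize(m)  # 0.25 0.5 1
#' @export
max_normalize <- function(x) {
  validate_expression_matrix(x)
  if (nrow(x) == 0) return(x)
  mx <- apply(x, 1, max)
  bad <- rownames(x)[mx <= 0]
  if (length(bad) > 0) {
    stop("gene(s) with non-positive maximum cannot be max-normalized: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  x / mx
}

#' Drop zero-variance genes
#'
#' Removes genes that are constant across samples (including all-zero genes,
#' which [max_normalize()] rejects). The number of dropped genes is logged.
#'
#' @param x expression matrix.
#' @return matrix restricted to non-constant genes; attribute
#'   `"dropped_genes"` holds the removed IDs.
#' @export
drop_constant_genes <- function(x) {
  validate_expression_matrix(x)
  if (nrow(x) == 0) return(x)
  keep <- apply(x, 1, function(r) max(r) > min(r))
  dropped <- rownames(x)[!keep]
  if (length(dropped) > 0) {
    log_msg("dropped %d constant gene(s)", length(dropped))
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- dropped
  out
}

#' Pool two feature blocks over shared samples
#'
#' Row-stacks two expression matrices (e.g., RNA-seq genes and a microarray
#' signature) over the intersection of their samples. Each block is
#' max-normalized independently before stacking, and feature IDs are
#' prefixed with a source tag so the namespaces stay disjoint.
#'
#' @param primary,secondary expression matrices sharing (some) samples.
#' @param tags length-2 character vector of source prefixes.
#' @return pooled expression matrix over the common samples.
#' @export
pool_features <- function(primary, secondary, tags = c("rna", "arr")) {
  validate_expression_matrix(primary)
  validate_expression_matrix(secondary)
  stopifnot(length(tags) == 2, !anyNA(tags), tags[1] != tags[2])
  common <- intersect(colnames(primary), colnames(secondary))
  if (length(common) == 0) stop("no samples shared between the two blocks")
  a <- max_normalize(primary[, common, drop = FALSE])
  b <- max_normalize(secondary[, common, drop = FALSE])
  rownames(a) <- paste(tags[1], rownames(a), sep = ":")
  rownames(b) <- paste(tags[2], rownames(b), sep = ":")
  rbind(a, b)
}

#' Biotype/length filter specification for long non-coding genes
#'
#' The default retains the six GENCODE biotypes grouped as long non-coding
#' (lincRNA, antisense, sense_intronic, sense_overlapping,
#' processed_transcript, processed_pseudogene) with a minimum annotated
#' length of 200 bp, the conventional lncRNA length cutoff.
#'
#' @param allowed_biotypes character vector of biotypes to keep.
#' @param min_length_bp minimum annotated feature span in bp (>= 1).
#' @return object of class `biotype_filter_spec`.
#' @export
biotype_filter_spec <- function(allowed_biotypes = LNC_BIOTYPES,
                                min_length_bp = 200L) {
  allowed_biotypes <- canonical_biotype(allowed_biotypes)
  if (length(allowed_biotypes) == 0) stop("allowed_biotypes must be non-empty")
  min_length_bp <- as.integer(min_length_bp)
  if (is.na(min_length_bp) || min_length_bp < 1L) {
    stop("min_length_bp must be a positive integer")
  }
  structure(list(allowed_biotypes = unique(allowed_biotypes),
                 min_length_bp = min_length_bp),
            class = "biotype_filter_spec")
}

#' GENCODE biotypes grouped as long non-coding
#' @export
LNC_BIOTYPES <- c("lincRNA", "antisense", "sense_intronic",
                  "sense_overlapping", "processed_transcript",
                  "processed_pseudogene")

# tolerate the common misspelling of processed_transcript
canonical_biotype <- function(x) {
  x <- as.character(x)
  x[x == "processed_transcripted"] <- "processed_transcript"
  x
}

#' Filter an expression matrix by biotype and length
#'
#' Keeps exactly the genes whose annotated biotype is in
#' `spec$allowed_biotypes` and whose annotated length is at least
#' `spec$min_length_bp`. Genes absent from the annotation are dropped with
#' a warning (count logged); samples are untouched.
#'
#' @param x expression matrix.
#' @param annotation gene annotation `data.frame` from [read_annotation()]
#'   (columns `gene_id`, `biotype`, `length_bp`).
#' @param spec a [biotype_filter_spec()].
#' @return filtered expression matrix.
#' @export
filter_noncoding <- function(x, annotation, spec = biotype_filter_spec()) {
  validate_expression_matrix(x)
  stopifnot(inherits(spec, "biotype_filter_spec"),
            all(c("gene_id", "biotype", "length_bp") %in% names(annotation)))
  ann <- annotation[!duplicated(annotation$gene_id), , drop = FALSE]
  idx <- match(rownames(x), ann$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " gene(s) absent from annotation were dropped")
    log_msg("filter_noncoding: %d gene(s) not in annotation", sum(missing))
  }
  biotype <- canonical_biotype(ann$biotype[idx])
  keep <- !missing &
    biotype %in% spec$allowed_biotypes &
    ann$length_bp[idx] >= spec$min_length_bp
  x[keep, , drop = FALSE]
}
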