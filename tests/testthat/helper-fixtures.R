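# 4-class Gaussian blobs in which each class has `npc` private features
# (shifted only in that class) on top of `p_null` pure-noise features.
# Values are shifted positive so the matrix passes expression validation.
make_blobs <- function(n_per_class = 20, npc = 1, p_null = 4, shift = 5,
                       classes = SUBTYPE_LEVELS, seed = 1) {
  set.seed(seed)
  K <- length(classes)
  n <- n_per_class * K
  p <- npc * K + p_null
  X <- matrix(abs(rnorm(p * n)), p, n)
  labels <- rep(classes, each = n_per_class)
  private <- split(seq_len(npc * K), rep(seq_len(K), each = npc))
  for (k in seq_len(K)) {
    X[private[[k]], labels == classes[k]] <-
      X[private[[k]], labels == classes[k]] + shift
  }
  dimnames(X) <- list(sprintf("g%02d", seq_len(p)),
                      sprintf("s%03d", seq_len(n)))
  names(labels) <- colnames(X)
  list(X = X, labels = labels,
       private = lapply(private, function(i) rownames(X)[i]))
}

# write a small GENCODE-style GTF with gene features
write_test_gtf <- function(df, path) {
  attrs <- ifelse(is.na(df$biotype),
                  sprintf('gene_id "%s";', df$gene_id),
                  sprintf('gene_id "%s"; gene_type "%s";',
                          df$gene_id, df$biotype))
  writeLines(paste(df$chrom, "test", "gene", df$start, df$end,
                   ".", "+", ".", attrs, sep = "\t"), path)
  path
}

# small expression TSV on disk
write_test_expr_tsv <- function(path, mat, ids = rownames(mat)) {
  df <- data.frame(gene_id = ids, mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# default-condition synthetic cohort at reduced size for unit tests
small_cohort <- function(seed = 1, n = 120, p = 200) {
  gen_cohort(sim_spec(n_samples = n, n_genes = p, seed = seed))
}
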