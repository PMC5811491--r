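`%||%` <- function(x, y) if (is.null(x)) y else x

# canonical key for an unordered gene pair (symbols never contain tabs)
edge_key <- function(from, to) paste(from, to, sep = "\t")

# extract the member symbols from a gene_set or a raw character vector
as_symbols <- function(x, context = NULL) {
  if (inherits(x, "gene_set")) return(x$members)
  sort(unique(normalize_symbols(x, context = context)))
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# small deterministic child-seed derivation so one pipeline seed can drive
# several independent generator calls (kept well below .Machine$integer.max)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919L * k) %% 2147483647)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
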