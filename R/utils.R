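# Internal helpers shared across modules.

# Coerce a wide expression tibble (first column = gene ids, remaining columns =
# samples) or a numeric matrix with dimnames into a genes x samples matrix.
as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
    }
    m <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort(sprintf("`%s` needs one identifier column plus sample columns.", arg))
    }
    ids <- as.character(x[[1]])
    body <- x[-1]
    bad <- names(body)[!vapply(body, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric expression column(s) in `%s`: %s",
        arg, paste(head(bad, 3), collapse = ", ")
      ))
    }
    m <- as.matrix(body)
    rownames(m) <- ids
  } else {
    abort(sprintf("`%s` must be a data frame or a numeric matrix.", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("Duplicate gene identifiers in `%s`.", arg))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("Duplicate sample identifiers in `%s`.", arg))
  }
  if (anyNA(m)) {
    abort(sprintf("`%s` contains missing values; see `read_expression(impute_missing=)`.", arg))
  }
  storage.mode(m) <- "double"
  m
}

# Wide tibble view of a genes x samples matrix.
expr_as_tibble <- function(m) {
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

# Validate / normalise a signature tibble: columns gene, sign in {-1, +1}.
as_signature <- function(sig, arg = "signature") {
  if (!is.data.frame(sig) || !all(c("gene", "sign") %in% names(sig))) {
    abort(sprintf("`%s` must be a data frame with columns `gene` and `sign`.", arg))
  }
  sig <- tibble(gene = trimws(as.character(sig$gene)), sign = as.integer(sig$sign))
  if (!all(sig$sign %in% c(-1L, 1L))) {
    abort(sprintf("`%s$sign` must be +1 or -1.", arg))
  }
  sig <- dplyr::distinct(sig)
  conflict <- sig$gene[duplicated(sig$gene)]
  if (length(conflict) > 0) {
    abort(sprintf(
      "Conflicting sign for gene(s): %s",
      paste(head(unique(conflict), 5), collapse = ", ")
    ))
  }
  if (nrow(sig) < 2) abort(sprintf("`%s` needs at least 2 genes.", arg))
  sig
}

# Prior-sign lookup for a set of genes, preserving the order of `genes`.
signature_signs <- function(sig, genes) {
  idx <- match(genes, sig$gene)
  if (anyNA(idx)) {
    abort(sprintf(
      "Gene(s) absent from signature: %s",
      paste(head(genes[is.na(idx)], 5), collapse = ", ")
    ))
  }
  sig$sign[idx]
}

# Run `expr` under a locally-seeded RNG when `seed` is given; otherwise leave
# the caller's RNG stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Paired two-sided Wilcoxon signed-rank p-value with the all-zero-differences
# convention p = 1 (identical inputs carry no evidence either way).
paired_wilcoxon_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) return(1)
  suppressWarnings(wilcox.test(x, y, paired = TRUE, alternative = "two.sided")$p.value)
}

# Coerce an activity profile (tibble with sample/score or bare numeric) to a
# named score vector.
as_score_vector <- function(x, arg = "scores") {
  if (is.data.frame(x)) {
    if (!all(c("sample", "score") %in% names(x))) {
      abort(sprintf("`%s` must have columns `sample` and `score`.", arg))
    }
    setNames(as.numeric(x$score), as.character(x$sample))
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    abort(sprintf("`%s` must be an activity tibble or a numeric vector.", arg))
  }
}
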