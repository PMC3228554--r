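#' Read a gene expression matrix from delimited text
#'
#' Reads a tab- or comma-delimited table with one header row and one identifier
#' column into the package's wide expression form: a tibble with a `gene`
#' column followed by one numeric column per sample (log-scale expression is
#' assumed throughout the package but not enforced here).
#'
#' Duplicate gene rows are collapsed by their mean (a message reports how
#' many); duplicate sample identifiers are an error. Rows whose every value is
#' non-numeric are dropped with a message; a row that is only partially
#' numeric is an error naming the offending cell.
#'
#' @param path Path to a TSV/CSV file. The delimiter is sniffed from the
#'   header line (tab wins over comma).
#' @param orientation `"genes_in_rows"` (default) if rows are genes and columns
#'   samples, `"samples_in_rows"` for the transpose. Loading a transposed file
#'   with the other flag yields the identical table.
#' @param impute_missing If `TRUE`, missing cells are imputed with the
#'   per-gene median (a message reports the count). Default `FALSE`: missing
#'   values are an error, since downstream correlations assume complete
#'   pairwise vectors.
#' @return A tibble: column `gene` plus one numeric column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3\ts4", "A\t1\t2\t3\t4", "B\t4\t3\t2\t1"), tf)
#' read_expression(tf)
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            impute_missing = FALSE) {
  orientation <- rlang::arg_match(orientation)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, trim_ws = TRUE,
                           name_repair = "minimal")
  if (ncol(raw) < 2) abort("Expression file needs an identifier column plus data columns.")
  ids <- trimws(as.character(raw[[1]]))
  body <- raw[-1]

  num <- purrr::map(body, ~ suppressWarnings(as.numeric(.x)))
  m <- do.call(cbind, num)
  colnames(m) <- names(body)

  introduced <- is.na(m) & !is.na(as.matrix(body)) & as.matrix(body) != "NA"
  all_bad <- rowSums(!is.na(m)) == 0
  if (any(all_bad)) {
    inform(sprintf("Dropped %d row(s) with no numeric values.", sum(all_bad)))
    m <- m[!all_bad, , drop = FALSE]
    ids <- ids[!all_bad]
    introduced <- introduced[!all_bad, , drop = FALSE]
  }
  if (any(introduced)) {
    w <- which(introduced, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Unparseable value at row '%s', column '%s'.",
      ids[w[1]], colnames(m)[w[2]]
    ))
  }
  rownames(m) <- ids

  if (orientation == "samples_in_rows") {
    m <- t(m)
  }
  if (anyDuplicated(colnames(m))) {
    abort("Duplicate sample identifiers in expression file.")
  }
  if (anyDuplicated(rownames(m))) {
    dup_n <- sum(duplicated(rownames(m)))
    inform(sprintf("Collapsed %d duplicate gene row(s) by mean.", dup_n))
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  if (anyNA(m)) {
    if (!impute_missing) {
      abort("Missing values in expression data; set `impute_missing = TRUE` to impute per-gene medians.")
    }
    n_miss <- sum(is.na(m))
    for (i in which(rowSums(is.na(m)) > 0)) {
      m[i, is.na(m[i, ])] <- median(m[i, ], na.rm = TRUE)
    }
    inform(sprintf("Imputed %d missing value(s) with per-gene medians.", n_miss))
  }
  if (nrow(m) < 1) abort("No usable gene rows in expression file.")
  expr_as_tibble(m)
}

#' Read a pathway signature
#'
#' A signature maps genes to the sign of their expected regulation upon
#' pathway activation: `+1` (up) or `-1` (down). Either a single two-column
#' table (`gene`, `sign`) is read from `path`, or two plain one-gene-per-line
#' list files are given via `up` / `down` (either may be omitted: a signature
#' may be all-up or all-down).
#'
#' Recognised sign tokens: `1`, `+1`, `-1`, `up`, `down` (case-insensitive).
#' A gene listed twice with the same sign is deduplicated; with conflicting
#' signs it is an error.
#'
#' @param path Path to a two-column delimited file (no header required; a
#'   header line whose second field is not a sign token is skipped).
#' @param up,down Paths to plain gene-list files, one gene per line.
#' @return A tibble with columns `gene` (character) and `sign` (integer).
#' @export
read_signature <- function(path = NULL, up = NULL, down = NULL) {
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) abort("Empty signature file.")
    fields <- strsplit(lines, "[\t,]")
    ok <- vapply(fields, length, integer(1)) >= 2
    if (!all(ok)) abort("Signature rows must have two columns: gene, sign.")
    gene <- trimws(vapply(fields, `[[`, character(1), 1))
    token <- tolower(trimws(vapply(fields, `[[`, character(1), 2)))
    # allow one header line
    if (token[1] %in% c("sign", "direction", "regulation")) {
      gene <- gene[-1]; token <- token[-1]
    }
    if (length(gene) == 0) abort("Empty signature file.")
    sign_map <- c("1" = 1L, "+1" = 1L, "up" = 1L, "-1" = -1L, "down" = -1L)
    if (!all(token %in% names(sign_map))) {
      abort(sprintf(
        "Unrecognised sign token(s): %s",
        paste(head(unique(token[!token %in% names(sign_map)]), 3), collapse = ", ")
      ))
    }
    sig <- tibble(gene = gene, sign = unname(sign_map[token]))
  } else {
    read_list <- function(p) {
      if (is.null(p)) return(character(0))
      x <- trimws(readLines(p))
      x[nzchar(x)]
    }
    sig <- dplyr::bind_rows(
      tibble(gene = read_list(up), sign = 1L),
      tibble(gene = read_list(down), sign = -1L)
    )
    if (nrow(sig) == 0) abort("Empty signature: no genes in `up`/`down` lists.")
  }
  sig <- dplyr::distinct(sig)
  conflict <- unique(sig$gene[duplicated(sig$gene)])
  if (length(conflict) > 0) {
    abort(sprintf(
      "Conflicting sign for gene(s): %s",
      paste(head(conflict, 5), collapse = ", ")
    ))
  }
  sig
}

#' Write / read a relevance network as edge + node tables
#'
#' The interchange format is two UTF-8, LF-terminated TSVs: an edge list
#' (`gene_a`, `gene_b`, `cor`, `observed_sign`, `predicted_sign`,
#' `consistent`) and a node table (`gene`, `degree`, `prior_sign`). The pair
#' of files round-trips topology, signs and degrees losslessly.
#'
#' @param net A `relevance_network` or `dart_component` object.
#' @param dir Output directory (created if absent); files are written as
#'   `<prefix>_edges.tsv` and `<prefix>_nodes.tsv`.
#' @param prefix File-name prefix, default `"network"`.
#' @return `write_network()` invisibly returns the two file paths;
#'   `read_network()` returns a list with tibbles `edges` and `nodes`.
#' @export
write_network <- function(net, dir, prefix = "network") {
  edges <- if (inherits(net, "dart_component")) net$edges else net$edges
  nodes <- network_node_table(net)
  edge_out <- dplyr::select(
    edges,
    gene_a = "gene_a", gene_b = "gene_b", cor = "cor",
    observed_sign = "obs_sign", predicted_sign = "pred_sign",
    consistent = "consistent"
  )
  edge_out$consistent <- as.integer(edge_out$consistent)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_edges.tsv"))
  np <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  readr::write_tsv(edge_out, ep)
  readr::write_tsv(nodes, np)
  invisible(c(edges = ep, nodes = np))
}

network_node_table <- function(net) {
  nodes <- net$nodes
  deg <- rep(0L, nrow(nodes))
  if (nrow(net$edges) > 0) {
    cnt <- table(c(net$edges$gene_a, net$edges$gene_b))
    deg <- as.integer(cnt[nodes$gene])
    deg[is.na(deg)] <- 0L
  }
  tibble(gene = nodes$gene, degree = deg, prior_sign = nodes$sign)
}

#' @rdname write_network
#' @export
read_network <- function(dir, prefix = "network") {
  ep <- file.path(dir, paste0(prefix, "_edges.tsv"))
  np <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  edges <- readr::read_tsv(ep, col_types = readr::cols(
    gene_a = "c", gene_b = "c", cor = "d",
    observed_sign = "i", predicted_sign = "i", consistent = "i"
  ), progress = FALSE)
  nodes <- readr::read_tsv(np, col_types = readr::cols(
    gene = "c", degree = "i", prior_sign = "i"
  ), progress = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Write an activity profile as TSV
#'
#' @param activity An activity tibble (`sample`, `score`, `method`, ...).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_activity <- function(activity, path) {
  readr::write_tsv(activity, path)
  invisible(path)
}
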