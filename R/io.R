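#' Read per-state expression tables
#'
#' Each file is a TSV/CSV with gene identifiers in the first column and one
#' sample per remaining column. Rows sharing a gene identifier are merged by
#' their mean; the gene universe is harmonized to the identifiers common to
#' all states (in the order of the first file), with a warning when genes
#' are dropped.
#'
#' @param paths character vector of file paths, one per state.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.csv` means comma, otherwise tab).
#' @return list with `x` (list of genes x samples matrices sharing row
#'   names), `gene_ids`, and `n` (sample sizes).
#' @export
read_expression_tables <- function(paths, sep = NULL) {
  if (!length(paths)) stop("at least one expression file is required")
  tabs <- lapply(paths, function(path) {
    s <- if (is.null(sep)) {
      if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    } else sep
    df <- utils::read.table(path, header = TRUE, sep = s,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression file needs a gene column plus samples: ", path)
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!apply(df[, -1L, drop = FALSE], 2L, is.numeric))[1L]
      stop("non-numeric values in column '", colnames(df)[-1L][bad],
           "' of ", path)
    }
    if (anyDuplicated(genes)) {
      vals <- rowsum(vals, group = genes, reorder = FALSE) /
        as.vector(table(factor(genes, levels = unique(genes))))
      genes <- unique(genes)
    }
    rownames(vals) <- genes
    vals
  })
  common <- rownames(tabs[[1L]])
  for (tab in tabs[-1L]) common <- common[common %in% rownames(tab)]
  if (!length(common)) stop("no gene identifiers shared across all states")
  dropped <- sum(vapply(tabs, nrow, integer(1L))) - length(common) * length(tabs)
  if (dropped > 0) {
    warning(dropped, " gene rows dropped while harmonizing states to ",
            length(common), " shared genes")
  }
  x <- lapply(tabs, function(tab) tab[common, , drop = FALSE])
  list(x = x, gene_ids = common, n = vapply(x, ncol, integer(1L)))
}

#' Read a GMT pathway file
#'
#' Standard GMT dialect: one pathway per line, tab-separated, with the name
#' and description in the first two fields and gene symbols after.
#'
#' @param path GMT file path.
#' @param gene_ids optional expression gene universe; pathway genes absent
#'   from it are dropped (a message reports the count) and pathways are
#'   returned as index vectors into `gene_ids`.
#' @return named list of character vectors (or integer index vectors when
#'   `gene_ids` is given; emptied pathways are removed).
#' @export
read_gmt <- function(path, gene_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", ln, ": need name, description and >= 1 gene")
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  if (!is.null(gene_ids)) {
    total_dropped <- 0L
    sets <- lapply(sets, function(s) {
      idx <- match(s, gene_ids)
      total_dropped <<- total_dropped + sum(is.na(idx))
      sort(idx[!is.na(idx)])
    })
    if (total_dropped > 0) {
      message(total_dropped, " pathway genes absent from the expression data were dropped")
    }
    sets <- sets[vapply(sets, length, integer(1L)) > 0L]
  }
  sets
}

#' Read an undirected edge list (two-column TSV or SIF)
#'
#' Two-column files are read as `gene_a <tab> gene_b`; three-column files
#' are treated as SIF (`source  interaction  target`). Duplicates and
#' reversed duplicates collapse; self-loops are dropped.
#'
#' @param path file path.
#' @return two-column character matrix of unique undirected edges.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- matrix(character(0), 0L, 2L)
  for (ln in seq_along(lines)) {
    fields <- strsplit(trimws(lines[ln]), "[\t ]+")[[1L]]
    pair <- if (length(fields) == 2L) fields
            else if (length(fields) >= 3L) fields[c(1L, 3L)]
            else stop("malformed edge list line ", ln)
    edges <- rbind(edges, pair)
  }
  if (!nrow(edges)) return(unname(edges))
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "\r"))
  unname(edges[!duplicated(key), , drop = FALSE])
}

#' Write estimated networks as edge lists
#'
#' Writes one `state<k>_edges.tsv` per state (`gene_a`, `gene_b`, `weight`,
#' upper triangle, exact zeros omitted, sorted by gene pair) and one
#' `differential_<k>_<k'>.tsv` per state pair with the signed differences.
#' Writes are atomic (temporary file, then rename).
#'
#' @param fit a `wfpgl` fit.
#' @param out_dir output directory (created if needed).
#' @param tol difference tolerance for the differential lists.
#' @return invisibly, the vector of files written.
#' @export
write_networks <- function(fit, out_dir, tol = 1e-8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- fit$gene_ids
  written <- character(0)
  for (k in seq_len(fit$K)) {
    m <- fit$networks[[k]]
    idx <- which(upper.tri(m) & m != 0)
    ij <- arrayInd(idx, dim(m))
    df <- data.frame(gene_a = ids[ij[, 1L]], gene_b = ids[ij[, 2L]],
                     weight = signif(m[idx], 10), stringsAsFactors = FALSE)
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    written <- c(written, atomic_write_tsv(df, file.path(out_dir,
      sprintf("state%d_edges.tsv", k))))
  }
  if (fit$K >= 2L) {
    pr <- utils::combn(fit$K, 2L)
    for (q in seq_len(ncol(pr))) {
      de <- differential_edges(fit$networks[[pr[1L, q]]],
                               fit$networks[[pr[2L, q]]],
                               tol = tol, gene_ids = ids)
      de$difference <- signif(de$difference, 10)
      written <- c(written, atomic_write_tsv(de, file.path(out_dir,
        sprintf("differential_%d_%d.tsv", pr[1L, q], pr[2L, q]))))
    }
  }
  invisible(written)
}

#' Write a JSON run report
#'
#' @param report named list (configuration, iteration counts, residuals...).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Write a scenario to disk in analysis-ready form
#'
#' Emits per-state expression TSVs, the pathway collection as a GMT file,
#' the prior network as an edge list, and per-state ground-truth edge lists,
#' so a simulated directory can be fed straight back through
#' [read_expression_tables()], [read_gmt()] and [read_edge_list()].
#'
#' @param scenario a [wfpgl_scenario()] object.
#' @param out_dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- scenario$gene_ids
  written <- character(0)
  for (k in seq_along(scenario$x)) {
    m <- scenario$x[[k]]
    df <- data.frame(gene = ids, signif(m, 10), check.names = FALSE)
    colnames(df)[-1L] <- sprintf("s%d", seq_len(ncol(m)))
    written <- c(written, atomic_write_tsv(df, file.path(out_dir,
      sprintf("expression_state%d.tsv", k))))
  }
  gmt <- vapply(seq_along(scenario$pathways), function(t) {
    paste(c(sprintf("pathway%02d", t), "simulated",
            ids[scenario$pathways[[t]]]), collapse = "\t")
  }, character(1L))
  gmt_path <- file.path(out_dir, "pathways.gmt")
  tmp <- tempfile(tmpdir = out_dir)
  writeLines(gmt, tmp)
  file.rename(tmp, gmt_path)
  written <- c(written, gmt_path)
  g <- scenario$prior
  idx <- which(upper.tri(g) & g != 0)
  ij <- arrayInd(idx, dim(g))
  prior_df <- data.frame(gene_a = ids[ij[, 1L]], gene_b = ids[ij[, 2L]])
  written <- c(written, atomic_write_tsv(prior_df,
    file.path(out_dir, "prior_edges.tsv")))
  for (k in seq_along(scenario$truth$M_weighted)) {
    mw <- scenario$truth$M_weighted[[k]] * scenario$Q
    idx <- which(upper.tri(mw) & mw != 0)
    ij <- arrayInd(idx, dim(mw))
    df <- data.frame(gene_a = ids[ij[, 1L]], gene_b = ids[ij[, 2L]],
                     weight = signif(mw[idx], 10))
    written <- c(written, atomic_write_tsv(df, file.path(out_dir,
      sprintf("truth_state%d_edges.tsv", k))))
  }
  invisible(written)
}
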