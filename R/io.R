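#' Read and write expression datasets, edge lists and SIF files
#'
#' All formats are tab-separated UTF-8 text. Header lines beginning `#`
#' carry provenance (package version, writing parameters and a config hash)
#' and are ignored on read. Expression matrices have genes as rows (first
#' column the gene identifier) and samples as columns; the sample metadata
#' sidecar has one row per sample. Edge lists have columns
#' `parent child sign weight` over a declared gene universe; SIF files use
#' `parent activates|inhibits child`.
#'
#' @name mikana_io
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("mikana"))
}

# FNV-1a hash of the canonical parameter string, for provenance lines.
config_hash <- function(params) {
  s <- paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                   character(1)),
             sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

provenance_lines <- function(what, params = list()) {
  c(sprintf("# mikana %s: %s", pkg_version(), what),
    sprintf("# config_hash: %s", config_hash(params)))
}

strip_comments <- function(lines) {
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' @rdname mikana_io
#' @param data An `expression_dataset`.
#' @param matrix_path Path of the expression matrix file.
#' @param meta_path Path of the sample-metadata file.
#' @export
write_expression <- function(data, matrix_path, meta_path) {
  prov <- provenance_lines("expression matrix",
                           list(genes = nrow(data$matrix),
                                samples = ncol(data$matrix),
                                noise = data$noise_level))
  con <- file(matrix_path, "w")
  writeLines(prov, con)
  writeLines(paste(c("gene", colnames(data$matrix)), collapse = "\t"), con)
  utils::write.table(data$matrix, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  close(con)
  meta <- data$sample_meta
  meta$noise_level <- data$noise_level
  con <- file(meta_path, "w")
  writeLines(provenance_lines("sample metadata", list(samples = nrow(meta))), con)
  suppressWarnings(utils::write.table(meta, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  close(con)
  invisible(c(matrix_path, meta_path))
}

#' @rdname mikana_io
#' @return `read_expression` returns a validated `expression_dataset` with
#'   gene order as in the file; duplicated gene (probe) identifiers are
#'   permitted but flagged with a warning.
#' @export
read_expression <- function(matrix_path, meta_path) {
  lines <- strip_comments(readLines(matrix_path))
  if (!length(lines)) stop_mikana("%s: empty expression file", matrix_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop_mikana("%s: duplicated sample ids: %s", matrix_path,
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    warning(sprintf("%s: duplicated gene ids kept as-is: %s", matrix_path,
                    paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  m <- matrix(NA_real_, length(rows), length(sample_ids),
              dimnames = list(genes, sample_ids))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1]
    if (length(vals) != length(sample_ids)) {
      stop_mikana("%s line %d: %d values for %d samples", matrix_path, i + 1,
                  length(vals), length(sample_ids))
    }
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      stop_mikana("%s line %d: non-numeric cell '%s'", matrix_path, i + 1,
                  vals[which(is.na(num))[1]])
    }
    m[i, ] <- num
  }
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            na.strings = "NA")
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing)) {
    stop_mikana("%s: metadata missing for sample(s): %s", meta_path,
                paste(missing, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  noise <- if ("noise_level" %in% names(meta) && nrow(meta)) {
    meta$noise_level[1]
  } else 0
  expression_dataset(m, meta[setdiff(names(meta), "noise_level")],
                     noise_level = noise %||% 0)
}

#' @rdname mikana_io
#' @param net A `gene_network`.
#' @param path File path.
#' @export
write_edges <- function(net, path) {
  con <- file(path, "w")
  writeLines(provenance_lines("edge list",
                              list(genes = length(net$genes),
                                   edges = nrow(net$edges))), con)
  writeLines(paste0("# genes: ", paste(net$genes, collapse = " ")), con)
  writeLines("parent\tchild\tsign\tweight", con)
  e <- net$edges
  if (nrow(e)) {
    ord <- order(e$parent, e$child)
    utils::write.table(
      data.frame(parent = net$genes[e$parent[ord]],
                 child = net$genes[e$child[ord]],
                 sign = e$sign[ord], weight = e$weight[ord]),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  close(con)
  invisible(path)
}

#' @rdname mikana_io
#' @param genes Optional gene universe (character); defaults to the universe
#'   declared in the file's `# genes:` header, or to the identifiers seen.
#' @return `read_edges` and `read_sif` return a `gene_network`. Self-loop
#'   rows are dropped and duplicated edges deduplicated, each with a
#'   warning; malformed rows raise an error naming the line.
#' @export
read_edges <- function(path, genes = NULL) {
  raw <- readLines(path)
  gl <- grep("^# genes: ", raw, value = TRUE)
  if (is.null(genes) && length(gl)) {
    genes <- strsplit(sub("^# genes: ", "", gl[1]), " ", fixed = TRUE)[[1]]
  }
  lines <- strip_comments(raw)
  if (length(lines) && identical(strsplit(lines[1], "\t")[[1]][1], "parent")) {
    lines <- lines[-1]
  }
  parse_edge_rows(lines, path, genes, sif = FALSE)
}

parse_edge_rows <- function(lines, path, genes, sif) {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (sif) 3L else 3L
  parent <- character(0); child <- character(0)
  sign <- integer(0); weight <- numeric(0)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < need) {
      stop_mikana("%s line %d: expected at least %d fields", path, i, need)
    }
    if (sif) {
      if (!r[2] %in% c("activates", "inhibits")) {
        stop_mikana("%s line %d: unknown relation '%s'", path, i, r[2])
      }
      parent <- c(parent, r[1]); child <- c(child, r[3])
      sign <- c(sign, if (r[2] == "activates") 1L else -1L)
      weight <- c(weight, NA_real_)
    } else {
      s <- suppressWarnings(as.integer(r[3]))
      if (is.na(s) && r[3] != "NA") {
        stop_mikana("%s line %d: bad sign '%s'", path, i, r[3])
      }
      w <- if (length(r) >= 4) suppressWarnings(as.numeric(r[4])) else NA_real_
      parent <- c(parent, r[1]); child <- c(child, r[2])
      sign <- c(sign, s); weight <- c(weight, w)
    }
  }
  if (is.null(genes)) genes <- unique(c(parent, child))
  bad <- setdiff(c(parent, child), genes)
  if (length(bad)) {
    stop_mikana("%s: gene(s) outside declared universe: %s", path,
                paste(unique(bad), collapse = ", "))
  }
  pi <- match(parent, genes); ci <- match(child, genes)
  self <- pi == ci
  if (any(self)) {
    warning(sprintf("%s: dropped %d self-loop row(s)", path, sum(self)))
    pi <- pi[!self]; ci <- ci[!self]; sign <- sign[!self]; weight <- weight[!self]
  }
  dup <- duplicated(paste(pi, ci))
  if (any(dup)) {
    warning(sprintf("%s: deduplicated %d repeated edge(s)", path, sum(dup)))
    pi <- pi[!dup]; ci <- ci[!dup]; sign <- sign[!dup]; weight <- weight[!dup]
  }
  gene_network(genes, data.frame(parent = pi, child = ci,
                                 sign = sign, weight = weight))
}

#' @rdname mikana_io
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  con <- file(path, "w")
  if (nrow(e)) {
    ord <- order(e$parent, e$child)
    writeLines(sprintf("%s\t%s\t%s",
                       net$genes[e$parent[ord]],
                       ifelse(e$sign[ord] == -1L, "inhibits", "activates"),
                       net$genes[e$child[ord]]), con)
  }
  close(con)
  invisible(path)
}

#' @rdname mikana_io
#' @export
read_sif <- function(path, genes = NULL) {
  lines <- strip_comments(readLines(path))
  parse_edge_rows(lines, path, genes, sif = TRUE)
}

#' @rdname mikana_io
#' @param score An `edge_score`.
#' @export
write_score_report <- function(score, path) {
  con <- file(path, "w")
  writeLines(provenance_lines("edge score report", score[c("tp", "fp", "fn")]), con)
  writeLines("metric\tvalue", con)
  writeLines(sprintf("%s\t%s",
                     c("tp", "fp", "fn", "sensitivity", "fdr"),
                     c(score$tp, score$fp, score$fn,
                       ifelse(is.na(score$sensitivity), "undefined", score$sensitivity),
                       ifelse(is.na(score$fdr), "undefined", score$fdr))), con)
  close(con)
  invisible(path)
}
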