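## Readers/writers for every file the pipeline touches. Canonical internal
## orientation is samples-as-rows; classic OTU-table files are OTUs-as-rows.

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                               trim = TRUE),
         format(signif(x, 6), scientific = FALSE, trim = TRUE))
}

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

# parse a TSV with row ids in column 1 into a numeric matrix, with strict
# validation that names offending line numbers (1-based, incl. header)
parse_id_matrix <- function(path) {
  cells <- read_tsv_lines(path)
  header <- cells[[1]]
  ncol_expect <- length(header)
  col_ids <- header[-1]
  if (anyDuplicated(col_ids)) {
    stop("duplicate column ids in ", path, ": ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  n <- length(cells) - 1L
  if (n < 1) stop("no data rows in ", path)
  row_ids <- character(n)
  m <- matrix(NA_real_, n, length(col_ids))
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncol_expect) {
      stop("ragged row at line ", i + 1L, " of ", path, ": expected ",
           ncol_expect, " fields, found ", length(row))
    }
    row_ids[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      stop("non-numeric value at line ", i + 1L, " of ", path)
    }
    if (any(v < 0)) {
      stop("negative value at line ", i + 1L, " of ", path)
    }
    m[i, ] <- v
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  dimnames(m) <- list(row_ids, col_ids)
  m
}

write_id_matrix <- function(m, path, corner = "#ID") {
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
}

#' Read a classic tab-separated OTU table
#'
#' Accepts either orientation. When `metadata` is supplied the orientation
#' is detected by intersecting row/column ids with the metadata sample ids;
#' otherwise the classic dialect (OTUs as rows, samples as columns) is
#' assumed. The returned matrix is always samples-as-rows.
#'
#' @param path TSV file; first column holds ids, header row holds the other
#'   axis; an optional leading `#OTU ID` corner label is tolerated.
#' @param metadata optional data.frame with a `sample_id` column, used for
#'   orientation detection.
#' @return numeric matrix, samples as rows, OTUs as columns.
#' @export
read_otu_table <- function(path, metadata = NULL) {
  m <- parse_id_matrix(path)
  samples_as_rows <- FALSE
  if (!is.null(metadata)) {
    ids <- metadata$sample_id
    row_hits <- length(intersect(rownames(m), ids))
    col_hits <- length(intersect(colnames(m), ids))
    samples_as_rows <- row_hits >= col_hits
  }
  if (!samples_as_rows) m <- t(m)
  m
}

#' Write an OTU table in the classic dialect (OTUs as rows)
#' @param table samples-as-rows matrix.
#' @param path output TSV path.
#' @export
write_otu_table <- function(table, path) {
  write_id_matrix(t(table), path, corner = "#OTU ID")
}

#' Read a BIOM-JSON OTU table (optional path; requires the biomformat
#' package). Returns samples-as-rows.
#' @param path BIOM (JSON dialect) file.
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the biomformat package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  t(m)
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
           "species")
RANK_PREFIX <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")

#' Read greengenes-style lineage strings
#'
#' Two-column TSV: OTU id, then a `k__X; p__Y; ...` lineage. Rank prefixes
#' are stripped; empty or missing ranks become `"unclassified"`.
#' @param path TSV file.
#' @return data.frame with `otu_id` and the seven canonical rank columns.
#' @export
read_lineages <- function(path) {
  cells <- read_tsv_lines(path)
  # tolerate an optional header line
  if (identical(tolower(cells[[1]][1]), "otu_id") ||
      grepl("^#", cells[[1]][1])) cells <- cells[-1]
  out <- data.frame(otu_id = vapply(cells, `[[`, "", 1),
                    stringsAsFactors = FALSE)
  for (r in RANKS) out[[r]] <- "unclassified"
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) < 2) next
    parts <- trimws(strsplit(cells[[i]][2], ";", fixed = TRUE)[[1]])
    for (p in parts[nzchar(parts)]) {
      if (!grepl("^[a-z]__", p)) {
        stop("unknown rank prefix in lineage '", p, "' (line ", i, ")")
      }
      key <- substr(p, 1, 1)
      if (!key %in% names(RANK_PREFIX)) {
        stop("unknown rank prefix '", key, "__' (line ", i, ")")
      }
      val <- sub("^[a-z]__", "", p)
      if (nzchar(val)) out[i, RANK_PREFIX[[key]]] <- val
    }
  }
  if (anyDuplicated(out$otu_id)) stop("duplicate OTU ids in ", path)
  out
}

#' Write a taxonomy map as greengenes-style lineage strings
#' @param taxonomy data.frame as returned by [read_lineages()].
#' @param path output TSV path.
#' @export
write_lineages <- function(taxonomy, path) {
  pref <- stats::setNames(names(RANK_PREFIX), RANK_PREFIX)
  lines <- vapply(seq_len(nrow(taxonomy)), function(i) {
    fields <- vapply(RANKS, function(r) {
      v <- taxonomy[[r]][i]
      paste0(pref[[r]], "__", if (identical(v, "unclassified")) "" else v)
    }, "")
    paste(taxonomy$otu_id[i], paste(fields, collapse = "; "), sep = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read / write sample metadata (sample_id, group, gender)
#' @param path TSV with header `sample_id  group  gender`.
#' @export
read_metadata <- function(path) {
  cells <- read_tsv_lines(path)
  header <- tolower(cells[[1]])
  need <- c("sample_id", "group", "gender")
  if (!all(need %in% header)) {
    stop("metadata must have columns sample_id, group, gender")
  }
  idx <- match(need, header)
  rows <- cells[-1]
  if (!length(rows)) stop("no data rows in ", path)
  out <- data.frame(
    sample_id = vapply(rows, `[[`, "", idx[1]),
    group = vapply(rows, `[[`, "", idx[2]),
    gender = vapply(rows, `[[`, "", idx[3]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in ", path)
  out
}

#' @rdname read_metadata
#' @param metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read / write a gene-content matrix (OTUs as rows, functions as columns)
#' @param path TSV path.
#' @export
read_gene_content <- function(path) parse_id_matrix(path)

#' @rdname read_gene_content
#' @param gc OTU x function matrix.
#' @export
write_gene_content <- function(gc, path) {
  write_id_matrix(gc, path, corner = "#OTU ID")
}

#' Read / write the function hierarchy
#'
#' Flat 4-column TSV (`function_id`, `level3`, `level2`, `level1`), one row
#' per (function, level-3 pathway) pair; a function may map to several
#' level-3 pathways, each level-3 pathway to exactly one level-2 parent.
#' @param path TSV path.
#' @export
read_hierarchy <- function(path) {
  cells <- read_tsv_lines(path)
  if (identical(tolower(cells[[1]][1]), "function_id")) cells <- cells[-1]
  if (!length(cells)) stop("no data rows in ", path)
  bad <- which(lengths(cells) != 4)
  if (length(bad)) stop("hierarchy rows must have 4 fields (line ",
                        bad[1] + 1L, ")")
  h <- data.frame(function_id = vapply(cells, `[[`, "", 1),
                  level3 = vapply(cells, `[[`, "", 2),
                  level2 = vapply(cells, `[[`, "", 3),
                  level1 = vapply(cells, `[[`, "", 4),
                  stringsAsFactors = FALSE)
  chk <- unique(h[, c("level3", "level2")])
  if (anyDuplicated(chk$level3)) {
    stop("a level-3 pathway maps to more than one level-2 parent")
  }
  h
}

#' @rdname read_hierarchy
#' @param hierarchy data.frame as returned by [read_hierarchy()].
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy[, c("function_id", "level3", "level2",
                                   "level1")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write an organism-trait table (OTUs x traits, memberships in
#' `[0,1]`)
#' @param path TSV path.
#' @export
read_traits <- function(path) {
  m <- parse_id_matrix(path)
  if (any(m > 1)) stop("trait memberships must lie in [0,1]")
  m
}

#' @rdname read_traits
#' @param traits OTU x trait matrix.
#' @export
write_traits <- function(traits, path) {
  write_id_matrix(traits, path, corner = "#OTU ID")
}

#' Write a predicted function profile (samples as rows)
#' @param profile samples x functions matrix.
#' @param path TSV path.
#' @export
write_profile <- function(profile, path) {
  write_id_matrix(profile, path, corner = "#Sample ID")
}

#' @rdname write_profile
#' @export
read_profile <- function(path) parse_id_matrix(path)

#' Export a functional network
#'
#' Writes the edge list (function pair, correlation, permutation p) as TSV
#' and, optionally, the graph as GraphML.
#' @param net an igraph network from [build_network()].
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML path.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  df <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(net, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Write a full synthetic bundle to a directory
#' @param bundle a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             copy_numbers = file.path(dir, "copy_numbers.tsv"),
             gene_content = file.path(dir, "gene_content.tsv"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             traits = file.path(dir, "traits.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  write_otu_table(bundle$otu_table, paths["otu_table"])
  write_lineages(bundle$taxonomy, paths["taxonomy"])
  utils::write.table(data.frame(otu_id = names(bundle$copy_numbers),
                                copies = unname(bundle$copy_numbers)),
                     paths["copy_numbers"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_content(bundle$gene_content, paths["gene_content"])
  write_hierarchy(bundle$hierarchy, paths["hierarchy"])
  write_traits(bundle$traits, paths["traits"])
  write_metadata(bundle$metadata, paths["metadata"])
  paths
}

#' Read 16S copy numbers (otu_id, copies TSV)
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_copy_numbers <- function(path) {
  cells <- read_tsv_lines(path)
  if (identical(tolower(cells[[1]][1]), "otu_id")) cells <- cells[-1]
  if (!length(cells)) stop("no data rows in ", path)
  v <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 2)))
  if (anyNA(v)) stop("non-numeric copy number in ", path)
  stats::setNames(v, vapply(cells, `[[`, "", 1))
}
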