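#' Read a genes x samples expression (or beta) matrix from TSV
#'
#' The first column holds gene (or probe) identifiers, remaining columns
#' one sample each. Duplicate identifiers and missing cells are hard
#' errors naming the offending row.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an id column plus samples")
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop(sprintf("duplicate gene id '%s' at data line %d", ids[dup[1]],
                 dup[1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in expression TSV")
  na_row <- which(rowSums(is.na(m)) > 0)
  if (length(na_row) > 0)
    stop(sprintf("missing value(s) at data line %d (gene '%s')",
                 na_row[1], ids[na_row[1]]))
  rownames(m) <- ids
  m
}

#' Write a genes x samples matrix as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the identifier column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_col = "gene_id") {
  stop_if_not_matrix(mat)
  vals <- apply(mat, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(mat))
  df <- data.frame(id = rownames(mat), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival records from CSV
#'
#' Expects columns `sample`, `time`, `event`.
#'
#' @param path CSV file path.
#' @return A validated data.frame (`sample`, `time`, `event`).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df)))
    stop("survival CSV must have columns sample, time, event")
  validate_records(df[, c("sample", "time", "event")])
}

#' Write survival records to CSV
#'
#' @param records data.frame `sample`, `time`, `event`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(records, path) {
  validate_records(records)
  write.table(records[, c("sample", "time", "event")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Lines with fewer than 3 fields are hard errors naming the line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    sets[[fields[1]]] <- fields[-(1:2)]
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network's regulons as a GMT file
#'
#' One set per regulon, named after its TF; with `signed = TRUE` members
#' carry a `+`/`-` suffix for their mode of action.
#'
#' @param network a `regnet`.
#' @param path output path.
#' @param signed append mode suffixes.
#' @param size_filtered write only regulons passing the size filter.
#' @return `path`, invisibly.
#' @export
write_regulons_gmt <- function(network, path, signed = FALSE,
                               size_filtered = TRUE) {
  regs <- regulons(network, size_filtered = size_filtered)
  sets <- lapply(regs, function(r) {
    if (signed)
      paste0(names(r$mode), ifelse(r$mode > 0, "+", "-"))
    else
      names(r$mode)
  })
  write_gmt(sets, path)
}

#' Write a network's edges as TSV
#'
#' Columns: `tf`, `target`, `mi`, `mode`, `p_adj` when built from a
#' `regnet`; a raw edge data.frame is written as is.
#'
#' @param network a `regnet` (or an edge data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  df <- if (inherits(network, "regnet")) {
    do.call(rbind, lapply(network$regulons, function(r)
      data.frame(tf = r$tf, target = names(r$mode), mi = unname(r$targets),
                 mode = unname(r$mode), stringsAsFactors = FALSE)))
  } else {
    network
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' TF-target edges with MI weight and mode attributes, for network
#' viewers.
#'
#' @param network a `regnet`.
#' @param path output path.
#' @param size_filtered export only regulons passing the size filter.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, size_filtered = TRUE) {
  regs <- regulons(network, size_filtered = size_filtered)
  if (length(regs) == 0) stop("no regulon to export")
  edges <- do.call(rbind, lapply(regs, function(r)
    data.frame(from = r$tf, to = names(r$mode), weight = unname(r$targets),
               mode = unname(r$mode), stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a probe-to-gene map from TSV
#'
#' Expects columns `probe`, `gene`; each probe must map to exactly one
#' gene.
#'
#' @param path TSV file path.
#' @return data.frame `probe`, `gene`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(df)))
    stop("probe map TSV must have columns probe, gene")
  dup <- which(duplicated(df$probe))
  if (length(dup) > 0)
    stop(sprintf("probe '%s' mapped more than once (data line %d)",
                 df$probe[dup[1]], dup[1]))
  df[, c("probe", "gene")]
}

#' Write a probe-to-gene map to TSV
#'
#' @param probe_map data.frame `probe`, `gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(probe_map, path) {
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  write.table(probe_map[, c("probe", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a planted truth to JSON
#'
#' @param truth a [generate_truth()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- list(regulons = lapply(truth$regulons, as.list),
              cluster_of = as.list(truth$cluster_of),
              non_mr_tfs = truth$non_mr_tfs,
              tfs = truth$tfs, genes = truth$genes,
              config = unclass(truth$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read signed regulons from a GMT file into a network object
#'
#' Inverse of [write_regulons_gmt()] with `signed = TRUE`: member suffixes
#' `+`/`-` become modes of action. Unsuffixed members default to mode +1.
#'
#' @param path GMT file path.
#' @param universe optional gene universe; defaults to all genes seen in
#'   the file.
#' @param min_size regulon size filter recorded on the network.
#' @return A `regnet` (MI weights are unavailable from GMT and set to 1).
#' @export
read_regulons_gmt <- function(path, universe = NULL, min_size = 15) {
  sets <- read_gmt(path)
  regs <- lapply(names(sets), function(tf) {
    members <- sets[[tf]]
    mode <- ifelse(grepl("-$", members), -1L, 1L)
    gene <- sub("[+-]$", "", members)
    list(tf = tf, targets = setNames(rep(1, length(gene)), gene),
         mode = setNames(mode, gene), size = length(gene),
         pass_size = length(gene) >= min_size)
  })
  names(regs) <- names(sets)
  if (is.null(universe))
    universe <- sort(unique(c(names(sets),
                              unlist(lapply(regs, function(r)
                                names(r$mode))))))
  structure(list(regulons = regs, universe = universe,
                 params = list(min_size = min_size, source = path)),
            class = "regnet")
}
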