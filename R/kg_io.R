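#' Column dialect for triplet files
#'
#' A SemMedDB-style triplet table has six columns: subject concept id,
#' predicate label, object concept id, subject mapping score, object mapping
#' score, and co-occurrence count. Files from other sources can rearrange
#' these; a dialect names the source column (by position) for each field.
#'
#' @param subject_id,predicate,object_id,subject_score,object_score,cooccurrence
#'   1-based column positions in the file.
#' @param sep Field separator (default tab).
#' @param header Logical: does the file carry a header line? If `NA`
#'   (default) the first line is inspected: it is treated as a header when
#'   the score columns are non-numeric.
#' @return A list of class `kg_dialect`.
#' @export
kg_dialect <- function(subject_id = 1L, predicate = 2L, object_id = 3L,
                       subject_score = 4L, object_score = 5L,
                       cooccurrence = 6L, sep = "\t", header = NA) {
  d <- list(subject_id = subject_id, predicate = predicate,
            object_id = object_id, subject_score = subject_score,
            object_score = object_score, cooccurrence = cooccurrence,
            sep = sep, header = header)
  cols <- unlist(d[1:6])
  if (anyDuplicated(cols) || any(cols < 1L)) {
    stop("dialect column positions must be distinct positive integers")
  }
  structure(d, class = "kg_dialect")
}

#' Read a triplet file
#'
#' Parses a tabular file of \[subject-predicate-object\] predications with
#' their confidence metadata into a triplet data frame with columns
#' `subject_id`, `predicate`, `object_id`, `subject_score`, `object_score`,
#' `cooccurrence` (one row per record, in file order).
#'
#' @param path Path to the triplet file.
#' @param dialect A [kg_dialect()] describing the column layout.
#' @return A `data.frame` of triplet records.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("C01\tTREATS\tC02\t800\t900\t5",
#'              "C01\tCAUSES\tC03\t700\t650\t2"), tf)
#' read_triplets(tf)
read_triplets <- function(path, dialect = kg_dialect()) {
  if (!file.exists(path)) stop("triplet file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ncol_needed <- max(unlist(dialect[1:6]))
  first_data <- 1L
  if (length(lines)) {
    fields1 <- strsplit(lines[[1L]], dialect$sep, fixed = TRUE)[[1L]]
    is_header <- if (is.na(dialect$header)) {
      length(fields1) >= ncol_needed &&
        anyNA(suppressWarnings(as.numeric(
          fields1[c(dialect$subject_score, dialect$object_score,
                    dialect$cooccurrence)])))
    } else dialect$header
    if (isTRUE(is_header)) first_data <- 2L
  }
  out <- empty_triplets()
  if (first_data > length(lines)) return(out)
  data_lines <- lines[first_data:length(lines)]
  parts <- strsplit(data_lines, dialect$sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < ncol_needed)
  if (length(bad)) {
    stop("parse error at line ", bad[1L] + first_data - 1L,
         ": expected at least ", ncol_needed, " fields, found ", nf[bad[1L]])
  }
  get_col <- function(j) vapply(parts, `[[`, "", j)
  num_col <- function(j, what) {
    raw <- get_col(j)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      i <- which(is.na(val))[1L]
      stop("parse error at line ", i + first_data - 1L,
           ": non-numeric ", what, " '", raw[i], "'")
    }
    val
  }
  rec <- data.frame(
    subject_id    = get_col(dialect$subject_id),
    predicate     = get_col(dialect$predicate),
    object_id     = get_col(dialect$object_id),
    subject_score = num_col(dialect$subject_score, "subject score"),
    object_score  = num_col(dialect$object_score, "object score"),
    cooccurrence  = num_col(dialect$cooccurrence, "co-occurrence count"),
    stringsAsFactors = FALSE
  )
  validate_triplets(rec)
  rec
}

empty_triplets <- function() {
  data.frame(subject_id = character(), predicate = character(),
             object_id = character(), subject_score = numeric(),
             object_score = numeric(), cooccurrence = numeric(),
             stringsAsFactors = FALSE)
}

validate_triplets <- function(rec) {
  stopifnot(is.data.frame(rec))
  need <- c("subject_id", "predicate", "object_id",
            "subject_score", "object_score", "cooccurrence")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("triplet table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(rec)) {
    if (any(!nzchar(rec$subject_id)) || any(!nzchar(rec$object_id))) {
      stop("empty subject or object identifier")
    }
    if (any(rec$subject_score < 0) || any(rec$object_score < 0)) {
      stop("mapping scores must be nonnegative")
    }
    if (any(rec$cooccurrence < 1)) stop("co-occurrence counts must be >= 1")
  }
  invisible(rec)
}

#' Build a knowledge graph from triplet records
#'
#' Aggregates duplicate (subject, predicate, object) records -- summing
#' co-occurrence counts and taking the maximum of the mapping scores -- and
#' indexes the result as a heterogeneous graph whose adjacency entries are
#' (predicate, neighbour) pairs. Reaching the same neighbour through two
#' different predicates yields two distinct entries. In undirected mode
#' (the default) every triplet also contributes the reverse entry with the
#' same scores, so random walks never strand at sink vertices.
#'
#' @param records Triplet data frame as returned by [read_triplets()].
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return An object of class `kg_graph` with elements `vertices`,
#'   `predicates`, `edges` (the aggregated records), `adj` (flat adjacency
#'   table with integer ids), `adj_index` (per-vertex row indices into
#'   `adj`), `entity_index`, `predicate_index`, and `mode`.
#' @export
build_graph <- function(records, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  validate_triplets(records)
  if (!nrow(records)) stop("cannot build a graph from zero records")

  key <- paste(records$subject_id, records$predicate, records$object_id,
               sep = "\r")
  grp <- match(key, unique(key))
  edges <- records[!duplicated(key), , drop = FALSE]
  edges$cooccurrence <- as.numeric(
    tapply(records$cooccurrence, grp, sum)[as.character(seq_len(nrow(edges)))])
  edges$subject_score <- as.numeric(
    tapply(records$subject_score, grp, max)[as.character(seq_len(nrow(edges)))])
  edges$object_score <- as.numeric(
    tapply(records$object_score, grp, max)[as.character(seq_len(nrow(edges)))])
  rownames(edges) <- NULL

  vertices <- sort(unique(c(edges$subject_id, edges$object_id)))
  predicates <- sort(unique(edges$predicate))
  entity_index <- stats::setNames(seq_along(vertices), vertices)
  predicate_index <- stats::setNames(seq_along(predicates), predicates)

  s <- entity_index[edges$subject_id]
  o <- entity_index[edges$object_id]
  p <- predicate_index[edges$predicate]
  eid <- seq_len(nrow(edges))
  if (mode == "undirected") {
    adj <- data.frame(from = c(s, o), pred = c(p, p), to = c(o, s),
                      edge_id = c(eid, eid))
  } else {
    adj <- data.frame(from = s, pred = p, to = o, edge_id = eid)
  }
  adj_index <- split(seq_len(nrow(adj)), factor(adj$from,
                                                levels = seq_along(vertices)))
  structure(list(vertices = vertices, predicates = predicates, edges = edges,
                 adj = adj, adj_index = adj_index,
                 entity_index = entity_index,
                 predicate_index = predicate_index, mode = mode),
            class = "kg_graph")
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("kg_graph: %d vertices, %d predicates, %d aggregated triplets (%s)\n",
              length(x$vertices), length(x$predicates), nrow(x$edges), x$mode))
  invisible(x)
}

#' Neighbourhood of a vertex
#'
#' Returns the (predicate, neighbour) adjacency entries of `v` as a data
#' frame with columns `predicate`, `neighbor`, `edge_id`.
#'
#' @param graph A `kg_graph`.
#' @param v Vertex identifier.
#' @export
neighborhood <- function(graph, v) {
  idx <- graph$entity_index[[v]]
  if (is.null(idx)) stop("unknown vertex: ", v)
  rows <- graph$adj_index[[idx]]
  data.frame(predicate = graph$predicates[graph$adj$pred[rows]],
             neighbor = graph$vertices[graph$adj$to[rows]],
             edge_id = graph$adj$edge_id[rows],
             stringsAsFactors = FALSE)
}

#' Write an embedding table in word2vec text format
#'
#' First line is `<vocabulary size> <dimension>`; each subsequent line is an
#' identifier followed by its vector components.
#'
#' @param table Numeric matrix with one row per identifier (rownames are the
#'   identifiers).
#' @param path Output path.
#' @param digits Significant digits for the components (default 8).
#' @export
write_embeddings <- function(table, path, digits = 8L) {
  stopifnot(is.matrix(table), nrow(table) >= 1L, !is.null(rownames(table)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table), ncol(table)), con)
  body <- apply(table, 1L, function(v)
    paste(formatC(v, digits = digits, format = "g"), collapse = " "))
  writeLines(paste(rownames(table), body), con)
  invisible(path)
}

#' Read an embedding table in word2vec text format
#'
#' @param path Path to the embedding file.
#' @return Numeric matrix with identifiers as rownames.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file")
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed embedding header")
  nvec <- hdr[1L]; dim <- hdr[2L]
  if (length(lines) - 1L != nvec) {
    stop("embedding file declares ", nvec, " vectors but contains ",
         length(lines) - 1L)
  }
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  ids <- vapply(parts, `[[`, "", 1L)
  bad <- which(lengths(parts) != dim + 1L)
  if (length(bad)) {
    stop("row for '", ids[bad[1L]], "' has ", lengths(parts)[bad[1L]] - 1L,
         " components, expected ", dim)
  }
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  if (anyNA(mat)) stop("non-numeric embedding component")
  rownames(mat) <- ids
  mat
}
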