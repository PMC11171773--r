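# Enumerations shared by the PKN data model.
PKN_SIGNS      <- c("activation", "repression", "unknown")
PKN_MECHANISMS <- c("transcriptional_regulation", "ppi", "metabolic",
                    "correlation", "virtual")
NODE_KINDS     <- c("gene", "protein", "complex", "metabolite")

# Mechanisms that carry direction. PPI and correlation edges are undirected:
# complexes signal both ways, correlations are symmetric by construction.
DIRECTED_MECHANISMS <- c("transcriptional_regulation", "metabolic", "virtual")

#' Construct a signed prior knowledge network
#'
#' A `knowledge_network` holds the signed, mechanism-typed interaction map that
#' every downstream analysis runs against: nodes (genes, proteins, complexes,
#' metabolites), a multiset of edges with regulatory sign, interaction
#' mechanism and a literature-derived influence-factor (IF) reliability score,
#' and the current IF threshold used to flag low-confidence edges.
#'
#' @param edges data frame with columns `source`, `target`, `sign`,
#'   `mechanism`, `if_score`, `reference`. Missing optional columns are filled
#'   (`sign` "unknown", `mechanism` "transcriptional_regulation",
#'   `if_score` 1, `reference` "").
#' @param nodes optional data frame with columns `id` and `kind`; nodes
#'   appearing only in `edges` are added with kind "gene".
#' @param members named list mapping complex node ids to character vectors of
#'   member node ids.
#' @param if_threshold IF score below which edges are flagged low-confidence
#'   (default 0.86).
#' @return An object of class `knowledge_network` with components `nodes`
#'   (data frame `id`, `kind`), `edges` (data frame with sign, mechanism,
#'   `if_score`, `reference`, `low_confidence`, `directed`), `members`, and
#'   `if_threshold`.
#' @examples
#' net <- knowledge_network(data.frame(
#'   source = "soxR", target = "soxS",
#'   sign = "activation", mechanism = "transcriptional_regulation",
#'   if_score = 0.95, reference = "demo"))
#' net
#' @export
knowledge_network <- function(edges, nodes = NULL, members = list(),
                              if_threshold = 0.86) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    stopifnot(all(c("source", "target") %in% names(edges)))
  } else {
    edges <- data.frame(source = character(), target = character())
  }
  if (is.null(edges$sign)) edges$sign <- rep("unknown", nrow(edges))
  if (is.null(edges$mechanism)) {
    edges$mechanism <- rep("transcriptional_regulation", nrow(edges))
  }
  if (is.null(edges$if_score)) edges$if_score <- rep(1, nrow(edges))
  if (is.null(edges$reference)) edges$reference <- rep("", nrow(edges))

  bad_sign <- !(edges$sign %in% PKN_SIGNS)
  if (any(bad_sign)) {
    warning(sprintf("%d edge(s) with unrecognized sign mapped to 'unknown': %s",
                    sum(bad_sign),
                    paste(unique(edges$sign[bad_sign]), collapse = ", ")))
    edges$sign[bad_sign] <- "unknown"
  }
  bad_mech <- !(edges$mechanism %in% PKN_MECHANISMS)
  if (any(bad_mech)) {
    stop("unrecognized mechanism: ",
         paste(unique(edges$mechanism[bad_mech]), collapse = ", "))
  }
  edges$if_score <- as.numeric(edges$if_score)
  if (anyNA(edges$if_score) || any(edges$if_score < 0)) {
    stop("if_score must be numeric and non-negative")
  }
  edges$directed <- edges$mechanism %in% DIRECTED_MECHANISMS
  edges$low_confidence <- edges$if_score < if_threshold

  self_cor <- edges$mechanism == "correlation" & edges$source == edges$target
  if (any(self_cor)) stop("correlation self-loops are not allowed")

  ids <- unique(c(edges$source, edges$target, names(members),
                  if (!is.null(nodes)) nodes$id))
  kind <- rep("gene", length(ids))
  names(kind) <- ids
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "kind") %in% names(nodes)))
    if (anyDuplicated(nodes$id)) stop("duplicate node ids in node table")
    if (!all(nodes$kind %in% NODE_KINDS)) stop("unrecognized node kind")
    kind[nodes$id] <- nodes$kind
  }
  kind[names(members)] <- "complex"
  node_df <- data.frame(id = ids, kind = unname(kind),
                        stringsAsFactors = FALSE)

  for (cx in names(members)) {
    if (length(members[[cx]]) == 0L) {
      stop("complex '", cx, "' has no members")
    }
  }

  structure(list(nodes = node_df, edges = edges, members = members,
                 if_threshold = if_threshold),
            class = "knowledge_network")
}

#' @export
print.knowledge_network <- function(x, ...) {
  cat(sprintf("knowledge_network: %d nodes, %d edges (IF threshold %.2f, %d low-confidence)\n",
              nrow(x$nodes), nrow(x$edges), x$if_threshold,
              sum(x$edges$low_confidence)))
  tab <- table(x$edges$mechanism)
  for (m in names(tab)) cat(sprintf("  %-27s %d\n", m, tab[[m]]))
  invisible(x)
}

#' Read a prior knowledge network from disk
#'
#' Supported dialects: `tsv` (tab-separated edge table with header columns
#' `source`, `target`, `sign`, `mechanism`, `if_score`, `reference`), `sif`
#' (Cytoscape simple interaction format, `source<TAB>sign<TAB>target...`), and
#' `graphml` (attribute names mirror the TSV columns). Unknown sign strings
#' map to `"unknown"` with a warning; a row referencing fewer than the
#' required columns raises a parse error naming the line.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param if_threshold IF reliability threshold (default 0.86).
#' @return A [knowledge_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, dialect = c("tsv", "sif", "graphml"),
                         if_threshold = 0.86) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path)
    if (length(lines) == 0L || all(!nzchar(lines))) {
      return(knowledge_network(data.frame(source = character(),
                                          target = character()),
                               if_threshold = if_threshold))
    }
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    required <- c("source", "target", "sign", "mechanism", "if_score",
                  "reference")
    if (!all(required %in% header)) {
      stop("TSV network header must contain: ",
           paste(setdiff(required, header), collapse = ", "))
    }
    body <- lines[-1L][nzchar(lines[-1L])]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < length(header))) {
      stop("malformed network row at line ",
           which(nf < length(header))[1L] + 1L)
    }
    mat <- do.call(rbind, fields)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
    suppressWarnings(df$if_score <- as.numeric(df$if_score))
    if (anyNA(df$if_score)) {
      stop("non-numeric if_score at line ", which(is.na(df$if_score))[1L] + 1L)
    }
    knowledge_network(df[, required], if_threshold = if_threshold)
  } else if (dialect == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      return(knowledge_network(data.frame(source = character(),
                                          target = character()),
                               if_threshold = if_threshold))
    }
    fields <- strsplit(lines, "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) stop("malformed SIF row at line ", which(nf < 3L)[1L])
    # SIF allows several targets per row: source relation t1 t2 ...
    rows <- lapply(fields, function(f) {
      data.frame(source = f[1L], sign = f[2L], target = f[-(1:2)],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$mechanism <- "transcriptional_regulation"
    df$if_score <- 1
    df$reference <- ""
    knowledge_network(df[, c("source", "target", "sign", "mechanism",
                             "if_score", "reference")],
                      if_threshold = if_threshold)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ea <- igraph::as_data_frame(g, what = "edges")
    names(ea)[names(ea) == "from"] <- "source"
    names(ea)[names(ea) == "to"] <- "target"
    keep <- intersect(c("source", "target", "sign", "mechanism", "if_score",
                        "reference"), names(ea))
    knowledge_network(ea[, keep, drop = FALSE], if_threshold = if_threshold)
  }
}

#' Write a prior knowledge network as a TSV edge table
#'
#' Writes the canonical six-column edge table. IF scores are written with
#' full precision so that a read/write/read round trip reproduces the edge
#' multiset bit-exactly.
#'
#' @param net a [knowledge_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  out <- data.frame(source = e$source, target = e$target, sign = e$sign,
                    mechanism = e$mechanism,
                    if_score = sprintf("%.17g", e$if_score),
                    reference = e$reference, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag low-confidence edges by influence-factor score
#'
#' Edges whose IF score falls strictly below `threshold` are marked
#' `low_confidence = TRUE`; no edge is removed. Downstream path search skips
#' flagged edges by default but the network itself stays intact.
#'
#' @param net a [knowledge_network()].
#' @param threshold non-negative IF cutoff (default 0.86).
#' @return The network with refreshed `low_confidence` flags and
#'   `if_threshold` set to `threshold`.
#' @export
filter_by_if <- function(net, threshold = 0.86) {
  stopifnot(inherits(net, "knowledge_network"), threshold >= 0)
  net$edges$low_confidence <- net$edges$if_score < threshold
  net$if_threshold <- threshold
  net
}

#' Expand complex nodes with virtual member edges
#'
#' Adds, for every complex node, one directed member-to-complex edge per
#' member with mechanism `"virtual"` and sign `"activation"`, so signals can
#' flow from components into the assembled regulator. Original edges are
#' untouched. The direction is a modeling choice (see the methods vignette)
#' and can be reversed.
#'
#' @param net a [knowledge_network()] whose `members` list declares complexes.
#' @param direction `"member_to_complex"` (default) or `"complex_to_member"`.
#' @return The expanded network.
#' @export
expand_virtual <- function(net, direction = c("member_to_complex",
                                              "complex_to_member")) {
  direction <- match.arg(direction)
  stopifnot(inherits(net, "knowledge_network"))
  if (length(net$members) == 0L) return(net)
  ids <- net$nodes$id
  new_edges <- lapply(names(net$members), function(cx) {
    mem <- net$members[[cx]]
    missing <- setdiff(mem, ids)
    if (length(missing) > 0L) {
      stop("complex '", cx, "' has unknown member(s): ",
           paste(missing, collapse = ", "))
    }
    if (direction == "member_to_complex") {
      data.frame(source = mem, target = cx, stringsAsFactors = FALSE)
    } else {
      data.frame(source = cx, target = mem, stringsAsFactors = FALSE)
    }
  })
  new_edges <- do.call(rbind, new_edges)
  new_edges$sign <- "activation"
  new_edges$mechanism <- "virtual"
  new_edges$if_score <- 1
  new_edges$reference <- "virtual_expansion"
  new_edges$directed <- TRUE
  new_edges$low_confidence <- FALSE
  net$edges <- rbind(net$edges, new_edges[, names(net$edges)])
  net
}

#' Mechanism-restricted view of a network
#'
#' Returns the subnetwork of edges whose mechanism is in `mechanisms`,
#' together with their endpoint nodes only. The dysregulation analysis runs
#' on the correlation + regulatory layers; path search runs on the directed
#' regulatory layers.
#'
#' @param net a [knowledge_network()].
#' @param mechanisms non-empty character vector of mechanism names.
#' @return A [knowledge_network()] view.
#' @export
mechanism_view <- function(net, mechanisms) {
  stopifnot(inherits(net, "knowledge_network"), length(mechanisms) > 0L)
  if (!all(mechanisms %in% PKN_MECHANISMS)) {
    stop("unrecognized mechanism: ",
         paste(setdiff(mechanisms, PKN_MECHANISMS), collapse = ", "))
  }
  keep <- net$edges$mechanism %in% mechanisms
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- unique(c(edges$source, edges$target))
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 members = net$members[names(net$members) %in% ids],
                 if_threshold = net$if_threshold),
            class = "knowledge_network")
}
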