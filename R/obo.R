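# GO hierarchy: OBO parsing, the DAG container, and depth distances.

OBO_NAMESPACES <- c(cellular_component = "CC", molecular_function = "MF",
                    biological_process = "BP")

# internal constructor shared by read_obo() and make_toy_dag();
# validates acyclicity and namespace consistency
new_go_dag <- function(ids, namespaces, names_, parents, edge_type) {
  if (anyDuplicated(ids)) stop("duplicate term ids in DAG")
  idx <- seq_along(ids)
  names(idx) <- ids
  np <- lengths(parents)
  pvec <- unlist(parents, use.names = FALSE)
  unknown <- setdiff(pvec, ids)
  if (length(unknown)) {
    stop(sprintf("DAG edge points to unknown term '%s'", unknown[1L]))
  }
  child <- rep(idx, np)
  parent <- idx[pvec]
  if (length(child) && any(namespaces[child] != namespaces[parent])) {
    k <- which(namespaces[child] != namespaces[parent])[1L]
    stop(sprintf("edge %s -> %s crosses GO taxonomies", ids[child[k]],
                 ids[parent[k]]))
  }
  # Kahn's algorithm: acyclicity check (child -> parent edges)
  out_deg <- tabulate(child, nbins = length(ids))
  kids <- split(child, factor(parent, levels = idx))
  queue <- which(out_deg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (c_ in kids[[v]]) {
      out_deg[c_] <- out_deg[c_] - 1L
      if (out_deg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (seen < length(ids)) {
    member <- ids[which(out_deg > 0L)[1L]]
    stop(sprintf("GO hierarchy contains a cycle (involving %s)", member))
  }
  # undirected adjacency for distance queries
  adj <- lapply(idx, function(i) integer(0))
  for (k in seq_along(child)) {
    adj[[child[k]]] <- c(adj[[child[k]]], parent[k])
    adj[[parent[k]]] <- c(adj[[parent[k]]], child[k])
  }
  adj <- lapply(adj, unique)
  roots <- ids[!(idx %in% child)]
  structure(list(ids = ids, namespace = namespaces, name = names_,
                 index = idx, parents = lapply(parents, function(p) unname(idx[p])),
                 edge_type = edge_type, adjacency = adj, roots = roots),
            class = "go_dag")
}

#' Parse a GO hierarchy in OBO format
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file. `is_a:` lines and
#' `relationship: part_of` lines become directed child-to-parent edges (the
#' edge types kept are configurable downstream, both are stored). Obsolete
#' terms are dropped; the number dropped is reported as an attribute and a
#' warning. The result is validated: acyclic, no cross-taxonomy edges,
#' every term carries a namespace.
#'
#' @param file path to an OBO file, or a character vector of lines.
#' @return an object of class `"go_dag"` with term ids, namespaces (CC/MF/
#'   BP), term names, child-to-parent index lists tagged by edge type, an
#'   undirected adjacency list, and per-taxonomy roots.
#' @seealso [dag_distance()], [map_to_essential()]
#' @export
read_obo <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanzas found in OBO input")
  stanza_ends <- c(term_starts[-1L] - 1L, length(lines))
  other_stanzas <- which(grepl("^\\[", lines) & lines != "[Term]")
  ids <- character(0); nss <- character(0); nms <- character(0)
  parents <- list(); etypes <- list()
  n_obsolete <- 0L
  for (k in seq_along(term_starts)) {
    block <- lines[term_starts[k]:stanza_ends[k]]
    cut <- other_stanzas[other_stanzas > term_starts[k]]
    if (length(cut) && cut[1L] <= stanza_ends[k]) {
      block <- lines[term_starts[k]:(cut[1L] - 1L)]
    }
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v)) sub("\\s*!.*$", "", substring(v[1L], nchar(key) + 3L)) else NA_character_
    }
    if (any(startsWith(block, "is_obsolete: true"))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- trimws(get1("id"))
    if (is.na(id)) stop("OBO [Term] stanza without an id")
    ns <- trimws(get1("namespace"))
    if (is.na(ns) || !ns %in% names(OBO_NAMESPACES)) {
      stop(sprintf("term %s: missing or unknown namespace", id))
    }
    isa <- trimws(sub("\\s*!.*$", "",
                      substring(block[startsWith(block, "is_a: ")], 7L)))
    po <- block[startsWith(block, "relationship: part_of ")]
    po <- trimws(sub("\\s*!.*$", "", substring(po, 23L)))
    ids <- c(ids, id)
    nss <- c(nss, unname(OBO_NAMESPACES[ns]))
    nm <- get1("name")
    nms <- c(nms, if (is.na(nm)) id else trimws(nm))
    parents[[length(parents) + 1L]] <- c(isa, po)
    etypes[[length(etypes) + 1L]] <- c(rep("is_a", length(isa)),
                                       rep("part_of", length(po)))
  }
  # drop edges to obsolete/missing terms silently only if obsolete
  known <- unique(ids)
  parents <- lapply(parents, function(p) p)  # keep; validated in constructor
  dag <- new_go_dag(ids, nss, nms, parents, etypes)
  if (n_obsolete > 0L) {
    warning(sprintf("dropped %d obsolete term(s)", n_obsolete))
  }
  attr(dag, "n_obsolete") <- n_obsolete
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms (%s), %d edges, roots: %s\n",
              length(x$ids),
              paste(sprintf("%s %d", names(table(x$namespace)),
                            table(x$namespace)), collapse = ", "),
              sum(lengths(x$parents)), paste(x$roots, collapse = " ")))
  invisible(x)
}

# breadth-first distances from node index `from` to all nodes within
# max_distance, in the undirected view of the hierarchy, restricted to the
# taxonomy of `from` and (optionally) to a subset of edge types
bfs_distances <- function(dag, from, max_distance = Inf, edge_types = NULL) {
  adj <- dag$adjacency
  if (!is.null(edge_types) && !setequal(edge_types, c("is_a", "part_of"))) {
    # rebuild adjacency with the requested edge types only
    adj <- lapply(seq_along(dag$ids), function(i) integer(0))
    for (i in seq_along(dag$ids)) {
      keep <- dag$edge_type[[i]] %in% edge_types
      for (p in dag$parents[[i]][keep]) {
        adj[[i]] <- c(adj[[i]], p)
        adj[[p]] <- c(adj[[p]], i)
      }
    }
    adj <- lapply(adj, unique)
  }
  ns <- dag$namespace[from]
  dist <- rep(Inf, length(dag$ids))
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) && d < max_distance) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt]) & dag$namespace[nxt] == ns]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Depth distance between two GO terms
#'
#' Length of the shortest path between `g` and `e` in the undirected view
#' of the hierarchy edges (`is_a` and `part_of` by default), or `Inf` when
#' the two terms belong to different GO taxonomies -- hierarchical mapping
#' never crosses taxonomies. `dag_distance(dag, g, g)` is 0.
#'
#' @param dag a `"go_dag"`.
#' @param g,e GO term ids present in `dag`.
#' @param edge_types subset of `c("is_a", "part_of")` to traverse.
#' @return non-negative integer distance, or `Inf`.
#' @export
dag_distance <- function(dag, g, e, edge_types = c("is_a", "part_of")) {
  for (t in c(g, e)) {
    if (!t %in% dag$ids) stop(sprintf("term %s is not in the DAG", t))
  }
  gi <- dag$index[[g]]; ei <- dag$index[[e]]
  if (dag$namespace[gi] != dag$namespace[ei]) return(Inf)
  if (gi == ei) return(0L)
  d <- bfs_distances(dag, gi, edge_types = edge_types)[ei]
  if (is.finite(d)) as.integer(d) else Inf
}
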