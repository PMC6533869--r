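#' Construct an ontology object
#'
#' An ontology is a directed acyclic graph of concepts connected by is_a
#' edges. Each concept carries a canonical name and zero or more synonyms;
#' the name and every synonym are treated as interchangeable surface forms
#' of the concept when building training data.
#'
#' @param names named character vector, concept id -> canonical name.
#' @param parents named list, concept id -> character vector of parent ids
#'   (empty vector for roots). Ids absent from the list are treated as roots.
#' @param synonyms named list, concept id -> character vector of synonym
#'   strings (may be missing or empty).
#' @param alt_ids named character vector, alternate id -> primary id.
#'
#' @return An object of class `ontology` with fields `ids`, `names`,
#'   `synonyms`, `parents`, `alt_ids`, `roots` and `topo_order` (a total
#'   order in which every parent precedes all of its children).
#' @export
ontology <- function(names, parents = list(), synonyms = list(),
                     alt_ids = character()) {
  ids <- base::names(names)
  if (is.null(ids) || anyDuplicated(ids) > 0L || any(!nzchar(ids))) {
    stop("`names` must be uniquely named by non-empty concept ids")
  }
  par <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    p <- parents[[id]]
    p <- unique(as.character(p %||% character()))
    bad <- setdiff(p, ids)
    if (length(bad) > 0L) {
      stop("dangling is_a target(s) for '", id, "': ",
           paste(bad, collapse = ", "))
    }
    par[[id]] <- p
  }
  syn <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) syn[[id]] <- unique(as.character(synonyms[[id]] %||% character()))
  topo <- topo_sort_ids(ids, par)
  roots <- ids[vapply(par, length, integer(1)) == 0L]
  structure(
    list(ids = ids, names = names, synonyms = syn, parents = par,
         alt_ids = alt_ids, roots = roots, topo_order = topo),
    class = "ontology"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn's algorithm over parent edges; errors naming a cycle member.
topo_sort_ids <- function(ids, parents) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  children <- vector("list", n)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    p <- parents[[ids[i]]]
    indeg[i] <- length(p)
    for (pid in p) {
      j <- idx[[pid]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  queue <- which(indeg == 0L)
  if (length(queue) == 0L && n > 0L) {
    stop("cycle detected in is_a graph involving '", ids[1L], "'")
  }
  order <- integer(0)
  while (length(queue) > 0L) {
    # smallest index first for a deterministic order
    queue <- sort(queue)
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (j in children[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(order) < n) {
    member <- ids[setdiff(seq_len(n), order)][1L]
    stop("cycle detected in is_a graph involving '", member, "'")
  }
  ids[order]
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", length(x$ids), "concepts,", length(x$roots), "root(s),",
      sum(lengths(x$synonyms)), "synonyms\n")
  invisible(x)
}

#' Parse an OBO flat file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file, keeping the keys
#' `id`, `name`, `synonym`, `is_a`, `alt_id` and `is_obsolete`. Obsolete
#' terms are skipped entirely; `alt_id` values are recorded as aliases
#' resolving to the primary id. Synonym scope qualifiers (EXACT, BROAD, ...)
#' are ignored: every quoted synonym string is kept.
#'
#' @param path path to an OBO file.
#' @return An [ontology()] object.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stanza_starts <- which(trimws(lines) == "[Term]")
  nms <- character(); syn <- list(); par <- list(); alt <- character()
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  for (k in seq_along(stanza_starts)) {
    if (ends[k] <= stanza_starts[k]) next
    block <- lines[(stanza_starts[k] + 1L):ends[k]]
    # stop at the next stanza header of any type (e.g. [Typedef])
    hdr <- grep("^\\[.*\\]\\s*$", trimws(block))
    if (length(hdr) > 0L) block <- block[seq_len(hdr[1L] - 1L)]
    block <- block[grepl("^[a-zA-Z_]+:", block)]
    keyval <- regmatches(block, regexpr("^[a-zA-Z_]+:", block))
    get_vals <- function(key) {
      sel <- keyval == paste0(key, ":")
      trimws(sub("^[a-zA-Z_]+:", "", block[sel]))
    }
    if (any(grepl("^true", get_vals("is_obsolete")))) next
    id <- get_vals("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    nm <- get_vals("name")[1L]
    if (is.na(nm)) nm <- id
    isa <- sub("\\s*!.*$", "", get_vals("is_a"))
    syn_lines <- get_vals("synonym")
    syn_txt <- regmatches(syn_lines, regexpr('"[^"]*"', syn_lines))
    syn_txt <- gsub('"', "", syn_txt, fixed = TRUE)
    nms[id] <- nm
    par[[id]] <- isa
    syn[[id]] <- syn_txt
    for (a in get_vals("alt_id")) alt[a] <- id
  }
  if (length(nms) == 0L) stop("no [Term] stanzas found in ", path)
  ontology(nms, parents = par, synonyms = syn, alt_ids = alt)
}

#' Write an ontology to an OBO flat file
#'
#' Emits one `[Term]` stanza per concept so that subsets produced by
#' [build_closed_subset()] round-trip through [parse_obo()].
#'
#' @param ont an [ontology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in ont$ids) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", ont$names[[id]]), con)
    for (s in ont$synonyms[[id]]) {
      writeLines(paste0("synonym: \"", s, "\" EXACT []"), con)
    }
    for (p in ont$parents[[id]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Ancestor closure of a concept
#'
#' Returns the reflexive-transitive closure of a concept over is_a edges:
#' the concept itself plus every ancestor reachable through parent links.
#'
#' @param ont an [ontology()] object.
#' @param id a concept id present in `ont`.
#' @return Character vector of concept ids (unordered set semantics).
#' @export
ancestors <- function(ont, id) {
  if (!id %in% ont$ids) stop("unknown concept id: ", id)
  seen <- id
  frontier <- id
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(ont$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Build the ancestry matrix of an ontology
#'
#' The ancestry matrix A has one row and column per concept. Row i is
#' defined recursively along the taxonomy: for a root it is the unit vector
#' on itself; otherwise it is its unit vector plus the mean of its parents'
#' rows. Consequently `A[i, j]` is nonzero only when j is an ancestor of i
#' (or j = i), `A[i, i] = 1`, and coefficients reaching a shared ancestor
#' through several paths accumulate additively. Composing raw concept
#' embeddings as `A %*% H_raw` yields final embeddings in which each concept
#' inherits its (averaged) parents' position and adds its own offset.
#'
#' @param ont an [ontology()] object.
#' @return An object of class `ancestry_matrix`: a list with `ids` (row and
#'   column order) and `A` (a sparse [Matrix::sparseMatrix()]).
#' @export
build_ancestry_matrix <- function(ont) {
  ids <- ont$ids
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  rows <- vector("list", n) # each: named numeric, names = column index
  for (id in ont$topo_order) {
    i <- idx[[id]]
    p <- ont$parents[[id]]
    acc <- stats::setNames(1, as.character(i))
    if (length(p) > 0L) {
      w <- 1 / length(p)
      for (pid in p) {
        prow <- rows[[idx[[pid]]]]
        common <- intersect(names(acc), names(prow))
        acc[common] <- acc[common] + w * prow[common]
        new <- setdiff(names(prow), names(acc))
        acc <- c(acc, w * prow[new])
      }
    }
    rows[[i]] <- acc
  }
  nnz <- lengths(rows)
  A <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), nnz),
    j = as.integer(unlist(lapply(rows, names), use.names = FALSE)),
    x = unlist(rows, use.names = FALSE),
    dims = c(n, n), dimnames = list(ids, ids)
  )
  structure(list(ids = ids, A = A), class = "ancestry_matrix")
}

#' Extract an ancestor-closed subset of an ontology
#'
#' Restricts an ontology to the union of the ancestor closures of a set of
#' seed concepts, so that the result is itself a well-formed ontology (every
#' parent edge stays inside the retained set). This mirrors the common
#' construction of a training subset from the concepts mapped by an external
#' code system: the mapped concepts are the seeds and all missing ancestors
#' are added to obtain a single connected hierarchy.
#'
#' @param ont an [ontology()] object.
#' @param seed_ids character vector of concept ids to retain.
#' @return A list with `ontology` (the closed subset) and `counts`
#'   (`seeds`, `added_ancestors`, `total`; always
#'   `total == seeds + added_ancestors`).
#' @export
build_closed_subset <- function(ont, seed_ids) {
  seed_ids <- unique(as.character(seed_ids))
  bad <- setdiff(seed_ids, ont$ids)
  if (length(bad) > 0L) stop("unknown seed id(s): ", paste(bad, collapse = ", "))
  keep <- unique(unlist(lapply(seed_ids, function(s) ancestors(ont, s)),
                        use.names = FALSE))
  keep <- ont$ids[ont$ids %in% keep] # preserve original id order
  sub <- ontology(
    ont$names[keep],
    parents = lapply(stats::setNames(keep, keep),
                     function(id) intersect(ont$parents[[id]], keep)),
    synonyms = ont$synonyms[keep],
    alt_ids = ont$alt_ids[ont$alt_ids %in% keep]
  )
  counts <- list(seeds = length(seed_ids),
                 added_ancestors = length(keep) - length(seed_ids),
                 total = length(keep))
  list(ontology = sub, counts = counts)
}
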