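#' Read an SWC morphology file as a skeleton model
#'
#' The SWC parent-pointer tree is split into unbranched traces: a new trace
#' starts at every root, every branch point, and every type-code change, and
#' the boundary node is duplicated into each child trace so that every trace
#' is an independent polyline of one constituent kind. Node ids are
#' renumbered model-wide (duplicated branch nodes could not keep unique
#' ids). SWC type code 1 maps to the soma constituent, 0 to `other`, and
#' all remaining codes (axon, dendrites, custom) to `neurite`. Coordinates
#' and radii are taken as micrometres.
#'
#' @param path Path to an SWC file (7 whitespace-separated columns:
#'   id, type, x, y, z, radius, parent; `#` comment lines ignored).
#' @return A [skeleton_model()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no SWC records in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7L))
    stop("malformed SWC record (expected 7 columns) at line ",
         which(lengths(fields) != 7L)[1L], " of ", path)
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7L, byrow = TRUE)
  if (anyNA(tab)) stop("non-numeric SWC field in ", path)
  id <- as.integer(tab[, 1L]); type <- as.integer(tab[, 2L])
  parent <- as.integer(tab[, 7L])
  if (anyDuplicated(id)) stop("duplicate SWC node id in ", path)
  row_of <- match(parent, id)
  orphan <- which(parent != -1L & is.na(row_of))
  if (length(orphan))
    stop("orphan SWC node(s) ", paste(id[orphan], collapse = ", "),
         ": parent id not present in ", path)

  n <- length(id)
  # cycle check: following parent pointers must reach a root within n steps
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (parent[j] != -1L) {
      j <- row_of[j]; steps <- steps + 1L
      if (steps > n) stop("cyclic parent pointers in ", path)
    }
  }

  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- row_of[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  nchild <- lengths(children)
  roots <- which(parent == -1L)
  if (!length(roots)) stop("no root node (parent -1) in ", path)

  kind_of <- function(tc) if (tc == 1L) "soma" else if (tc == 0L) "other" else "neurite"

  traces <- list()
  n_emitted <- 0L
  emit <- function(rows) {
    tid <- sprintf("T%04d", length(traces) + 1L)
    # node ids are renumbered: branch-node duplication would otherwise break
    # model-wide uniqueness
    traces[[length(traces) + 1L]] <<- neurite_trace(
      xyz = tab[rows, 3:5, drop = FALSE], radius = tab[rows, 6L],
      kind = kind_of(type[rows[length(rows)]]), trace_id = tid,
      node_id = n_emitted + seq_along(rows), validate = FALSE)
    n_emitted <<- n_emitted + length(rows)
  }
  # depth-first over segments, in file order; a segment also breaks where
  # the SWC type code changes, so each trace is one constituent kind
  for (r in roots) {
    if (nchild[r] == 0L) { emit(r); next } # isolated node; caught by validation
    stack <- lapply(rev(children[[r]]), function(ch) c(r, ch))
    while (length(stack)) {
      seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      rows <- seg
      cur <- seg[2L]
      while (nchild[cur] == 1L && type[children[[cur]][1L]] == type[cur]) {
        cur <- children[[cur]][1L]
        rows <- c(rows, cur)
      }
      emit(rows)
      nxt <- if (nchild[cur] > 1L) children[[cur]]
             else if (nchild[cur] == 1L) children[[cur]][1L]  # type change
             else integer(0)
      for (ch in rev(nxt)) stack[[length(stack) + 1L]] <- c(cur, ch)
    }
  }
  skeleton_model(traces, dataset_id = sub("\\.[^.]*$", "", basename(path)),
                 validate = FALSE)
}

#' Write a skeleton model as SWC
#'
#' Each trace is written as an independent rooted path (first node has
#' parent -1); node ids are renumbered sequentially. Because branch nodes are
#' duplicated across traces when a tree is split, writing a model that came
#' from a branched SWC produces duplicated coordinates at former branch
#' points, which re-read as the same trace partition.
#'
#' @param model A valid [skeleton_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(model, path) {
  v <- validate_model(model)
  if (length(v)) stop("refusing to write invalid model: ",
                      paste(v, collapse = "; "))
  out <- c(paste0("# dataset ", model$dataset_id),
           "# id type x y z radius parent")
  nid <- 0L
  for (tr in model$traces) {
    tc <- switch(tr$kind, soma = 1L, other = 0L, 3L)
    n <- nrow(tr$xyz)
    ids <- nid + seq_len(n)
    par <- c(-1L, ids[-n])
    nid <- nid + n
    out <- c(out, sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                          ids, tc, tr$xyz[, 1L], tr$xyz[, 2L], tr$xyz[, 3L],
                          tr$radius, par))
  }
  writeLines(out, path)
  invisible(path)
}
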