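#' Read a traced skeleton model from a PDB-dialect coordinate file
#'
#' Skeleton models are stored in a fixed-column PDB dialect: every node is an
#' `ATOM` (or `HETATM`) record, one chain per trace with `TER` records
#' between traces, the residue sequence number giving node order within the
#' trace. Coordinates in the x/y/z columns are interpreted directly as
#' micrometres (no Angstrom conversion); the node radius lives in the
#' occupancy column (two-decimal precision); the residue name encodes the
#' constituent kind (`NEU` = neurite, `SOM` = soma, anything else =
#' `other`). The dataset id is carried on a `REMARK 200 DATASET_ID` line and
#' falls back to the file name.
#'
#' @param path Path to the file.
#' @param dialect_options List of dialect switches: `radius_column`
#'   (`"occupancy"`, the default, or `"bfactor"`) and `coordinate_scale`
#'   (multiplier applied to raw coordinates; default 1, i.e. file units are
#'   already micrometres).
#' @return A [skeleton_model()].
#' @export
read_pdb_skeleton <- function(path, dialect_options = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  opts <- pdb_dialect(dialect_options)
  lines <- readLines(path, warn = FALSE)

  dataset_id <- sub("\\.[^.]*$", "", basename(path))
  rem <- grep("^REMARK 200 DATASET_ID ", lines, value = TRUE)
  if (length(rem)) dataset_id <- trimws(sub("^REMARK 200 DATASET_ID ", "", rem[1L]))

  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_ter <- startsWith(lines, "TER")
  idx <- which(is_atom)

  traces <- list()
  cur <- NULL # accumulator: list of parsed record rows
  prev_chain <- NULL
  prev_resseq <- NULL
  flush <- function() {
    if (is.null(cur) || !length(cur$serial)) return(invisible())
    tid <- sprintf("T%04d", length(traces) + 1L)
    if (length(cur$serial) < 2L)
      stop("trace ", tid, " in ", path, " has fewer than 2 nodes")
    traces[[length(traces) + 1L]] <<- neurite_trace(
      xyz = cbind(cur$x, cur$y, cur$z) * opts$coordinate_scale,
      radius = cur$radius, kind = cur$kind[1L], trace_id = tid,
      node_id = cur$serial, validate = FALSE)
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    if (is_ter[i]) { flush(); prev_chain <- NULL; prev_resseq <- NULL; next }
    if (!is_atom[i]) next
    r <- parse_pdb_atom(lines[i], i, opts)
    # new trace on chain change or residue-number reset (TER is canonical)
    if (!is.null(prev_chain) &&
        (r$chain != prev_chain || r$resseq <= prev_resseq)) flush()
    if (is.null(cur))
      cur <- list(serial = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), radius = numeric(0), kind = character(0))
    cur$serial <- c(cur$serial, r$serial)
    cur$x <- c(cur$x, r$x); cur$y <- c(cur$y, r$y); cur$z <- c(cur$z, r$z)
    cur$radius <- c(cur$radius, r$radius)
    cur$kind <- c(cur$kind, r$kind)
    prev_chain <- r$chain; prev_resseq <- r$resseq
  }
  flush()

  ids <- unlist(lapply(traces, `[[`, "node_id"))
  if (anyDuplicated(ids))
    stop("duplicate node_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  skeleton_model(traces, dataset_id = dataset_id, validate = FALSE)
}

pdb_dialect <- function(dialect_options) {
  opts <- list(radius_column = "occupancy", coordinate_scale = 1)
  opts[names(dialect_options)] <- dialect_options
  opts$radius_column <- match.arg(opts$radius_column, c("occupancy", "bfactor"))
  stopifnot(is.numeric(opts$coordinate_scale), opts$coordinate_scale > 0)
  opts
}

parse_pdb_atom <- function(line, lineno, opts) {
  if (nchar(line) < 66L)
    stop("malformed fixed-column record at line ", lineno,
         " (shorter than 66 columns)")
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v)) stop("malformed fixed-column record at line ", lineno,
                       ": unreadable ", what)
    v
  }
  resname <- trimws(substr(line, 18L, 20L))
  occ <- num(55L, 60L, "occupancy")
  bfac <- num(61L, 66L, "temperature factor")
  list(serial = as.integer(num(7L, 11L, "serial")),
       chain = substr(line, 22L, 22L),
       resseq = as.integer(num(23L, 26L, "residue number")),
       x = num(31L, 38L, "x"), y = num(39L, 46L, "y"), z = num(47L, 54L, "z"),
       radius = if (opts$radius_column == "occupancy") occ else bfac,
       kind = switch(resname, NEU = "neurite", SOM = "soma", "other"))
}

#' Write a traced skeleton model to a PDB-dialect coordinate file
#'
#' Serialization counterpart of [read_pdb_skeleton()] (same dialect).
#' Coordinates are written at three-decimal (0.001 um) precision and radii
#' at two decimals; values that do not fit the fixed columns raise an error
#' rather than being truncated silently.
#'
#' @param model A valid [skeleton_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_skeleton <- function(model, path) {
  v <- validate_model(model)
  if (length(v)) stop("refusing to write invalid model: ",
                      paste(v, collapse = "; "))
  chains <- rep_len(c(LETTERS, letters, as.character(0:9)),
                    max(1L, length(model$traces)))
  out <- c(paste0("REMARK 200 DATASET_ID ", model$dataset_id))
  serial <- 0L
  for (k in seq_along(model$traces)) {
    tr <- model$traces[[k]]
    resname <- switch(tr$kind, neurite = "NEU", soma = "SOM", "OTH")
    n <- nrow(tr$xyz)
    if (n > 9999L) stop("trace ", tr$trace_id,
                        " exceeds 9999 nodes (residue column width)")
    r2 <- round(tr$radius, 2)
    if (any(r2 > 999.99)) stop("radius exceeds occupancy column width (> 999.99)")
    if (any(r2 <= 0)) stop("radius rounds to zero at occupancy precision ",
                           "(< 0.005 um) in trace ", tr$trace_id)
    if (any(tr$xyz > 9999.999) || any(tr$xyz < -999.999))
      stop("coordinate outside fixed-column range [-999.999, 9999.999] um")
    serials <- serial + seq_len(n)
    serial <- serial + n
    if (serial > 99999L) stop("model exceeds 99999 nodes (serial column width)")
    out <- c(out, sprintf(
      "ATOM  %5d  C   %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      serials, resname, chains[k], seq_len(n),
      tr$xyz[, 1L], tr$xyz[, 2L], tr$xyz[, 3L], r2, 0), "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
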