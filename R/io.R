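#' Read a multi-frame XYZ file
#'
#' Standard XYZ: per frame an atom-count line, a comment line, then one
#' `element x y z` record per atom.  Coordinates in scientific notation
#' are accepted.  Malformed count lines and truncated frames raise parse
#' errors naming the offending line.
#'
#' @param file Input filename.
#' @return List of conformations (atom labels from the element column).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  confs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("XYZ parse error at line ", i, ": expected an atom count, got ",
           sQuote(trimws(lines[i])))
    if (i + 1L + n > length(lines))
      stop("XYZ parse error at line ", i, ": frame declares ", n,
           " atoms but the file ends at line ", length(lines))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop("XYZ parse error at line ", i + 1L + bad[1L],
           ": expected 'element x y z'")
    labels <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      v
    }, numeric(3)))
    bad <- which(rowSums(is.na(coords)) > 0)
    if (length(bad))
      stop("XYZ parse error at line ", i + 1L + bad[1L],
           ": non-numeric coordinate")
    confs[[length(confs) + 1L]] <- conformation(coords, labels)
    i <- i + 2L + n
  }
  if (!length(confs)) stop("XYZ parse error: no frames in ", file)
  confs
}

#' Write conformations as a multi-frame XYZ file
#'
#' Toy-mode conformations in fewer than 3 dimensions are zero-padded to
#' 3 columns (XYZ is a 3D format); record the true dimension in an
#' accompanying manifest when round-tripping such paths.
#'
#' @param confs A conformation or list of conformations.
#' @param file Output filename.
#' @param comments Optional per-frame comment lines.
#' @export
write_xyz <- function(confs, file, comments = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- base::file(file, "w")
  on.exit(close(con))
  for (fi in seq_along(confs)) {
    cf <- as_conformation(confs[[fi]])
    X <- cf$coords
    if (ncol(X) > 3L) stop("XYZ supports at most 3 spatial dimensions")
    if (ncol(X) < 3L) X <- cbind(X, matrix(0, nrow(X), 3L - ncol(X)))
    labels <- cf$labels
    if (is.null(labels)) labels <- rep("X", nrow(X))
    writeLines(as.character(nrow(X)), con)
    writeLines(if (is.null(comments)) paste("frame", fi) else comments[fi],
               con)
    writeLines(sprintf("%s %.10g %.10g %.10g", labels, X[, 1], X[, 2],
                       X[, 3]), con)
  }
  invisible(file)
}

#' Read coordinates from a PDB file with a simple selection
#'
#' Reads the first model of a PDB file (via bio3d) and applies a
#' selection on residue numbers and/or atom names.  Alternate locations
#' keep the highest-occupancy conformer (a message notes how many were
#' dropped); insertion codes are rejected loudly because residue
#' numbering becomes ambiguous.  Selections use the 1-based PDB residue
#' numbering convention.
#'
#' @param file PDB filename.
#' @param resno Optional residue numbers to keep (e.g. `92:140`).
#' @param elety Optional atom names to keep (e.g. `"CA"`).
#' @param heavy_only Drop hydrogens (element H) when `TRUE`.
#' @return A conformation (coordinates in Angstrom) with labels
#'   `"<resid><resno>:<atomname>"`.
#' @export
read_pdb_coords <- function(file, resno = NULL, elety = NULL,
                            heavy_only = FALSE) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  ins <- !is.na(at$insert) & nzchar(trimws(at$insert))
  if (any(ins))
    stop("PDB file contains insertion codes (residues ",
         paste(unique(at$resno[ins]), collapse = ", "),
         "); renumber before use (selections are 1-based residue numbers)")
  alt <- !is.na(at$alt) & nzchar(trimws(at$alt))
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    dropped <- sum(!keep)
    if (dropped > 0L)
      message("read_pdb_coords: kept highest-occupancy conformer, ",
              "dropped ", dropped, " altLoc atoms")
    at <- at[keep, , drop = FALSE]
  }
  sel <- rep(TRUE, nrow(at))
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  if (!is.null(elety)) sel <- sel & trimws(at$elety) %in% elety
  if (heavy_only) {
    elem <- trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                          substr(trimws(at$elety), 1L, 1L), at$elesy))
    sel <- sel & toupper(elem) != "H"
  }
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty selection: no atoms match resno = ",
         if (is.null(resno)) "<any>" else paste(range(resno), collapse = "-"),
         ", elety = ", if (is.null(elety)) "<any>" else
           paste(elety, collapse = ","),
         if (heavy_only) ", heavy atoms only",
         " (1-based residue numbers)")
  conformation(cbind(at$x, at$y, at$z),
               paste0(at$resid, at$resno, ":", trimws(at$elety)))
}

#' Serialize a path to a manifest directory
#'
#' Writes the node coordinates as multi-frame XYZ plus a JSON manifest
#' recording the metric, lambda, the true spatial dimension (XYZ pads to
#' 3), and provenance (command, seed, timestamp, package version).
#'
#' @param path A [taps_path()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded as provenance.
#' @param command Free-form provenance string.
#' @return The directory, invisibly.
#' @export
write_path_manifest <- function(path, dir, seed = NA_integer_,
                                command = "write_path_manifest") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  node_file <- "nodes.xyz"
  write_xyz(path$nodes, file.path(dir, node_file))
  dim_k <- ncol(path$nodes[[1L]]$coords)
  manifest <- list(
    version = "1",
    metric = list(kind = path$metric$kind,
                  align_idx = path$metric$align_idx,
                  compute_idx = path$metric$compute_idx),
    lambda = path$lambda,
    n_nodes = path_length(path),
    dim = dim_k,
    node_file = node_file,
    endpoints_fixed = path$endpoints_fixed,
    provenance = list(command = command, seed = seed,
                      timestamp = format(Sys.time(), tz = "UTC"),
                      package = as.character(utils::packageVersion("tapsr"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a path back from a manifest directory
#'
#' lambda is recomputed from the (re-read) node coordinates rather than
#' trusted from the manifest; a warning is raised if the stored value
#' disagrees beyond round-off from the coordinate precision.
#'
#' @param dir Directory written by [write_path_manifest()].
#' @return A [taps_path()].
#' @export
read_path_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest found at ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  confs <- read_xyz(file.path(dir, manifest$node_file))
  if (length(confs) != manifest$n_nodes)
    stop("manifest declares ", manifest$n_nodes, " nodes but ",
         manifest$node_file, " holds ", length(confs), " frames")
  k <- manifest$dim
  nodes <- lapply(confs, function(cf)
    conformation(cf$coords[, seq_len(k), drop = FALSE], cf$labels))
  metric <- if (identical(manifest$metric$kind, "rmsd"))
    metric_spec("rmsd", manifest$metric$align_idx,
                manifest$metric$compute_idx)
  else metric_spec("euclidean")
  path <- taps_path(nodes, metric, isTRUE(manifest$endpoints_fixed))
  if (is.finite(manifest$lambda) &&
      abs(path$lambda - manifest$lambda) > 1e-4 * abs(manifest$lambda))
    warning("stored lambda ", manifest$lambda,
            " differs from value recomputed from coordinates (",
            format(path$lambda, digits = 8), "); using the recomputed one")
  path
}
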