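# Plain-text container for gridded voxels and field grids, and CSV readers
# and writers for perturber lists and signal time courses. The grid container
# is a '#'-prefixed key/value header followed by whitespace-separated columns
# of per-element values, flattened in R column-major order (first axis
# fastest). Per-label properties may replace per-element columns via
# '# prop:' header lines.

.grid_magic <- "# boldsim_grid v1"

#' Save a gridded voxel (and optionally its field) to a text container
#'
#' @param gv a [gridded_voxel()].
#' @param path output file.
#' @param dbz optional field-offset array (T) of matching shape, stored as a
#'   `dbz` column so a discretized voxel and its precomputed field can be
#'   reused across simulations.
#' @return `path`, invisibly.
#' @export
save_gridded_voxel <- function(gv, path, dbz = NULL) {
  spec <- gv$spec
  cols <- list(label = as.vector(gv$label), dchi = as.vector(gv$dchi))
  for (nm in c("t2", "t1")) if (!is.null(gv[[nm]])) cols[[nm]] <- as.vector(gv[[nm]])
  if (!is.null(dbz)) {
    stopifnot(identical(dim(dbz), dim(gv$label)))
    cols$dbz <- as.vector(dbz)
  }
  hdr <- c(.grid_magic,
           sprintf("# ndim: %d", spec$ndim),
           sprintf("# N: %d", spec$N),
           sprintf("# W: %.17g", spec$W),
           sprintf("# B0: %.17g", spec$B0),
           sprintf("# B0_dir: %.17g %.17g %.17g", spec$B0_dir[1],
                   spec$B0_dir[2], spec$B0_dir[3]),
           if (length(gv$perm))
             sprintf("# perm: %s", paste(format(gv$perm, digits = 17), collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(cols), con, row.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

read_grid_header <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || hdr[1] != .grid_magic)
    stop("not a boldsim grid container: ", path)
  kv <- list()
  for (l in hdr[-1]) {
    m <- regmatches(l, regexec("^# ([A-Za-z0-9_]+): (.*)$", l))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- c(kv[[m[2]]], m[3])
  }
  kv$n_header <- length(hdr)
  kv
}

#' Load a gridded voxel / custom perturber mask from a text container
#'
#' Accepts either a per-element `dchi` column or per-label `prop` header
#' lines (`# prop: <label> <dchi> [t2 t1]`); with the latter, every positive
#' label appearing in the grid must have a property line.
#'
#' @param path file written by [save_gridded_voxel()] or assembled externally
#'   in the documented layout.
#' @return A [gridded_voxel()]; if the file carries a `dbz` column the field
#'   grid is attached as attribute `"dbz"`.
#' @export
load_perturber_mask <- function(path) {
  kv <- read_grid_header(path)
  ndim <- as.integer(kv$ndim); N <- as.integer(kv$N)
  W <- as.numeric(kv$W); B0 <- as.numeric(kv$B0)
  B0_dir <- as.numeric(strsplit(kv$B0_dir, " +")[[1]])
  spec <- voxel_spec(ndim, W, "gridded", N = N, B0 = B0, B0_dir = B0_dir)
  dat <- utils::read.table(path, header = TRUE, comment.char = "#")
  n_el <- N^ndim
  if (nrow(dat) != n_el)
    stop(sprintf("grid data has %d rows but N^ndim = %d", nrow(dat), n_el))
  shape <- rep(N, ndim)
  label <- array(as.integer(dat$label), dim = shape)
  props <- NULL
  if (!is.null(kv$prop)) {
    props <- do.call(rbind, lapply(kv$prop, function(s)
      as.numeric(strsplit(trimws(s), " +")[[1]])))
  }
  if (!is.null(dat$dchi)) {
    dchi <- array(dat$dchi, dim = shape)
  } else if (!is.null(props)) {
    labs <- sort(unique(label[label > 0L]))
    missing <- setdiff(labs, props[, 1])
    if (length(missing))
      stop("no susceptibility given for label(s): ",
           paste(missing, collapse = ", "))
    dchi_by <- numeric(max(labs))
    dchi_by[props[, 1]] <- props[, 2]
    dchi <- array(c(0, dchi_by)[label + 1L], dim = shape)
  } else stop("container has neither a dchi column nor prop header lines")
  grab <- function(col, pcol) {
    if (!is.null(dat[[col]])) return(array(dat[[col]], dim = shape))
    if (!is.null(props) && ncol(props) >= pcol) {
      v <- c(NA, props[, pcol][match(seq_len(max(props[, 1])), props[, 1])])
      if (all(is.na(v[-1]))) return(NULL)
      return(array(v[label + 1L], dim = shape))
    }
    NULL
  }
  perm <- if (!is.null(kv$perm)) as.numeric(strsplit(kv$perm, " +")[[1]]) else NULL
  gv <- gridded_voxel(spec, label, dchi, t2 = grab("t2", 3), t1 = grab("t1", 4),
                      perm = perm, allow_background_chi = TRUE)
  if (!is.null(dat$dbz)) attr(gv, "dbz") <- array(dat$dbz, dim = shape)
  gv
}

#' Read and write perturber lists as CSV
#'
#' Columns are the documented per-class layouts: 2D cylinders
#' `radius,cx,cy,theta,phi0,dchi,perm`; 3D cylinders
#' `radius,px,py,pz,dx,dy,dz,dchi,perm`; spheres
#' `radius,cx,cy,cz,dchi,perm`. A `# kind: <kind>` header line records the
#' class. Externally generated packings (e.g. axon cross-sections) can be
#' imported this way.
#'
#' @param perturbers a `perturber_set`.
#' @param path CSV file.
#' @return `write_perturbers` returns `path` invisibly; `read_perturbers`
#'   returns a `perturber_set`.
#' @export
write_perturbers <- function(perturbers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", pert_kind(perturbers)), con)
  df <- as.data.frame(lapply(as.data.frame(unclass(perturbers)), format,
                             digits = 17))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_perturbers
#' @export
read_perturbers <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# kind: ([a-z0-9]+)$", first))[[1]]
  if (length(m) != 2L || !(m[2] %in% names(.pert_cols)))
    stop("missing or unknown '# kind:' header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  new_perturber_set(df, m[2])
}
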