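#' Read a protein structure (PDB or mmCIF)
#'
#' Parses all ATOM/HETATM records of the first model. Alternate locations are
#' resolved to the highest-occupancy conformer, ties broken by first listed.
#' Author residue numbering and insertion codes are preserved verbatim.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param identifier Identifier stored on the model; defaults to the file
#'   base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: no such file: ", path,
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop(sprintf("read_structure: cannot parse '%s' as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  if (is.null(identifier)) {
    identifier <- sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE)
  }
  bio3d_to_model(pdb, identifier = identifier)
}

# Convert a bio3d pdb object (first model) to a structure_model, applying the
# altloc rule: keep highest occupancy, first-listed on ties.
bio3d_to_model <- function(pdb, identifier = "") {
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("read_structure: empty model (no atom records)", call. = FALSE)
  }
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  alt <- if (is.null(at$alt)) rep("", nrow(at)) else ifelse(is.na(at$alt), "", at$alt)
  ins <- if (is.null(at$insert)) rep("", nrow(at)) else ifelse(is.na(at$insert), "", at$insert)
  chain <- ifelse(is.na(at$chain), "", at$chain)
  key <- paste(chain, at$resno, ins, at$elety)
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]   # which.max takes the first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  structure_model(
    tibble::tibble(
      serial = as.integer(at$eleno),
      atom   = at$elety,
      resid  = at$resid,
      chain  = chain[keep],
      resno  = as.integer(at$resno),
      ins    = ins[keep],
      x = at$x, y = at$y, z = at$z,
      elem = if (is.null(at$elesy)) substr(at$elety, 1L, 1L) else at$elesy,
      occ  = occ[keep]),
    identifier = identifier)
}

#' Read a coordinate trajectory from a multi-model PDB
#'
#' The reference trajectory format is a self-describing multi-model PDB
#' (MODEL/ENDMDL records). A topology may be supplied to enforce congruence;
#' otherwise the first model serves as topology.
#'
#' @param path Multi-model PDB file.
#' @param topology Optional [structure_model()] the frames must match.
#' @param dt_ns Frame spacing in ns used to synthesize time stamps (the PDB
#'   format carries none); frame `i` is at `(i - 1) * dt_ns`.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, dt_ns = 1) {
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path,
                               call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("read_trajectory: cannot parse ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  top <- bio3d_to_model(pdb, identifier = basename(path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!is.null(topology)) {
    if (nrow(topology) != nrow(top)) {
      stop(sprintf(
        "read_trajectory: frame atom count %d does not match topology %d",
        nrow(top), nrow(topology)), call. = FALSE)
    }
    top <- topology
  }
  if (ncol(xyz) != 3L * nrow(top)) {
    stop(sprintf(
      "read_trajectory: frames carry %d atoms but topology has %d",
      ncol(xyz) %/% 3L, nrow(top)), call. = FALSE)
  }
  trajectory(top, xyz, times = (seq_len(nrow(xyz)) - 1) * dt_ns)
}

#' Write a structure model as PDB
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(model))),
                   resno = model$resno,
                   resid = model$resid,
                   eleno = model$serial,
                   elety = model$atom,
                   chain = model$chain,
                   insert = ifelse(model$ins == "", NA, model$ins),
                   o = model$occ)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  bio3d::write.pdb(file = path,
                   xyz = traj$xyz,
                   resno = top$resno,
                   resid = top$resid,
                   eleno = top$serial,
                   elety = top$atom,
                   chain = top$chain,
                   insert = ifelse(top$ins == "", NA, top$ins),
                   o = top$occ)
  invisible(path)
}

#' Write a per-frame time series to CSV
#'
#' One row per frame, a `time_ns` column first, locale-independent decimal
#' point (plain CSV).
#'
#' @param series Data frame with a `time_ns` column (any of the package's
#'   series types qualifies).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  series <- tibble::as_tibble(as.data.frame(series))
  if (nrow(series) == 0L) {
    stop("write_timeseries: empty series", call. = FALSE)
  }
  if (!"time_ns" %in% names(series)) {
    stop("write_timeseries: series must have a time_ns column", call. = FALSE)
  }
  series <- dplyr::select(series, "time_ns", dplyr::everything())
  series <- dplyr::select(series, dplyr::where(~ !is.list(.x)))
  readr::write_csv(series, path, progress = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#' @param path CSV file.
#' @return A tibble.
#' @export
read_timeseries <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
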