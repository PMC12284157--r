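#' Acquisition metadata for a localization table
#'
#' @param n_frames total number of acquisition frames per imaging round.
#' @param fov field-of-view extent in nm, length-2 numeric `c(width, height)`.
#' @param pixel_size camera pixel size in nm per pixel (the effective pixel
#'   size of the detection path; 130 nm for the instrument emulated by the
#'   synthetic generator).
#' @param is_3d logical; whether the acquisition carries an axial coordinate.
#' @return an `acquisition_meta` object (named list).
#' @export
acquisition_meta <- function(n_frames, fov, pixel_size = 130, is_3d = FALSE) {
  stopifnot(length(n_frames) == 1L, n_frames >= 1)
  if (length(fov) == 1L) fov <- c(fov, fov)
  if (length(fov) != 2L || any(!is.finite(fov)) || any(fov <= 0)) {
    stop("'fov' must be strictly positive (width, height) in nm")
  }
  assert_scalar_pos(pixel_size, "pixel_size")
  structure(list(n_frames = as.integer(n_frames), fov = as.numeric(fov),
                 pixel_size = as.numeric(pixel_size), is_3d = isTRUE(is_3d)),
            class = "acquisition_meta")
}

#' Imaging-round to target mapping
#'
#' Two sets of four orthogonal docking-strand sequences are used per
#' experiment: rounds 1-4 read out the ALFA channel (therapeutic antibody),
#' rounds 5-8 the GFP channel (receptor). Each round maps to exactly one
#' target.
#'
#' @param round_id integer vector of round labels (1..8).
#' @return character vector of target labels ("ALFA" or "GFP").
#' @export
round_target <- function(round_id) {
  out <- ifelse(round_id >= 1 & round_id <= 4, "ALFA",
                ifelse(round_id >= 5 & round_id <= 8, "GFP", NA_character_))
  if (anyNA(out)) stop("round_id outside 1..8")
  out
}

.loc_required <- c("x", "y", "frame")
.loc_optional <- c("z", "sigma_xy", "sigma_z", "round_id", "target_id")

#' Construct and validate a localization table
#'
#' One row per DNA-PAINT localization (blink). Positions are always stored in
#' nanometers; frames are 0-based integers. 2D vs 3D is encoded by the
#' presence of a `z` column, not by a separate type.
#'
#' @param df data.frame/data.table with columns `x`, `y`, `frame` and
#'   optionally `z`, `sigma_xy`, `sigma_z`, `round_id`, `target_id`.
#' @param meta optional [acquisition_meta()].
#' @param validate run invariant checks (default TRUE).
#' @return a `loc_table` (data.table subclass) with the meta attached.
#' @export
loc_table <- function(df, meta = NULL, validate = TRUE) {
  dt <- data.table::as.data.table(df)
  missing_cols <- setdiff(.loc_required, names(dt))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c(.loc_required, .loc_optional), names(dt))
  dt <- dt[, keep, with = FALSE]
  if (nrow(dt)) {
    dt[, `:=`(x = as.numeric(x), y = as.numeric(y), frame = as.integer(frame))]
    if ("z" %in% names(dt)) dt[, z := as.numeric(z)]
  }
  data.table::setattr(dt, "meta", meta)
  data.table::setattr(dt, "class", c("loc_table", class(dt)))
  if (validate) validate_loc_table(dt)
  dt
}

#' Validate localization-table invariants
#'
#' Checks positivity of precisions, frame bounds against the acquisition
#' metadata, and consistency of the round-to-target mapping (each round label
#' must map to exactly one target).
#'
#' @param table a [loc_table()].
#' @return the table, invisibly; errors on violation.
#' @export
validate_loc_table <- function(table) {
  dt <- table
  if (nrow(dt) == 0L) return(invisible(table))
  if ("sigma_xy" %in% names(dt) && any(!is.na(dt$sigma_xy) & dt$sigma_xy <= 0)) {
    stop("validation error: sigma_xy must be > 0")
  }
  if ("z" %in% names(dt) && "sigma_z" %in% names(dt) &&
      any(!is.na(dt$sigma_z) & dt$sigma_z <= 0)) {
    stop("validation error: sigma_z must be > 0")
  }
  if (any(dt$frame < 0)) stop("validation error: frame must be >= 0")
  meta <- attr(table, "meta")
  if (!is.null(meta) && any(dt$frame >= meta$n_frames)) {
    stop("validation error: frame must be < n_frames")
  }
  if (all(c("round_id", "target_id") %in% names(dt))) {
    map <- unique(dt[!is.na(round_id), .(round_id, target_id)])
    if (anyDuplicated(map$round_id)) {
      stop("validation error: a round_id maps to more than one target_id")
    }
  }
  invisible(table)
}

#' Read a localization table from CSV or HDF5
#'
#' CSV files need a header row with at least `x`, `y`, `frame`. HDF5 files
#' use a single group `locs` with one 1-D dataset per column and the
#' acquisition metadata stored as group attributes (the layout written by
#' [write_localizations()]); this mirrors the common SMLM convention of one
#' array per field. Positions given in camera pixels are converted to nm with
#' `meta$pixel_size` at read time; everything downstream is in nm.
#'
#' @param path file path.
#' @param meta [acquisition_meta()]; for HDF5 it may be omitted and is then
#'   recovered from the file attributes.
#' @param format "auto" (by extension), "csv" or "hdf5".
#' @param units units of x/y/z in the file: "nm" (default) or "px".
#' @param column_map optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(x = "x_col_in_file")`; useful for foreign
#'   table dialects.
#' @return a validated [loc_table()] in nm.
#' @export
read_localizations <- function(path, meta = NULL,
                               format = c("auto", "csv", "hdf5"),
                               units = c("nm", "px"), column_map = NULL) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "csv") {
    dt <- data.table::fread(path)
  } else {
    cols <- rhdf5::h5ls(path)
    cols <- cols[cols$group == "/locs" & cols$otype == "H5I_DATASET", "name"]
    dt <- data.table::as.data.table(
      lapply(stats::setNames(cols, cols),
             function(cl) as.vector(rhdf5::h5read(path, paste0("locs/", cl)))))
    if (is.null(meta)) {
      at <- rhdf5::h5readAttributes(path, "locs")
      if (length(at)) {
        meta <- acquisition_meta(n_frames = at$n_frames, fov = at$fov,
                                 pixel_size = at$pixel_size,
                                 is_3d = as.logical(at$is_3d))
      }
    }
  }
  if (!is.null(column_map)) {
    data.table::setnames(dt, old = unname(column_map), new = names(column_map),
                         skip_absent = TRUE)
  }
  if (nrow(dt) && units == "px") {
    if (is.null(meta)) stop("pixel units require 'meta' with pixel_size")
    for (cl in intersect(c("x", "y", "sigma_xy"), names(dt))) {
      data.table::set(dt, j = cl, value = dt[[cl]] * meta$pixel_size)
    }
    # z (from astigmatism calibration) is conventionally already in nm
  }
  loc_table(dt, meta = meta)
}

#' Write a localization table to CSV or HDF5
#'
#' The HDF5 layout is one group `locs` holding a 1-D dataset per column plus
#' the acquisition metadata as group attributes. Round-trips through either
#' format are lossless.
#'
#' @param table a validated [loc_table()].
#' @param path output path.
#' @param format "auto" (by extension), "csv" or "hdf5".
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  validate_loc_table(table)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "csv") {
    out <- data.table::as.data.table(table)
    # full 17-significant-digit rendering so numeric round-trips are bitwise
    for (cl in names(out)) {
      if (is.double(out[[cl]])) {
        data.table::set(out, j = cl, value = sprintf("%.17g", out[[cl]]))
      }
    }
    data.table::fwrite(out, path)
  } else {
    if (file.exists(path)) unlink(path)
    ok <- try(rhdf5::h5createFile(path), silent = TRUE)
    if (inherits(ok, "try-error") || !isTRUE(ok)) stop("I/O error: cannot write ", path)
    rhdf5::h5createGroup(path, "locs")
    for (cl in names(table)) {
      rhdf5::h5write(table[[cl]], path, paste0("locs/", cl))
    }
    meta <- attr(table, "meta")
    if (!is.null(meta)) {
      fid <- rhdf5::H5Fopen(path)
      gid <- rhdf5::H5Gopen(fid, "locs")
      rhdf5::h5writeAttribute(meta$n_frames, gid, "n_frames")
      rhdf5::h5writeAttribute(meta$fov, gid, "fov")
      rhdf5::h5writeAttribute(meta$pixel_size, gid, "pixel_size")
      rhdf5::h5writeAttribute(as.integer(meta$is_3d), gid, "is_3d")
      rhdf5::H5Gclose(gid)
      rhdf5::H5Fclose(fid)
    }
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Split a localization table by molecular target
#'
#' @param table a [loc_table()] with a populated `target_id` column.
#' @return named list of `loc_table`s, one per target label; row counts sum
#'   to the input count (a partition).
#' @export
split_by_target <- function(table) {
  if (!"target_id" %in% names(table)) stop("target_id column not populated")
  known <- c("ALFA", "GFP")
  labs <- unique(as.character(table$target_id))
  bad <- setdiff(labs, known)
  if (length(bad)) {
    stop("unknown target label(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  meta <- attr(table, "meta")
  out <- lapply(stats::setNames(labs, labs), function(lb) {
    loc_table(table[table$target_id == lb, ], meta = meta, validate = FALSE)
  })
  out
}
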