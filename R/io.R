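# Minimal NIfTI-1 input/output.  Only what the pipeline needs: single-file
# .nii (optionally gzipped), 3-D volumes, little- or big-endian, the common
# numeric datatypes, sform affine.  No resampling, no reorientation.

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE)     # float64
)

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`).  The voxel data
#' is returned as a numeric 3-D array (scale slope/intercept applied) along
#' with the affine (sform if set, else a diagonal from `pixdim`).  No
#' resampling or reorientation is performed.
#'
#' @param path Path to the file.
#' @return A list with `volume` (3-D array), `affine` (4x4 matrix), and
#'   `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop("NIfTI file not found: ", path, call. = FALSE)
  }
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  rd <- function(raw, what, n, size, endian) {
    readBin(raw, what, n = n, size = size, endian = endian, signed = TRUE)
  }
  endian <- "little"
  sizeof_hdr <- rd(hdr[1:4], "integer", 1L, 4L, endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd(hdr[1:4], "integer", 1L, 4L, endian)
    if (sizeof_hdr != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }
  dims <- rd(hdr[41:56], "integer", 8L, 2L, endian)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[(4 + 1):(ndim + 1)] > 1L)) {
    stop("4-D NIfTI not supported: ", path, call. = FALSE)
  }
  if (ndim < 3L) dims[(ndim + 2):4] <- 1L
  shp <- dims[2:4]
  datatype <- rd(hdr[71:72], "integer", 1L, 2L, endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    stop("unsupported NIfTI datatype ", datatype, ": ", path, call. = FALSE)
  }
  pixdim <- rd(hdr[77:108], "double", 8L, 4L, endian)
  vox_offset <- rd(hdr[109:112], "double", 1L, 4L, endian)
  scl_slope <- rd(hdr[113:116], "double", 1L, 4L, endian)
  scl_inter <- rd(hdr[117:120], "double", 1L, 4L, endian)
  sform_code <- rd(hdr[255:256], "integer", 1L, 2L, endian)
  srow <- matrix(rd(hdr[281:328], "double", 12L, 4L, endian), 3L, 4L,
                 byrow = TRUE)

  # skip from byte 348 to vox_offset (gz connections cannot seek)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shp)
  vals <- if (dt$what == "integer" && dt$size == 1L) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                       endian = endian))
  } else {
    as.numeric(readBin(con, dt$what, n = n, size = dt$size, endian = endian))
  }
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pixdim[2:4], 1))
  list(volume = array(vals, dim = shp), affine = affine, datatype = datatype)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Writes a single-file uncompressed (or gzipped, by extension) NIfTI-1
#' image with float32 voxels and the given affine stored as sform.
#'
#' @param volume A numeric 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine (default: identity, 1 mm isotropic).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, affine = diag(4)) {
  stopifnot(length(dim(volume)) == 3L, all(dim(affine) == c(4L, 4L)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, ...
  w_i16(c(3L, dim(volume), 1L, 1L, 1L, 1L))   # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..3
  w_i16(0L)                         # intent_code
  w_i16(16L)                        # datatype: float32
  w_i16(32L)                        # bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, 1, 1, 1, 0, 0, 0, 0))  # pixdim[8] (qfac 1, 1 mm isotropic)
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L)                         # slice_end
  w_raw(2L)                         # slice_code, xyzt_units
  w_f32(c(0, 0, 0))                 # cal_max, cal_min, slice_duration
  w_f32(0)                          # toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L + 24L)                  # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code, sform_code
  w_f32(numeric(6))                 # quatern b,c,d + offsets x,y,z
  w_f32(t(affine[1:3, ]))           # srow_x, srow_y, srow_z
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                         # extension indicator
  w_f32(as.numeric(volume))
  invisible(path)
}

# ---- manifest --------------------------------------------------------------

#' Read and validate a subject manifest
#'
#' Tab-separated file with header columns `subject_id`, one column per
#' modality (file path, empty cell = modality missing for that subject),
#' `label` (0/1) and `fold`.  All validation failures are reported together.
#'
#' @param path Path to the TSV file.
#' @param modalities Optional expected modality column names; defaults to
#'   every column between `subject_id` and `label`.
#' @param check_paths Verify that referenced volume files exist.
#' @return A data.frame of class `mmfe_manifest` with a `modalities`
#'   attribute.
#' @export
read_manifest <- function(path, modalities = NULL, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("subject_id", "label", "fold")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(modalities)) {
    modalities <- setdiff(names(df), required)
  }
  errors <- character()
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L) {
    errors <- c(errors, paste0("duplicate subject_id: ",
                               paste(unique(dup), collapse = ", ")))
  }
  lab <- suppressWarnings(as.integer(df$label))
  bad_lab <- which(is.na(lab) | !lab %in% c(0L, 1L))
  if (length(bad_lab) > 0L) {
    errors <- c(errors, paste0("non-binary label for subject: ",
                               paste(df$subject_id[bad_lab], collapse = ", ")))
  }
  fold <- suppressWarnings(as.integer(df$fold))
  if (check_paths) {
    for (m in modalities) {
      p <- df[[m]]
      dangling <- which(nzchar(p) & !file.exists(p))
      if (length(dangling) > 0L) {
        errors <- c(errors, paste0("dangling path in column ", m, ": ",
                                   paste(p[dangling], collapse = ", ")))
      }
    }
  }
  if (length(errors) > 0L) {
    stop("manifest validation failed:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  df$label <- lab
  df$fold <- fold
  structure(df, class = c("mmfe_manifest", "data.frame"),
            modalities = modalities)
}

#' Write a manifest / cohort to disk
#'
#' Exports a synthetic cohort as NIfTI volumes plus a TSV manifest
#' (`subject_id`, one path column per modality, `label`, `fold`).
#'
#' @param cohort An `mmfe_cohort`.
#' @param dir Output directory (created if needed).
#' @param gzip Write `.nii.gz` instead of `.nii`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = FALSE) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  mods <- cohort_modalities(cohort)
  ext <- if (gzip) ".nii.gz" else ".nii"
  rows <- lapply(cohort, function(s) {
    paths <- vapply(mods, function(m) {
      if (m %in% s$missing || is.null(s$volumes[[m]])) return("")
      p <- file.path(dir, "volumes", paste0(s$subject_id, "_", m, ext))
      write_nifti(s$volumes[[m]], p)
      p
    }, character(1))
    c(subject_id = s$subject_id, paths, label = s$label, fold = s$fold)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(df, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Reads every referenced volume into memory; empty cells become missing
#' modalities.
#'
#' @param manifest An `mmfe_manifest` (or path to one).
#' @return An `mmfe_cohort`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  mods <- attr(manifest, "modalities")
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    vols <- stats::setNames(vector("list", length(mods)), mods)
    missing <- character()
    for (m in mods) {
      p <- manifest[[m]][i]
      if (nzchar(p)) vols[[m]] <- read_nifti(p)$volume
      else missing <- c(missing, m)
    }
    list(subject_id = manifest$subject_id[i], volumes = vols,
         label = manifest$label[i], fold = manifest$fold[i],
         missing = missing)
  })
  structure(samples, class = "mmfe_cohort", spec = NULL, modalities = mods)
}

# ---- run configuration -----------------------------------------------------

run_config_schema <- function() {
  list(
    cohort = names(formals(cohort_spec)),
    backbone = names(formals(backbone_spec)),
    train = setdiff(names(formals(train_config)), "backbone"),
    match = c("lambda_b", "lambda_h", "lambda_cs"),
    out_dir = NA, seed = NA
  )
}

#' Read and validate a JSON run configuration
#'
#' The configuration mirrors [cohort_spec()], [backbone_spec()],
#' [train_config()] and [match_weights()] under the keys `cohort`,
#' `backbone`, `train` and `match`, plus `out_dir` and `seed`.  Unknown keys
#' are rejected with the failing key path.
#'
#' @param path Path to a JSON file.
#' @return A validated nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A nested list (as parsed from JSON).
#' @export
validate_run_config <- function(cfg) {
  schema <- run_config_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top) > 0L) {
    stop("unknown config key: ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(schema)) {
    allowed <- schema[[section]]
    if (length(allowed) == 1L && is.na(allowed[1])) next
    bad <- setdiff(names(cfg[[section]]), allowed)
    if (length(bad) > 0L) {
      stop("unknown config key: ", section, ".", bad[1], call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

# Build the typed objects out of a run_config (with defaults filled in).
config_objects <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed %||% 1L
  spec <- do.call(cohort_spec, modifyList(list(seed = seed),
                                          as.list(cfg$cohort %||% list())))
  bb <- do.call(backbone_spec, as.list(cfg$backbone %||% list()))
  mw <- do.call(match_weights, as.list(cfg$match %||% list()))
  tr_args <- as.list(cfg$train %||% list())
  tr_args$backbone <- bb
  tr_args$match_weights <- mw
  tr_args$seed <- seed
  list(seed = seed, cohort = spec, backbone = bb, match = mw,
       train_args = tr_args)
}
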