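#' Write and read field snapshots as legacy ASCII VTK
#'
#' Snapshots are stored as `STRUCTURED_POINTS` datasets with four named
#' `SCALARS` arrays (`A`, `H`, `S`, `Y`), voxel order x-fastest, values
#' printed with 17 significant digits so a write/read round trip reproduces
#' the fields exactly. Files are readable by ParaView and other standard
#' VTK consumers.
#'
#' @param state an `rd_state` (or `rd_run`, whose final state is written).
#' @param domain the matching [rd_domain()].
#' @param path output file path.
#' @return `write_vtk()` returns `path` invisibly. `read_vtk()` returns a
#'   list with `state` (an `rd_state`; `step`/`t` recovered from the
#'   header comment when present) and `domain`.
#' @export
write_vtk <- function(state, domain, path) {
  if (inherits(state, "rd_run")) {
    domain <- state$domain
    state <- state$final
  }
  stopifnot(inherits(state, "rd_state"), inherits(domain, "rd_domain"))
  dm <- domain_dim(domain)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("branchrd snapshot step=%d t=%.17g", state$step,
                       state$t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dm[1], dm[2], dm[3]),
               sprintf("SPACING %g %g %g", domain$h, domain$h, domain$h),
               "ORIGIN 0 0 0",
               sprintf("POINT_DATA %d", prod(dm))), con)
  for (nm in c("A", "H", "S", "Y")) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", as.vector(state[[nm]])), con)
  }
  invisible(path)
}

#' @rdname write_vtk
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  need <- function(i, pattern, what) {
    if (i > length(lines) || !grepl(pattern, lines[i]))
      stop(sprintf("malformed VTK file at line %d (expected %s): '%s'",
                   i, what, if (i <= length(lines)) lines[i] else "<eof>"),
           call. = FALSE)
    lines[i]
  }
  need(1, "^# vtk DataFile", "VTK header")
  title <- lines[2]
  need(3, "^ASCII$", "ASCII marker")
  need(4, "^DATASET STRUCTURED_POINTS$", "STRUCTURED_POINTS dataset")
  dims <- as.integer(strsplit(need(5, "^DIMENSIONS ", "DIMENSIONS"),
                              "\\s+")[[1]][2:4])
  sp <- as.numeric(strsplit(need(6, "^SPACING ", "SPACING"), "\\s+")[[1]][2:4])
  need(7, "^ORIGIN ", "ORIGIN")
  npts <- as.integer(strsplit(need(8, "^POINT_DATA ", "POINT_DATA"),
                              "\\s+")[[1]][2])
  if (npts != prod(dims))
    stop("malformed VTK file at line 8: POINT_DATA count does not match ",
         "DIMENSIONS", call. = FALSE)

  fields <- list()
  i <- 9L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hdr <- need(i, "^SCALARS ", "SCALARS header")
    nm <- strsplit(hdr, "\\s+")[[1]][2]
    need(i + 1L, "^LOOKUP_TABLE", "LOOKUP_TABLE")
    i <- i + 2L
    vals <- numeric(0)
    while (length(vals) < npts && i <= length(lines)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                "\\s+")[[1]]))
      if (anyNA(v))
        stop(sprintf("malformed VTK file at line %d: non-numeric data in ",
                     i), "array '", nm, "'", call. = FALSE)
      vals <- c(vals, v)
      i <- i + 1L
    }
    if (length(vals) != npts)
      stop("malformed VTK file: array '", nm, "' has ", length(vals),
           " values, expected ", npts, call. = FALSE)
    fields[[nm]] <- array(vals, dims)
  }
  missing <- setdiff(c("A", "H", "S", "Y"), names(fields))
  if (length(missing))
    stop("VTK snapshot is missing required array(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  step <- 0L; tt <- 0
  m <- regmatches(title, regexec("step=(\\d+) t=([-0-9.eE+]+)", title))[[1]]
  if (length(m) == 3L) { step <- as.integer(m[2]); tt <- as.numeric(m[3]) }
  state <- structure(list(A = fields$A, H = fields$H, S = fields$S,
                          Y = fields$Y, step = step, t = tt),
                     class = "rd_state")
  domain <- rd_domain(dims[1], dims[2], dims[3], h = sp[1])
  list(state = state, domain = domain)
}

checkpoint_version <- "branchrd-checkpoint-1"

#' Checkpoint and restore a run
#'
#' A checkpoint is a VTK snapshot plus a JSON sidecar (`<path>.json`)
#' holding the format version and the resolved run configuration. Because
#' the dynamics are deterministic and the fluctuation RNG is consumed
#' entirely at initialization, restoring a checkpoint and continuing the
#' run reproduces the uninterrupted trajectory bit for bit.
#'
#' @param state an `rd_state` to save.
#' @param domain the matching [rd_domain()].
#' @param path checkpoint file path.
#' @param params,stepper,init optional configs recorded in the sidecar.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `restore_checkpoint()` returns a list with `state`, `domain` and
#'   `meta` (the sidecar contents). A missing/corrupt sidecar or a format
#'   version mismatch is an error and no partial state is returned.
#' @export
save_checkpoint <- function(state, domain, path, params = NULL,
                            stepper = NULL, init = NULL) {
  write_vtk(state, domain, path)
  meta <- list(version = checkpoint_version, step = state$step, t = state$t,
               params = if (!is.null(params)) unclass(params),
               stepper = if (!is.null(stepper)) unclass(stepper),
               init = if (!is.null(init))
                 unclass(init)[!vapply(unclass(init), is.null, logical(1))])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
restore_checkpoint <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("checkpoint sidecar not found: ", side, call. = FALSE)
  meta <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                   error = function(e)
                     stop("corrupt checkpoint sidecar: ", conditionMessage(e),
                          call. = FALSE))
  if (!identical(meta$version, checkpoint_version))
    stop("checkpoint version mismatch: file has '", meta$version,
         "', this build reads '", checkpoint_version, "'", call. = FALSE)
  snap <- tryCatch(read_vtk(path),
                   error = function(e)
                     stop("corrupt checkpoint: ", conditionMessage(e),
                          call. = FALSE))
  list(state = snap$state, domain = snap$domain, meta = meta)
}

#' Run metadata sidecar
#'
#' Writes a JSON record of a completed run: the fully resolved
#' configuration, package version, H-floor clamp count and the per-snapshot
#' field ranges, enough to reproduce the run bit-identically.
#'
#' @param run an `rd_run`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(run, path) {
  stopifnot(inherits(run, "rd_run"))
  meta <- list(
    software = paste0("branchrd ",
                      as.character(utils::packageVersion("branchrd"))),
    params = unclass(run$params),
    domain = unclass(run$domain),
    init = unclass(run$init)[!vapply(unclass(run$init), is.null, logical(1))],
    stepper = unclass(run$stepper),
    clamp_count = run$clamp_count,
    snapshot_log = run$log)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any of the blocks `params`, `domain`, `init`,
#' `stepper`; keys inside each block are passed to the corresponding
#' constructor, so omitted keys take package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `params`, `domain`, `init`, `stepper`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(params = do.call(rd_params, cfg$params %||% list()),
       domain = do.call(rd_domain, cfg$domain %||% list()),
       init = do.call(rd_init, cfg$init %||% list()),
       stepper = do.call(rd_stepper, cfg$stepper %||% list()))
}
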