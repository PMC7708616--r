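# Canonical flat serialization of a config, used both by the key=value
# writer and for the snapshot digest.
config_to_lines <- function(config) {
  fields <- setdiff(config_fields(), "sweep_pairs")
  lines <- vapply(fields, function(f) {
    v <- config[[f]]
    sprintf("%s = %s", f,
            if (is.character(v)) v else format(v, digits = 17))
  }, character(1))
  if (!is.null(config$sweep_pairs)) {
    pairs <- apply(config$sweep_pairs, 1L, function(p)
      paste(format(p, digits = 17, trim = TRUE), collapse = ":"))
    lines <- c(lines, sprintf("sweep_pairs = %s", paste(pairs, collapse = ";")))
  }
  unname(lines)
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(config_to_lines(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a configuration as a flat key=value file
#'
#' @param config An [experiment_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nfsom_config"))
  writeLines(config_to_lines(config), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Parses `key = value` lines (blank lines and `#` comments ignored),
#' rejects unknown keys, applies the mode's defaults for everything not
#' given, and validates the result collectively. An empty file with
#' `mode = "stable_demo"` therefore yields the full stable-demo defaults.
#'
#' @param path Path to the file.
#' @param mode Mode override; defaults to the file's `mode` key, or
#'   `"custom"` when absent.
#' @return A validated [experiment_config()].
#' @export
read_config <- function(path, mode = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  kv <- regmatches(raw, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", raw))
  bad <- raw[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(shQuote(bad), collapse = ", "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  unknown <- setdiff(keys, config_fields())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  parsed <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    parsed[[key]] <- if (key %in% c("mode", "coupling")) {
      val
    } else if (key == "sweep_pairs") {
      pair_strs <- strsplit(val, ";", fixed = TRUE)[[1]]
      pairs <- t(vapply(pair_strs, function(p)
        as.numeric(strsplit(p, ":", fixed = TRUE)[[1]]), numeric(2)))
      dimnames(pairs) <- list(NULL, c("Ke", "Ki"))
      pairs
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config key `", key, "` is not numeric: ", val)
      if (key %in% c("grid_n", "epochs", "seed", "q", "log_stride"))
        num <- as.integer(num)
      num
    }
  }
  if (is.null(mode)) mode <- parsed$mode %||% "custom"
  parsed$mode <- NULL
  do.call(experiment_config, c(list(mode = mode), parsed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a per-epoch trace
#'
#' The trace is a CSV with header `epoch, distortion, mean_weight_change,
#' field_max`. Non-finite values (e.g. the field maximum at a blowup epoch)
#' are serialized as empty fields and restored as `NA`. The round trip is
#' lossless for finite doubles.
#'
#' @param trace A data frame with the four trace columns.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace data frame.
#' @export
write_trace <- function(trace, path) {
  cols <- c("epoch", "distortion", "mean_weight_change", "field_max")
  if (!is.data.frame(trace) || !all(cols %in% names(trace)))
    stop("`trace` must be a data frame with columns ",
         paste(cols, collapse = ", "))
  out <- trace[, cols, drop = FALSE]
  for (cc in cols) {
    v <- out[[cc]]
    v[!is.finite(v)] <- NA
    out[[cc]] <- v
  }
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("failed to parse trace file ", path, ": ",
                             conditionMessage(e))
  )
  cols <- c("epoch", "distortion", "mean_weight_change", "field_max")
  if (!all(cols %in% names(df)))
    stop("trace file ", path, " is missing column(s): ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  df$epoch <- as.integer(df$epoch)
  df
}

#' Snapshot of a training run
#'
#' Bundles the codebook, the field state, the epoch index and a digest of
#' the generating configuration so a snapshot can be matched to its run.
#'
#' @param codebook `k x m` codebook matrix.
#' @param field Field values (length `k` vector or grid-shaped).
#' @param epoch Epoch index the snapshot was taken at.
#' @param config The run's [experiment_config()].
#' @return An object of class `nfsom_snapshot`.
#' @export
snapshot_record <- function(codebook, field, epoch, config) {
  stopifnot(is.matrix(codebook), inherits(config, "nfsom_config"))
  field <- as.vector(field)
  if (length(field) != nrow(codebook))
    stop("`field` must have one value per codebook row")
  structure(
    list(codebook = codebook, field = field, epoch = as.integer(epoch),
         config_digest = config_digest(config)),
    class = "nfsom_snapshot"
  )
}

#' Write / read a snapshot
#'
#' Snapshots are stored as a JSON named-array container written at full
#' double precision, so the array round trip is exact. On read, a digest
#' differing from `config`'s raises a warning; a codebook whose shape does
#' not match `expect_k` raises an error.
#'
#' @param snapshot An [snapshot_record()].
#' @param path File path.
#' @param config Optional config to check the digest against on read.
#' @param expect_k Optional expected node count.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns the `nfsom_snapshot`.
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "nfsom_snapshot"))
  # digits = I(17): full significant precision, so doubles round-trip exactly
  jsonlite::write_json(
    list(codebook = snapshot$codebook, field = snapshot$field,
         epoch = snapshot$epoch, config_digest = snapshot$config_digest),
    path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, config = NULL, expect_k = NULL) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  codebook <- as.matrix(obj$codebook)
  if (!is.null(expect_k) && nrow(codebook) != expect_k)
    stop("snapshot codebook has ", nrow(codebook),
         " rows but ", expect_k, " nodes were expected")
  if (length(obj$field) != nrow(codebook))
    stop("snapshot field length does not match the codebook")
  snap <- structure(
    list(codebook = codebook, field = as.numeric(obj$field),
         epoch = as.integer(obj$epoch),
         config_digest = obj$config_digest),
    class = "nfsom_snapshot"
  )
  if (!is.null(config) && !identical(config_digest(config), snap$config_digest))
    warning("snapshot was produced by a different configuration ",
            "(digest mismatch)")
  snap
}
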