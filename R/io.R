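#' Write a frame trace to a tab-delimited text file
#'
#' One row per frame; metadata (channel, frame time, and any extra
#' key/values such as seed or preset) is stored in `# key=value` comment
#' lines before the column header. FRET traces have columns
#' `time_s`, `donor`, `acceptor`; PIFE traces `time_s`, `intensity`.
#'
#' @param trace A `frame_trace`.
#' @param path Output file.
#' @param extra Named list of additional metadata key/values.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, extra = list()) {
  stopifnot(inherits(trace, "frame_trace"))
  meta <- c(list(channel = trace$channel, frame_time = trace$frame_time),
            extra)
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v)
                   if (is.numeric(v)) sprintf("%.17g", v)
                   else as.character(v), character(1)))
  g17 <- function(x) sprintf("%.17g", x)   # exact double round trip
  df <- if (trace$channel == "fret")
    data.frame(time_s = g17(trace$time), donor = g17(trace$donor),
               acceptor = g17(trace$acceptor))
  else data.frame(time_s = g17(trace$time), intensity = g17(trace$intensity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse "# key=value" comment headers from the top of a trace file.
.parse_meta <- function(lines) {
  m <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in m) {
    kv <- sub("^#\\s*", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num) || identical(val, "NA")) num else val
    }
  }
  out
}

#' Read one or more frame traces from tab-delimited text
#'
#' Reads a trace file written by [write_trace()] (or any file in the same
#' layout), tolerating `# key=value` comment headers. Columns are
#' validated strictly; a malformed row produces an error naming the
#' offending line. Given a directory, all `*.tsv` files in it are read and
#' returned as a list.
#'
#' @param path A trace file or a directory of trace files.
#' @return A `frame_trace`, or a named list of them for a directory.
#' @export
read_traces <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (length(files) == 0) stop("no .tsv trace files in ", path)
    out <- lapply(files, read_traces)
    names(out) <- basename(files)
    return(out)
  }
  lines <- readLines(path)
  meta <- .parse_meta(lines)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) < 2) stop("no data rows in ", path)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  channel <- if (all(c("time_s", "donor", "acceptor") %in% header)) "fret"
             else if (all(c("time_s", "intensity") %in% header)) "pife"
             else stop("unrecognized columns in ", path, ": ",
                       paste(header, collapse = ", "))
  ncol_expected <- length(header)
  rows <- body_idx[-1]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncol_expected)
  if (length(bad))
    stop("malformed row in ", path, " at line ", rows[bad[1]], ": expected ",
         ncol_expected, " fields, found ", lengths(fields)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = ncol_expected, byrow = TRUE)
  colnames(m) <- header
  if (anyNA(m))
    stop("non-numeric value in ", path, " at line ",
         rows[which(rowSums(is.na(m)) > 0)[1]])
  ft <- if (!is.null(meta$frame_time)) meta$frame_time
        else if (nrow(m) > 1) m[2, "time_s"] - m[1, "time_s"] else 0.05
  if (channel == "fret")
    .new_frame_trace("fret", ft, donor = m[, "donor"],
                     acceptor = m[, "acceptor"], meta = meta)
  else
    .new_frame_trace("pife", ft, intensity = m[, "intensity"], meta = meta)
}

#' Write a ground-truth state path as tab-delimited text
#' @param path_obj A `state_path`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_state_path <- function(path_obj, path) {
  df <- data.frame(state = path_obj$state,
                   entry_s = sprintf("%.17g", path_obj$entry),
                   exit_s = sprintf("%.17g", path_obj$exit))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth state path written by [write_state_path()]
#' @param path File path.
#' @return A `state_path`.
#' @export
read_state_path <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(state = df$state, entry = as.numeric(df$entry_s),
                    exit = as.numeric(df$exit_s), stringsAsFactors = FALSE)
  structure(out, total_duration = out$exit[nrow(out)],
            class = c("state_path", "data.frame"))
}

#' Write a synthetic dataset to a directory
#'
#' Traces go to `traces/trace_NNNN.tsv`, ground-truth paths to
#' `truth/truth_NNNN.tsv`, and all generator parameters to
#' `manifest.yaml`, so any analysis of the dataset is reproducible from
#' the directory alone.
#'
#' @param ds An `sm_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sm_dataset"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$traces)) {
    write_trace(ds$traces[[i]],
                file.path(dir, "traces", sprintf("trace_%04d.tsv", i)),
                extra = list(preset = ds$manifest$preset,
                             seed = ds$manifest$seed))
    write_state_path(ds$paths[[i]],
                     file.path(dir, "truth", sprintf("truth_%04d.tsv", i)))
  }
  yaml::write_yaml(ds$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return An `sm_dataset` (scheme reconstructed from the manifest preset
#'   when possible, otherwise `NULL`).
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  traces <- read_traces(file.path(dir, "traces"))
  tf <- sort(list.files(file.path(dir, "truth"), pattern = "\\.tsv$",
                        full.names = TRUE))
  paths <- lapply(tf, read_state_path)
  scheme <- if (manifest$preset %in% preset_names())
    make_preset(manifest$preset) else NULL
  structure(list(traces = unname(traces), paths = paths, scheme = scheme,
                 manifest = manifest),
            class = "sm_dataset")
}

#' Read and validate a run configuration
#'
#' A YAML file of pipeline parameters (preset, n_traces, duration,
#' frame_time, emission model, moving-average window, seed, out_dir).
#' Every field is validated before any stage runs; unknown keys are an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return Named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(preset = "aaf_n1", n_traces = 120, duration = 100,
                   frame_time = 0.05, total_intensity = 1000,
                   noise_sd = NULL, window = NULL, seed = 1,
                   association_rate = 0.5, channel = "fret",
                   out_dir = "results")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$preset %in% preset_names())
    stop("config: unknown preset '", cfg$preset, "'")
  if (!is.numeric(cfg$n_traces) || cfg$n_traces < 1)
    stop("config: n_traces must be >= 1")
  if (cfg$duration <= 0) stop("config: duration must be positive")
  if (cfg$frame_time <= 0) stop("config: frame_time must be positive")
  if (!is.null(cfg$window) && (cfg$window %% 2 == 0))
    stop("config: window must be odd")
  if (!cfg$channel %in% c("fret", "pife"))
    stop("config: channel must be 'fret' or 'pife'")
  structure(cfg, class = c("run_config", "list"))
}
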