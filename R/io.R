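# File formats and configuration: grayscale TIFF stacks in and out,
# 16-bit label stacks, CSV track tables, and a YAML run configuration that
# round-trips every pipeline constant.

page_to_matrix <- function(page, where) {
  if (is.list(page)) page <- page[[1L]]
  d <- dim(page)
  if (length(d) == 3L) {
    if (d[3L] > 1L && !all(page[, , 1L] == page[, , 2L]))
      stop("non-grayscale TIFF page in ", where)
    page <- page[, , 1L]
  }
  m <- as.matrix(page)
  storage.mode(m) <- "double"
  m
}

#' Read a grayscale image stack
#'
#' Accepts a multi-page TIFF or a directory of single-page TIFFs
#' (lexicographic order = acquisition order). Frames are promoted to
#' float64 matrices; integer data arrives scaled to `[0, 1]` as read by
#' the tiff package.
#'
#' @param path TIFF file or directory.
#' @return list of numeric matrices, all the same shape.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files in directory ", path)
    frames <- lapply(seq_along(files), function(i) {
      pg <- tryCatch(tiff::readTIFF(files[i]),
                     error = function(e) stop("unreadable frame ", i, " (",
                                              files[i], "): ",
                                              conditionMessage(e)))
      page_to_matrix(pg, paste0("frame ", i))
    })
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(seq_along(pages), function(i)
      page_to_matrix(pages[[i]], paste0("page ", i)))
  }
  d <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d))
      stop("frame ", i, " shape ", paste(dim(frames[[i]]), collapse = "x"),
           " differs from frame 1 (", paste(d, collapse = "x"), ")")
  frames
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` and stored as 16-bit samples.
#'
#' @param stack list of numeric matrices.
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack, function(m) clip01(as_mat(m)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a label stack as 16-bit multi-page TIFF
#'
#' @param labels list of integer label matrices (or a single matrix);
#'   labels above 65535 are rejected; background 0 is preserved.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  if (is.matrix(labels)) labels <- list(labels)
  for (m in labels) {
    if (any(m < 0L)) stop("negative labels are not allowed")
    if (max(m) > 65535L) stop("labels above 65535 cannot be stored in 16 bits")
  }
  pages <- lapply(labels, function(m) as_mat(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label stack written by [write_labels()]
#'
#' @param path TIFF file.
#' @return list of integer label matrices.
#' @export
read_labels <- function(path) {
  lapply(read_stack(path), function(m) {
    out <- as.integer(round(m * 65535))
    dim(out) <- dim(m)
    out
  })
}

#' Write a track table as CSV
#'
#' One row per (frame, cell) with the header
#' `frame,label,area,centroid_row,centroid_col,status`, ordered by frame
#' then label; byte output is deterministic for a fixed table.
#'
#' @param tracks a `yeast_tracks` object or its `table` data.frame.
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  tab <- if (inherits(tracks, "yeast_tracks")) tracks$table else tracks
  cols <- c("frame", "label", "area", "centroid_row", "centroid_col",
            "status")
  tab <- tab[order(tab$frame, tab$label), cols, drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table CSV
#'
#' @param path CSV written by [write_tracks()].
#' @return data.frame.
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the modality and every parameter group into one object that
#' round-trips losslessly through YAML.
#'
#' @param modality `"phase"`, `"brightfield"` or `"composite"`.
#' @param prep,subroutine,seeding,tracker parameter objects.
#' @param worker_count reserved for parallel maps over cells; results are
#'   defined to be independent of it.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(modality = "phase", prep = prep_params(),
                       subroutine = subroutine_params(),
                       seeding = seeding_params(),
                       tracker = tracker_params(),
                       worker_count = 1L, log_level = "info") {
  modality <- match.arg(modality, c("phase", "brightfield", "composite"))
  log_level <- match.arg(log_level, c("quiet", "info", "debug"))
  stopifnot(inherits(prep, "prep_params"),
            inherits(subroutine, "subroutine_params"),
            inherits(seeding, "seeding_params"),
            inherits(tracker, "tracker_params"))
  structure(list(modality = modality, prep = prep, subroutine = subroutine,
                 seeding = seeding, tracker = tracker,
                 worker_count = as.integer(worker_count),
                 log_level = log_level),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n  modality:", x$modality,
      " workers:", x$worker_count, " log:", x$log_level, "\n")
  invisible(x)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()] object.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys, at the top level or inside a parameter group, are
#' rejected; every value is re-validated through the parameter
#' constructors, so a read configuration is exactly as strict as one built
#' in code.
#'
#' @param path YAML file written by [write_config()] (or by hand).
#' @return a [run_config()] object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("modality", "prep", "subroutine", "seeding", "tracker",
             "worker_count", "log_level")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  ctors <- list(prep = prep_params, subroutine = subroutine_params,
                seeding = seeding_params, tracker = tracker_params)
  args <- list()
  for (grp in names(ctors)) {
    vals <- raw[[grp]] %||% list()
    bad <- setdiff(names(vals), names(formals(ctors[[grp]])))
    if (length(bad) > 0L)
      stop("unknown keys in '", grp, "': ", paste(bad, collapse = ", "))
    args[[grp]] <- do.call(ctors[[grp]], vals)
  }
  run_config(modality = raw$modality %||% "phase",
             prep = args$prep, subroutine = args$subroutine,
             seeding = args$seeding, tracker = args$tracker,
             worker_count = raw$worker_count %||% 1L,
             log_level = raw$log_level %||% "info")
}
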