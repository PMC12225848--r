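#' Write a cohort to CSV (portable fallback)
#'
#' One matrix file per trial (`trial_<n>.csv`, channels x samples, no
#' header) plus `manifest.csv` (per-trial metadata incl. the channel-region
#' map) and `spec.json` (the full cohort spec and planted ground truth).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(file = character(0))
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    fn <- sprintf("trial_%04d.csv", i)
    utils::write.table(tr$data, file.path(dir, fn), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    man <- rbind(man, data.frame(
      file = fn, subject = tr$subject_id, condition = tr$condition,
      rt_ms = tr$rt, correct = tr$correct, fs = tr$sampling_rate,
      channel_regions = paste(tr$channel_regions, collapse = ";")))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(cohort$spec),
         ground_truth = lapply(cohort$ground_truth$coupling_edges, unclass),
         rt_model = cohort$ground_truth$rt_model),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir cohort directory.
#' @return A `cohort` object (spec-derived fields are kept as plain lists).
#' @export
read_cohort_csv <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  trials <- lapply(seq_len(nrow(man)), function(i) {
    m <- man[i, ]
    data <- as.matrix(utils::read.csv(file.path(dir, m$file), header = FALSE))
    dimnames(data) <- NULL
    trial_recording(data = data, condition = m$condition, rt = m$rt_ms,
                    correct = as.logical(m$correct), subject_id = m$subject,
                    channel_regions = strsplit(m$channel_regions, ";")[[1]],
                    sampling_rate = m$fs)
  })
  meta <- if (file.exists(file.path(dir, "spec.json")))
    jsonlite::read_json(file.path(dir, "spec.json")) else NULL
  structure(list(trials = trials,
                 ground_truth = meta$ground_truth, spec = meta$spec),
            class = "cohort")
}

#' Write a cohort to HDF5
#'
#' Layout: group `/subject_<id>/trial_<n>` with dataset `data`
#' (channels x samples) and attributes `condition`, `rt_ms`, `correct`,
#' `fs`; each subject group carries attribute `channel_regions`. A JSON
#' sidecar (`<file>.json`) stores the spec and ground truth. Requires the
#' `rhdf5` package.
#'
#' @param cohort a [generate_cohort()] result.
#' @param file output `.h5` path.
#' @return `file`, invisibly.
#' @export
write_cohort_h5 <- function(cohort, file) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 output; use write_cohort_csv()")
  if (file.exists(file)) unlink(file)
  rhdf5::h5createFile(file)
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  subj <- split(seq_along(cohort$trials),
                vapply(cohort$trials, `[[`, 1, "subject_id"))
  for (sid in names(subj)) {
    grp <- paste0("subject_", sid)
    gid <- rhdf5::H5Gcreate(fid, grp)
    rhdf5::h5writeAttribute(
      cohort$trials[[subj[[sid]][1]]]$channel_regions, gid,
      "channel_regions")
    for (j in seq_along(subj[[sid]])) {
      tr <- cohort$trials[[subj[[sid]][j]]]
      tid <- rhdf5::H5Gcreate(gid, sprintf("trial_%d", j))
      rhdf5::h5writeDataset(tr$data, tid, "data")
      rhdf5::h5writeAttribute(tr$condition, tid, "condition")
      rhdf5::h5writeAttribute(tr$rt, tid, "rt_ms")
      rhdf5::h5writeAttribute(as.integer(tr$correct), tid, "correct")
      rhdf5::h5writeAttribute(tr$sampling_rate, tid, "fs")
      rhdf5::H5Gclose(tid)
    }
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
  jsonlite::write_json(
    list(spec = unclass(cohort$spec),
         ground_truth = lapply(cohort$ground_truth$coupling_edges, unclass)),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file)
}

#' Read a cohort written by [write_cohort_h5()]
#'
#' @param file `.h5` path.
#' @return A `cohort` object.
#' @export
read_cohort_h5 <- function(file) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 input")
  ls <- rhdf5::h5ls(file)
  trials <- list()
  subjects <- grep("^subject_", ls$name[ls$group == "/"], value = TRUE)
  for (grp in subjects) {
    sid <- sub("subject_", "", grp)
    regions <- rhdf5::h5readAttributes(file, grp)$channel_regions
    tnames <- ls$name[ls$group == paste0("/", grp)]
    tnames <- tnames[order(as.integer(sub("trial_", "", tnames)))]
    for (tn in tnames) {
      path <- paste0(grp, "/", tn)
      at <- rhdf5::h5readAttributes(file, path)
      data <- rhdf5::h5read(file, paste0(path, "/data"))
      trials[[length(trials) + 1L]] <- trial_recording(
        data = data, condition = at$condition, rt = at$rt_ms,
        correct = as.logical(at$correct), subject_id = sid,
        channel_regions = as.character(regions), sampling_rate = at$fs)
    }
  }
  rhdf5::h5closeAll()
  structure(list(trials = trials, ground_truth = NULL, spec = NULL),
            class = "cohort")
}

#' Long-format band-connectivity table
#'
#' @param cohort a cohort.
#' @param bands band names.
#' @param max_order passed to [fit_var()].
#' @return data.frame (subject, trial, band, source, target, value).
#' @export
connectivity_table <- function(cohort, bands = "theta", max_order = 15L) {
  rows <- list()
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    conn <- trial_connectivity(tr, bands = bands, max_order = max_order)
    for (b in bands) {
      C <- conn[[b]]$C
      k <- nrow(C)
      idx <- which(row(C) != col(C))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = tr$subject_id, trial = i, band = b,
        source = col(C)[idx], target = row(C)[idx], value = C[idx])
    }
  }
  do.call(rbind, rows)
}
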