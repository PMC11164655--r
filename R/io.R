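# File interchange: epoch HDF5 containers and tidy CSV tables.

#' Write / read epoch sets as HDF5
#'
#' Layout: one group per participant, one subgroup per condition
#' (`focus.context`), each holding a `data` dataset (epochs x channels x
#' samples, microvolts) and `sfreq`, `channel_names`, `epoch_window_ms` and
#' `trial_ids` datasets. Requires the `rhdf5` package.
#'
#' @param epoch_sets Named list of `epoch_set` objects (as produced by
#'   [simulate_eeg_epochs()]).
#' @param path HDF5 file path (overwritten).
#' @param participant Participant group name.
#' @return `read_epochs_h5()` returns the named list of `epoch_set`s.
#' @export
write_epochs_h5 <- function(epoch_sets, path, participant = "P01") {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 epoch I/O")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, participant)
  for (nm in names(epoch_sets)) {
    es <- epoch_sets[[nm]]
    grp <- paste0(participant, "/", nm)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(es$data, path, paste0(grp, "/data"))
    rhdf5::h5write(es$sfreq, path, paste0(grp, "/sfreq"))
    rhdf5::h5write(es$channel_names, path, paste0(grp, "/channel_names"))
    rhdf5::h5write(es$window_ms, path, paste0(grp, "/epoch_window_ms"))
    if (!is.null(es$trial_ids)) {
      rhdf5::h5write(as.integer(es$trial_ids), path, paste0(grp, "/trial_ids"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs_h5
#' @export
read_epochs_h5 <- function(path, participant = "P01") {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 epoch I/O")
  }
  idx <- rhdf5::h5ls(path)
  conds <- idx$name[idx$group == paste0("/", participant) &
                      idx$otype == "H5I_GROUP"]
  out <- lapply(conds, function(nm) {
    grp <- paste0(participant, "/", nm)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ids <- tryCatch(as.integer(rhdf5::h5read(path, paste0(grp, "/trial_ids"))),
                    error = function(e) NULL)
    epoch_set(rhdf5::h5read(path, paste0(grp, "/data")),
              sfreq = as.numeric(rhdf5::h5read(path, paste0(grp, "/sfreq"))),
              channel_names = as.character(
                rhdf5::h5read(path, paste0(grp, "/channel_names"))),
              condition = list(focus = parts[1], context = parts[2]),
              trial_ids = ids,
              window_ms = as.numeric(
                rhdf5::h5read(path, paste0(grp, "/epoch_window_ms"))))
  })
  rhdf5::h5closeAll()
  stats::setNames(out, conds)
}

#' Write / read tidy amplitude or effect tables as CSV
#'
#' @param x Data frame from [ssvep_amplitudes()] or [attentional_effects()].
#' @param path File path.
#' @return `read_amplitudes()` returns the data frame.
#' @export
write_amplitudes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitudes
#' @export
read_amplitudes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a response table as TSV
#'
#' @param responses Data frame with `trial_id`, `time_ms`.
#' @param path File path.
#' @return `read_responses()` returns the data frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
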