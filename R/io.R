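#' Write / read component time courses as delimited text
#'
#' One row per TR, one column per component; the header carries the
#' component ids.
#'
#' @param ts a [timecourse_set()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_timecourses <- function(ts, path, sep = "\t") {
  write.table(ts$data, path, sep = sep, row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @param tr_seconds repetition time to attach on read.
#' @param subject_id subject id to attach on read.
#' @export
read_timecourses <- function(path, tr_seconds, subject_id = basename(path),
                             sep = "\t") {
  x <- as.matrix(read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE))
  timecourse_set(x, tr_seconds, subject_id)
}

#' Write / read the subject metadata table
#' @param meta data.frame of subject metadata.
#' @param path file path.
#' @export
write_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_meta
#' @param group_levels order of the group factor levels.
#' @export
read_meta <- function(path, group_levels = NULL) {
  meta <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  meta$group <- if (is.null(group_levels)) factor(meta$group)
                else factor(meta$group, levels = group_levels)
  meta
}

#' Write / read frame-wise displacement traces (long format)
#' @param fd_traces named list of numeric FD vectors.
#' @param path file path.
#' @export
write_fd_traces <- function(fd_traces, path) {
  long <- data.frame(
    subject_id = rep(names(fd_traces), lengths(fd_traces)),
    volume = unlist(lapply(fd_traces, seq_along), use.names = FALSE),
    fd = unlist(fd_traces, use.names = FALSE))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fd_traces
#' @export
read_fd_traces <- function(path) {
  long <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  split(long$fd, factor(long$subject_id, levels = unique(long$subject_id)))
}

#' Write / read a connectivity (or edge-variance) matrix as delimited text
#' @param conn a `conn_matrix` or plain matrix.
#' @param path file path.
#' @export
write_conn_matrix <- function(conn, path) {
  values <- if (inherits(conn, "conn_matrix")) conn$values else conn
  write.table(values, path, sep = "\t", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @param scale scale flag to attach on read.
#' @export
read_conn_matrix <- function(path, scale = "fisher_z") {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  rownames(m) <- colnames(m)
  conn_matrix(m, scale, colnames(m))
}

#' Persist a window stack (binary array container + JSON sidecar)
#'
#' The array itself is stored in R's native serialization; the window
#' parameters travel in a human-readable JSON sidecar next to it.
#'
#' @param stack a [windowed_fc()] stack.
#' @param path file path (`.rds`); the sidecar is `path` + `.json`.
#' @export
write_window_stack <- function(stack, path) {
  saveRDS(stack, path)
  sidecar <- list(subject_id = stack$subject_id,
                  n_windows = dim(stack$windows)[1],
                  n_components = dim(stack$windows)[2],
                  window_length_tr = stack$window_length_tr,
                  sigma_tr = stack$sigma_tr, step_tr = stack$step_tr,
                  tr_seconds = stack$tr_seconds,
                  onsets = stack$onsets)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_window_stack
#' @export
read_window_stack <- function(path) readRDS(path)

#' Write / read the generator ground-truth record as JSON
#' @param truth truth record from [simulate_cohort()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite simplifies equal-length sequences to a matrix; restore the
  # one-vector-per-subject layout the generator produced
  if (is.matrix(truth$state_sequences)) {
    truth$state_sequences <- lapply(seq_len(nrow(truth$state_sequences)),
                                    function(i) {
                                      as.integer(truth$state_sequences[i, ])
                                    })
  } else if (is.list(truth$state_sequences)) {
    truth$state_sequences <- lapply(truth$state_sequences, as.integer)
  }
  truth
}

#' Write a cohort (time courses, metadata, FD traces, truth) to a directory
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timecourses"), recursive = TRUE,
             showWarnings = FALSE)
  for (ts in cohort$timecourses) {
    write_timecourses(ts, file.path(dir, "timecourses",
                                    paste0(ts$subject_id, ".tsv")))
  }
  write_meta(cohort$meta, file.path(dir, "meta.tsv"))
  write_fd_traces(cohort$fd_traces, file.path(dir, "fd_traces.tsv"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
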