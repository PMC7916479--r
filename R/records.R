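# The study's per-subject record layout: a 5-D epoch array
# channel(8) x time x electrode x block x target, 250 Hz, epochs spanning
# 0.5 s before to 2.34 s after stimulus onset. Electrode index 1 = wet,
# 2 = dry.

ELECTRODE_LEVELS <- c("wet", "dry")

#' Construct a per-subject epoch record
#'
#' @param data 5-D numeric array channel x time x electrode x block x target.
#' @param sampling_rate Hz (default 250).
#' @param channel_names Channel labels (default the standard 8-channel
#'   montage).
#' @param epoch_window Numeric `c(pre=, post=)` seconds around stimulus onset
#'   (default 0.5 and 2.34).
#' @param electrodes Electrode labels along axis 3, in order
#'   (default wet, dry truncated to the axis length).
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(data, sampling_rate = 250,
                           channel_names = ssvep_channels(),
                           epoch_window = c(pre = 0.5, post = 2.34),
                           electrodes = ELECTRODE_LEVELS[seq_len(dim(data)[3])]) {
  d <- dim(data)
  if (length(d) != 5)
    stop("`data` must be a 5-D array (channel x time x electrode x block x target), got rank ",
         length(d), call. = FALSE)
  if (d[1] != length(channel_names))
    stop("channel axis length ", d[1], " != ", length(channel_names),
         " channel names", call. = FALSE)
  expect_t <- round(sum(epoch_window) * sampling_rate)
  if (d[2] != expect_t)
    stop("time axis length ", d[2], " != round((pre+post) * rate) = ",
         expect_t, call. = FALSE)
  if (d[3] != length(electrodes))
    stop("electrode axis length ", d[3], " != ", length(electrodes),
         " labels", call. = FALSE)
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_names = channel_names, epoch_window = epoch_window,
                 electrodes = electrodes),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  d <- dim(x$data)
  cat("<subject_record> [", paste(d, collapse = ", "), "] at",
      x$sampling_rate, "Hz; electrodes:", paste(x$electrodes, collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a per-subject record to a MAT file
#'
#' Writes the 5-D epoch array under the variable name `"data"`. Refuses to
#' write if any (electrode, block, target) cell is entirely missing (all-NA).
#'
#' @param record A [subject_record()].
#' @param path Output path (conventionally `S&lt;xxx&gt;.mat`).
#' @return `path`, invisibly.
#' @export
write_subject_record <- function(record, path) {
  stopifnot(inherits(record, "subject_record"))
  d <- dim(record$data)
  missing <- list()
  for (e in seq_len(d[3])) for (b in seq_len(d[4])) for (k in seq_len(d[5])) {
    if (all(is.na(record$data[, , e, b, k])))
      missing[[length(missing) + 1]] <- sprintf(
        "(electrode=%s, block=%d, target=%d)", record$electrodes[e], b, k)
  }
  if (length(missing) > 0)
    stop("incomplete epoch grid; missing cells: ",
         paste(unlist(missing), collapse = ", "), call. = FALSE)
  write_mat(list(data = record$data), path)
}

#' Load a per-subject record from a MAT file
#'
#' Expects a variable `"data"` holding a rank-5 array in the layout
#' channel x time x electrode x block x target. The deposited records are
#' \[8, 710, 2, 10, 12\]; synthetic records may carry fewer blocks or a
#' single electrode session.
#'
#' @param path MAT file path.
#' @param sampling_rate Sampling rate of the stored epochs (default 250 Hz).
#' @param strict If TRUE, require the exact deposited shape
#'   \[8, 710, 2, 10, 12\].
#' @return A [subject_record()].
#' @export
load_subject_record <- function(path, sampling_rate = 250, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- read_mat(path)
  if (is.null(vars$data))
    stop("MAT file has no variable named 'data': ", path, call. = FALSE)
  d <- dim(vars$data)
  if (length(d) != 5)
    stop("expected rank-5 'data' array [channel, time, electrode, block, target]; found rank ",
         length(d), " with shape [", paste(d, collapse = ", "), "]",
         call. = FALSE)
  if (d[1] != 8 || d[5] != 12 || !(d[3] %in% 1:2))
    stop("expected shape [8, T, 1|2, B, 12]; found [",
         paste(d, collapse = ", "), "]", call. = FALSE)
  if (strict && !identical(d, c(8L, 710L, 2L, 10L, 12L)))
    stop("expected deposited shape [8, 710, 2, 10, 12]; found [",
         paste(d, collapse = ", "), "]", call. = FALSE)
  subject_record(vars$data, sampling_rate = sampling_rate)
}

#' Write / load impedance records
#'
#' The impedance file holds a 4-D array
#' \[headband type(2: 1=wet, 2=dry), channel(8), block(10), subject\] in
#' kOhm under the variable `"impedance"`.
#'
#' @param record An `impedance_record` (see [simulate_impedance()]).
#' @param path MAT file path.
#' @return `path` invisibly / an `impedance_record`.
#' @export
write_impedance <- function(record, path) {
  stopifnot(inherits(record, "impedance_record"))
  write_mat(list(impedance = record$values), path)
}

#' @rdname write_impedance
#' @export
load_impedance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- read_mat(path)
  nm <- intersect(c("impedance", "Impedance", "data"), names(vars))
  if (length(nm) == 0)
    stop("no impedance variable found in ", path, call. = FALSE)
  vals <- vars[[nm[1]]]
  d <- dim(vals)
  if (length(d) != 4)
    stop("expected rank-4 impedance array [type, channel, block, subject]; found rank ",
         length(d), " with shape [", paste(d, collapse = ", "), "]",
         call. = FALSE)
  if (d[1] != 2 || d[2] != 8)
    stop("expected shape [2, 8, B, S]; found [", paste(d, collapse = ", "),
         "]", call. = FALSE)
  if (any(vals < 0, na.rm = TRUE))
    stop("impedance values must be non-negative", call. = FALSE)
  structure(list(values = vals), class = "impedance_record")
}

SUBJECT_INFO_COLS <- c(
  "subject_index", "gender", "age", "dominant_hand",
  "comfort_dry", "pain_onset_dry_h", "comfort_wet", "pain_onset_wet_h",
  "preference_comfort", "preference_comfort_convenience")

#' Simulate, write, and load the subject-information table
#'
#' Ten columns per subject: index, gender, age, dominant hand, then six
#' questionnaire fields (comfort levels 1-4 per headband, pain-onset times in
#' hours, and two preference items). Stored as CSV; a numeric-coded MAT
#' mirror (variable `"subjects_information"`) is written alongside when
#' `mat_path` is given.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return A tibble with the 10 documented columns.
#' @export
simulate_subject_info <- function(n_subjects, seed = 1) {
  with_seed(seed, tibble::tibble(
    subject_index = seq_len(n_subjects),
    gender = sample(c("M", "F"), n_subjects, replace = TRUE, prob = c(0.63, 0.37)),
    age = pmax(8, pmin(52, round(stats::rnorm(n_subjects, 30, 8)))),
    dominant_hand = sample(c("R", "L"), n_subjects, replace = TRUE, prob = c(0.9, 0.1)),
    comfort_dry = sample(1:4, n_subjects, replace = TRUE, prob = c(0.21, 0.46, 0.14, 0.19)),
    pain_onset_dry_h = round(stats::runif(n_subjects, 0.3, 1.0), 2),
    comfort_wet = sample(1:4, n_subjects, replace = TRUE, prob = c(0.83, 0.14, 0.03, 0.0)),
    pain_onset_wet_h = round(stats::runif(n_subjects, 0.5, 1.2), 2),
    preference_comfort = sample(c("wet", "dry", "either"), n_subjects,
                                replace = TRUE, prob = c(0.83, 0.06, 0.11)),
    preference_comfort_convenience = sample(c("wet", "dry", "either"),
                                            n_subjects, replace = TRUE,
                                            prob = c(0.69, 0.14, 0.17))
  ))
}

#' @rdname simulate_subject_info
#' @param info Subject-info tibble with the 10 documented columns.
#' @param csv_path CSV output path.
#' @param mat_path Optional MAT mirror path.
#' @export
write_subject_info <- function(info, csv_path, mat_path = NULL) {
  stopifnot(all(SUBJECT_INFO_COLS %in% names(info)))
  utils::write.csv(info[SUBJECT_INFO_COLS], csv_path, row.names = FALSE)
  if (!is.null(mat_path)) {
    code <- function(x, levels) as.double(match(x, levels))
    m <- cbind(info$subject_index,
               code(info$gender, c("M", "F")),
               info$age,
               code(info$dominant_hand, c("R", "L")),
               info$comfort_dry, info$pain_onset_dry_h,
               info$comfort_wet, info$pain_onset_wet_h,
               code(info$preference_comfort, c("wet", "dry", "either")),
               code(info$preference_comfort_convenience, c("wet", "dry", "either")))
    write_mat(list(subjects_information = m), mat_path)
  }
  invisible(csv_path)
}

#' @rdname simulate_subject_info
#' @param path CSV path written by [write_subject_info()].
#' @export
load_subject_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(SUBJECT_INFO_COLS, names(info))
  if (length(missing) > 0)
    stop("subject info missing documented columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  info[SUBJECT_INFO_COLS]
}
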