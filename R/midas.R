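#' Read a perturbation dataset in MIDAS format
#'
#' MIDAS is the CSV dialect used by the CellNOpt tool chain. Column prefixes
#' drive the interpretation: `TR:` columns are treatments (a trailing `i`
#' marks an inhibitor of the named node, otherwise the column is a stimulus;
#' `CellLine` columns are ignored), `DA:` columns give acquisition times and
#' `DV:` columns the measured values. Each row is one experimental condition
#' at one acquisition time; values are kept untouched (see
#' [normalize_dataset()]).
#'
#' @param path MIDAS CSV path.
#' @return An object of class `midas_data`: the experimental roles
#'   (`$roles`), the condition design (`$conditions`, 0/1 data frame over
#'   stimuli then inhibitables), available acquisition times (`$times`) and
#'   the raw long-format measurements. Use [select_time()] to obtain the
#'   single-time dataset the models are scored against.
#' @export
read_midas <- function(path) {
  if (!file.exists(path)) stop("MIDAS file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- names(raw)
  tr_cols <- grep("^TR:", cn, value = TRUE)
  tr_cols <- tr_cols[!grepl("CellLine", tr_cols, ignore.case = TRUE)]
  da_cols <- grep("^DA:", cn, value = TRUE)
  dv_cols <- grep("^DV:", cn, value = TRUE)
  if (!length(dv_cols)) stop("MIDAS format error: no DV: columns")
  readouts <- sub("^DV:", "", dv_cols)
  da_names <- sub("^DA:", "", da_cols)
  for (r in readouts)
    if (!(r %in% da_names) && !("ALL" %in% da_names))
      stop("MIDAS format error: DV:", r, " has no matching DA: column")
  tr_names <- sub("^TR:", "", tr_cols)
  is_inhib <- grepl("i$", tr_names)
  stimuli <- tr_names[!is_inhib]
  inhibitables <- sub("i$", "", tr_names[is_inhib])

  num <- function(col) {
    v <- raw[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    suppressWarnings(out <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("MIDAS format error: non-numeric value '", v[bad[1]],
           "' in column ", col, ", row ", bad[1])
    out
  }
  as_mat <- function(cols) {
    if (!length(cols)) return(matrix(numeric(0), nrow = nrow(raw), ncol = 0))
    matrix(unlist(lapply(cols, num)), nrow = nrow(raw))
  }
  tr <- as_mat(tr_cols)
  tr <- matrix(as.integer(!is.na(tr) & tr != 0), nrow = nrow(raw))
  colnames(tr) <- tr_names
  dv <- as_mat(dv_cols)
  da <- if (length(da_cols)) as_mat(da_cols) else NULL
  time_of <- function(row, r) {
    j <- match(r, da_names)
    if (is.na(j)) j <- match("ALL", da_names)
    da[row, j]
  }
  # long format: condition key x readout x time x value
  ckey <- if (ncol(tr)) apply(tr, 1L, paste, collapse = ",") else rep("", nrow(raw))
  cond_first <- !duplicated(ckey)
  cond_levels <- ckey[cond_first]
  cond_id <- match(ckey, cond_levels)
  long <- do.call(rbind, lapply(seq_along(readouts), function(j) {
    data.frame(cond = cond_id,
               readout = readouts[j],
               time = vapply(seq_len(nrow(raw)), time_of, 0, r = readouts[j]),
               value = dv[, j])
  }))
  conditions <- as.data.frame(tr[cond_first, , drop = FALSE])
  names(conditions) <- tr_names
  roles <- structure(list(stimuli = sort(stimuli),
                          inhibitables = sort(inhibitables),
                          readouts = sort(readouts)), class = "midas_roles")
  structure(list(roles = roles,
                 conditions = conditions,
                 stimuli = stimuli, inhibitables = inhibitables,
                 readouts = readouts,
                 long = long,
                 times = sort(unique(long$time[!is.na(long$value)]))),
            class = "midas_data")
}

#' @export
print.midas_data <- function(x, ...) {
  cat(sprintf("MIDAS data: %d conditions, %d readouts, times {%s}\n",
              nrow(x$conditions), length(x$readouts),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Select the dataset at one acquisition time
#'
#' Boolean steady-state predictions are compared with measurements taken at
#' early times after stimulation, so scoring uses a single acquisition time.
#' The default is the earliest strictly positive time (time 0 is the
#' pre-stimulation baseline).
#'
#' @param x a `midas_data` from [read_midas()].
#' @param time acquisition time; `NULL` selects the default.
#' @return An object of class `midas_dataset` with fields `stimuli`,
#'   `inhibitables`, `readouts`, 0/1 matrices `stim` and `inhib`
#'   (conditions x roles), the `values` matrix (conditions x readouts,
#'   `NA` = missing) and `time`.
#' @export
select_time <- function(x, time = NULL) {
  stopifnot(inherits(x, "midas_data"))
  if (is.null(time)) {
    pos <- x$times[x$times > 0]
    if (!length(pos))
      stop("no strictly positive acquisition time available (times: ",
           paste(x$times, collapse = ", "), ")")
    time <- min(pos)
  }
  if (!(time %in% x$times))
    stop("time ", time, " not in dataset; available times: ",
         paste(x$times, collapse = ", "))
  n <- nrow(x$conditions)
  m <- length(x$readouts)
  values <- matrix(NA_real_, n, m, dimnames = list(NULL, x$readouts))
  sel <- x$long[!is.na(x$long$time) & x$long$time == time, , drop = FALSE]
  sel <- sel[!duplicated(sel[c("cond", "readout")]), , drop = FALSE]
  values[cbind(sel$cond, match(sel$readout, x$readouts))] <- sel$value
  stim_cols <- match(x$stimuli, names(x$conditions))
  inhib_cols <- match(paste0(x$inhibitables, "i"), names(x$conditions))
  stim <- as.matrix(x$conditions)[, stim_cols, drop = FALSE]
  colnames(stim) <- x$stimuli
  inhib <- as.matrix(x$conditions)[, inhib_cols, drop = FALSE]
  colnames(inhib) <- x$inhibitables
  structure(list(stimuli = x$stimuli, inhibitables = x$inhibitables,
                 readouts = x$readouts, stim = stim, inhib = inhib,
                 values = values, time = time),
            class = "midas_dataset")
}

#' @export
print.midas_dataset <- function(x, ...) {
  cat(sprintf("MIDAS dataset at t=%s: %d conditions x %d readouts (%d missing)\n",
              format(x$time), nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Normalize measurements to the unit interval
#'
#' @param x a `midas_dataset`.
#' @param mode `"minmax"` rescales each readout column linearly to `[0, 1]`
#'   (a constant column maps to 0); `"passthrough"` asserts values are
#'   already within `[0, 1]` and leaves them untouched.
#' @return The dataset with normalized `values`; missing entries stay missing.
#' @export
normalize_dataset <- function(x, mode = c("minmax", "passthrough")) {
  stopifnot(inherits(x, "midas_dataset"))
  mode <- match.arg(mode)
  v <- x$values
  if (mode == "passthrough") {
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("passthrough normalization: values outside [0, 1]")
    return(x)
  }
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    if (all(is.na(col))) next
    lo <- min(col, na.rm = TRUE); hi <- max(col, na.rm = TRUE)
    v[, j] <- if (hi > lo) (col - lo) / (hi - lo) else 0 * col
  }
  x$values <- v
  x
}

#' Discretize values onto a fixed decimal grid
#'
#' Rounds to the nearest multiple of `10^-precision`, ties away from zero,
#' so that scoring arithmetic is exact on the integer grid
#' `0..10^precision`. Missing values stay missing; the operation is
#' idempotent.
#'
#' @param x numeric vector or matrix with values in `[0, 1]` (or `NA`).
#' @param precision number of decimal digits retained (default 2).
#' @return `x` rounded onto the grid.
#' @export
discretize_values <- function(x, precision = 2) {
  stopifnot(precision >= 0)
  s <- 10^precision
  out <- floor(x * s + 0.5 + 1e-9) / s
  out[is.na(x)] <- NA
  out
}

#' Write a single-time dataset as a MIDAS CSV
#'
#' Non-missing values are written with full precision and survive a
#' write/read round trip bit-exactly.
#'
#' @param x a `midas_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_midas <- function(x, path) {
  stopifnot(inherits(x, "midas_dataset"))
  header <- c(paste0("TR:", x$stimuli),
              paste0("TR:", x$inhibitables, "i", recycle0 = TRUE),
              paste0("DA:", x$readouts), paste0("DV:", x$readouts))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  n <- nrow(x$values)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(x$stim[i, ], x$inhib[i, ],
            rep(sprintf("%.17g", x$time), length(x$readouts)),
            fmt(x$values[i, ])), collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}
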