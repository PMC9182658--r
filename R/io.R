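# Motion file I/O.
#
# Canonical motion format: delimited text, one row per frame, header row
# with column names: time (s), 6 base-pose values (m, rad; extrinsic XYZ
# Euler), 66 joint angles (rad, named q_<segment>_<flex|abd|rot>), and
# optionally 6 hand-wrench values (N, N m). Angles are stored in radians
# by default; a `# units: degrees` first line switches the angle columns.

motion_colnames <- function(model) {
  qn <- character(model$n_dof)
  for (i in seq_along(model$names)) {
    k <- model$ndof_seg[i]
    if (k == 0) next
    qn[model$q_start[i] + seq_len(k)] <-
      paste0("q_", model$names[i], "_", c("flex", "abd", "rot")[seq_len(k)])
  }
  c("time", "base_x", "base_y", "base_z", "base_rx", "base_ry", "base_rz",
    qn)
}

#' Write / read a motion sequence as delimited text
#'
#' Lossless round trip of times, base poses, joint angles and (when
#' present) the hand wrench stream. Files carry a header row naming every
#' column; parse failures report the offending line.
#'
#' @param motion a `lem_motion`.
#' @param path file path (`.csv`).
#' @param degrees store angle columns in degrees instead of radians.
#' @param model a `lem_skeleton` (column naming / validation).
#' @return `read_motion` returns a `lem_motion`.
#' @export
write_motion <- function(motion, path, degrees = FALSE,
                         model = lemr_model()) {
  cols <- motion_colnames(model)
  ang <- motion$Q
  rpy <- motion$base_rpy
  if (degrees) {
    ang <- ang * 180 / pi
    rpy <- rpy * 180 / pi
  }
  df <- data.frame(motion$time, motion$base_pos, rpy, ang)
  names(df) <- cols
  if (!is.null(motion$wrench)) {
    w <- as.data.frame(motion$wrench)
    names(w) <- c("wrench_fx", "wrench_fy", "wrench_fz",
                  "wrench_mx", "wrench_my", "wrench_mz")
    df <- cbind(df, w)
  }
  if (degrees) {
    writeLines("# units: degrees", path)
    data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path, model = lemr_model()) {
  if (!file.exists(path)) stop("no such motion file: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("parse error: empty motion file ", path)
  degrees <- grepl("^#\\s*units:\\s*degrees", first)
  dt <- tryCatch(
    data.table::fread(path, skip = if (degrees) 1L else 0L, header = TRUE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) stop("parse error: motion file ", path, " has no frames")
  expected <- motion_colnames(model)
  have <- names(dt)
  wr_cols <- grep("^wrench_", have, value = TRUE)
  body <- setdiff(have, wr_cols)
  if (length(body) != length(expected))
    stop("parse error: expected ", length(expected),
         " non-wrench columns (time + 6 base + ", model$n_dof,
         " angles), found ", length(body))
  if (!identical(body, expected))
    stop("parse error: column names do not match the canonical layout; ",
         "first mismatch: ", body[which(body != expected)[1]])
  M <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt)), nrow(dt),
           dimnames = list(NULL, names(dt))))
  if (anyNA(M)) {
    bad <- which(rowSums(is.na(M)) > 0)[1]
    stop("parse error: non-numeric cell at data line ", bad)
  }
  ang <- M[, 8:(7 + model$n_dof), drop = FALSE]
  rpy <- M[, 5:7, drop = FALSE]
  if (degrees) {
    ang <- ang * pi / 180
    rpy <- rpy * pi / 180
  }
  out <- list(time = M[, 1], Q = unname(ang),
              base_pos = unname(M[, 2:4, drop = FALSE]),
              base_rpy = unname(rpy),
              rate = if (nrow(M) > 1)
                1 / stats::median(diff(M[, 1])) else NA_real_)
  if (length(wr_cols) == 6)
    out$wrench <- unname(M[, wr_cols, drop = FALSE])
  structure(out, class = "lem_motion")
}

#' Write a per-frame score stream as delimited text
#'
#' @param time frame times (s).
#' @param grand grand score vector.
#' @param local optional data.frame of local scores.
#' @param path file path.
#' @export
write_scores <- function(time, grand, local = NULL, path) {
  df <- data.frame(time = time, grand = grand)
  if (!is.null(local)) df <- cbind(df, local)
  data.table::fwrite(df, path)
  invisible(path)
}
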