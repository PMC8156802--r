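# Trajectory CSV dialect: optional first line "# tau=<seconds> subject=<label>",
# then header "frame,m01_x,m01_y,m01_z,...,m10_x,m10_y,m10_z", one row per
# frame, '.' decimal separator, UTF-8. Coordinates are meters.

trajectory_header <- function(n_markers = 10L) {
  c("frame",
    as.vector(t(outer(sprintf("m%02d", seq_len(n_markers)),
                      c("x", "y", "z"), paste, sep = "_"))))
}

#' Read a marker-trajectory CSV file
#'
#' Parses the plain-text trajectory dialect written by
#' [write_trajectory_file()]: an optional comment line
#' `# tau=<seconds> subject=<label>`, a header row
#' `frame,m01_x,m01_y,m01_z,...,m10_x,m10_y,m10_z`, and one row per frame.
#' Frames are kept in file order.
#'
#' @param path Path to the CSV file.
#' @param tau Fallback sampling interval (seconds) when the file carries no
#'   `tau=` comment. Default 0.2 s.
#' @param subject Fallback subject label when the file carries none; defaults
#'   to the file name without extension.
#' @param n_markers Expected marker count (default 10, the standard set).
#'
#' @return A [gait_trajectory].
#' @export
read_trajectory_file <- function(path, tau = 0.2, subject = NULL,
                                 n_markers = 10L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) && grepl("^#", lines[1])) {
    meta <- lines[1]
    m <- regmatches(meta, regexec("tau=([0-9.eE+-]+)", meta))[[1]]
    if (length(m) == 2L) tau <- as.numeric(m[2])
    m <- regmatches(meta, regexec("subject=([^ ,]+)", meta))[[1]]
    if (length(m) == 2L) subject <- m[2]
    lines <- lines[-1]
  }
  if (is.null(subject))
    subject <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) < 1L)
    stop("trajectory file has no header row: ", path, call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  expected <- trajectory_header(n_markers)
  if (length(header) != length(expected) || !all(header == expected)) {
    missing <- setdiff(expected, header)
    extra <- setdiff(header, expected)
    stop("trajectory format error in ", path, ": ",
         if (length(missing)) paste0("missing column(s) ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(missing) && length(extra)) "; " else "",
         if (length(extra)) paste0("unexpected column(s) ",
                                   paste(extra, collapse = ", ")) else "",
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) < 2L)
    stop("insufficient data in ", path,
         ": at least 2 frame rows are required", call. = FALSE)
  cells <- strsplit(body, ",", fixed = TRUE)
  ncells <- lengths(cells)
  if (any(ncells != length(expected)))
    stop("parse error in ", path, ": row ", which(ncells != length(expected))[1],
         " has ", ncells[which(ncells != length(expected))[1]],
         " fields, expected ", length(expected), call. = FALSE)
  num <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(body),
           ncol = length(expected), byrow = TRUE))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("parse error in ", path, ": non-numeric value in data row ", bad,
         call. = FALSE)
  }
  coords <- array(num[, -1, drop = FALSE],
                  dim = c(length(body), 3L, n_markers))
  # columns are m01_x,m01_y,m01_z,... -> axis varies fastest
  coords <- aperm(coords, c(1, 3, 2))
  gait_trajectory(coords, subject = subject, tau = tau,
                  frame_index = as.integer(num[, 1]))
}

#' Write a marker-trajectory CSV file
#'
#' Emits the trajectory CSV dialect (see [read_trajectory_file()]) with a
#' `# tau=... subject=...` comment line and full double precision, so that a
#' write/read round trip reproduces the coordinates exactly.
#'
#' @param traj A valid [gait_trajectory].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_file <- function(traj, path) {
  if (!inherits(traj, "gait_trajectory"))
    stop("`traj` must be a gait_trajectory", call. = FALSE)
  if (!all(is.finite(traj$coords)))
    stop("refusing to write trajectory with non-finite coordinates",
         call. = FALSE)
  nm <- n_markers(traj)
  nt <- n_frames(traj)
  # frame rows: frame index then x,y,z per marker
  flat <- matrix(aperm(traj$coords, c(3, 2, 1)), nrow = nt, byrow = TRUE)
  rows <- vapply(seq_len(nt), function(i) {
    paste(c(traj$frame_index[i],
            format(flat[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  }, character(1))
  out <- c(sprintf("# tau=%s subject=%s",
                   format(traj$tau, digits = 17), traj$subject),
           paste(trajectory_header(nm), collapse = ","),
           rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
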