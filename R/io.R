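#' Read an enzyme assay table
#'
#' CSV dialect: columns `variant,T,S_mM,rate,E0_nM,replicate` (header
#' required). Returned with the internal column names used by the fitting
#' functions.
#'
#' @param path File path.
#' @return Data frame with columns `variant`, `T`, `S`, `v`, `E0`,
#'   `replicate`.
#' @export
read_assay_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("variant", "T", "S_mM", "rate", "E0_nM", "replicate")
  if (!all(req %in% names(d)))
    stop("assay CSV needs columns ", paste(req, collapse = ","),
         call. = FALSE)
  data.frame(variant = d$variant, T = d$T, S = d$S_mM, v = d$rate,
             E0 = d$E0_nM, replicate = d$replicate)
}

#' Write an enzyme assay table
#'
#' @param data Assay data frame as produced by [generate_assay_data()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(data, path) {
  out <- data.frame(variant = data$variant, T = data$T, S_mM = data$S,
                    rate = data$v, E0_nM = data$E0,
                    replicate = data$replicate)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read ITC injection heats
#'
#' CSV dialect: columns `injection,volume_ul,heat_uJ`. The titration
#' protocol (cell volume, concentrations, temperature) is supplied
#' separately via [titration_protocol()].
#'
#' @param path File path.
#' @return Data frame with columns `injection`, `volume_ul`, `heat_uJ`.
#' @export
read_itc_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("injection", "volume_ul", "heat_uJ")
  if (!all(req %in% names(d)))
    stop("ITC CSV needs columns ", paste(req, collapse = ","), call. = FALSE)
  d[req]
}

#' Read a denaturation curve
#'
#' CSV dialect: columns `denaturant_M,signal`.
#'
#' @param path File path.
#' @return Data frame with columns `D` and `y`.
#' @export
read_denaturation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("denaturant_M", "signal") %in% names(d)))
    stop("denaturation CSV needs columns denaturant_M,signal", call. = FALSE)
  data.frame(D = d$denaturant_M, y = d$signal)
}

#' Read a dihedral time series
#'
#' CSV dialect: columns `time_ps,chi1,chi2,chi3,chi4` (degrees).
#'
#' @param path File path.
#' @return List with `time` (ps) and `chi` (n x 4 matrix).
#' @export
read_dihedral_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_ps", "chi1", "chi2", "chi3", "chi4")
  if (!all(req %in% names(d)))
    stop("dihedral CSV needs columns ", paste(req, collapse = ","),
         call. = FALSE)
  list(time = d$time_ps, chi = as.matrix(d[, c("chi1", "chi2",
                                               "chi3", "chi4")]))
}

#' Read a distance time series
#'
#' CSV dialect: columns `time_ps,distance_A`.
#'
#' @param path File path.
#' @return Data frame with columns `time` (ps) and `d` (Angstrom).
#' @export
read_distance_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ps", "distance_A") %in% names(d)))
    stop("distance CSV needs columns time_ps,distance_A", call. = FALSE)
  data.frame(time = d$time_ps, d = d$distance_A)
}

#' Read a multi-frame XYZ coordinate file
#'
#' Plain-text dialect: each frame is a block of whitespace-separated
#' `label x y z` lines preceded by a line giving the atom count and an
#' optional comment line (the common multi-frame XYZ layout). Chosen over
#' binary trajectory formats to keep the package free of MD-toolkit
#' coupling.
#'
#' @param path File path.
#' @return List of n x 3 coordinate matrices with atom labels as
#'   rownames.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    natm <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natm)) stop("malformed XYZ: expected atom count at line ", i,
                          call. = FALSE)
    block <- lines[(i + 1L):min(i + natm + 1L, length(lines))]
    # comment line is optional: detect whether the first block line parses
    first <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    has_comment <- length(first) < 4L ||
      any(is.na(suppressWarnings(as.numeric(first[2:4]))))
    rows <- if (has_comment) block[2:(natm + 1L)] else block[1:natm]
    toks <- strsplit(trimws(rows), "\\s+")
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    rownames(xyz) <- vapply(toks, `[[`, "", 1L)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 1L + has_comment + natm
  }
  frames
}

#' Write a multi-frame XYZ coordinate file
#'
#' @param frames List of n x 3 coordinate matrices (rownames used as atom
#'   labels; `"X"` when absent).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- as.matrix(frames[[k]])
    lab <- rownames(f)
    if (is.null(lab)) lab <- rep("X", nrow(f))
    writeLines(as.character(nrow(f)), con)
    writeLines(paste("frame", k), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, f[, 1], f[, 2], f[, 3]),
               con)
  }
  invisible(path)
}
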