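# STAR (RELION dialect) particle metadata.  Column mapping used throughout:
#   rlnAngleRot -> alpha, rlnAngleTilt -> beta, rlnAnglePsi -> gamma (ZYZ),
#   rlnDefocusU/V -> defocus (mean; written equal), rlnImageName NNN@file
#   (1-based slice at the boundary, 0-based internally).

star_tokenize <- function(line) {
  scan(text = line, what = character(), quiet = TRUE)
}

#' Read particle metadata from a STAR file
#'
#' Accepts both the optics-group dialect (`data_optics` + `data_particles`)
#' and the legacy single-block dialect with per-particle optics columns.
#'
#' @param path STAR file.
#' @return object of class `particle_metadata`: list with `particles`
#'   (data.frame: `image_file`, `slice` 0-based, `alpha`, `beta`, `gamma`
#'   degrees, `defocus` Angstrom, `optics_group`) and `optics` (data.frame:
#'   `optics_group`, `voltage_kv`, `pixel_size`, `spherical_aberration_mm`,
#'   `amplitude_contrast`, `lambda_scale`).
#' @export
read_particle_star <- function(path) {
  if (!file.exists(path)) stop(sprintf("STAR file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    l <- trimws(lines[i])
    if (startsWith(l, "data_")) {
      block_name <- l
      i <- i + 1L
      # seek loop_
      while (i <= n && trimws(lines[i]) != "loop_") {
        if (startsWith(trimws(lines[i]), "data_")) break
        i <- i + 1L
      }
      if (i > n || trimws(lines[i]) != "loop_") next
      i <- i + 1L
      cols <- character()
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tok <- star_tokenize(trimws(lines[i]))
        cols <- c(cols, sub("^_", "", tok[1]))
        i <- i + 1L
      }
      rows <- list(); first_line <- i
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (l2 == "" || startsWith(l2, "data_") || startsWith(l2, "#")) break
        tok <- star_tokenize(l2)
        if (length(tok) != length(cols))
          stop(sprintf("malformed STAR row at line %d: %d fields, expected %d",
                       i, length(tok), length(cols)))
        rows[[length(rows) + 1L]] <- tok
        i <- i + 1L
      }
      if (length(rows)) {
        m <- do.call(rbind, rows)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- cols
        blocks[[block_name]] <- df
      }
    } else i <- i + 1L
  }
  if (!length(blocks)) stop("no data blocks found in STAR file")

  pick <- function(df, col, required = TRUE, numeric = TRUE) {
    if (!col %in% names(df)) {
      if (required) stop(sprintf("required STAR column missing: _%s", col))
      return(NULL)
    }
    if (numeric) as.numeric(df[[col]]) else df[[col]]
  }

  part <- if ("data_particles" %in% names(blocks)) blocks[["data_particles"]]
          else blocks[[setdiff(names(blocks), "data_optics")[1]]]
  if (is.null(part)) stop("no particle block found in STAR file")

  img <- pick(part, "rlnImageName", numeric = FALSE)
  split_img <- regmatches(img, regexec("^([0-9]+)@(.+)$", img))
  bad <- vapply(split_img, length, 1L) != 3L
  if (any(bad)) stop("rlnImageName entries must look like 000001@stack.mrcs")
  slice <- vapply(split_img, function(x) as.integer(x[2]), 1L) - 1L
  files <- vapply(split_img, function(x) x[3], "")

  du <- pick(part, "rlnDefocusU")
  dv <- pick(part, "rlnDefocusV", required = FALSE)
  defocus <- if (is.null(dv)) du else (du + dv) / 2
  if (any(!is.finite(defocus)) || any(defocus <= 0))
    stop("defocus values must be finite and positive")
  og <- pick(part, "rlnOpticsGroup", required = FALSE)
  particles <- data.frame(
    image_file = files, slice = slice,
    alpha = pick(part, "rlnAngleRot"),
    beta = pick(part, "rlnAngleTilt"),
    gamma = pick(part, "rlnAnglePsi"),
    defocus = defocus,
    optics_group = if (is.null(og)) 1 else og,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(particles[c("alpha", "beta", "gamma")]))))
    stop("Euler angles must be finite")

  optics <- if ("data_optics" %in% names(blocks)) {
    ob <- blocks[["data_optics"]]
    data.frame(
      optics_group = pick(ob, "rlnOpticsGroup", required = FALSE) %||% 1,
      voltage_kv = pick(ob, "rlnVoltage"),
      pixel_size = pick(ob, "rlnImagePixelSize"),
      spherical_aberration_mm = pick(ob, "rlnSphericalAberration",
                                     required = FALSE) %||% 2.7,
      amplitude_contrast = pick(ob, "rlnAmplitudeContrast",
                                required = FALSE) %||% 0.07,
      lambda_scale = pick(ob, "ligoLambdaScale", required = FALSE) %||% 1)
  } else {
    px <- pick(part, "rlnImagePixelSize", required = FALSE) %||%
      pick(part, "rlnDetectorPixelSize", required = FALSE)
    if (is.null(px)) stop("required STAR column missing: _rlnImagePixelSize")
    data.frame(optics_group = 1,
               voltage_kv = pick(part, "rlnVoltage")[1],
               pixel_size = px[1],
               spherical_aberration_mm = 2.7, amplitude_contrast = 0.07,
               lambda_scale = 1)
  }
  structure(list(particles = particles, optics = optics),
            class = "particle_metadata")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write particle metadata as a STAR file
#'
#' Writes the optics-group dialect; numeric fields use 17 significant
#' digits so a writer/reader round trip preserves doubles exactly.
#'
#' @param path output file.
#' @param poses data.frame with `alpha`, `beta`, `gamma` (degrees).
#' @param defoci per-particle defocus, Angstrom.
#' @param optics an [ewald_optics()].
#' @param image_file stack filename referenced by `rlnImageName`.
#' @return invisibly, `path`.
#' @export
write_particle_star <- function(path, poses, defoci, optics,
                                image_file = "particles.mrcs") {
  np <- nrow(poses)
  g <- function(x) sprintf("%.17g", x)
  out <- c(
    "", "data_optics", "", "loop_",
    "_rlnOpticsGroup #1", "_rlnVoltage #2", "_rlnImagePixelSize #3",
    "_rlnSphericalAberration #4", "_rlnAmplitudeContrast #5",
    "_ligoLambdaScale #6",
    paste(1, g(optics$voltage_kv), g(optics$pixel_size),
          g(optics$spherical_aberration_mm), g(optics$amplitude_contrast),
          g(optics$lambda_scale)),
    "", "data_particles", "", "loop_",
    "_rlnImageName #1", "_rlnAngleRot #2", "_rlnAngleTilt #3",
    "_rlnAnglePsi #4", "_rlnDefocusU #5", "_rlnDefocusV #6",
    "_rlnOpticsGroup #7",
    paste(sprintf("%06d@%s", seq_len(np), image_file),
          g(poses$alpha), g(poses$beta), g(poses$gamma),
          g(defoci), g(defoci), 1),
    "")
  writeLines(out, path)
  invisible(path)
}

#' Construct optics from a read metadata table
#'
#' @param meta a `particle_metadata` from [read_particle_star()].
#' @return an [ewald_optics()] for optics group 1.
#' @export
optics_from_metadata <- function(meta) {
  o <- meta$optics[1, ]
  ewald_optics(o$voltage_kv, o$pixel_size,
               spherical_aberration_mm = o$spherical_aberration_mm,
               amplitude_contrast = o$amplitude_contrast,
               lambda_scale = o$lambda_scale)
}
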