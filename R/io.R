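#' @title File formats
#' @description Plain-text and PNG raster I/O, loss-free trajectory
#'   persistence (per-time CSV field tables + index), frame-stack
#'   persistence, and the YAML run configuration with strict key checking
#'   and a stable content hash.
#' @name io
NULL

#' Read a grayscale raster mask (PNG or plain-text PGM)
#'
#' @param path file ending in `.png`, `.pgm` (P2 ASCII or P5 binary).
#' @return Numeric matrix in `[0, 1]`, rows = image rows.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
    return(img)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported mask format: .", ext, " (use PNG or PGM)")
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw[1:min(2, length(raw))])
  if (identical(txt, "P2")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    tok <- unlist(strsplit(paste(lines, collapse = " "), "\\s+"),
                  use.names = FALSE)
    tok <- tok[nzchar(tok)]
    if (!identical(tok[1], "P2")) stop("corrupt PGM: bad magic")
    tok <- as.numeric(tok[-1])
    w <- tok[1]; h <- tok[2]; maxv <- tok[3]
    px <- tok[-(1:3)]
    if (length(px) != w * h) stop("corrupt PGM: pixel count mismatch")
    matrix(px / maxv, nrow = h, ncol = w, byrow = TRUE)
  } else if (identical(txt, "P5")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readLines(con, n = 1L)  # magic
    hdr <- c()
    while (length(hdr) < 3L) {
      ln <- readLines(con, n = 1L)
      ln <- sub("#.*", "", ln)
      hdr <- c(hdr, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      hdr <- hdr[!is.na(hdr)]
    }
    w <- hdr[1]; h <- hdr[2]; maxv <- hdr[3]
    sz <- if (maxv > 255) 2L else 1L
    px <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE,
                  endian = "big")
    matrix(px / maxv, nrow = h, ncol = w, byrow = TRUE)
  } else stop("not a PGM file: ", path)
}

#' Write a matrix as an ASCII PGM (P2) image
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param maxval maximum gray value (255 for 8-bit, 65535 for 16-bit).
#' @return Invisibly, `path`.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 1))
  v <- round(img * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  # one text line per image row (P2 is row-major)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Export a light pattern as a raster (PNG and/or PGM by extension)
#'
#' Writes the intensity field scaled to the device maximum, plus a
#' sidecar `<file>.scale.txt` with mm_per_px and the intensity scale.
#'
#' @param pattern a `light_pattern`.
#' @param path output path (`.png` or `.pgm`).
#' @return Invisibly, `path`.
#' @export
write_pattern_image <- function(pattern, path) {
  stopifnot(inherits(pattern, "light_pattern"))
  I <- pattern$I / DEVICE_I_MAX
  if (!is.matrix(I)) I <- matrix(I, nrow = 1L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(pmin(pmax(I, 0), 1), path)
  else if (ext == "pgm") write_pgm(pmin(pmax(I, 0), 1), path)
  else stop("unsupported raster format: .", ext)
  writeLines(c(sprintf("mm_per_px = %.17g", pattern$grid$spacing),
               sprintf("I_max_mW_cm2 = %.17g", DEVICE_I_MAX)),
             paste0(path, ".scale.txt"))
  invisible(path)
}

# -- trajectory persistence ----------------------------------------------

#' Persist a trajectory as a directory of plain-text tables
#'
#' One full-precision CSV per stored time (columns x[, y], S, H, E, N, U),
#' an `index.csv` (time, file, per-field min/max) and the solver
#' diagnostics + grid as JSON. The round trip through [load_trajectory()]
#' is loss-free.
#'
#' @param traj a `trajectory`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- traj$grid
  x <- grid_coords(g, 1L)
  idx <- NULL
  for (i in seq_along(traj$times)) {
    s <- traj$states[[i]]
    fn <- sprintf("fields_%04d.csv", i)
    df <- if (g$ndim == 1L)
      data.frame(x = x, S = s$S, H = s$H, E = s$E, N = s$N, U = s$U)
    else {
      y <- grid_coords(g, 2L)
      data.frame(x = rep(x, times = g$n[2]), y = rep(y, each = g$n[1]),
                 S = as.numeric(s$S), H = as.numeric(s$H),
                 E = as.numeric(s$E), N = as.numeric(s$N),
                 U = as.numeric(s$U))
    }
    num <- vapply(df, function(col) sprintf("%.17g", col),
                  character(nrow(df)))
    writeLines(c(paste(names(df), collapse = ","),
                 apply(matrix(num, nrow = nrow(df)), 1, paste,
                       collapse = ",")),
               file.path(dir, fn))
    rng <- vapply(FIELDS, function(f) range(s[[f]]), numeric(2))
    idx <- rbind(idx, data.frame(
      time = s$t, file = fn,
      t(stats::setNames(as.numeric(rng),
                        paste0(rep(FIELDS, each = 2), c("_min", "_max"))))))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  meta <- list(grid = list(ndim = g$ndim, extent = g$extent,
                           spacing = g$spacing, bc = g$bc),
               diagnostics = traj$diagnostics,
               pattern_meta = traj$pattern_meta,
               params = if (!is.null(traj$params))
                 serialize_params(traj$params) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load a trajectory saved by [save_trajectory()]
#'
#' @param dir directory written by [save_trajectory()].
#' @return A `trajectory`.
#' @export
load_trajectory <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  g <- rd_grid(meta$grid$extent, meta$grid$spacing, meta$grid$bc)
  states <- lapply(seq_len(nrow(idx)), function(i) {
    df <- utils::read.csv(file.path(dir, idx$file[i]),
                          colClasses = "numeric")
    shape <- function(v) { if (g$ndim == 2L) dim(v) <- g$n; v }
    structure(list(t = idx$time[i], S = shape(df$S), H = shape(df$H),
                   E = shape(df$E), N = shape(df$N), U = shape(df$U),
                   grid = g), class = "sim_state")
  })
  p <- if (!is.null(meta$params))
    params_from_list(deserialize_params(as.list(meta$params))) else NULL
  diag_ <- meta$diagnostics
  if (!is.null(diag_$clipped)) diag_$clipped <- unlist(diag_$clipped)
  structure(list(times = idx$time, states = states, grid = g, params = p,
                 pattern_meta = meta$pattern_meta, alpha = NULL,
                 diagnostics = diag_),
            class = "trajectory")
}

#' Persist a synthetic frame stack as per-page PGM files plus an index
#'
#' @param stack a [synth_timelapse()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
save_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "synth_timelapse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gmax <- stack$calib$gmax
  as_img <- function(f) {
    m <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
    m / gmax
  }
  write_pgm(as_img(stack$background), file.path(dir, "background.pgm"),
            maxval = gmax)
  files <- sprintf("frame_%04d.pgm", seq_along(stack$frames))
  for (i in seq_along(stack$frames))
    write_pgm(as_img(stack$frames[[i]]), file.path(dir, files[i]),
              maxval = gmax)
  utils::write.csv(data.frame(time = stack$times, page = seq_along(files),
                              file = files),
                   file.path(dir, "index.csv"), row.names = FALSE)
  write_calibration_csv(stack$calib, file.path(dir, "calibration.csv"))
  jsonlite::write_json(stack$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a frame stack saved by [save_frame_stack()]
#'
#' @param dir directory written by [save_frame_stack()].
#' @return List with `frames` (integer matrices), `background`, `times`,
#'   `calib`, `meta`.
#' @export
load_frame_stack <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  calib <- read_calibration_csv(file.path(dir, "calibration.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gmax <- calib$gmax
  rd <- function(f) {
    m <- read_pgm(file.path(dir, f)) * gmax
    storage.mode(m) <- "integer"
    m
  }
  list(frames = lapply(idx$file, rd),
       background = rd("background.pgm"),
       times = idx$time, calib = calib, meta = meta)
}

# -- run configuration ---------------------------------------------------

# JSON/YAML have no Inf literal; encode unbounded parameters as "Inf"
serialize_params <- function(p) {
  lapply(unclass(p), function(v)
    if (is.numeric(v) && is.infinite(v)) "Inf" else v)
}

deserialize_params <- function(l) {
  l <- l[!vapply(l, is.null, logical(1))]
  lapply(l, function(v) if (identical(v, "Inf")) Inf else v)
}

config_template <- function() {
  list(
    grid = list(extent = 40, spacing = 0.1, bc = "noflux"),
    params = serialize_params(kinetic_params()),
    pattern = list(generator = "uniform", I0 = DEVICE_I_MAX, lambda = NULL,
                   duty = 0.25, w = NULL, center = NULL, mask = NULL,
                   mm_per_px = NULL),
    mapping = list(kind = "binary", threshold = 0.1 * DEVICE_I_MAX,
                   I_half = NULL, n = 2),
    init = list(S0 = 10 / 342.30, N0 = 1e6),
    solver = list(rtol = 1e-6, atol = 1e-9, max_dt = 0.05,
                  t_end = 40, out_times = NULL),
    observe = list(I_bg = 1500, a = 12000, N_ref = 1e6, bits = 16,
                   psf_sigma = 0.2, noise_sd = 30),
    seed = 1L)
}

#' Read and resolve a YAML run configuration
#'
#' Unknown keys are rejected with the offending path; missing keys take
#' the documented defaults. The resolved configuration carries a stable
#' FNV-1a content hash used to stamp outputs.
#'
#' @param path YAML file, or `NULL` for the pure defaults.
#' @return List of class `run_config` with attribute `hash`.
#' @export
read_run_config <- function(path = NULL) {
  tmpl <- config_template()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config error: top level must be a mapping")
  check_keys <- function(user, ref, where) {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      stop("config error: unknown key(s) ",
           paste0(where, unknown, collapse = ", "))
  }
  check_keys(cfg, tmpl, "")
  for (sec in names(cfg)) {
    if (is.list(tmpl[[sec]]) && is.list(cfg[[sec]]))
      check_keys(cfg[[sec]], tmpl[[sec]], paste0(sec, "."))
  }
  merged <- utils::modifyList(tmpl, cfg)
  merged$params <- serialize_params(
    params_from_list(deserialize_params(merged$params)))
  out <- structure(merged, class = "run_config")
  attr(out, "hash") <- config_hash(merged)
  out
}

# FNV-1a 32-bit over the canonical JSON serialization (doubles used as
# 32-bit registers; the multiply is split to stay under 2^53)
config_hash <- function(cfg) {
  # canonical form: YAML round trips drop empty (NULL) keys, so they must
  # not participate in the hash
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, drop_nulls)
  }
  js <- jsonlite::toJSON(drop_nulls(unclass(cfg)), auto_unbox = TRUE,
                         digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- ((h %% 65536) * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a resolved configuration back to YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

# build model objects from a resolved config
config_build <- function(cfg) {
  g <- rd_grid(unlist(cfg$grid$extent), cfg$grid$spacing,
               unlist(cfg$grid$bc))
  p <- params_from_list(deserialize_params(cfg$params))
  pt <- cfg$pattern
  pattern <- switch(pt$generator,
    uniform = light_uniform(g, pt$I0),
    single_line = light_single_line(g, pt$w, pt$I0,
                                    pt$center %||% (g$extent[1] / 2)),
    periodic_lines = light_periodic_lines(g, pt$lambda, pt$duty, pt$I0),
    from_image = light_from_image(pt$mask, pt$mm_per_px, g, pt$I0),
    stop("config error: unknown pattern generator '", pt$generator, "'"))
  mp <- cfg$mapping
  alpha <- if (identical(mp$kind, "hill"))
    alpha_map(pattern, p, "hill", I_half = mp$I_half, n = mp$n)
  else alpha_map(pattern, p, "binary", threshold = mp$threshold)
  st0 <- initial_state(g, S0 = cfg$init$S0, N0 = cfg$init$N0)
  ctrl <- cfg$solver[c("rtol", "atol", "max_dt")]
  list(grid = g, params = p, pattern = pattern, alpha = alpha,
       state0 = st0, control = ctrl,
       t_end = cfg$solver$t_end,
       out_times = if (is.null(cfg$solver$out_times)) NULL else
         unlist(cfg$solver$out_times))
}
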