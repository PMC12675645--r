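# Image/volume readers and writers, run configuration, and the end-to-end
# pipeline. Images are stored as PGM (portable graymap, 8- or 16-bit, binary
# P5 or ASCII P2) with a JSON metadata sidecar; configurations are JSON.

#' Write a grayscale image as PGM
#'
#' Integer matrices are written as-is at the requested bit depth (lossless
#' round trip); floating-point matrices are expected on `[0, 1]` and are
#' quantized to the full range of the bit depth.
#'
#' @param img numeric or integer matrix.
#' @param path output path.
#' @param bits 8 or 16.
#' @param format `"P5"` (binary, default) or `"P2"` (ASCII).
#' @return the path, invisibly.
#' @export
write_pgm <- function(img, path, bits = 8L, format = c("P5", "P2")) {
  format <- match.arg(format)
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  maxval <- 2L^bits - 1L
  if (is.double(img)) {
    if (min(img) < 0 || max(img) > 1)
      stop("floating-point images must lie in [0, 1]; normalize first")
    q <- round(img * maxval)
  } else {
    q <- img
    if (min(q) < 0 || max(q) > maxval)
      stop("integer image exceeds the ", bits, "-bit range")
  }
  header <- sprintf("%s\n%d %d\n%d\n", format, ncol(q), nrow(q), maxval)
  # PGM is row-major from the top row
  vals <- as.integer(t(q))
  if (format == "P2") {
    body <- paste(apply(q, 1, paste, collapse = " "), collapse = "\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(header, body, "\n"), con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    if (bits == 8L) writeBin(vals, con, size = 1)
    else writeBin(vals, con, size = 2, endian = "big")
  }
  invisible(path)
}

#' Read a PGM image
#'
#' @param path a P2 or P5 PGM file.
#' @return integer matrix with attribute `maxval`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens (magic, width, height, maxval), '#' comments allowed
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("corrupt PGM: truncated header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      # separator
    } else {
      word <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
        word <- paste0(word, ch)
      }
      tok <- c(tok, word)
    }
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5") || anyNA(c(w, h, maxval)))
    stop("unsupported or corrupt PGM: ", path)
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("corrupt PGM: expected ", n, " pixels")
  out <- matrix(vals, h, w, byrow = TRUE)
  attr(out, "maxval") <- maxval
  out
}

#' Write / read a radiograph with its metadata sidecar
#'
#' The pixel array is max-normalized over its own range, quantized at the
#' requested bit depth and stored as PGM; the range, pixel spacing and
#' acquisition metadata go to `<path>.json`. Reading reverses the
#' quantization using the sidecar (exact up to the stored bit depth).
#'
#' @param rg a [radiograph()].
#' @param path `.pgm` output path.
#' @param bits 8 or 16 (default 16).
#' @param format `"P5"` or `"P2"`.
#' @return `write_radiograph` the path invisibly; `read_radiograph` a
#'   [radiograph()].
#' @export
write_radiograph <- function(rg, path, bits = 16L, format = "P5") {
  stopifnot(inherits(rg, "radiograph"))
  r <- range(rg$pixels)
  write_pgm(norm01(rg$pixels), path, bits = bits, format = format)
  ang <- rg$meta$angles
  side <- list(min = r[1], max = r[2], bits = bits,
               pixel_spacing = rg$pixel_spacing,
               energy = rg$meta$energy, phase = rg$meta$phase,
               kind = rg$meta$kind,
               angles = if (!is.null(ang))
                 list(theta = ang$theta, phi = ang$phi, gamma = ang$gamma))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_radiograph
#' @export
read_radiograph <- function(path) {
  q <- read_pgm(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("metadata sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  px <- q / attr(q, "maxval") * (side$max - side$min) + side$min
  ang <- if (!is.null(side$angles))
    acquisition_angles(side$angles$theta, side$angles$phi, side$angles$gamma)
  radiograph(px, pixel_spacing = unlist(side$pixel_spacing),
             energy = side$energy %||% NA_character_,
             phase = side$phase %||% NA_integer_,
             angles = ang, kind = side$kind %||% "SE")
}

#' Save / load a phantom volume
#'
#' Runtime serialization of a `material_volume` (single RDS file).
#'
#' @param vol a `material_volume`.
#' @param path file path.
#' @return `load_volume` the volume; `save_volume` the path, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "material_volume"))
  saveRDS(vol, path)
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) {
  vol <- readRDS(path)
  stopifnot(inherits(vol, "material_volume"))
  vol
}

#' Default end-to-end run configuration
#'
#' A deliberately small configuration that exercises all four pipeline parts
#' in seconds; scale the grid, epochs and cases up for real runs.
#'
#' @param seed master seed (fans out per stage via [derive_seed()]).
#' @return nested configuration list (JSON-serializable).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    sim = list(shape = c(32L, 32L, 32L), spacing = 8, tumor_diameter = 20),
    grid = list(gantry_deg = c(90, 180), couch_deg = c(0, 16), phases = 1:5),
    omega = 0.5,
    model = list(depth = 2L, base_filters = 4L, input_shape = c(32L, 32L),
                 epochs = 2L, batch_size = 4L),
    cases = list(list(theta = 9, phi = 28, gantry = 180, n_frames = 20L,
                      cycles = 2L, tumor_diameter = 20)),
    tracker = list(search_radius = 8)
  )
}

#' Read / write a run configuration (JSON)
#' @param config configuration list.
#' @param path JSON file path.
#' @return `read_run_config` the configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

pipeline_log <- function(out_dir, stage, t0) {
  msg <- sprintf("[%s] %s: %.2f s", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0)
  cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  message(msg)
}

#' Run the four-part pipeline
#'
#' Part 1 prepares the (SE, DES) training dataset from the phantom; part 2
#' trains the residual U-Net; part 3 synthesizes DES for the configured test
#' cases; part 4 runs the SE-vs-DES tracking comparison. Each part writes its
#' artifacts under `out_dir/partN_*`; with `resume = "partN"` the outputs of
#' earlier parts are loaded from disk instead of recomputed.
#'
#' @param config configuration list, see [default_run_config()].
#' @param out_dir output directory (created if needed).
#' @param resume `NULL` (run everything) or one of `"part2"`, `"part3"`,
#'   `"part4"`.
#' @return invisible list with the per-part artifacts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         resume = NULL) {
  if (!is.null(resume))
    resume <- match.arg(resume, c("part2", "part3", "part4"))
  start_at <- if (is.null(resume)) 1L else as.integer(substring(resume, 5))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- list(shape = as.integer(config$sim$shape), spacing = config$sim$spacing)
  omega <- config$omega %||% 0.5
  d1 <- file.path(out_dir, "part1_dataset")
  d2 <- file.path(out_dir, "part2_model")
  d3 <- file.path(out_dir, "part3_synthesis")
  d4 <- file.path(out_dir, "part4_tracking")

  # Part 1: training data preparation
  if (start_at <= 1) {
    t0 <- as.numeric(Sys.time())
    unlink(d1, recursive = TRUE)
    pcfg <- phantom_config(shape = sim$shape, spacing = sim$spacing,
                           tumor_diameter = config$sim$tumor_diameter %||% 10)
    grid <- enumerate_training_grid(gantry_deg = config$grid$gantry_deg,
                                    couch_deg = config$grid$couch_deg,
                                    phases = config$grid$phases)
    ds <- generate_dataset(pcfg, grid, omega = omega,
                           seed = derive_seed(config$seed, "dataset"),
                           out_dir = d1)
    saveRDS(ds$pairs, file.path(d1, "pairs.rds"))
    pipeline_log(out_dir, "part1 (dataset)", t0)
  } else {
    if (!file.exists(file.path(d1, "pairs.rds")))
      stop("part1: cannot resume, ", d1, " is missing")
    ds <- list(pairs = readRDS(file.path(d1, "pairs.rds")))
  }

  # Part 2: model training
  if (start_at <= 2) {
    t0 <- as.numeric(Sys.time())
    unlink(d2, recursive = TRUE)
    dir.create(d2, recursive = TRUE, showWarnings = FALSE)
    margs <- config$model
    mcfg <- unet_config(depth = margs$depth %||% 3L,
                        base_filters = margs$base_filters %||% 8L,
                        input_shape = margs$input_shape %||% sim$shape[c(1, 3)],
                        epochs = margs$epochs %||% 20L,
                        batch_size = margs$batch_size %||% 8L,
                        seed = derive_seed(config$seed, "model"))
    model <- train_synthesizer(build_model(mcfg), ds$pairs)
    save_synthesizer(model, file.path(d2, "model.rds"))
    write.csv(model$history, file.path(d2, "training_log.csv"),
              row.names = FALSE)
    pipeline_log(out_dir, "part2 (training)", t0)
  } else {
    if (!file.exists(file.path(d2, "model.rds")))
      stop("part2: cannot resume, ", d2, " is missing")
    model <- load_synthesizer(file.path(d2, "model.rds"))
  }

  cases <- lapply(config$cases, function(cc) do.call(case_config, cc))

  # Part 3: DES synthesis on the test cases
  if (start_at <= 3) {
    t0 <- as.numeric(Sys.time())
    unlink(d3, recursive = TRUE)
    dir.create(d3, recursive = TRUE, showWarnings = FALSE)
    for (ci in seq_along(cases)) {
      s <- simulate_case(cases[[ci]], sim, omega = omega)
      used <- which(!duplicated(s$phases))
      for (i in used) {
        syn <- synthesize(model, s$se[[i]])
        write_radiograph(syn, file.path(d3, sprintf("case%02d_phase%02d_des.pgm",
                                                    ci, s$phases[i])))
      }
    }
    eval_tab <- run_synthesis_eval(model, cases, sim, omega = omega)
    jsonlite::write_json(eval_tab, file.path(d3, "synthesis_eval.json"),
                         digits = NA, pretty = TRUE)
    pipeline_log(out_dir, "part3 (synthesis)", t0)
  } else {
    eval_tab <- jsonlite::read_json(file.path(d3, "synthesis_eval.json"),
                                    simplifyVector = TRUE)
  }

  # Part 4: tumor tracking comparison
  t0 <- as.numeric(Sys.time())
  unlink(d4, recursive = TRUE)
  dir.create(d4, recursive = TRUE, showWarnings = FALSE)
  report <- run_tracking_comparison(cases, sim,
                                    search_radius = config$tracker$search_radius %||% 20,
                                    seed = derive_seed(config$seed, "tracking"),
                                    omega = omega)
  jsonlite::write_json(report, file.path(d4, "tracking_report.json"),
                       digits = NA, pretty = TRUE)
  write.csv(report$cases, file.path(d4, "tracking_report.csv"),
            row.names = FALSE)
  pipeline_log(out_dir, "part4 (tracking)", t0)

  invisible(list(pairs = ds$pairs, model = model, synthesis_eval = eval_tab,
                 tracking = report))
}
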