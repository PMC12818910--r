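# End-to-end pipeline and IO glue: configuration, orchestration
# (segmentation -> contour -> optional normalization -> centerline ->
# tip/bottom -> kinematics -> optional kymograph + band fits), and the
# standard-format readers/writers.

fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

natural_sort <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(gsub("\\D*(\\d+).*", "\\1", base)))
  num[is.na(num)] <- Inf
  paths[order(num, base)]
}

#' Read an image sequence from disk
#'
#' Accepts one multi-page TIFF path or a character vector / glob of
#' single-page files (natural-sorted by the first number in the filename).
#'
#' @param path file path(s) or a glob pattern.
#' @param pixel_size micrometers per px; `dt` frame interval.
#' @param time_unit time axis unit label.
#' @return an [image_sequence()] with channel `"main"`.
#' @export
read_sequence <- function(path, pixel_size, dt, time_unit = "min") {
  if (length(path) == 1 && !file.exists(path)) {
    expanded <- Sys.glob(path)
    if (length(expanded) == 0) stop("cannot read input: ", path)
    path <- expanded
  }
  if (length(path) > 1) path <- natural_sort(path)
  frames <- list()
  for (p in path) {
    if (!file.exists(p)) stop("cannot read input: ", p)
    for (m in read_tiff(p)) frames[[length(frames) + 1]] <- m
  }
  image_sequence(list(main = frames), pixel_size, dt, time_unit)
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with explicit defaults; the
#' full realized configuration (no silent defaults) is written to the run
#' log.
#'
#' @param input contour-channel input: path(s) or an [image_sequence()].
#' @param signal optional signal-channel input: path(s), or NULL. Ignored
#'   when `input` is a multi-channel [image_sequence()] with a `"signal"`
#'   channel.
#' @param masks optional externally generated mask path(s); switches
#'   segmentation to external-mask ingestion.
#' @param pixel_size,dt,time_unit calibration (used when `input` is a path).
#' @param normalize rigidly align frames before analysis (default TRUE).
#' @param reference_frame 0-based reference frame for normalization.
#' @param registration_strategy `"successive"` or `"direct"`.
#' @param register_on_mask register on Otsu masks instead of intensities.
#' @param search search ranges for [register_frame()].
#' @param polarity `"bright_object"` or `"dark_object"` for Otsu.
#' @param smooth_contours,contour_frac lowess smoothing of contours
#'   (default off; the published default is raw contours).
#' @param centerline_span loess span conditioning the centerline body
#'   before arc-length measurement (0 disables; see
#'   [extrapolate_to_edge()]).
#' @param k terminal points for tip/bottom extrapolation.
#' @param min_branch_length skeleton pruning threshold (px); NULL = auto
#'   (half the estimated cell width).
#' @param bottom_anchor c(x, y) identifying the bottom end in frame 0;
#'   required (there is no unsupervised tip/bottom assignment).
#' @param anchor kymograph anchor, `"bottom"` or `"tip"`.
#' @param profile_step,halfwidth axial profile sampling (um); halfwidth
#'   NULL = 40% of the local cell width.
#' @param profile_stat `"mean"` or `"max"` across the cross-section.
#' @param end_k band-end multiplier (ends at mu +/- end_k * sigma).
#' @param velocity_window moving-average window for dL/dt (1 = off).
#' @param outdir output directory.
#' @param seed top-level seed (the pipeline itself is deterministic; the
#'   seed is recorded and forwarded to anything stochastic).
#' @param write_plots write PNG plots (default TRUE).
#' @return a validated `run_config` list.
#' @export
run_config <- function(input, signal = NULL, masks = NULL, pixel_size = 1,
                       dt = 1, time_unit = "min", normalize = TRUE,
                       reference_frame = 0L,
                       registration_strategy = "successive",
                       register_on_mask = FALSE,
                       search = list(u = c(-15, 15), v = c(-15, 15),
                                     theta = c(-15, 15)),
                       polarity = "bright_object", smooth_contours = FALSE,
                       contour_frac = 0.05, centerline_span = 0.2, k = 5L,
                       min_branch_length = NULL, bottom_anchor = NULL,
                       anchor = "bottom", profile_step = 0.5,
                       halfwidth = NULL, profile_stat = "mean", end_k = 1,
                       velocity_window = 1L, outdir = tempfile("tipgrow_run"),
                       seed = 1L, write_plots = TRUE) {
  stopifnot(pixel_size > 0, dt > 0)
  cfg <- as.list(environment())
  cfg$segmentation_mode <- if (is.null(masks)) "otsu" else "external_masks"
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  flat <- cfg[!vapply(cfg, function(x) inherits(x, "image_sequence"), TRUE)]
  fnv1a(paste(deparse(flat), collapse = ""))
}

#' Run the full tip-growth pipeline
#'
#' Executes segmentation -> contour -> (normalization) -> centerline ->
#' tip/bottom -> kinematics, and, when a signal channel is present,
#' kymograph construction and band tracking. All tables are written under
#' `config$outdir` along with a JSON run log carrying every realized
#' parameter, the configuration hash and the package version. Deterministic
#' given configuration + seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a result bundle: `trace`, `centerlines`, `contours`,
#'   `transforms`, `profiles`, `kymograph`, `band`, `outdir`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  seq <- if (inherits(config$input, "image_sequence")) config$input
         else read_sequence(config$input, config$pixel_size, config$dt,
                            config$time_unit)
  if (!is.null(config$signal) && is.character(config$signal)) {
    sigseq <- read_sequence(config$signal, seq$pixel_size, seq$dt)
    if (n_frames(sigseq) != n_frames(seq))
      stop("signal channel frame count mismatch")
    seq$channels$signal <- sigseq$channels$main
  }
  nf <- n_frames(seq)
  dimv <- dim(seq$channels[[1]][[1]])
  stage <- function(name, frame, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s, frame %s] %s", name, frame, conditionMessage(e)),
           call. = FALSE))
  }

  transforms <- NULL
  if (config$normalize) {
    reg <- stage("register", "all",
      normalize_sequence(seq, config$reference_frame, channel = "main",
                         strategy = config$registration_strategy,
                         search = config$search,
                         use_mask = config$register_on_mask,
                         polarity = config$polarity))
    seq <- reg$seq
    transforms <- reg$transforms
    write.csv(transforms_table(transforms),
              file.path(config$outdir, "transforms.csv"), row.names = FALSE)
  }

  masks <- if (config$segmentation_mode == "external_masks") {
    m <- stage("load_masks", "all",
               load_masks(config$masks, nf, shape = dimv))
    if (config$normalize)
      m <- lapply(seq_len(nf), function(i) {
        t <- transforms[[i]]
        g <- apply_rigid(m[[i]]$grid * 1, t$u, t$v, t$theta) > 0.5
        structure(list(grid = cpp_fill_holes(g), frame_index = i - 1L),
                  class = "binary_mask")
      })
    m
  } else {
    lapply(seq_len(nf), function(i)
      stage("binarize_otsu", i - 1,
            binarize_otsu(get_frame(seq, i - 1, "main"), config$polarity,
                          i - 1L)))
  }

  contours <- lapply(seq_len(nf), function(i) {
    cc <- stage("extract_contour", i - 1, extract_contour(masks[[i]]))
    if (config$smooth_contours)
      cc <- stage("smooth_contour", i - 1,
                  smooth_contour(cc, config$contour_frac))
    cc
  })
  write_contours(contours, file.path(config$outdir, "contours.csv"))

  centerlines <- vector("list", nf)
  prev <- NULL
  for (i in seq_len(nf)) {
    cl <- stage("centerline", i - 1, {
      sk <- voronoi_skeleton(contours[[i]])
      poly <- prune_to_centerline(sk, config$min_branch_length)
      extrapolate_to_edge(poly, contours[[i]], config$k, seq$pixel_size,
                          smooth_span = config$centerline_span)
    })
    cl <- stage("orient", i - 1,
                orient_centerline(cl, prev = prev,
                                  anchor = if (is.null(prev))
                                    config$bottom_anchor else NULL))
    centerlines[[i]] <- cl
    prev <- cl
  }
  write_centerlines(centerlines, config$outdir)

  trace <- stage("kinematics", "all",
                 build_tip_trace(centerlines, transforms = NULL,
                                 dt = seq$dt, pixel_size = seq$pixel_size,
                                 velocity_window = config$velocity_window))
  write.csv(trace, file.path(config$outdir, "trace.csv"), row.names = FALSE)
  if (config$write_plots)
    plot_tip_trace(trace, file.path(config$outdir, "trace.png"),
                   seq$time_unit)

  profiles <- kymo <- band <- NULL
  if ("signal" %in% names(seq$channels)) {
    profiles <- lapply(seq_len(nf), function(i)
      stage("profile", i - 1,
            profile_along_centerline(get_frame(seq, i - 1, "signal"),
                                     centerlines[[i]],
                                     halfwidth = config$halfwidth,
                                     step = config$profile_step,
                                     contour = contours[[i]],
                                     stat = config$profile_stat)))
    kymo <- stage("kymograph", "all",
                  build_kymograph(profiles, config$anchor, seq$dt))
    write_kymograph(kymo, config$outdir)
    band <- stage("band", "all", track_band(profiles, seq$dt, config$end_k))
    write.csv(band, file.path(config$outdir, "band.csv"), row.names = FALSE)
  }

  log <- list(package = "tipgrow",
              version = as.character(utils::packageVersion("tipgrow")),
              config_hash = config_hash(config),
              config = config[!vapply(config, function(x)
                inherits(x, "image_sequence"), TRUE)],
              n_frames = nf, frame_shape = dimv,
              channels = names(seq$channels))
  jsonlite::write_json(log, file.path(config$outdir, "runlog.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  invisible(list(trace = trace, centerlines = centerlines,
                 contours = contours, transforms = transforms,
                 profiles = profiles, kymograph = kymo, band = band,
                 outdir = config$outdir, log = log))
}
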