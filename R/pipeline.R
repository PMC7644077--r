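#' @include AllClasses.R videoio.R edges.R spectrum.R evm.R motion.R validate.R synthio.R preprocess.R
NULL

.allowedKeys <- list(
  top = c("seed", "output_dir", "input", "synth", "roi", "channels",
          "preprocess", "edges", "spectrum", "magnify", "directors",
          "phase", "validate", "plots"),
  input = c("path", "frame_rate", "nz", "z_index"),
  synth = c("kind", "size", "frames", "frame_rate", "motion_freq",
            "amplitude_px", "direction_deg", "noise_sigma", "radius"),
  preprocess = c("deconvolve", "stabilize"),
  deconvolve = c("iterations", "psf_path", "psf_size"),
  stabilize = c("reference", "smooth_window", "search"),
  edges = c("gth", "method", "window"),
  spectrum = c("L", "taper", "channel"),
  magnify = c("alpha", "freq", "band", "levels", "orientations",
              "sigma_spatial"),
  directors = c("l", "mth", "mth_auto", "control_roi", "quantile"),
  phase = c("n_fit"),
  validate = c("control_path", "alphas", "freq", "band",
               "noise_threshold"))

.checkKeys <- function(block, name) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), .allowedKeys[[name]])
  if (length(bad))
    stop("unknown key(s) in '", if (name == "top") "config" else name,
         "': ", paste(bad, collapse = ", "), call. = FALSE)
  invisible()
}

.validateConfig <- function(cfg) {
  .checkKeys(cfg, "top")
  for (nm in c("input", "synth", "preprocess", "edges", "spectrum",
               "magnify", "directors", "phase", "validate"))
    .checkKeys(cfg[[nm]], nm)
  if (!is.null(cfg$preprocess)) {
    .checkKeys(cfg$preprocess$deconvolve, "deconvolve")
    .checkKeys(cfg$preprocess$stabilize, "stabilize")
  }
  if (is.null(cfg$input) && is.null(cfg$synth))
    stop("config needs an 'input' or a 'synth' block", call. = FALSE)
  invisible(cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline from a config
#'
#' Executes the enabled stages in order — synthesize or read the input
#' video, crop/select channels, preprocess (deconvolution,
#' stabilization), detect edges, estimate the spectrum, magnify, detect
#' motion directors, annotate phase, and validate against a control —
#' writing every intermediate artifact into \code{output_dir} together
#' with a manifest (parameters, package version, key results, md5
#' checksums of all written files) so any run can be reproduced and
#' compared. All stochastic steps derive from the single \code{seed}
#' (default 1, fixed rather than time-based).
#'
#' @param config path to a YAML config file, or an equivalent named
#'   list. Unknown keys are rejected before any computation.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validateConfig(cfg)
  outDir <- cfg$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  artifacts <- character()
  results <- list()
  saveVideo <- function(v, name) {
    p <- file.path(outDir, name)
    writeVideo(v, p)
    artifacts <<- c(artifacts, p, .metaPath(p))
    p
  }
  saveTable <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }

  video <- if (!is.null(cfg$synth)) .stage("synth", {
    s <- cfg$synth
    spec <- fixtureSpec(kind = s$kind %||% "oscillating_texture",
                        size = unlist(s$size %||% c(128L, 128L)),
                        frames = s$frames %||% 480L,
                        frameRate = s$frame_rate %||% 24,
                        motionFreq = s$motion_freq %||% 1,
                        amplitudePx = s$amplitude_px %||% 0.36,
                        directionDeg = s$direction_deg %||% 90,
                        noiseSigma = s$noise_sigma %||% 0.01,
                        seed = seed,
                        radius = s$radius %||%
                          (min(unlist(s$size %||% c(128L, 128L))) / 4))
    fx <- makeFixture(spec)
    saveVideo(fx$video, "input.tif")
    saveTable(fx$truth, "truth.csv")
    fx$video
  }) else .stage("input", {
    readVideo(cfg$input$path, frameRate = cfg$input$frame_rate,
              nz = cfg$input$nz %||% 1L, zIndex = cfg$input$z_index %||% 1L)
  })

  if (!is.null(cfg$roi)) video <- .stage("roi", {
    r <- unlist(cfg$roi)
    cropROI(video, rectROI(r[1], r[2], r[3], r[4]))
  })
  if (!is.null(cfg$channels))
    video <- .stage("channels", selectChannels(video, unlist(cfg$channels)))

  if (!is.null(cfg$preprocess)) video <- .stage("preprocess", {
    pp <- cfg$preprocess
    v <- video
    if (!is.null(pp$deconvolve)) {
      dc <- pp$deconvolve
      psf <- if (!is.null(dc$psf_path))
        psfModel(tiff::readTIFF(dc$psf_path)) else NULL
      v <- deconvolve(v, psf, iterations = dc$iterations %||% 10L,
                      psfSize = dc$psf_size %||% 7L)
    }
    if (!is.null(pp$stabilize)) {
      st <- pp$stabilize
      res <- stabilize(v, reference = st$reference %||% 1L,
                       smoothWindow = st$smooth_window %||% 5L,
                       search = st$search %||% 4L)
      saveTable(transforms(res), "transforms.csv")
      v <- res@video
    }
    saveVideo(v, "preprocessed.tif")
    v
  })

  edgeMask <- NULL
  if (!is.null(cfg$edges)) edgeMask <- .stage("edges", {
    e <- cfg$edges
    em <- detectEdges(video, gth = e$gth, method = e$method %||% "sobel",
                      window = if (!is.null(e$window)) unlist(e$window))
    saveTable(edgeCoords(em), "edges.csv")
    results$edge_pixels <- edgeCount(em)
    em
  })

  spec <- NULL
  if (!is.null(cfg$spectrum)) spec <- .stage("spectrum", {
    if (is.null(edgeMask)) stop("spectrum stage requires an edges stage")
    s <- cfg$spectrum
    sp <- estimateSpectrum(video, edgeMask, L = s$L,
                           channel = s$channel %||% 1L,
                           taper = s$taper %||% "none")
    saveTable(spectrumTable(sp), "spectrum.csv")
    results$dominant_freq_hz <- dominantFreq(sp)
    results$dominant_period_s <- dominantPeriod(sp)
    results$prominence_pct <- sp@dominantProminence
    results$M <- sp@M
    results$L <- sp@L
    results$N <- nFrames(video)
    sp
  })

  magnified <- NULL
  if (!is.null(cfg$magnify)) magnified <- .stage("magnify", {
    m <- cfg$magnify
    freq <- m$freq %||% (if (!is.null(spec)) dominantFreq(spec) else
      stop("magnify needs 'freq' or a spectrum stage"))
    params <- magnificationParams(
      alpha = m$alpha %||% 10,
      centerFreq = freq,
      halfBand = m$band %||% max(0.1 * freq,
                                 frameRate(video) / nFrames(video)),
      levels = m$levels %||% 4L,
      orientations = m$orientations %||% 4L,
      sigmaSpatial = m$sigma_spatial %||% 2)
    mv <- magnify(video, params)
    saveVideo(mv, "magnified.tif")
    results$alpha <- params@alpha
    results$magnified_freq_hz <- freq
    mv
  })

  directors <- NULL
  if (!is.null(cfg$directors)) directors <- .stage("directors", {
    dcfg <- cfg$directors
    target <- magnified %||% video
    grid <- buildGrid(frameDim(target), dcfg$l %||% 9L)
    mth <- if (isTRUE(dcfg$mth_auto)) {
      r <- unlist(dcfg$control_roi)
      autoMotionThreshold(target, rectROI(r[1], r[2], r[3], r[4]),
                          dcfg$l %||% 9L, dcfg$quantile %||% 0.95)
    } else dcfg$mth
    dirs <- findDirectors(target, grid, mth)
    if (length(dirs)) saveTable(directorTable(dirs), "directors.csv")
    results$n_directors <- length(dirs)
    saveVideo(renderDirectors(target, dirs), "annotated.tif")
    dirs
  })

  if (!is.null(cfg$phase)) .stage("phase", {
    if (is.null(directors) || !length(directors))
      stop("phase stage requires a directors stage with detections")
    best <- directors[[which.max(vapply(directors,
                                        function(d) max(d@scores),
                                        numeric(1)))]]
    ky <- phaseAnnotate(magnified %||% video, best,
                        nFit = cfg$phase$n_fit %||% 5L)
    saveTable(data.frame(frame = seq_along(ky@cmTrack) - 1L,
                         cm = ky@cmTrack, phase_sign = ky@phaseSign),
              "phase.csv")
    results$phase_flips <- sum(diff(sign(ky@phaseSign[ky@phaseSign != 0])) != 0)
  })

  if (!is.null(cfg$validate)) .stage("validate", {
    vc <- cfg$validate
    control <- readVideo(vc$control_path)
    freq <- vc$freq %||% (if (!is.null(spec)) dominantFreq(spec) else
      stop("validate needs 'freq' or a spectrum stage"))
    params <- magnificationParams(1, freq,
                                  halfBand = vc$band %||% 0.1 * freq)
    curve <- noiseFloorCurve(video, control,
                             unlist(vc$alphas %||% c(2, 5, 10, 20)),
                             params,
                             noiseThreshold = vc$noise_threshold %||% 1e-4)
    saveTable(curve@table, "noise_floor.csv")
    results$noise_floor_verdicts <- paste(curve@table$verdict,
                                           collapse = ",")
  })

  manifest <- list(
    package = "cellmag",
    version = tryCatch(as.character(utils::packageVersion("cellmag")), error = function(e) "dev"),
    seed = seed,
    config = cfg,
    results = results,
    artifacts = as.list(tools::md5sum(sort(unique(artifacts)))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
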