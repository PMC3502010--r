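# Readers/writers for the formats the pipeline touches (PNG and TIFF
# grayscale images, CSV contours and feature tables, JSON reports) and the
# top-level pipeline runner. Intensities are converted to real values on
# read and re-quantized only on write.

#' Read a grayscale image
#'
#' Reads PNG or TIFF. RGB(A) input is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) with a warning. Intensities are
#' returned on a `[0, 255]` scale (fractional values are preserved for
#' float TIFF). DICOM is not supported.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    stop("unsupported format: .", ext, " (PNG or TIFF expected)",
         call. = FALSE))
  if (length(dim(a)) == 3) {
    warning("multi-channel image converted to luminance")
    ch <- dim(a)[3]
    a <- if (ch >= 3)
      0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    else a[, , 1]
  }
  a
}

#' Write a grayscale image
#'
#' Rescales the (given or observed) intensity `range` to `[0, 1]` and
#' writes it: PNG quantized to 8 bits, TIFF as 32-bit float (so fractional
#' intensities survive a round trip through [read_image()] when
#' `range = c(0, 255)`).
#'
#' @param image Numeric matrix.
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @param range Intensity range mapped to black..white
#'   (default: observed range).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, range = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (is.null(range)) range <- c(min(image), max(image))
  span <- diff(range)
  norm <- if (span > 0) (image - range[1]) / span else image * 0
  norm <- pmin(pmax(norm, 0), 1)
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 32, reduce = FALSE)
  } else stop("unsupported format: .", ext, call. = FALSE)
  invisible(path)
}

#' Write / read a contour as CSV
#'
#' Plain two-column `x,y` CSV, one vertex per row, implicitly closed.
#'
#' @param contour 2-column matrix.
#' @param path CSV path.
#' @return `path` (write) or the contour matrix (read).
#' @export
write_contour <- function(contour, path) {
  utils::write.csv(data.frame(x = contour[, 1], y = contour[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y")])
}

#' Run configuration
#'
#' Bundles the per-stage parameters and the global seed for
#' [run_pipeline()].
#'
#' @param seed Global integer seed; every stochastic stage derives its
#'   stream from it.
#' @param diffusion A [diffusion_params()].
#' @param snake A [snake_params()].
#' @param svm An [svm_config()].
#' @param selection A [selection_config()].
#' @param spacing Pixel spacing in mm for size features.
#' @param repulsive Use the repulsive external force for segmentation.
#' @param canny_sigma,canny_q Edge-extraction smoothing scale and
#'   high-threshold quantile.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, diffusion = diffusion_params(),
                       snake = snake_params(), svm = svm_config(),
                       selection = selection_config(seed = seed),
                       spacing = 1, repulsive = TRUE,
                       canny_sigma = 1, canny_q = 0.9) {
  structure(list(seed = seed, diffusion = diffusion, snake = snake,
                 svm = svm, selection = selection, spacing = spacing,
                 repulsive = repulsive, canny_sigma = canny_sigma,
                 canny_q = canny_q),
            class = "run_config")
}

#' Run the full analysis pipeline on one image
#'
#' Chains the three stages on a single image: edge-enhanced diffusion
#' denoising, repulsive-snake segmentation from the supplied initial
#' contour(s), and morphometric feature extraction for each segmented
#' node. All artifacts (denoised image, edge map, contours, masks, feature
#' table) are written under `out_dir` together with a provenance JSON
#' recording parameters and seed; a re-run with the same config and inputs
#' reproduces the outputs byte for byte.
#'
#' @param image Numeric matrix (the observed image).
#' @param inits List of initial contours (2-column matrices), one per node.
#' @param config A [run_config()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return List with `denoised`, `edges`, and per-node `contours`, `masks`,
#'   plus the `features` data frame (one row per node, 19 canonical
#'   columns).
#' @export
run_pipeline <- function(image, inits, config = run_config(),
                         out_dir = NULL) {
  check_image(image)
  if (inherits(inits, "matrix")) inits <- list(inits)
  if (length(inits) == 0)
    stop("at least one initial contour is required", call. = FALSE)
  for (ct in inits)
    if (!is.matrix(ct) || ncol(ct) != 2 || nrow(ct) < 8)
      stop("each initial contour must be an (x, y) matrix with >= 8 points",
           call. = FALSE)

  denoised <- edge_enhanced_diffusion(image, config$diffusion)
  thr <- canny_auto_thresholds(denoised, config$canny_sigma, config$canny_q)
  edges <- canny_edges(denoised, thr$low, thr$high, config$canny_sigma)

  contours <- vector("list", length(inits))
  masks <- vector("list", length(inits))
  feats <- matrix(NA_real_, length(inits), 19,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_along(inits)) {
    seg <- segment_node(denoised, inits[[i]], config$snake,
                        repulsive = config$repulsive)
    contours[[i]] <- seg$contour
    masks[[i]] <- seg$mask
    feats[i, ] <- extract_features(denoised, seg$mask, config$spacing)
  }
  features <- data.frame(node = seq_along(inits), feats,
                         check.names = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(denoised, file.path(out_dir, "denoised.tif"))
    write_image(edges, file.path(out_dir, "edges.png"), range = c(0, 1))
    for (i in seq_along(inits)) {
      write_contour(contours[[i]],
                    file.path(out_dir, sprintf("contour_%02d.csv", i)))
      write_image(masks[[i]], file.path(out_dir,
                                        sprintf("mask_%02d.png", i)),
                  range = c(0, 1))
    }
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    prov <- list(
      package = "nodemorph",
      version = as.character(utils::packageVersion("nodemorph")),
      seed = config$seed,
      n_nodes = length(inits),
      diffusion = unclass(config$diffusion),
      snake = unclass(config$snake),
      spacing = config$spacing,
      repulsive = config$repulsive,
      canny = list(sigma = config$canny_sigma, q = config$canny_q,
                   low = thr$low, high = thr$high))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(denoised = denoised, edges = edges, contours = contours,
       masks = masks, features = features)
}
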