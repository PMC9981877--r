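## TIFF + JSON sidecar I/O. TIFF float writers clamp to [0, 1], so every
## page is stored affinely rescaled with its offset/scale recorded in the
## sidecar; readers invert the transform. Round trips are exact at 32-bit
## float precision.

SCHEMA_VERSION <- "1"

pageScale <- function(m) {
  lo <- min(m); hi <- max(m)
  list(offset = lo, scale = if (hi > lo) hi - lo else 1)
}

writeFloatTiff <- function(m, path, sc = pageScale(m)) {
  tiff::writeTIFF((m - sc$offset) / sc$scale, path,
                  bits.per.sample = 32L, reduce = FALSE)
  sc
}

readFloatTiff <- function(path, sc) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * sc$scale + sc$offset
}

configToList <- function(config) {
  list(wavelength_nm = config@wavelengthNm, bandwidth_nm = config@bandwidthNm,
       na = config@na, na_obs = config@naObs, n_medium = config@nMedium,
       pixel_size_nm = config@pixelSizeNm, image_shape = config@imageShape,
       tau_abs = config@tauAbs, tau_ph = config@tauPh,
       orientations_deg = config@orientationsDeg)
}

configFromList <- function(lst) {
  acquisitionConfig(wavelengthNm = lst$wavelength_nm, bandwidthNm = lst$bandwidth_nm,
                    na = lst$na, naObs = lst$na_obs, nMedium = lst$n_medium,
                    pixelSizeNm = lst$pixel_size_nm, imageShape = lst$image_shape,
                    tauAbs = lst$tau_abs, tauPh = lst$tau_ph,
                    orientationsDeg = lst$orientations_deg)
}

#' Write / read a DPC stack
#'
#' A stack is stored as one 32-bit float TIFF per frame,
#' `<prefix>_dpc<angle>.tif` and `<prefix>_bg<angle>.tif`, plus a JSON
#' sidecar `<prefix>_stack.json` carrying the orientations, the acquisition
#' configuration and the per-page intensity offset/scale (TIFF float storage
#' is confined to [0, 1]). `readStack()` accepts the prefix or the sidecar
#' path. A legacy sidecar without background entries loads with unit
#' backgrounds and a warning.
#'
#' @param stack a [DPCStack-class].
#' @param prefix output path prefix (directories must exist).
#' @return `writeStack()` returns the sidecar path invisibly; `readStack()`
#'   returns a [DPCStack-class].
#' @export
writeStack <- function(stack, prefix) {
  stopifnot(is(stack, "DPCStack"))
  pages <- list()
  for (i in seq_along(stack@images)) {
    a <- format(stack@orientationsDeg[i])
    fImg <- paste0(prefix, "_dpc", a, ".tif")
    fBg <- paste0(prefix, "_bg", a, ".tif")
    scI <- writeFloatTiff(stack@images[[i]], fImg)
    scB <- writeFloatTiff(stack@backgrounds[[i]], fBg)
    pages[[length(pages) + 1L]] <- list(angle_deg = stack@orientationsDeg[i],
                                        image = basename(fImg), image_offset = scI$offset,
                                        image_scale = scI$scale, background = basename(fBg),
                                        background_offset = scB$offset,
                                        background_scale = scB$scale)
  }
  sidecar <- paste0(prefix, "_stack.json")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            type = "dpc_stack",
                            orientations_deg = stack@orientationsDeg,
                            config = configToList(stack@config),
                            pages = pages),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' @rdname writeStack
#' @param path prefix or sidecar path of a written stack.
#' @export
readStack <- function(path) {
  sidecar <- if (grepl("_stack\\.json$", path)) path else paste0(path, "_stack.json")
  if (!file.exists(sidecar)) stop("stack sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("orientations_deg", "config", "pages")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("stack sidecar schema error; missing keys: ", paste(missing, collapse = ", "))
  pages <- meta$pages
  if (nrow(pages) != length(meta$orientations_deg))
    stop(sprintf("stack sidecar schema error: %d orientations but %d pages",
                 length(meta$orientations_deg), nrow(pages)))
  dir <- dirname(sidecar)
  imgs <- list(); bgs <- list()
  for (i in seq_len(nrow(pages))) {
    imgs[[i]] <- readFloatTiff(file.path(dir, pages$image[i]),
                               list(offset = pages$image_offset[i],
                                    scale = pages$image_scale[i]))
    if (is.null(pages$background) || is.na(pages$background[i])) {
      warning("no background recorded for orientation ", pages$angle_deg[i],
              "; assuming a unit flat field")
      bgs[[i]] <- matrix(1, nrow(imgs[[i]]), ncol(imgs[[i]]))
    } else {
      bgs[[i]] <- readFloatTiff(file.path(dir, pages$background[i]),
                                list(offset = pages$background_offset[i],
                                     scale = pages$background_scale[i]))
    }
  }
  new("DPCStack", images = imgs, backgrounds = bgs,
      orientationsDeg = as.numeric(meta$orientations_deg),
      config = configFromList(meta$config))
}

#' Write / read a phantom
#'
#' Stored as a multi-page 32-bit float TIFF (pages: deltaN, kMap, thickness,
#' labels) plus a JSON sidecar with the truth-cluster table, generator
#' parameters and per-page scaling.
#'
#' @param phantom a [ComplexPhantom-class].
#' @param prefix output path prefix.
#' @return `writePhantom()` returns the sidecar path invisibly;
#'   `readPhantom()` returns a [ComplexPhantom-class].
#' @export
writePhantom <- function(phantom, prefix) {
  stopifnot(is(phantom, "ComplexPhantom"))
  pagesM <- list(phantom@deltaN, phantom@kMap, phantom@thickness,
                 phantom@truthLabels * 1)
  scs <- lapply(pagesM, pageScale)
  tiff::writeTIFF(lapply(seq_along(pagesM), function(i)
    (pagesM[[i]] - scs[[i]]$offset) / scs[[i]]$scale),
    paste0(prefix, "_phantom.tif"), bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(prefix, "_phantom.json")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, type = "phantom",
                            pixel_size_nm = phantom@pixelSizeNm,
                            page_names = c("delta_n", "k_map", "thickness", "labels"),
                            page_offsets = vapply(scs, `[[`, numeric(1), "offset"),
                            page_scales = vapply(scs, `[[`, numeric(1), "scale"),
                            truth_clusters = phantom@truthClusters,
                            meta = phantom@meta),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' @rdname writePhantom
#' @param prefix path prefix used at write time.
#' @export
readPhantom <- function(prefix) {
  sidecar <- if (grepl("_phantom\\.json$", prefix)) prefix else paste0(prefix, "_phantom.json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tifPath <- sub("\\.json$", ".tif", sidecar)
  pages <- tiff::readTIFF(tifPath, all = TRUE)
  m <- lapply(seq_along(pages), function(i)
    pages[[i]] * meta$page_scales[i] + meta$page_offsets[i])
  tc <- as.data.frame(meta$truth_clusters)
  if (nrow(tc) == 0)
    tc <- data.frame(row = integer(0), col = integer(0), radiusNm = numeric(0))
  new("ComplexPhantom", deltaN = m[[1]], kMap = pmax(m[[2]], 0),
      thickness = pmax(m[[3]], 0), pixelSizeNm = meta$pixel_size_nm,
      truthLabels = matrix(as.integer(round(m[[4]])), nrow(m[[4]])),
      truthClusters = tc, meta = as.list(meta$meta))
}

#' Write a reconstruction result
#'
#' Writes `<prefix>_phi.tif`, `<prefix>_mu.tif` and `<prefix>_k.tif` (32-bit
#' float, scaled) plus a JSON provenance record with all parameters used.
#'
#' @param recon a [ReconstructionResult-class].
#' @param prefix output path prefix.
#' @return the provenance JSON path, invisibly.
#' @export
writeReconstruction <- function(recon, prefix) {
  stopifnot(is(recon, "ReconstructionResult"))
  scPhi <- writeFloatTiff(recon@phi, paste0(prefix, "_phi.tif"))
  scMu <- writeFloatTiff(recon@mu, paste0(prefix, "_mu.tif"))
  scK <- writeFloatTiff(recon@kMap, paste0(prefix, "_k.tif"))
  sidecar <- paste0(prefix, "_recon.json")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, type = "reconstruction",
                            tau_abs = recon@tauAbs, tau_ph = recon@tauPh,
                            path_length_nm = recon@pathLengthNm,
                            config = configToList(recon@config),
                            scales = list(phi = scPhi, mu = scMu, k = scK)),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a single-image TIFF as a plain matrix
#'
#' Convenience reader for CLI inputs: first page, first channel, raw values
#' in [0, 1] unless a sidecar scale is supplied.
#'
#' @param path TIFF path.
#' @return numeric matrix.
#' @export
readImageTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}
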