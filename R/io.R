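# File I/O: raster images in, documented binary containers for fields and
# spectral estimates (a directory of flat little-endian double grids plus a
# JSON manifest, which avoids any format dialect ambiguity).

.container_version <- "1"

.largest_dyadic <- function(n) 2L^floor(log2(n))

#' Read a multichannel raster image as a field
#'
#' Reads an 8/16-bit RGB PNG or TIFF (or a field container directory written
#' by [write_field()]), scales intensities to `[0, 1]`, keeps the first three
#' channels and centre-crops to the largest dyadic dimensions. Images are
#' never resampled (resampling would alter their spectral content).
#'
#' @param path image file or container directory.
#' @return An [ls2w_field()].
#' @export
read_multichannel_image <- function(path) {
  if (dir.exists(path)) return(read_field(path))
  if (!file.exists(path)) stop("cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext,
                     " (PNG or TIFF expected)"))
  if (length(dim(img)) < 3L || dim(img)[3] < 3L)
    stop("image must have at least 3 channels (got ",
         if (length(dim(img)) < 3L) 1L else dim(img)[3], ")")
  img <- img[, , 1:3, drop = FALSE]
  R0 <- dim(img)[1]; S0 <- dim(img)[2]
  if (min(R0, S0) < 32L) stop("image too small: ", R0, " x ", S0,
                              " (need at least 32 x 32)")
  R <- .largest_dyadic(R0); S <- .largest_dyadic(S0)
  r0 <- floor((R0 - R) / 2); c0 <- floor((S0 - S) / 2)
  ls2w_field(img[r0 + seq_len(R), c0 + seq_len(S), , drop = FALSE])
}

.write_grids <- function(path, planes, manifest) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(planes))
    writeBin(as.vector(planes[[nm]]), file.path(path, paste0(nm, ".bin")),
             size = 8L, endian = "little")
  manifest$version <- .container_version
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.read_manifest <- function(path, type) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(man$version), .container_version))
    stop("container version mismatch: found ", man$version,
         ", expected ", .container_version)
  if (!identical(man$type, type))
    stop("container at ", path, " holds '", man$type, "', not '", type, "'")
  man
}

.read_grid <- function(path, nm, R, S) {
  f <- file.path(path, paste0(nm, ".bin"))
  if (!file.exists(f)) stop("container is missing plane ", nm)
  v <- readBin(f, "double", n = R * S, size = 8L, endian = "little")
  if (length(v) != R * S) stop("plane ", nm, " has wrong size")
  matrix(v, R, S)
}

#' Field and estimate containers
#'
#' Lossless on-disk representation: a directory holding one flat
#' little-endian `double` grid per plane (`*.bin`, column-major) and a
#' `manifest.json` with dimensions and metadata. `write_field`/`read_field`
#' round-trip an [ls2w_field()] bit-exactly; `write_estimate`/`read_estimate`
#' do the same for an [mvlws()] fit including its settings.
#'
#' @param field an [ls2w_field()].
#' @param path container directory (created if needed).
#' @return `read_field` returns the field; `read_estimate` the fit; the
#'   writers return `path` invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ls2w_field"))
  d <- dim(field)
  planes <- lapply(seq_len(d[3]), function(i) field[, , i])
  names(planes) <- paste0("channel", seq_len(d[3]))
  .write_grids(path, planes,
               list(type = "field", R = d[1], S = d[2], m = d[3],
                    process = attr(field, "process"),
                    seed = attr(field, "seed")))
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  man <- .read_manifest(path, "field")
  x <- array(NA_real_, c(man$R, man$S, man$m))
  for (i in seq_len(man$m))
    x[, , i] <- .read_grid(path, paste0("channel", i), man$R, man$S)
  ls2w_field(x, process = man$process, seed = man$seed)
}

#' @rdname write_field
#' @param fit an [mvlws()] fit.
#' @export
write_estimate <- function(fit, path) {
  stopifnot(inherits(fit, "mvlws"))
  d <- fit$dim; nEta <- 3L * fit$J
  planes <- list()
  for (k in seq_len(nrow(fit$pairs)))
    for (e in seq_len(nEta))
      planes[[paste0("S", .pair_label(fit$pairs[k, , drop = FALSE]),
                     "_eta", e)]] <- fit$S[, , e, k]
  if (!is.null(fit$rho))
    for (k in seq_len(nrow(fit$cpairs)))
      for (e in seq_len(nEta))
        planes[[paste0("rho", .pair_label(fit$cpairs[k, , drop = FALSE]),
                       "_eta", e)]] <- fit$rho[, , e, k]
  .write_grids(path, planes,
               list(type = "estimate", R = d[1], S = d[2], m = fit$m,
                    J = fit$J, family = fit$filter$family,
                    number = fit$filter$number, kernel = fit$kernel,
                    h = fit$h, eps = fit$eps,
                    floored = unname(fit$counts["floored"]),
                    clipped = unname(fit$counts["clipped"])))
}

#' @rdname write_field
#' @export
read_estimate <- function(path) {
  man <- .read_manifest(path, "estimate")
  m <- man$m; J <- man$J; nEta <- 3L * J
  pairs <- .pair_table(m, diag = TRUE)
  cpairs <- if (m > 1) .pair_table(m, diag = FALSE)
  Sarr <- array(NA_real_, c(man$R, man$S, nEta, nrow(pairs)))
  for (k in seq_len(nrow(pairs)))
    for (e in seq_len(nEta))
      Sarr[, , e, k] <- .read_grid(path,
        paste0("S", .pair_label(pairs[k, , drop = FALSE]), "_eta", e),
        man$R, man$S)
  rho <- NULL
  if (!is.null(cpairs)) {
    rho <- array(NA_real_, c(man$R, man$S, nEta, nrow(cpairs)))
    for (k in seq_len(nrow(cpairs)))
      for (e in seq_len(nEta))
        rho[, , e, k] <- .read_grid(path,
          paste0("rho", .pair_label(cpairs[k, , drop = FALSE]), "_eta", e),
          man$R, man$S)
  }
  fl <- ls2w_filter(man$family,
                    if (!is.null(man$number)) man$number else 1)
  structure(list(S = Sarr, rho = rho, pairs = pairs, cpairs = cpairs,
                 m = m, J = J, dim = c(man$R, man$S), filter = fl,
                 kernel = man$kernel, h = man$h, eps = man$eps,
                 counts = c(floored = man$floored, clipped = man$clipped)),
            class = "mvlws")
}
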