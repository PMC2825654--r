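#' Write an image with metadata
#'
#' Writes three files: `<path>.txt`, a full-precision plain-text matrix (the
#' exact, diff-able carrier; read-back is bit-exact); `<path>.tif`, a 32-bit
#' float TIFF for interchange, affinely rescaled to `[0, 1]` with the scale
#' and offset recorded in the sidecar; and `<path>.meta`, a key-value
#' metadata sidecar. Non-finite pixel values are rejected.
#'
#' @param image numeric matrix of finite values.
#' @param path output path without extension (or with `.tif`/`.txt`, which
#'   is stripped).
#' @param metadata named list of scalar metadata values (e.g. seed,
#'   n_photons, collimator, distance).
#' @return the base path, invisibly.
#' @export
write_image <- function(image, path, metadata = list()) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!all(is.finite(image)))
    stop("image contains non-finite values; refusing to write")
  base <- sub("\\.(tif|tiff|txt)$", "", path)
  ## exact text matrix
  txt <- apply(image, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = "\t"))
  writeLines(txt, paste0(base, ".txt"))
  ## scaled float TIFF (the tiff package stores floats in [0, 1] only)
  lo <- min(image); hi <- max(image)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image - lo) / scale, paste0(base, ".tif"),
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(metadata,
            list(n_u = nrow(image), n_v = ncol(image),
                 tiff_offset = lo, tiff_scale = scale))
  writeLines(sprintf("%s: %s", names(meta),
                     vapply(meta, function(v)
                       formatC(v, format = if (is.numeric(v)) "g" else "s",
                               digits = 17), "")),
             paste0(base, ".meta"))
  invisible(base)
}

#' Read an image written by [write_image()]
#'
#' Reads the plain-text matrix (exact) when present, otherwise the TIFF
#' (undoing the recorded scaling, float32 precision).
#'
#' @param path base path (extension optional).
#' @return the image matrix, with the parsed sidecar attached as attribute
#'   `"metadata"` when present.
#' @export
read_image <- function(path) {
  base <- sub("\\.(tif|tiff|txt)$", "", path)
  meta <- NULL
  if (file.exists(paste0(base, ".meta"))) {
    lines <- readLines(paste0(base, ".meta"))
    kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
    meta <- stats::setNames(
      lapply(kv, function(m) {
        num <- suppressWarnings(as.numeric(m[3]))
        if (is.na(num)) m[3] else num
      }),
      vapply(kv, `[`, "", 2))
  }
  if (file.exists(paste0(base, ".txt"))) {
    img <- as.matrix(utils::read.table(paste0(base, ".txt"), sep = "\t"))
    dimnames(img) <- NULL
  } else if (file.exists(paste0(base, ".tif"))) {
    img <- tiff::readTIFF(paste0(base, ".tif"))
    if (!is.null(meta))
      img <- img * meta$tiff_scale + meta$tiff_offset
  } else {
    stop("no image found at '", base, "' (.txt or .tif)")
  }
  attr(img, "metadata") <- meta
  img
}

#' Write a tally report
#'
#' Plain-text key-value dump of a transport run's conservation accounting:
#' launched, absorbed, escaped, capped, escaped and detected per scatter
#' class.
#'
#' @param run a `scatter_run` from [simulate_transport()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(run, path) {
  stopifnot(inherits(run, "scatter_run"))
  t <- run$tally
  lines <- c(
    sprintf("launched: %.0f", t$launched),
    sprintf("absorbed: %.0f", t$absorbed),
    sprintf("escaped: %.0f", t$escaped),
    sprintf("capped: %.0f", t$capped),
    sprintf("conservation_ok: %s",
            t$launched == t$absorbed + t$escaped),
    sprintf("seed: %d", run$seed),
    sprintf("escaped_%s: %.0f", names(t$escaped_by_class),
            t$escaped_by_class))
  for (d in rownames(t$detected))
    lines <- c(lines, sprintf("detected_%s_%s: %.0f", d,
                              colnames(t$detected), t$detected[d, ]))
  writeLines(lines, path)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' YAML with fields: `phantom` (path to a phantom file, resolved relative to
#' the config), `detector` (`n_u`, `n_v`, `pitch`), `collimators` (list of
#' `{aspect, distance}`), `physics` (`energy_keV`, `l`,
#' `target_mean_angle_deg`), `n_photons`, `seed`. Unknown top-level keys are
#' rejected.
#'
#' @param path config file path.
#' @return a validated list of class `run_config` with the phantom loaded.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config '", path,
                                           "' is not valid YAML: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || length(obj) == 0)
    stop("config '", path, "' is empty")
  known <- c("phantom", "detector", "collimators", "physics",
             "n_photons", "seed")
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("config '", path, "': unknown key(s): ",
         paste(bad, collapse = ", "))
  for (f in c("phantom", "detector", "collimators", "n_photons", "seed"))
    if (is.null(obj[[f]]))
      stop("config '", path, "': missing required field '", f, "'")
  phantom_path <- obj$phantom
  if (!file.exists(phantom_path))
    phantom_path <- file.path(dirname(path), obj$phantom)
  if (!file.exists(phantom_path))
    stop("config '", path, "': phantom file '", obj$phantom, "' not found")
  ph <- read_phantom(phantom_path)
  det <- obj$detector
  grid <- detector_grid(det$n_u, det$n_v, det$pitch)
  if (length(obj$collimators) < 1)
    stop("config '", path, "': need at least one collimator entry")
  detectors <- lapply(obj$collimators, function(cl) {
    if (is.null(cl$aspect) || is.null(cl$distance))
      stop("config '", path,
           "': each collimator needs 'aspect' and 'distance'")
    detector_config(collimator_spec(cl$aspect), cl$distance, grid)
  })
  phys <- obj$physics
  if (is.null(phys)) phys <- list()
  structure(list(
    phantom = ph, phantom_path = phantom_path, grid = grid,
    detectors = detectors,
    energy_keV = if (is.null(phys$energy_keV)) 50 else phys$energy_keV,
    l = if (is.null(phys$l)) 2 else phys$l,
    target_mean_angle = (if (is.null(phys$target_mean_angle_deg)) 4.3
                         else phys$target_mean_angle_deg) * pi / 180,
    n_photons = obj$n_photons, seed = obj$seed),
    class = "run_config")
}

#' Write the packaged simulation fixtures
#'
#' `table1_full` is the headline configuration: the reference water-slab
#' phantom, a 600 x 600 detector at 0.02 cm pitch, collimation aspect
#' ratios 50 and 10 at 2.5 cm plus aspect 10 at 17.5 cm, and 2e10 photons.
#' `table1_reduced` is the desk-scale variant used by the test-suite and
#' acceptance runs: 60 x 60 pixels at 0.2 cm pitch and 1e7 photons, same
#' phantom, collimators and distances.
#'
#' @param name `"table1_full"` or `"table1_reduced"`.
#' @param dir output directory (created if needed).
#' @return (invisibly) named list with paths `phantom`, `run`, `materials`.
#' @export
make_fixture <- function(name, dir = ".") {
  if (!name %in% c("table1_full", "table1_reduced"))
    stop("unknown fixture '", name,
         "'; available: table1_full, table1_reduced")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- build_table1_phantom()
  p_ph <- file.path(dir, paste0(name, "_phantom.yaml"))
  write_phantom(ph, p_ph)
  p_mat <- file.path(dir, paste0(name, "_materials.tsv"))
  write_material_table(table1_materials(), p_mat)
  cfg <- if (name == "table1_full") {
    list(detector = list(n_u = 600L, n_v = 600L, pitch = 0.02),
         n_photons = 2e10)
  } else {
    list(detector = list(n_u = 60L, n_v = 60L, pitch = 0.2),
         n_photons = 1e7)
  }
  obj <- list(
    phantom = basename(p_ph),
    detector = cfg$detector,
    collimators = list(list(aspect = 50, distance = 2.5),
                       list(aspect = 10, distance = 2.5),
                       list(aspect = 10, distance = 17.5)),
    physics = list(energy_keV = 50, l = 2, target_mean_angle_deg = 4.3),
    n_photons = cfg$n_photons, seed = 1L)
  p_run <- file.path(dir, paste0(name, "_run.yaml"))
  writeLines(yaml::as.yaml(obj, precision = 15L), p_run)
  invisible(list(phantom = p_ph, run = p_run, materials = p_mat))
}
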