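# VBF: the pipeline's serialized result document. The original tool stored
# its semantics in an opaque binary file; here the same content - contours
# of the slice and zones, layer scheme, bundles with traits, provenance -
# is a documented JSON dialect so results stay inspectable and testable.

.VBF_SCHEMA <- "stemsect-vbf-1"

#' Assemble a VBF document
#'
#' @param zones a [detect_function_zones()] result.
#' @param bundles a [detect_vascular_bundles()] result, a list of bundles,
#'   or `NULL`.
#' @param traits optional per-bundle trait table ([bundle_traits_table()]).
#' @param layers optional [layer_partition()] result.
#' @param cal the [calibration_range()] used (for provenance).
#' @param provenance named list of free-form provenance entries
#'   (parameters, seeds, source file).
#' @return an object of class `vbf_document`.
#' @export
vbf_document <- function(zones, bundles = NULL, traits = NULL,
                         layers = NULL, cal = calibration_range(),
                         provenance = list()) {
  stopifnot(inherits(zones, "function_zones"))
  bl <- if (inherits(bundles, "vb_detection")) bundles$bundles else bundles
  structure(list(
    schema_version = .VBF_SCHEMA,
    calibration = list(hu_min = cal$hu_min, hu_max = cal$hu_max,
                       pixel_size_mm = zones$pixel_size_mm),
    dim = zones$dim,
    zones = list(
      contour1 = zones$contour1$points,
      contour2 = zones$contour2$points,
      contour3 = zones$contour3$points,
      stem_center = zones$stem_center),
    layers = if (!is.null(layers))
      list(mode = layers$mode, n_layers = layers$n_layers,
           table = layers$layers) else NULL,
    bundles = lapply(seq_along(bl), function(i) {
      b <- bl[[i]]
      list(id = i, zone = b$zone, merged = isTRUE(b$merged_flag),
           dc_mm = b$dc_mm, area_mm2 = b$area_mm2,
           points = b$contour$points,
           traits = if (!is.null(traits) && nrow(traits) >= i)
             as.list(traits[i, setdiff(names(traits), "bundle")]) else NULL)
    }),
    provenance = c(provenance, list(tool = "stemsect",
                                    version = as.character(
                                      utils::packageVersion("stemsect"))))),
    class = "vbf_document")
}

#' Serialize a VBF document to JSON
#'
#' Contours are written as integer point lists, trait values at full double
#' precision; [deserialize_vbf()] reproduces every contour point and trait
#' value exactly.
#'
#' @param doc a [vbf_document()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
serialize_vbf <- function(doc, path) {
  stopifnot(inherits(doc, "vbf_document"))
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' Load a VBF document from JSON
#'
#' @param path a file written by [serialize_vbf()].
#' @return a `vbf_document`.
#' @export
deserialize_vbf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed VBF file: ", conditionMessage(e)))
  if (is.null(doc$schema_version) || !identical(doc$schema_version,
                                                .VBF_SCHEMA))
    stop("unsupported VBF schema version: ",
         if (is.null(doc$schema_version)) "<missing>" else doc$schema_version)
  as_pts <- function(p)
    matrix(as.integer(unlist(p)), ncol = 2L, byrow = TRUE)
  doc$zones$contour1 <- as_pts(doc$zones$contour1)
  doc$zones$contour2 <- as_pts(doc$zones$contour2)
  doc$zones$contour3 <- as_pts(doc$zones$contour3)
  doc$zones$stem_center <- as.numeric(unlist(doc$zones$stem_center))
  doc$dim <- as.integer(unlist(doc$dim))
  doc$bundles <- lapply(doc$bundles, function(b) {
    b$points <- as_pts(b$points)
    b$traits <- if (!is.null(b$traits)) lapply(b$traits, unlist)
    b
  })
  if (!is.null(doc$layers) && !is.null(doc$layers$table))
    doc$layers$table <- as.data.frame(lapply(doc$layers$table, unlist))
  structure(doc, class = "vbf_document")
}

#' Coefficient of determination of bundle counting
#'
#' R-squared of the ordinary least-squares regression of computed counts on
#' observed (manual) counts, with a free intercept - the convention of
#' counting-validation scatter plots. Equals 1 for any exact linear
#' relation with non-zero slope and is invariant to common scaling.
#'
#' @param observed,computed equal-length numeric vectors, n >= 2.
#' @return R-squared in `[0, 1]`.
#' @export
counting_r2 <- function(observed, computed) {
  stopifnot(length(observed) == length(computed), length(observed) >= 2L)
  if (sd(observed) == 0)
    stop("undefined R-squared: observed counts have zero variance")
  ss_tot <- sum((computed - mean(computed))^2)
  if (ss_tot == 0) return(0)        # constant predictions explain nothing
  fit <- lm(computed ~ observed)
  1 - sum(resid(fit)^2) / ss_tot
}

#' Run the full pipeline over a batch of slices
#'
#' Inputs may be image file paths, [slice_image()] objects or
#' [generate_phantom()] results. Each slice is segmented, bundles are
#' detected and phenotyped, and a VBF JSON plus a per-bundle CSV are
#' written; per-slice failures are logged and skipped. An aggregate CSV
#' holds one row of slice/zone traits per successful slice.
#'
#' @param inputs list of inputs (or a character vector of paths).
#' @param out_dir output directory (created; must be writable).
#' @param zone_par a [zone_params()].
#' @param detect_par a [detect_params()].
#' @param n_layers,layer_mode layer scheme settings.
#' @param pixel_size_mm pixel size for path inputs.
#' @param cal calibration for 16-bit path inputs.
#' @return invisibly, the aggregate `data.frame` (also written to
#'   `aggregate.csv`).
#' @export
run_batch <- function(inputs, out_dir, zone_par = zone_params(),
                      detect_par = detect_params(), n_layers = 5L,
                      layer_mode = "EA", pixel_size_mm = 0.01355,
                      cal = calibration_range()) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  ok <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.access(out_dir, 2L) == 0L
  }, error = function(e) FALSE)
  if (!ok) stop("unwritable output directory: ", out_dir)
  log_lines <- c(sprintf("stemsect batch %s", format(Sys.time())),
                 sprintf("zone: %s", paste(names(zone_par), unlist(zone_par),
                                           sep = "=", collapse = " ")),
                 sprintf("detect: %s",
                         paste(names(detect_par),
                               unlist(detect_par), sep = "=", collapse = " ")))
  rows <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    id <- if (is.character(inp)) {
      sub("\\.[^.]*$", "", basename(inp))
    } else if (inherits(inp, "phantom_truth")) {
      inp$image$source_id
    } else if (inherits(inp, "slice_image")) {
      if (nzchar(inp$source_id)) inp$source_id else sprintf("slice%03d", i)
    } else sprintf("slice%03d", i)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- if (is.character(inp)) {
        load_slice(inp, pixel_size_mm = pixel_size_mm, cal = cal)
      } else if (inherits(inp, "phantom_truth")) {
        inp$image
      } else if (inherits(inp, "slice_image")) {
        inp
      } else stop("unsupported input type")
      zones <- detect_function_zones(img, zone_par)
      det <- detect_vascular_bundles(img, zones, detect_par)
      scheme <- layer_partition(zones, n_layers, layer_mode,
                                bundles = det$bundles, img = img)
      tt <- bundle_traits_table(det, zones, img, scheme)
      zt <- zone_growth_traits(zones, det, img)
      doc <- vbf_document(zones, det, traits = tt, layers = scheme,
                          cal = cal,
                          provenance = list(source = id))
      serialize_vbf(doc, file.path(out_dir, paste0(id, ".vbf.json")))
      if (nrow(tt))
        write.csv(tt, file.path(out_dir, paste0(id, "_bundles.csv")),
                  row.names = FALSE)
      data.frame(slice = id, n_total = det$n_total, n_inner = det$n_inner,
                 n_periphery = det$n_periphery,
                 AEFZ_epidermis = zt$AEFZ[["epidermis"]],
                 AEFZ_periphery = zt$AEFZ[["periphery"]],
                 AEFZ_inner = zt$AEFZ[["inner"]],
                 AVBPZ = zt$AVBPZ, AVBIZ = zt$AVBIZ,
                 VAVPZ = zt$VAVPZ, VAVIZ = zt$VAVIZ,
                 slice_AI = zt$slice_AI,
                 substance_ratio = zt$substance_ratio,
                 epidermis_thickness_mm = zt$epidermis_thickness_mm)
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      log_lines <- c(log_lines,
                     sprintf("FAIL %s (%.1fs): %s", id, dt,
                             conditionMessage(res)))
    } else {
      log_lines <- c(log_lines, sprintf("OK   %s (%.1fs)", id, dt))
      rows[[length(rows) + 1L]] <- res
    }
  }
  agg <- if (length(rows)) do.call(rbind, rows) else data.frame()
  write.csv(agg, file.path(out_dir, "aggregate.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "batch.log"))
  invisible(agg)
}
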