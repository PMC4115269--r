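# JSON filter serialization.  Versioned, with an explicit coordinate-
# frame tag; all angles radians, all distances pixels.  Round trips are
# lossless: numbers are written at full precision.

.filter_format_version <- "1.0"

vfilter_to_list <- function(f) {
  list(type = "vcosfire",
       tuples = as.list(f$tuples),
       blur = list(sigma0 = f$blur$sigma0, alpha = f$blur$alpha),
       t1 = f$t1,
       params = list(bandwidth = f$params$bandwidth,
                     aspect = f$params$aspect),
       spec = if (!is.null(f$spec))
         list(beta = f$spec$beta, gamma = f$spec$gamma))
}

vfilter_from_list <- function(l) {
  structure(list(
    tuples = data.frame(lambda = unlist(l$tuples$lambda),
                        theta = unlist(l$tuples$theta),
                        rho = unlist(l$tuples$rho),
                        phi = unlist(l$tuples$phi)),
    blur = blur_params(l$blur$sigma0, l$blur$alpha),
    t1 = l$t1,
    params = gabor_params(l$params$bandwidth, l$params$aspect),
    spec = if (!is.null(l$spec)) vertex_spec(l$spec$beta, l$spec$gamma)),
    class = "vcosfire_filter")
}

#' Save a COSFIRE filter to a JSON file
#'
#' Writes a versioned JSON description (nested vertex-filter specs, all
#' angles in radians, all distances in pixels, coordinate frame tagged
#' `"math-y-up"`).  Works for both shape-level (`scosfire_filter`) and
#' vertex-level (`vcosfire_filter`) filters.
#'
#' @param filter The filter to save.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_filter <- function(filter, path) {
  body <- if (inherits(filter, "scosfire_filter")) {
    list(format = "scosfire-filter", version = .filter_format_version,
         frame = filter$frame, type = "scosfire",
         tuples = lapply(filter$tuples, function(tp)
           list(v = vfilter_to_list(tp$v), rho = tp$rho, phi = tp$phi,
                bank_index = tp$bank_index)),
         blur = list(sigma0 = filter$blur$sigma0,
                     alpha = filter$blur$alpha),
         t1 = filter$t1, t2 = filter$t2, t3 = filter$t3,
         sigma_p = filter$sigma_p, suppression = filter$suppression,
         center = as.numeric(filter$center), source = filter$source)
  } else if (inherits(filter, "vcosfire_filter")) {
    c(list(format = "scosfire-filter", version = .filter_format_version,
           frame = .math_frame_tag), vfilter_to_list(filter))
  } else stop("not a COSFIRE filter")
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a COSFIRE filter from a JSON file
#'
#' @param path Path written by [save_filter()].
#' @return An `scosfire_filter` or `vcosfire_filter`.
#' @export
load_filter <- function(path) {
  l <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e)
                  stop("malformed filter file: ", conditionMessage(e)))
  if (!identical(l$format, "scosfire-filter"))
    stop("not a COSFIRE filter file")
  if (!identical(l$version, .filter_format_version))
    stop("unsupported filter format version: ", l$version)
  if (identical(l$type, "vcosfire")) return(vfilter_from_list(l))
  if (!identical(l$type, "scosfire")) stop("unknown filter type")
  if (!identical(l$frame, .math_frame_tag))
    stop("unsupported coordinate frame: ", l$frame)
  tuples <- lapply(l$tuples, function(tp)
    list(v = vfilter_from_list(tp$v), rho = tp$rho, phi = tp$phi,
         bank_index = tp$bank_index))
  structure(list(tuples = tuples,
                 blur = blur_params(l$blur$sigma0, l$blur$alpha),
                 t1 = l$t1, t2 = l$t2, t3 = l$t3,
                 sigma_p = unlist(l$sigma_p),
                 suppression = l$suppression %||% 0,
                 center = unlist(l$center), frame = l$frame,
                 source = l$source),
            class = "scosfire_filter")
}
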