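#' Write a voxel field to disk
#'
#' Two containers are supported: `"raw"` (JSON sidecar with metadata plus a
#' flat little/big-endian binary of doubles — bit-exact round trips, the
#' default) and `"json"` (fully self-contained text; values round-trip to
#' full printed double precision, i.e. within one ulp).  Complex fields interleave
#' real/imaginary parts; vector fields store the 4-d array column-major.
#'
#' @param field A `voxel_field`.
#' @param path Output path of the JSON (sidecar) file.
#' @param format `"raw"` or `"json"`.
#' @param byte_order `"little"` or `"big"` (raw format).
#' @return `path`, invisibly.
#' @export
write_voxel_field <- function(field, path, format = c("raw", "json"),
                              byte_order = c("little", "big")) {
  format <- match.arg(format)
  byte_order <- match.arg(byte_order)
  v <- field$values
  dtype <- if (is.complex(v)) "complex"
           else if (length(dim(v)) == 4) "vector" else "double"
  meta <- list(dims = field$dims, spacing = field$spacing,
               origin = field$origin, kind = field$kind, dtype = dtype,
               format = format)
  if (format == "json") {
    meta$values <- if (dtype == "complex")
      list(re = as.numeric(Re(v)), im = as.numeric(Im(v)))
    else as.numeric(v)
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  } else {
    raw_file <- paste0(sub("\\.json$", "", path), ".raw")
    meta$raw_file <- basename(raw_file)
    meta$byte_order <- byte_order
    buf <- if (dtype == "complex")
      as.numeric(rbind(Re(as.vector(v)), Im(as.vector(v))))
    else as.numeric(v)
    con <- file(raw_file, "wb")
    on.exit(close(con))
    writeBin(buf, con, size = 8, endian = byte_order)
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a voxel field written by [write_voxel_field()]
#'
#' @param path Path of the JSON (sidecar) file.
#' @return A `voxel_field`; masks are validated to contain only 0/1.
#' @export
read_voxel_field <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("dims", "spacing", "origin", "kind", "dtype"))
    if (is.null(meta[[key]]))
      stop(sprintf("voxel container is missing the '%s' entry", key))
  d <- as.integer(meta$dims)
  nval <- prod(d) * (if (meta$dtype == "vector") 3L else 1L)
  if (identical(meta$format, "json")) {
    buf <- meta$values
    v <- if (meta$dtype == "complex") complex(real = buf$re,
                                              imaginary = buf$im)
         else as.numeric(buf)
  } else {
    raw_path <- file.path(dirname(path), meta$raw_file)
    if (!file.exists(raw_path))
      stop("voxel container is missing its raw payload: ", raw_path)
    nread <- if (meta$dtype == "complex") 2L * nval else nval
    con <- file(raw_path, "rb")
    on.exit(close(con))
    buf <- readBin(con, "double", n = nread, size = 8,
                   endian = meta$byte_order %||% "little")
    if (length(buf) != nread)
      stop("shape mismatch: raw payload has the wrong length")
    v <- if (meta$dtype == "complex")
      complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
    else buf
  }
  if (length(v) != nval) stop("shape mismatch between dims and values")
  arr <- if (meta$dtype == "vector") array(v, c(d, 3L)) else array(v, d)
  voxel_field(arr, spacing = as.numeric(meta$spacing),
              origin = as.numeric(meta$origin), kind = meta$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a sequence model to JSON
#'
#' @param seq A [sequence_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_json <- function(seq, path) {
  obj <- list(
    name = seq$name, tr = seq$tr, duration = seq$duration,
    duty_cycle = seq$duty_cycle, b1rms = seq$b1rms,
    freq_encode_axis = seq$freq_encode_axis, family = seq$family,
    rf_pulses = lapply(seq$rf_pulses, function(p)
      p[c("flip_angle", "duration", "shape", "time_bandwidth",
          "apodization", "window_fraction", "envelope_samples")]),
    gradient_events = lapply(seq$gradient_events, function(e)
      e[c("channel", "kind", "amplitude", "ramp_time", "flat_time",
          "start_time", "samples", "sample_dt")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a sequence model from JSON
#'
#' @param path Path written by [write_sequence_json()] (or hand-authored to
#'   the same schema).
#' @return A [sequence_model()].
#' @export
read_sequence_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pulses <- lapply(o$rf_pulses, function(p)
    rf_pulse(p$flip_angle, p$duration, p$shape,
             time_bandwidth = p$time_bandwidth %||% 4,
             apodization = p$apodization %||% "hanning",
             window_fraction = p$window_fraction %||% 1,
             envelope_samples = unlist(p$envelope_samples)))
  events <- lapply(o$gradient_events, function(e)
    gradient_event(e$channel, e$kind,
                   amplitude = e$amplitude %||% 0,
                   ramp_time = e$ramp_time %||% 0,
                   flat_time = e$flat_time %||% 0,
                   start_time = e$start_time %||% 0,
                   samples = unlist(e$samples), sample_dt = e$sample_dt))
  sequence_model(o$name, o$tr, o$duration, rf_pulses = pulses,
                 gradient_events = events, duty_cycle = o$duty_cycle %||% 1,
                 b1rms = o$b1rms,
                 freq_encode_axis = o$freq_encode_axis %||% NA_character_,
                 family = o$family %||% NA_character_)
}
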