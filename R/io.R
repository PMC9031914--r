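# column name mapping between internal objects and the instrument-style CSV
.col_out <- c(elapsed = "elapsed_s", CO2_r = "CO2_r_ppm", CO2_s = "CO2_s_ppm",
              par = "Qin")
.col_in <- stats::setNames(names(.col_out), .col_out)

.units_line <- "A=umol.m-2.s-1 CO2=umol.mol-1 PAR=umol.m-2.s-1 gsw=mol.m-2.s-1"

#' Write a trace or curve as an instrument-style CSV
#'
#' Writes a gas-exchange/fluorescence table with a metadata header block
#' (lines prefixed \code{#}: object type, units, gas condition, dark
#' fluorescence constants) followed by a column-name row. Instrument-style
#' column names are used (\code{elapsed_s}, \code{CO2_r_ppm},
#' \code{CO2_s_ppm}, \code{Qin}, ...). Simulation ground-truth metadata is
#' deliberately not serialised.
#'
#' @param x An \code{aci_curve}, \code{racir_trace}, \code{light_curve},
#'   \code{fluor_trace} or \code{laisk_segments}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_gasex_table()]
#' @export
write_gasex_csv <- function(x, path) {
  type <- intersect(class(x), c("aci_curve", "racir_trace", "light_curve",
                                "fluor_trace", "laisk_segments"))
  if (length(type) == 0) stop("unsupported object type", call. = FALSE)
  header <- c(
    sprintf("# leafgasx: %s", type[1]),
    sprintf("# units: %s", .units_line)
  )
  if (!is.null(attr(x, "condition"))) {
    header <- c(header, sprintf("# condition: %s", attr(x, "condition")))
  }
  if (!is.null(attr(x, "Fo"))) {
    header <- c(header, sprintf("# Fo: %.6g", attr(x, "Fo")),
                sprintf("# Fm: %.6g", attr(x, "Fm")))
  }
  df <- as.data.frame(x)
  ren <- intersect(names(df), names(.col_out))
  names(df)[match(ren, names(df))] <- .col_out[ren]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# guess the field separator of a plain CSV from its header line
sniff_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr(";", line))) >
      lengths(regmatches(line, gregexpr(",", line)))) ";" else ","
}

#' Read a gas-exchange or fluorescence table
#'
#' Reads either the instrument-style dialect written by [write_gasex_csv()]
#' (metadata lines prefixed \code{#}, then a header row) or a plain CSV with
#' comma or semicolon separator (sniffed). Column names may be either
#' instrument-style or internal; unknown columns are preserved.
#'
#' @param path File path.
#' @param as Object type to construct: \code{"aci_curve"},
#'   \code{"racir_trace"}, \code{"light_curve"}, \code{"fluor_trace"} or
#'   \code{"laisk_segments"}. Defaults to the type recorded in the header;
#'   required for plain files.
#' @param dialect \code{"auto"} (default), \code{"instrument"} or
#'   \code{"plain"}.
#' @return The reconstructed object.
#' @export
read_gasex_table <- function(path, as = NULL,
                             dialect = c("auto", "instrument", "plain")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  if (dialect == "auto") {
    dialect <- if (length(meta_lines) > 0) "instrument" else "plain"
  }
  meta <- list()
  if (dialect == "instrument") {
    for (ln in meta_lines) {
      kv <- sub("^#\\s*", "", ln)
      key <- sub(":.*$", "", kv)
      val <- trimws(sub("^[^:]*:\\s*", "", kv))
      meta[[key]] <- val
    }
    if (!is.null(meta$units) && meta$units != .units_line) {
      stop(sprintf("unit mismatch in header: '%s'", meta$units), call. = FALSE)
    }
    body <- lines[!grepl("^#", lines)]
    sep <- ","
  } else {
    body <- lines
    sep <- sniff_sep(body[1])
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"), sep = sep,
                        stringsAsFactors = FALSE)
  ren <- intersect(names(df), names(.col_in))
  names(df)[match(ren, names(df))] <- .col_in[ren]
  type <- as %||% meta$leafgasx
  if (is.null(type)) {
    stop("object type unknown: pass `as` for plain files", call. = FALSE)
  }
  required <- switch(
    type,
    aci_curve = c("Ci", "A"),
    racir_trace = c("elapsed", "CO2_r", "CO2_s", "A", "Ci", "gsw", "direction"),
    light_curve = c("par", "A"),
    fluor_trace = c("step", "par", "Fs", "Fmp", "Fo_dark", "Fmp_dark"),
    laisk_segments = c("Ci", "A", "par"),
    stop(sprintf("unknown object type '%s'", type), call. = FALSE)
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s) for %s: %s", type,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (type == "fluor_trace" && (is.null(meta$Fo) || is.null(meta$Fm))) {
    stop("fluor_trace files need '# Fo:' and '# Fm:' header lines", call. = FALSE)
  }
  src <- list(source = path)
  switch(
    type,
    aci_curve = new_aci_curve(df, meta = src),
    racir_trace = new_racir_trace(df, meta = src),
    light_curve = new_light_curve(
      df, condition = meta$condition %||% "photorespiratory", meta = src),
    fluor_trace = new_fluor_trace(
      df, Fo = as.numeric(meta$Fo), Fm = as.numeric(meta$Fm), meta = src),
    laisk_segments = new_laisk_segments(df, meta = src)
  )
}
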