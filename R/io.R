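## Localization table I/O.
##
## Two CSV dialects are supported. The native dialect stores positions in
## nm with a commented metadata header (units, pixel size, seed, config
## hash) so a file is self-describing. The picasso dialect uses the column
## names of the Picasso localization format (frame, x, y in camera pixels,
## photons, lpx, lpy) and converts pixel units to nm at the boundary using
## the pixel size.

picasso_cols_ <- c(frame = "frame", x = "x", y = "y", photons = "photons",
                   sigma_loc_x = "lpx", sigma_loc_y = "lpy")

#' Write a localization table
#'
#' @param table a localization table.
#' @param path output file path.
#' @param dialect `"native_csv"` (positions in nm, metadata header) or
#'   `"picasso_csv"` (Picasso column names, positions and precisions in
#'   camera pixels).
#' @param pixel_size camera pixel size in nm; required for the picasso
#'   dialect, recorded as provenance in the native dialect.
#' @param meta named list of extra provenance entries (e.g. `seed`,
#'   `config_hash`) embedded in the native header.
#' @return The path, invisibly.
#' @export
write_locs <- function(table, path, dialect = c("native_csv", "picasso_csv"),
                       pixel_size = 108, meta = list()) {
  dialect <- match.arg(dialect)
  validate_loc_table(table)
  df <- as.data.frame(table)
  if (dialect == "picasso_csv") {
    if (!is_pos_num(pixel_size)) stop_arg("pixel_size must be positive")
    df$x <- df$x / pixel_size
    df$y <- df$y / pixel_size
    df$sigma_loc_x <- df$sigma_loc_x / pixel_size
    df$sigma_loc_y <- df$sigma_loc_y / pixel_size
    names(df)[match(names(picasso_cols_), names(df), nomatch = 0)] <-
      picasso_cols_[names(picasso_cols_) %in% names(df)]
  }
  chr <- as.data.frame(lapply(df, format_full_), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(chr) <- names(df)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "native_csv") {
    writeLines(c("# paintquant_locs: 1",
                 "# units: nm",
                 sprintf("# pixel_size_nm: %s", format_full_(pixel_size)),
                 vapply(names(meta), function(k)
                   sprintf("# %s: %s", k, as.character(meta[[k]])), "")),
               con)
  }
  utils::write.table(chr, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table
#'
#' @param path input file path.
#' @param dialect `"native_csv"` or `"picasso_csv"`.
#' @param pixel_size pixel size in nm for the picasso dialect (required
#'   there; ignored for native files, which carry their own).
#' @return A localization table in nm; native metadata is attached as
#'   attribute `meta`.
#' @export
read_locs <- function(path, dialect = c("native_csv", "picasso_csv"),
                      pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  if (dialect == "native_csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta_lines <- sub("^#\\s*", "", lines[hdr])
    meta <- list()
    for (ml in meta_lines) {
      kv <- strsplit(ml, ":\\s*")[[1]]
      if (length(kv) >= 2) meta[[kv[1]]] <- paste(kv[-1], collapse = ":")
    }
    if (is.null(meta$units))
      stop_arg("native table %s carries no unit metadata", path)
    if (!identical(meta$units, "nm"))
      stop_arg("unsupported units '%s' (positions must be nm)", meta$units)
    df <- read.csv(text = paste(lines[-hdr], collapse = "\n"))
    check_schema_(df)
    attr(df, "meta") <- meta
    return(df)
  }
  if (!is_pos_num(pixel_size %||% 0))
    stop_arg("pixel_size is required to read picasso-dialect tables")
  df <- read.csv(path)
  inv <- stats::setNames(names(picasso_cols_), picasso_cols_)
  names(df)[match(names(inv), names(df), nomatch = 0)] <-
    inv[names(inv) %in% names(df)]
  check_schema_(df)
  df$x <- df$x * pixel_size
  df$y <- df$y * pixel_size
  df$sigma_loc_x <- df$sigma_loc_x * pixel_size
  df$sigma_loc_y <- df$sigma_loc_y * pixel_size
  attr(df, "meta") <- list(units = "nm", pixel_size_nm = pixel_size)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_schema_ <- function(df) {
  miss <- setdiff(loc_required_cols, names(df))
  if (length(miss))
    stop_arg("schema error: missing column(s) %s", paste(sQuote(miss), collapse = ", "))
  invisible(df)
}

#' Write a ground-truth sidecar for a simulated table
#'
#' @param truth the `truth` element of [simulate_paint()] output.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
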