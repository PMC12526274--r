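#' Write leaf contours to disk
#'
#' Two interchangeable plain-text dialects are supported: a long-format
#' CSV with one row per vertex (columns `leaf_id`, `progeny_id`,
#' `hybridization`, `vertex_index`, `x_cm`, `y_cm`, `is_base`, `is_apex`)
#' and an equivalent nested JSON document. Both round-trip through
#' [read_contours()] with at least nanometre fidelity.
#'
#' @param contours list of [leaf_contour()] objects.
#' @param path output file; the format is inferred from the extension
#'   unless given explicitly.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!length(contours)) stop("no contours to write", call. = FALSE)
  contours <- lapply(contours, stopifnot_contour)

  if (format == "csv") {
    rows <- lapply(contours, function(ct) {
      n <- nrow(ct$vertices)
      data.frame(leaf_id = ct$leaf_id, progeny_id = ct$progeny_id,
                 hybridization = ct$hybridization, vertex_index = seq_len(n),
                 x_cm = ct$vertices[, 1L], y_cm = ct$vertices[, 2L],
                 is_base = as.integer(seq_len(n) == ct$base_index),
                 is_apex = as.integer(seq_len(n) == ct$apex_index),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    utils::write.csv(format_numeric(df, c("x_cm", "y_cm")), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    leaves <- lapply(contours, function(ct) {
      list(leaf_id = ct$leaf_id, progeny_id = ct$progeny_id,
           hybridization = ct$hybridization, base_index = ct$base_index,
           apex_index = ct$apex_index,
           vertices = unname(apply(ct$vertices, 1L, as.numeric,
                                   simplify = FALSE)))
    })
    jsonlite::write_json(list(leaves = leaves), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

format_numeric <- function(df, cols) {
  for (cl in cols) df[[cl]] <- sprintf("%.12g", df[[cl]])
  df
}

#' Read leaf contours written by [write_contours()]
#'
#' @param path CSV or JSON file (dialects documented in
#'   [write_contours()]).
#' @return list of [leaf_contour()] objects.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty contour file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$leaves) || !length(doc$leaves))
      stop("contour JSON contains no leaves", call. = FALSE)
    return(lapply(doc$leaves, function(lf) {
      v <- do.call(rbind, lapply(lf$vertices, unlist))
      leaf_contour(v, base_index = lf$base_index, apex_index = lf$apex_index,
                   leaf_id = lf$leaf_id, progeny_id = lf$progeny_id,
                   hybridization = normalize_hybridization(lf$hybridization))
    }))
  }

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_id", "progeny_id", "hybridization", "vertex_index",
            "x_cm", "y_cm", "is_base", "is_apex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("contour CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("contour CSV has no data rows", call. = FALSE)
  bad <- which(!is.finite(df$x_cm) | !is.finite(df$y_cm) |
               !is.finite(df$vertex_index))
  if (length(bad))
    stop("malformed contour rows (1-based data lines): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  lapply(split(df, factor(df$leaf_id, levels = unique(df$leaf_id))),
         function(d) {
    d <- d[order(d$vertex_index), , drop = FALSE]
    bi <- which(d$is_base == 1L)
    ai <- which(d$is_apex == 1L)
    if (length(bi) != 1L || length(ai) != 1L)
      stop("leaf ", d$leaf_id[1L],
           " must mark exactly one base and one apex vertex", call. = FALSE)
    leaf_contour(cbind(d$x_cm, d$y_cm), base_index = bi, apex_index = ai,
                 leaf_id = d$leaf_id[1L], progeny_id = d$progeny_id[1L],
                 hybridization = normalize_hybridization(d$hybridization[1L]))
  })
}

normalize_hybridization <- function(x) {
  x <- as.character(x)
  if (x %in% c("IntraH", "InterH", "unknown")) return(x)
  warning("unknown hybridization label '", x, "'; recorded as 'unknown'",
          call. = FALSE)
  "unknown"
}

#' Write a measurement table
#'
#' @param measurements data frame from [measure_leaves()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  d <- check_measurements(measurements,
                          need = c("leaf_id", "progeny_id", "hybridization",
                                   "L_cm", "W_cm", "LS_cm2", "RWL"))
  utils::write.csv(format_numeric(d, c("L_cm", "W_cm", "LS_cm2", "RWL")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table
#'
#' @param path CSV written by [write_measurements()] (or any CSV with the
#'   same columns).
#' @return measurement data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_measurements(d, need = c("L_cm", "W_cm", "LS_cm2"))
  d
}
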