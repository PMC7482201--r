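#' Load an egocentric contact table from CSV
#'
#' Reads a UTF-8, comma-separated, '.'-decimal file with a mandatory
#' header containing `ego_id`, `alter_id` and `contact_rate_per_day`
#' columns.  Malformed rows (non-numeric or nonpositive rates,
#' duplicated alters within an ego) are reported with their line
#' numbers (header = line 1).
#'
#' @param path path to the CSV file.
#' @return a data frame with columns `ego_id`, `alter_id`,
#'   `contact_rate_per_day`.
#' @export
load_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty contact table: ", path, call. = FALSE)
  required <- c("ego_id", "alter_id", "contact_rate_per_day")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(df$contact_rate_per_day))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(is.na(rate) | !is.finite(rate))
  if (length(bad)) {
    stop("non-numeric contact rate at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  bad <- which(rate <= 0)
  if (length(bad)) {
    stop("nonpositive contact rate (", rate[bad[1L]], ") at line ",
         line[bad[1L]], " of ", path, call. = FALSE)
  }
  dup <- stats::aggregate(seq_len(nrow(df)),
                          by = list(ego = df$ego_id, alter = df$alter_id),
                          FUN = length)
  if (any(dup$x > 1L)) {
    d <- dup[dup$x > 1L, ][1L, ]
    stop("duplicated alter '", d$alter, "' for ego '", d$ego, "' in ", path,
         call. = FALSE)
  }
  data.frame(ego_id = df$ego_id, alter_id = df$alter_id,
             contact_rate_per_day = rate, stringsAsFactors = FALSE)
}

#' Write a result object to disk
#'
#' Serialises package result objects to stable plain-text formats:
#' layer fits, layer schemes and effort profiles to JSON; reach curves
#' and ensemble run tables to headed CSV.  Round-tripping reproduces
#' numeric values to at least 1e-12 (JSON is written with full
#' precision).
#'
#' @param x a `layer_fit`, `layer_scheme`, `effort_profile`,
#'   `reach_curve`, `sim_ensemble`, data frame or plain named list.
#' @param path output path.
#' @param format `"json"` or `"csv"`; the default picks the natural
#'   format for the object (CSV for tabular objects, JSON otherwise).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL) {
  tabular <- inherits(x, "reach_curve") || inherits(x, "sim_ensemble") ||
    (is.data.frame(x) && !inherits(x, "layer_fit"))
  if (is.null(format)) format <- if (tabular) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  obj <- serialize_result(x)
  if (format == "csv") {
    if (!is.data.frame(obj)) {
      stop("object of class ", paste(class(x), collapse = "/"),
           " has no CSV representation; use format = \"json\"",
           call. = FALSE)
    }
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

serialize_result <- function(x) {
  if (inherits(x, "layer_fit")) {
    out <- list(k = x$k, breaks = x$breaks,
                within_class_ssd = x$within_class_ssd,
                class_sizes = x$class_sizes)
    if (!is.null(x$cumulative_sizes)) {
      out$cumulative_sizes <- x$cumulative_sizes
      out$mean_scaling_ratio <- x$mean_scaling_ratio
    }
    if (!is.null(x$selection_scores)) {
      out$selection_scores <- as.list(x$selection_scores)
    }
    return(out)
  }
  if (inherits(x, "layer_scheme")) {
    return(list(cumulative_sizes = x$cumulative_sizes, label = x$label))
  }
  if (inherits(x, "effort_profile")) {
    return(list(annulus_shares = x$annulus_shares))
  }
  if (inherits(x, "sim_ensemble")) return(x$runs)
  if (inherits(x, "reach_curve")) return(as.data.frame(x))
  x
}

#' Read a layer fit back from JSON
#'
#' Inverse of [write_report()] for layer-detection results.
#'
#' @param path path to a JSON file written by [write_report()].
#' @return a named list with the stored fields (`k`, `breaks`,
#'   `cumulative_sizes`, ...).
#' @export
read_layers_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
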