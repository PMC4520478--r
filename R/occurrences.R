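HABITAT_LEVELS <- c("surface", "transitional", "subterranean", "unknown")
GEOLOGY_LEVELS <- c("flysch", "limestone", "unknown")

#' Build and validate an occurrence table
#'
#' The central record container: one row per (locality, species) presence with
#' planar km coordinates and two categorical attributes, the habitat type
#' along the epi-hypogean gradient (\code{surface} streams and reservoirs,
#' \code{transitional} springs and sinks, \code{subterranean} caves and
#' tunnels) and the geological basement (\code{flysch} or \code{limestone}).
#'
#' @param df A data.frame with columns \code{locality_id}, \code{species},
#'   \code{x}, \code{y} and optionally \code{habitat} and \code{geology}
#'   (missing columns are filled with \code{"unknown"}).
#' @return A validated data.frame of class \code{occurrence_table}.
#' @export
occurrence_table <- function(df) {
  need <- c("locality_id", "species", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"habitat" %in% names(df)) df$habitat <- "unknown"
  if (!"geology" %in% names(df)) df$geology <- "unknown"
  df <- df[, c(need, "habitat", "geology")]
  df$locality_id <- as.character(df$locality_id)
  df$species <- as.character(df$species)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$habitat <- as.character(df$habitat)
  df$geology <- as.character(df$geology)

  bad <- which(!nzchar(df$locality_id) | is.na(df$locality_id))
  if (length(bad))
    stop("empty locality_id at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("non-finite coordinates at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!(df$habitat %in% HABITAT_LEVELS))
  if (length(bad))
    stop(sprintf("invalid habitat value(s) at row(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(HABITAT_LEVELS, collapse = ", ")),
         call. = FALSE)
  bad <- which(!(df$geology %in% GEOLOGY_LEVELS))
  if (length(bad))
    stop(sprintf("invalid geology value(s) at row(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(GEOLOGY_LEVELS, collapse = ", ")),
         call. = FALSE)
  key <- paste(df$locality_id, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop("duplicate (locality_id, species) pair(s) at row(s) ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read / write occurrence records as CSV
#'
#' @param path CSV file with a header; see \code{\link{occurrence_table}} for
#'   the column contract. \code{col_map} allows reading files whose columns
#'   are named differently (a named character vector, e.g.
#'   \code{c(locality_id = "site", species = "taxon")}).
#' @param col_map Optional mapping from the canonical column names to the
#'   names used in the file.
#' @return An \code{occurrence_table}.
#' @export
read_occurrences <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      have <- col_map[[canon]]
      if (!have %in% names(df))
        stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                     have, canon, path), call. = FALSE)
      names(df)[names(df) == have] <- canon
    }
  }
  occurrence_table(df)
}

#' @rdname read_occurrences
#' @param occ An \code{occurrence_table}.
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_table"))
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("<occurrence_table> %d records, %d species, %d localities\n",
              nrow(x), length(unique(x$species)), length(unique(x$locality_id))))
  NextMethod()
}
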