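#' Construct a microbe-drug association dataset
#'
#' Builds the binary adjacency matrix \code{S} (drugs on rows, microbes on
#' columns) from a two-column table of known associations. Identifier order
#' is lexicographic unless explicit orderings are supplied, so repeated loads
#' of the same pair set give byte-identical matrices.
#'
#' @param pairs data.frame with columns \code{drug} and \code{microbe}
#'   (character). Duplicate pairs are collapsed.
#' @param drug_ids,microbe_ids optional explicit row/column orderings; must
#'   cover every identifier appearing in \code{pairs}.
#' @return An object of class \code{mda_dataset}: list with \code{drug_ids},
#'   \code{microbe_ids} and binary matrix \code{S} (\code{Nr x Nm}, dimnames
#'   set).
#' @export
mda_dataset <- function(pairs, drug_ids = NULL, microbe_ids = NULL) {
  if (!is.data.frame(pairs) || !all(c("drug", "microbe") %in% names(pairs))) {
    stop_mdassoc("`pairs` must be a data.frame with columns drug, microbe",
                 "mdassoc_validation_error")
  }
  pairs$drug <- as.character(pairs$drug)
  pairs$microbe <- as.character(pairs$microbe)
  if (anyNA(pairs$drug) || anyNA(pairs$microbe) ||
      any(!nzchar(pairs$drug)) || any(!nzchar(pairs$microbe))) {
    stop_mdassoc("association pairs contain empty or missing identifiers",
                 "mdassoc_validation_error")
  }
  n_raw <- nrow(pairs)
  pairs <- unique(pairs[, c("drug", "microbe")])
  n_dup <- n_raw - nrow(pairs)
  if (n_dup > 0) msg_info("collapsed ", n_dup, " duplicate association pair(s)")

  if (is.null(drug_ids)) drug_ids <- sort(unique(pairs$drug))
  if (is.null(microbe_ids)) microbe_ids <- sort(unique(pairs$microbe))
  if (anyDuplicated(drug_ids) || anyDuplicated(microbe_ids)) {
    stop_mdassoc("drug_ids / microbe_ids must not contain duplicates",
                 "mdassoc_validation_error")
  }
  miss_d <- setdiff(unique(pairs$drug), drug_ids)
  miss_m <- setdiff(unique(pairs$microbe), microbe_ids)
  if (length(miss_d) || length(miss_m)) {
    stop_mdassoc(paste0("identifiers in pairs missing from supplied order: ",
                        paste(c(miss_d, miss_m), collapse = ", ")),
                 "mdassoc_validation_error")
  }

  S <- matrix(0, length(drug_ids), length(microbe_ids),
              dimnames = list(drug_ids, microbe_ids))
  S[cbind(match(pairs$drug, drug_ids), match(pairs$microbe, microbe_ids))] <- 1
  structure(list(drug_ids = drug_ids, microbe_ids = microbe_ids, S = S),
            class = "mda_dataset")
}

#' @export
print.mda_dataset <- function(x, ...) {
  cat("<mda_dataset> ", length(x$drug_ids), " drugs x ",
      length(x$microbe_ids), " microbes, ",
      sum(x$S), " known associations\n", sep = "")
  invisible(x)
}

#' Load an association list from a delimited file
#'
#' Reads a two-column (drug, microbe) TSV or CSV, deduplicates pairs and
#' builds the adjacency matrix. Counts of drugs, microbes and associations
#' are reported on load.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"csv"}; default guessed from the file
#'   extension.
#' @param header logical; whether the first row is a header. Default
#'   \code{TRUE} if the first row does not recur elsewhere as data is not
#'   guessed -- pass explicitly for headerless files.
#' @inheritParams mda_dataset
#' @return \code{mda_dataset}.
#' @export
load_associations <- function(path, format = c("auto", "tsv", "csv"),
                              header = TRUE,
                              drug_ids = NULL, microbe_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_mdassoc(paste0("association file not found: ", path), "mdassoc_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || (header && length(lines) == 1L)) {
    stop_mdassoc(paste0("association file is empty: ", path), "mdassoc_io_error")
  }
  body <- if (header) lines[-1L] else lines
  body_offset <- if (header) 1L else 0L
  fields <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop_mdassoc(paste0("malformed association row at line ",
                        bad[1L] + body_offset, " of ", path,
                        " (expected 2 ", format, " fields, got ", nf[bad[1L]], ")"),
                 "mdassoc_io_error")
  }
  pairs <- data.frame(
    drug    = trimws(vapply(fields, `[[`, "", 1L)),
    microbe = trimws(vapply(fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  empty <- which(!nzchar(pairs$drug) | !nzchar(pairs$microbe))
  if (length(empty)) {
    stop_mdassoc(paste0("empty identifier at line ", empty[1L] + body_offset,
                        " of ", path), "mdassoc_io_error")
  }
  ds <- mda_dataset(pairs, drug_ids = drug_ids, microbe_ids = microbe_ids)
  msg_info("loaded ", length(ds$drug_ids), " drugs, ",
           length(ds$microbe_ids), " microbes, ",
           sum(ds$S), " associations from ", path)
  ds
}

#' Write an association dataset back to disk
#'
#' @param dataset \code{mda_dataset}.
#' @param path output file path.
#' @param format \code{"tsv"} (pair list) or \code{"csv"} (pair list with
#'   comma separator) or \code{"dense"} (labeled dense adjacency CSV).
#' @param header write a header row (pair-list formats).
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(dataset, path, format = c("tsv", "csv", "dense"),
                               header = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "mda_dataset"))
  if (format == "dense") {
    utils::write.csv(dataset$S, path, row.names = TRUE)
    return(invisible(path))
  }
  idx <- which(dataset$S == 1, arr.ind = TRUE)
  pairs <- data.frame(drug = dataset$drug_ids[idx[, 1]],
                      microbe = dataset$microbe_ids[idx[, 2]])
  pairs <- pairs[order(pairs$drug, pairs$microbe), ]
  utils::write.table(pairs, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, col.names = header, quote = FALSE)
  invisible(path)
}

#' Load a precomputed similarity matrix
#'
#' Reads a labeled square CSV (first column and header are identifiers),
#' reorders it to the dataset's identifier order, symmetrizes as
#' \code{(A + t(A))/2} when asymmetric beyond 1e-8, and clips values into
#' [0, 1]. Intended for externally computed drug structural or microbe
#' functional similarities.
#'
#' @param path labeled square CSV.
#' @param entity \code{"drug"} or \code{"microbe"}.
#' @param measure \code{"structural"} or \code{"functional"}.
#' @param ids ordered identifier vector the matrix must cover.
#' @return \code{mda_similarity} (see [similarity_matrix()]).
#' @export
load_similarity <- function(path, entity = c("drug", "microbe"),
                            measure = c("structural", "functional"), ids) {
  entity <- match.arg(entity)
  measure <- match.arg(measure)
  if (!file.exists(path)) {
    stop_mdassoc(paste0("similarity file not found: ", path), "mdassoc_io_error")
  }
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw, is.numeric, logical(1)))
    stop_mdassoc(paste0("non-numeric similarity column(s): ",
                        paste(names(raw)[bad], collapse = ", ")),
                 "mdassoc_io_error")
  }
  missing <- setdiff(ids, intersect(rownames(m), colnames(m)))
  if (length(missing)) {
    stop_mdassoc(paste0("similarity matrix missing identifier(s): ",
                        paste(missing, collapse = ", ")),
                 "mdassoc_validation_error")
  }
  m <- m[ids, ids, drop = FALSE]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    msg_info("symmetrizing ", entity, " ", measure,
             " similarity (max asymmetry ", signif(asym, 3), ")")
    m <- (m + t(m)) / 2
  }
  n_clip <- sum(m < 0 | m > 1)
  if (n_clip > 0) {
    msg_info("clipped ", n_clip, " similarity value(s) into [0, 1]")
    m[m < 0] <- 0
    m[m > 1] <- 1
  }
  similarity_matrix(m, entity = entity, measure = measure)
}
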