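## Plain-text serialization layer.
##
## Epoched recordings and pattern sets are stored as a directory of TSV
## matrices plus a JSON metadata file carrying a schema_version; RDMs as CSV
## with a condition_id header and NaN diagonal.  Text containers keep every
## artifact diffable and readable without special tooling; round trips are
## lossless for labels/metadata and within double-precision printing for
## data.

nf_schema_version <- "1.0"

#' Write / read an epoched recording
#'
#' The on-disk layout is a directory with `meta.json` (sfreq,
#' participant_id, modality, time axis, schema_version), `channels.tsv`,
#' `labels.tsv` and `data.tsv` (one row per trial x channel, columns
#' `trial`, `channel`, then one column per timepoint).
#'
#' @param x An [epoched_recording()].
#' @param path Directory to create/overwrite.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   `epoched_recording`.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoched_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = nf_schema_version, sfreq = x$sfreq,
               participant_id = x$participant_id, modality = x$modality,
               time_ms = x$time_ms, dims = dim(x$data))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(x$channels, file.path(path, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$labels, file.path(path, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  tab <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                    channel = rep(seq_len(d[2]), times = d[1]))
  tab <- cbind(tab, as.data.frame(flat))
  names(tab)[-(1:2)] <- sprintf("t%d", seq_len(d[3]))
  utils::write.table(format(tab, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(path, "data.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  need <- c("meta.json", "channels.tsv", "labels.tsv", "data.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("epoch container at ", path, " is missing: ",
         paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$schema_version, nf_schema_version)) {
    stop("schema_version mismatch: found ", meta$schema_version,
         ", expected ", nf_schema_version)
  }
  channels <- utils::read.delim(file.path(path, "channels.tsv"),
                                stringsAsFactors = FALSE)
  labels <- utils::read.delim(file.path(path, "labels.tsv"),
                              stringsAsFactors = FALSE)
  tab <- utils::read.delim(file.path(path, "data.tsv"))
  d <- as.integer(meta$dims)
  if (nrow(tab) != d[1] * d[2] || ncol(tab) != d[3] + 2) {
    stop("data.tsv shape inconsistent with meta.json dims (",
         paste(d, collapse = " x "), ")")
  }
  flat <- as.matrix(tab[, -(1:2), drop = FALSE])
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  epoched_recording(data, as.numeric(meta$time_ms), as.numeric(meta$sfreq), channels,
                    labels, meta$participant_id, meta$modality)
}

#' Write / read an RDM as CSV
#'
#' One header row of condition ids, one data row per condition; the diagonal
#' is stored as `NaN`.  On read the matrix is validated: asymmetry beyond
#' `1e-9` is rejected.
#'
#' @param x An [rdm()].
#' @param path CSV file path.
#' @return `write_rdm` returns `path` invisibly; `read_rdm` an `rdm`.
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  m <- unclass(x)
  colnames(m) <- attr(x, "condition_order")
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab)
  ord <- suppressWarnings(as.integer(colnames(m)))
  if (anyNA(ord)) ord <- colnames(m)
  dimnames(m) <- NULL
  offd <- abs(m - t(m))
  if (any(offd[is.finite(offd)] > 1e-9)) {
    stop("RDM in ", path, " is asymmetric beyond 1e-9")
  }
  rdm((m + t(m)) / 2, ord)
}

#' Write / read an fMRI-style pattern set
#'
#' Directory layout: `meta.json` (roi, participant_id, schema_version),
#' `labels.tsv`, `betas.tsv`.
#'
#' @param x A [pattern_set()].
#' @param path Directory.
#' @return `write_patterns` returns `path` invisibly; `read_patterns` a
#'   `pattern_set`.
#' @export
write_patterns <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(schema_version = nf_schema_version, roi = x$roi,
                            participant_id = x$participant_id,
                            dims = dim(x$betas)),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(x$labels, file.path(path, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(format(as.data.frame(x$betas), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     file.path(path, "betas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$schema_version, nf_schema_version)) {
    stop("schema_version mismatch in ", path)
  }
  labels <- utils::read.delim(file.path(path, "labels.tsv"),
                              stringsAsFactors = FALSE)
  betas <- as.matrix(utils::read.delim(file.path(path, "betas.tsv")))
  dimnames(betas) <- NULL
  pattern_set(betas, labels, meta$roi, meta$participant_id)
}

#' Write a decoding result as long-format TSV with a JSON provenance sidecar
#'
#' @param result A `decoding_result`.
#' @param path TSV file path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_decoding_result <- function(result, path) {
  d <- dim(result$accuracy)
  time <- if (all(is.na(result$time_ms))) NA_real_ else result$time_ms
  tab <- expand.grid(participant = result$participant_ids,
                     category = result$categories,
                     time_ms = time, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tab$scheme <- result$scheme
  tab$accuracy <- as.vector(result$accuracy)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- list(scheme = result$scheme,
               params = result$params[setdiff(names(result$params), "")],
               n_participants = d[1], categories = result$categories)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a condition table as TSV
#' @param design A `condition_table`.
#' @param path File path.
#' @export
write_condition_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
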