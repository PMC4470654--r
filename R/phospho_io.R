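# Readers and writers for phosphosite matrices, sample labels, PPI edge
# lists, and signature reports. Protein identifiers in the matrix and the
# edge list must already share a namespace; no identifier mapping is done.

MISSING_SENTINELS <- c("", "na", "nan")

#' Construct a phosphosite quantification matrix
#'
#' Container for a sites-by-samples matrix of log10-transformed ratios.
#' Missing observations are stored as `NA`; the presence mask is derived,
#' never imputed at this stage.
#'
#' @param values Numeric matrix, sites in rows, samples in columns. `NA`
#'   marks a missing observation.
#' @param sites Data frame with columns `site_id`, `protein_id` and
#'   (optionally) `residue_position`, one row per matrix row.
#' @param samples Character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return An object of class `phospho_matrix` with elements `values`,
#'   `sites` and `samples`.
#' @export
phospho_matrix <- function(values, sites, samples = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(sites$residue_position)) {
    sites$residue_position <- sub("^.*_", "", sites$site_id)
  }
  stopifnot(nrow(sites) == nrow(values))
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(values)))
  if (length(samples) != ncol(values)) {
    stop("number of sample ids does not match number of value columns")
  }
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup)) {
    stop("duplicate site id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(sites$protein_id) | is.na(sites$protein_id))) {
    stop("every site needs a non-empty protein_id")
  }
  bad <- is.infinite(values)
  if (any(bad)) stop("non-finite values present at ", sum(bad), " cells")
  rownames(values) <- sites$site_id
  colnames(values) <- samples
  structure(
    list(values = values, sites = sites, samples = samples),
    class = "phospho_matrix"
  )
}

#' @export
print.phospho_matrix <- function(x, ...) {
  cat(sprintf(
    "phospho_matrix: %d sites x %d samples (%d proteins, %.1f%% missing)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$sites$protein_id)),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.phospho_matrix <- function(x) dim(x$values)

#' Presence mask of a phosphosite matrix
#'
#' @param mat A [phospho_matrix()].
#' @return Logical sites-by-samples matrix, `TRUE` where a value was
#'   observed.
#' @export
presence_mask <- function(mat) !is.na(mat$values)

parse_numeric_cells <- function(chr, path) {
  chr_trim <- trimws(chr)
  missing <- tolower(chr_trim) %in% MISSING_SENTINELS | is.na(chr_trim)
  out <- suppressWarnings(as.numeric(chr_trim))
  bad <- which(!missing & is.na(out))
  if (length(bad)) {
    i <- bad[1]
    rc <- arrayInd(i, dim(chr))
    stop(sprintf(
      "non-numeric cell '%s' at data row %d, sample column %d in %s",
      chr[i], rc[1], rc[2], path
    ))
  }
  out[missing] <- NA_real_
  matrix(out, nrow = nrow(chr), ncol = ncol(chr))
}

#' Read a phosphosite matrix from delimited text
#'
#' Expects a header row, one row per site and one column per sample.
#' Empty cells and the sentinels `"NA"`/`"NaN"` (case-insensitive) become
#' missing values; any other non-numeric cell is an error.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param site_col,protein_col Column names or indices holding the site and
#'   protein identifiers.
#' @param sample_cols Columns holding sample values; defaults to every
#'   column not used as an identifier.
#' @param sep Field separator; guessed from the file extension by default.
#' @param transpose If `TRUE` the file stores samples in rows and sites in
#'   columns and is transposed after reading.
#' @return A [phospho_matrix()].
#' @export
read_phospho_matrix <- function(path, site_col = 1L, protein_col = 2L,
                                sample_cols = NULL, sep = NULL,
                                transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (transpose) {
    # samples-in-rows layout: first column holds sample ids
    sample_ids <- df[[1]]
    site_ids <- colnames(df)[-1]
    vals <- parse_numeric_cells(t(as.matrix(df[, -1, drop = FALSE])), path)
    sites <- data.frame(site_id = site_ids,
                        protein_id = sub("[-_].*$", "", site_ids),
                        stringsAsFactors = FALSE)
    return(phospho_matrix(vals, sites, sample_ids))
  }
  col_idx <- function(x) if (is.character(x)) match(x, colnames(df)) else as.integer(x)
  si <- col_idx(site_col); pi <- col_idx(protein_col)
  if (is.na(si) || is.na(pi)) stop("site/protein column not found in header")
  if (is.null(sample_cols)) {
    sample_cols <- setdiff(seq_along(df), c(si, pi))
  } else {
    sample_cols <- vapply(sample_cols, col_idx, integer(1))
  }
  vals <- parse_numeric_cells(as.matrix(df[, sample_cols, drop = FALSE]), path)
  sites <- data.frame(site_id = df[[si]], protein_id = df[[pi]],
                      stringsAsFactors = FALSE)
  phospho_matrix(vals, sites, colnames(df)[sample_cols])
}

#' Write a phosphosite matrix as TSV
#'
#' Missing values are written as empty cells, so a write/read cycle is the
#' identity on values and presence mask.
#'
#' @param mat A [phospho_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phospho_matrix <- function(mat, path) {
  df <- data.frame(site_id = mat$sites$site_id,
                   protein_id = mat$sites$protein_id,
                   mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("site_id", "protein_id", mat$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample response labels
#'
#' Two-column delimited file: sample id and label. Labels may be coded
#' `sensitive`/`resistant` (case-insensitive) or `1`/`-1`.
#'
#' @param path Path to the label file.
#' @return Named integer vector with values `+1` (sensitive) and `-1`
#'   (resistant).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "",
                          colClasses = "character")
  if (tolower(df[1, 2]) %in% c("label", "class", "response")) df <- df[-1, , drop = FALSE]
  lab <- tolower(trimws(df[[2]]))
  out <- ifelse(lab %in% c("sensitive", "1", "+1"), 1L,
         ifelse(lab %in% c("resistant", "-1"), -1L, NA_integer_))
  if (anyNA(out)) stop("unrecognized label(s): ",
                       paste(unique(df[[2]][is.na(out)]), collapse = ", "))
  names(out) <- trimws(df[[1]])
  if (anyDuplicated(names(out))) stop("duplicate sample id in label file")
  check_labels(out)
  out
}

check_labels <- function(labels) {
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be coded +1/-1")
  if (!all(c(-1L, 1L) %in% labels)) stop("both classes must be non-empty")
  invisible(labels)
}

#' Write per-sample response labels
#' @param labels Named vector of `+1`/`-1` labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample = names(labels),
                   label = ifelse(labels > 0, "sensitive", "resistant"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Three whitespace- or tab-delimited columns: protein A, protein B,
#' confidence. The STRING `protein.links` dialect stores confidences as
#' integers on a 0-999 scale; pass `score_scale = "string_0_999"` to divide
#' by 1000. Self-loops are dropped and duplicate undirected edges collapse
#' to the maximum confidence.
#'
#' @param path Path to the edge-list file.
#' @param score_scale Either `"unit"` (confidences already in \[0,1\]) or
#'   `"string_0_999"`.
#' @return Data frame of class `ppi_edges` with columns `protein_a`,
#'   `protein_b`, `confidence`.
#' @export
read_ppi_edges <- function(path, score_scale = c("unit", "string_0_999")) {
  score_scale <- match.arg(score_scale)
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "",
                          colClasses = "character")
  if (ncol(df) < 3) stop("edge list needs three columns")
  # tolerate a STRING-style header line
  if (is.na(suppressWarnings(as.numeric(df[1, 3])))) df <- df[-1, , drop = FALSE]
  s <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(s)) stop("non-numeric confidence at line ", which(is.na(s))[1])
  if (score_scale == "string_0_999") {
    if (any(s < 0 | s > 999)) stop("confidence outside 0-999 scale")
    s <- s / 1000
  } else if (any(s < 0 | s > 1)) {
    stop("confidence outside [0,1]; did you mean score_scale='string_0_999'?")
  }
  ppi_edges(df[[1]], df[[2]], s)
}

#' Construct a PPI edge list
#'
#' @param protein_a,protein_b Character vectors of interactor identifiers.
#' @param confidence Numeric confidences in \[0,1\].
#' @return Data frame of class `ppi_edges`; self-loops removed, duplicate
#'   undirected edges collapsed to the maximum confidence.
#' @export
ppi_edges <- function(protein_a, protein_b, confidence) {
  stopifnot(all(confidence >= 0 & confidence <= 1))
  keep <- protein_a != protein_b
  a <- pmin(protein_a[keep], protein_b[keep])
  b <- pmax(protein_a[keep], protein_b[keep])
  s <- confidence[keep]
  key <- paste(a, b, sep = "\r")
  best <- tapply(s, key, max)
  ord <- order(names(best))
  ab <- do.call(rbind, strsplit(names(best)[ord], "\r", fixed = TRUE))
  out <- data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
                    confidence = as.numeric(best[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ppi_edges", "data.frame")
  out
}

#' Write a PPI edge list as TSV
#' @param edges A `ppi_edges` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Report matrix proteins absent from the PPI network
#'
#' The matrix and edge list must share an identifier namespace; this
#' diagnostic lists the proteins that failed to join.
#'
#' @param mat A [phospho_matrix()].
#' @param edges A `ppi_edges` data frame.
#' @return Character vector of matrix protein ids absent from the edge list.
#' @export
join_failure_report <- function(mat, edges) {
  setdiff(unique(mat$sites$protein_id),
          unique(c(edges$protein_a, edges$protein_b)))
}

#' Write the signature report of a pipeline run
#'
#' Emits `solutions.tsv` (one row per filtered front solution: member
#' sites, objective scores, cluster and representative flag),
#' `predictions.tsv` when a validation set was scored, a generation log,
#' and `report.json` holding the same content in structured form.
#'
#' @param result A `pareto_result` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_signature_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create report directory: ", dir)
  sol <- result$solutions
  if (is.null(sol) || nrow(sol) == 0) {
    warning("empty Pareto front: writing report with zero solution rows")
    sol <- data.frame(solution = integer(), sites = character(),
                      size = integer(), separation = double(),
                      relevance = double(), cluster = integer(),
                      representative = logical())
  }
  files <- file.path(dir, "solutions.tsv")
  utils::write.table(sol, files[1], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$fallback_distance <- if (is.null(cfg$fallback_distance)) "auto" else cfg$fallback_distance
  json <- list(solutions = sol, config = cfg,
               candidates = result$candidates$site_id,
               generations = result$ga$generations)
  if (!is.null(result$validation)) {
    pred <- result$validation
    f <- file.path(dir, "predictions.tsv")
    utils::write.table(pred$per_sample, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    json$validation <- list(per_sample = pred$per_sample,
                            summary = pred$summary)
  }
  if (!is.null(result$ga$log)) {
    f <- file.path(dir, "generations.tsv")
    utils::write.table(result$ga$log, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "report.json")
  jsonlite::write_json(json, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
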