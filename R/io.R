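#' Read a genotype matrix from file
#'
#' Matrix Market coordinate files (\code{.mtx}, the primary exchange format:
#' natively sparse and language-neutral, 1-based indices in the external
#' representation) load as sparse; delimited text loads dense and is
#' sparsified. Values must be non-negative integers; the coding is inferred
#' (\code{"binary"} iff every value is 0/1) unless overridden, and a forced
#' coding that the values violate is an error.
#'
#' Orientation is loci-by-individuals (rows are variants). A transposed file
#' is read without complaint but silently computes locus-locus similarity
#' downstream.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension), \code{"mtx"}, or \code{"tsv"}
#'   (any whitespace-delimited dense text).
#' @param coding optional coding override, validated against the values.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genotype_matrix <- function(path, format = c("auto", "mtx", "tsv"),
                                 coding = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  V <- if (format == "mtx") {
    tryCatch(Matrix::readMM(path),
             error = function(e) stop("malformed Matrix Market file '", path,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  genotype_matrix(V, coding = coding)
}

#' Write a genotype matrix to Matrix Market coordinate format
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output path (conventionally \code{.mtx}).
#' @return the path, invisibly.
#' @export
write_genotype_matrix <- function(G, path) {
  G <- as_genotype_matrix(G)
  Matrix::writeMM(G$values, path)
  invisible(path)
}

#' Write a dense similarity matrix as TSV
#'
#' Header row holds 1-based sample indices; 10 significant digits.
#'
#' @param S symmetric matrix (output of the reference similarities).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_similarity_matrix <- function(S, path) {
  S <- as.matrix(S)
  m <- ncol(S)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(paste0("s", seq_len(m)), collapse = "\t"), con)
  utils::write.table(format(S, digits = 10, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write eigenvectors with a provenance sidecar
#'
#' TSV with header \code{sample, PC1..PCk}, one row per individual, floats at
#' 10 significant digits. A JSON sidecar (\code{<path>.json}) records the
#' eigenvalues and the full randomized-SVD provenance (\code{k}, \code{q},
#' \code{seed}, \code{method}) so any run can be replayed exactly.
#'
#' @param result an \code{eigen_result} from \code{\link{fast_eigenvectors}}
#'   or \code{\link{randomized_svd}}.
#' @param path output TSV path.
#' @param labels optional length-\eqn{m} sample labels (default
#'   \code{sample1..sampleM}).
#' @return the path, invisibly; the sidecar lands at \code{paste0(path, ".json")}.
#' @export
write_eigenvectors <- function(result, path, labels = NULL) {
  U <- result$vectors
  m <- nrow(U)
  k <- ncol(U)
  if (is.null(labels)) labels <- paste0("sample", seq_len(m))
  if (length(labels) != m) stop("labels must have length ", m, call. = FALSE)
  df <- data.frame(sample = as.character(labels),
                   matrix(formatC(U, digits = 10, format = "g"), m, k),
                   check.names = FALSE)
  names(df) <- c("sample", paste0("PC", seq_len(k)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(eigenvalues = as.numeric(result$values), k = result$k, q = result$q,
         seed = result$seed, method = result$method,
         degenerate = isTRUE(result$degenerate)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read eigenvectors written by \code{write_eigenvectors}
#'
#' @param path TSV path.
#' @return list with \code{vectors} (numeric matrix), \code{labels}, and
#'   \code{sidecar} (parsed JSON, or NULL if absent).
#' @export
read_eigenvectors <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  side <- paste0(path, ".json")
  list(vectors = as.matrix(df[, -1, drop = FALSE]),
       labels = df[[1]],
       sidecar = if (file.exists(side)) jsonlite::read_json(side,
                                                            simplifyVector = TRUE)
                 else NULL)
}

#' Run-configuration round trip
#'
#' Flat named lists of subcommand parameters (matrix kind, k, q, seed, norm,
#' gap method, paths, weighted-Jaccard count basis, log level) are stored as
#' YAML or JSON by extension. Reading then writing reproduces the
#' configuration losslessly.
#'
#' @param config named list of scalar parameters.
#' @param path destination (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{write_run_config}: the path, invisibly;
#'   \code{read_run_config}: the named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    writeLines(yaml::as.yaml(config), path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @param path config file to read.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
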