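#' Model container serialization
#'
#' Writes a fitted model to a single JSON container holding the
#' parameter matrices, the prior vector and a metadata record
#' (dimensions, optional creation seed, format version).  Numbers are
#' serialized at full precision, so write-read round-trips are
#' bit-exact.
#'
#' @param model a [beta_mca()], [beta_mca_scalar()] or
#'   [noisyor_params()] object.
#' @param path output file path.
#' @param seed optional creation seed stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NULL) {
  # doubles are stored as %.17g strings: 17 significant digits
  # round-trip IEEE doubles exactly, making containers bit-exact
  num <- function(x) {
    if (is.matrix(x)) {
      list(dim = dim(x), values = sprintf("%.17g", x))
    } else {
      list(dim = length(x), values = sprintf("%.17g", x))
    }
  }
  if (inherits(model, "beta_mca_scalar")) {
    payload <- list(type = "beta_mca_scalar", M = num(model$M),
                    sigma2 = num(model$sigma2), pi = num(model$pi))
  } else if (inherits(model, "beta_mca")) {
    payload <- list(type = "beta_mca", W = num(model$W),
                    V = num(model$V), pi = num(model$pi))
  } else if (inherits(model, "noisyor")) {
    payload <- list(type = "noisyor", priors = num(model$priors),
                    weights = num(model$weights), leak = num(model$leak))
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  obj <- c(list(format = "betamca-model", version = 1L,
                D = model$D, H = model$H,
                seed = if (is.null(seed)) NA else seed),
           payload)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()`: the reconstructed model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- function(f) {
    if (is.null(obj[[f]])) {
      stop(sprintf("model container is missing field '%s'", f),
           call. = FALSE)
    }
    obj[[f]]
  }
  if (!identical(need("format"), "betamca-model")) {
    stop("not a betamca model container", call. = FALSE)
  }
  den <- function(f) {
    fld <- need(f)
    vals <- as.numeric(fld$values)
    if (length(fld$dim) == 2) matrix(vals, fld$dim[1], fld$dim[2])
    else vals
  }
  type <- need("type")
  if (type == "beta_mca") {
    beta_mca(den("W"), den("V"), den("pi"))
  } else if (type == "beta_mca_scalar") {
    beta_mca_scalar(den("M"), den("sigma2"), den("pi"))
  } else if (type == "noisyor") {
    noisyor_params(den("priors"), den("weights"), den("leak"))
  } else {
    stop(sprintf("unknown model type '%s'", type), call. = FALSE)
  }
}

#' Dataset CSV helpers
#'
#' Datasets are plain comma-separated files with a one-line header
#' `y1,...,yD` (plus `s0,...,sH` columns when latent states are
#' included), `.` decimal marks, UTF-8.
#'
#' @param Y `N x D` data matrix.
#' @param path file path.
#' @param S optional `N x (H+1)` latent state matrix to store
#'   alongside.
#' @return `path` invisibly; `read_dataset_csv()` returns a list with
#'   `Y` and (if present) `S`.
#' @export
write_dataset_csv <- function(Y, path, S = NULL) {
  Y <- rbind(Y)
  df <- as.data.frame(Y)
  names(df) <- paste0("y", seq_len(ncol(Y)))
  if (!is.null(S)) {
    S <- rbind(S)
    dfs <- as.data.frame(S)
    names(dfs) <- paste0("s", seq_len(ncol(S)) - 1L)
    df <- cbind(df, dfs)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  ycols <- grep("^y[0-9]+$", names(df))
  scols <- grep("^s[0-9]+$", names(df))
  if (length(ycols) == 0) {
    stop("no y columns found in dataset CSV", call. = FALSE)
  }
  out <- list(Y = as.matrix(df[, ycols, drop = FALSE]))
  if (length(scols) > 0) {
    out$S <- as.matrix(df[, scols, drop = FALSE])
  }
  out
}

#' Grayscale PGM image IO
#'
#' Reads the plain (`P2`) and raw (`P5`) 8-bit netpbm grayscale
#' formats and writes plain `P2`; intensities map linearly to
#' \[0, 1\].
#'
#' @param path file path.
#' @return `read_pgm()`: numeric matrix in \[0,1\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) {
    stop("not an 8-bit grayscale PGM file", call. = FALSE)
  }
  tokens <- character(0)
  while (length(tokens) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "[[:space:]]+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  nc <- as.integer(tokens[1])
  nr <- as.integer(tokens[2])
  maxv <- as.integer(tokens[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", nr * nc))
  } else {
    vals <- scan(con, what = integer(), n = nr * nc, quiet = TRUE)
  }
  matrix(vals, nr, nc, byrow = TRUE) / maxv
}

#' @rdname read_pgm
#' @param img matrix with values in \[0,1\].
#' @export
write_pgm <- function(img, path) {
  vals <- round(pmin(pmax(img, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"),
             con)
  apply(vals, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Grayscale PNG image IO
#'
#' Thin wrappers over the `png` package (color images are averaged to
#' grayscale on read).
#'
#' @param path file path.
#' @return `read_gray_png()`: numeric matrix in \[0,1\].
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG IO", call. = FALSE)
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE],
               c(1, 2), mean)
  }
  a
}

#' @rdname read_gray_png
#' @param img matrix with values in \[0,1\].
#' @export
write_gray_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG IO", call. = FALSE)
  }
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' ROC curve CSV export
#'
#' @param roc a [roc_auc()] result.
#' @param path output path; columns `fpr`, `tpr`, `threshold`.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(
    roc$curve[, c("fpr", "tpr", "threshold")], path, row.names = FALSE)
  invisible(path)
}
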