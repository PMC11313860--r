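#' Read a gene-by-cell count matrix
#'
#' Accepts either a 10x-style MatrixMarket directory — `matrix.mtx[.gz]`
#' plus `features.tsv[.gz]` (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`,
#' with 1-based coordinate indices — or a dense TSV/CSV file with gene rows
#' and a header of cell barcodes. Gzipped variants are read transparently.
#'
#' @param path Directory (MTX triplet) or file (TSV/CSV).
#' @return Integer matrix with gene rownames and barcode colnames.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) return(read_mtx_dir(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, comment = "#")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

find_10x_file <- function(dir, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(s, ext))
    if (file.exists(f)) return(f)
  }
  stop("missing ", stems[1], "[.gz] in ", dir, call. = FALSE)
}

read_mtx_dir <- function(dir) {
  fm <- find_10x_file(dir, "matrix.mtx")
  ff <- find_10x_file(dir, c("features.tsv", "genes.tsv"))
  fb <- find_10x_file(dir, "barcodes.tsv")
  open_maybe_gz <- function(f) if (endsWith(f, ".gz")) gzfile(f) else file(f)
  M <- tryCatch(Matrix::readMM(open_maybe_gz(fm)),
                error = function(e)
                  stop("malformed MatrixMarket file ", fm, ": ",
                       conditionMessage(e), call. = FALSE))
  feats <- readr::read_tsv(ff, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  bcs <- readr::read_tsv(fb, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(feats) != nrow(M))
    stop("feature count mismatch with matrix dims in ", ff, call. = FALSE)
  if (nrow(bcs) != ncol(M))
    stop("barcode count mismatch with matrix dims in ", fb, call. = FALSE)
  m <- as.matrix(M)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(as.character(feats[[1]]), as.character(bcs[[1]]))
  m
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts Integer gene-by-cell matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param gzip Write gzipped files (default `FALSE` for diff-friendliness).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  fm <- file.path(dir, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(sp, tmp)
    con <- gzfile(fm, "wb")
    writeLines(readLines(tmp), con)
    close(con)
    unlink(tmp)
  } else {
    Matrix::writeMM(sp, fm)
  }
  readr::write_tsv(tibble::tibble(id = rownames(counts),
                                  name = rownames(counts),
                                  type = "Gene Expression"),
                   file.path(dir, paste0("features.tsv", ext)),
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(counts)),
                   file.path(dir, paste0("barcodes.tsv", ext)),
                   col_names = FALSE)
  invisible(dir)
}

#' Read smRNA-FISH spot counts
#'
#' CSV with a cell identifier column and an integer spot-count column;
#' the resulting vector feeds the same fitting pipeline as scRNA counts
#' (FISH counts are unthinned, so the inferred eject rate is on the
#' absolute scale).
#'
#' @param path CSV file.
#' @return Named integer vector of per-cell counts.
#' @export
read_fish_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse ", path, call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expected a non-empty CSV with cell and count columns",
         call. = FALSE)
  cnt <- df[[2]]
  if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    stop("spot counts must be non-negative integers", call. = FALSE)
  setNames(as.integer(cnt), as.character(df[[1]]))
}

#' Read a half-life table
#'
#' TSV with columns `gene` and `half_life_hours` (header optional when two
#' unnamed columns are supplied).
#'
#' @param path TSV file.
#' @return Tibble `gene`, `half_life_hours`.
#' @export
read_half_lives <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  if (!all(c("gene", "half_life_hours") %in% names(df))) {
    if (ncol(df) >= 2L) {
      names(df)[1:2] <- c("gene", "half_life_hours")
    } else {
      stop("expected columns gene, half_life_hours in ", path, call. = FALSE)
    }
  }
  tibble::as_tibble(df[, c("gene", "half_life_hours")])
}

# polynomial rolling hash of a configuration (31-bit), for the output-file
# provenance header; no cryptographic strength needed, just diffability
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a result table with a provenance header
#'
#' TSV with a single `#`-prefixed metadata line carrying the package
#' version, a hash of the run configuration, and the seed, so reruns are
#' diffable.
#'
#' @param tbl Data frame.
#' @param path Output file.
#' @param config Named list of run parameters (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(tbl, path, config = list()) {
  hdr <- sprintf("# burstkit %s | config %s%s",
                 as.character(utils::packageVersion("burstkit")),
                 config_hash(config),
                 if (!is.null(config$seed))
                   sprintf(" | seed %s", config$seed) else "")
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a table written by [write_result_tsv()]
#' @param path TSV file.
#' @return Tibble (the `#` header is skipped).
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
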